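#' Substrate class scheme
#'
#' The benthoscape uses five named substrate classes, coded 0 to 4, plus a
#' distinct `nodata` level for cells without substrate information. `nodata`
#' is a first-class categorical level throughout the package because
#' selection estimates are reported for unmapped areas just like for any
#' mapped substrate.
#'
#' The default reference level for all selection models is
#' `silt_mud_gravel` ("silt/mud with <= 50% gravel"), the least abundant
#' mapped class in the motivating system.
#'
#' @return A tibble with columns `code` (integer; `NA` for `nodata`),
#'   `level` (the factor level used across the package) and `name`
#'   (a human-readable label).
#' @export
#' @examples
#' substrate_classes()
substrate_classes <- function() {
  tibble::tibble(
    code = c(0L, 1L, 2L, 3L, 4L, NA),
    level = c("coarse_sediment", "silt_mud_gravel", "mixed_sediment",
              "deep_silt_mud", "shallow_silt_mud", "nodata"),
    name = c("Coarse sediments", "Silt/mud with ≤ 50% gravel",
             "Mixed sediments with a veneer of mud",
             "Deep silt/mud (> 50 m)", "Shallow silt/mud (≤ 50 m)",
             "No data")
  )
}

#' @rdname substrate_classes
#' @export
substrate_levels <- function() substrate_classes()$level

#' @rdname substrate_classes
#' @export
substrate_reference <- function() "silt_mud_gravel"

# integer codes (NA = nodata) -> factor over the full level set
substrate_factor <- function(code) {
  sc <- substrate_classes()
  lev <- sc$level[match(code, sc$code)]
  lev[is.na(code)] <- "nodata"
  factor(lev, levels = sc$level)
}

# factor/character levels -> integer codes (NA for nodata)
substrate_code <- function(level) {
  sc <- substrate_classes()
  i <- match(as.character(level), sc$level)
  if (anyNA(i)) {
    abort(paste0("unknown substrate level(s): ",
                 paste(unique(setdiff(as.character(level), sc$level)),
                       collapse = ", ")))
  }
  sc$code[i]
}
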