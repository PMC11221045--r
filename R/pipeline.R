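#' Pipeline configuration
#'
#' Collects every stage setting and per-stage seed in one list. Defaults
#' are the analysis defaults used throughout the package: 95% retention
#' candidates, final HPE cut-off 25 (strict `<`), 48-h post-release
#' removal, a 10-min sampling rate with 2-min tolerance, 10
#' pseudo-absences per presence, 100 subsample refits of 100 points per
#' individual, 100 random steps per stratum, 1000 bootstrap replicates,
#' and a 20-strata minimum per individual.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param ... Overrides of any default listed in `pipeline_defaults()`.
#' @param yaml_path Optional YAML file of overrides (applied before
#'   `...`).
#' @return A list of class `bs_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, ..., yaml_path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(yaml_path)) {
    over <- yaml::read_yaml(yaml_path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg$out_dir <- out_dir
  structure(cfg, class = "bs_pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    positions_csv = NULL,   # NULL = run the simulate stage
    raster_path = NULL,
    # simulate stage
    sim = list(n_rows = 120, n_cols = 120, cell_size = 1,
               n_individuals = 4, steps_per_individual = 400,
               shape = 1.5, scale = 3, kappa = 1,
               beta = c(mixed_sediment = 0.8, coarse_sediment = -0.4),
               n_sync = 16, sync_fixes = 150),
    # qc stage
    retain = 0.95, final_cutoff = 25, post_release_hours = 48,
    # prep stage
    rate = 600, tolerance = 120,
    # rsf stage
    ratio = 10, reruns = 100, per_individual = 100,
    # issf stage
    n_random_steps = 100, bootstrap_B = 1000, min_strata = 20,
    reference = substrate_reference(),
    seeds = list(simulate = 101, rsf = 202, issf = 303)
  )
}

#' @rdname pipeline_config
#' @param out_dir Output directory.
#' @details `demo_config()` is the bundled synthetic scenario: a 100x100 m
#'   benthoscape, four animals tracked for 100 h (so the 48-h post-release
#'   window still leaves ample data), and stage sizes reduced from the
#'   analysis defaults to keep a desk run fast. It exercises every stage
#'   end to end.
#' @export
demo_config <- function(out_dir) {
  pipeline_config(
    out_dir,
    sim = list(n_rows = 100, n_cols = 100, cell_size = 1,
               n_individuals = 4, steps_per_individual = 600,
               shape = 1.5, scale = 3, kappa = 1,
               beta = c(mixed_sediment = 0.8, coarse_sediment = -0.4),
               n_sync = 16, sync_fixes = 150),
    reruns = 30, per_individual = 60,
    n_random_steps = 30, bootstrap_B = 60
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — `simulate` (skipped when a positions CSV
#' and raster are supplied) → `qc` → `prep` → `rsf` → `issf` → `report` —
#' writing every stage's artifact (CSV/JSON) under `config$out_dir`
#' together with a manifest listing inputs, seeds, row counts and a
#' content hash of every output file. Reruns with an identical config are
#' byte-identical. A stage failure aborts with the stage name and leaves a
#' `FAILED` marker next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (a list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bs_pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), seeds = config$seeds)
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
    manifest$stages[[name]] <<- res
    res
  }

  # -- simulate ---------------------------------------------------------
  if (is.null(config$positions_csv)) {
    sim <- stage("simulate", function() {
      s <- config$sim
      sc <- sim_config(n_rows = s$n_rows, n_cols = s$n_cols,
                       cell_size = s$cell_size,
                       shape = s$shape, scale = s$scale, kappa = s$kappa,
                       seed = config$seeds$simulate)
      raster <- generate_benthoscape(sc)
      write_raster(raster, file.path(out, "benthoscape.asc"))
      seeds <- derive_seeds(config$seeds$simulate, 2 * s$n_individuals + 1)
      mid <- c(mean(range(c(raster$origin_x, raster_xmax(raster)))),
               mean(range(c(raster$origin_y, raster_ymax(raster)))))
      fixes <- purrr::map_dfr(seq_len(s$n_individuals), function(i) {
        tr <- simulate_track(raster, beta = s$beta, shape = s$shape,
                             scale = s$scale, kappa = s$kappa,
                             start = mid,
                             n_steps = s$steps_per_individual,
                             seed = seeds[[i]])
        observe_track(tr, sc, tag_id = sprintf("animal%02d", i),
                      seed = seeds[[s$n_individuals + i]])
      })
      sync <- generate_sync_tags(raster, n = s$n_sync, config = sc,
                                 n_fixes = s$sync_fixes,
                                 seed = seeds[[2 * s$n_individuals + 1]])
      all <- dplyr::bind_rows(fixes, sync)
      write_positions_csv(all, file.path(out, "positions.csv"))
      list(n_fixes = nrow(fixes), n_sync = nrow(sync),
           raster = "benthoscape.asc", positions = "positions.csv")
    })
    positions_path <- file.path(out, "positions.csv")
    raster_path <- file.path(out, "benthoscape.asc")
  } else {
    positions_path <- config$positions_csv
    raster_path <- config$raster_path
    if (is.null(raster_path) || !file.exists(raster_path)) {
      abort(paste0("raster path missing or does not exist: ",
                   raster_path %||% "<NULL>"))
    }
    if (!file.exists(positions_path)) {
      abort(paste0("positions CSV does not exist: ", positions_path))
    }
  }

  fixes <- read_positions_csv(positions_path)
  raster <- read_raster(raster_path)

  # -- qc ---------------------------------------------------------------
  qc <- stage("qc", function() {
    sync <- fixes[fixes$is_sync, , drop = FALSE]
    cand <- candidate_cutoff(sync, retain = config$retain)
    reports <- purrr::map_dfr(cand$cutoff, function(co)
      cutoff_report(sync, co))
    final <- cutoff_report(sync, config$final_cutoff, comparator = "<")
    filtered <- filter_positions(fixes, cutoff = config$final_cutoff,
                                 post_release_hours = config$post_release_hours)
    write_positions_csv(filtered, file.path(out, "filtered_positions.csv"))
    jsonlite::write_json(
      list(candidates = cand, candidate_reports = reports,
           final_cutoff = config$final_cutoff, final_report = final,
           counts = attr(filtered, "counts")),
      file.path(out, "qc_report.json"), dataframe = "rows", digits = NA)
    list(n_before = sum(!fixes$is_sync), n_after = nrow(filtered),
         candidates = cand$cutoff)
  })

  filtered <- read_positions_csv(file.path(out, "filtered_positions.csv"))

  # -- prep -------------------------------------------------------------
  prep <- stage("prep", function() {
    # observation error can push a fix outside the mapped extent
    inb <- raster_contains(raster, filtered$x, filtered$y)
    filtered <- filtered[inb, , drop = FALSE]
    bursts <- resample_fixes(filtered, rate = config$rate,
                             tolerance = config$tolerance)
    steps <- build_steps(bursts) |>
      filter_steps(require_ta = FALSE) |>
      attach_covariates(raster)
    write.csv(steps, file.path(out, "steps.csv"), row.names = FALSE)
    list(n_kept_fixes = nrow(bursts), n_steps = nrow(steps),
         n_bursts = length(unique(bursts$burst_id)))
  })

  steps <- utils::read.csv(file.path(out, "steps.csv"),
                           stringsAsFactors = FALSE)
  steps <- tibble::as_tibble(steps)
  steps$start_class <- factor(steps$start_class, levels = substrate_levels())
  steps$end_class <- factor(steps$end_class, levels = substrate_levels())

  # -- rsf --------------------------------------------------------------
  rsf_res <- stage("rsf", function() {
    pres <- tibble::tibble(tag_id = filtered$tag_id, x = filtered$x,
                           y = filtered$y)
    # clip presences to the raster extent: positional error can push an
    # observed fix slightly past the mapped area
    ok <- raster_contains(raster, pres$x, pres$y)
    pres <- pres[ok, , drop = FALSE]
    ua <- draw_pseudo_absences(pres, raster, ratio = config$ratio,
                               seed = config$seeds$rsf)
    fit <- rsf_resample_fit(ua, reruns = config$reruns,
                            per_individual = config$per_individual,
                            reference = config$reference,
                            seed = config$seeds$rsf)
    write.csv(fit$coefficients, file.path(out, "rsf_coefficients.csv"),
              row.names = FALSE)
    rss <- relative_selection_strength(fit)
    jsonlite::write_json(rss, file.path(out, "rsf_rss.json"),
                         dataframe = "rows", digits = NA)
    list(n_use_available = nrow(ua), reruns = config$reruns,
         excluded = fit$excluded)
  })

  # -- issf -------------------------------------------------------------
  issf_res <- stage("issf", function() {
    tags <- unique(steps$tag_id)
    seeds <- derive_seeds(config$seeds$issf, length(tags))
    fits <- list()
    skipped <- character(0)
    for (i in seq_along(tags)) {
      st <- steps[steps$tag_id == tags[i], , drop = FALSE]
      st <- filter_steps(st, require_ta = TRUE)
      res <- tryCatch({
        kern <- fit_tentative_kernel(st)
        strata <- draw_random_steps(st, kern, n = config$n_random_steps,
                                    raster = raster, seed = seeds[[i]])
        fit <- fit_issf(strata, B = config$bootstrap_B,
                        min_strata = config$min_strata,
                        reference = config$reference, seed = seeds[[i]])
        list(fit = fit, kernel = kern,
             updated = update_kernel(kern, fit))
      }, error = function(e) {
        inform(paste0("iSSF skipped for ", tags[i], ": ",
                      conditionMessage(e)))
        NULL
      })
      if (is.null(res)) skipped <- c(skipped, tags[i]) else
        fits[[tags[i]]] <- res
    }
    est <- purrr::imap_dfr(fits, function(f, tg)
      dplyr::mutate(f$fit$estimates, tag_id = tg, .before = 1))
    write.csv(est, file.path(out, "issf_estimates.csv"), row.names = FALSE)
    upd <- purrr::imap_dfr(fits, function(f, tg)
      dplyr::mutate(f$updated, tag_id = tg, .before = 1))
    jsonlite::write_json(upd, file.path(out, "issf_updated_kernels.json"),
                         dataframe = "rows", digits = NA)
    list(n_fitted = length(fits), skipped = skipped)
  })

  # -- report -----------------------------------------------------------
  stage("report", function() {
    r <- write_reports(out)
    list(tables = names(r))
  })

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest$outputs <- lapply(setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out, f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Assemble report tables from stage artifacts
#'
#' Reads the stage outputs under `out_dir` and writes the three
#' publication-shaped tables: an RSS boxplot table (median, quartiles and
#' whiskers per substrate class), a per-individual point-estimate + CI
#' table for the iSSF terms, and term-by-individual estimate/SD matrices
#' for the turning-angle and step-length movement models.
#'
#' @param out_dir Directory holding `rsf_coefficients.csv` and
#'   `issf_estimates.csv`.
#' @return A list of the three tibbles, invisibly; each written as CSV.
#' @export
write_reports <- function(out_dir) {
  rsf_path <- file.path(out_dir, "rsf_coefficients.csv")
  issf_path <- file.path(out_dir, "issf_estimates.csv")
  res <- list()

  if (file.exists(rsf_path)) {
    coefs <- tibble::as_tibble(utils::read.csv(rsf_path))
    res$rss_boxplot <- coefs |>
      dplyr::group_by(class = .data$term) |>
      dplyr::summarise(
        rss_median = exp(median(.data$estimate)),
        rss_q25 = exp(quantile(.data$estimate, 0.25, names = FALSE)),
        rss_q75 = exp(quantile(.data$estimate, 0.75, names = FALSE)),
        rss_lo = exp(min(.data$estimate)),
        rss_hi = exp(max(.data$estimate)),
        .groups = "drop"
      )
    write.csv(res$rss_boxplot, file.path(out_dir, "report_rss_boxplot.csv"),
              row.names = FALSE)
  }

  if (file.exists(issf_path)) {
    est <- tibble::as_tibble(utils::read.csv(issf_path))
    if (nrow(est) == 0) {
      res$note <- "zero eligible individuals for the iSSF"
      writeLines(res$note, file.path(out_dir, "report_issf_note.txt"))
    } else {
      res$issf_ci <- est |>
        dplyr::select("tag_id", "term", "estimate",
                      dplyr::starts_with("conf."))
      write.csv(res$issf_ci, file.path(out_dir, "report_issf_ci.csv"),
                row.names = FALSE)
      movement <- function(pattern) {
        est |>
          dplyr::filter(grepl(pattern, .data$term)) |>
          dplyr::mutate(start_class = sub(pattern, "",
                                          sub("^start_", "", .data$term))) |>
          dplyr::select("start_class", "tag_id",
                        estimate = "boot_mean", sd = "boot_sd") |>
          tidyr::pivot_wider(names_from = "tag_id",
                             values_from = c("estimate", "sd"))
      }
      res$turning_angle_table <- movement(":cos_ta$")
      res$step_length_table <- movement(":log_sl$")
      write.csv(res$turning_angle_table,
                file.path(out_dir, "report_turning_angle.csv"),
                row.names = FALSE)
      write.csv(res$step_length_table,
                file.path(out_dir, "report_step_length.csv"),
                row.names = FALSE)
    }
  }
  invisible(res)
}
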