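#' Continuous environmental layer stack
#'
#' A list of continuous rasters (bathymetry/backscatter derivatives) on an
#' identical grid, the input to the benthoscape classifier. Layers reuse
#' the [bentho_raster()] geometry but hold numeric matrices.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param origin_x,origin_y,cell_size Shared grid geometry.
#' @return An object of class `bs_layer_stack`.
#' @export
layer_stack <- function(layers, origin_x = 0, origin_y = 0, cell_size = 1) {
  if (length(layers) < 1 || !all(vapply(layers, is.matrix, logical(1)))) {
    abort("`layers` must be a list of matrices")
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all layers must share the same grid dimensions")
  }
  if (is.null(names(layers))) {
    names(layers) <- paste0("layer", seq_along(layers))
  }
  structure(list(layers = layers, origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size,
                 n_rows = dims[1, 1], n_cols = dims[2, 1]),
            class = "bs_layer_stack")
}

#' PCA of standardized environmental layers
#'
#' Standardizes each layer over unmasked (finite-in-all-layers) cells and
#' eigendecomposes the correlation matrix, keeping the smallest prefix of
#' components whose cumulative explained variance reaches
#' `variance_target`. Correlation-matrix PCA is used because the layers
#' (depth, backscatter, derivatives) live on incommensurate scales.
#'
#' @param stack A [layer_stack()].
#' @param variance_target Cumulative explained-variance target
#'   (default 0.95).
#' @return A list of class `bs_pca`: `scores` (cells x retained components
#'   matrix with `NA` rows for masked cells), `explained` (all fractions,
#'   summing to 1), `retained`, `mask` (logical vector of usable cells),
#'   `stack` geometry.
#' @export
pca_retain <- function(stack, variance_target = 0.95) {
  stopifnot(inherits(stack, "bs_layer_stack"))
  k <- length(stack$layers)
  if (k < 2) abort("need at least 2 layers for a PCA")
  M <- vapply(stack$layers, as.vector, numeric(stack$n_rows * stack$n_cols))
  mask <- rowSums(!is.finite(M)) == 0
  if (sum(mask) < 10) abort("fewer than 10 unmasked cells")
  Mu <- M[mask, , drop = FALSE]
  sds <- apply(Mu, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant layer(s): ",
                 paste(names(stack$layers)[sds == 0], collapse = ", ")))
  }
  Z <- scale(Mu)
  C <- stats::cor(Mu)
  eig <- eigen(C, symmetric = TRUE)
  explained <- eig$values / sum(eig$values)
  retained <- which(cumsum(explained) >= variance_target - 1e-12)[1]
  scores_u <- Z %*% eig$vectors[, seq_len(retained), drop = FALSE]
  scores <- matrix(NA_real_, nrow(M), retained)
  scores[mask, ] <- scores_u
  colnames(scores) <- paste0("PC", seq_len(retained))
  structure(list(scores = scores, explained = explained,
                 retained = retained, mask = mask,
                 loadings = eig$vectors,
                 n_rows = stack$n_rows, n_cols = stack$n_cols,
                 origin_x = stack$origin_x, origin_y = stack$origin_y,
                 cell_size = stack$cell_size),
            class = "bs_pca")
}

#' Unsupervised clustering of component scores into a class raster
#'
#' k-means over per-cell component vectors: k-means++ seeding, then Lloyd
#' iterations to an assignment fixpoint (or `max_iter`), with empty
#' clusters re-seeded from the point farthest from its centre. The result
#' is deterministic given the seed. Cluster labels are arbitrary until
#' relabelled against ground truth.
#'
#' @param pca A [pca_retain()] result (or a cells x features matrix plus
#'   geometry via `...` is not supported — use the pca object).
#' @param k Number of clusters (>= 2).
#' @param max_iter Lloyd iteration cap.
#' @param seed Integer seed.
#' @return A list of class `bs_clustering`: `cluster` (integer vector per
#'   cell, `NA` where masked), `centers`, `withinss_trace` (total
#'   within-cluster sum of squares per iteration, non-increasing),
#'   geometry fields.
#' @export
iso_cluster <- function(pca, k, max_iter = 100, seed = NULL) {
  if (k < 2) abort("`k` must be >= 2")
  X <- pca$scores[pca$mask, , drop = FALSE]
  if (nrow(unique(X)) < k) {
    abort("fewer distinct cell vectors than clusters")
  }
  res <- with_seed(seed, kmeans_lloyd(X, k, max_iter))
  cluster <- rep(NA_integer_, length(pca$mask))
  cluster[pca$mask] <- res$cluster
  structure(list(cluster = cluster, centers = res$centers,
                 withinss_trace = res$trace,
                 n_rows = pca$n_rows, n_cols = pca$n_cols,
                 origin_x = pca$origin_x, origin_y = pca$origin_y,
                 cell_size = pca$cell_size),
            class = "bs_clustering")
}

# k-means++ seeding followed by Lloyd iterations with empty-cluster
# reseeding from the farthest point
kmeans_lloyd <- function(X, k, max_iter) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    pick <- sample.int(n, 1, prob = pmax(d2, 1e-300))
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  assign_to <- function(centers) {
    D <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    list(cluster = max.col(-D, ties.method = "first"),
         mind = pmax(D[cbind(seq_len(n), max.col(-D, ties.method = "first"))], 0))
  }
  a <- assign_to(centers)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      if (!any(a$cluster == j)) {           # reseed from the farthest point
        far <- which.max(a$mind)
        centers[j, ] <- X[far, ]
        a <- assign_to(centers)
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[a$cluster == j, , drop = FALSE])
    }
    new_a <- assign_to(centers)
    trace <- c(trace, sum(new_a$mind))
    if (all(new_a$cluster == a$cluster)) { a <- new_a; break }
    a <- new_a
  }
  list(cluster = a$cluster, centers = centers, trace = trace)
}

#' Accuracy assessment against ground-truth points
#'
#' Builds the predicted-by-true confusion matrix and reports overall
#' accuracy (trace over total), Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the row and
#' column marginals, and the per-class user's accuracy (correct
#' predictions of a class over all predictions of that class; undefined —
#' `NA` — for classes never predicted). Kappa is reported as a proportion
#' in `[-1, 1]`.
#'
#' @param predicted,truth Vectors of class labels at ground-truth points
#'   (coerced to a shared factor level set).
#' @return An object of class `bs_accuracy`: `confusion` (rows =
#'   predicted), `overall_accuracy`, `kappa`, `users_accuracy` (named).
#' @export
accuracy_assessment <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0) {
    abort("`predicted` and `truth` must be equal-length, non-empty")
  }
  lev <- union(unique(as.character(predicted)), unique(as.character(truth)))
  p <- factor(as.character(predicted), levels = lev)
  t_ <- factor(as.character(truth), levels = lev)
  cm <- table(predicted = p, truth = t_)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  ua <- diag(cm) / rowSums(cm)
  ua[rowSums(cm) == 0] <- NA_real_
  structure(list(confusion = cm, overall_accuracy = po, kappa = kappa,
                 users_accuracy = ua),
            class = "bs_accuracy")
}

#' @export
print.bs_accuracy <- function(x, ...) {
  cat("<bs_accuracy> overall ", format(100 * x$overall_accuracy, digits = 3),
      "%, kappa ", format(x$kappa, digits = 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bs_accuracy <- function(x, ...) {
  tibble::tibble(class = names(x$users_accuracy),
                 users_accuracy = unname(x$users_accuracy),
                 n_predicted = unname(rowSums(x$confusion)))
}

#' @exportS3Method generics::glance
glance.bs_accuracy <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy, kappa = x$kappa,
                 n = sum(x$confusion))
}

#' Relabel unsupervised clusters by majority vote at ground-truth points
#'
#' Maps each cluster to the most frequent true class among the
#' ground-truth points falling in it (ties broken by first level;
#' clusters with no ground truth stay unlabelled as `NA`).
#'
#' @param clustering A [iso_cluster()] result.
#' @param x,y Ground-truth point coordinates.
#' @param true_class True class labels at the points.
#' @return A list: `mapping` (cluster -> label), `predicted` (labels at
#'   the points), suitable for [accuracy_assessment()].
#' @export
relabel_clusters <- function(clustering, x, y, true_class) {
  col <- floor((x - clustering$origin_x) / clustering$cell_size) + 1L
  row <- floor((y - clustering$origin_y) / clustering$cell_size) + 1L
  if (any(row < 1 | row > clustering$n_rows | col < 1 | col > clustering$n_cols)) {
    abort("ground-truth point outside the clustered raster")
  }
  idx <- row + (col - 1L) * clustering$n_rows
  cl <- clustering$cluster[idx]
  k <- nrow(clustering$centers)
  mapping <- rep(NA_character_, k)
  for (j in seq_len(k)) {
    hits <- true_class[!is.na(cl) & cl == j]
    if (length(hits) > 0) {
      tab <- table(hits)
      mapping[j] <- names(tab)[which.max(tab)]
    }
  }
  list(mapping = mapping, predicted = mapping[cl])
}
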