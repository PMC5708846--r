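#' PCA over binding-pocket C-alpha coordinates
#'
#' Each (already superimposed) pocket is flattened to a `3 * n_residues`
#' feature vector; the decomposition is covariance PCA on raw Angstrom
#' coordinates (mean-centred, no per-feature scaling, matching a
#' like-for-like comparison of C-alpha positions). Components are ordered
#' by explained variance; each loading vector is sign-fixed so its
#' largest-magnitude element is positive.
#'
#' @param pockets List of `binding_pocket`s with identical residue lists,
#'   superimposed beforehand (see [superimpose_pockets()]).
#' @param n_components Number of components to keep (default 2); clipped
#'   with a warning when it exceeds `n_models - 1`.
#' @param ids Optional model identifiers (defaults to list names, else
#'   `model_1..n`).
#' @return A `pocket_pca` object: `scores` tibble (`model`, `PC1..PCk`),
#'   `explained_fraction`, `rotation`, `center`, `zero_variance` flag.
#' @export
pocket_pca <- function(pockets, n_components = 2, ids = NULL) {
  if (length(pockets) < 2) abort_pf("need >= 2 pockets", "dimension_error")
  ref <- pockets[[1]]
  purrr::walk(pockets[-1], check_same_residues, a = ref)
  ids <- ids %||% names(pockets) %||% paste0("model_", seq_along(pockets))
  x <- do.call(rbind, purrr::map(pockets, ~ as.numeric(t(.x$ca_coords))))
  n <- nrow(x)
  k_max <- min(n - 1, ncol(x))
  if (n_components > k_max) {
    warning("n_components clipped from ", n_components, " to ", k_max)
    n_components <- k_max
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  total_var <- sum(xc^2) / (n - 1)
  if (total_var < 1e-12) {
    scores <- matrix(0, n, n_components)
    expl <- rep(0, n_components)
    rotation <- matrix(0, ncol(x), n_components)
    zero <- TRUE
  } else {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(n_components, ncol(p$rotation)))
    rotation <- p$rotation[, keep, drop = FALSE]
    # sign convention: largest-|loading| element positive
    for (j in seq_len(ncol(rotation))) {
      i_max <- which.max(abs(rotation[, j]))
      if (rotation[i_max, j] < 0) rotation[, j] <- -rotation[, j]
    }
    scores <- xc %*% rotation
    expl <- (p$sdev^2 / sum(p$sdev^2))[keep]
    zero <- FALSE
  }
  sc <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(sc) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(model = ids), sc),
    explained_fraction = expl, rotation = rotation, center = center,
    total_variance = total_var, zero_variance = zero, annotation = NULL),
    class = "pocket_pca")
}

#' Annotate PCA scores with Jaccard distance to a reference fingerprint
#'
#' Adds, per model, the Jaccard distance between that model's interaction
#' fingerprint and a reference fingerprint (typically the destination
#' X-ray complex); used as the colour map on PCA score plots.
#'
#' @param pca A `pocket_pca`.
#' @param ifps List of fingerprints, one per model, in score-row order.
#' @param reference The reference fingerprint.
#' @return The `pocket_pca` with `annotation` populated (also added as an
#'   `annotation` column of `scores`).
#' @export
annotate_by_reference <- function(pca, ifps, reference) {
  if (length(ifps) != nrow(pca$scores)) {
    abort_pf(paste0("got ", length(ifps), " fingerprints for ",
                    nrow(pca$scores), " models"), "dimension_error")
  }
  ann <- purrr::map_dbl(ifps, ~ jaccard_distance(.x, reference)$d_j)
  pca$annotation <- ann
  pca$scores$annotation <- ann
  pca
}

#' @export
print.pocket_pca <- function(x, ...) {
  cat("<pocket_pca> ", nrow(x$scores), " models, ",
      length(x$explained_fraction), " components (",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname pocket_pca
#' @param x A `pocket_pca` object.
#' @param ... Unused.
#' @export
tidy.pocket_pca <- function(x, ...) x$scores

#' @rdname pocket_pca
#' @export
glance.pocket_pca <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$scores),
                 n_components = length(x$explained_fraction),
                 total_variance = x$total_variance,
                 zero_variance = x$zero_variance,
                 cum_explained = sum(x$explained_fraction))
}

#' Score plot of a pocket PCA
#'
#' First two components with the explained-variance percentage in the axis
#' titles (e.g. "PC1 (50%)"); points are coloured by the Jaccard-distance
#' annotation when present.
#'
#' @param object A `pocket_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pocket_pca <- function(object, ...) {
  sc <- object$scores
  if (!"PC2" %in% names(sc)) sc$PC2 <- 0
  ef <- c(object$explained_fraction, 0, 0)
  lab <- function(i) sprintf("PC%d (%.0f%%)", i, 100 * ef[i])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(object$annotation)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$annotation),
                                 size = 2) +
      ggplot2::scale_colour_viridis_c(name = "d_J to reference",
                                      limits = c(0, 1))
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}

#' Write PCA scores to CSV and explained variance to JSON
#'
#' @param pca A `pocket_pca`.
#' @param scores_csv,variance_json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_pca_outputs <- function(pca, scores_csv = NULL, variance_json = NULL) {
  if (!is.null(scores_csv)) {
    utils::write.csv(pca$scores, scores_csv, row.names = FALSE)
  }
  if (!is.null(variance_json)) {
    jsonlite::write_json(
      list(explained_fraction = pca$explained_fraction,
           total_variance = pca$total_variance,
           zero_variance = pca$zero_variance),
      variance_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(scores_csv, variance_json))
}
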