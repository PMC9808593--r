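#' @title Two-component PCA of the torsion feature table
#' @description Mean-centred (never variance-scaled: all seven features
#'   share the same unit, degrees) principal components of the angle table,
#'   with explained-variance ratios and per-sample projections carrying
#'   provenance. Angles enter as linear values on `[0, 360)`, the same
#'   convention the classifier uses.
#' @name pca
NULL

#' Fit a two-component PCA
#'
#' Components come from the singular value decomposition of the centred
#' matrix; each component's sign is fixed so its largest-magnitude loading
#' is positive, making results deterministic.
#'
#' @param ds a `torsion_dataset` (or data frame with the seven angle
#'   columns), at least 3 samples.
#' @return a `torsion_pca`: `components` (7 x 2 orthonormal loading
#'   matrix), `explained_variance_ratio` (two descending fractions),
#'   `mean_vector`, and `projected` — a data frame of per-sample `pc1`/`pc2`
#'   with the provenance columns of `ds`.
#' @export
fit_pca <- function(ds) {
  X <- as.matrix(as.data.frame(ds)[, ANGLE_NAMES])
  if (nrow(X) < 3L) stop("fit_pca() needs at least 3 samples", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (sum(Xc^2) < 1e-12) {
    stop("degenerate input: all samples identical", call. = FALSE)
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  comps <- p$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  colnames(comps) <- c("pc1", "pc2")
  ratio <- (p$sdev^2 / sum(p$sdev^2))[1:2]
  scores <- Xc %*% comps
  prov <- intersect(c("pdb_id", "chain", "resseq", "base", "class", "label",
                      "tract_position"), names(as.data.frame(ds)))
  projected <- cbind(as.data.frame(ds)[, prov, drop = FALSE],
                     data.frame(pc1 = scores[, 1L], pc2 = scores[, 2L]))
  rownames(projected) <- NULL
  structure(list(components = comps, explained_variance_ratio = ratio,
                 mean_vector = ctr, projected = projected),
            class = "torsion_pca")
}

#' @export
print.torsion_pca <- function(x, ...) {
  cat(sprintf("torsion_pca: %d samples, explained variance %.1f%% + %.1f%% = %.1f%%\n",
              nrow(x$projected), 100 * x$explained_variance_ratio[1L],
              100 * x$explained_variance_ratio[2L],
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project samples onto fitted components
#'
#' @param res a `torsion_pca`.
#' @param samples data frame with the seven angle columns, complete.
#' @return n x 2 matrix of coordinates `(x - mean) %*% components`.
#' @export
project <- function(res, samples) {
  X <- as.matrix(as.data.frame(samples)[, ANGLE_NAMES])
  if (anyNA(X)) stop("project() requires complete samples", call. = FALSE)
  sweep(X, 2L, res$mean_vector) %*% res$components
}

#' Scatter plot of the projected samples
#'
#' @param res a `torsion_pca`.
#' @param colour_by provenance column used for colour.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_pca <- function(res, colour_by = "class") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pca() needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(res$projected,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * res$explained_variance_ratio[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * res$explained_variance_ratio[2L])
    ) +
    ggplot2::theme_minimal()
}
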