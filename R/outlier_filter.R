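#' Embed cells on principal components
#'
#' Cells are projected onto the leading principal components of the
#' (optionally log1p-transformed) expression matrix, with cells as
#' observations and genes as variables. Data are centered but not scaled.
#' Component signs are fixed deterministically: within each component the
#' gene loading with the largest magnitude is made positive.
#'
#' The log1p transform is applied for embedding and distance computations
#' only; imputation always works on untransformed values.
#'
#' @param m expression matrix (genes x cells).
#' @param n_components number of components (default 2).
#' @param transform `"log1p"` (default) or `"none"`.
#' @return cells x n_components score matrix, columns ordered by
#'   decreasing explained variance.
#' @export
pca_embed <- function(m, n_components = 2L, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  validate_expression_matrix(m, warn_nonint = FALSE)
  n_cells <- ncol(m)
  if (n_cells < 3L) stop("PCA embedding needs at least 3 cells")
  if (n_components > n_cells) stop("fewer cells than requested components")
  x <- t(if (transform == "log1p") log1p(m) else m)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rot <- pc$rotation
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- colnames(m)
  scores
}

#' Nearest-neighbor distance per cell
#'
#' For each cell, the Euclidean distance to its closest other cell
#' (self excluded) in the embedding.
#'
#' @param embedding cells x k coordinate matrix.
#' @return named numeric vector of nearest distances, one per cell.
#' @export
nearest_distances <- function(embedding) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 2L) stop("nearest distances need at least 2 cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  out <- apply(d, 1L, min)
  names(out) <- rownames(embedding)
  out
}

#' Flag outlier cells from nearest distances
#'
#' A cell is an outlier iff its nearest-neighbor distance strictly exceeds
#' the threshold. Under the default `"paper"` rule the threshold is
#' `q1 + 1.5 * (q3 - q1)`; `"tukey"` uses the conventional upper fence
#' `q3 + 1.5 * (q3 - q1)`. Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param dis numeric vector of nearest distances (length >= 4).
#' @param rule `"paper"` (default) or `"tukey"`.
#' @return list with `q1`, `q3`, `threshold`, `rule` and integer
#'   `outliers` (indices into `dis`).
#' @export
detect_outliers <- function(dis, rule = c("paper", "tukey")) {
  rule <- match.arg(rule)
  if (length(dis) < 4L) stop("outlier detection needs at least 4 cells")
  if (any(dis < 0)) stop("distances must be nonnegative")
  q <- stats::quantile(dis, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  threshold <- if (rule == "paper") q[1] + 1.5 * iqr else q[2] + 1.5 * iqr
  list(q1 = q[1], q3 = q[2], threshold = threshold, rule = rule,
       outliers = which(dis > threshold))
}

#' Remove outlier cells before imputation
#'
#' Embeds cells on the first two principal components, computes per-cell
#' nearest distances, applies the quartile rule, and returns the matrix
#' restricted to kept cells (original order preserved) together with a
#' full report.
#'
#' @param m expression matrix with at least 4 cells.
#' @param rule quartile rule, see [detect_outliers()].
#' @param keep_outliers if TRUE the returned matrix keeps all cells;
#'   outliers are only flagged in the report.
#' @param n_components embedding dimension (default 2).
#' @return list with `matrix` (kept cells) and `report` (embedding,
#'   per-cell nearest distance, quartiles, threshold, outlier and kept
#'   cell names).
#' @export
filter_outliers <- function(m, rule = c("paper", "tukey"),
                            keep_outliers = FALSE, n_components = 2L) {
  rule <- match.arg(rule)
  validate_expression_matrix(m, warn_nonint = FALSE)
  if (ncol(m) < 4L) stop("outlier filtering needs at least 4 cells")
  emb <- pca_embed(m, n_components = n_components)
  dis <- nearest_distances(emb)
  det <- detect_outliers(dis, rule = rule)
  out_idx <- det$outliers
  if (length(out_idx) == ncol(m)) {
    stop("all cells flagged as outliers; input looks pathological")
  }
  keep_idx <- setdiff(seq_len(ncol(m)), out_idx)
  report <- list(
    embedding = emb,
    nearest_distance = dis,
    q1 = det$q1, q3 = det$q3, threshold = det$threshold, rule = rule,
    outlier_cells = colnames(m)[out_idx],
    kept_cells = colnames(m)[keep_idx]
  )
  kept <- if (keep_outliers) m else m[, keep_idx, drop = FALSE]
  list(matrix = kept, report = report)
}
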