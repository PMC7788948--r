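#' Select informative genes by dropout-residual scoring
#'
#' Follows the scmap feature-selection contract: for every gene whose
#' dropout fraction d_g (fraction of zero entries across cells) lies
#' strictly between 0 and 1, regress `log2(100 * d_g)` on the mean
#' log2(x + 1) expression e_g by ordinary least squares across eligible
#' genes; a gene's score is its residual. Genes sitting above the trend
#' (high dropout for their expression level) are the informative,
#' bimodal markers. The `n_features` genes with the largest residuals
#' are returned.
#'
#' If no gene is eligible (every gene all-zero or never-zero) the
#' selection falls back, with a warning, to the genes with the largest
#' variance of log2(x + 1).
#'
#' @param m expression matrix.
#' @param n_features number of genes to select (default 500).
#' @return list with `gene_indices` (positions into the rows of `m`,
#'   in decreasing score order) and `scores`.
#' @export
select_features <- function(m, n_features = 500L) {
  validate_expression_matrix(m, warn_nonint = FALSE)
  if (n_features < 1L) stop("n_features must be positive")
  d <- rowMeans(m == 0)
  e <- rowMeans(log2(m + 1))
  eligible <- which(d > 0 & d < 1)
  if (length(eligible) == 0L) {
    warning("no gene with dropout fraction in (0,1); falling back to log-variance ranking")
    v <- apply(log2(m + 1), 1L, stats::var)
    # score ties broken by gene name so selection is permutation-invariant;
    # scores are rounded so floating-point noise cannot split tied groups
    ord <- order(-round(v, 9), rownames(m))
    take <- ord[seq_len(min(n_features, length(ord)))]
    return(list(gene_indices = take, scores = v[take]))
  }
  y <- log2(100 * d[eligible])
  x <- e[eligible]
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  # sparse data yields many genes with identical (dropout, mean) profiles
  # and hence tied residuals; rank on rounded scores with gene-name
  # tie-breaks so selection is permutation-invariant
  ord <- order(-round(res, 9), rownames(m)[eligible])
  take <- ord[seq_len(min(n_features, length(ord)))]
  list(gene_indices = eligible[take], scores = unname(res[take]))
}

#' Similarity between two cell profiles
#'
#' Computes cosine similarity or Pearson/Spearman correlation between two
#' equal-length vectors. Callers are expected to pass log2(x + 1)
#' transformed values restricted to selected features. A zero-norm vector
#' (cosine) or zero-variance vector (correlations) yields similarity 0
#' with a warning.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param metric `"cosine"` (default), `"pearson"` or `"spearman"`.
#' @return similarity in \[-1, 1\].
#' @export
cell_similarity <- function(a, b, metric = c("cosine", "pearson", "spearman")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("vectors must have length >= 2")
  if (metric == "cosine") {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) {
      warning("zero-norm vector; cosine similarity defined as 0")
      return(0)
    }
    return(sum(a * b) / (na * nb))
  }
  if (metric == "spearman") { a <- rank(a); b <- rank(b) }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance vector; correlation defined as 0")
    return(0)
  }
  stats::cor(a, b)
}

.similarity_matrix <- function(L, metric) {
  # L: features x cells, already log2(x+1)
  if (metric == "cosine") {
    nrm <- sqrt(colSums(L^2))
    bad <- nrm == 0
    if (any(bad)) {
      warning(sum(bad), " cell(s) with zero norm on the feature set; their similarities are 0")
      nrm[bad] <- 1
    }
    S <- crossprod(sweep(L, 2L, nrm, "/"))
    S[bad, ] <- 0; S[, bad] <- 0
    return(S)
  }
  if (metric == "spearman") L <- apply(L, 2L, rank)
  sds <- apply(L, 2L, stats::sd)
  bad <- sds == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero variance on the feature set; their similarities are 0")
  }
  S <- suppressWarnings(stats::cor(L))
  S[!is.finite(S)] <- 0
  S[bad, ] <- 0; S[, bad] <- 0
  S
}

#' Find the most similar cells for every cell
#'
#' Similarities are computed on log2(x + 1) values restricted to the
#' selected features. For each query cell the `k` most similar other
#' cells are retained (never itself), ties broken by ascending cell
#' index for determinism.
#'
#' @param m expression matrix with >= 2 cells.
#' @param features feature set from [select_features()]; `NULL` uses all
#'   genes.
#' @param k neighbors to keep per cell before gap filtering (default 20).
#' @param metric similarity metric, see [cell_similarity()].
#' @return list of neighbor sets, one per cell, each a list with
#'   `query` (cell name), `idx` (neighbor column indices), `similarity`
#'   (descending) and `metric`.
#' @export
find_neighbors <- function(m, features = NULL, k = 20L,
                           metric = c("cosine", "pearson", "spearman")) {
  metric <- match.arg(metric)
  validate_expression_matrix(m, warn_nonint = FALSE)
  n_cells <- ncol(m)
  if (n_cells < 2L) stop("neighbor search needs at least 2 cells")
  sub <- if (is.null(features)) m else m[features$gene_indices, , drop = FALSE]
  L <- log2(sub + 1)
  S <- .similarity_matrix(L, metric)
  k_eff <- min(k, n_cells - 1L)
  lapply(seq_len(n_cells), function(ci) {
    s <- S[, ci]
    others <- setdiff(seq_len(n_cells), ci)
    ord <- others[order(-s[others], others)]
    take <- ord[seq_len(k_eff)]
    list(query = colnames(m)[ci], idx = take,
         similarity = unname(s[take]), metric = metric)
  })
}

#' Drop neighbors far below the best similarity
#'
#' Keeps neighbor i iff `s_max - s_i <= gap` where `s_max` is the best
#' similarity in the set; order is preserved and the best neighbor always
#' survives.
#'
#' @param ns one neighbor set as produced by [find_neighbors()].
#' @param gap maximum allowed similarity difference (default 0.1).
#' @return the filtered neighbor set.
#' @export
filter_by_similarity_gap <- function(ns, gap = 0.1) {
  if (length(ns$idx) == 0L) stop("neighbor set is empty")
  keep <- (max(ns$similarity) - ns$similarity) <= gap
  ns$idx <- ns$idx[keep]
  ns$similarity <- ns$similarity[keep]
  ns
}
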