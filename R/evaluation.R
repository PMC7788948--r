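#' Intra- and inter-class distance summary
#'
#' Compactness score of a labeled expression matrix. With Dis(X, Y) the
#' squared Euclidean distance between two cell columns,
#' \deqn{Dis_{intra} = \sum_i \frac{1}{N_i N_i} \sum_{k,l} Dis(X^i_k, X^i_l)}
#' summed over all ordered within-class pairs including k = l, and
#' \deqn{Dis_{inter} = \sum_{i \ne j} \frac{1}{N_i N_j} \sum_{k,l} Dis(X^i_k, X^j_l)}
#' over ordered pairs of distinct classes. The ratio
#' `dis_ratio = dis_intra / dis_inter` is the single-number summary:
#' smaller means tighter classes relative to their separation.
#'
#' Distances are computed on untransformed values by default
#' (`transform = "log1p"` switches to log space).
#'
#' @param m expression matrix.
#' @param labels per-cell class labels (length = ncol(m)); at least two
#'   distinct classes.
#' @param transform `"none"` (default) or `"log1p"`.
#' @return list with `dis_intra`, `dis_inter`, `dis_ratio`.
#' @export
intra_inter_distance <- function(m, labels, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  validate_expression_matrix(m, warn_nonint = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop("one label per cell required")
  v <- if (transform == "log1p") log1p(m) else m
  groups <- split(seq_len(ncol(v)), labels)
  if (length(groups) < 2L) stop("inter-class distance needs at least 2 classes")
  D2 <- as.matrix(stats::dist(t(v)))^2
  dis_intra <- 0
  for (idx in groups) {
    dis_intra <- dis_intra + sum(D2[idx, idx]) / (length(idx)^2)
  }
  dis_inter <- 0
  kn <- names(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i == j) next
      gi <- groups[[i]]; gj <- groups[[j]]
      dis_inter <- dis_inter + sum(D2[gi, gj]) / (length(gi) * length(gj))
    }
  }
  list(dis_intra = dis_intra, dis_inter = dis_inter,
       dis_ratio = dis_intra / dis_inter)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement:
#' `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`, where `n_ij` is the
#' contingency table of the two labelings and `a_i`, `b_j` its margins.
#' 1 means identical partitions (up to label names), values near 0 mean
#' the partitions are independent.
#'
#' @param a,b label vectors of equal length >= 2.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 observations")
  tab <- table(as.character(a), as.character(b))
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  E <- sum_a * sum_b / choose(n, 2)
  M <- (sum_a + sum_b) / 2
  if (M == E) return(if (sum_ij == E) 1 else 0)
  (sum_ij - E) / (M - E)
}

#' K-means clustering score
#'
#' Clusters cells by K-means (10 restarts, seeded) on the first two
#' principal components of log(1 + x) — the same transform used for
#' visualization — and scores the partition against reference labels
#' with the adjusted Rand index.
#'
#' @param m expression matrix.
#' @param true_labels reference per-cell labels.
#' @param k number of clusters (>= 2, <= cells).
#' @param seed RNG seed for the K-means restarts (default 1).
#' @param nstart K-means restarts (default 10).
#' @return list with `labels` (predicted cluster per cell) and `ari`.
#' @export
cluster_and_score <- function(m, true_labels, k, seed = 1L, nstart = 10L) {
  validate_expression_matrix(m, warn_nonint = FALSE)
  if (k < 2L) stop("k must be at least 2")
  if (k > ncol(m)) stop("more clusters than cells")
  if (length(true_labels) != ncol(m)) stop("one label per cell required")
  emb <- pca_embed(m, n_components = 2L, transform = "log1p")
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 50L)
  pred <- stats::setNames(km$cluster, colnames(m))
  list(labels = pred, ari = adjusted_rand_index(pred, true_labels))
}

#' Zero accounting between two matrices
#'
#' Counts how many zeros of the input matrix were resolved (zero before,
#' nonzero after) versus retained by the modification.
#'
#' @param before,after expression matrices of identical shape and labels.
#' @return list with `total_entries`, `zeros_before`, `zeros_after`,
#'   `resolved`, `retained_zeros`, `zero_fraction_before`,
#'   `zero_fraction_after`.
#' @export
zero_accounting <- function(before, after) {
  if (!identical(dim(before), dim(after)) ||
      !identical(dimnames(before), dimnames(after))) {
    stop("matrices must have identical shape and labels")
  }
  zb <- before == 0
  za <- after == 0
  total <- length(before)
  list(total_entries = total,
       zeros_before = sum(zb),
       zeros_after = sum(za),
       resolved = sum(zb & !za),
       retained_zeros = sum(zb & za),
       zero_fraction_before = sum(zb) / total,
       zero_fraction_after = sum(za) / total)
}

#' PCA scatter plot of cells
#'
#' Plots cells on the first two principal components of log(1 + x),
#' colored by label, and writes the image to `out` (PNG or PDF inferred
#' from the extension).
#'
#' @param m expression matrix.
#' @param labels optional per-cell labels for coloring.
#' @param out output image path.
#' @param width,height device size in pixels (PNG) or inches (PDF).
#' @return `out`, invisibly.
#' @export
pca_scatter <- function(m, labels = NULL, out, width = 800, height = 600) {
  emb <- pca_embed(m, n_components = 2L, transform = "log1p")
  ext <- tolower(tools::file_ext(out))
  if (ext == "pdf") grDevices::pdf(out, width = width / 100, height = height / 100)
  else grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off())
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1L
  graphics::plot(emb[, 1], emb[, 2], col = col, pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = "Cells on the first two principal components")
  if (!is.null(labels)) {
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19,
                     bty = "n")
  }
  invisible(out)
}

#' Paper-scale simulation study
#'
#' For each seed: simulate a dataset at the given configuration, impute
#' it with default settings, and score both raw and modified matrices by
#' K-means ARI (k = number of simulated types, on 2 PCs of log1p) and by
#' the intra/inter-class distance ratio. The raw matrix is scored on all
#' simulated cells; the modified matrix on the cells kept by the
#' outlier filter.
#'
#' @param seeds integer vector of simulation seeds.
#' @param sim template [sim_config()]; its seed field is replaced by
#'   each element of `seeds` in turn.
#' @param ... passed to [impute_all()].
#' @return data.frame with one row per seed: `ari_raw`, `ari_mod`,
#'   `dis_raw`, `dis_mod`, `zero_fraction_before`, `zero_fraction_after`,
#'   `n_kept_cells`.
#' @export
run_simulation_study <- function(seeds = 1:10, sim = sim_config(), ...) {
  rows <- lapply(seeds, function(s) {
    cfg <- sim
    cfg$seed <- as.integer(s)
    ds <- simulate_cells(cfg)
    k <- cfg$n_types
    raw_score <- cluster_and_score(ds$observed_matrix, ds$labels, k, seed = s)
    dis_raw <- intra_inter_distance(ds$observed_matrix, ds$labels)
    res <- impute_all(ds$observed_matrix, ...)
    kept <- colnames(res$matrix)
    mod_score <- cluster_and_score(res$matrix, ds$labels[kept], k, seed = s)
    dis_mod <- intra_inter_distance(res$matrix, ds$labels[kept])
    data.frame(seed = s,
               ari_raw = raw_score$ari, ari_mod = mod_score$ari,
               dis_raw = dis_raw$dis_ratio, dis_mod = dis_mod$dis_ratio,
               zero_fraction_before = res$report$zero_fraction_before,
               zero_fraction_after = res$report$zero_fraction_after,
               n_kept_cells = length(kept))
  })
  do.call(rbind, rows)
}
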