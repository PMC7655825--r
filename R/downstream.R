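# Downstream calling and scoring: bimodal Gaussian thresholds, the dead-cell
# filter, factor-model imputation, the Chr7/Chr10 malignancy score, imaging
# meta-features, and subsampled Mann-Whitney differential expression.

# Two-component univariate Gaussian mixture by EM with quantile
# initialization (means at the 25th/75th percentiles, common starting sd,
# equal weights). Deterministic.
fit_gaussian_mixture2 <- function(x, max_iter = 500, tol = 1e-6) {
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  sigma <- rep(max(sd(x), .Machine$double.eps), 2)
  lambda <- c(0.5, 0.5)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- lambda[1] * dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    lambda <- c(mean(r), 1 - mean(r))
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sigma <- sqrt(c(
      sum(r * (x - mu[1])^2) / sum(r),
      sum((1 - r) * (x - mu[2])^2) / sum(1 - r)
    ))
    sigma <- pmax(sigma, diff(range(x)) * 1e-9 + .Machine$double.xmin)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll, iter = iter)
}

#' Threshold between the modes of a bimodal distribution
#'
#' Fits a two-component Gaussian mixture, histograms the values, and returns
#' the center of the least-populated ("shortest") histogram bin lying
#' strictly between the two fitted component means (ties between equally
#' empty bins: the middle one).
#'
#' @param values numeric vector (>= 100 values).
#' @param bins histogram bin count (default 50).
#' @return the threshold, with the mixture fit attached as attribute `fit`.
#' @export
bimodal_threshold <- function(values, bins = 50) {
  if (length(values) < 100) stop("bimodal threshold needs >= 100 values")
  fit <- fit_gaussian_mixture2(values)
  breaks <- seq(min(values), max(values), length.out = bins + 1)
  bin_width <- breaks[2] - breaks[1]
  if (abs(diff(fit$mu)) < bin_width) {
    stop(sprintf(
      "degenerate mixture: component means %.4g and %.4g are closer than one bin width (%.4g)",
      fit$mu[1], fit$mu[2], bin_width))
  }
  counts <- tabulate(
    pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), bins),
    nbins = bins
  )
  centers <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  lo <- min(fit$mu); hi <- max(fit$mu)
  between <- which(centers > lo & centers < hi)
  thr <- if (length(between) == 0) {
    (lo + hi) / 2
  } else {
    mins <- between[counts[between] == min(counts[between])]
    centers[mins[ceiling(length(mins) / 2)]]
  }
  attr(thr, "fit") <- fit
  thr
}

#' Dead-cell filter from live-stain intensity
#'
#' Fits a single Gaussian to the intensities and drops cells below its 5th
#' percentile (mu - 1.645 sigma); low-staining cells are presumed dead.
#'
#' @param intensities numeric vector (>= 20 cells).
#' @param quantile_cut lower tail probability (default 0.05).
#' @return list with `keep` (logical vector) and `threshold`.
#' @export
dead_cell_filter <- function(intensities, quantile_cut = 0.05) {
  if (length(intensities) < 20) stop("dead-cell filter needs >= 20 cells")
  thr <- mean(intensities) + qnorm(quantile_cut) * sd(intensities)
  list(keep = intensities >= thr, threshold = thr)
}

#' Imputed expression from a factor model
#'
#' Multiplies the cell and gene weight matrices of a nonnegative factor
#' model (e.g. the expectations of theta and beta from hierarchical Poisson
#' factorization) and log-transforms: log2(expected counts / 10000 + 1).
#'
#' @param theta cells x K nonnegative cell-weight matrix.
#' @param beta genes x K nonnegative gene-weight matrix.
#' @return cells x genes imputed log-expression matrix.
#' @export
impute_expression <- function(theta, beta) {
  theta <- as.matrix(theta); beta <- as.matrix(beta)
  stopifnot(ncol(theta) == ncol(beta))
  if (any(theta < 0) || any(beta < 0)) stop("factor matrices must be nonnegative")
  log2(theta %*% t(beta) / 10000 + 1)
}

#' Malignancy score and malignant/non-malignant calls
#'
#' Per cell: mean imputed expression over Chr7 genes minus mean over Chr10
#' genes (Chr7 gain and Chr10 loss are the canonical GBM aneuploidies). A
#' double-Gaussian threshold ([bimodal_threshold()]) on the scores separates
#' malignant (score > threshold) from non-malignant cells.
#'
#' @param imputed cells x genes matrix from [impute_expression()]
#'   (column names = genes).
#' @param chr7_genes,chr10_genes non-empty character vectors of gene names.
#' @return data.frame `score`, `label`; threshold in attribute `threshold`.
#' @export
malignancy_score <- function(imputed, chr7_genes, chr10_genes) {
  if (length(chr7_genes) == 0 || length(chr10_genes) == 0) {
    stop("both chromosome gene sets must be non-empty")
  }
  stopifnot(all(chr7_genes %in% colnames(imputed)),
            all(chr10_genes %in% colnames(imputed)))
  score <- rowMeans(imputed[, chr7_genes, drop = FALSE]) -
    rowMeans(imputed[, chr10_genes, drop = FALSE])
  thr <- bimodal_threshold(score)
  out <- data.frame(score = score,
                    label = ifelse(score > thr, "malignant", "non-malignant"))
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' Imaging meta-features
#'
#' Z-scores each imaging feature, clusters the features by average-linkage
#' hierarchical clustering with correlation distance, cuts the dendrogram at
#' `k` clusters, and averages the member z-scores of each cluster per cell.
#' With the sixteen standard features and k = 3 the clusters correspond to
#' cell size, shape and staining intensity.
#'
#' @param features cells x features numeric matrix or data.frame.
#' @param k number of feature clusters (default 3).
#' @return list with `meta` (cells x k matrix, columns `meta_1..k`),
#'   `feature_clusters` (named integer vector) and `hclust`.
#' @export
metafeatures <- function(features, k = 3) {
  m <- as.matrix(features)
  stopifnot(nrow(m) >= 3)
  keep <- apply(m, 2, sd) > 0
  if (!all(keep)) {
    warning("dropping constant features: ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  z <- scale(m)
  hc <- hclust(as.dist(1 - cor(z)), method = "average")
  cl <- cutree(hc, k = k)
  meta <- vapply(seq_len(k), function(g) {
    rowMeans(z[, cl == g, drop = FALSE])
  }, numeric(nrow(z)))
  colnames(meta) <- paste0("meta_", seq_len(k))
  rownames(meta) <- rownames(m)
  list(meta = meta, feature_clusters = cl, hclust = hc)
}

#' Cluster cells by imaging meta-features
#'
#' Average-linkage hierarchical clustering of cells on correlation distance
#' over the meta-features, cut at `k` clusters.
#'
#' @param meta cells x meta-features matrix (from [metafeatures()]).
#' @param k number of cell clusters (default 2).
#' @return integer cluster labels (ids arbitrary).
#' @export
cluster_cells_by_metafeatures <- function(meta, k = 2) {
  meta <- as.matrix(meta)
  if (nrow(meta) < 2) stop("need >= 2 cells to cluster")
  hc <- hclust(as.dist(1 - cor(t(meta))), method = "average")
  cutree(hc, k = k)
}

# Binomial thinning of a count matrix at a fixed per-molecule keep rate.
thin_counts <- function(counts, rate) {
  m <- as.matrix(counts)
  kept <- rbinom(length(m), size = as.vector(m), prob = rate)
  matrix(kept, nrow(m), dimnames = dimnames(m))
}

#' Subsampled Mann-Whitney differential expression
#'
#' Pairwise comparison of two cell groups: (1) the larger group is randomly
#' subsampled to the size of the smaller; (2) molecules of the deeper group
#' are binomially thinned so both groups have the same average molecules per
#' cell; (3) counts are normalized (default: per-cell size factors to the
#' common mean; externally computed size factors may be supplied); (4) each
#' gene is tested with a two-sided Mann-Whitney U test (normal approximation
#' with tie correction); (5) p values are Benjamini-Hochberg adjusted.
#'
#' @param counts_a,counts_b genes x cells count matrices (same genes).
#' @param seed integer seed for the subsampling draws.
#' @param size_factors optional list with elements `a` and `b`: per-cell
#'   size factors applied instead of the default normalization.
#' @return data.frame `gene`, `U`, `p`, `fdr`, `direction` (+1 where group A
#'   is higher, -1 where lower); genes with all-zero counts in both groups
#'   get NA statistics.
#' @export
differential_expression <- function(counts_a, counts_b, seed = 1L,
                                    size_factors = NULL) {
  a <- as.matrix(counts_a); b <- as.matrix(counts_b)
  stopifnot(nrow(a) == nrow(b))
  if (ncol(a) < 10 || ncol(b) < 10) stop("both groups need >= 10 cells")
  with_seed(seed, {
    n <- min(ncol(a), ncol(b))
    if (ncol(a) > n) a <- a[, sample(ncol(a), n), drop = FALSE]
    if (ncol(b) > n) b <- b[, sample(ncol(b), n), drop = FALSE]
    ma <- mean(colSums(a)); mb <- mean(colSums(b))
    if (ma > mb) a <- thin_counts(a, mb / ma)
    if (mb > ma) b <- thin_counts(b, ma / mb)
  })
  if (is.null(size_factors)) {
    common <- mean(c(colSums(a), colSums(b)))
    sf_a <- colSums(a) / common
    sf_b <- colSums(b) / common
  } else {
    sf_a <- size_factors$a; sf_b <- size_factors$b
  }
  an <- sweep(a, 2, pmax(sf_a, .Machine$double.eps), `/`)
  bn <- sweep(b, 2, pmax(sf_b, .Machine$double.eps), `/`)
  genes <- rownames(a)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(a)))
  U <- p <- rep(NA_real_, nrow(a))
  for (g in seq_len(nrow(a))) {
    if (all(an[g, ] == 0) && all(bn[g, ] == 0)) next
    wt <- suppressWarnings(
      wilcox.test(an[g, ], bn[g, ], alternative = "two.sided", exact = FALSE,
                  correct = TRUE)
    )
    U[g] <- unname(wt$statistic)
    p[g] <- wt$p.value
  }
  data.frame(
    gene = genes, U = U, p = p,
    fdr = p.adjust(p, method = "BH"),
    direction = sign(rowMeans(an) - rowMeans(bn))
  )
}
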