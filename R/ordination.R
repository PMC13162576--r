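#' Principal component analysis of samples
#'
#' Samples are observations and proteins variables; columns are centered but
#' not scaled, as is standard for log-scale intensity data. Components are
#' ordered by decreasing variance, and the sign of each component is fixed so
#' that its largest-magnitude loading is positive (a deterministic
#' convention — PCA signs are otherwise arbitrary).
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param subset Optional character vector of protein ids to restrict the
#'   analysis to (e.g. the differentially abundant set).
#' @return Object of class `"coab_pca"`: list with `scores` (sample x
#'   component), `loadings` (protein x component), `variance_fraction`.
#' @export
coab_pca <- function(m, subset = NULL) {
  v <- ab_values(m)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, rownames(v))
    if (length(unknown))
      stop("subset proteins not in matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    if (length(subset) == 0) stop("empty protein subset", call. = FALSE)
    v <- v[subset, , drop = FALSE]
  }
  if (ncol(v) < 2) stop("need at least 2 samples for PCA", call. = FALSE)
  pr <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf), class = "coab_pca")
}

#' @export
print.coab_pca <- function(x, ...) {
  k <- min(3L, length(x$variance_fraction))
  cat("PCA of", nrow(x$scores), "samples on", nrow(x$loadings), "proteins\n")
  cat(sprintf("  PC%d: %.1f%% variance\n", seq_len(k),
              100 * x$variance_fraction[seq_len(k)]), sep = "")
  invisible(x)
}

# pseudo-F and R^2 from a squared-distance matrix and group labels
permanova_stats <- function(d2, g) {
  N <- length(g)
  sst <- sum(d2[upper.tri(d2)]) / N
  ssw <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssb <- sst - ssw
  k <- nlevels(g)
  list(F = (ssb / (k - 1)) / (ssw / (N - k)), R2 = ssb / sst)
}

#' PERMANOVA (Adonis) test of group structure
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' among samples. The total sum of squares is the sum of squared pairwise
#' distances divided by N, the within-group sum uses within-group pairs
#' divided by group size, and the pseudo-F statistic is
#' `(SS_between/(g-1)) / (SS_within/(N-g))`. The p-value is the +1-corrected
#' fraction of label permutations whose pseudo-F reaches the observed one:
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`.
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param groups Per-sample group labels (coerced to factor), aligned with
#'   the matrix columns.
#' @param n_perm Number of label permutations (paper-style default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `"coab_permanova"`: list with `pseudo_F`,
#'   `R_squared`, `p_value`, `n_permutations`, `seed`.
#' @export
coab_permanova <- function(m, groups, n_perm = 999L, seed = 1L) {
  v <- ab_values(m)
  g <- factor(groups)
  N <- ncol(v)
  if (length(g) != N) stop("one group label per sample required", call. = FALSE)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (nlevels(g) >= N) stop("more groups than residual df allows", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d2 <- as.matrix(stats::dist(t(v)))^2
  obs <- permanova_stats(d2, g)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- g[sample.int(N)]
    if (permanova_stats(d2, gp)$F >= obs$F) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = obs$F, R_squared = obs$R2,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_permutations = as.integer(n_perm), seed = as.integer(seed)),
            class = "coab_permanova")
}

#' @export
print.coab_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (Euclidean): pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$R_squared, x$p_value, x$n_permutations))
  invisible(x)
}
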