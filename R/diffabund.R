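#' Per-protein one-way ANOVA across developmental stages
#'
#' Row-wise one-way ANOVA of log2 abundance on stage: for every protein,
#' `F = MS_between / MS_within` with degrees of freedom (g - 1, N - g), p from
#' the upper tail of the F distribution, and Benjamini-Hochberg q-values
#' across the testable family. Proteins with zero total variance are flagged
#' (`F` and `p` are `NA`) and excluded from the FDR family; proteins with zero
#' within-group variance but distinct group means receive the smallest
#' representable positive p with a warning.
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param design Data.frame with `sample_id` and `stage_days` columns; every
#'   matrix sample must appear exactly once. Alignment is by id, not position.
#' @return Data.frame with one row per protein: `protein_id`, `F_statistic`,
#'   `p_value`, `q_value`, `flagged`.
#' @examples
#' sim <- generate_dataset(syn_params(n_proteins = 60, module_sizes = c(20L),
#'                                    trend_kinds = "increasing",
#'                                    trait_specs = list(), seed = 3))
#' head(anova_per_protein(sim$abundance, sim$design))
#' @export
anova_per_protein <- function(m, design) {
  if (ab_scale(m) != "log2")
    stop("anova_per_protein expects a log2-scale matrix", call. = FALSE)
  al <- align_to_design(m, design)
  x <- al$x
  g <- factor(al$design$stage_days)
  ng <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 stages", call. = FALSE)
  if (any(ng < 2)) stop("every stage needs at least 2 replicates", call. = FALSE)

  N <- ncol(x); k <- nlevels(g)
  G <- stats::model.matrix(~ 0 + g)              # N x k indicator
  means <- (x %*% G) %*% diag(1 / as.numeric(ng), k)
  grand <- rowMeans(x)
  ssb <- as.numeric((sweep(means, 1, grand)^2) %*% as.numeric(ng))
  sst <- rowSums(sweep(x, 1, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1; df2 <- N - k
  if (df2 < 1) stop("no residual degrees of freedom", call. = FALSE)

  tol <- 1e-12 * pmax(sst, 1)
  flagged <- sst < .Machine$double.eps * N       # no variance at all
  degen <- !flagged & ssw < tol                   # exact fit, unequal means
  Fs <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fs, df1, df2, lower.tail = FALSE)
  if (any(degen)) {
    warning(sum(degen),
            " protein(s) with zero within-group variance; p set to the ",
            "smallest representable positive value")
    p[degen] <- .Machine$double.xmin
    Fs[degen] <- Inf
  }
  Fs[flagged] <- NA_real_
  p[flagged] <- NA_real_
  data.frame(
    protein_id = rownames(x),
    F_statistic = Fs,
    p_value = p,
    q_value = bh_adjust(p),
    flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps the standard step-up procedure with the missing-value policy used
#' throughout the package: `NA` entries (flagged proteins) are excluded from
#' the family — the family size m is reduced accordingly — and reinserted as
#' `NA` in the original order.
#'
#' @param p Numeric vector of p-values in (0, 1], possibly with `NA`s.
#' @return q-values in the input order; `NA` where the input was `NA`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Tukey HSD post hoc contrasts for one protein
#'
#' All-pairs stage comparisons for a single protein using the Tukey-Kramer
#' studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`, with p from
#' the studentized range distribution with parameters (g, N - g).
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param design Sample design (see [anova_per_protein()]).
#' @param protein Protein id (a rowname of `m`).
#' @return Data.frame with one row per stage pair: `stage_a`, `stage_b`
#'   (days, a < b), `mean_diff` (mean at b minus mean at a, log2 units),
#'   `q_statistic`, `p_adj`.
#' @export
tukey_hsd <- function(m, design, protein) {
  al <- align_to_design(m, design)
  x <- al$x
  if (!protein %in% rownames(x))
    stop("unknown protein: ", protein, call. = FALSE)
  y <- x[protein, ]
  g <- factor(al$design$stage_days)
  ng <- tapply(y, g, length)
  if (any(ng < 2)) stop("every stage needs at least 2 replicates", call. = FALSE)
  means <- tapply(y, g, mean)
  N <- length(y); k <- nlevels(g)
  ssw <- sum((y - means[g])^2)
  df2 <- N - k
  msw <- ssw / df2
  if (msw <= 0)
    stop("zero within-group variance for protein ", protein, call. = FALSE)
  pairs <- utils::combn(levels(g), 2)
  stage_a <- as.integer(pairs[1, ]); stage_b <- as.integer(pairs[2, ])
  na <- as.numeric(ng[pairs[1, ]]); nb <- as.numeric(ng[pairs[2, ]])
  diff <- as.numeric(means[pairs[2, ]] - means[pairs[1, ]])
  qs <- abs(diff) / sqrt(msw / 2 * (1 / na + 1 / nb))
  data.frame(
    protein_id = protein, stage_a = stage_a, stage_b = stage_b,
    mean_diff = diff, q_statistic = qs,
    p_adj = stats::ptukey(qs, nmeans = k, df = df2, lower.tail = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# align matrix columns and design rows by sample id (design may be a
# superset of the matrix samples); errors on samples missing from the design
align_to_design <- function(m, design) {
  v <- ab_values(m)
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample ids in design", call. = FALSE)
  missing <- setdiff(colnames(v), design$sample_id)
  if (length(missing))
    stop("design is missing samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- design[design$sample_id %in% colnames(v), , drop = FALSE]
  list(x = v[, d$sample_id, drop = FALSE], design = d)
}
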