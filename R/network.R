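#' Pearson correlation matrix of protein profiles
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @return Symmetric protein x protein correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  v <- ab_values(m)
  vr <- apply(v, 1, stats::var)
  if (any(vr == 0))
    stop("zero-variance protein(s): ",
         paste(utils::head(rownames(v)[vr == 0], 5), collapse = ", "),
         "; filter before computing correlations", call. = FALSE)
  stats::cor(t(v))
}

#' Soft-thresholded adjacency
#'
#' Unsigned: `a_ij = |cor_ij|^beta`; signed: `a_ij = ((1 + cor_ij)/2)^beta`.
#' The diagonal is set to 0, the convention used by connectivity and
#' topological overlap.
#'
#' @param cor Protein x protein correlation matrix.
#' @param beta Soft-thresholding power (>= 1).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return Adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
soft_adjacency <- function(cor, beta = 6, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  a <- if (type == "unsigned") abs(cor)^beta else ((1 + cor) / 2)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity vector `k` into `n_bins` equal-width bins, then
#' regresses log10(mean frequency per bin) on log10(mean k per bin). The
#' returned statistic is R^2 multiplied by the negative sign of the slope, so
#' decreasing (scale-free-like) connectivity laws score positive.
#'
#' @param k Connectivity vector (`rowSums` of an adjacency with zero
#'   diagonal).
#' @param n_bins Number of equal-width bins (default 10).
#' @return Signed R^2 in \[-1, 1\].
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  if (length(unique(k)) < 2)
    stop("all connectivities equal; scale-free fit undefined", call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 2)
    stop("fewer than 2 usable bins; scale-free fit undefined", call. = FALSE)
  fit <- suppressWarnings(stats::lm(log10(freq[keep]) ~ log10(mean_k[keep])))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Scan candidate soft-thresholding powers
#'
#' Computes the signed scale-free fit and mean connectivity for each candidate
#' power and selects the smallest power whose fit reaches
#' `scale_free_target`; if none qualifies, the power with the maximal fit is
#' returned with a warning flag.
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param candidate_powers Powers to scan (default 1..20).
#' @param scale_free_target Signed R^2 threshold (paper-style default 0.8).
#' @param type Network type, see [soft_adjacency()].
#' @param n_bins Bins for [scale_free_fit()].
#' @return List with `beta` (selected power), `scan` (data.frame: `power`,
#'   `signed_r_squared`, `mean_k`), `reached_target` (logical).
#' @export
pick_soft_threshold <- function(m, candidate_powers = 1:20,
                                scale_free_target = 0.8,
                                type = c("unsigned", "signed"),
                                n_bins = 10L) {
  type <- match.arg(type)
  if (length(candidate_powers) == 0)
    stop("candidate_powers must be non-empty", call. = FALSE)
  C <- correlation_matrix(m)
  scan <- data.frame(power = candidate_powers,
                     signed_r_squared = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    a <- soft_adjacency(C, candidate_powers[i], type = type)
    k <- rowSums(a)
    scan$mean_k[i] <- mean(k)
    scan$signed_r_squared[i] <- tryCatch(scale_free_fit(k, n_bins),
                                         error = function(e) NA_real_)
  }
  sel <- select_soft_threshold(scan, scale_free_target)
  c(sel, list(scan = scan))
}

#' Select a power from a soft-threshold scan table
#'
#' @param scan Data.frame with columns `power` and `signed_r_squared`.
#' @param scale_free_target Signed R^2 threshold.
#' @return List with `beta` and `reached_target`.
#' @export
select_soft_threshold <- function(scan, scale_free_target = 0.8) {
  ok <- which(!is.na(scan$signed_r_squared) &
                scan$signed_r_squared >= scale_free_target)
  if (length(ok))
    return(list(beta = scan$power[ok[1]], reached_target = TRUE))
  warning("no candidate power reached the scale-free target ",
          scale_free_target, "; using the best-fitting power")
  best <- which.max(scan$signed_r_squared)
  list(beta = scan$power[best], reached_target = FALSE)
}

#' Topological overlap matrix
#'
#' `omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `l_ij = sum_u a_iu a_uj` (the zero diagonal makes the sum skip `u = i, j`)
#' and `k_i = sum_j a_ij`; the diagonal is 1. Pairs with a zero denominator
#' (isolated pair) get overlap 0.
#'
#' @param adjacency Symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return TOM similarity matrix; `1 - tom` is the clustering dissimilarity.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency diagonal must be 0", call. = FALSE)
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]",
                               call. = FALSE)
  k <- rowSums(a)
  l <- a %*% a                       # zero diagonal excludes u = i and u = j
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  tom[denom <= 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by hierarchical clustering of the TOM dissimilarity
#'
#' Average-linkage clustering on `1 - TOM`, cut at `cut_height` times the
#' maximal merge height. Clusters smaller than `min_module_size` are assigned
#' label 0 (unassigned); surviving modules are relabeled 1..K by decreasing
#' size.
#'
#' @param tom TOM similarity matrix from [topological_overlap()].
#' @param cut_height Fraction of the maximal merge height at which the tree
#'   is cut (default 0.99).
#' @param min_module_size Minimum members a cluster needs to become a module
#'   (default 30).
#' @return List with `labels` (named integer vector, 0 = unassigned) and
#'   `tree` (the `hclust` object).
#' @export
detect_modules <- function(tom, cut_height = 0.99, min_module_size = 30L) {
  n <- nrow(tom)
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (min_module_size > n) {
    warning("min_module_size exceeds the number of proteins; all unassigned")
    labels <- stats::setNames(integer(n), rownames(tom))
    return(list(labels = labels, tree = tree))
  }
  cl <- stats::cutree(tree, h = cut_height * max(tree$height))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(n)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]  # big first, stable
    for (i in seq_along(keep)) labels[cl == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(tom)
  list(labels = labels, tree = tree)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component across samples
#' of its standardized member profiles (each protein centered and scaled to
#' unit variance), itself scaled to unit variance and sign-oriented so it
#' correlates non-negatively with the module's mean standardized profile. A
#' single-member module's eigengene is that protein's standardized profile.
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param labels Integer module labels per protein (0 = unassigned), named by
#'   protein id.
#' @return Module x sample matrix of eigengenes (rownames `"M1"`, ...), each
#'   row with zero mean and unit variance.
#' @export
module_eigengenes <- function(m, labels) {
  v <- ab_values(m)
  labels <- labels[rownames(v)]
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules to summarize", call. = FALSE)
  me <- matrix(0, length(mods), ncol(v),
               dimnames = list(paste0("M", mods), colnames(v)))
  for (i in seq_along(mods)) {
    xs <- v[labels == mods[i], , drop = FALSE]
    xs <- t(scale(t(xs)))            # per-protein standardize
    if (nrow(xs) == 1) {
      e <- as.numeric(xs)
    } else {
      e <- svd(xs, nu = 0, nv = 1)$v[, 1]
    }
    e <- e / stats::sd(e)
    mu <- colMeans(xs)
    if (stats::sd(mu) > 0 && stats::cor(e, mu) < 0) e <- -e
    me[i, ] <- e - mean(e)
  }
  me
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the pair of modules whose eigengenes are most
#' correlated, as long as that correlation exceeds `merge_cor_threshold`;
#' eigengenes are recomputed after every merge. Final labels are compacted to
#' 1..K by decreasing module size, so the result is deterministic.
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param labels Module labels (see [module_eigengenes()]).
#' @param merge_cor_threshold Eigengene correlation above which modules merge
#'   (paper-style default 0.8).
#' @return List with `labels` (merged, compacted) and `n_merges`.
#' @export
merge_close_modules <- function(m, labels, merge_cor_threshold = 0.8) {
  labels <- labels[rownames(ab_values(m))]
  n_merges <- 0L
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(m, labels)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    if (cc[best[1], best[2]] <= merge_cor_threshold) break
    pair <- sort(mods[c(best[1], best[2])])
    labels[labels == pair[2]] <- pair[1]
    n_merges <- n_merges + 1L
  }
  # compact: relabel by decreasing size, ties by old label
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods)) {
    sizes <- vapply(mods, function(md) sum(labels == md), 0L)
    ord <- mods[order(-sizes, mods)]
    new <- labels
    for (i in seq_along(ord)) new[labels == ord[i]] <- i
    labels <- new
  }
  list(labels = labels, n_merges = n_merges)
}

#' Module membership (kME)
#'
#' Pearson correlation of every protein profile with every module eigengene.
#'
#' @param m An [abundance_matrix()] on the log2 scale.
#' @param eigengenes Module x sample matrix from [module_eigengenes()].
#' @return Protein x module matrix of correlations in \[-1, 1\].
#' @export
module_membership <- function(m, eigengenes) {
  v <- ab_values(m)
  vr <- apply(v, 1, stats::var)
  if (any(vr == 0))
    stop("zero-variance protein(s): ",
         paste(utils::head(rownames(v)[vr == 0], 5), collapse = ", "),
         call. = FALSE)
  stats::cor(t(v), t(eigengenes))
}

#' Module-trait correlations with parametric p-values
#'
#' Pearson correlation between each module eigengene and each trait, with a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df. A
#' pair is flagged significant when `|r| > trait_cor_threshold` and
#' `p < alpha`.
#'
#' @param eigengenes Module x sample matrix.
#' @param traits Sample x trait numeric matrix; rownames must match the
#'   eigengene sample ids (alignment is by id).
#' @param trait_cor_threshold Correlation magnitude for significance
#'   (paper-style default 0.7).
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with one row per (module, trait): `module`, `trait`,
#'   `r`, `p_value`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     trait_cor_threshold = 0.7,
                                     alpha = 0.05) {
  tr <- align_traits(eigengenes, traits)
  n <- ncol(eigengenes)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  r <- stats::cor(t(eigengenes), tr)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  out <- expand.grid(module = rownames(r), trait = colnames(r),
                     stringsAsFactors = FALSE)
  out$r <- as.numeric(r)
  out$p_value <- as.numeric(p)
  out$significant <- abs(out$r) > trait_cor_threshold & out$p_value < alpha
  out
}

#' Permutation validation of module-trait correlations
#'
#' For each trait, the sample order of the trait vector is permuted B times
#' and the two-sided empirical p-value per module is
#' `(1 + #{|r_perm| >= |r_obs|}) / (B + 1)`. The same permutation sequence is
#' applied across modules for a given trait (so module p-values for one trait
#' share a null), and traits are permuted independently.
#'
#' @param eigengenes Module x sample matrix.
#' @param traits Sample x trait matrix (aligned by sample id).
#' @param n_permutations Number of permutations B (paper-style default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return Data.frame with `module`, `trait`, `perm_p`; row order matches
#'   [module_trait_correlation()].
#' @export
permutation_validation <- function(eigengenes, traits,
                                   n_permutations = 1000L, seed = 1L) {
  tr <- align_traits(eigengenes, traits)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  n <- ncol(eigengenes)
  me_t <- t(eigengenes)
  set.seed(seed)
  pm <- matrix(NA_real_, nrow(eigengenes), ncol(tr),
               dimnames = list(rownames(eigengenes), colnames(tr)))
  for (j in seq_len(ncol(tr))) {
    y <- tr[, j]
    r_obs <- abs(as.numeric(stats::cor(me_t, y)))
    exceed <- integer(length(r_obs))
    for (b in seq_len(n_permutations)) {
      rp <- abs(as.numeric(stats::cor(me_t, y[sample.int(n)])))
      exceed <- exceed + (rp >= r_obs)
    }
    pm[, j] <- (1 + exceed) / (n_permutations + 1)
  }
  out <- expand.grid(module = rownames(pm), trait = colnames(pm),
                     stringsAsFactors = FALSE)
  out$perm_p <- as.numeric(pm)
  out
}

# align a sample x trait matrix to the eigengene sample order; checks
# variance and coverage
align_traits <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("trait table needs sample rownames", call. = FALSE)
  missing <- setdiff(colnames(eigengenes), rownames(traits))
  if (length(missing))
    stop("trait table is missing samples: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tr <- traits[colnames(eigengenes), , drop = FALSE]
  sds <- apply(tr, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait(s): ",
         paste(colnames(tr)[sds == 0], collapse = ", "), call. = FALSE)
  tr
}

#' Hub proteins per module
#'
#' The hub of a module is its member with maximal kME to the module's own
#' eigengene (ties broken lexicographically by protein id); its neighbor list
#' holds the `top_n` other members ranked by adjacency to the hub.
#'
#' @param labels Module labels (named integer vector).
#' @param kME Protein x module membership matrix from [module_membership()].
#' @param adjacency Adjacency matrix (same protein order as `kME`).
#' @param top_n Neighbors to report (clipped to module size - 1).
#' @return Data.frame with one row per module: `module`, `hub_protein`,
#'   `module_membership_score`, and a list-column `neighbors` of data.frames
#'   (`protein_id`, `adjacency`).
#' @export
identify_hubs <- function(labels, kME, adjacency, top_n = 10L) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules", call. = FALSE)
  rows <- lapply(mods, function(md) {
    members <- sort(names(labels)[labels == md])
    km <- kME[members, paste0("M", md)]
    hub <- members[which(km == max(km))][1]      # lexicographic tie-break
    others <- setdiff(members, hub)
    adj <- adjacency[hub, others]
    ord <- order(-adj, others)
    top <- utils::head(ord, top_n)
    list(module = md, hub_protein = hub,
         module_membership_score = unname(km[hub]),
         neighbors = data.frame(protein_id = others[top],
                                adjacency = unname(adj[top]),
                                stringsAsFactors = FALSE))
  })
  out <- data.frame(
    module = vapply(rows, `[[`, 0L, "module"),
    hub_protein = vapply(rows, `[[`, "", "hub_protein"),
    module_membership_score = vapply(rows, `[[`, 0, "module_membership_score"),
    stringsAsFactors = FALSE
  )
  out$neighbors <- lapply(rows, `[[`, "neighbors")
  out
}
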