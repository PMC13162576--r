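#' Fit a weighted protein co-abundance network
#'
#' The package's core model. From a normalized log2 abundance matrix it
#' (1) computes the Pearson correlation matrix and a soft-thresholded
#' adjacency (`|cor|^beta`, or the signed variant), selecting `beta` by the
#' scale-free topology criterion when `beta = "auto"`; (2) computes the
#' topological overlap matrix and detects modules by average-linkage
#' clustering of `1 - TOM`; (3) merges modules whose eigengenes correlate
#' above `merge_cor_threshold`; (4) computes module eigengenes and per-protein
#' module membership (kME); (5) if traits are supplied, correlates eigengenes
#' with traits, flags pairs with `|r| > trait_cor_threshold` and
#' `p < alpha`, and validates them against a permutation null; and
#' (6) reports each module's hub protein (maximal own-module kME) with its
#' strongest-adjacency neighbors.
#'
#' @param x An [abundance_matrix()] on the log2 scale (normalize first; see
#'   [cyclic_loess_normalize()]).
#' @param traits Optional sample x trait numeric matrix with sample rownames.
#' @param beta Soft-thresholding power, or `"auto"` to select by
#'   [pick_soft_threshold()].
#' @param candidate_powers,scale_free_target Passed to
#'   [pick_soft_threshold()] when `beta = "auto"`.
#' @param network_type `"unsigned"` or `"signed"`; see [soft_adjacency()].
#' @param cut_height,min_module_size Passed to [detect_modules()].
#' @param merge_cor_threshold Passed to [merge_close_modules()].
#' @param trait_cor_threshold,alpha Passed to [module_trait_correlation()].
#' @param n_permutations,seed Passed to [permutation_validation()].
#' @param top_n_neighbors Hub neighbor count, see [identify_hubs()].
#' @param keep_matrices Keep the adjacency and TOM in the returned object
#'   (memory: two dense protein x protein matrices).
#' @return Object of class `"coab"`: list with `labels`, `module_sizes`,
#'   `eigengenes`, `kME`, `module_trait` (with `perm_p` when traits given),
#'   `hubs`, `beta`, `scan` (when auto-selected), `tree`, `params`, `call`,
#'   and optionally `adjacency`/`tom`.
#' @examples
#' sim <- generate_dataset(syn_params(seed = 1))
#' fit <- coab(sim$abundance, sim$traits, min_module_size = 10,
#'             n_permutations = 200, seed = 1)
#' fit
#' summary(fit)
#' @export
coab <- function(x, traits = NULL, beta = "auto",
                 candidate_powers = 1:20, scale_free_target = 0.8,
                 network_type = c("unsigned", "signed"),
                 cut_height = 0.99, min_module_size = 30L,
                 merge_cor_threshold = 0.8,
                 trait_cor_threshold = 0.7, alpha = 0.05,
                 n_permutations = 1000L, seed = 1L,
                 top_n_neighbors = 10L, keep_matrices = FALSE) {
  network_type <- match.arg(network_type)
  if (ab_scale(x) != "log2")
    stop("coab expects a log2-scale matrix; see log2_transform()",
         call. = FALSE)

  scan <- NULL
  if (identical(beta, "auto")) {
    sel <- pick_soft_threshold(x, candidate_powers, scale_free_target,
                               type = network_type)
    beta <- sel$beta
    scan <- sel$scan
  }
  C <- correlation_matrix(x)
  A <- soft_adjacency(C, beta, type = network_type)
  tom <- topological_overlap(A)
  det <- detect_modules(tom, cut_height, min_module_size)
  labels <- det$labels
  n_merges <- 0L
  if (any(labels > 0)) {
    mg <- merge_close_modules(x, labels, merge_cor_threshold)
    labels <- mg$labels
    n_merges <- mg$n_merges
  }
  if (!any(labels > 0)) {
    warning("no modules detected; returning labels only")
    return(structure(list(labels = labels, module_sizes = integer(0),
                          eigengenes = NULL, kME = NULL, module_trait = NULL,
                          hubs = NULL, beta = beta, scan = scan,
                          tree = det$tree,
                          params = list(network_type = network_type,
                                        cut_height = cut_height,
                                        min_module_size = min_module_size),
                          call = match.call()),
                     class = "coab"))
  }

  me <- module_eigengenes(x, labels)
  kme <- module_membership(x, me)
  hubs <- identify_hubs(labels, kme, A, top_n = top_n_neighbors)

  mt <- NULL
  if (!is.null(traits)) {
    mt <- module_trait_correlation(me, traits, trait_cor_threshold, alpha)
    pv <- permutation_validation(me, traits, n_permutations, seed)
    mt <- merge(mt, pv, by = c("module", "trait"), sort = FALSE)
    mt <- mt[order(mt$trait, mt$module), , drop = FALSE]
    rownames(mt) <- NULL
  }

  sizes <- table(factor(labels[labels > 0]))
  structure(list(
    labels = labels,
    module_sizes = stats::setNames(as.integer(sizes),
                                   paste0("M", names(sizes))),
    eigengenes = me, kME = kme, module_trait = mt, hubs = hubs,
    beta = beta, scan = scan, tree = det$tree, n_merges = n_merges,
    adjacency = if (keep_matrices) A, tom = if (keep_matrices) tom,
    params = list(network_type = network_type, cut_height = cut_height,
                  min_module_size = min_module_size,
                  merge_cor_threshold = merge_cor_threshold,
                  trait_cor_threshold = trait_cor_threshold, alpha = alpha,
                  n_permutations = as.integer(n_permutations),
                  seed = as.integer(seed)),
    call = match.call()
  ), class = "coab")
}

#' @export
print.coab <- function(x, ...) {
  cat("Weighted co-abundance network\n")
  cat(sprintf("  %d proteins, %d samples; beta = %s (%s)\n",
              length(x$labels), ncol(x$eigengenes %||% matrix(ncol = 0)),
              format(x$beta), x$params$network_type))
  k <- length(x$module_sizes)
  cat(sprintf("  %d module(s): %s; %d unassigned\n", k,
              if (k) paste0(names(x$module_sizes), "=", x$module_sizes,
                            collapse = ", ") else "none",
              sum(x$labels == 0)))
  if (!is.null(x$module_trait)) {
    sig <- x$module_trait[x$module_trait$significant, , drop = FALSE]
    cat(sprintf("  %d significant module-trait pair(s)\n", nrow(sig)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.coab <- function(object, ...) {
  structure(list(
    module_sizes = object$module_sizes,
    beta = object$beta,
    n_unassigned = sum(object$labels == 0),
    module_trait = object$module_trait,
    hubs = object$hubs
  ), class = "summary.coab")
}

#' @export
print.summary.coab <- function(x, ...) {
  cat("Module sizes:\n"); print(x$module_sizes)
  cat("Unassigned proteins:", x$n_unassigned, "\n")
  if (!is.null(x$hubs)) {
    cat("\nHub proteins:\n")
    print(x$hubs[, c("module", "hub_protein", "module_membership_score")])
  }
  if (!is.null(x$module_trait)) {
    cat("\nModule-trait correlations:\n")
    print(x$module_trait, digits = 3)
  }
  invisible(x)
}

#' Plot a fitted co-abundance network
#'
#' @param x A `"coab"` object.
#' @param which `"dendrogram"` (clustering tree with module labels),
#'   `"heatmap"` (module-trait correlation matrix), or `"scan"`
#'   (scale-free fit vs power, when `beta = "auto"` was used).
#' @param ... Further graphical arguments (ignored).
#' @export
plot.coab <- function(x, which = c("dendrogram", "heatmap", "scan"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    plot(x$tree, labels = FALSE, hang = -1,
         main = "TOM dissimilarity clustering", xlab = "", sub = "")
  } else if (which == "heatmap") {
    if (is.null(x$module_trait)) stop("no traits were supplied", call. = FALSE)
    mt <- x$module_trait
    mods <- sort(unique(mt$module)); trs <- unique(mt$trait)
    z <- matrix(NA_real_, length(mods), length(trs),
                dimnames = list(mods, trs))
    z[cbind(match(mt$module, mods), match(mt$trait, trs))] <- mt$r
    graphics::image(seq_along(trs), seq_along(mods), t(z), zlim = c(-1, 1),
                    col = grDevices::hcl.colors(41, "Blue-Red 2"),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Module-trait correlations")
    graphics::axis(1, seq_along(trs), trs, las = 2)
    graphics::axis(2, seq_along(mods), mods, las = 1)
    graphics::text(rep(seq_along(trs), each = length(mods)),
                   rep(seq_along(mods), length(trs)),
                   sprintf("%.2f", z))
  } else {
    if (is.null(x$scan)) stop("beta was fixed; no scan available", call. = FALSE)
    plot(x$scan$power, x$scan$signed_r_squared, type = "b",
         xlab = "soft-thresholding power",
         ylab = expression("signed scale-free fit" ~ R^2))
    graphics::abline(h = 0.8, lty = 2)
  }
  invisible(x)
}
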