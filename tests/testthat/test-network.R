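test_that("correlation matrix matches the direct formula and flags degenerate rows", {
  m <- random_log2_matrix(10, 18, seed = 1)
  v <- unclass(m)
  C <- correlation_matrix(m)
  expect_equal(unname(diag(C)), rep(1, 10))
  # direct covariance/sd oracle on a few pairs
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    i <- pair[1]; j <- pair[2]
    r <- cov(v[i, ], v[j, ]) / (sd(v[i, ]) * sd(v[j, ]))
    expect_equal(C[i, j], r, tolerance = 1e-10)
  }
  # anti-correlation
  v2 <- rbind(x = v[1, ], y = -v[1, ])
  C2 <- correlation_matrix(abundance_matrix(v2, "log2"))
  expect_equal(C2["x", "y"], -1, tolerance = 1e-12)
  v3 <- v; v3[2, ] <- 7
  expect_error(correlation_matrix(abundance_matrix(v3, "log2")),
               "zero-variance.*P002")
})

test_that("soft adjacency follows |cor|^beta with zero diagonal", {
  C <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0.25, -0.5, 0.25, 1), 3, 3)
  A <- soft_adjacency(C, 6)
  expect_equal(A[1, 2], 0.5^6)          # 0.015625
  expect_equal(A[1, 3], 0.5^6)          # unsigned symmetry
  expect_equal(unname(diag(A)), rep(0, 3))
  expect_equal(soft_adjacency(C, 1)[1, 3], 0.5)  # beta = 1 gives |cor|
  As <- soft_adjacency(C, 2, type = "signed")
  expect_equal(As[1, 3], ((1 - 0.5) / 2)^2)
  expect_error(soft_adjacency(C, 0.5), ">= 1")
})

test_that("scale-free fit is exact on log-linear binned connectivity", {
  # counts 8,4,2,1 at k = 2,4,8,16: log-frequency exactly linear in log k
  k <- rep(c(2, 4, 8, 16), times = c(8, 4, 2, 1))
  expect_equal(scale_free_fit(k, n_bins = 10), 1, tolerance = 1e-6)
  # increasing frequency with k -> non-positive signed R^2
  k2 <- rep(c(2, 4, 8, 16), times = c(1, 2, 4, 8))
  expect_lte(scale_free_fit(k2, n_bins = 10), 0)
  expect_error(scale_free_fit(rep(3, 10)), "undefined")
})

test_that("scale-free fit equals a direct least-squares oracle on binned data", {
  set.seed(2)
  k <- runif(400, 0.1, 30)
  n_bins <- 10
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  mk <- tapply(k, bin, mean); fr <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mk)
  x <- log10(mk[keep]); y <- log10(fr[keep])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- cor(x, y)^2
  expect_equal(scale_free_fit(k, n_bins), -sign(slope) * r2,
               tolerance = 1e-10)
})

test_that("power selection takes the first crossing or falls back to argmax", {
  scan <- data.frame(power = c(2, 4, 6, 8),
                     signed_r_squared = c(0.2, 0.5, 0.85, 0.9))
  expect_equal(select_soft_threshold(scan, 0.8)$beta, 6)
  expect_true(select_soft_threshold(scan, 0.8)$reached_target)
  expect_warning(sel <- select_soft_threshold(scan, 0.99), "best-fitting")
  expect_equal(sel$beta, 8)
  expect_false(sel$reached_target)
})

test_that("soft-threshold scan varies non-trivially on modular data", {
  for (s in 1:5) {
    sim <- generate_dataset(syn_params(n_proteins = 120,
                                       module_sizes = c(40L, 40L),
                                       trend_kinds = c("increasing", "peaked"),
                                       trait_specs = list(), seed = s))
    sel <- suppressWarnings(pick_soft_threshold(sim$abundance, 1:12))
    expect_true(sel$beta %in% 1:12)
    expect_gt(diff(range(sel$scan$signed_r_squared, na.rm = TRUE)), 0.01)
  }
})

test_that("TOM handles its closed-form corner cases", {
  # complete triangle: every omega = (1+1)/(2+1-1) = 1
  a <- matrix(1, 3, 3); diag(a) <- 0
  w <- topological_overlap(a)
  expect_equal(w, matrix(1, 3, 3), ignore_attr = TRUE)
  # isolated node: omega = 0 against every other node
  a2 <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  w2 <- topological_overlap(a2)
  expect_equal(w2[3, 1], 0)
  expect_equal(w2[3, 2], 0)
  expect_equal(diag(w2), rep(1, 3))
  expect_error(topological_overlap(matrix(c(1, 0, 0, 1), 2, 2)), "diagonal")
})

test_that("TOM equals the brute-force triple-loop oracle on random graphs", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("module detection recovers planted blocks and ignores noise", {
  # two perfectly coherent blocks
  set.seed(9)
  s1 <- rnorm(12); s2 <- rnorm(12)
  v <- rbind(t(sapply(1:8, function(i) 20 + i * s1)),
             t(sapply(1:8, function(i) 5 + i * s2)))
  dimnames(v) <- list(sprintf("P%02d", 1:16), sprintf("s%02d", 1:12))
  m <- abundance_matrix(v, "log2")
  A <- soft_adjacency(correlation_matrix(m), 6)
  det <- detect_modules(topological_overlap(A), min_module_size = 5)
  expect_equal(length(unique(det$labels[det$labels > 0])), 2)
  expect_equal(length(unique(det$labels[1:8])), 1)
  expect_equal(length(unique(det$labels[9:16])), 1)
  expect_false(det$labels[1] == det$labels[9])

  # pure noise: mostly unassigned at min size 30
  unassigned <- sapply(1:10, function(s) {
    mm <- random_log2_matrix(200, 18, seed = 100 + s)
    A <- soft_adjacency(correlation_matrix(mm), 6)
    d <- detect_modules(topological_overlap(A), min_module_size = 30)
    mean(d$labels == 0)
  })
  expect_gte(mean(unassigned >= 0.8), 0.8)

  # min_module_size larger than the matrix -> all unassigned with warning
  mm <- random_log2_matrix(10, 8)
  A <- soft_adjacency(correlation_matrix(mm), 6)
  expect_warning(d0 <- detect_modules(topological_overlap(A),
                                      min_module_size = 50), "unassigned")
  expect_true(all(d0$labels == 0))
})

test_that("module detection is invariant to protein order", {
  sim <- generate_dataset(syn_params(n_proteins = 90,
                                     module_sizes = c(30L, 30L),
                                     trend_kinds = c("increasing", "decreasing"),
                                     trait_specs = list(), seed = 6))
  m <- sim$abundance
  fit_labels <- function(mm) {
    A <- soft_adjacency(correlation_matrix(mm), 6)
    detect_modules(topological_overlap(A), min_module_size = 10)$labels
  }
  l1 <- fit_labels(m)
  set.seed(1)
  perm <- sample(nrow(m))
  l2 <- fit_labels(m[perm, ])
  expect_equal(l2[names(l1)], l1)
})

test_that("eigengenes summarize modules with the documented orientation", {
  # rank-1 module: eigengene reproduces the common profile
  s <- as.numeric(scale(rnorm(10)))
  v <- t(sapply(1:6, function(i) 20 + i * s))
  dimnames(v) <- list(sprintf("P%d", 1:6), sprintf("s%02d", 1:10))
  m <- abundance_matrix(v, "log2")
  labels <- setNames(rep(1L, 6), rownames(v))
  me <- module_eigengenes(m, labels)
  expect_equal(abs(cor(me[1, ], s)), 1, tolerance = 1e-10)
  expect_equal(mean(me[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(me[1, ]), 1, tolerance = 1e-12)
  # orientation: non-negative correlation with the mean member profile
  xs <- t(scale(t(v)))
  expect_gte(cor(me[1, ], colMeans(xs)), 0)

  # planted module: eigengene recovers the seed profile
  cors <- sapply(1:10, function(s) {
    sim <- generate_dataset(syn_params(n_proteins = 50, module_sizes = 50L,
                                       trend_kinds = "increasing",
                                       within_module_cor = 0.8,
                                       trait_specs = list(), seed = s))
    me <- module_eigengenes(sim$abundance, sim$truth$module_labels)
    abs(cor(me[1, ], sim$truth$seed_profiles[1, ]))
  })
  expect_gte(median(cors), 0.95)
})

test_that("modules merge iff their eigengene correlation exceeds the threshold", {
  build_two_modules <- function(rho, seed = 31) {
    set.seed(seed)
    n <- 18
    z1 <- as.numeric(scale(rnorm(n)))
    z2r <- rnorm(n)
    z2 <- as.numeric(scale(rho * z1 + sqrt(1 - rho^2) *
                             as.numeric(scale(resid(lm(z2r ~ z1))))))
    v <- rbind(t(sapply(1:12, function(i) 20 + z1 + rnorm(n, 0, 0.05))),
               t(sapply(1:12, function(i) 20 + z2 + rnorm(n, 0, 0.05))))
    dimnames(v) <- list(sprintf("P%02d", 1:24), sprintf("s%02d", 1:n))
    list(m = abundance_matrix(v, "log2"),
         labels = setNames(rep(c(1L, 2L), each = 12), rownames(v)))
  }
  close_pair <- build_two_modules(0.95)
  merged <- merge_close_modules(close_pair$m, close_pair$labels, 0.8)
  expect_equal(length(unique(merged$labels[merged$labels > 0])), 1)
  expect_equal(merged$n_merges, 1L)

  far_pair <- build_two_modules(0.3)
  kept <- merge_close_modules(far_pair$m, far_pair$labels, 0.8)
  expect_equal(length(unique(kept$labels[kept$labels > 0])), 2)
  expect_equal(kept$n_merges, 0L)

  # threshold 1 never merges generic data
  none <- merge_close_modules(close_pair$m, close_pair$labels, 1)
  expect_equal(length(unique(none$labels[none$labels > 0])), 2)
})

test_that("kME is the protein-eigengene correlation, bounded in [-1, 1]", {
  sim <- generate_dataset(syn_params(n_proteins = 60, module_sizes = 30L,
                                     trend_kinds = "peaked",
                                     trait_specs = list(), seed = 2))
  me <- module_eigengenes(sim$abundance, sim$truth$module_labels)
  kme <- module_membership(sim$abundance, me)
  expect_true(all(kme >= -1 & kme <= 1))
  # protein equal to the eigengene -> kME 1
  v <- rbind(unclass(sim$abundance), EIG = 20 + me[1, ])
  kme2 <- module_membership(abundance_matrix(v, "log2"), me)
  expect_equal(kme2["EIG", "M1"], 1, tolerance = 1e-10)
  # residualized construction -> kME ~ 0
  set.seed(3)
  ortho <- resid(lm(rnorm(18) ~ me[1, ]))
  v3 <- rbind(unclass(sim$abundance), ORTH = 20 + ortho)
  kme3 <- module_membership(abundance_matrix(v3, "log2"), me)
  expect_lt(abs(kme3["ORTH", "M1"]), 1e-10)
})

test_that("module-trait correlation matches the t-distribution closed form", {
  set.seed(8)
  me <- matrix(as.numeric(scale(rnorm(18))), 1, 18,
               dimnames = list("M1", sprintf("s%02d", 1:18)))
  tr <- matrix(rnorm(18), 18, 1,
               dimnames = list(colnames(me), "trait"))
  res <- module_trait_correlation(me, tr)
  r <- cor(me[1, ], tr[, 1])
  tstat <- r * sqrt(16 / (1 - r^2))
  expect_equal(res$p_value, 2 * pt(abs(tstat), 16, lower.tail = FALSE),
               tolerance = 1e-12)
  # r = 0.7, n = 18: t ~ 3.92, p ~ 0.0012
  t_ref <- 0.7 * sqrt(16 / (1 - 0.49))
  expect_lt(abs(t_ref - 3.92), 0.01)
  expect_lt(abs(2 * pt(t_ref, 16, lower.tail = FALSE) - 0.0012), 1e-4)
  # trait equal to the eigengene: r = 1, significant
  tr2 <- cbind(tr, self = me[1, ])
  res2 <- module_trait_correlation(me, tr2)
  self_row <- res2[res2$trait == "self", ]
  expect_equal(self_row$r, 1, tolerance = 1e-12)
  expect_true(self_row$significant)
  expect_error(module_trait_correlation(me, cbind(flat = rep(1, 18))),
               "sample rownames")
  tr3 <- tr; tr3[, 1] <- 5
  expect_error(module_trait_correlation(me, tr3), "constant trait")
})

test_that("permutation p attains its floor for a self-trait and honors B", {
  set.seed(13)
  me <- matrix(as.numeric(scale(rnorm(18))), 1, 18,
               dimnames = list("M1", sprintf("s%02d", 1:18)))
  tr <- matrix(me[1, ], 18, 1, dimnames = list(colnames(me), "self"))
  res <- permutation_validation(me, tr, n_permutations = 1000, seed = 7)
  expect_equal(res$perm_p, 1 / 1001, tolerance = 1e-12)
  # B = 1 admits only two p values
  res1 <- permutation_validation(me, tr, n_permutations = 1, seed = 7)
  expect_true(res1$perm_p %in% c(0.5, 1))
})

test_that("permutation test is calibrated under the null", {
  sim <- generate_dataset(syn_params(n_proteins = 40, module_sizes = 20L,
                                     trend_kinds = "increasing",
                                     trait_specs = list(), seed = 1))
  me <- module_eigengenes(sim$abundance, sim$truth$module_labels)
  set.seed(55)
  rej <- mean(replicate(400, {
    tr <- matrix(rnorm(18), 18, 1, dimnames = list(colnames(me), "null"))
    permutation_validation(me, tr, n_permutations = 199,
                           seed = sample.int(1e6, 1))$perm_p <= 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("parametric and permutation p-values rank pairs the same way", {
  sim <- generate_dataset(syn_params(seed = 4))
  fit <- coab(sim$abundance, sim$traits, min_module_size = 10,
              n_permutations = 500, seed = 4)
  mt <- fit$module_trait
  expect_gte(cor(rank(mt$p_value), rank(mt$perm_p), method = "spearman"), 0.9)
})

test_that("hubs have maximal own-module kME with documented tie-breaks", {
  sim <- generate_dataset(syn_params(n_proteins = 40, module_sizes = 20L,
                                     trend_kinds = "increasing",
                                     trait_specs = list(), seed = 10))
  m <- sim$abundance
  labels <- sim$truth$module_labels
  me <- module_eigengenes(m, labels)
  kme <- module_membership(m, me)
  A <- soft_adjacency(correlation_matrix(m), 6)
  hubs <- identify_hubs(labels, kme, A, top_n = 5)
  members <- names(labels)[labels == 1]
  expect_true(hubs$hub_protein %in% members)
  expect_equal(hubs$module_membership_score,
               max(kme[members, "M1"]), tolerance = 1e-12)
  expect_equal(nrow(hubs$neighbors[[1]]), 5)
  # top_n larger than the module clips to all other members
  hubs_all <- identify_hubs(labels, kme, A, top_n = 100)
  expect_equal(nrow(hubs_all$neighbors[[1]]), 19)
  # duplicated profiles tie in kME -> lexicographically first id wins
  v <- unclass(m)
  v2 <- rbind(v, AAA = v[hubs$hub_protein, ])
  labels2 <- c(labels, AAA = 1L)
  m2 <- abundance_matrix(v2, "log2")
  me2 <- module_eigengenes(m2, labels2)
  kme2 <- module_membership(m2, me2)
  A2 <- soft_adjacency(correlation_matrix(m2), 6)
  hubs2 <- identify_hubs(labels2, kme2, A2)
  expect_equal(hubs2$hub_protein, "AAA")
})

test_that("a planted seed-equal protein is usually the hub", {
  wins <- sapply(1:10, function(s) {
    sim <- generate_dataset(syn_params(n_proteins = 30, module_sizes = 30L,
                                       trend_kinds = "increasing",
                                       trait_specs = list(), seed = 200 + s))
    v <- unclass(sim$abundance)
    v["P0001", ] <- 20 + sim$truth$seed_profiles[1, ]  # exact seed copy
    m <- abundance_matrix(v, "log2")
    labels <- sim$truth$module_labels
    me <- module_eigengenes(m, labels)
    kme <- module_membership(m, me)
    A <- soft_adjacency(correlation_matrix(m), 6)
    identify_hubs(labels, kme, A)$hub_protein == "P0001"
  })
  expect_gte(mean(wins), 0.6)
})

test_that("coab end-to-end fit returns a coherent object", {
  sim <- generate_dataset(syn_params(seed = 5))
  fit <- coab(sim$abundance, sim$traits, min_module_size = 10,
              n_permutations = 100, seed = 5)
  expect_s3_class(fit, "coab")
  expect_equal(length(fit$labels), 500)
  expect_true(all(fit$module_sizes >= 10))
  expect_equal(nrow(fit$eigengenes), length(fit$module_sizes))
  expect_equal(dim(fit$kME), c(500L, length(fit$module_sizes)))
  expect_true(all(c("r", "p_value", "perm_p", "significant") %in%
                    colnames(fit$module_trait)))
  expect_output(print(fit), "co-abundance network")
  expect_output(print(summary(fit)), "Hub proteins")
})
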