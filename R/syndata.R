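#' Sample design for a staged study
#'
#' Builds the sample-to-stage mapping for a developmental time-course with a
#' fixed number of biological replicates per stage. Sample ids are
#' deterministic functions of (stage, replicate), e.g. `"d060_r1"`.
#'
#' @param stage_days Integer vector of stage ages in days, strictly
#'   increasing. Default is the six postnatal stages 60..360 d.
#' @param reps_per_stage Replicates per stage (default 3).
#' @return A data.frame with columns `sample_id`, `stage_days`, `replicate`;
#'   one row per sample.
#' @examples
#' d <- generate_design()        # 6 stages x 3 replicates = 18 samples
#' nrow(d)
#' @export
generate_design <- function(stage_days = c(60L, 120L, 180L, 240L, 300L, 360L),
                            reps_per_stage = 3L) {
  if (length(stage_days) == 0) stop("stage_days must be non-empty", call. = FALSE)
  if (any(diff(stage_days) <= 0))
    stop("stage_days must be strictly increasing", call. = FALSE)
  if (reps_per_stage < 1) stop("reps_per_stage must be >= 1", call. = FALSE)
  stage <- rep(stage_days, each = reps_per_stage)
  rep_i <- rep(seq_len(reps_per_stage), times = length(stage_days))
  data.frame(
    sample_id = sprintf("d%03d_r%d", stage, rep_i),
    stage_days = as.integer(stage),
    replicate = as.integer(rep_i),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the synthetic dataset generator
#'
#' The defaults emulate the study design the pipeline is built for: 18
#' samples (6 stages x 3 replicates), 500 proteins with 4 planted
#' co-abundance modules of 50 proteins each, module stage-trends
#' increasing / increasing / decreasing / peaked (peak at 300 d), a target
#' protein-to-seed correlation of 0.8 within modules, and one carcass trait
#' coupled to each module with |loading| 0.9 (signs alternating so
#' fat-associated and lean-associated modules carry opposite correlation
#' signs), plus one uncoupled trait.
#'
#' @param n_proteins Total number of proteins.
#' @param module_sizes Integer vector of planted module sizes; their sum must
#'   not exceed `n_proteins`. Proteins beyond the modules are background noise.
#' @param trend_kinds Character vector, one of `"increasing"`, `"decreasing"`,
#'   `"peaked"`, `"flat"` per module. `"flat"` modules co-vary around a random
#'   (stage-unrelated) seed profile.
#' @param peak_stage Stage (days) at which `"peaked"` trends attain their
#'   maximum (default 300).
#' @param within_module_cor Target correlation in (0,1) between a member
#'   protein and its module seed profile.
#' @param trend_share Fraction in (0,1\] of a seed profile's variance carried
#'   by its deterministic stage trend; the remainder is a module-specific
#'   replicate-level component, centered within each stage so stage means
#'   follow the trend exactly. Without it, modules sharing a trend kind would
#'   have identical seeds and be unrecoverable as separate modules. The
#'   default 0.3 keeps population seed-profile correlations (at most
#'   `trend_share` in magnitude between any two trends) clearly below the 0.8
#'   eigengene merge criterion even after sampling noise at 18 samples, so the
#'   planted modules are distinct modules under the pipeline's own
#'   definition.
#' @param trait_specs List of trait specifications, each a list with fields
#'   `name`, `module` (module index or `NA` for an uncoupled trait),
#'   `loading` in \[-1, 1\], and optionally `noise_sd` (default
#'   `sqrt(1 - loading^2)` so the expected trait-eigengene correlation equals
#'   the loading). `NULL` (the default) builds one trait per module with
#'   |loading| 0.9 and alternating signs, plus an uncoupled trait.
#' @param stage_days,reps_per_stage Passed to [generate_design()].
#' @param background_sd Standard deviation of protein profiles around their
#'   baseline (log2 units); also the amplitude of module signals.
#' @param baseline_log2 Mean log2 intensity of the proteome.
#' @param seed Integer RNG seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `"syn_params"`.
#' @export
syn_params <- function(n_proteins = 500L,
                       module_sizes = rep(50L, 4L),
                       trend_kinds = c("increasing", "increasing",
                                       "decreasing", "peaked"),
                       peak_stage = 300L,
                       within_module_cor = 0.8,
                       trend_share = 0.3,
                       trait_specs = NULL,
                       stage_days = c(60L, 120L, 180L, 240L, 300L, 360L),
                       reps_per_stage = 3L,
                       background_sd = 1,
                       baseline_log2 = 20,
                       seed = 1L) {
  n_modules <- length(module_sizes)
  if (n_modules > 0 && sum(module_sizes) > n_proteins)
    stop("sum(module_sizes) exceeds n_proteins", call. = FALSE)
  if (any(module_sizes < 1)) stop("module sizes must be positive", call. = FALSE)
  if (length(trend_kinds) != n_modules)
    stop("need one trend kind per module", call. = FALSE)
  ok <- trend_kinds %in% c("increasing", "decreasing", "peaked", "flat")
  if (!all(ok))
    stop("invalid trend kind: ", paste(trend_kinds[!ok], collapse = ", "),
         call. = FALSE)
  if (within_module_cor <= 0 || within_module_cor >= 1)
    stop("within_module_cor must lie strictly in (0, 1)", call. = FALSE)
  if (trend_share <= 0 || trend_share > 1)
    stop("trend_share must lie in (0, 1]", call. = FALSE)
  if (is.null(trait_specs))
    trait_specs <- default_trait_specs(n_modules)
  for (ts in trait_specs) {
    if (!is.na(ts$module) && (ts$module < 1 || ts$module > n_modules))
      stop("trait '", ts$name, "' references a non-existent module",
           call. = FALSE)
    if (abs(ts$loading) > 1)
      stop("trait loading must lie in [-1, 1]", call. = FALSE)
  }
  if (background_sd <= 0) stop("background_sd must be positive", call. = FALSE)
  structure(list(
    n_proteins = as.integer(n_proteins), module_sizes = as.integer(module_sizes),
    trend_kinds = trend_kinds, peak_stage = as.integer(peak_stage),
    within_module_cor = within_module_cor, trend_share = trend_share,
    trait_specs = trait_specs,
    stage_days = as.integer(stage_days),
    reps_per_stage = as.integer(reps_per_stage),
    background_sd = background_sd, baseline_log2 = baseline_log2,
    seed = as.integer(seed)
  ), class = "syn_params")
}

# default traits: one per module with |loading| 0.9, alternating signs (the
# carcass-trait structure where fat- and lean-associated modules correlate
# with opposite signs), plus one uncoupled trait
default_trait_specs <- function(n_modules) {
  base_names <- c("fat_percent", "lean_percent", "bone_percent", "backfat_mm")
  specs <- lapply(seq_len(n_modules), function(m) {
    nm <- if (m <= length(base_names)) base_names[m] else paste0("trait_", m)
    list(name = nm, module = m, loading = 0.9 * (-1)^(m - 1))
  })
  c(specs, list(list(name = "carcass_weight", module = NA, loading = 0)))
}

# module seed profile: deterministic stage trend (ramp / reversed ramp /
# triangle) carrying `trend_share` of the variance, plus a module-specific
# replicate-level component centered within each stage (so stage means equal
# the trend exactly); standardized to zero mean / unit sd across samples.
# "flat" seeds are pure replicate-level variation (no stage trend).
trend_profile <- function(kind, stage_days, reps_per_stage, peak_stage,
                          trend_share) {
  k <- seq_along(stage_days)
  base <- switch(kind,
    increasing = k,
    decreasing = -k,
    peaked = -abs(k - which.min(abs(stage_days - peak_stage))),
    flat = NULL
  )
  n <- length(stage_days) * reps_per_stage
  z <- stats::rnorm(n)
  if (reps_per_stage > 1) {
    stage <- rep(k, each = reps_per_stage)
    z <- z - stats::ave(z, stage)          # stage means exactly 0
  }
  if (is.null(base)) return(as.numeric(scale(z)))
  trend <- as.numeric(scale(rep(base, each = reps_per_stage)))
  z <- if (stats::sd(z) > 0) as.numeric(scale(z)) else z
  as.numeric(scale(sqrt(trend_share) * trend + sqrt(1 - trend_share) * z))
}

#' Generate a synthetic proteomics dataset with planted modules
#'
#' Single-common-factor signal model: a member protein of module `m` with
#' seed profile `s_m` is
#' `baseline_i + background_sd * (r * s_m + sqrt(1 - r^2) * e)` with
#' `e ~ N(0, I)` and `r = within_module_cor`, so the population correlation of
#' every member with the seed is exactly `r` and the expected pairwise
#' within-module correlation is `r^2`. Background proteins are independent
#' noise around their baseline. Each coupled trait is
#' `loading * s_m + N(0, noise_sd)` on the standardized scale; uncoupled
#' traits are pure noise.
#'
#' @param params A [syn_params()] object.
#' @param scale Output scale: `"log2"` (default) or `"raw"` (values are
#'   exponentiated, `2^x`, to exercise the log2 entry point).
#' @return A list with components `abundance` ([abundance_matrix()]),
#'   `traits` (sample x trait numeric matrix), `design` (data.frame from
#'   [generate_design()]) and `truth` (list with `module_labels` — integer
#'   per protein, 0 = background —, `seed_profiles` (module x sample),
#'   `trait_loadings`, `trait_modules`, `seed`).
#' @examples
#' sim <- generate_dataset(syn_params(n_proteins = 100,
#'                                    module_sizes = c(20, 20),
#'                                    trend_kinds = c("increasing", "peaked"),
#'                                    trait_specs = list(), seed = 7))
#' dim(sim$abundance)
#' @export
generate_dataset <- function(params = syn_params(), scale = c("log2", "raw")) {
  stopifnot(inherits(params, "syn_params"))
  scale <- match.arg(scale)
  set.seed(params$seed)
  design <- generate_design(params$stage_days, params$reps_per_stage)
  n_samp <- nrow(design)
  n_mod <- length(params$module_sizes)
  p <- params$n_proteins
  r <- params$within_module_cor

  seeds <- matrix(0, nrow = n_mod, ncol = n_samp,
                  dimnames = list(if (n_mod) paste0("M", seq_len(n_mod)),
                                  design$sample_id))
  for (m in seq_len(n_mod))
    seeds[m, ] <- trend_profile(params$trend_kinds[m], params$stage_days,
                                params$reps_per_stage, params$peak_stage,
                                params$trend_share)

  labels <- integer(p)
  if (n_mod > 0)
    labels[seq_len(sum(params$module_sizes))] <-
      rep(seq_len(n_mod), times = params$module_sizes)
  ids <- sprintf("P%04d", seq_len(p))
  names(labels) <- ids

  baseline <- stats::rnorm(p, params$baseline_log2, 1.5)
  noise <- matrix(stats::rnorm(p * n_samp), p, n_samp)
  x <- matrix(0, p, n_samp, dimnames = list(ids, design$sample_id))
  for (i in seq_len(p)) {
    m <- labels[i]
    prof <- if (m > 0) r * seeds[m, ] + sqrt(1 - r^2) * noise[i, ] else noise[i, ]
    x[i, ] <- baseline[i] + params$background_sd * prof
  }

  n_tr <- length(params$trait_specs)
  traits <- matrix(0, n_samp, n_tr,
                   dimnames = list(design$sample_id,
                                   vapply(params$trait_specs, `[[`, "", "name")))
  loadings <- numeric(n_tr)
  modules <- rep(NA_integer_, n_tr)
  for (j in seq_len(n_tr)) {
    ts <- params$trait_specs[[j]]
    noise_sd <- if (!is.null(ts$noise_sd)) ts$noise_sd else
      sqrt(max(0, 1 - ts$loading^2))
    traits[, j] <- if (!is.na(ts$module))
      ts$loading * seeds[ts$module, ] + stats::rnorm(n_samp, 0, noise_sd)
    else
      stats::rnorm(n_samp, 0, max(noise_sd, 1))
    loadings[j] <- ts$loading
    modules[j] <- if (is.na(ts$module)) NA_integer_ else as.integer(ts$module)
  }

  if (scale == "raw") x <- 2^x
  list(
    abundance = abundance_matrix(x, scale = scale),
    traits = traits,
    design = design,
    truth = list(module_labels = labels, seed_profiles = seeds,
                 trait_loadings = loadings, trait_modules = modules,
                 seed = params$seed)
  )
}

#' Write a synthetic dataset to a directory as TSV + JSON sidecar
#'
#' @param sim Output of [generate_dataset()].
#' @param params The [syn_params()] used (stored as JSON sidecar).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "abundance.tsv"),
    design = file.path(dir, "design.tsv"),
    traits = file.path(dir, "traits.tsv"),
    truth = file.path(dir, "truth_labels.tsv"),
    params = file.path(dir, "params.json")
  )
  write_abundance_tsv(sim$abundance, paths["matrix"])
  utils::write.table(sim$design, paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$traits, paths["traits"], id_col = "sample_id")
  utils::write.table(
    data.frame(protein_id = names(sim$truth$module_labels),
               module = sim$truth$module_labels),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(params), paths["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
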