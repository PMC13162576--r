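#' Read a protein x sample abundance matrix from TSV
#'
#' Expects a header row of sample ids and protein ids in the first column.
#' Duplicate protein ids, ragged rows and non-numeric cells are errors; empty
#' cells are parsed as missing.
#'
#' @param path TSV file path.
#' @param scale Scale flag of the stored values (`"log2"` or `"raw"`).
#' @return An [abundance_matrix()].
#' @export
read_abundance_tsv <- function(path, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  if (ncol(d) < 2) stop("matrix TSV needs an id column plus samples", call. = FALSE)
  ids <- d[[1]]
  if (anyDuplicated(ids))
    stop("duplicated protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  v <- matrix(NA_real_, nrow(d), ncol(d) - 1,
              dimnames = list(ids, colnames(d)[-1]))
  for (j in 2:ncol(d)) {
    col <- d[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad[1]], bad[1], colnames(d)[j]), call. = FALSE)
    v[, j - 1] <- num
  }
  abundance_matrix(v, scale = scale)
}

#' Write an abundance matrix to TSV
#'
#' @param m An [abundance_matrix()] (or plain matrix).
#' @param path Output file path.
#' @export
write_abundance_tsv <- function(m, path) {
  write_matrix_tsv(ab_values(m), path, id_col = "protein_id")
}

# generic matrix writer: first column = rownames under `id_col`
write_matrix_tsv <- function(v, path, id_col = "id") {
  d <- data.frame(rownames(v), v, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c(id_col, colnames(v))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read the sample design table
#'
#' TSV with columns `sample_id`, `stage_days`, `replicate`.
#'
#' @param path TSV file path.
#' @return Data.frame as produced by [generate_design()].
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage_days")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("design table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample ids in design table", call. = FALSE)
  d
}

#' Read the sample x trait table
#'
#' TSV with `sample_id` in the first column, one numeric column per trait.
#' Extra trait columns are preserved in file order.
#'
#' @param path TSV file path.
#' @return Numeric matrix with sample rownames.
#' @export
read_trait_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- d[[1]]
  if (anyDuplicated(ids))
    stop("duplicated sample ids in trait table", call. = FALSE)
  v <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(v)) stop("trait columns must be numeric", call. = FALSE)
  rownames(v) <- ids
  v
}

#' Run the full analysis pipeline
#'
#' Drives normalize -> differential abundance -> ordination -> network ->
#' (optional) enrichment from a configuration list or JSON/YAML file, writing
#' every stage's outputs plus a JSON manifest (parameters, seeds, input
#' checksums, output checksums) and a log to an output directory. Reruns with
#' an identical configuration reproduce all result files bit-identically (the
#' log carries the only timestamps).
#'
#' Config fields: `matrix` (path, required), `design` (path, required),
#' `traits`, `annotations` (GMT or two-column TSV), `out_dir` (required),
#' `matrix_scale` ("raw" or "log2"), `span`, `iterations`, `missing_policy`,
#' `alpha`, `dap_threshold` ("q" or "p"), `n_perm_ordination`, `pca_subset`
#' ("all" or "dap"), `beta` ("auto" or a power), `scale_free_target`,
#' `network_type`, `cut_height`, `min_module_size`, `merge_cor_threshold`,
#' `trait_cor_threshold`, `n_permutations`, `seed`.
#'
#' @param config A named list, or path to a JSON (or YAML, if the yaml
#'   package is installed) file with the fields above.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  def <- list(matrix_scale = "raw", span = 0.7, iterations = 3L,
              missing_policy = "drop_any", alpha = 0.05,
              dap_threshold = "q", n_perm_ordination = 999L,
              pca_subset = "all", beta = "auto", scale_free_target = 0.8,
              network_type = "unsigned", cut_height = 0.99,
              min_module_size = 30L, merge_cor_threshold = 0.8,
              trait_cor_threshold = 0.7, n_permutations = 1000L, seed = 1L,
              top_n_neighbors = 10L)
  cfg <- utils::modifyList(def, cfg)
  for (f in c("matrix", "design", "out_dir"))
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required",
                                call. = FALSE)
  if (cfg$n_permutations < 1 || cfg$n_perm_ordination < 1)
    stop("permutation counts must be >= 1", call. = FALSE)
  for (f in c("matrix", "design", "traits", "annotations")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config path for '", f, "' does not exist: ", p, call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  run_stage <- function(stage, expr) {
    logf("stage %s: start", stage)
    tryCatch(expr, error = function(e) {
      logf("stage %s: ERROR %s", stage, conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           "; completed outputs remain in ", cfg$out_dir, call. = FALSE)
    })
  }

  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(cfg$out_dir, name)
    writer(p)
    paths <<- c(paths, p)
    logf("wrote %s", name)
  }

  # --- preprocess ---
  m <- run_stage("normalize", {
    m <- read_abundance_tsv(cfg$matrix, scale = cfg$matrix_scale)
    design <- read_design_tsv(cfg$design)
    m <- filter_missing(m, policy = cfg$missing_policy)
    if (ab_scale(m) == "raw") m <- log2_transform(m)
    m <- cyclic_loess_normalize(m, span = cfg$span,
                                iterations = cfg$iterations)
    emit("normalized.tsv", function(p) write_abundance_tsv(m, p))
    m
  })
  design <- read_design_tsv(cfg$design)
  traits <- if (!is.null(cfg$traits)) read_trait_tsv(cfg$traits)

  # --- differential abundance ---
  diff <- run_stage("diff", {
    diff <- anova_per_protein(m, design)
    emit("anova.tsv", function(p)
      utils::write.table(diff, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    gate <- if (cfg$dap_threshold == "q") diff$q_value else diff$p_value
    daps <- diff$protein_id[!is.na(gate) & gate < cfg$alpha]
    if (length(daps)) {
      pw <- do.call(rbind, lapply(daps, function(pr)
        tukey_hsd(m, design, pr)))
      emit("tukey_pairwise.tsv", function(p)
        utils::write.table(pw, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }
    logf("%d/%d proteins pass %s < %g", length(daps), nrow(diff),
         cfg$dap_threshold, cfg$alpha)
    attr(diff, "daps") <- daps
    diff
  })

  # --- ordination ---
  run_stage("ordinate", {
    subset <- if (cfg$pca_subset == "dap") attr(diff, "daps")
    if (!is.null(subset) && length(subset) == 0) {
      logf("no proteins pass the DAP gate; PCA falls back to all proteins")
      subset <- NULL
    }
    pca <- coab_pca(m, subset = subset)
    emit("pca_scores.tsv", function(p)
      write_matrix_tsv(pca$scores, p, id_col = "sample_id"))
    emit("pca_variance.tsv", function(p)
      utils::write.table(
        data.frame(component = seq_along(pca$variance_fraction),
                   variance_fraction = pca$variance_fraction),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
    al <- align_to_design(m, design)
    pm <- coab_permanova(abundance_matrix(al$x, "log2"),
                         al$design$stage_days,
                         n_perm = cfg$n_perm_ordination, seed = cfg$seed)
    emit("permanova.json", function(p)
      jsonlite::write_json(unclass(pm), p, auto_unbox = TRUE, digits = NA))
  })

  # --- network ---
  fit <- run_stage("network", {
    fit <- coab(m, traits = traits, beta = cfg$beta,
                scale_free_target = cfg$scale_free_target,
                network_type = cfg$network_type,
                cut_height = cfg$cut_height,
                min_module_size = cfg$min_module_size,
                merge_cor_threshold = cfg$merge_cor_threshold,
                trait_cor_threshold = cfg$trait_cor_threshold,
                alpha = cfg$alpha, n_permutations = cfg$n_permutations,
                seed = cfg$seed, top_n_neighbors = cfg$top_n_neighbors)
    emit("modules.tsv", function(p)
      utils::write.table(
        data.frame(protein_id = names(fit$labels), module = fit$labels),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
    if (!is.null(fit$scan))
      emit("soft_threshold_scan.tsv", function(p)
        utils::write.table(fit$scan, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    if (!is.null(fit$eigengenes)) {
      emit("eigengenes.tsv", function(p)
        write_matrix_tsv(fit$eigengenes, p, id_col = "module"))
      emit("kme.tsv", function(p)
        write_matrix_tsv(fit$kME, p, id_col = "protein_id"))
      emit("hubs.json", function(p)
        jsonlite::write_json(
          lapply(seq_len(nrow(fit$hubs)), function(i) list(
            module = fit$hubs$module[i],
            hub_protein = fit$hubs$hub_protein[i],
            module_membership_score = fit$hubs$module_membership_score[i],
            neighbors = fit$hubs$neighbors[[i]]
          )), p, auto_unbox = TRUE, digits = NA))
    }
    if (!is.null(fit$module_trait))
      emit("module_trait.tsv", function(p)
        utils::write.table(fit$module_trait, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    fit
  })

  # --- enrichment (optional) ---
  if (!is.null(cfg$annotations) && length(fit$module_sizes)) {
    run_stage("enrich", {
      sets <- if (grepl("\\.gmt$", cfg$annotations))
        read_gmt(cfg$annotations) else read_annotation_tsv(cfg$annotations)
      universe <- names(fit$labels)
      sets <- lapply(sets, intersect, universe)
      enr <- do.call(rbind, lapply(seq_along(fit$module_sizes), function(i) {
        q <- names(fit$labels)[fit$labels == i]
        e <- fisher_ora(q, sets, universe)
        cbind(module = i, e)
      }))
      emit("enrichment.tsv", function(p)
        utils::write.table(enr, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    })
  }

  # --- manifest ---
  inputs <- Filter(Negate(is.null),
                   cfg[c("matrix", "design", "traits", "annotations")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("coabnet")),
    config = cfg,
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    output_checksums = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("pipeline complete: %d result files", length(paths))
  invisible(cfg$out_dir)
}

# accept a list, a JSON path, or a YAML path
load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || !file.exists(config))
    stop("config must be a list or an existing file path", call. = FALSE)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package", call. = FALSE)
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}
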