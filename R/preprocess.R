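#' Log2-transform a raw intensity matrix
#'
#' Elementwise base-2 logarithm of strictly positive raw intensities; the
#' scale flag of the result is `"log2"`. This is the statistical entry point
#' of the pipeline: all downstream stages (normalization, ANOVA, PCA, the
#' co-abundance network) operate on the log2 scale.
#'
#' @param m An [abundance_matrix()] on the raw scale.
#' @return An [abundance_matrix()] on the log2 scale.
#' @export
log2_transform <- function(m) {
  if (ab_scale(m) != "raw")
    stop("log2_transform expects a raw-scale matrix", call. = FALSE)
  v <- ab_values(m)
  bad <- which(v <= 0 & !is.na(v), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive intensity at protein '%s', sample '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]),
         call. = FALSE)
  abundance_matrix(log2(v), scale = "log2")
}

#' Fast cyclic loess normalization
#'
#' Removes intensity-dependent offsets between samples on the log2 scale.
#' Each sample is normalized against the row-mean reference: a degree-1
#' locally weighted regression of (sample - row mean) on the row mean is
#' fitted with tricube weights and subtracted, cycling over samples for
#' `iterations` passes (the "fast" cyclic loess of the limma package). After
#' normalization the original grand mean of the matrix is restored so
#' absolute log2 levels remain interpretable.
#'
#' @param m An [abundance_matrix()] on the log2 scale, no missing values.
#' @param span Loess span in (0, 1]; fraction of proteins in each local fit.
#' @param iterations Number of cyclic passes.
#' @return Normalized [abundance_matrix()] on the log2 scale.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, iterations = 3L) {
  if (ab_scale(m) != "log2")
    stop("cyclic_loess_normalize expects a log2-scale matrix", call. = FALSE)
  v <- ab_values(m)
  if (ncol(v) < 2) stop("need at least 2 samples to normalize", call. = FALSE)
  if (anyNA(v)) stop("missing values present; apply filter_missing() first",
                     call. = FALSE)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    stop("span must lie in (0, 1]", call. = FALSE)
  out <- limma::normalizeCyclicLoess(v, span = span, iterations = iterations,
                                     method = "fast")
  dimnames(out) <- dimnames(v)
  # restore the grand mean removed by the reference-based correction
  out <- out + (mean(v) - mean(out))
  abundance_matrix(out, scale = "log2")
}

#' Filter proteins by missing-data policy
#'
#' @param m An [abundance_matrix()].
#' @param policy `"drop_any"` removes proteins with any missing cell
#'   (default: complete rows are required by correlation and PCA);
#'   `"max_fraction"` keeps proteins whose missing fraction is at most
#'   `max_fraction`.
#' @param max_fraction Tolerated missing fraction under `"max_fraction"`.
#' @return Filtered [abundance_matrix()]; row order of survivors preserved.
#' @export
filter_missing <- function(m, policy = c("drop_any", "max_fraction"),
                           max_fraction = 0.5) {
  policy <- match.arg(policy)
  v <- ab_values(m)
  frac <- rowMeans(is.na(v))
  keep <- if (policy == "drop_any") frac == 0 else frac <= max_fraction
  if (!any(keep))
    stop("missing-data policy would remove every protein", call. = FALSE)
  if (any(!keep))
    message(sum(!keep), " protein(s) removed by missing-data policy '",
            policy, "'")
  abundance_matrix(v[keep, , drop = FALSE], scale = ab_scale(m))
}
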