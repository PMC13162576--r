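#' Protein abundance matrix
#'
#' Light container for a protein x sample intensity matrix. Rows are proteins,
#' columns are samples; a `scale` attribute records whether values are raw
#' intensities (strictly positive) or log2-transformed intensities.
#'
#' @param values Numeric matrix with unique, non-empty rownames (protein ids)
#'   and colnames (sample ids).
#' @param scale Either `"raw"` or `"log2"`.
#' @return A numeric matrix of class `"abundance_matrix"` with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(2^(1:6), 3, 2, dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' a <- abundance_matrix(m, scale = "raw")
#' ab_scale(a)
#' @export
abundance_matrix <- function(values, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs protein rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (scale == "raw" && any(values <= 0, na.rm = TRUE)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("raw-scale matrix has non-positive value at protein '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  if (scale == "log2" && any(!is.finite(values) & !is.na(values)))
    stop("log2-scale matrix must contain finite values", call. = FALSE)
  structure(values, scale = scale, class = c("abundance_matrix", "matrix", "array"))
}

#' @rdname abundance_matrix
#' @param x An `abundance_matrix` (or plain matrix, treated as log2 scale).
#' @export
ab_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "log2" else s
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x), ncol(x), ab_scale(x)))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = ab_scale(x),
                     class = c("abundance_matrix", "matrix", "array"))
  out
}

# internal: strip class, return plain numeric matrix
ab_values <- function(x) {
  attr(x, "scale") <- NULL
  unclass(x)
}
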