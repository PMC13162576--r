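#' Over-representation analysis via one-sided Fisher's exact test
#'
#' For each annotation term, tests whether the query protein list (e.g. a
#' module's members) overlaps the term's protein set more than expected under
#' random sampling from the universe: one-sided hypergeometric tail
#' `p = P(X >= k | N, K, n)`, with Benjamini-Hochberg correction across
#' terms. The universe should be the measured proteome (the analyzed matrix's
#' proteins), not the annotation file's union.
#'
#' @param query Character vector of protein ids; must be a subset of
#'   `universe`.
#' @param sets Named list of character vectors (term id -> protein ids).
#' @param universe Character vector of background protein ids.
#' @return Data.frame sorted by p-value: `term`, `overlap` (k), `term_size`
#'   (K, within the universe), `query_size` (n), `universe_size` (N),
#'   `fold_enrichment` ((k/n)/(K/N)), `p_value`, `q_value`.
#' @examples
#' u <- paste0("P", 1:20)
#' fisher_ora(u[1:5], list(T1 = u[1:5], T2 = u[6:10]), u)
#' @export
fisher_ora <- function(query, sets, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(universe) < 2) stop("universe must have >= 2 proteins", call. = FALSE)
  if (length(sets) == 0) stop("need at least one annotation set", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("annotation sets must be named by term id", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query proteins outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(term) {
    set <- intersect(unique(sets[[term]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K > 0 && n > 0) (k / n) / (K / N) else 0
    data.frame(term = term, overlap = k, term_size = K, query_size = n,
               universe_size = N, fold_enrichment = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read annotation sets
#'
#' `read_annotation_tsv()` reads a two-column TSV (`term_id`, `protein_id`);
#' `read_gmt()` reads GMT (term, description, members...).
#'
#' @param path File path.
#' @return Named list of character vectors (term id -> protein ids).
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("annotation TSV needs two columns", call. = FALSE)
  split(d[[2]], d[[1]])
}

#' @rdname read_annotation_tsv
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}
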