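# Gene-set over-representation: one-sided hypergeometric test of the
# overlap between a query gene list and each set of a GMT collection,
# with BH adjustment across the tested sets.

#' Hypergeometric over-representation analysis
#'
#' For each set, the overlap `k` between the query and the set (both
#' intersected with the universe) is tested against the hypergeometric
#' upper tail `P(X >= k)` with universe size `N`, set size `K` and query
#' size `n`. Sets empty after intersection with the universe are skipped
#' with a warning. q-values are BH-adjusted across the tested sets and the
#' table is sorted by p.
#'
#' @param query character vector of query gene ids (a subset of the
#'   universe; genes outside it are dropped with a warning).
#' @param collection a [gene_set_collection()] (or named list of gene-id
#'   vectors).
#' @param universe character vector of all tested gene ids.
#' @return A data.frame of class `enrichment_table` with columns `set`,
#'   `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
hypergeometric_ora <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_field("universe", "must be nonempty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query genes outside the universe were dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop_field("query", "must be nonempty within the universe")
  if (!inherits(collection, "gene_set_collection")) {
    collection <- gene_set_collection(collection)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    if (K == 0L) {
      warning(sprintf("set '%s' is empty after intersection with the universe; skipped",
                      nm))
      return(NULL)
    }
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    stop("no gene sets overlap the universe", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
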