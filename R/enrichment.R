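#' Hypergeometric over-representation analysis
#'
#' For each gene set with at least one overlapping gene, tests the query
#' against the collection's universe with the upper-tail hypergeometric
#' probability \eqn{P(X \ge k)}, \eqn{X \sim} Hypergeometric(M, K, n), and
#' corrects across all tested terms with Benjamini-Hochberg.  Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query Character vector of gene IDs.
#' @param collection A `gene_set_collection`.
#' @param q_max Significance threshold on the BH-adjusted p (default 0.05,
#'   strict `<`).
#' @return An `enrichment_result` data frame with columns `term_id`,
#'   `term_name`, `k` (overlap), `K` (set size), `n` (query size), `M`
#'   (universe size), `p`, `q`, `significant` and `genes` (list of overlap
#'   gene vectors), ordered by increasing p.
#' @export
enrich <- function(query, collection, q_max = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) stop("query is empty after universe filtering", call. = FALSE)
  M <- length(collection$universe)
  n <- length(query)
  overlaps <- lapply(collection$sets, intersect, x = query)
  k <- vapply(overlaps, length, 1L)
  keep <- k >= 1L
  if (!any(keep)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(), M = integer(),
                      p = numeric(), q = numeric(), significant = logical())
    out$genes <- list()
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  ids <- names(collection$sets)[keep]
  K <- vapply(collection$sets[keep], length, 1L)
  kk <- k[keep]
  p <- stats::phyper(kk - 1L, K, M - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = ids,
                    term_name = unname(collection$names[ids]),
                    k = kk, K = K, n = n, M = M, p = p, q = q,
                    significant = q < q_max,
                    stringsAsFactors = FALSE)
  out$genes <- lapply(overlaps[keep], sort)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Core pathways per herb from disease-anchored enrichment
#'
#' Candidate terms are the disease-significant terms.  For each herb, the
#' terms whose per-herb enriched-gene count k strictly exceeds the third
#' quartile (type-7) of that herb's k distribution over the candidate terms
#' are retained as its core pathways.  A herb overlapping no candidate term
#' gets an empty set; candidate terms missing from a herb's results count as
#' k = 0.
#'
#' @param per_herb_results Named list (herb -> `enrichment_result`), computed
#'   on the same collection as `disease_results`.
#' @param disease_results An `enrichment_result` for the disease gene list.
#' @return Named list (herb -> character vector of core term IDs).
#' @export
core_pathways <- function(per_herb_results, disease_results) {
  stopifnot(inherits(disease_results, "enrichment_result"))
  candidates <- disease_results$term_id[disease_results$significant]
  lapply(per_herb_results, function(res) {
    if (length(candidates) == 0L) return(character())
    k <- stats::setNames(rep(0L, length(candidates)), candidates)
    hit <- intersect(res$term_id, candidates)
    k[hit] <- res$k[match(hit, res$term_id)]
    if (all(k == 0L)) return(character())
    q3 <- stats::quantile(as.numeric(k), 0.75, type = 7, names = FALSE)
    sort(candidates[k > q3])
  })
}
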