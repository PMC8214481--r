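#' Build the weighted co-prescription network
#'
#' Herbs are nodes; the weight of an edge is the number of prescriptions in
#' which the two herbs are used together.  Counting is presence-based (a
#' prescription contributes at most 1 to any pair) and implemented as a sparse
#' herb-by-prescription incidence cross-product.
#'
#' @param db A `transaction_db`.
#' @param cohort Optional cohort filter (`"case"` or `"control"`).
#' @return A `herb_network`: list with `edges` (data frame `herb_a`, `herb_b`,
#'   `weight`, with `herb_a < herb_b`), `herbs` (all herb IDs in the filtered
#'   data, including edge-less ones), `n_herbs` (the N of the shell
#'   criterion) and `total_weight` (S_N, the summed weight of all pairs).
#' @export
build_herb_network <- function(db, cohort = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  keep <- if (is.null(cohort)) seq_along(db$id) else which(db$cohort == cohort)
  if (length(keep) == 0L) stop("no transactions after cohort filtering", call. = FALSE)
  herbs_by_tx <- db$herbs[keep]
  herb_ids <- sort(unique(unlist(herbs_by_tx, use.names = FALSE)))
  lens <- lengths(herbs_by_tx)
  inc <- Matrix::sparseMatrix(
    i = match(unlist(herbs_by_tx, use.names = FALSE), herb_ids),
    j = rep(seq_along(herbs_by_tx), lens),
    x = 1,
    dims = c(length(herb_ids), length(herbs_by_tx))
  )
  co <- Matrix::tcrossprod(inc)
  co <- methods::as(Matrix::triu(co, k = 1), "TsparseMatrix")
  edges <- data.frame(
    herb_a = herb_ids[co@i + 1L],
    herb_b = herb_ids[co@j + 1L],
    weight = co@x,
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$weight > 0, , drop = FALSE]
  edges <- edges[order(-edges$weight, edges$herb_a, edges$herb_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, herbs = herb_ids,
                 n_herbs = length(herb_ids),
                 total_weight = sum(edges$weight)),
            class = "herb_network")
}

#' @export
print.herb_network <- function(x, ...) {
  cat("herb_network:", x$n_herbs, "herbs,", nrow(x$edges),
      "edges, total pair weight", x$total_weight, "\n")
  invisible(x)
}

#' Extract one main-herb shell layer
#'
#' Edges are sorted by weight (descending; ties broken lexicographically on
#' the herb pair) and the cumulative weight S_k of the top k edges is tested
#' against the degree-coefficient criterion
#' \deqn{S_k \cdot N \ge k^{\alpha} \cdot S_N,}
#' where N is the number of herbs and S_N the total pair weight.  The layer is
#' the largest prefix K of edges satisfying the criterion.  Because k^alpha
#' grows quickly, a pathological residual may satisfy the criterion for no k;
#' the single heaviest edge is then returned with `fallback = TRUE` so the
#' iterative peel always terminates.
#'
#' @param net A `herb_network` (possibly a residual from a previous call).
#' @param alpha Degree coefficient (default 2.4).
#' @param n_total N of the criterion; defaults to `net$n_herbs`.  Pass the
#'   original herb count when peeling residuals, since N is defined on all
#'   herbs in the data.
#' @param total_weight S_N of the criterion; defaults to the network's current
#'   total weight (the residual's weight during iterative peeling).
#' @return List with `layer` (edge data frame in descending-weight order),
#'   `k` (number of retained edges), `cumulative_weights` (S_k for the
#'   retained prefix), `fallback` (logical) and `residual` (a `herb_network`
#'   without the layer edges; `n_herbs` unchanged).
#' @export
extract_shell <- function(net, alpha = 2.4, n_total = net$n_herbs,
                          total_weight = net$total_weight) {
  stopifnot(inherits(net, "herb_network"), alpha > 0)
  edges <- net$edges
  if (nrow(edges) == 0L) stop("network has no edges", call. = FALSE)
  edges <- edges[order(-edges$weight, edges$herb_a, edges$herb_b), , drop = FALSE]
  s_k <- cumsum(edges$weight)
  k_seq <- seq_len(nrow(edges))
  ok <- s_k * n_total >= k_seq^alpha * total_weight
  fallback <- !any(ok)
  k <- if (fallback) 1L else max(which(ok))
  if (fallback) {
    warning("shell criterion not satisfied for any k; returning the heaviest edge",
            call. = FALSE)
  }
  layer <- edges[seq_len(k), , drop = FALSE]
  rownames(layer) <- NULL
  rest <- edges[-seq_len(k), , drop = FALSE]
  rownames(rest) <- NULL
  residual <- structure(list(edges = rest, herbs = net$herbs,
                             n_herbs = net$n_herbs,
                             total_weight = sum(rest$weight)),
                        class = "herb_network")
  list(layer = layer, k = k, cumulative_weights = s_k[seq_len(k)],
       fallback = fallback, residual = residual)
}

#' Iteratively extract the shell hierarchy
#'
#' Repeats [extract_shell()] on the residual network until it is edge-less or
#' `max_layers` is reached.  N is held fixed at the original herb count across
#' iterations; S_N is the residual's remaining weight.  The herbs incident to
#' layer-1 edges are reported as the core herbs.
#'
#' @param net A `herb_network`.
#' @param alpha Degree coefficient (default 2.4).
#' @param max_layers Maximum number of layers (default unlimited).
#' @return A `shell_result`: list with `layers` (list of edge data frames,
#'   each in descending-weight order), `alpha`, `core_herbs` (herbs incident
#'   to layer-1 edges, sorted), `fallback` (logical per layer) and
#'   `n_herbs`.
#' @export
extract_hierarchy <- function(net, alpha = 2.4, max_layers = Inf) {
  stopifnot(inherits(net, "herb_network"))
  n_total <- net$n_herbs
  layers <- list()
  fallback <- logical()
  current <- net
  while (nrow(current$edges) > 0L && length(layers) < max_layers) {
    step <- extract_shell(current, alpha = alpha, n_total = n_total)
    layers[[length(layers) + 1L]] <- step$layer
    fallback[length(layers)] <- step$fallback
    current <- step$residual
  }
  core <- if (length(layers) > 0L) {
    sort(unique(c(layers[[1L]]$herb_a, layers[[1L]]$herb_b)))
  } else {
    character()
  }
  structure(list(layers = layers, alpha = alpha, core_herbs = core,
                 fallback = fallback, n_herbs = n_total),
            class = "shell_result")
}

#' @export
print.shell_result <- function(x, ...) {
  cat("shell_result:", length(x$layers), "layers (alpha =", x$alpha, ");",
      "core herbs:", paste(x$core_herbs, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a shell hierarchy to a layered edge table
#' @param result A `shell_result`.
#' @return Data frame with columns `layer`, `herb_a`, `herb_b`, `weight`.
#' @export
shell_layers_table <- function(result) {
  stopifnot(inherits(result, "shell_result"))
  if (length(result$layers) == 0L) {
    return(data.frame(layer = integer(), herb_a = character(),
                      herb_b = character(), weight = numeric()))
  }
  out <- do.call(rbind, Map(function(l, i) cbind(layer = i, l),
                            result$layers, seq_along(result$layers)))
  rownames(out) <- NULL
  out
}
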