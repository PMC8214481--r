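#' Assemble the compound-target-disease-gene network
#'
#' Takes the confidence-filtered protein interaction edges, adds one node per
#' compound with weight-1 edges to its targets, and marks disease genes.
#' Disease genes absent from the interaction network are kept as isolated
#' seed nodes (with a warning), since they may still be targeted by compounds.
#'
#' @param ppi Edge data frame from [read_edge_list()] / [clean_edge_list()].
#' @param annotations Named list of `herb_annotation` objects (may be empty).
#' @param disease_genes Character vector of disease gene IDs.
#' @return A `molecular_network`: list with `nodes` (data frame `id`,
#'   `is_compound`, `is_target`, `is_disease`), `edges` (data frame `from`,
#'   `to`, `weight`) and `herb_of_compound` (named character vector).
#' @export
build_molecular_network <- function(ppi, annotations = list(),
                                    disease_genes = character()) {
  if (nrow(ppi) == 0L && length(annotations) == 0L) {
    stop("cannot build a network from empty interaction and annotation inputs",
         call. = FALSE)
  }
  ct_edges <- do.call(rbind, lapply(annotations, function(a) {
    if (length(a$targets) == 0L) return(NULL)
    expand.grid(from = a$compounds, to = a$targets,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  # a compound shared by several herbs keeps a single node; dedupe its edges
  if (!is.null(ct_edges)) ct_edges <- unique(ct_edges)

  compounds <- unique(unlist(lapply(annotations, `[[`, "compounds"), use.names = FALSE))
  targets <- unique(unlist(lapply(annotations, `[[`, "targets"), use.names = FALSE))
  ppi_nodes <- unique(c(ppi$protein_a, ppi$protein_b))
  disease_genes <- unique(as.character(disease_genes))
  isolated <- setdiff(disease_genes, c(ppi_nodes, targets))
  if (length(isolated) > 0L) {
    warning(length(isolated), " disease gene(s) absent from the interaction ",
            "network kept as isolated nodes", call. = FALSE)
  }
  ids <- sort(unique(c(ppi_nodes, targets, compounds, disease_genes)))
  nodes <- data.frame(id = ids,
                      is_compound = ids %in% compounds,
                      is_target = ids %in% targets,
                      is_disease = ids %in% disease_genes,
                      stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = ppi$protein_a, to = ppi$protein_b,
               weight = ppi$confidence, stringsAsFactors = FALSE),
    if (!is.null(ct_edges)) data.frame(from = ct_edges$from, to = ct_edges$to,
                                       weight = 1, stringsAsFactors = FALSE)
  )
  herb_of_compound <- unlist(lapply(annotations, function(a) {
    stats::setNames(rep(a$herb_id, length(a$compounds)), a$compounds)
  }))
  # a compound in several herbs: keep first assignment for reporting only
  herb_of_compound <- herb_of_compound[!duplicated(names(herb_of_compound))]
  structure(list(nodes = nodes, edges = edges,
                 herb_of_compound = herb_of_compound),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat("molecular_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$is_compound), "compounds,", sum(x$nodes$is_target), "targets,",
      sum(x$nodes$is_disease), "disease genes ),", nrow(x$edges), "edges\n")
  invisible(x)
}

# internal: molecular_network or edge data frame -> simple undirected igraph
as_undirected_graph <- function(net, protein_only = FALSE) {
  if (inherits(net, "molecular_network")) {
    edges <- net$edges
    vertices <- net$nodes$id
    if (protein_only) {
      keep_nodes <- net$nodes$id[!net$nodes$is_compound]
      edges <- edges[edges$from %in% keep_nodes & edges$to %in% keep_nodes, ,
                     drop = FALSE]
      vertices <- keep_nodes
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = vertices))
  } else {
    g <- igraph::graph_from_data_frame(net, directed = FALSE)
  }
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Detect dense complexes with the MCODE algorithm
#'
#' The published three-stage procedure on the unweighted target/gene view of
#' the network: (i) each node is weighted by the product of the core number k
#' and the density of the highest k-core of its closed neighbourhood (nodes
#' with degree below `degree_cutoff` score 0); (ii) complexes grow greedily
#' outward from the highest-weighted unseen seed, admitting unseen neighbours
#' whose weight exceeds `(1 - node_score_cutoff)` times the seed weight;
#' (iii) with `haircut`, singly-connected members are removed.  Complexes are
#' scored by density times size and reported in descending order.
#'
#' @param net A `molecular_network` (compound nodes are excluded) or an
#'   undirected edge data frame / igraph.
#' @param degree_cutoff Minimum degree for a node to receive a weight
#'   (default 2).
#' @param node_score_cutoff Allowed fractional drop from the seed weight
#'   (default 0.2).
#' @param haircut Remove degree-1 members from each complex (default TRUE).
#' @return List of complexes, each a list with `members` (character),
#'   `score` (density x size) and `density`; sorted by decreasing score.
#' @export
mcode_cores <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                        haircut = TRUE) {
  g <- as_undirected_graph(net, protein_only = TRUE)
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  names_g <- igraph::V(g)$name
  deg <- igraph::degree(g)

  weight <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    m <- igraph::vcount(core_sub)
    dens <- if (m > 1) 2 * igraph::ecount(core_sub) / (m * (m - 1)) else 0
    weight[v] <- kmax * dens
  }

  order_v <- order(-weight, names_g)
  seen <- logical(n)
  complexes <- list()
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  for (seed in order_v) {
    if (seen[seed] || weight[seed] <= 0) next
    threshold <- (1 - node_score_cutoff) * weight[seed]
    members <- seed
    seen[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0L) {
      nbs <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nbs <- nbs[!seen[nbs] & weight[nbs] > threshold]
      seen[nbs] <- TRUE
      members <- c(members, nbs)
      frontier <- nbs
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    if (haircut) {
      keep <- igraph::degree(sub) >= 2
      if (!all(keep)) sub <- igraph::induced_subgraph(sub, which(keep))
    }
    m <- igraph::vcount(sub)
    if (m < 2L) next
    dens <- 2 * igraph::ecount(sub) / (m * (m - 1))
    complexes[[length(complexes) + 1L]] <-
      list(members = sort(igraph::V(sub)$name), score = dens * m, density = dens)
  }
  complexes[order(-vapply(complexes, `[[`, 0, "score"))]
}

#' Random walk with restart on the molecular network
#'
#' Iterates \eqn{p \leftarrow (1-c) W p + c s} with W the column-normalised
#' weighted adjacency (interaction confidences and weight-1 compound-target
#' edges), s uniform over the seed nodes and c the restart probability, until
#' the L1 change drops below `tol`.  The stationary vector C^RWR measures each
#' node's proximity to the seeds.
#'
#' @param net A `molecular_network`, or an edge data frame with columns
#'   `from`/`to` (or the first two columns as node pairs) and optional
#'   `weight`.
#' @param seeds Character vector of seed node IDs (must be present).
#' @param restart_prob Restart probability c in (0, 1] (default 0.75).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter Maximum iterations (default 10000).
#' @return An `rwr_scores`: list with `scores` (named numeric, sums to 1 when
#'   every node reachable from the seeds has at least one edge), `restart_prob`,
#'   `seeds`, `iterations` and `converged`.
#' @export
rwr <- function(net, seeds, restart_prob = 0.75, tol = 1e-9, max_iter = 10000L) {
  stopifnot(restart_prob > 0, restart_prob <= 1)
  if (inherits(net, "molecular_network")) {
    ids <- net$nodes$id
    edges <- net$edges
  } else {
    edges <- data.frame(from = as.character(net[[1L]]), to = as.character(net[[2L]]),
                        weight = if ("weight" %in% names(net)) net$weight
                                 else if (ncol(net) >= 3L) as.numeric(net[[3L]])
                                 else 1,
                        stringsAsFactors = FALSE)
    ids <- sort(unique(c(edges$from, edges$to)))
  }
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set is empty", call. = FALSE)
  missing <- setdiff(seeds, ids)
  if (length(missing) > 0L) {
    stop("seed(s) not in the network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- length(ids)
  i <- match(edges$from, ids); j <- match(edges$to, ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2L), dims = c(n, n))
  colsum <- Matrix::colSums(A)
  nz <- colsum > 0
  W <- A %*% Matrix::Diagonal(n, x = ifelse(nz, 1 / pmax(colsum, 1e-300), 0))

  s <- numeric(n)
  s[match(seeds, ids)] <- 1 / length(seeds)
  p <- s
  converged <- restart_prob == 1
  iter <- 0L
  while (!converged && iter < max_iter) {
    p_new <- as.numeric((1 - restart_prob) * (W %*% p)) + restart_prob * s
    delta <- sum(abs(p_new - p))
    p <- p_new
    iter <- iter + 1L
    if (delta < tol) converged <- TRUE
  }
  structure(list(scores = stats::setNames(p, ids), restart_prob = restart_prob,
                 seeds = seeds, iterations = iter, converged = converged),
            class = "rwr_scores")
}

#' @export
print.rwr_scores <- function(x, ...) {
  cat("rwr_scores:", length(x$scores), "nodes,", length(x$seeds), "seeds,",
      "restart", x$restart_prob, "-",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Retain compounds in the upper quartile of the RWR scores
#'
#' Computes the third quartile (type-7 linear interpolation) over the
#' compound scores and keeps compounds strictly above it, ranked by score
#' (descending; ties broken by node ID).  With fewer than 4 compounds every
#' compound is retained with a warning.
#'
#' @param scores An `rwr_scores`.
#' @param compounds Character vector of compound node IDs.
#' @return Data frame with columns `compound`, `score`, `retained`, ordered
#'   by decreasing score.
#' @export
retain_core_compounds <- function(scores, compounds) {
  stopifnot(inherits(scores, "rwr_scores"))
  compounds <- unique(as.character(compounds))
  missing <- setdiff(compounds, names(scores$scores))
  if (length(missing) > 0L) {
    stop("compound(s) without a score: ", paste(utils::head(missing, 5L),
                                                collapse = ", "), call. = FALSE)
  }
  x <- scores$scores[compounds]
  out <- data.frame(compound = compounds, score = as.numeric(x),
                    stringsAsFactors = FALSE)
  if (length(compounds) < 4L) {
    warning("fewer than 4 compounds: retaining all", call. = FALSE)
    out$retained <- TRUE
  } else {
    q3 <- stats::quantile(out$score, 0.75, type = 7, names = FALSE)
    out$retained <- out$score > q3
    if (!any(out$retained)) {
      warning("no compound strictly above the third quartile", call. = FALSE)
    }
  }
  out <- out[order(-out$score, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}
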