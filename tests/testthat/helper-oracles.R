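# Independent brute-force oracles used to validate the package's algorithms.
# These deliberately recompute everything from first principles and share no
# code with the implementation paths they check.

# all frequent itemsets by exhaustive subset enumeration
oracle_frequent <- function(tx, min_support) {
  items <- sort(unique(unlist(tx)))
  n <- length(tx)
  out <- list()
  for (size in seq_along(items)) {
    for (set in utils::combn(items, size, simplify = FALSE)) {
      count <- sum(vapply(tx, function(t) all(set %in% t), NA))
      if (count / n >= min_support - 1e-12) {
        out[[length(out) + 1L]] <- list(items = set, count = count)
      }
    }
  }
  out
}

# all (lhs, single rhs) rules from exhaustively enumerated counts
oracle_rules <- function(tx, min_support, min_confidence) {
  n <- length(tx)
  freq <- oracle_frequent(tx, min_support)
  count_of <- function(set) {
    sum(vapply(tx, function(t) all(set %in% t), NA))
  }
  rows <- list()
  for (f in freq) {
    if (length(f$items) < 2L) next
    for (r in f$items) {
      lhs <- setdiff(f$items, r)
      support <- f$count / n
      coverage <- count_of(lhs) / n
      confidence <- support / coverage
      lift <- confidence / (count_of(r) / n)
      if (support > min_support && confidence > min_confidence) {
        rows[[length(rows) + 1L]] <- data.frame(
          lhs_label = paste(lhs, collapse = "+"), rhs_label = r,
          support = support, confidence = confidence, coverage = coverage,
          lift = lift, count = f$count, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$lhs_label, out$rhs_label), , drop = FALSE]
}

# shell criterion evaluated for every k from a plain sorted-edge loop
oracle_shell_k <- function(weights, n_herbs, alpha, total_weight = sum(weights)) {
  w <- sort(weights, decreasing = TRUE)
  best <- 0L
  s <- 0
  for (k in seq_along(w)) {
    s <- s + w[k]
    if (s * n_herbs >= k^alpha * total_weight) best <- k
  }
  best
}

# greedy Ward by recomputing the ESS of every candidate union from scratch;
# same tie-break contract as the implementation (smallest min-row-index pair)
oracle_ward <- function(x) {
  n <- nrow(x)
  ess_of <- function(rows) {
    sub <- x[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- lapply(seq_len(n), identity)
  labels <- seq_len(n)
  merges <- list()
  deltas <- numeric()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- ess_of(c(clusters[[i]], clusters[[j]])) -
          ess_of(clusters[[i]]) - ess_of(clusters[[j]])
        lo <- min(labels[i], labels[j]); hi <- max(labels[i], labels[j])
        if (is.null(best) || cost < best$cost - 1e-12 ||
            (abs(cost - best$cost) <= 1e-12 &&
             (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
          best <- list(cost = cost, lo = lo, hi = hi,
                       i = which(labels == lo), j = which(labels == hi))
        }
      }
    }
    merges[[length(merges) + 1L]] <- sort(c(best$lo, best$hi))
    deltas <- c(deltas, best$cost)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
    labels <- labels[-best$j]
  }
  list(pairs = merges, delta = deltas)
}

# merge-partner pairs (as min-row-index labels) from a ward_clustering object
ward_merge_pairs <- function(wc) {
  n <- length(wc$labels)
  min_member <- integer(nrow(wc$merge))
  lapply(seq_len(nrow(wc$merge)), function(step) {
    decode <- function(code) {
      if (code < 0L) -code else min_member[code]
    }
    a <- decode(wc$merge[step, 1L]); b <- decode(wc$merge[step, 2L])
    min_member[step] <<- min(a, b)
    sort(c(a, b))
  })
}

# exact upper-tail hypergeometric probability from binomial coefficients
oracle_hyper_p <- function(k, K, M, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(M - K, n - ks)) / choose(M, n)
}

# random transaction list: n transactions over the given items
random_tx <- function(n, items, min_size = 1L, max_size = length(items)) {
  lapply(seq_len(n), function(i) {
    sample(items, sample(min_size:max_size, 1L))
  })
}

random_tx_db <- function(n, items, ...) {
  tx <- random_tx(n, items, ...)
  new_transaction_db(sprintf("p%03d", seq_len(n)),
                     sample(c("case", "control"), n, replace = TRUE), tx)
}

# random connected-ish weighted graph as an edge data frame
random_edge_df <- function(n_nodes, p_edge = 0.3, weighted = TRUE) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  # keep a spanning path so the graph is connected
  path <- cbind(nodes[-n_nodes], nodes[-1L])
  df <- unique(data.frame(
    from = c(pairs[1L, keep], path[, 1L]),
    to = c(pairs[2L, keep], path[, 2L]),
    stringsAsFactors = FALSE))
  df$weight <- if (weighted) stats::runif(nrow(df), 0.1, 1) else 1
  df
}

# dense linear-solve RWR: c (I - (1-c) W)^{-1} s
oracle_rwr <- function(edge_df, seeds, c_restart) {
  ids <- sort(unique(c(edge_df$from, edge_df$to)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edge_df))) {
    A[edge_df$from[r], edge_df$to[r]] <- A[edge_df$from[r], edge_df$to[r]] + edge_df$weight[r]
    A[edge_df$to[r], edge_df$from[r]] <- A[edge_df$to[r], edge_df$from[r]] + edge_df$weight[r]
  }
  W <- sweep(A, 2, pmax(colSums(A), 1e-300), "/")
  s <- stats::setNames(numeric(n), ids)
  s[seeds] <- 1 / length(seeds)
  drop(c_restart * solve(diag(n) - (1 - c_restart) * W) %*% s)
}

# strip classes/attributes so rule tables compare as plain data frames
plain_df <- function(d) {
  d <- as.data.frame(d)
  attr(d, "n_transactions") <- NULL
  attr(d, "min_support") <- NULL
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}
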