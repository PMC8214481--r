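#' Frequent-itemset mining with the Apriori algorithm
#'
#' Level-wise candidate generation with the downward-closure pruning property
#' (every subset of a frequent itemset is frequent).  Support is
#' presence-based: `support(X) = |{transactions containing X}| / n`.
#'
#' @param db A `transaction_db` (cohort labels are ignored; filter first with
#'   [build_herb_network()]-style subsetting if needed).
#' @param min_support Minimum support (inclusive), in (0, 1].
#' @param max_len Maximum itemset size explored.
#' @return A `frequent_itemsets` data frame with columns `items` (list of
#'   sorted character vectors), `size`, `count` and `support`, with
#'   attributes `n_transactions` and `min_support`.  Ordered by size, then
#'   lexicographically.
#' @export
apriori <- function(db, min_support, max_len = Inf) {
  stopifnot(inherits(db, "transaction_db"))
  stopifnot(min_support > 0, min_support <= 1)
  n <- length(db$herbs)
  if (n == 0L) stop("empty transaction database", call. = FALSE)
  tx <- lapply(db$herbs, sort)
  tol <- 1e-12
  min_count <- min_support * n - tol

  item_counts <- table(unlist(tx, use.names = FALSE))
  frequent_items <- sort(names(item_counts)[item_counts >= min_count])

  all_sets <- list(); all_counts <- integer()
  level_sets <- as.list(frequent_items)
  level_counts <- as.integer(item_counts[frequent_items])
  k <- 1L
  while (length(level_sets) > 0L) {
    all_sets <- c(all_sets, level_sets)
    all_counts <- c(all_counts, level_counts)
    if (k + 1L > max_len) break
    keys <- vapply(level_sets, paste, "", collapse = "\r")
    candidates <- apriori_candidates(level_sets, keys)
    if (length(candidates) == 0L) break
    counts <- vapply(candidates, function(cand) {
      sum(vapply(tx, function(t) all(cand %in% t), NA))
    }, 0L)
    keep <- counts >= min_count
    level_sets <- candidates[keep]
    level_counts <- counts[keep]
    k <- k + 1L
  }

  out <- data.frame(size = vapply(all_sets, length, 1L),
                    count = all_counts,
                    support = all_counts / n)
  out$items <- all_sets
  keys <- vapply(all_sets, paste, "", collapse = "\r")
  out <- out[order(out$size, keys), c("items", "size", "count", "support")]
  rownames(out) <- NULL
  attr(out, "n_transactions") <- n
  attr(out, "min_support") <- min_support
  class(out) <- c("frequent_itemsets", "data.frame")
  out
}

# join sorted (k-1)-sets sharing their first k-2 items, then prune candidates
# with an infrequent (k-1)-subset
apriori_candidates <- function(level_sets, keys) {
  k1 <- length(level_sets[[1L]])
  prefixes <- vapply(level_sets, function(s) paste(s[-k1], collapse = "\r"), "")
  candidates <- list()
  for (grp in split(seq_along(level_sets), prefixes)) {
    if (length(grp) < 2L) next
    lasts <- vapply(level_sets[grp], `[[`, "", k1)
    ord <- order(lasts)
    grp <- grp[ord]; lasts <- lasts[ord]
    for (i in seq_len(length(grp) - 1L)) {
      for (j in seq((i + 1L), length(grp))) {
        cand <- c(level_sets[[grp[i]]], lasts[j])
        subs_ok <- all(vapply(seq_along(cand), function(d) {
          paste(cand[-d], collapse = "\r") %in% keys
        }, NA))
        if (subs_ok) candidates[[length(candidates) + 1L]] <- cand
      }
    }
  }
  candidates
}

#' Generate association rules from frequent itemsets
#'
#' Every frequent itemset of size >= 2 is partitioned into (LHS, single-item
#' RHS) rules (multi-item RHS behind `max_rhs`).  Metrics:
#' `support = count/n`, `coverage = support(LHS)`,
#' `confidence = support/coverage`, `lift = confidence/support(RHS)`.
#' Rules are kept when `support > min_support` and
#' `confidence > min_confidence` (strict inequalities by default;
#' set `strict = FALSE` for `>=`).
#'
#' @param frequents A `frequent_itemsets` object from [apriori()], mined at a
#'   `min_support` no larger than the rule threshold.
#' @param min_support Rule support threshold (default 0.2).
#' @param min_confidence Rule confidence threshold (default 0.5).
#' @param max_rhs Maximum RHS size (default 1).
#' @param strict Use strict `>` thresholds (default TRUE).
#' @return An `association_rules` data frame with columns `lhs` (list of
#'   character vectors), `rhs` (list of character vectors), `lhs_label`,
#'   `rhs_label`, `support`, `confidence`, `coverage`, `lift`, `count`,
#'   ordered by decreasing lift then support.
#' @export
generate_rules <- function(frequents, min_support = 0.2, min_confidence = 0.5,
                           max_rhs = 1, strict = TRUE) {
  stopifnot(inherits(frequents, "frequent_itemsets"))
  if (attr(frequents, "min_support") > min_support + 1e-12) {
    stop("frequent itemsets were mined at min_support above the rule threshold",
         call. = FALSE)
  }
  n <- attr(frequents, "n_transactions")
  keys <- vapply(frequents$items, paste, "", collapse = "\r")
  count_of <- stats::setNames(frequents$count, keys)
  keep_rule <- if (strict) {
    function(s, conf) s > min_support & conf > min_confidence
  } else {
    function(s, conf) s >= min_support - 1e-12 & conf >= min_confidence - 1e-12
  }

  rows <- list()
  for (idx in which(frequents$size >= 2L)) {
    items <- frequents$items[[idx]]
    cnt <- frequents$count[idx]
    m <- length(items)
    for (rhs_size in seq_len(min(max_rhs, m - 1L))) {
      rhs_sets <- utils::combn(items, rhs_size, simplify = FALSE)
      for (rhs in rhs_sets) {
        lhs <- setdiff(items, rhs)
        cov_cnt <- count_of[[paste(lhs, collapse = "\r")]]
        rhs_cnt <- count_of[[paste(rhs, collapse = "\r")]]
        support <- cnt / n
        coverage <- cov_cnt / n
        confidence <- support / coverage
        lift <- confidence / (rhs_cnt / n)
        if (keep_rule(support, confidence)) {
          rows[[length(rows) + 1L]] <- list(lhs = lhs, rhs = rhs,
                                            support = support,
                                            confidence = confidence,
                                            coverage = coverage, lift = lift,
                                            count = cnt)
        }
      }
    }
  }
  out <- data.frame(
    lhs_label = vapply(rows, function(r) paste(r$lhs, collapse = "+"), ""),
    rhs_label = vapply(rows, function(r) paste(r$rhs, collapse = "+"), ""),
    support = vapply(rows, `[[`, 0, "support"),
    confidence = vapply(rows, `[[`, 0, "confidence"),
    coverage = vapply(rows, `[[`, 0, "coverage"),
    lift = vapply(rows, `[[`, 0, "lift"),
    count = vapply(rows, `[[`, 0, "count"),
    stringsAsFactors = FALSE
  )
  out$lhs <- lapply(rows, `[[`, "lhs")
  out$rhs <- lapply(rows, `[[`, "rhs")
  out <- out[order(-out$lift, -out$support, out$lhs_label, out$rhs_label),
             c("lhs", "rhs", "lhs_label", "rhs_label", "support", "confidence",
               "coverage", "lift", "count")]
  rownames(out) <- NULL
  attr(out, "n_transactions") <- n
  class(out) <- c("association_rules", "data.frame")
  out
}

#' Group association rules by k-means on their item incidence
#'
#' Rules are embedded as binary incidence vectors over the union of LHS and
#' RHS items (LHS and RHS blocks kept separate, so A=>B and B=>A differ) and
#' clustered with seeded k-means restarts; duplicated rules always co-cluster.
#'
#' @param rules An `association_rules` data frame.
#' @param k Number of groups.
#' @param seed Integer seed (k-means is deterministic under it).
#' @param nstart Number of k-means restarts (default 10).
#' @return Integer vector of cluster labels, one per rule.
#' @export
group_rules <- function(rules, k, seed = 1L, nstart = 10L) {
  stopifnot(inherits(rules, "association_rules"), k >= 1)
  if (nrow(rules) < k) stop("fewer rules than clusters requested", call. = FALSE)
  items <- sort(unique(unlist(c(rules$lhs, rules$rhs), use.names = FALSE)))
  embed <- function(sets) {
    m <- matrix(0, nrow = length(sets), ncol = length(items))
    for (i in seq_along(sets)) m[i, match(sets[[i]], items)] <- 1
    m
  }
  x <- cbind(embed(rules$lhs), embed(rules$rhs))
  ux <- unique(x)
  n_distinct <- nrow(ux)
  if (k > n_distinct) {
    stop("k exceeds the number of distinct rule incidence vectors (",
         n_distinct, ")", call. = FALSE)
  }
  if (k == n_distinct) {
    key <- apply(x, 1L, paste, collapse = "")
    return(as.integer(match(key, unique(key))))
  }
  set.seed(seed)
  best <- NULL
  # restarts seeded from distinct vectors so initial centers never coincide
  for (r in seq_len(nstart)) {
    centers <- ux[sample.int(n_distinct, k), , drop = FALSE]
    fit <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  as.integer(best$cluster)
}
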