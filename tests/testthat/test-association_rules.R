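as_db <- function(tx) {
  new_transaction_db(sprintf("p%03d", seq_along(tx)), rep("case", length(tx)), tx)
}

test_that("apriori finds all and only the frequent itemsets", {
  db <- as_db(list(c("A", "B")))
  fr <- apriori(db, 0.5)
  labels <- vapply(fr$items, paste, "", collapse = "+")
  expect_setequal(labels, c("A", "B", "A+B"))

  db2 <- as_db(list(c("A", "B"), c("A", "C"), c("A", "B")))
  fr2 <- apriori(db2, 1.0)
  expect_equal(vapply(fr2$items, paste, "", collapse = "+"), "A")
  expect_error(apriori(as_db(list()), 0.5), "empty")
})

test_that("apriori and rule metrics match brute-force enumeration on random databases", {
  set.seed(11)
  for (rep in 1:50) {
    tx <- random_tx(30, LETTERS[1:8], min_size = 1, max_size = 6)
    db <- as_db(tx)
    min_sup <- sample(c(0.1, 0.2, 0.3), 1)
    fr <- apriori(db, min_sup)
    oracle <- oracle_frequent(lapply(tx, unique), min_sup)
    o_labels <- sort(vapply(oracle, function(f) paste(sort(f$items), collapse = "+"), ""))
    labels <- vapply(fr$items, paste, "", collapse = "+")
    expect_identical(sort(labels), o_labels)
    o_counts <- stats::setNames(vapply(oracle, `[[`, 0L, "count"),
                                vapply(oracle, function(f) paste(sort(f$items), collapse = "+"), ""))
    expect_identical(as.integer(fr$count), as.integer(unname(o_counts[labels])))

    rules <- generate_rules(fr, min_support = min_sup, min_confidence = 0.5)
    o_rules <- oracle_rules(lapply(tx, unique), min_sup, 0.5)
    if (is.null(o_rules)) {
      expect_equal(nrow(rules), 0L)
    } else {
      got <- rules[order(rules$lhs_label, rules$rhs_label),
                   c("lhs_label", "rhs_label", "support", "confidence",
                     "coverage", "lift", "count")]
      got <- plain_df(got); o_rules <- plain_df(o_rules)
      got$count <- as.numeric(got$count); o_rules$count <- as.numeric(o_rules$count)
      expect_equal(got, o_rules, tolerance = 1e-12)
    }
  }
})

test_that("downward closure holds for every reported itemset", {
  set.seed(12)
  tx <- random_tx(40, LETTERS[1:7], max_size = 5)
  fr <- apriori(as_db(tx), 0.15)
  labels <- vapply(fr$items, paste, "", collapse = "\r")
  for (i in which(fr$size > 1L)) {
    for (d in seq_along(fr$items[[i]])) {
      expect_true(paste(fr$items[[i]][-d], collapse = "\r") %in% labels)
    }
  }
})

test_that("apriori output is independent of transaction order", {
  set.seed(13)
  tx <- random_tx(25, LETTERS[1:6], max_size = 4)
  fr1 <- apriori(as_db(tx), 0.2)
  fr2 <- apriori(as_db(tx[sample(length(tx))]), 0.2)
  expect_equal(fr1$items, fr2$items)
  expect_equal(fr1$count, fr2$count)
})

test_that("rule metric identities hold and lift is symmetric", {
  set.seed(14)
  tx <- random_tx(40, LETTERS[1:6], min_size = 2, max_size = 5)
  db <- as_db(tx)
  fr <- apriori(db, 0.05)
  rules <- generate_rules(fr, min_support = 0.05, min_confidence = 0, strict = FALSE)
  n <- attr(rules, "n_transactions")
  expect_equal(rules$support, rules$count / n, tolerance = 1e-12)
  expect_equal(rules$confidence, rules$support / rules$coverage, tolerance = 1e-12)
  expect_true(all(rules$support <= rules$coverage + 1e-12))
  # lift symmetry for single-item two-sided rules
  pair_rules <- rules[lengths(rules$lhs) == 1L, ]
  key <- paste(pair_rules$lhs_label, pair_rules$rhs_label)
  rev_key <- paste(pair_rules$rhs_label, pair_rules$lhs_label)
  m <- match(rev_key, key)
  ok <- !is.na(m)
  expect_true(any(ok))
  expect_equal(pair_rules$lift[ok], pair_rules$lift[m[ok]], tolerance = 1e-12)
})

test_that("strict thresholds exclude boundary rules by default", {
  # A+B in exactly half the transactions: support == 0.5
  tx <- c(rep(list(c("A", "B")), 5), rep(list("A"), 5))
  fr <- apriori(as_db(tx), 0.4)
  strict <- generate_rules(fr, min_support = 0.5, min_confidence = 0.4)
  expect_false("A" %in% strict$lhs_label)
  loose <- generate_rules(fr, min_support = 0.5, min_confidence = 0.4,
                          strict = FALSE)
  expect_true("A" %in% loose$lhs_label)
})

test_that("rule grouping is deterministic, co-clusters duplicates and recovers blocks", {
  # two disjoint item blocks yield two clear rule families
  set.seed(15)
  block <- function(items, n) {
    lapply(seq_len(n), function(i) sample(items, 3))
  }
  tx <- c(block(c("A", "B", "C", "D"), 60), block(c("W", "X", "Y", "Z"), 60))
  fr <- apriori(as_db(tx), 0.05)
  rules <- generate_rules(fr, min_support = 0.05, min_confidence = 0.1)
  expect_gt(nrow(rules), 4)
  hits <- 0L
  for (s in 1:20) {
    cl <- group_rules(rules, k = 2, seed = s)
    in_first <- vapply(rules$lhs, function(l) l[1] %in% c("A", "B", "C", "D"), NA)
    if (length(unique(cl[in_first])) == 1L &&
        length(unique(cl[!in_first])) == 1L &&
        cl[in_first][1] != cl[!in_first][1]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  expect_identical(group_rules(rules, 2, seed = 3), group_rules(rules, 2, seed = 3))

  # duplicated rules co-cluster; k = #distinct vectors gives singleton classes
  dup <- rules[c(1, 1, 2, 3), ]
  class(dup) <- class(rules)
  attr(dup, "n_transactions") <- attr(rules, "n_transactions")
  cl <- group_rules(dup, k = 3, seed = 1)
  expect_equal(cl[1], cl[2])
  expect_length(unique(cl), 3L)
  expect_error(group_rules(dup, k = 4, seed = 1), "distinct")
})
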