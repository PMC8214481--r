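toy_net <- function(weights = c(AB = 10, AC = 5, BC = 1)) {
  # explicit network with known weights, bypassing counting
  pairs <- do.call(rbind, strsplit(names(weights), ""))
  structure(list(edges = data.frame(herb_a = pairs[, 1], herb_b = pairs[, 2],
                                    weight = as.numeric(weights),
                                    stringsAsFactors = FALSE),
                 herbs = sort(unique(c(pairs))), n_herbs = length(unique(c(pairs))),
                 total_weight = sum(weights)),
            class = "herb_network")
}

test_that("co-prescription weights are pairwise prescription counts", {
  db <- new_transaction_db(paste0("p", 1:4), rep("case", 4),
                           list(c("A", "B"), c("A", "B"), c("A", "C"), "D"))
  net <- build_herb_network(db)
  expect_equal(net$n_herbs, 4L)              # D has no edges but is a herb
  expect_equal(net$edges$weight[net$edges$herb_a == "A" & net$edges$herb_b == "B"], 2)
  expect_equal(net$edges$weight[net$edges$herb_a == "A" & net$edges$herb_b == "C"], 1)
  expect_false(any(net$edges$herb_a == "B" & net$edges$herb_b == "C"))
  expect_equal(net$total_weight, 3)
})

test_that("co-prescription counting matches a brute-force double loop", {
  set.seed(101)
  for (rep in 1:3) {
    tx <- random_tx(50, LETTERS[1:10], min_size = 1, max_size = 6)
    db <- new_transaction_db(sprintf("p%02d", 1:50), rep("case", 50), tx)
    net <- build_herb_network(db)
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges$herb_a[r]; b <- net$edges$herb_b[r]
      brute <- sum(vapply(tx, function(t) a %in% t && b %in% t, NA))
      expect_equal(net$edges$weight[r], brute)
    }
    # no zero-weight pair missing: total must match brute-force total
    brute_total <- sum(vapply(tx, function(t) choose(length(unique(t)), 2), 0))
    expect_equal(net$total_weight, brute_total)
  }
})

test_that("shell criterion retains the hand-evaluated prefix", {
  net <- toy_net()                            # AB 10, AC 5, BC 1, N = 3
  s <- extract_shell(net, alpha = 2.4)
  # k=1: 10*3 >= 16; k=2: 15*3 < 2^2.4*16; so the layer is {AB}
  expect_equal(s$k, 1L)
  expect_equal(s$layer$herb_a, "A")
  expect_equal(s$layer$herb_b, "B")
  expect_false(s$fallback)
  expect_equal(s$residual$total_weight, 6)
  expect_equal(s$residual$n_herbs, 3L)        # N unchanged on the residual
})

test_that("alpha -> 0 with uniform weights retains every edge", {
  net <- toy_net(c(AB = 4, AC = 4, BC = 4))
  s <- extract_shell(net, alpha = 1e-9)
  expect_equal(s$k, 3L)
})

test_that("single-edge networks give exactly one layer and K >= 1 holds", {
  net <- toy_net(c(AB = 7))
  s <- extract_shell(net, alpha = 2.4)
  expect_equal(s$k, 1L)
  h <- extract_hierarchy(net, alpha = 2.4)
  expect_length(h$layers, 1L)
  expect_equal(h$core_herbs, c("A", "B"))
})

test_that("shell extraction agrees with brute-force criterion evaluation", {
  set.seed(202)
  for (rep in 1:100) {
    n_herbs <- sample(4:10, 1)
    herbs <- LETTERS[seq_len(n_herbs)]
    pairs <- utils::combn(herbs, 2)
    keep <- runif(ncol(pairs)) < 0.6
    if (!any(keep)) keep[1] <- TRUE
    w <- sample(1:50, sum(keep), replace = TRUE)
    net <- structure(list(
      edges = data.frame(herb_a = pairs[1, keep], herb_b = pairs[2, keep],
                         weight = w, stringsAsFactors = FALSE),
      herbs = herbs, n_herbs = n_herbs, total_weight = sum(w)),
      class = "herb_network")
    expected_k <- oracle_shell_k(w, n_herbs, 2.4)
    s <- suppressWarnings(extract_shell(net, alpha = 2.4))
    expect_equal(s$k, max(expected_k, 1L))
    expect_equal(s$fallback, expected_k == 0L)
    # layers partition the edges when run to exhaustion, conserving weight
    h <- suppressWarnings(extract_hierarchy(net, alpha = 2.4))
    flat <- shell_layers_table(h)
    expect_equal(sum(flat$weight), net$total_weight)
    key <- paste(flat$herb_a, flat$herb_b)
    expect_setequal(key, paste(net$edges$herb_a, net$edges$herb_b))
    expect_false(any(duplicated(key)))
  }
})

test_that("tie-breaks are lexicographic and output order-invariant", {
  db1 <- new_transaction_db(paste0("p", 1:3), rep("case", 3),
                            list(c("B", "C"), c("A", "B"), c("A", "C")))
  db2 <- new_transaction_db(paste0("q", 1:3), rep("case", 3),
                            list(c("A", "B"), c("A", "C"), c("B", "C")))
  n1 <- build_herb_network(db1); n2 <- build_herb_network(db2)
  expect_equal(n1$edges, n2$edges)
  s <- extract_shell(n1, alpha = 1e-9)        # all weights tie at 1
  expect_equal(paste(s$layer$herb_a, s$layer$herb_b), c("A B", "A C", "B C"))
})

test_that("layer-1 weights dominate layer-2 weights at matched rank", {
  set.seed(303)
  db <- simulate_cohort(cohort_spec(n_case = 200, n_control = 0,
                                    herb_universe_size = 30, mean_rx_size = 6,
                                    sd_rx_size = 1, core_herbs = c("X", "Y"),
                                    specific_herbs = character(), seed = 77))
  h <- suppressWarnings(extract_hierarchy(build_herb_network(db), alpha = 2.4))
  if (length(h$layers) >= 2) {
    w1 <- h$layers[[1]]$weight; w2 <- h$layers[[2]]$weight
    m <- min(length(w1), length(w2))
    expect_true(all(w1[seq_len(m)] >= w2[seq_len(m)]))
  }
  expect_error(build_herb_network(db, cohort = "control"), "no transactions")
})
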