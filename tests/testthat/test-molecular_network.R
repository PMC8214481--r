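test_that("network assembly unions PPI, compound-target edges and disease genes", {
  ppi <- clean_edge_list(data.frame(a = c("g1", "g2"), b = c("g2", "g3"),
                                    score = c(0.95, 0.91)))
  expect_equal(nrow(build_molecular_network(ppi)$edges), 2L)

  ann <- list(H1 = new_herb_annotation("H1", compounds = "c1",
                                       targets = c("g1", "g4")))
  net <- suppressWarnings(build_molecular_network(ppi, ann, c("g3", "g9")))
  expect_equal(nrow(net$edges), 4L)               # 2 PPI + 2 compound-target
  expect_setequal(net$nodes$id, c("g1", "g2", "g3", "g4", "g9", "c1"))
  expect_true(net$nodes$is_disease[net$nodes$id == "g9"])   # isolated seed kept
  expect_warning(build_molecular_network(ppi, ann, "g9"), "isolated")
  expect_true(net$nodes$is_compound[net$nodes$id == "c1"])
  expect_equal(sum(net$nodes$is_target), 2L)
})

test_that("MCODE: cliques are found, low-degree graphs give nothing, bridges do not merge", {
  # 4-clique plus isolated-ish vertices -> exactly the clique
  clique <- t(utils::combn(paste0("a", 1:4), 2))
  extra <- rbind(c("a1", "x"), c("x", "y"))
  g <- data.frame(from = c(clique[, 1], extra[, 1]),
                  to = c(clique[, 2], extra[, 2]))
  cores <- mcode_cores(g)
  expect_length(cores, 1L)
  expect_equal(cores[[1]]$members, paste0("a", 1:4))
  expect_equal(cores[[1]]$density, 1)

  # max degree 1: no node passes the degree cutoff
  expect_length(mcode_cores(data.frame(from = c("a", "c"), to = c("b", "d"))), 0L)

  # two 4-cliques joined through a bridge node: two complexes, the bridge
  # endpoints retained only via their own cliques, the bridge node excluded
  cl2 <- t(utils::combn(paste0("b", 1:4), 2))
  bridged <- data.frame(
    from = c(clique[, 1], cl2[, 1], "a1", "b1"),
    to = c(clique[, 2], cl2[, 2], "z", "z"))
  cores2 <- mcode_cores(bridged)
  expect_length(cores2, 2L)
  members <- lapply(cores2, `[[`, "members")
  expect_setequal(members, list(paste0("a", 1:4), paste0("b", 1:4)))
  expect_false("z" %in% unlist(members))
})

test_that("MCODE haircut trims singly-connected members", {
  # v hangs off the clique via a1 only (plus a leaf w that gives v degree 2);
  # a permissive score cutoff admits v into the clique complex, where it has
  # in-complex degree 1 and is removed exactly when haircut is on
  clique <- t(utils::combn(paste0("a", 1:4), 2))
  g <- data.frame(from = c(clique[, 1], "a1", "v"),
                  to = c(clique[, 2], "v", "w"))
  with_haircut <- mcode_cores(g, node_score_cutoff = 0.9, haircut = TRUE)
  expect_equal(with_haircut[[1]]$members, paste0("a", 1:4))
  without <- mcode_cores(g, node_score_cutoff = 0.9, haircut = FALSE)
  expect_setequal(without[[1]]$members, c(paste0("a", 1:4), "v"))
})

test_that("RWR matches the direct linear solve and conserves probability", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_edge_df(sample(10:50, 1), p_edge = 0.15)
    ids <- unique(c(g$from, g$to))
    seeds <- sample(ids, sample(1:3, 1))
    sc <- rwr(g, seeds, restart_prob = 0.75)
    expect_true(sc$converged)
    expect_lt(abs(sum(sc$scores) - 1), 1e-9)
    expect_true(all(sc$scores >= 0))
    ref <- oracle_rwr(g, seeds, 0.75)
    expect_equal(sc$scores[names(ref)], ref, tolerance = 1e-8)
  }
})

test_that("RWR degenerate cases: full restart, disconnection, missing seeds", {
  g <- data.frame(from = c("a", "b", "x"), to = c("b", "c", "y"), weight = 1)
  full <- rwr(g, c("a", "b"), restart_prob = 1)
  expect_equal(unname(full$scores[c("a", "b")]), c(0.5, 0.5))
  expect_equal(unname(full$scores[c("c", "x", "y")]), c(0, 0, 0))

  part <- rwr(g, "a", restart_prob = 0.75)
  expect_equal(unname(part$scores[c("x", "y")]), c(0, 0))
  expect_error(rwr(g, c("a", "nope")), "nope")
  expect_error(rwr(g, character()), "empty")
})

test_that("adding a seed-to-node edge never decreases that node's score", {
  set.seed(22)
  for (rep in 1:100) {
    g <- random_edge_df(sample(8:15, 1), p_edge = 0.25)
    ids <- sort(unique(c(g$from, g$to)))
    seed_node <- sample(ids, 1)
    absent <- ids[!ids %in% c(g$to[g$from == seed_node], g$from[g$to == seed_node],
                              seed_node)]
    if (length(absent) == 0) next
    v <- sample(absent, 1)
    before <- rwr(g, seed_node, 0.75)$scores[v]
    g2 <- rbind(g, data.frame(from = seed_node, to = v, weight = 1))
    after <- rwr(g2, seed_node, 0.75)$scores[v]
    expect_gte(after + 1e-12, before)
  }
})

test_that("upper-quartile compound retention uses a strict type-7 Q3 cut", {
  sc <- structure(list(scores = stats::setNames((1:8) / 36, paste0("c", 1:8)),
                       restart_prob = 0.75, seeds = "s", iterations = 1,
                       converged = TRUE), class = "rwr_scores")
  out <- retain_core_compounds(sc, paste0("c", 1:8))
  expect_equal(out$compound[out$retained], c("c8", "c7"))   # only values > 6.25/36

  tie <- sc; tie$scores[] <- 0.125
  expect_warning(out2 <- retain_core_compounds(tie, paste0("c", 1:8)), "quartile")
  expect_false(any(out2$retained))
  expect_equal(out2$compound, paste0("c", 1:8))             # deterministic tie order

  few <- structure(list(scores = c(a = .5, b = .3, c = .2), restart_prob = .75,
                        seeds = "s", iterations = 1, converged = TRUE),
                   class = "rwr_scores")
  expect_warning(out3 <- retain_core_compounds(few, c("a", "b", "c")), "fewer")
  expect_true(all(out3$retained))
})
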