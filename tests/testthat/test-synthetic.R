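test_that("cohort simulation honours degenerate and null settings", {
  spec <- cohort_spec(n_case = 50, n_control = 50, herb_universe_size = 30,
                      mean_rx_size = 5, sd_rx_size = 1,
                      core_herbs = "anchor", core_inclusion_prob = 1,
                      specific_herbs = character(), seed = 11)
  db <- simulate_cohort(spec)
  expect_true(all(vapply(db$herbs, function(h) "anchor" %in% h, NA)))

  # rr_target = 1: empirical case/control frequency ratio near 1
  null_spec <- cohort_spec(n_case = 3000, n_control = 3000,
                           herb_universe_size = 30, mean_rx_size = 5,
                           sd_rx_size = 1, core_herbs = character(),
                           specific_herbs = "spec1", specific_bg_prob = 0.2,
                           rr_target = 1, seed = 12)
  db0 <- simulate_cohort(null_spec)
  in_rx <- vapply(db0$herbs, function(h) "spec1" %in% h, NA)
  ratio <- mean(in_rx[db0$cohort == "case"]) / mean(in_rx[db0$cohort == "control"])
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("prescription size distribution recovers its mean and sd parameters", {
  spec <- cohort_spec(n_case = 1000, n_control = 1000, seed = 21)
  db <- simulate_cohort(spec)
  sizes <- lengths(db$herbs)
  expect_lt(abs(mean(sizes) - 23.84), 0.2)
  expect_lt(abs(stats::sd(sizes) - 3.88), 0.3)
})

test_that("cohort simulation is reproducible under the seed", {
  spec <- cohort_spec(n_case = 40, n_control = 40, herb_universe_size = 60,
                      mean_rx_size = 8, sd_rx_size = 2, seed = 33)
  db1 <- simulate_cohort(spec)
  db2 <- simulate_cohort(spec)
  expect_identical(db1, db2)
  spec2 <- spec; spec2$seed <- 34L
  expect_false(identical(simulate_cohort(spec2)$herbs, db1$herbs))
})

test_that("infeasible cohort specs are rejected", {
  expect_error(cohort_spec(herb_universe_size = 5), "universe")
  expect_error(cohort_spec(rr_target = 30, specific_bg_prob = 0.5), "<= 1")
})

test_that("molecular simulation: degenerate density, overlap, determinism", {
  spec <- molecular_spec(n_proteins = 40, ppi_density = 0, n_herbs = 3,
                         n_compounds = 6, n_disease_genes = 10,
                         disease_overlap_frac = 1, n_terms = 4, set_size = 8,
                         seed = 5)
  mol <- simulate_molecular(spec)
  expect_equal(nrow(mol$ppi), 0L)
  all_targets <- unique(unlist(lapply(mol$annotations, `[[`, "targets")))
  expect_true(all(mol$disease_genes %in% all_targets))
  expect_identical(simulate_molecular(spec), mol)

  pa <- simulate_molecular(molecular_spec(n_proteins = 40,
                                          ppi_model = "preferential_attachment",
                                          ppi_m = 2, n_herbs = 3, n_compounds = 6,
                                          n_disease_genes = 10, n_terms = 4,
                                          set_size = 8, seed = 6))
  expect_gt(nrow(pa$ppi), 0L)
  expect_true(all(pa$ppi$confidence >= 0.4 & pa$ppi$confidence <= 1))
})

test_that("gene sets are valid and the planted term carries disease genes", {
  mol <- simulate_molecular(molecular_spec(n_proteins = 500,
                                           n_disease_genes = 100,
                                           n_terms = 10, set_size = 50,
                                           planted_term_enrichment = 5, seed = 9))
  coll <- mol$gene_sets
  expect_true(all(unlist(coll$sets) %in% coll$universe))
  planted_frac <- mean(coll$sets[[mol$planted_term]] %in% mol$disease_genes)
  other_frac <- mean(unlist(coll$sets[-1]) %in% mol$disease_genes)
  # weighted sampling without replacement depletes the disease pool, so the
  # realised fold is below the nominal 5 but stays well above background
  expect_gt(planted_frac, 1.5 * other_frac)
})

test_that("a full synthetic input bundle round-trips through the file formats", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(n_case = 30, n_control = 30, herb_universe_size = 40,
                    mean_rx_size = 6, sd_rx_size = 1,
                    core_herbs = c("H01", "H02"), specific_herbs = "H03",
                    seed = 44)
  ms <- molecular_spec(n_proteins = 60, ppi_density = 0.05, n_herbs = 3,
                       herb_ids = c("H01", "H02", "H03"), n_compounds = 9,
                       n_disease_genes = 12, n_terms = 5, set_size = 10,
                       seed = 45)
  paths <- write_synthetic_inputs(cs, ms, dir)
  expect_true(all(file.exists(paths)))
  db <- read_transactions(paths[["transactions"]])
  expect_equal(n_transactions(db), 60L)
  mol_edges <- read_edge_list(paths[["ppi"]], min_confidence = 0)
  expect_gt(nrow(mol_edges), 0L)
  ann <- read_herb_annotations(paths[["annotations"]])
  expect_setequal(names(ann), c("H01", "H02", "H03"))
  expect_gt(length(read_id_list(paths[["disease_genes"]])), 0L)
  expect_length(read_gmt(paths[["gene_sets"]])$sets, 5L)
})
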