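#' Specification for a synthetic prescription cohort
#'
#' Describes the generative model behind [simulate_cohort()].  Defaults mirror
#' a hospital-scale co-prescription study of hypertensive nephropathy:
#' prescriptions of 23.84 +/- 3.88 herbs drawn from a universe of 425 herbs,
#' with a planted densely co-prescribed core block and case-enriched specific
#' herbs on a Zipf-weighted background.
#'
#' @param n_case,n_control Number of case / control prescriptions.
#' @param herb_universe_size Total number of distinct herb IDs (core and
#'   specific herbs included).
#' @param mean_rx_size,sd_rx_size Mean and SD of herbs per prescription;
#'   sizes are drawn from a rounded normal truncated to
#'   `[1, herb_universe_size]`.
#' @param core_herbs Character vector of planted core herb IDs, each included
#'   in any prescription independently with probability `core_inclusion_prob`.
#' @param core_inclusion_prob Per-herb inclusion probability of core herbs.
#' @param specific_herbs Character vector of planted disease-specific herbs.
#' @param specific_bg_prob Background (control) inclusion probability of each
#'   specific herb.
#' @param rr_target Prescription-level relative risk planted for specific
#'   herbs: case inclusion probability is `rr_target * specific_bg_prob`.
#' @param background_zipf_exponent Exponent s of the Zipf weights
#'   (rank^-s) used for background herb popularity; 0 gives a flat background.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_case = 1499,
                        n_control = 1500,
                        herb_universe_size = 425,
                        mean_rx_size = 23.84,
                        sd_rx_size = 3.88,
                        core_herbs = c("huangqi", "danshen", "dangshen", "fuling",
                                       "baizhu", "danggui", "chenpi", "banxia",
                                       "gancao"),
                        core_inclusion_prob = 0.8,
                        specific_herbs = c("qumai", "cheqianzi", "ezhu",
                                           "qianshi", "niuxi"),
                        specific_bg_prob = 0.05,
                        rr_target = 3,
                        background_zipf_exponent = 1,
                        seed = 1L) {
  spec <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
               herb_universe_size = as.integer(herb_universe_size),
               mean_rx_size = mean_rx_size, sd_rx_size = sd_rx_size,
               core_herbs = as.character(core_herbs),
               core_inclusion_prob = core_inclusion_prob,
               specific_herbs = as.character(specific_herbs),
               specific_bg_prob = specific_bg_prob, rr_target = rr_target,
               background_zipf_exponent = background_zipf_exponent,
               seed = as.integer(seed))
  stopifnot(spec$n_case >= 0, spec$n_control >= 0,
            spec$mean_rx_size > 0, spec$sd_rx_size >= 0,
            spec$core_inclusion_prob > 0, spec$core_inclusion_prob <= 1,
            spec$specific_bg_prob >= 0, spec$rr_target >= 0,
            spec$background_zipf_exponent >= 0)
  if (spec$rr_target * spec$specific_bg_prob > 1) {
    stop("rr_target * specific_bg_prob must be <= 1", call. = FALSE)
  }
  if (anyDuplicated(c(spec$core_herbs, spec$specific_herbs))) {
    stop("core and specific herb lists must be disjoint and unique", call. = FALSE)
  }
  n_named <- length(spec$core_herbs) + length(spec$specific_herbs)
  if (n_named > spec$herb_universe_size) {
    stop("herb universe smaller than the planted core + specific herbs", call. = FALSE)
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a cohort-labelled prescription database
#'
#' Each prescription draws a size from a rounded truncated normal, includes
#' each core herb with its fixed probability, includes each specific herb with
#' probability `rr_target * specific_bg_prob` (cases) or `specific_bg_prob`
#' (controls), and fills the remaining slots by Zipf-weighted sampling without
#' replacement from the background herbs.  Reproducible under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `transaction_db` (see [read_transactions()]).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_case + spec$n_control
  if (n == 0L) stop("empty cohort spec", call. = FALSE)
  set.seed(spec$seed)
  n_bg <- spec$herb_universe_size - length(spec$core_herbs) - length(spec$specific_herbs)
  bg_herbs <- if (n_bg > 0) sprintf("herb%04d", seq_len(n_bg)) else character()
  bg_w <- if (n_bg > 0) seq_len(n_bg)^(-spec$background_zipf_exponent) else numeric()

  cohort <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  sizes <- round(stats::rnorm(n, spec$mean_rx_size, spec$sd_rx_size))
  sizes <- pmin(pmax(sizes, 1L), spec$herb_universe_size)

  n_core <- length(spec$core_herbs)
  n_spec <- length(spec$specific_herbs)
  core_in <- matrix(stats::runif(n * n_core) < spec$core_inclusion_prob,
                    nrow = n, ncol = n_core)
  p_spec <- ifelse(cohort == "case",
                   spec$rr_target * spec$specific_bg_prob, spec$specific_bg_prob)
  spec_in <- if (n_spec == 0L) {
    matrix(FALSE, nrow = n, ncol = 0L)
  } else {
    matrix(stats::runif(n * n_spec), nrow = n, ncol = n_spec) <
      matrix(rep(p_spec, n_spec), nrow = n, ncol = n_spec)
  }

  herbs <- vector("list", n)
  for (i in seq_len(n)) {
    fixed <- c(spec$core_herbs[core_in[i, ]], spec$specific_herbs[spec_in[i, ]])
    n_fill <- min(sizes[i] - length(fixed), n_bg)
    fill <- if (n_fill > 0) sample(bg_herbs, n_fill, prob = bg_w) else character()
    rx <- c(fixed, fill)
    if (length(rx) == 0L) rx <- sample(bg_herbs, 1L, prob = bg_w)
    herbs[[i]] <- rx
  }
  new_transaction_db(sprintf("p%05d", seq_len(n)), cohort, herbs)
}

#' Specification for a synthetic molecular data set
#'
#' Describes the generative model behind [simulate_molecular()]: a random
#' protein-protein interaction network, bipartite compound-target edges
#' grouped into herbs, a disease gene list partially overlapping the herb
#' targets, and a gene-set collection with one planted term whose
#' disease-gene density is `planted_term_enrichment` times the background
#' density.
#'
#' @param n_proteins Number of protein (gene) nodes.
#' @param ppi_model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param ppi_density Edge probability for the Erdos-Renyi model.
#' @param ppi_m Edges added per step for preferential attachment.
#' @param n_herbs Number of herbs annotated (ignored when `herb_ids` given).
#' @param herb_ids Optional explicit herb IDs to annotate (e.g. the planted
#'   core and specific herbs of a [cohort_spec()]).
#' @param n_compounds Number of compounds, assigned round-robin to herbs.
#' @param targets_per_compound_mean Mean of the (1 + Poisson) target count per
#'   compound.
#' @param n_disease_genes Number of disease genes.
#' @param disease_overlap_frac Fraction of disease genes drawn from the herb
#'   target pool (the rest come from non-target proteins where possible).
#' @param n_terms Number of gene sets.
#' @param set_size Genes per set.
#' @param planted_term_enrichment Sampling weight multiplier for disease genes
#'   in the first ("planted") term; 1 plants nothing.
#' @param confidence_range Range of simulated interaction confidences (0-1).
#' @param symptoms_per_herb Number of symptom IDs drawn per herb from a pool of
#'   `3 * n_herbs` symptoms.
#' @param seed Integer seed.
#' @return A validated `molecular_spec` list.
#' @export
molecular_spec <- function(n_proteins = 500,
                           ppi_model = c("erdos_renyi", "preferential_attachment"),
                           ppi_density = 0.02,
                           ppi_m = 3,
                           n_herbs = 14,
                           herb_ids = NULL,
                           n_compounds = 80,
                           targets_per_compound_mean = 3,
                           n_disease_genes = 50,
                           disease_overlap_frac = 0.5,
                           n_terms = 30,
                           set_size = 25,
                           planted_term_enrichment = 5,
                           confidence_range = c(0.4, 1),
                           symptoms_per_herb = 8,
                           seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               ppi_model = match.arg(ppi_model),
               ppi_density = ppi_density, ppi_m = as.integer(ppi_m),
               n_herbs = if (is.null(herb_ids)) as.integer(n_herbs)
                         else length(herb_ids),
               herb_ids = if (is.null(herb_ids)) NULL else as.character(herb_ids),
               n_compounds = as.integer(n_compounds),
               targets_per_compound_mean = targets_per_compound_mean,
               n_disease_genes = as.integer(n_disease_genes),
               disease_overlap_frac = disease_overlap_frac,
               n_terms = as.integer(n_terms), set_size = as.integer(set_size),
               planted_term_enrichment = planted_term_enrichment,
               confidence_range = confidence_range,
               symptoms_per_herb = as.integer(symptoms_per_herb),
               seed = as.integer(seed))
  stopifnot(spec$n_proteins > 0, spec$ppi_density >= 0, spec$ppi_density <= 1,
            spec$n_disease_genes <= spec$n_proteins,
            spec$disease_overlap_frac >= 0, spec$disease_overlap_frac <= 1,
            spec$planted_term_enrichment > 0,
            spec$set_size <= spec$n_proteins,
            spec$n_herbs > 0, spec$n_compounds >= spec$n_herbs)
  class(spec) <- "molecular_spec"
  spec
}

#' Simulate molecular inputs: PPI, herb annotations, disease genes, gene sets
#'
#' @param spec A [molecular_spec()].
#' @return List with elements `ppi` (canonical edge data frame with simulated
#'   confidences), `annotations` (named list of `herb_annotation`),
#'   `disease_genes` (character), `gene_sets` (`gene_set_collection`, universe
#'   = all proteins) and `planted_term` (ID of the planted set).
#' @export
simulate_molecular <- function(spec) {
  stopifnot(inherits(spec, "molecular_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_proteins))

  g <- if (spec$ppi_model == "erdos_renyi") {
    igraph::sample_gnp(spec$n_proteins, spec$ppi_density)
  } else {
    igraph::sample_pa(spec$n_proteins, m = spec$ppi_m, directed = FALSE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi <- if (nrow(el) > 0) {
    clean_edge_list(data.frame(
      a = genes[el[, 1L]], b = genes[el[, 2L]],
      confidence = stats::runif(nrow(el), spec$confidence_range[1L],
                                spec$confidence_range[2L])))
  } else {
    data.frame(protein_a = character(), protein_b = character(),
               confidence = numeric(), stringsAsFactors = FALSE)
  }

  herbs <- if (is.null(spec$herb_ids)) sprintf("H%02d", seq_len(spec$n_herbs))
           else spec$herb_ids
  compounds <- sprintf("c%04d", seq_len(spec$n_compounds))
  herb_of_compound <- rep_len(herbs, spec$n_compounds)
  n_targets <- 1L + stats::rpois(spec$n_compounds,
                                 max(spec$targets_per_compound_mean - 1, 0))
  compound_targets <- lapply(n_targets, function(k) {
    sample(genes, min(k, length(genes)))
  })
  names(compound_targets) <- compounds

  symptom_pool <- sprintf("s%03d", seq_len(3L * spec$n_herbs))
  annotations <- lapply(herbs, function(h) {
    cps <- compounds[herb_of_compound == h]
    new_herb_annotation(
      herb_id = h, compounds = cps,
      targets = unique(unlist(compound_targets[cps], use.names = FALSE)),
      symptoms = sample(symptom_pool, min(spec$symptoms_per_herb,
                                          length(symptom_pool)))
    )
  })
  names(annotations) <- herbs

  target_pool <- unique(unlist(compound_targets, use.names = FALSE))
  n_from_targets <- min(round(spec$disease_overlap_frac * spec$n_disease_genes),
                        length(target_pool))
  from_targets <- sample(target_pool, n_from_targets)
  rest_pool <- setdiff(genes, from_targets)
  non_target_pool <- setdiff(rest_pool, target_pool)
  n_rest <- spec$n_disease_genes - n_from_targets
  # prefer non-target genes for the non-overlapping part so overlap_frac is honoured
  rest <- if (n_rest <= length(non_target_pool)) {
    sample(non_target_pool, n_rest)
  } else {
    c(non_target_pool, sample(setdiff(rest_pool, non_target_pool),
                              n_rest - length(non_target_pool)))
  }
  disease_genes <- sort(c(from_targets, rest))

  w <- rep(1, spec$n_proteins)
  sets <- vector("list", spec$n_terms)
  for (t in seq_len(spec$n_terms)) {
    wt <- w
    if (t == 1L && spec$planted_term_enrichment != 1) {
      wt[genes %in% disease_genes] <- spec$planted_term_enrichment
    }
    sets[[t]] <- sample(genes, spec$set_size, prob = wt)
  }
  ids <- sprintf("T%03d", seq_len(spec$n_terms))
  names(sets) <- ids
  gene_sets <- new_gene_set_collection(
    sets, stats::setNames(paste("synthetic term", ids), ids), universe = genes)

  list(ppi = ppi, annotations = annotations, disease_genes = disease_genes,
       gene_sets = gene_sets, planted_term = ids[1L])
}

#' Write a full synthetic input bundle to disk
#'
#' Writes the cohort and molecular outputs in the package's file formats
#' (transactions CSV, STRING-style edge TSV, long-form annotation TSV, gene
#' list, GMT) so a pipeline run can start from files alone.
#'
#' @param cohort_spec A [cohort_spec()].
#' @param molecular_spec A [molecular_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(cohort_spec, molecular_spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- simulate_cohort(cohort_spec)
  mol <- simulate_molecular(molecular_spec)
  paths <- c(
    transactions = file.path(dir, "transactions.csv"),
    ppi = file.path(dir, "ppi.tsv"),
    annotations = file.path(dir, "herb_annotations.tsv"),
    disease_genes = file.path(dir, "disease_genes.txt"),
    gene_sets = file.path(dir, "gene_sets.gmt")
  )
  write_transactions(db, paths[["transactions"]])
  write_edge_list(mol$ppi, paths[["ppi"]], scale = "string")
  write_herb_annotations(mol$annotations, paths[["annotations"]])
  write_id_list(mol$disease_genes, paths[["disease_genes"]])
  write_gmt(mol$gene_sets, paths[["gene_sets"]])
  invisible(paths)
}
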