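#' Pipeline configuration
#'
#' Collects the input paths and every stage threshold.  Defaults are the
#' study-standard values: degree coefficient 2.4, RR > 1 with p < 0.05,
#' Support > 0.2 with Confidence > 0.5, interaction confidence >= 0.9,
#' restart probability 0.75, Q < 0.05, and per-level cluster counts
#' 4 (symptom), 3 (target), 4 (GO), 4 (KEGG).
#'
#' @param transactions,ppi,annotations,disease_genes,gene_sets Input paths
#'   (see [read_transactions()], [read_edge_list()],
#'   [read_herb_annotations()], [read_id_list()], [read_gmt()]).
#' @param alpha Degree coefficient for shell extraction.
#' @param max_layers Maximum shell layers.
#' @param rr_min,p_max Specific-herb thresholds.
#' @param min_support,min_confidence Association-rule thresholds (strict `>`).
#' @param ppi_min_confidence Interaction confidence threshold.
#' @param restart_prob RWR restart probability.
#' @param q_max Enrichment significance threshold.
#' @param k_symptom,k_target,k_go,k_kegg Cluster counts per profile level.
#' @param rule_groups Number of k-means groups for rules (NULL to skip).
#' @param seed Integer seed for the seeded stages (rule grouping).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(transactions, ppi, annotations, disease_genes,
                            gene_sets,
                            alpha = 2.4, max_layers = 3,
                            rr_min = 1, p_max = 0.05,
                            min_support = 0.2, min_confidence = 0.5,
                            ppi_min_confidence = 0.9,
                            restart_prob = 0.75, q_max = 0.05,
                            k_symptom = 4, k_target = 3, k_go = 4, k_kegg = 4,
                            rule_groups = NULL, seed = 1L) {
  cfg <- list(paths = list(transactions = transactions, ppi = ppi,
                           annotations = annotations,
                           disease_genes = disease_genes,
                           gene_sets = gene_sets),
              alpha = alpha, max_layers = max_layers,
              rr_min = rr_min, p_max = p_max,
              min_support = min_support, min_confidence = min_confidence,
              ppi_min_confidence = ppi_min_confidence,
              restart_prob = restart_prob, q_max = q_max,
              k_symptom = k_symptom, k_target = k_target,
              k_go = k_go, k_kegg = k_kegg,
              rule_groups = rule_groups, seed = as.integer(seed))
  stopifnot(cfg$alpha > 0, cfg$rr_min >= 0,
            cfg$p_max > 0, cfg$p_max <= 1,
            cfg$min_support > 0, cfg$min_support <= 1,
            cfg$min_confidence >= 0, cfg$min_confidence <= 1,
            cfg$ppi_min_confidence >= 0, cfg$ppi_min_confidence <= 1,
            cfg$restart_prob > 0, cfg$restart_prob <= 1,
            cfg$q_max > 0, cfg$q_max <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds the same fields as [pipeline_config()]; input paths go
#' under a `paths:` mapping and are resolved relative to the YAML file.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  args <- y[setdiff(names(y), "paths")]
  args <- c(lapply(y$paths, resolve), args)
  do.call(pipeline_config, args)
}

# stable md5 of the configuration (paths excluded: the manifest records input
# checksums separately, so the hash changes iff an analysis setting changes)
config_hash <- function(config) {
  settings <- config[setdiff(names(config), "paths")]
  settings <- settings[order(names(settings))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full mining pipeline
#'
#' Executes the stages in study order on the configured inputs: (1) build the
#' case co-prescription network and peel the shell hierarchy (core herbs);
#' (2) screen disease-specific herbs by relative risk and chi-square;
#' (3) mine association rules on case prescriptions with Apriori;
#' (4) assemble the compound-target-disease network, detect MCODE complexes,
#' rank compounds by RWR from the disease-gene seeds and retain the upper
#' quartile; (5) run hypergeometric enrichment for the disease genes and for
#' each herb's targets, and derive per-herb core pathways; (6) build
#' symptom/target (binary) and pathway (count) profiles for the focus herbs
#' and cluster each with Ward/ESS.  Every output is written as TSV under
#' `out_dir` together with a JSON manifest recording the configuration hash,
#' seed and input checksums.  Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed); NULL writes nothing.
#' @return Invisibly, a result bundle: list with `core_herbs`,
#'   `specific_herbs`, `focus_herbs`, `rules`, `rule_groups`, `shells`,
#'   `complexes`, `compound_ranking`, `disease_enrichment`,
#'   `herb_enrichment`, `core_pathways`, `profiles`, `assignments`,
#'   `cluster_table` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  db <- stage("read_transactions", read_transactions(config$paths$transactions))
  ppi <- stage("read_ppi",
               read_edge_list(config$paths$ppi, config$ppi_min_confidence))
  annotations <- stage("read_annotations",
                       read_herb_annotations(config$paths$annotations))
  disease_genes <- stage("read_disease_genes",
                         read_id_list(config$paths$disease_genes))
  gene_sets <- stage("read_gene_sets", read_gmt(config$paths$gene_sets))

  # 1. co-prescription network and shell hierarchy on case prescriptions
  net <- stage("herb_network", build_herb_network(db, cohort = "case"))
  shells <- stage("shell_extraction",
                  suppressWarnings(extract_hierarchy(net, alpha = config$alpha,
                                                     max_layers = config$max_layers)))

  # 2. disease-specific herbs
  spec_tab <- stage("specificity",
                    suppressWarnings(specific_herbs(db, rr_min = config$rr_min,
                                                    p_max = config$p_max)))
  specific <- spec_tab$herb_id[spec_tab$selected]

  # 3. association rules on case prescriptions
  case_db <- new_transaction_db(db$id[db$cohort == "case"],
                                db$cohort[db$cohort == "case"],
                                db$herbs[db$cohort == "case"])
  frequents <- stage("apriori", apriori(case_db, min_support = config$min_support))
  rules <- stage("rules", generate_rules(frequents,
                                         min_support = config$min_support,
                                         min_confidence = config$min_confidence))
  rule_groups <- if (!is.null(config$rule_groups) && nrow(rules) >= config$rule_groups) {
    stage("rule_grouping", group_rules(rules, config$rule_groups, seed = config$seed))
  }

  # the focus herbs: shell cores plus RR-specific herbs (the study's 14-herb analog)
  focus <- sort(union(shells$core_herbs, specific))

  # 4. molecular network, complexes, compound ranking
  mol <- stage("molecular_network",
               suppressWarnings(build_molecular_network(ppi, annotations,
                                                        disease_genes)))
  complexes <- stage("mcode", mcode_cores(mol))
  seeds <- intersect(disease_genes, mol$nodes$id)
  rwr_scores <- stage("rwr", rwr(mol, seeds, restart_prob = config$restart_prob))
  compound_ids <- mol$nodes$id[mol$nodes$is_compound]
  ranking <- stage("compound_retention",
                   suppressWarnings(retain_core_compounds(rwr_scores, compound_ids)))

  # 5. enrichment: disease genes and per-herb targets
  disease_enr <- stage("disease_enrichment",
                       suppressWarnings(enrich(disease_genes, gene_sets,
                                               q_max = config$q_max)))
  herb_enr <- list()
  for (h in names(annotations)) {
    targets <- intersect(annotations[[h]]$targets, gene_sets$universe)
    if (length(targets) > 0L) {
      herb_enr[[h]] <- stage(paste0("enrichment_", h),
                             suppressWarnings(enrich(targets, gene_sets,
                                                     q_max = config$q_max)))
    }
  }
  core_paths <- stage("core_pathways", core_pathways(herb_enr, disease_enr))

  # 6. multi-level profiles and Ward clustering for the annotated focus herbs
  prof_herbs <- intersect(names(annotations), focus)
  if (length(prof_herbs) < 2L) prof_herbs <- names(annotations)
  profiles <- list(); assignments <- list()
  lvl_cfg <- list(symptom = config$k_symptom, target = config$k_target,
                  kegg = config$k_kegg)
  feature_fun <- list(
    symptom = function(h) annotations[[h]]$symptoms,
    target = function(h) annotations[[h]]$targets,
    # pathway level: enriched-gene counts on the disease-significant terms
    kegg = function(h) {
      res <- herb_enr[[h]]
      if (is.null(res)) return(numeric())
      cand <- disease_enr$term_id[disease_enr$significant]
      hit <- intersect(res$term_id, cand)
      stats::setNames(as.numeric(res$k[match(hit, res$term_id)]), hit)
    }
  )
  for (lvl in names(lvl_cfg)) {
    feats <- lapply(prof_herbs, feature_fun[[lvl]])
    names(feats) <- prof_herbs
    prof <- tryCatch(
      suppressWarnings(build_profile(feats, level = lvl)),
      error = function(e) NULL)
    if (is.null(prof)) next
    k <- min(lvl_cfg[[lvl]], nrow(prof))
    cl <- ward_cluster(prof)
    profiles[[lvl]] <- prof
    assignments[[lvl]] <- cut_ward(cl, k)
  }
  cluster_table <- if (length(assignments) > 0L) multilevel_summary(assignments)

  manifest <- list(
    package_version = as.character(utils::packageVersion("herbnet")),
    config_hash = config_hash(config),
    seed = config$seed,
    settings = config[setdiff(names(config), "paths")],
    inputs = lapply(config$paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )

  bundle <- list(core_herbs = shells$core_herbs, specific_herbs = specific,
                 focus_herbs = focus, specificity = spec_tab,
                 rules = rules, rule_groups = rule_groups, shells = shells,
                 complexes = complexes, compound_ranking = ranking,
                 rwr = rwr_scores,
                 disease_enrichment = disease_enr, herb_enrichment = herb_enr,
                 core_pathways = core_paths, profiles = profiles,
                 assignments = assignments, cluster_table = cluster_table,
                 manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

# write the result bundle as TSV/JSON files under out_dir
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(shell_layers_table(bundle$shells), "shell_layers.tsv")
  writeLines(bundle$core_herbs, file.path(out_dir, "core_herbs.txt"))
  wt(bundle$specificity, "specific_herbs.tsv")
  rules_flat <- bundle$rules
  rules_flat$lhs <- NULL; rules_flat$rhs <- NULL
  names(rules_flat)[names(rules_flat) == "lhs_label"] <- "LHS"
  names(rules_flat)[names(rules_flat) == "rhs_label"] <- "RHS"
  names(rules_flat) <- c("LHS", "RHS", "Support", "Confidence", "Coverage",
                         "Lift", "Count")
  if (!is.null(bundle$rule_groups)) rules_flat$Group <- bundle$rule_groups
  wt(rules_flat, "association_rules.tsv")
  wt(bundle$compound_ranking, "compound_ranking.tsv")
  enr_flat <- bundle$disease_enrichment
  enr_flat$genes <- vapply(enr_flat$genes, paste, "", collapse = ";")
  wt(enr_flat, "disease_enrichment.tsv")
  if (!is.null(bundle$cluster_table)) wt(bundle$cluster_table, "cluster_table.tsv")
  complexes_df <- do.call(rbind, lapply(seq_along(bundle$complexes), function(i) {
    data.frame(complex = i, score = bundle$complexes[[i]]$score,
               members = paste(bundle$complexes[[i]]$members, collapse = ";"))
  }))
  if (!is.null(complexes_df)) wt(complexes_df, "complexes.tsv")
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
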