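#' Read cohort-labelled prescription transactions
#'
#' Reads a CSV with header `prescription_id,cohort,herbs` where `herbs` is a
#' semicolon-separated list of herb IDs, and validates it into a
#' `transaction_db`. Duplicate herb mentions within one prescription are
#' collapsed: all downstream statistics (support, co-occurrence weights,
#' relative-risk numerators) are presence-based, so a transaction is a set.
#'
#' @param path Path to the CSV file.
#' @param cohort_map Optional named character vector mapping raw cohort labels
#'   in the file to `"case"`/`"control"`, e.g. `c(HN = "case", other = "control")`.
#'   Labels already equal to `case`/`control` need no mapping.
#' @return A `transaction_db`: list with elements `id` (character),
#'   `cohort` (factor with levels case/control) and `herbs`
#'   (list of character vectors, each non-empty and deduplicated).
#' @seealso [write_transactions()], [simulate_cohort()]
#' @export
read_transactions <- function(path, cohort_map = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("prescription_id", "cohort", "herbs")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("transaction file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort <- raw$cohort
  if (!is.null(cohort_map)) {
    mapped <- !is.na(match(cohort, names(cohort_map)))
    cohort[mapped] <- cohort_map[cohort[mapped]]
  }
  bad <- which(!cohort %in% c("case", "control"))
  if (length(bad) > 0L) {
    stop("unknown cohort label(s) in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         ": ", paste(unique(raw$cohort[bad]), collapse = ", "), call. = FALSE)
  }
  herbs <- lapply(strsplit(raw$herbs, ";", fixed = TRUE), function(h) {
    unique(h[nzchar(h)])
  })
  new_transaction_db(raw$prescription_id, cohort, herbs)
}

#' Construct and validate a transaction database
#'
#' @param id Character vector of unique prescription IDs.
#' @param cohort Character/factor vector of `"case"`/`"control"` labels.
#' @param herbs List of character vectors of herb IDs (one set per prescription).
#' @return A validated `transaction_db`.
#' @export
new_transaction_db <- function(id, cohort, herbs) {
  id <- as.character(id)
  stopifnot(length(id) == length(cohort), length(id) == length(herbs))
  if (anyDuplicated(id)) {
    stop("duplicate prescription_id(s): ",
         paste(utils::head(unique(id[duplicated(id)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  herbs <- lapply(herbs, function(h) unique(as.character(h)))
  empty <- vapply(herbs, length, 1L) == 0L
  if (any(empty)) {
    stop("prescription(s) with empty herb set: ",
         paste(utils::head(id[empty], 5L), collapse = ", "), call. = FALSE)
  }
  db <- list(id = id,
             cohort = factor(as.character(cohort), levels = c("case", "control")),
             herbs = herbs)
  if (anyNA(db$cohort)) stop("cohort labels must be 'case' or 'control'", call. = FALSE)
  class(db) <- "transaction_db"
  db
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("transaction_db:", length(x$id), "prescriptions (",
      sum(x$cohort == "case"), "case /", sum(x$cohort == "control"), "control ),",
      length(unique(unlist(x$herbs))), "distinct herbs\n")
  invisible(x)
}

#' Number of transactions in a transaction database
#' @param db A `transaction_db`.
#' @return Integer count.
#' @export
n_transactions <- function(db) length(db$id)

#' Write transactions to CSV
#'
#' Inverse of [read_transactions()]; herb sets are written sorted so the
#' reader/writer round-trip is the identity on canonical files.
#'
#' @param db A `transaction_db`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(db, path) {
  out <- data.frame(
    prescription_id = db$id,
    cohort = as.character(db$cohort),
    herbs = vapply(db$herbs, function(h) paste(sort(h), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term<TAB>description<TAB>gene1<TAB>gene2...`.
#' The gene universe defaults to the union of all member genes unless supplied.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of universe gene IDs; must contain
#'   every member gene.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors), `names` (named character vector of term descriptions) and
#'   `universe` (character vector).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(short, 5L), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term ID(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  descs <- vapply(fields, `[[`, "", 2L)
  names(descs) <- ids
  new_gene_set_collection(sets, descs, universe)
}

#' Construct and validate a gene-set collection
#'
#' @param sets Named list of character vectors (term ID -> member genes).
#' @param names Optional named character vector of term descriptions.
#' @param universe Optional universe gene IDs (default: union of all members).
#' @return A `gene_set_collection`.
#' @export
new_gene_set_collection <- function(sets, names = NULL, universe = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set(s)", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(members)
  } else {
    universe <- unique(as.character(universe))
    outside <- setdiff(members, universe)
    if (length(outside) > 0L) {
      stop("gene(s) outside the supplied universe: ",
           paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(names)) {
    names <- stats::setNames(base::names(sets), base::names(sets))
  }
  structure(list(sets = sets, names = names, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' Sets and members are written in sorted order so `read_gmt(write_gmt(x))`
#' is the identity on canonical files.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  ids <- sort(names(collection$sets))
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$names[[id]], sort(collection$sets[[id]])),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a confidence-scored interaction edge list
#'
#' Reads a STRING-style TSV (`protein1`, `protein2`, `combined_score`).  Scores
#' may be on the 0-1 scale or STRING's 0-1000 scale; the scale is auto-detected
#' (any score > 1 means the file is on the 0-1000 scale and is divided by
#' 1000).  Self-loops are dropped, edges are undirected and deduplicated
#' keeping the maximum confidence, and only edges at or above `min_confidence`
#' are retained.
#'
#' @param path Path to the TSV (with header).
#' @param min_confidence Minimum retained confidence on the 0-1 scale
#'   (default 0.9, the usual high-confidence cut-off).
#' @return A data frame with columns `protein_a`, `protein_b`, `confidence`,
#'   with `protein_a < protein_b` and rows sorted.
#' @export
read_edge_list <- function(path, min_confidence = 0.9) {
  raw <- utils::read.delim(path, colClasses = c("character", "character", "numeric"),
                           check.names = FALSE)
  if (ncol(raw) < 3L) stop("edge list needs 3 columns", call. = FALSE)
  edges <- data.frame(protein_a = raw[[1L]], protein_b = raw[[2L]],
                      confidence = raw[[3L]], stringsAsFactors = FALSE)
  clean_edge_list(edges, min_confidence)
}

#' Canonicalise a raw edge list
#'
#' Workhorse behind [read_edge_list()], exposed so in-memory edge sets (for
#' example from [simulate_molecular()]) go through identical validation.
#'
#' @param edges Data frame with node pair columns and a score column (in that
#'   order).
#' @param min_confidence Minimum retained confidence on the 0-1 scale.
#' @return Canonical edge data frame (see [read_edge_list()]).
#' @export
clean_edge_list <- function(edges, min_confidence = 0) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  score <- as.numeric(edges[[3L]])
  if (any(is.na(score)) || any(score < 0) || any(score > 1000)) {
    stop("scores must be in [0,1] or [0,1000]", call. = FALSE)
  }
  if (any(score > 1)) score <- score / 1000
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  conf <- tapply(score, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[[`, "", 1L),
                    protein_b = vapply(parts, `[[`, "", 2L),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  out <- out[out$confidence >= min_confidence, , drop = FALSE]
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge list to TSV
#' @param edges Edge data frame as returned by [read_edge_list()].
#' @param path Output path.
#' @param scale Either `"unit"` (write confidences in 0-1) or `"string"`
#'   (multiply by 1000, STRING convention).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, scale = c("unit", "string")) {
  scale <- match.arg(scale)
  out <- data.frame(protein1 = edges$protein_a, protein2 = edges$protein_b,
                    combined_score = if (scale == "string") round(edges$confidence * 1000)
                                     else edges$confidence)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read herb annotations from a long-form TSV
#'
#' Expects columns `herb_id`, `relation` (one of `compound`, `target`,
#' `symptom`) and `value`.  Returns one `herb_annotation` per herb with its
#' compound, target and symptom ID sets.
#'
#' @param path Path to the TSV (with header).
#' @return Named list of `herb_annotation` objects (fields `herb_id`,
#'   `compounds`, `targets`, `symptoms`).
#' @export
read_herb_annotations <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("herb_id", "relation", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("annotation file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !raw$relation %in% c("compound", "target", "symptom")
  if (any(bad)) {
    stop("unknown relation(s): ", paste(unique(raw$relation[bad]), collapse = ", "),
         call. = FALSE)
  }
  herbs <- sort(unique(raw$herb_id))
  ann <- lapply(herbs, function(h) {
    sub <- raw[raw$herb_id == h, , drop = FALSE]
    new_herb_annotation(
      herb_id = h,
      compounds = sub$value[sub$relation == "compound"],
      targets = sub$value[sub$relation == "target"],
      symptoms = sub$value[sub$relation == "symptom"]
    )
  })
  stats::setNames(ann, herbs)
}

#' Construct an herb annotation
#'
#' Compound, target and symptom ID namespaces must be disjoint.
#'
#' @param herb_id Herb ID.
#' @param compounds,targets,symptoms Character vectors of IDs (deduplicated).
#' @return A `herb_annotation`.
#' @export
new_herb_annotation <- function(herb_id, compounds = character(),
                                targets = character(), symptoms = character()) {
  compounds <- unique(as.character(compounds))
  targets <- unique(as.character(targets))
  symptoms <- unique(as.character(symptoms))
  overlap <- c(intersect(compounds, targets), intersect(compounds, symptoms),
               intersect(targets, symptoms))
  if (length(overlap) > 0L) {
    stop("herb ", herb_id, ": ID(s) used in more than one namespace: ",
         paste(utils::head(unique(overlap), 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(herb_id = as.character(herb_id), compounds = compounds,
                 targets = targets, symptoms = symptoms),
            class = "herb_annotation")
}

#' Write herb annotations to a long-form TSV
#' @param annotations Named list of `herb_annotation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_herb_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    data.frame(
      herb_id = a$herb_id,
      relation = rep(c("compound", "target", "symptom"),
                     c(length(a$compounds), length(a$targets), length(a$symptoms))),
      value = c(sort(a$compounds), sort(a$targets), sort(a$symptoms)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain ID list (one per line)
#' @param path Path to the file.
#' @return Character vector of unique non-empty IDs.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  unique(ids[nzchar(trimws(ids))])
}

#' Write a plain ID list (one per line)
#' @param ids Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_list <- function(ids, path) {
  writeLines(sort(unique(as.character(ids))), path)
  invisible(path)
}
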