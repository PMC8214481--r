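#' Reference co-prescription rule metrics
#'
#' The ten highest-lift association rules reported for hypertensive
#' nephropathy herb prescriptions (support, confidence, coverage, lift and
#' transaction count at n = 1499 prescriptions), bundled as a reconstruction
#' fixture: from each row's count and rounded metrics the underlying 2x2
#' margins can be recovered and the transactions rebuilt, so the package's
#' rule metrics can be checked against independently printed values.
#'
#' @return Data frame with columns `lhs`, `rhs`, `support`, `confidence`,
#'   `coverage`, `lift`, `count`, `n_transactions`.
#' @seealso [reconstruct_rule_transactions()]
#' @export
hn_reference_rules <- function() {
  utils::read.delim(system.file("extdata", "hn_reference_rules.tsv",
                                package = "herbnet"),
                    stringsAsFactors = FALSE)
}

#' Rebuild a transaction database matching one reference rule row
#'
#' A rule row reports the exact co-occurrence count and rounded support,
#' confidence, coverage and lift.  The integer LHS margin is recovered by a
#' small consistency search around `count / confidence` (the true margin
#' always lies there given 3-decimal rounding), the RHS margin likewise from
#' `confidence / lift`; transactions are then laid out as
#' both-herbs / LHS-only / RHS-only / filler rows.  Mining the result
#' reproduces the printed metrics to printing precision.
#'
#' @param row One row of [hn_reference_rules()] (data frame or list).
#' @return A `transaction_db` with `n_transactions` rows, all labelled `case`.
#' @export
reconstruct_rule_transactions <- function(row) {
  n <- row$n_transactions
  both <- row$count
  fit_margin <- function(center, targets) {
    cand <- pmax(seq(floor(center) - 3L, ceiling(center) + 3L), both)
    err <- vapply(cand, function(m) {
      sum(vapply(targets, function(t) (t$fn(m) - t$printed)^2, 0))
    }, 0)
    cand[which.min(err)]
  }
  c_lhs <- fit_margin(both / row$confidence, list(
    list(fn = function(m) m / n, printed = row$coverage),
    list(fn = function(m) both / m, printed = row$confidence)
  ))
  c_rhs <- fit_margin(n * row$confidence / row$lift, list(
    list(fn = function(m) (both / c_lhs) / (m / n), printed = row$lift)
  ))
  counts <- c(both = both, lhs_only = c_lhs - both, rhs_only = c_rhs - both)
  counts <- c(counts, filler = n - sum(counts))
  stopifnot(all(counts >= 0))
  herbs <- c(rep(list(c(row$lhs, row$rhs)), counts["both"]),
             rep(list(row$lhs), counts["lhs_only"]),
             rep(list(row$rhs), counts["rhs_only"]),
             rep(list("filler_herb"), counts["filler"]))
  new_transaction_db(sprintf("p%04d", seq_len(n)), rep("case", n), herbs)
}
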