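#' Herb-use exposure tables for the case/control contrast
#'
#' For every herb occurring in at least one case prescription, tabulates
#' herb-use frequencies at the prescription level (one use per prescription
#' containing the herb): `n_ij` uses of the herb in case formulae, `n_i` total
#' herb uses in case formulae, `n_j` total uses of the herb in both cohorts,
#' and `N` total herb uses overall.
#'
#' @param db A `transaction_db` containing both cohorts.
#' @return Data frame with columns `herb_id`, `n_ij`, `n_i`, `n_j`, `N`.
#' @export
exposure_tables <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  if (!all(c("case", "control") %in% db$cohort)) {
    stop("both cohorts must be present for the case/control contrast", call. = FALSE)
  }
  is_case <- db$cohort == "case"
  case_herbs <- unlist(db$herbs[is_case], use.names = FALSE)
  all_herbs <- unlist(db$herbs, use.names = FALSE)
  n_i <- length(case_herbs)
  N <- length(all_herbs)
  herbs <- sort(unique(case_herbs))
  n_ij <- as.integer(table(factor(case_herbs, levels = herbs)))
  n_j <- as.integer(table(factor(all_herbs, levels = herbs)))
  data.frame(herb_id = herbs, n_ij = n_ij, n_i = n_i, n_j = n_j, N = N,
             stringsAsFactors = FALSE)
}

#' Relative risk of herb use between case and control formulae
#'
#' \deqn{RR = \frac{n_{ij}/n_i}{(n_j - n_{ij})/(N - n_i)}}
#' i.e. the herb's use proportion among case herb uses divided by its use
#' proportion among control herb uses.  When the herb is absent from controls
#' (`n_j == n_ij`) the ratio is `Inf`.
#'
#' @param n_ij Uses of the herb in case formulae.
#' @param n_i Total herb uses in case formulae.
#' @param n_j Total uses of the herb in both cohorts.
#' @param N Total herb uses overall.
#' @return Numeric vector of relative risks (vectorised over the counts).
#' @export
relative_risk <- function(n_ij, n_i, n_j, N) {
  if (any(n_i <= 0) || any(N <= n_i)) {
    stop("need n_i > 0 and N > n_i (both cohorts non-empty)", call. = FALSE)
  }
  if (any(n_ij > pmin(n_i, n_j))) stop("n_ij cannot exceed min(n_i, n_j)", call. = FALSE)
  (n_ij / n_i) / ((n_j - n_ij) / (N - n_i))
}

#' Pearson chi-square test for a 2x2 herb-use table
#'
#' The table is `a = n_ij`, `b = n_i - n_ij`, `c = n_j - n_ij`,
#' `d = N - n_i - n_j + n_ij`.  The statistic is the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with df = 1, without continuity
#' correction by default (counts here are large); the p-value comes from the
#' chi-square survival function.  Tables with a zero expected cell give `NA`.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param correct Apply the Yates continuity correction.
#' @return Data frame with columns `chi2` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative", call. = FALSE)
  # doubles: the closed form multiplies four margins and overflows integers
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  num <- abs(a * d - b * c)
  if (isTRUE(correct)) num <- pmax(num - n / 2, 0)
  chi2 <- ifelse(denom > 0, n * num^2 / denom, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = p)
}

#' Screen disease-specific herbs by relative risk and chi-square
#'
#' Combines [exposure_tables()], [relative_risk()] and [chi_square_2x2()]:
#' a herb is selected when `RR > rr_min` and `p < p_max` (raw p-values by
#' default; a Benjamini-Hochberg screen is available via `adjust`).  Herbs
#' whose 2x2 table has a zero expected cell are excluded with a warning.
#'
#' @param db A `transaction_db` with both cohorts.
#' @param rr_min Relative-risk threshold (default 1, strict `>`).
#' @param p_max Significance threshold (default 0.05, strict `<`).
#' @param correct Yates continuity correction for the chi-square test.
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Data frame with columns `herb_id`, `n_ij`, `n_i`, `n_j`, `N`,
#'   `rr`, `chi2`, `p` and logical `selected`, ordered by decreasing `rr`.
#' @export
specific_herbs <- function(db, rr_min = 1, p_max = 0.05, correct = FALSE,
                           adjust = "none") {
  tab <- exposure_tables(db)
  tab$rr <- relative_risk(tab$n_ij, tab$n_i, tab$n_j, tab$N)
  test <- chi_square_2x2(tab$n_ij, tab$n_i - tab$n_ij, tab$n_j - tab$n_ij,
                         tab$N - tab$n_i - tab$n_j + tab$n_ij, correct = correct)
  tab$chi2 <- test$chi2
  tab$p <- stats::p.adjust(test$p, method = adjust)
  undefined <- is.na(tab$p)
  if (any(undefined)) {
    warning(sum(undefined), " herb(s) excluded: zero expected cell in the 2x2 table",
            call. = FALSE)
    tab <- tab[!undefined, , drop = FALSE]
  }
  tab$selected <- tab$rr > rr_min & tab$p < p_max
  tab <- tab[order(-tab$rr, tab$herb_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
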