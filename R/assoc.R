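#' Fisher's exact test with the sample odds ratio
#'
#' Two-sided exact p-value by the point-probability method (the sum of
#' hypergeometric probabilities no larger than the observed table's, as in
#' [stats::fisher.test]) together with the sample odds ratio `ad / bc`
#' (`Inf` when `bc = 0`) -- not the conditional-MLE odds ratio that
#' `fisher.test` reports.
#'
#' @param a,b,c_,d Non-negative cell counts of the 2x2 table
#'   (exposed/outcome cross-tabulation: `a` exposed+outcome, `b`
#'   exposed-only, `c_` outcome-only, `d` neither).
#' @return List with `or` (sample OR), `p` (two-sided exact), `conf_int`
#'   (the exact conditional 95% CI from `fisher.test`).
#' @examples
#' fisher_exact(10, 10, 10, 10)$or   # 1
#' @export
fisher_exact <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid 2x2 table")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: odds ratio undefined")
  }
  ft <- stats::fisher.test(tab)
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  list(or = or, p = ft$p.value, conf_int = unname(ft$conf.int))
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples, each with at least 2 values and positive
#'   variance.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("degenerate variance: both samples constant")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Carrier / family-history / PRS correlation analyses
#'
#' Restricted to undiagnosed women in the Europe genetic-similarity group
#' (so normalized PRS values are comparable): Fisher's exact test of
#' carrier status against family history, and Welch t tests of the PRS
#' z-score against family history and against carrier status.
#'
#' @param cohort Cohort `data.frame`.
#' @return List with the three test results and the underlying 2x2 table.
#' @export
association_analyses <- function(cohort) {
  tl <- extract_first_codes(cohort_events(cohort),
                            phenotype_definitions()[c("brca", "fhx_brca")],
                            ids = cohort$participant_id)
  diagnosed <- !is.na(tl$brca)
  scores <- assign_percentiles(
    data.frame(participant_id = cohort$participant_id,
               raw_score = cohort$prs_raw,
               genetic_group = cohort$genetic_group,
               stringsAsFactors = FALSE),
    exclude = diagnosed)
  keep <- cohort$genetic_group == "Europe" & !diagnosed
  carrier <- nzchar(cohort$carrier_genes[keep])
  fhx <- !is.na(tl$fhx_brca[keep])
  z <- scores$z_score[keep]
  tab <- c(a = sum(carrier & fhx), b = sum(carrier & !fhx),
           c_ = sum(!carrier & fhx), d = sum(!carrier & !fhx))
  list(
    n = sum(keep),
    table = tab,
    fhx_vs_carrier = fisher_exact(tab["a"], tab["b"], tab["c_"], tab["d"]),
    prs_vs_fhx = welch_t(z[fhx], z[!fhx]),
    prs_vs_carrier = if (sum(carrier) >= 2) welch_t(z[carrier], z[!carrier])
                     else NULL
  )
}
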