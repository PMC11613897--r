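#' Define a genetic screening strategy
#'
#' A strategy flags a woman as high risk when any active clause holds:
#' a family-history code (optionally restricted to codes recorded before
#' the first breast-cancer diagnosis), a pathogenic variant in an
#' always-referred gene panel, a pathogenic variant in a conditional panel
#' coupled with a PRS in a top fraction, or a standalone top-fraction PRS.
#'
#' @param name Strategy label.
#' @param include_fhx Activate the family-history clause.
#' @param gene_panel_always Genes whose carriers are always flagged.
#' @param gene_panel_conditional Genes whose carriers are flagged only when
#'   also above the `conditional_prs_top_fraction` PRS cut.
#' @param conditional_prs_top_fraction Top fraction for the conditional
#'   panel (e.g. 0.5).
#' @param prs_top_fraction_standalone Top fraction flagging any woman
#'   regardless of carrier status (e.g. 0.1), or `NULL`.
#' @return Object of class `strategy_definition`.
#' @export
strategy_definition <- function(name,
                                include_fhx = FALSE,
                                gene_panel_always = character(),
                                gene_panel_conditional = character(),
                                conditional_prs_top_fraction = NULL,
                                prs_top_fraction_standalone = NULL) {
  stopifnot(all(gene_panel_always %in% PANEL_GENES),
            all(gene_panel_conditional %in% PANEL_GENES))
  for (f in list(conditional_prs_top_fraction, prs_top_fraction_standalone)) {
    if (!is.null(f) && (f <= 0 || f >= 1)) stop("top fractions must lie in (0, 1)")
  }
  if (length(gene_panel_conditional) && is.null(conditional_prs_top_fraction)) {
    stop("a conditional gene panel requires conditional_prs_top_fraction")
  }
  structure(list(name = name, include_fhx = include_fhx,
                 gene_panel_always = gene_panel_always,
                 gene_panel_conditional = gene_panel_conditional,
                 conditional_prs_top_fraction = conditional_prs_top_fraction,
                 prs_top_fraction_standalone = prs_top_fraction_standalone),
            class = "strategy_definition")
}

#' The screening strategies evaluated in the strategy comparison
#'
#' Strategy #1 refers women with a family history of breast cancer, a
#' pathogenic variant in BRCA1/BRCA2/PALB2, or a pathogenic variant in
#' ATM/CHEK2 coupled with a top-50% PRS. Strategy #2 drops family history
#' and refers carriers of any of the 5 genes or a top-10% PRS. The
#' remaining entries are the pure gene-panel rows and the
#' family-history-only best/worse-case rows of the comparison table.
#'
#' @return Named list of [strategy_definition()]s.
#' @export
default_strategies <- function() {
  list(
    brca12 = strategy_definition("BRCA1 + BRCA2",
                                 gene_panel_always = c("BRCA1", "BRCA2")),
    core_plus_conditional = strategy_definition(
      "BRCA1 + BRCA2 + PALB2 + (ATM + CHEK2) x top 50% PRS",
      gene_panel_always = c("BRCA1", "BRCA2", "PALB2"),
      gene_panel_conditional = c("ATM", "CHEK2"),
      conditional_prs_top_fraction = 0.5),
    panel5 = strategy_definition("BRCA1 + BRCA2 + PALB2 + ATM + CHEK2",
                                 gene_panel_always = PANEL_GENES),
    strat1 = strategy_definition(
      "Strategy #1: FHx or BRCA1/2/PALB2 or (ATM/CHEK2 x top 50% PRS)",
      include_fhx = TRUE,
      gene_panel_always = c("BRCA1", "BRCA2", "PALB2"),
      gene_panel_conditional = c("ATM", "CHEK2"),
      conditional_prs_top_fraction = 0.5),
    strat2 = strategy_definition(
      "Strategy #2: 5-gene panel or top 10% PRS",
      gene_panel_always = PANEL_GENES,
      prs_top_fraction_standalone = 0.1),
    fhx_best = strategy_definition("No genetic test, FHx best case",
                                   include_fhx = TRUE),
    fhx_worse = strategy_definition("No genetic test, FHx worse case",
                                    include_fhx = TRUE)
  )
}

#' Apply a strategy to a cohort
#'
#' @param cohort_info `data.frame` with `carrier_genes` (semicolon-joined),
#'   `prs_percentile`, `fhx_any` (any Z80.3 code) and `fhx_pre_dx` (Z80.3
#'   strictly before the simultaneity window of the first diagnosis).
#' @param strategy A [strategy_definition()].
#' @param fhx_mode `"any_time"` (best case, default) or `"pre_diagnosis"`
#'   (worse case) for the family-history clause.
#' @return Logical high-risk flags.
#' @export
assign_strategy <- function(cohort_info, strategy, fhx_mode = c("any_time", "pre_diagnosis")) {
  fhx_mode <- match.arg(fhx_mode)
  stopifnot(inherits(strategy, "strategy_definition"))
  n <- nrow(cohort_info)
  genes <- strsplit(cohort_info$carrier_genes, ";", fixed = TRUE)
  carries <- function(panel) {
    vapply(genes, function(g) any(g %in% panel), logical(1))
  }
  needs_prs <- length(strategy$gene_panel_conditional) > 0 ||
    !is.null(strategy$prs_top_fraction_standalone)
  if (needs_prs && (is.null(cohort_info$prs_percentile) ||
                    anyNA(cohort_info$prs_percentile))) {
    stop("strategy '", strategy$name, "' needs a PRS percentile for every woman")
  }
  flag <- rep(FALSE, n)
  if (strategy$include_fhx) {
    fhx <- if (fhx_mode == "any_time") cohort_info$fhx_any else cohort_info$fhx_pre_dx
    flag <- flag | (fhx %in% TRUE)
  }
  if (length(strategy$gene_panel_always)) {
    flag <- flag | carries(strategy$gene_panel_always)
  }
  if (length(strategy$gene_panel_conditional)) {
    flag <- flag | (carries(strategy$gene_panel_conditional) &
                      prs_top_flag(cohort_info$prs_percentile,
                                   strategy$conditional_prs_top_fraction))
  }
  if (!is.null(strategy$prs_top_fraction_standalone)) {
    flag <- flag | prs_top_flag(cohort_info$prs_percentile,
                                strategy$prs_top_fraction_standalone)
  }
  flag
}

#' Positive predictive value of a screening strategy
#'
#' Defined as the Kaplan-Meier probability of a breast-cancer diagnosis by
#' age 70 among screen-positive women; this function is the bounds-checked
#' identity on that KM read-out.
#'
#' @param km_event_prob_at70_positives KM cumulative incidence at 70 among
#'   positives.
#' @return The PPV.
#' @export
screening_ppv <- function(km_event_prob_at70_positives) {
  p <- km_event_prob_at70_positives
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("PPV must lie in [0, 1]")
  p
}

#' Specificity of a screening strategy
#'
#' `TN / (TN + FP)` with `TN = n_neg * (1 - p_event_neg)` (screen-negative
#' women free of diagnosis by 70) and `FP = n_pos * p_noevent_pos`
#' (screen-positive women free of diagnosis by 70).
#'
#' @param n_neg,n_pos Screen-negative / screen-positive counts.
#' @param p_event_neg KM probability of diagnosis by 70 among negatives.
#' @param p_noevent_pos KM probability of **no** diagnosis by 70 among
#'   positives (i.e. 1 - PPV).
#' @return Specificity in \[0, 1\].
#' @examples
#' screening_specificity(23593, 0.076, 1998, 0.66)   # 0.943
#' @export
screening_specificity <- function(n_neg, p_event_neg, n_pos, p_noevent_pos) {
  stopifnot(n_neg >= 0, n_pos >= 0,
            p_event_neg >= 0, p_event_neg <= 1,
            p_noevent_pos >= 0, p_noevent_pos <= 1)
  tn <- n_neg * (1 - p_event_neg)
  fp <- n_pos * p_noevent_pos
  if (tn + fp == 0) stop("TN + FP is zero; specificity undefined")
  tn / (tn + fp)
}

#' Number needed to screen
#'
#' `1 / ((n_pos / n_total) * p_event_by50_pos)`: the number of women who
#' must be screened so that one screen-positive woman is diagnosed with
#' breast cancer before age 50 (the preventable adverse outcome).
#'
#' @param n_pos Screen-positive count.
#' @param n_total Cohort size.
#' @param p_event_by50_pos KM probability of diagnosis before 50 among
#'   positives.
#' @param round_result Round to the nearest integer for reporting
#'   (default TRUE, matching printed precision).
#' @return NNS (`Inf` when no positive would be diagnosed by 50).
#' @examples
#' screening_nns(1998, 25591, 0.070)   # 183
#' @export
screening_nns <- function(n_pos, n_total, p_event_by50_pos, round_result = TRUE) {
  stopifnot(n_pos >= 0, n_total >= n_pos, p_event_by50_pos >= 0,
            p_event_by50_pos <= 1)
  denom <- (n_pos / n_total) * p_event_by50_pos
  if (denom == 0) return(Inf)
  out <- 1 / denom
  if (round_result) round(out) else out
}

#' False negatives of a screening strategy
#'
#' Women diagnosed with breast cancer before age 50 who were not flagged.
#'
#' @param dx_age First breast-cancer code age (NA when undiagnosed).
#' @param flags High-risk flags from [assign_strategy()].
#' @param age_cut Age boundary, default 50.
#' @return Count.
#' @export
false_negatives <- function(dx_age, flags, age_cut = 50) {
  sum(!is.na(dx_age) & dx_age < age_cut & !flags)
}

#' Strategy comparison table
#'
#' Evaluates each strategy on a cohort: positives and their population
#' fraction, the KM probability of diagnosis by 70 among positives (the
#' PPV) and among negatives, specificity, the KM probability of diagnosis
#' before 50 among positives with the derived NNS, false negatives, and
#' the family-history overlap among positives. High-risk labelling in the
#' report compares the PPV against a configurable cumulative-risk
#' threshold (20% by age 70); the threshold never enters the flag logic.
#'
#' @param cohort Cohort `data.frame`.
#' @param strategies List of [strategy_definition()]s, default
#'   [default_strategies()].
#' @param risk_threshold_70 Cumulative-incidence threshold defining the
#'   "high risk" label, default 0.20.
#' @param fhx_mode_by_strategy Optional named character vector overriding
#'   the FHx clause mode per strategy (the worse-case row uses
#'   `"pre_diagnosis"`).
#' @return `data.frame`, one row per strategy.
#' @export
strategy_table <- function(cohort, strategies = default_strategies(),
                           risk_threshold_70 = 0.20,
                           fhx_mode_by_strategy = c(fhx_worse = "pre_diagnosis")) {
  info <- screening_inputs(cohort)
  rec <- survival_records(cohort)
  n_total <- nrow(cohort)
  rows <- lapply(names(strategies), function(key) {
    st <- strategies[[key]]
    mode <- if (key %in% names(fhx_mode_by_strategy))
      fhx_mode_by_strategy[[key]] else "any_time"
    flag <- assign_strategy(info, st, fhx_mode = mode)
    n_pos <- sum(flag)
    pos_rec <- rec[flag, ]
    neg_rec <- rec[!flag, ]
    p70_pos <- if (n_pos) km_risk_at(km_fit(pos_rec), 70) else NA_real_
    p70_neg <- if (n_total - n_pos) km_risk_at(km_fit(neg_rec), 70) else NA_real_
    p50_pos <- if (n_pos) km_risk_at(km_fit(pos_rec), 50) else NA_real_
    spec <- if (n_pos == 0) 1 else
      screening_specificity(n_total - n_pos, p70_neg, n_pos, 1 - p70_pos)
    nns <- if (n_pos == 0) Inf else screening_nns(n_pos, n_total, p50_pos)
    dx_age <- ifelse(rec$event == 1L, rec$time, NA_real_)
    fhx_pos <- sum(info$fhx_any & flag)
    data.frame(
      strategy = st$name,
      n_pos = n_pos,
      pct_of_population = round(100 * n_pos / n_total, 1),
      ppv_km70 = if (is.na(p70_pos)) NA else round(100 * screening_ppv(p70_pos), 1),
      high_risk_label = !is.na(p70_pos) && p70_pos >= risk_threshold_70,
      specificity = round(100 * spec, 1),
      nns = nns,
      false_negatives = false_negatives(dx_age, flag),
      n_fhx_among_pos = fhx_pos,
      pct_fhx_among_pos = if (n_pos) round(100 * fhx_pos / n_pos, 1) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble per-woman screening inputs from a cohort
#'
#' Computes the carrier set, within-group PRS percentile, and the two
#' family-history indicators (any-time and pre-diagnosis) each strategy
#' clause consumes.
#'
#' @param cohort Cohort `data.frame`.
#' @return `data.frame` keyed by `participant_id`.
#' @export
screening_inputs <- function(cohort) {
  scores <- data.frame(participant_id = cohort$participant_id,
                       raw_score = cohort$prs_raw,
                       genetic_group = cohort$genetic_group,
                       stringsAsFactors = FALSE)
  scores <- assign_percentiles(scores)
  tl <- extract_first_codes(cohort_events(cohort),
                            phenotype_definitions()[c("brca", "fhx_brca")],
                            ids = cohort$participant_id)
  timing <- classify_timing(tl)
  data.frame(
    participant_id = cohort$participant_id,
    carrier_genes = cohort$carrier_genes,
    prs_percentile = scores$percentile,
    fhx_any = !is.na(tl$fhx_brca),
    fhx_pre_dx = !is.na(tl$fhx_brca) &
      (is.na(tl$brca) | timing$category == "before"),
    dx_age = tl$brca,
    stringsAsFactors = FALSE
  )
}
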