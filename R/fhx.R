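#' Default ICD-10-CM phenotype definitions
#'
#' Prefix sets over ICD-10-CM codes: breast cancer is C50 (malignant
#' neoplasm of breast), D05 (carcinoma in situ) or Z85.3 (personal history
#' of breast malignancy) -- secondary neoplasms (C79.x) are not breast
#' cancer under prefix matching; family history of breast cancer is Z80.3;
#' family history of other conditions is any Z80-Z84 code after excluding
#' Z80.3; comparator phenotypes are type 1/2 diabetes (E10/E11),
#' hypertension (I10) and rheumatoid arthritis (M06).
#'
#' @return Named list of prefix character vectors.
#' @export
phenotype_definitions <- function() {
  list(
    brca = c("C50", "D05", "Z85.3"),
    fhx_brca = "Z80.3",
    fhx_other = c("Z80", "Z81", "Z82", "Z83", "Z84"),
    t1d = "E10",
    t2d = "E11",
    htn = "I10",
    ra = "M06"
  )
}

#' First qualifying code age per phenotype
#'
#' For each phenotype, the earliest event age whose code starts with one of
#' the defined prefixes. The `fhx_other` phenotype first removes all Z80.3
#' codes, then matches the Z80-Z84 prefixes, so family history of breast
#' cancer never leaks into the other-condition set.
#'
#' @param events Long `data.frame` from [cohort_events()] (`participant_id`,
#'   `code`, `age`).
#' @param definitions Named list of prefix sets, default
#'   [phenotype_definitions()]; unknown phenotype names error.
#' @param ids Optional roster of participant ids to report (rows of all-NA
#'   for women with no qualifying codes).
#' @return Wide `data.frame`: `participant_id` plus one first-age column
#'   per phenotype (NA when absent).
#' @export
extract_first_codes <- function(events, definitions = phenotype_definitions(),
                                ids = NULL) {
  if (is.null(names(definitions)) || any(!nzchar(names(definitions)))) {
    stop("phenotype definitions must be named")
  }
  unknown <- setdiff(names(definitions), names(phenotype_definitions()))
  if (length(unknown)) {
    stop("unknown phenotype name(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(ids)) ids <- unique(events$participant_id)
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (ph in names(definitions)) {
    ev <- events
    if (ph == "fhx_other") {
      ev <- ev[!startsWith(ev$code, "Z80.3"), , drop = FALSE]
    }
    prefixes <- definitions[[ph]]
    hit <- Reduce(`|`, lapply(prefixes, function(p) startsWith(ev$code, p)),
                  accumulate = FALSE)
    if (is.null(hit)) hit <- logical(nrow(ev))
    ev <- ev[hit, , drop = FALSE]
    if (!nrow(ev)) {
      out[[ph]] <- rep(NA_real_, nrow(out))
    } else {
      first <- tapply(ev$age, ev$participant_id, min)
      out[[ph]] <- as.numeric(first[out$participant_id])
    }
  }
  rownames(out) <- NULL
  out
}

#' Timing of the first family-history code relative to the first
#' breast-cancer code
#'
#' The signed difference (FHx minus BrCa) in days classifies each woman:
#' within \[-7, +30\] days is `simultaneous`, earlier than -7 days is
#' `before`, later than +30 days is `after`; women with only one (or
#' neither) code are `fhx_only`, `brca_only` or `neither`.
#'
#' @param timeline `data.frame` with `participant_id`, `fhx_brca` and
#'   `brca` first-code ages in years (from [extract_first_codes()]).
#' @param window Simultaneity window in days, default `c(-7, 30)`.
#' @return `data.frame` with `participant_id`, `delta_days`, `category`.
#' @export
classify_timing <- function(timeline, window = c(-7, 30)) {
  stopifnot(all(c("participant_id", "fhx_brca", "brca") %in% names(timeline)))
  delta <- (timeline$fhx_brca - timeline$brca) * 365.25
  tol <- 1e-6   # seconds-scale tolerance so year->day conversion noise
                # cannot move a record across the window boundary
  category <- ifelse(
    is.na(timeline$fhx_brca) & is.na(timeline$brca), "neither",
    ifelse(is.na(timeline$brca), "fhx_only",
    ifelse(is.na(timeline$fhx_brca), "brca_only",
    ifelse(delta < window[1] - tol, "before",
    ifelse(delta > window[2] + tol, "after", "simultaneous")))))
  data.frame(participant_id = timeline$participant_id,
             delta_days = delta, category = category,
             stringsAsFactors = FALSE)
}

#' Enrichment of simultaneous family-history recording
#'
#' Compares the simultaneity of FHx-BrCa recording around the index
#' phenotype against a comparator phenotype: Pearson chi-square (no
#' continuity correction, 1 df) on the 2x2 table of (simultaneous,
#' not-simultaneous) counts.
#'
#' @param counts_index,counts_comparator Length-2 integer vectors
#'   `(simultaneous, not_simultaneous)`.
#' @return List with `statistic`, `p`, `expected` (warns when any expected
#'   cell is below 1).
#' @export
enrichment_test <- function(counts_index, counts_comparator) {
  stopifnot(length(counts_index) == 2L, length(counts_comparator) == 2L)
  tab <- rbind(index = counts_index, comparator = counts_comparator)
  ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(ex < 1)) warning("expected cell count below 1; chi-square unreliable")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value), expected = ex)
}

#' Remove family-history records subject to ascertainment bias
#'
#' Drops women whose first FHx-BrCa code was recorded simultaneously with
#' (within the window) or after their first breast-cancer diagnosis; women
#' without an FHx code, and FHx-positive women coded strictly before
#' diagnosis, are retained unchanged.
#'
#' @param cohort Cohort `data.frame`.
#' @param timing Output of [classify_timing()] aligned on
#'   `participant_id`; computed from the cohort when omitted.
#' @return The filtered cohort (event/censoring data of retained rows
#'   untouched).
#' @export
debias_cohort <- function(cohort, timing = NULL) {
  if (is.null(timing)) {
    tl <- extract_first_codes(cohort_events(cohort),
                              phenotype_definitions()[c("brca", "fhx_brca")],
                              ids = cohort$participant_id)
    timing <- classify_timing(tl)
  }
  cat_by_id <- stats::setNames(timing$category, timing$participant_id)
  drop <- cat_by_id[cohort$participant_id] %in% c("simultaneous", "after")
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
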