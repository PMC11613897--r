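#' Generate a synthetic screening cohort
#'
#' Draws one woman per row with the statistical structure the downstream
#' analyses assume: an ancestry-like genetic-similarity group, a bimodal
#' current-age distribution, an EHR span, Bernoulli carrier status per panel
#' gene, a group-shifted raw PRS, a breast-cancer onset age from a
#' proportional-hazards model with a piecewise-constant baseline hazard, a
#' family-history indicator with logistic dependence on carrier status and
#' PRS, and a dated ICD-10-CM code stream (C50/D05/Z85.3 for breast cancer,
#' Z80.3 for family history of breast cancer, Z80-Z84 for other family
#' history, E11/I10 comparator phenotypes).
#'
#' The baseline hazard scale is calibrated by 1-D root finding so that a
#' carrier-free woman at the median PRS has cumulative incidence
#' `baseline_cuminc_70` by age 70; the PRS log-hazard slope is calibrated so
#' the mean-hazard ratio of the top decile versus the 30-70th percentile
#' band equals `prs_top10_hr`; the per-participant hazard multiplier is the
#' maximum carried gene multiplier times `exp(beta * z)`. Onset after the
#' current age is censored (no code recorded). All randomness flows from
#' `config$seed`; the caller's RNG state is restored on exit.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` (one row per woman) with columns `participant_id`,
#'   `genetic_group`, `current_age`, `ehr_start_age`, `ehr_end_age`,
#'   `carrier_genes` (semicolon-joined, "" for none), `prs_raw`, `prs_z`
#'   (latent within-group standard score), `fhx_first_code_age` (NA when no
#'   Z80.3 code), and `diagnosis_events` (semicolon-delimited `code@age`).
#'   The config and calibrated constants are attached as attributes
#'   `sim_config` and `calibration`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_women = 500, seed = 42))
#' table(cohort$genetic_group)
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_women

  genetic_group <- sample(GENETIC_GROUPS, n, replace = TRUE,
                          prob = config$group_proportions[GENETIC_GROUPS])

  current_age <- .draw_bimodal_age(n, config$age_mix)
  ehr_span <- pmin(pmax(stats::rnorm(n, config$ehr_span_mean, config$ehr_span_sd), 0.5),
                   current_age - 1)
  ehr_start_age <- pmax(0, current_age - ehr_span)
  ehr_end_age <- current_age

  # carrier status: Bernoulli per gene at the configured population rates
  carrier_p <- config$gene_carrier_counts / 25591
  carrier_mat <- vapply(PANEL_GENES, function(g) {
    stats::runif(n) < carrier_p[[g]]
  }, logical(n))
  if (n == 1L) carrier_mat <- matrix(carrier_mat, nrow = 1,
                                     dimnames = list(NULL, PANEL_GENES))
  carrier_genes <- apply(carrier_mat, 1L, function(r) {
    paste(PANEL_GENES[r], collapse = ";")
  })

  # PRS: standard-normal within group, shifted/scaled to the raw scale
  z <- stats::rnorm(n)
  prs_raw <- config$prs_group_mean[genetic_group] +
    config$prs_group_sd[genetic_group] * z

  # proportional-hazards onset ages
  scale <- calibrate_baseline_scale(config)
  beta <- calibrate_prs_beta(config$prs_top10_hr)
  gene_mult <- apply(carrier_mat, 1L, function(r) {
    if (any(r)) max(config$gene_hr[PANEL_GENES[r]]) else 1
  })
  mult <- gene_mult * exp(beta * z)
  onset <- .draw_onset_age(n, scale * mult, config$age_bands, config$band_rel_hazard)
  affected <- onset <= current_age

  # family history indicator and code timing
  any_carrier <- as.numeric(rowSums(carrier_mat) > 0)
  alpha <- calibrate_fhx_intercept(any_carrier, z, config)
  p_fhx <- stats::plogis(alpha + log(config$fhx_carrier_or) * any_carrier +
                           config$fhx_prs_beta * z)
  fhx <- stats::runif(n) < p_fhx
  fhx_age <- .draw_fhx_age(fhx, affected, onset, current_age, ehr_start_age,
                           config$fhx_timing_mix)

  events <- .build_event_streams(n, affected, onset, current_age, ehr_start_age,
                                 fhx_age, config)

  cohort <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    genetic_group = genetic_group,
    current_age = current_age,
    ehr_start_age = ehr_start_age,
    ehr_end_age = ehr_end_age,
    carrier_genes = carrier_genes,
    prs_raw = as.numeric(prs_raw),
    prs_z = z,
    fhx_first_code_age = fhx_age,
    diagnosis_events = events,
    stringsAsFactors = FALSE
  )
  attr(cohort, "sim_config") <- config
  attr(cohort, "calibration") <- list(baseline_scale = scale, prs_beta = beta,
                                      fhx_intercept = alpha, seed = config$seed)
  cohort
}

# bimodal (two-component normal mixture) current age, truncated to range
.draw_bimodal_age <- function(n, mix) {
  comp <- sample.int(2L, n, replace = TRUE, prob = mix$weights)
  age <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  pmin(pmax(age, mix$range[1]), mix$range[2])
}

# invert the piecewise-constant cumulative hazard: T = H^{-1}(E/mult), E~Exp(1)
.draw_onset_age <- function(n, hazard_scale, age_bands, band_rel) {
  lo <- age_bands[-length(age_bands)]
  hi <- age_bands[-1]
  width <- hi - lo
  cum_end <- cumsum(band_rel * width)   # unit-scale cumhaz at band ends
  cum_start <- c(0, cum_end[-length(cum_end)])
  target <- stats::rexp(n) / hazard_scale   # required unit-scale cumhaz
  onset <- rep(Inf, n)
  for (j in seq_along(lo)) {
    in_band <- is.infinite(onset) & target <= cum_end[j] + 1e-15
    onset[in_band] <- lo[j] + (target[in_band] - cum_start[j]) / band_rel[j]
  }
  onset
}

# FHx first-code age: timing mixture relative to onset for affected women,
# uniform over the adult EHR span otherwise. Deltas are drawn in days.
.draw_fhx_age <- function(fhx, affected, onset, current_age, ehr_start_age, mix) {
  n <- length(fhx)
  fhx_age <- rep(NA_real_, n)
  aff_idx <- which(fhx & affected)
  if (length(aff_idx)) {
    cat3 <- sample(c("before", "simultaneous", "after"), length(aff_idx),
                   replace = TRUE, prob = mix)
    cap_days <- (current_age[aff_idx] - onset[aff_idx]) * 365.25
    # 'after' requires >30 days of follow-up past onset; reassign the rare
    # short-follow-up draws to the simultaneous window
    cat3[cat3 == "after" & cap_days < 31] <- "simultaneous"
    delta <- numeric(length(aff_idx))
    is_b <- cat3 == "before"
    is_s <- cat3 == "simultaneous"
    is_a <- cat3 == "after"
    if (any(is_b)) {
      span <- pmax(9, pmin(15 * 365.25, (onset[aff_idx][is_b] - 12) * 365.25))
      delta[is_b] <- -stats::runif(sum(is_b), 8, span)
    }
    if (any(is_s)) {
      delta[is_s] <- stats::runif(sum(is_s), -7, pmin(30, cap_days[is_s]))
    }
    if (any(is_a)) {
      delta[is_a] <- stats::runif(sum(is_a), 31, pmin(15 * 365.25, cap_days[is_a]))
    }
    fhx_age[aff_idx] <- onset[aff_idx] + delta / 365.25
  }
  un_idx <- which(fhx & !affected)
  if (length(un_idx)) {
    lo <- pmax(18, ehr_start_age[un_idx])
    lo <- pmin(lo, current_age[un_idx] - 0.1)
    fhx_age[un_idx] <- stats::runif(length(un_idx), lo, current_age[un_idx])
  }
  pmax(fhx_age, 0)
}

# assemble the per-participant `code@age` streams
.build_event_streams <- function(n, affected, onset, current_age, ehr_start_age,
                                 fhx_age, config) {
  codes <- vector("list", n)
  add <- function(i, code, age) {
    codes[[i]][[length(codes[[i]]) + 1L]] <<- sprintf("%s@%.17g", code, age)
  }
  brca_code <- sample(c("C50.911", "C50.912", "D05.11"), n, replace = TRUE,
                      prob = c(0.8, 0.1, 0.1))
  hist_later <- stats::runif(n) < 0.5
  adult_lo <- pmin(pmax(18, ehr_start_age), current_age - 0.1)
  other_fhx <- stats::runif(n) < config$other_fhx_prevalence
  other_fhx_code <- sample(c("Z80.0", "Z82.49", "Z83.3"), n, replace = TRUE)
  other_fhx_age <- stats::runif(n, adult_lo, current_age)
  comp_draw <- lapply(config$comparator_prevalence, function(p) stats::runif(n) < p)
  comp_age <- lapply(config$comparator_prevalence, function(p) {
    stats::runif(n, adult_lo, current_age)
  })
  comp_code <- c(T2D = "E11.9", HTN = "I10")
  for (i in seq_len(n)) {
    if (affected[i]) {
      add(i, brca_code[i], onset[i])
      if (hist_later[i] && onset[i] + 2 <= current_age[i]) {
        add(i, "Z85.3", onset[i] + 2)
      }
    }
    if (!is.na(fhx_age[i])) add(i, "Z80.3", fhx_age[i])
    if (other_fhx[i]) add(i, other_fhx_code[i], other_fhx_age[i])
    for (ph in names(comp_code)) {
      if (comp_draw[[ph]][i]) add(i, comp_code[[ph]], comp_age[[ph]][i])
    }
  }
  vapply(codes, function(x) paste(unlist(x), collapse = ";"), character(1))
}

#' Parse the diagnosis-event stream into long format
#'
#' @param cohort A cohort `data.frame` from [simulate_cohort()] or
#'   [read_cohort()].
#' @return `data.frame` with `participant_id`, `code`, `age`, one row per
#'   dated ICD-10-CM code.
#' @export
cohort_events <- function(cohort) {
  keep <- nzchar(cohort$diagnosis_events)
  if (!any(keep)) {
    return(data.frame(participant_id = character(), code = character(),
                      age = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(cohort$diagnosis_events[keep], ";", fixed = TRUE)
  nper <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  at <- regexpr("@", flat, fixed = TRUE)
  data.frame(
    participant_id = rep(cohort$participant_id[keep], nper),
    code = substr(flat, 1L, at - 1L),
    age = as.numeric(substr(flat, at + 1L, nchar(flat))),
    stringsAsFactors = FALSE
  )
}

#' Write / read a cohort table
#'
#' Tab-separated UTF-8 with header; diagnosis events serialized as a
#' semicolon-delimited `code@age` list. Numeric fields are written with
#' round-trip (`%.17g`) precision so `write_cohort()` followed by
#' [read_cohort()] reproduces the records exactly.
#'
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .validate_cohort(cohort)
  out <- cohort[, .cohort_columns()]
  for (col in c("current_age", "ehr_start_age", "ehr_end_age", "prs_raw",
                "prs_z", "fhx_first_code_age")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.cohort_columns <- function() {
  c("participant_id", "genetic_group", "current_age", "ehr_start_age",
    "ehr_end_age", "carrier_genes", "prs_raw", "prs_z", "fhx_first_code_age",
    "diagnosis_events")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.delim(path, sep = "\t", header = TRUE,
                              colClasses = "character", na.strings = "NA",
                              fileEncoding = "UTF-8")
  missing_cols <- setdiff(.cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("current_age", "ehr_start_age", "ehr_end_age", "prs_raw",
                "prs_z", "fhx_first_code_age")) {
    cohort[[col]] <- as.numeric(cohort[[col]])
  }
  cohort$carrier_genes[is.na(cohort$carrier_genes)] <- ""
  cohort$diagnosis_events[is.na(cohort$diagnosis_events)] <- ""
  .validate_cohort(cohort)
  cohort
}

.validate_cohort <- function(cohort) {
  req <- setdiff(.cohort_columns(), names(cohort))
  if (length(req)) stop("cohort lacks column(s): ", paste(req, collapse = ", "))
  if (!nrow(cohort)) return(invisible(cohort))
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop(sprintf("invalid cohort row(s) %s: %s",
                   paste(utils::head(which(cond), 5), collapse = ", "), what))
    }
  }
  bad(cohort$ehr_start_age > cohort$ehr_end_age, "ehr_start_age > ehr_end_age")
  bad(cohort$ehr_end_age > cohort$current_age + 1e-9, "ehr_end_age > current_age")
  genes <- strsplit(cohort$carrier_genes, ";", fixed = TRUE)
  bad(!vapply(genes, function(g) all(g %in% PANEL_GENES), logical(1)),
      "carrier gene outside the 5-gene panel")
  ev <- cohort_events(cohort)
  if (nrow(ev)) {
    cap <- stats::setNames(cohort$current_age, cohort$participant_id)
    off <- ev$age < 0 | ev$age > cap[ev$participant_id] + 1e-6 | is.na(ev$age)
    if (any(off)) {
      rows <- match(unique(ev$participant_id[off]), cohort$participant_id)
      stop("diagnosis event age outside [0, current_age] for row(s): ",
           paste(utils::head(rows, 5), collapse = ", "))
    }
  }
  invisible(cohort)
}

#' Build time-to-event records from a cohort
#'
#' Time scale is age with time zero at birth (no left truncation by
#' default, matching percentage-diagnosed-by-age survival read-outs):
#' `time` is the age at the first qualifying breast-cancer code for affected
#' women and the current age (censoring) otherwise. An `entry_age` column
#' (EHR start) is included so callers can opt into left truncation.
#'
#' @param cohort Cohort `data.frame`.
#' @param extra_covariates Optional `data.frame` keyed by `participant_id`
#'   merged onto the records.
#' @return `data.frame` with `participant_id`, `time`, `event`, `entry_age`
#'   plus carrier/PRS/FHx convenience columns.
#' @export
survival_records <- function(cohort, extra_covariates = NULL) {
  first <- extract_first_codes(cohort_events(cohort),
                               phenotype_definitions()["brca"],
                               ids = cohort$participant_id)
  brca_age <- first$brca[match(cohort$participant_id, first$participant_id)]
  event <- as.integer(!is.na(brca_age))
  time <- ifelse(event == 1L, brca_age, cohort$current_age)
  rec <- data.frame(
    participant_id = cohort$participant_id,
    time = pmax(time, 1e-6),
    event = event,
    entry_age = cohort$ehr_start_age,
    genetic_group = cohort$genetic_group,
    carrier_genes = cohort$carrier_genes,
    fhx = !is.na(cohort$fhx_first_code_age),
    prs_raw = cohort$prs_raw,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_covariates)) {
    rec <- merge(rec, extra_covariates, by = "participant_id", all.x = TRUE,
                 sort = FALSE)
    rec <- rec[match(cohort$participant_id, rec$participant_id), ]
    rownames(rec) <- NULL
  }
  rec
}

#' Carrier analysis group with gene precedence
#'
#' Multi-gene carriers are assigned to a single group by the precedence
#' BRCA1 > BRCA2 > PALB2 > ATM > CHEK2; non-carriers map to `"none"`.
#'
#' @param carrier_genes Character vector of semicolon-joined gene sets.
#' @return Character vector of analysis groups.
#' @export
carrier_analysis_group <- function(carrier_genes) {
  vapply(strsplit(carrier_genes, ";", fixed = TRUE), function(g) {
    g <- g[g %in% PANEL_GENES]
    if (!length(g)) "none" else PANEL_GENES[min(match(g, PANEL_GENES))]
  }, character(1))
}
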