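#' Panel genes considered for monogenic breast-cancer risk
#'
#' The five genes screened for predicted loss-of-function / pathogenic
#' variants, in the precedence order used to assign multi-gene carriers to a
#' single analysis group.
#' @export
PANEL_GENES <- c("BRCA1", "BRCA2", "PALB2", "ATM", "CHEK2")

#' Genetic-similarity groups used for PRS percentile normalization
#' @export
GENETIC_GROUPS <- c("Africa", "Americas", "EastAsia", "Europe", "Other", "SouthAsia")

#' Simulation configuration for the synthetic screening cohort
#'
#' Builds a validated configuration object for [simulate_cohort()]. Defaults
#' reproduce the statistical structure of a ~25,600-woman health-system
#' cohort: group sizes of an ancestry-like partition, per-gene carrier
#' counts totalling 410, per-gene hazard multipliers, a 9.3% carrier-free
#' median-PRS cumulative incidence by age 70, a top-decile PRS hazard ratio
#' of 2.4, 6.9% family-history (FHx) prevalence with carrier odds ratio 3.5,
#' and the 22/30/48 percent before/simultaneous/after FHx code-timing
#' mixture relative to the first breast-cancer code.
#'
#' @param n_women Cohort size.
#' @param group_proportions Named fractions over [GENETIC_GROUPS]; must sum
#'   to 1.
#' @param gene_carrier_counts Named expected carrier counts per panel gene,
#'   scaled by `n_women / 25591` internally so smaller test cohorts keep the
#'   same carrier rates.
#' @param gene_hr Named hazard multipliers per panel gene (>0).
#' @param prs_top10_hr Target hazard ratio of the top PRS decile versus the
#'   30th-70th percentile band.
#' @param baseline_cuminc_70 Cumulative incidence of breast cancer by age 70
#'   for a carrier-free woman at the median PRS.
#' @param fhx_prevalence Marginal fraction of women with a family-history
#'   code (ICD-10-CM Z80.3).
#' @param fhx_carrier_or Odds ratio linking FHx to carrier status.
#' @param fhx_prs_beta Log-odds increment of FHx per standard deviation of
#'   PRS (the published association is "positive and significant" without an
#'   effect size; the default is a modest 0.25).
#' @param fhx_timing_mix Probabilities (before, simultaneous, after) of the
#'   first FHx code relative to the first breast-cancer code among affected
#'   FHx-positive women; must sum to 1. "Simultaneous" means within -7 to
#'   +30 days.
#' @param ehr_span_mean,ehr_span_sd Mean/SD (years) of the truncated-normal
#'   EHR length.
#' @param age_mix Bimodal current-age model: list with `weights`, `means`,
#'   `sds` (two normal components) and `range` for truncation.
#' @param age_bands Breakpoints of the piecewise-constant baseline hazard
#'   (ages, increasing, first 0).
#' @param band_rel_hazard Relative per-year hazard in each band (length
#'   `length(age_bands) - 1`); the absolute scale is calibrated to
#'   `baseline_cuminc_70`.
#' @param prs_group_mean,prs_group_sd Named per-group mean/SD of the raw PRS.
#' @param other_fhx_prevalence Fraction with at least one non-breast family
#'   history code (Z80-Z84 excluding Z80.3).
#' @param comparator_prevalence Named prevalences for the comparator
#'   phenotypes (type 2 diabetes, hypertension) used in timing-enrichment
#'   checks.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @examples
#' cfg <- sim_config(n_women = 2000, seed = 7)
#' cfg$gene_carrier_counts
#' @export
sim_config <- function(n_women = 25591L,
                       group_proportions = c(Africa = 499, Americas = 3728,
                                             EastAsia = 832, Europe = 19484,
                                             Other = 929, SouthAsia = 119) / 25591,
                       gene_carrier_counts = c(BRCA1 = 70, BRCA2 = 89, PALB2 = 39,
                                               ATM = 94, CHEK2 = 118),
                       gene_hr = c(BRCA1 = 16.2, BRCA2 = 8.5, PALB2 = 6.3,
                                   ATM = 4.3, CHEK2 = 2.6),
                       prs_top10_hr = 2.4,
                       baseline_cuminc_70 = 0.093,
                       fhx_prevalence = 0.069,
                       fhx_carrier_or = 3.5,
                       fhx_prs_beta = 0.25,
                       fhx_timing_mix = c(before = 0.22, simultaneous = 0.30,
                                          after = 0.48),
                       ehr_span_mean = 12,
                       ehr_span_sd = 5,
                       age_mix = list(weights = c(0.68, 0.32),
                                      means = c(45, 71),
                                      sds = c(12, 7),
                                      range = c(19, 89)),
                       age_bands = c(0, 40, 50, 60, 70, 90),
                       band_rel_hazard = c(0.15, 1, 1.4, 1.8, 2.0),
                       prs_group_mean = c(Africa = -0.30, Americas = 0.15,
                                          EastAsia = -0.45, Europe = 0,
                                          Other = 0.05, SouthAsia = 0.20),
                       prs_group_sd = c(Africa = 1, Americas = 1, EastAsia = 1,
                                        Europe = 1, Other = 1, SouthAsia = 1),
                       other_fhx_prevalence = 0.268,
                       comparator_prevalence = c(T2D = 0.12, HTN = 0.35),
                       seed = 1L) {
  cfg <- list(
    n_women = as.integer(n_women),
    group_proportions = group_proportions,
    gene_carrier_counts = gene_carrier_counts,
    gene_hr = gene_hr,
    prs_top10_hr = prs_top10_hr,
    baseline_cuminc_70 = baseline_cuminc_70,
    fhx_prevalence = fhx_prevalence,
    fhx_carrier_or = fhx_carrier_or,
    fhx_prs_beta = fhx_prs_beta,
    fhx_timing_mix = fhx_timing_mix,
    ehr_span_mean = ehr_span_mean,
    ehr_span_sd = ehr_span_sd,
    age_mix = age_mix,
    age_bands = age_bands,
    band_rel_hazard = band_rel_hazard,
    prs_group_mean = prs_group_mean,
    prs_group_sd = prs_group_sd,
    other_fhx_prevalence = other_fhx_prevalence,
    comparator_prevalence = comparator_prevalence,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_women < 1L) stop("n_women must be >= 1")
  gp <- cfg$group_proportions
  if (!setequal(names(gp), GENETIC_GROUPS)) {
    stop("group_proportions must be named with exactly: ",
         paste(GENETIC_GROUPS, collapse = ", "))
  }
  if (abs(sum(gp) - 1) > 1e-9) stop("group_proportions must sum to 1")
  if (any(gp < 0 | gp > 1)) stop("group_proportions must lie in [0, 1]")
  if (!setequal(names(cfg$gene_carrier_counts), PANEL_GENES) ||
      !setequal(names(cfg$gene_hr), PANEL_GENES)) {
    stop("gene_carrier_counts and gene_hr must be named with the 5 panel genes")
  }
  if (any(cfg$gene_carrier_counts < 0)) stop("gene carrier counts must be >= 0")
  if (any(cfg$gene_hr <= 0) || cfg$prs_top10_hr <= 0) {
    stop("all hazard multipliers must be > 0")
  }
  for (f in c("baseline_cuminc_70", "fhx_prevalence")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop(f, " must lie in [0, 1); infeasible calibration otherwise")
    }
  }
  if (cfg$fhx_carrier_or <= 0) stop("fhx_carrier_or must be > 0")
  tm <- cfg$fhx_timing_mix
  if (length(tm) != 3L || abs(sum(tm) - 1) > 1e-9 || any(tm < 0)) {
    stop("fhx_timing_mix must be 3 non-negative probabilities summing to 1")
  }
  if (is.null(names(tm))) names(cfg$fhx_timing_mix) <-
      c("before", "simultaneous", "after")
  if (length(cfg$band_rel_hazard) != length(cfg$age_bands) - 1L ||
      any(diff(cfg$age_bands) <= 0) || cfg$age_bands[1] != 0 ||
      any(cfg$band_rel_hazard <= 0)) {
    stop("age_bands must be increasing from 0 with one positive relative hazard per band")
  }
  if (max(cfg$age_bands) < 70) stop("age_bands must extend to at least age 70")
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Every field of [sim_config()] may be given in the file; omitted fields
#' keep their defaults. Named vectors are written as YAML maps.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  raw <- lapply(raw, function(x) if (is.list(x) && is.null(x$weights)) unlist(x) else x)
  do.call(sim_config, raw)
}

# ---- calibration helpers ----------------------------------------------------

# Cumulative baseline hazard at age t for unit scale (relative bands only).
relative_cumhaz <- function(t, age_bands, band_rel_hazard) {
  lo <- age_bands[-length(age_bands)]
  hi <- age_bands[-1]
  vapply(t, function(tt) {
    sum(band_rel_hazard * pmax(0, pmin(tt, hi) - lo))
  }, numeric(1))
}

# Global hazard scale such that a woman with total multiplier 1 reaches the
# target cumulative incidence by age 70. 1-D root finding; fails explicitly
# when the target is infeasible.
calibrate_baseline_scale <- function(cfg) {
  target <- cfg$baseline_cuminc_70
  if (target >= 1 || target < 0) stop("infeasible calibration: baseline_cuminc_70 must be in [0, 1)")
  if (target == 0) return(0)
  H70 <- relative_cumhaz(70, cfg$age_bands, cfg$band_rel_hazard)
  f <- function(s) (1 - exp(-s * H70)) - target
  stats::uniroot(f, interval = c(1e-12, 10), tol = 1e-12)$root
}

# Expected value of exp(beta * Z) for Z ~ N(0,1) truncated to (a, b).
.trunc_exp_moment <- function(beta, a, b) {
  exp(beta^2 / 2) * (stats::pnorm(b - beta) - stats::pnorm(a - beta)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# PRS log-hazard slope beta such that the ratio of mean hazards, top decile
# versus 30th-70th percentile band of a standard-normal score, equals the
# configured top-decile HR.
calibrate_prs_beta <- function(prs_top10_hr) {
  if (prs_top10_hr == 1) return(0)
  q30 <- stats::qnorm(0.3); q70 <- stats::qnorm(0.7); q90 <- stats::qnorm(0.9)
  f <- function(beta) {
    .trunc_exp_moment(beta, q90, Inf) / .trunc_exp_moment(beta, q30, q70) -
      prs_top10_hr
  }
  stats::uniroot(f, interval = c(-3, 3), extendInt = "upX", tol = 1e-10)$root
}

# Logistic intercept giving the configured marginal FHx prevalence over the
# realized carrier indicators and PRS z-scores.
calibrate_fhx_intercept <- function(carrier, z, cfg) {
  eta <- log(cfg$fhx_carrier_or) * carrier + cfg$fhx_prs_beta * z
  f <- function(a) mean(stats::plogis(a + eta)) - cfg$fhx_prevalence
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}
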