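# Shared fixtures and independent oracles for the test suite.

# small-variant row builder with sensible defaults
make_variant <- function(variant_id = "v1", gene = "BRCA1", rsid = NA,
                         clnsig = NA, clnrevstat = NA, loftee = "none",
                         gnomad_filter_pass = TRUE, af_cohort = 1e-4,
                         manual_fail = FALSE) {
  data.frame(variant_id = variant_id, gene = gene, rsid = rsid,
             clnsig = clnsig, clnrevstat = clnrevstat, loftee = loftee,
             gnomad_filter_pass = gnomad_filter_pass, af_cohort = af_cohort,
             manual_fail = manual_fail, stringsAsFactors = FALSE)
}

# Independent brute-force truth table for the interpretation cascade,
# written against the rule text rather than the implementation: exact
# string comparison on canonical ClinVar strings after its own
# (deliberately separate) normalization.
cascade_oracle <- function(rsid, clnrevstat, clnsig, loftee, pass,
                           manual_fail = FALSE) {
  norm <- function(s) {
    if (is.na(s)) return(NA_character_)
    tolower(chartr("_", " ", s))
  }
  rv <- norm(clnrevstat)
  known_rv <- c("reviewed by expert panel",
                "criteria provided, multiple submitters, no conflicts",
                "criteria provided, single submitter",
                "criteria provided, conflicting interpretations",
                "no assertion criteria provided")
  if (!is.na(rv) && !(rv %in% known_rv)) rv <- NA_character_
  sg <- norm(clnsig)
  plp_set <- c("pathogenic", "likely pathogenic", "pathogenic/likely pathogenic")
  blb_set <- c("benign", "likely benign", "benign/likely benign")
  if (!pass || isTRUE(manual_fail)) return("excluded")
  if (!is.na(rsid) && rsid == "rs555607708") return("P/LP")
  if (!is.na(rv) && rv == "reviewed by expert panel") {
    if (!is.na(sg) && sg %in% plp_set) return("P/LP")
    if (!is.na(sg) && sg %in% blb_set) return("B/LB")
    if (!is.na(sg) && sg == "uncertain significance") return("VUS")
    return("not_pathogenic")
  }
  multi <- !is.na(rv) && rv == "criteria provided, multiple submitters, no conflicts"
  if (multi && !is.na(sg) && sg %in% blb_set) return("B/LB")
  if (multi && !is.na(sg) && sg == "uncertain significance") return("VUS")
  if (!is.na(loftee) && loftee == "HC") return("P/LP")
  "not_pathogenic"
}

# brute-force product-limit estimator over the risk-set table
km_oracle <- function(time, event, at) {
  dt <- sort(unique(time[event == 1]))
  s <- 1
  for (t in dt[dt <= at]) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# two-sample log-rank statistic from the O-E table, first principles
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  arm <- rep(0:1, c(length(time_a), length(time_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & arm == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# a quick mid-size default-rate cohort shared by several tests
small_cohort <- function(n = 4000, seed = 101, ...) {
  simulate_cohort(sim_config(n_women = n, seed = seed, ...))
}
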