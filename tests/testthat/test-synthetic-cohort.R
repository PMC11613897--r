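test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  set.seed(999)
  before <- .Random.seed
  a <- simulate_cohort(sim_config(n_women = 500, seed = 7))
  expect_identical(.Random.seed, before)
  b <- simulate_cohort(sim_config(n_women = 500, seed = 7))
  expect_identical(a, b)
  c_ <- simulate_cohort(sim_config(n_women = 500, seed = 8))
  expect_false(identical(a$prs_raw, c_$prs_raw))
})

test_that("cohort invariants hold: EHR ordering, event ages, panel genes", {
  cohort <- small_cohort()
  expect_true(all(cohort$ehr_start_age <= cohort$ehr_end_age))
  expect_true(all(cohort$ehr_end_age <= cohort$current_age + 1e-9))
  ev <- cohort_events(cohort)
  cap <- setNames(cohort$current_age, cohort$participant_id)
  expect_true(all(ev$age >= 0))
  expect_true(all(ev$age <= cap[ev$participant_id] + 1e-6))
  genes <- unlist(strsplit(cohort$carrier_genes, ";"))
  expect_true(all(genes %in% PANEL_GENES))
})

test_that("realized carrier counts stay within 4-sigma binomial bounds", {
  cfg <- sim_config(seed = 11)
  cohort <- simulate_cohort(cfg)
  p <- cfg$gene_carrier_counts / 25591
  for (g in PANEL_GENES) {
    n_g <- sum(vapply(strsplit(cohort$carrier_genes, ";"),
                      function(x) g %in% x, logical(1)))
    mu <- cfg$n_women * p[[g]]
    sigma <- sqrt(cfg$n_women * p[[g]] * (1 - p[[g]]))
    expect_lt(abs(n_g - mu), 4 * sigma)
  }
})

test_that("null configuration yields hazard ratios near 1 for every factor", {
  cfg <- sim_config(
    gene_hr = c(BRCA1 = 1, BRCA2 = 1, PALB2 = 1, ATM = 1, CHEK2 = 1),
    prs_top10_hr = 1, fhx_carrier_or = 1, fhx_prs_beta = 0, seed = 5)
  cohort <- simulate_cohort(cfg)
  rec <- survival_records(cohort)
  info <- screening_inputs(cohort)
  rec$carrier <- nzchar(rec$carrier_genes)
  rec$top10 <- info$prs_percentile > 90
  fit <- cox_fit(rec, c("carrier", "top10"))
  for (cv in names(fit$hr)) {
    expect_gt(1, fit$ci95[cv, "lower"])
    expect_lt(1, fit$ci95[cv, "upper"])
  }
  assoc <- fisher_exact(sum(rec$carrier & rec$fhx), sum(rec$carrier & !rec$fhx),
                        sum(!rec$carrier & rec$fhx), sum(!rec$carrier & !rec$fhx))
  expect_gt(1, assoc$conf_int[1])
  expect_lt(1, assoc$conf_int[2])
})

test_that("carrier-free middle-PRS KM incidence at 70 stays near the calibration target", {
  devs <- vapply(1:10, function(s) {
    cohort <- simulate_cohort(sim_config(seed = s))
    info <- screening_inputs(cohort)
    rec <- survival_records(cohort)
    mid <- !nzchar(cohort$carrier_genes) &
      info$prs_percentile > 30 & info$prs_percentile <= 70
    km_risk_at(km_fit(rec[mid, ]), 70) - 0.093
  }, numeric(1))
  expect_true(all(abs(devs) < 0.015))
})

test_that("affected women's FHx code timing recovers the configured mixture", {
  cfg <- sim_config(seed = 3)
  cohort <- simulate_cohort(cfg)
  tl <- extract_first_codes(cohort_events(cohort),
                            phenotype_definitions()[c("brca", "fhx_brca")],
                            ids = cohort$participant_id)
  tm <- classify_timing(tl)
  both <- tm$category %in% c("before", "simultaneous", "after")
  n <- sum(both)
  expect_equal(sum(tm$category[both] == "before") +
                 sum(tm$category[both] == "simultaneous") +
                 sum(tm$category[both] == "after"), n)
  p_hat <- mean(tm$category[both] == "simultaneous")
  p0 <- cfg$fhx_timing_mix[["simultaneous"]]
  expect_lt(abs(p_hat - p0), 4 * sqrt(p0 * (1 - p0) / n))
})

test_that("carrier-FHx odds ratio among unaffected women sits inside the exact CI", {
  cohort <- simulate_cohort(sim_config(seed = 2))
  rec <- survival_records(cohort)
  un <- rec$event == 0L
  carrier <- nzchar(rec$carrier_genes[un])
  fhx <- rec$fhx[un]
  ft <- fisher_exact(sum(carrier & fhx), sum(carrier & !fhx),
                     sum(!carrier & fhx), sum(!carrier & !fhx))
  expect_gt(3.5, ft$conf_int[1])
  expect_lt(3.5, ft$conf_int[2])
})

test_that("cohort tables round-trip through TSV exactly", {
  cohort <- small_cohort(n = 100, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, as.data.frame(cohort), ignore_attr = TRUE)
})

test_that("an empty cohort writes a headed file that reads back empty", {
  cohort <- small_cohort(n = 50, seed = 1)[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  expect_match(readLines(path)[1], "participant_id\tgenetic_group")
  back <- read_cohort(path)
  expect_equal(nrow(back), 0L)
})

test_that("malformed cohort rows are rejected with their row numbers", {
  cohort <- small_cohort(n = 20, seed = 9)
  bad <- cohort
  bad$ehr_start_age[3] <- bad$ehr_end_age[3] + 5
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_cohort(bad, path), "3.*ehr_start_age > ehr_end_age")
  bad2 <- cohort
  bad2$diagnosis_events[5] <- "C50.911@200"
  expect_error(write_cohort(bad2, path), "outside \\[0, current_age\\].*5")
})

test_that("infeasible calibration targets fail explicitly", {
  expect_error(sim_config(baseline_cuminc_70 = 1), "infeasible|\\[0, 1\\)")
  expect_error(sim_config(fhx_timing_mix = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(sim_config(gene_hr = c(BRCA1 = -1, BRCA2 = 1, PALB2 = 1,
                                      ATM = 1, CHEK2 = 1)), "> 0")
  expect_error(sim_config(group_proportions = c(Africa = 0.5, Americas = 0.6,
                                                EastAsia = 0, Europe = 0,
                                                Other = 0, SouthAsia = 0)),
               "sum to 1")
})

test_that("YAML configuration files reproduce the in-code defaults", {
  path <- system.file("extdata", "default_config.yaml", package = "brcascreen")
  cfg <- read_sim_config(path)
  ref <- sim_config()
  expect_equal(cfg$gene_hr, ref$gene_hr)
  expect_equal(cfg$fhx_timing_mix, ref$fhx_timing_mix)
  expect_equal(cfg$group_proportions[GENETIC_GROUPS],
               ref$group_proportions[GENETIC_GROUPS], tolerance = 1e-6)
  expect_equal(cfg$age_mix, ref$age_mix)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 3", bad)
  expect_error(read_sim_config(bad), "unknown config field.*not_a_field")
})
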