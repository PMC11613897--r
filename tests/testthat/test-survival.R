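toy3 <- data.frame(time = c(5, 10, 15), event = c(1, 0, 1))

test_that("product-limit values match hand computation on the toy curve", {
  km <- km_fit(toy3)
  expect_equal(km_risk_at(km, 5), 1 - 2 / 3)
  expect_equal(km_risk_at(km, 12), 1 / 3)     # flat between steps
  expect_equal(km_risk_at(km, 15), 1)          # (1 - 1/3) * (1 - 1/1) = 0
  expect_equal(km_risk_at(km, 4.9), 0)         # before the first event
  expect_equal(km_risk_at(km, 99), 1)          # carried forward
  expect_error(km_risk_at(km, -1), ">= 0")
})

test_that("km_fit equals the brute-force risk-set product on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    rec <- data.frame(time = sample(1:12, n, replace = TRUE),
                      event = rbinom(n, 1, 0.6))
    if (sum(rec$event) == 0) rec$event[1] <- 1
    km <- km_fit(rec)
    for (at in c(0.5, 3, 7.5, 12, 20)) {
      expect_equal(km_risk_at(km, at),
                   1 - km_oracle(rec$time, rec$event, at))
    }
  }
})

test_that("degenerate inputs: no events gives survival identically 1", {
  rec <- data.frame(time = c(3, 3, 3), event = c(0, 0, 0))
  expect_warning(km <- km_fit(rec), "no events")
  expect_equal(km_risk_at(km, 10), 0)
})

test_that("without censoring, cumulative incidence is the empirical CDF", {
  set.seed(6)
  t <- rexp(200, 0.1)
  km <- km_fit(data.frame(time = t, event = 1))
  for (at in c(2, 8, 20)) {
    expect_equal(km_risk_at(km, at), mean(t <= at))
  }
})

test_that("log-rank: zero on identical arms, hand O-E value, arm symmetry", {
  a <- data.frame(time = c(1, 3, 5), event = c(1, 1, 0))
  expect_equal(logrank(a, a)$statistic, 0)
  b <- data.frame(time = c(2, 4, 6), event = c(1, 1, 1))
  got <- logrank(a, b)
  want <- logrank_oracle(a$time, a$event, b$time, b$event)
  expect_equal(got$statistic, want)
  expect_equal(got$p, pchisq(want, 1, lower.tail = FALSE))
  expect_equal(logrank(b, a)$statistic, got$statistic)
  expect_error(logrank(data.frame(time = 1, event = 0),
                       data.frame(time = 2, event = 0)), "at least one event")
})

test_that("Cox fit on two identical groups is exactly null", {
  rec <- data.frame(time = rep(c(2, 4, 6, 8), 2), event = rep(c(1, 1, 0, 1), 2),
                    grp = rep(c(0, 1), each = 4))
  fit <- cox_fit(rec, "grp")
  expect_equal(unname(fit$hr), 1, tolerance = 1e-6)
  expect_gt(fit$p, 0.99)
})

test_that("partial likelihood at the estimate is no worse than at the null", {
  set.seed(13)
  rec <- data.frame(time = rexp(300), event = rbinom(300, 1, 0.7),
                    x = rnorm(300))
  fit <- cox_fit(rec, "x")
  null_ll <- fit$fit$loglik[1]
  expect_gte(fit$loglik, null_ll)
  # single binary covariate: sign of beta agrees with the O-E score direction
  rec$g <- as.integer(rec$x > 0)
  fit2 <- cox_fit(rec, "g")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = rec)
  expect_equal(sign(unname(fit2$coefficients)),
               sign(sd_$obs[2] - sd_$exp[2]))
})

test_that("two-group exponential data recover HR 2 inside the Wald CI in >=94% of seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n <- 5000
    grp <- rep(0:1, each = n / 2)
    t_event <- rexp(n, rate = 0.1 * ifelse(grp == 1, 2, 1))
    cens <- rexp(n, rate = 0.05)
    rec <- data.frame(time = pmin(t_event, cens),
                      event = as.integer(t_event <= cens), grp = grp)
    fit <- cox_fit(rec, "grp")
    fit$ci95[1, "lower"] <= 2 && 2 <= fit$ci95[1, "upper"]
  }, logical(1))
  expect_gte(mean(hits), 0.94)
})

test_that("constant covariates and event-poor data are rejected", {
  rec <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1), x = c(1, 1, 1))
  expect_error(cox_fit(rec, "x"), "constant covariate")
  rec2 <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0), x = c(0, 1, 0))
  expect_error(cox_fit(rec2, "x"), "at least 2 events")
})

test_that("fitted per-gene HR CIs cover the generating multipliers in >=90% of cohorts", {
  # nominal Wald coverage is 95%; 100 replicate cohorts keep the
  # Monte-Carlo error on the coverage estimate well below the 5-point margin
  cfg <- sim_config()
  covered <- matrix(NA, 100, length(PANEL_GENES),
                    dimnames = list(NULL, PANEL_GENES))
  for (s in 1:100) {
    cohort <- simulate_cohort(sim_config(seed = 5000 + s))
    rec <- survival_records(cohort)
    rec$z <- cohort$prs_z
    for (g in PANEL_GENES) {
      rec[[g]] <- carrier_analysis_group(rec$carrier_genes) == g
    }
    fit <- cox_fit(rec, c(PANEL_GENES, "z"))
    for (g in PANEL_GENES) {
      cv <- paste0(g, "TRUE")
      covered[s, g] <- fit$ci95[cv, "lower"] <= cfg$gene_hr[[g]] &&
        cfg$gene_hr[[g]] <= fit$ci95[cv, "upper"]
    }
  }
  expect_true(all(colMeans(covered) >= 0.90))
})

test_that("left truncation at EHR entry is available behind a flag", {
  cohort <- small_cohort(n = 3000, seed = 55)
  rec <- survival_records(cohort)
  rec <- rec[rec$time > rec$entry_age, ]
  km_lt <- km_fit(rec, left_truncate = TRUE)
  expect_s3_class(km_lt, "km_curve")
  rec$carrier <- nzchar(rec$carrier_genes)
  fit <- cox_fit(rec, "carrier", left_truncate = TRUE)
  expect_true(is.finite(fit$hr))
})
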