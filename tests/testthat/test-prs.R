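test_that("dosage uses GP, then GT, then the Hardy-Weinberg AF fallback", {
  expect_equal(dosage(gp0 = 0.1, gp1 = 0.8, gp2 = 0.1), 1.0)
  expect_equal(dosage(gp0 = 0.8, gp1 = 0.2, gp2 = 0.0), 0.2)
  expect_equal(dosage(gt = 2), 2)
  # fallback equals the expected allele count under HWE genotype probabilities
  af <- 0.25
  hw <- c((1 - af)^2, 2 * af * (1 - af), af^2)
  expect_equal(dosage(af_reference = af), 0.5)
  expect_equal(dosage(gp0 = hw[1], gp1 = hw[2], gp2 = hw[3]),
               dosage(af_reference = af))
  expect_error(dosage(), "no GP, no GT")
  expect_error(dosage(gp0 = 0.5, gp1 = 0.1, gp2 = 0.1), "sum to 1")
})

test_that("scoring is the weighted dosage sum and is linear in the weights", {
  model <- read_pgs_model(system.file("extdata", "synthetic_pgs15_scorefile.txt",
                                      package = "brcascreen"))
  expect_equal(nrow(model), 15L)
  expect_equal(model$effect_weight[1], 0.052)
  obs <- data.frame(
    participant_id = rep(c("A", "B"), each = 15),
    variant_id = rep(model$variant_id, 2),
    gt = c(rep(1, 15), rep(2, 15))
  )
  sc <- prs_score(model, obs)
  expect_equal(sc$raw_score[sc$participant_id == "A"], sum(model$effect_weight))
  expect_equal(sc$raw_score[sc$participant_id == "B"], 2 * sum(model$effect_weight))
  model2 <- model
  model2$effect_weight <- 2 * model2$effect_weight
  expect_equal(prs_score(model2, obs)$raw_score, 2 * sc$raw_score)
  zero <- model
  zero$effect_weight[] <- 0
  expect_true(all(prs_score(zero, obs)$raw_score == 0))
  obs_extra <- rbind(obs, data.frame(participant_id = "A",
                                     variant_id = "rs_not_in_model", gt = 1))
  expect_warning(prs_score(model, obs_extra), "absent from the model")
})

test_that("single-entry score: weight 0.3 at dosage 2 gives 0.6", {
  model <- data.frame(variant_id = "rs1", effect_allele = "A",
                      other_allele = "G", effect_weight = 0.3)
  obs <- data.frame(participant_id = "A", variant_id = "rs1", gt = 2)
  expect_equal(prs_score(model, obs)$raw_score, 0.6)
})

test_that("AF-fallback-only cohorts have zero score variance within a group", {
  model <- data.frame(variant_id = c("rs1", "rs2"), effect_allele = "A",
                      other_allele = "G", effect_weight = c(0.3, -0.2))
  obs <- expand.grid(participant_id = paste0("P", 1:8),
                     variant_id = c("rs1", "rs2"), stringsAsFactors = FALSE)
  obs$af_reference <- ifelse(obs$variant_id == "rs1", 0.2, 0.4)
  sc <- prs_score(model, obs)
  expect_equal(stats::var(sc$raw_score), 0)
  expect_equal(sc$raw_score[1], 0.3 * 0.4 - 0.2 * 0.8)
})

test_that("percentiles follow the average-rank convention within each group", {
  sc <- data.frame(participant_id = paste0("P", 1:7),
                   raw_score = c(0.1, 0.4, 0.2, 0.3, 1.0, 1.0, 5.0),
                   genetic_group = c(rep("Europe", 4), rep("Africa", 2), "Other"))
  out <- assign_percentiles(sc)
  expect_equal(out$percentile[1:4], c(25, 100, 50, 75))
  expect_equal(out$percentile[5:6], c(75, 75))   # average rank 1.5 of 2
  expect_equal(out$percentile[7], 100)           # one-woman group
})

test_that("distinct-score percentiles are distribution-free and unchanged by other groups", {
  set.seed(4)
  for (n in c(3, 10, 57)) {
    x <- data.frame(participant_id = paste0("P", 1:n),
                    raw_score = sample(stats::rcauchy(n)),
                    genetic_group = "Europe")
    p <- sort(assign_percentiles(x)$percentile)
    expect_equal(p, 100 * seq_len(n) / n)
    with_other <- rbind(x, data.frame(participant_id = "Q1", raw_score = 99,
                                      genetic_group = "Americas"))
    p2 <- assign_percentiles(with_other)
    expect_equal(p2$percentile[seq_len(n)], assign_percentiles(x)$percentile)
  }
})

test_that("top-fraction flags use a strict percentile boundary", {
  expect_true(prs_top_flag(95, 0.10))
  expect_false(prs_top_flag(90, 0.10))
  expect_error(prs_top_flag(50, 1.5), "\\(0, 1\\)")
  # distinct scores in a group of 1000 split exactly 500/500 at top 50%
  sc <- data.frame(participant_id = paste0("P", 1:1000),
                   raw_score = sample(1000), genetic_group = "Europe")
  p <- assign_percentiles(sc)$percentile
  expect_equal(sum(prs_top_flag(p, 0.5)), 500)
})

test_that("rank AUC equals the exhaustive pairwise comparison and the Mann-Whitney U", {
  score <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(prs_auc(score, case), 1.0)
  expect_equal(prs_auc(rep(1, 6), case), 0.5)
  s <- c(3, 1, 2, 2, 5, 0)
  pairs <- outer(s[case == TRUE], s[case == FALSE],
                 function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(prs_auc(s, case), mean(pairs))
  set.seed(8)
  for (i in 1:20) {
    x <- sample(20, 30, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(lab) || all(lab)) next
    u <- unname(suppressWarnings(
      stats::wilcox.test(x[lab], x[!lab])$statistic))
    expect_equal(prs_auc(x, lab), u / (sum(lab) * sum(!lab)))
  }
  expect_error(prs_auc(1:3, c(TRUE, TRUE, TRUE)), "case and one control")
})

test_that("callability QC drops variants missing in >10% of participants", {
  model <- data.frame(variant_id = c("rs1", "rs2"), effect_allele = "A",
                      other_allele = "G", effect_weight = c(0.1, 0.2))
  obs <- expand.grid(participant_id = paste0("P", 1:20),
                     variant_id = c("rs1", "rs2"), stringsAsFactors = FALSE)
  obs$gt <- 1
  obs$gt[obs$variant_id == "rs2" & obs$participant_id %in% paste0("P", 1:3)] <- NA
  kept <- prs_callability_filter(model, obs, n_participants = 20)
  expect_equal(kept$variant_id, "rs1")
  obs$gt[is.na(obs$gt)] <- 1
  expect_equal(prs_callability_filter(model, obs, 20)$variant_id, c("rs1", "rs2"))
})
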