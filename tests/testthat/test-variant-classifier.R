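test_that("each cascade branch fires on its canonical input", {
  v <- rbind(
    make_variant("v_del", "CHEK2", rsid = "rs555607708"),
    make_variant("v_panel_b", "BRCA1", clnsig = "Benign",
                 clnrevstat = "reviewed by expert panel"),
    make_variant("v_multi_vus", "ATM", clnsig = "Uncertain significance",
                 clnrevstat = "criteria provided, multiple submitters, no conflicts"),
    make_variant("v_lof", "BRCA2", loftee = "HC"),
    make_variant("v_missense", "PALB2"),
    make_variant("v_filtered", "BRCA1", loftee = "HC", gnomad_filter_pass = FALSE)
  )
  out <- classify_variants(v)
  expect_equal(out$label,
               c("P/LP", "B/LB", "VUS", "P/LP", "not_pathogenic", "excluded"))
  expect_equal(out$rule_fired,
               c("a_rs555607708", "b_expert_panel", "d_multi_submitter_vus",
                 "e_loftee_hc", "f_default", "gnomad_filter"))
})

test_that("the cascade matches a brute-force truth table over the full cross-product", {
  rsids <- c("rs555607708", "rs1234", NA)
  revs <- c("reviewed by expert panel",
            "criteria provided, multiple submitters, no conflicts",
            "Criteria_provided,_multiple_submitters,_no_conflicts",
            "criteria provided, single submitter",
            "some unknown review tier", NA)
  sigs <- c("Pathogenic", "Likely_pathogenic", "Pathogenic/Likely_pathogenic",
            "Benign", "Likely benign", "Uncertain significance",
            "Conflicting interpretations of pathogenicity", NA)
  lofs <- c("HC", "LC", "none")
  passes <- c(TRUE, FALSE)
  grid <- expand.grid(rsid = rsids, rev = revs, sig = sigs, lof = lofs,
                      pass = passes, stringsAsFactors = FALSE)
  v <- make_variant(sprintf("v%04d", seq_len(nrow(grid))), "CHEK2",
                    rsid = NA)[rep(1, nrow(grid)), ]
  v$variant_id <- sprintf("v%04d", seq_len(nrow(grid)))
  v$rsid <- grid$rsid
  v$clnrevstat <- grid$rev
  v$clnsig <- grid$sig
  v$loftee <- grid$lof
  v$gnomad_filter_pass <- grid$pass
  got <- suppressWarnings(suppressMessages(classify_variants(v)))$label
  want <- mapply(cascade_oracle, grid$rsid, grid$rev, grid$sig, grid$lof,
                 grid$pass)
  expect_equal(got, unname(want))
  expect_true(all(got %in% c("P/LP", "B/LB", "VUS", "not_pathogenic", "excluded")))
})

test_that("rule order matters: expert-panel benign beats a LOFTEE HC call", {
  v <- make_variant("v", "BRCA1", clnsig = "Benign",
                    clnrevstat = "reviewed by expert panel", loftee = "HC")
  out <- classify_variants(v)
  expect_equal(out$label, "B/LB")
  expect_equal(out$rule_fired, "b_expert_panel")
})

test_that("manual QC failures and off-panel genes are handled", {
  v <- make_variant("v", "ATM", loftee = "HC", manual_fail = TRUE)
  expect_equal(classify_variants(v)$label, "excluded")
  expect_error(classify_variants(make_variant("v", "TP53")),
               "outside the 5-gene panel")
})

test_that("CNV classification: only PASS exonic deletions are pathogenic", {
  cnv <- data.frame(
    variant_id = c("c1", "c2", "c3", "c4"),
    gene = c("BRCA1", "ATM", "BRCA2", "PALB2"),
    cnv_kind = c("deletion", "duplication", "deletion", "deletion"),
    cnv_pass = c(TRUE, TRUE, FALSE, TRUE),
    overlaps_coding_exon = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  out <- classify_cnvs(cnv)
  expect_equal(out$label, c("P/LP", "not_pathogenic", "excluded", "not_pathogenic"))
  bad <- cnv[1, ]; bad$cnv_kind <- "none"
  expect_error(classify_cnvs(bad), "deletion.*duplication")
})

test_that("carrier table keeps all genes but assigns one precedence group", {
  vars <- classify_variants(rbind(
    make_variant("b1", "BRCA1", loftee = "HC"),
    make_variant("b2", "BRCA2", loftee = "HC"),
    make_variant("benign", "BRCA1", clnsig = "Benign",
                 clnrevstat = "criteria provided, multiple submitters, no conflicts"),
    make_variant("filtered_lof", "PALB2", loftee = "HC",
                 gnomad_filter_pass = FALSE)
  ))
  gt <- data.frame(
    participant_id = c("A", "A", "B", "C", "D"),
    variant_id = c("b1", "b2", "benign", "b1", "filtered_lof"),
    GT = c("0/1", "0/1", "1/1", "0/0", "0/1"),
    stringsAsFactors = FALSE
  )
  ct <- carrier_table(vars, gt)
  expect_equal(ct$carrier_genes[ct$participant_id == "A"], "BRCA1;BRCA2")
  expect_equal(ct$analysis_group[ct$participant_id == "A"], "BRCA1")
  # benign-only, hom-ref, and excluded-variant genotypes never make carriers
  expect_equal(ct$carrier_genes[ct$participant_id %in% c("B", "C", "D")],
               c("", "", ""))
  expect_error(carrier_table(vars, data.frame(participant_id = "X",
                                              variant_id = "nope", GT = "0/1")),
               "unknown variant")
})

test_that("simulated annotations reproduce the cohort's carrier sets", {
  cohort <- small_cohort(n = 2000, seed = 77)
  ann <- simulate_variant_annotations(cohort, seed = 2)
  labels <- suppressMessages(classify_variants(ann$variants))
  ct <- carrier_table(labels, ann$genotypes,
                      participant_ids = cohort$participant_id)
  ct <- ct[match(cohort$participant_id, ct$participant_id), ]
  expect_equal(ct$carrier_genes, cohort$carrier_genes)
})

test_that("AF sanity report flags common P/LP calls but spares rs555607708", {
  vars <- classify_variants(rbind(
    make_variant("common_lof", "ATM", loftee = "HC", af_cohort = 0.002),
    make_variant("rare_lof", "ATM", loftee = "HC", af_cohort = 0.0002),
    make_variant("chek2del", "CHEK2", rsid = "rs555607708", af_cohort = 0.005)
  ))
  rep_ <- af_sanity_report(vars)
  expect_equal(rep_$variant_id, "common_lof")
  expect_equal(nrow(af_sanity_report(vars[0, ])), 0L)
})
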