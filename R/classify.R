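#' Rule-based variant interpretation cascade for population screening
#'
#' Classifies pre-annotated small variants in the 5-gene panel with the
#' first-match-wins cascade used for automated population screening:
#'
#' 1. variants failing the gnomAD quality filter (or flagged by manual QC)
#'    are excluded before any rule fires;
#' 2. (a) rs555607708 (CHEK2 c.1100del) is always P/LP;
#' 3. (b) an expert-panel ClinVar review keeps the panel's interpretation,
#'    mapped onto \{P/LP, B/LB, VUS\};
#' 4. (c) multiple submitters, no conflicts + Benign/Likely benign is B/LB;
#' 5. (d) multiple submitters, no conflicts + Uncertain significance is VUS;
#' 6. (e) a high-confidence LOFTEE call (HC) is P/LP;
#' 7. (f) everything else is not_pathogenic.
#'
#' ClinVar strings are matched case-insensitively with underscores treated
#' as spaces; combined values such as "Pathogenic/Likely_pathogenic" map to
#' P/LP. Unknown review-status strings are treated as absent (with a
#' message). Expert-panel labels outside the three classes fall through to
#' not_pathogenic with a warning.
#'
#' @param variants `data.frame` of small-variant annotations with columns
#'   `variant_id`, `gene`, `rsid`, `clnsig`, `clnrevstat`, `loftee`
#'   (`"HC"`, `"LC"` or `"none"`), `gnomad_filter_pass` (logical) and
#'   optionally `manual_fail` (logical; forces exclusion).
#' @return The input with `label` (one of `"P/LP"`, `"B/LB"`, `"VUS"`,
#'   `"not_pathogenic"`, `"excluded"`) and `rule_fired` columns appended.
#' @examples
#' v <- data.frame(variant_id = "22-28695869-AG-A", gene = "CHEK2",
#'                 rsid = "rs555607708", clnsig = NA, clnrevstat = NA,
#'                 loftee = "none", gnomad_filter_pass = TRUE)
#' classify_variants(v)[, c("label", "rule_fired")]
#' @export
classify_variants <- function(variants) {
  .check_panel_genes(variants$gene)
  if (!is.null(variants$is_cnv) && any(variants$is_cnv)) {
    stop("classify_variants() handles small variants only; ",
         "use classify_cnvs() for CNV records")
  }
  n <- nrow(variants)
  label <- character(n)
  rule <- character(n)
  revstat <- .normalize_clinvar(variants$clnrevstat)
  known_rev <- is.na(revstat) |
    grepl("reviewed by expert panel", revstat, fixed = TRUE) |
    grepl("criteria provided", revstat, fixed = TRUE) |
    grepl("no assertion", revstat, fixed = TRUE) |
    grepl("single submitter", revstat, fixed = TRUE) |
    grepl("conflicting", revstat, fixed = TRUE)
  if (any(!known_rev)) {
    message("treating ", sum(!known_rev),
            " unknown CLNREVSTAT string(s) as absent")
    revstat[!known_rev] <- NA_character_
  }
  sig <- .normalize_clinvar(variants$clnsig)
  sig_class <- .map_clnsig(sig)
  manual_fail <- if (is.null(variants$manual_fail)) rep(FALSE, n) else
    variants$manual_fail %in% TRUE
  expert <- !is.na(revstat) & grepl("reviewed by expert panel", revstat, fixed = TRUE)
  multi_nc <- !is.na(revstat) &
    grepl("criteria provided, multiple submitters, no conflicts", revstat, fixed = TRUE)
  loftee_hc <- !is.na(variants$loftee) & toupper(variants$loftee) == "HC"
  is_chek2_del <- !is.na(variants$rsid) & variants$rsid == "rs555607708"

  for (i in seq_len(n)) {
    if (!isTRUE(variants$gnomad_filter_pass[i])) {
      label[i] <- "excluded"; rule[i] <- "gnomad_filter"
    } else if (manual_fail[i]) {
      label[i] <- "excluded"; rule[i] <- "manual_qc"
    } else if (is_chek2_del[i]) {
      label[i] <- "P/LP"; rule[i] <- "a_rs555607708"
    } else if (expert[i]) {
      cls <- sig_class[i]
      if (is.na(cls)) {
        warning("expert-panel review with unmapped CLNSIG '",
                variants$clnsig[i], "'; labelling not_pathogenic")
        label[i] <- "not_pathogenic"
      } else {
        label[i] <- cls
      }
      rule[i] <- "b_expert_panel"
    } else if (multi_nc[i] && identical(sig_class[i], "B/LB")) {
      label[i] <- "B/LB"; rule[i] <- "c_multi_submitter_blb"
    } else if (multi_nc[i] && identical(sig_class[i], "VUS")) {
      label[i] <- "VUS"; rule[i] <- "d_multi_submitter_vus"
    } else if (loftee_hc[i]) {
      label[i] <- "P/LP"; rule[i] <- "e_loftee_hc"
    } else {
      label[i] <- "not_pathogenic"; rule[i] <- "f_default"
    }
  }
  variants$label <- label
  variants$rule_fired <- rule
  variants
}

.check_panel_genes <- function(gene) {
  bad <- setdiff(unique(gene), PANEL_GENES)
  if (length(bad)) {
    stop("gene(s) outside the 5-gene panel rejected: ",
         paste(bad, collapse = ", "))
  }
}

.normalize_clinvar <- function(x) {
  if (is.null(x)) return(NA_character_)
  out <- tolower(gsub("_", " ", as.character(x), fixed = TRUE))
  out[!nzchar(trimws(out))] <- NA_character_
  out
}

# canonical CLNSIG strings -> {P/LP, B/LB, VUS, NA}
.map_clnsig <- function(sig_norm) {
  out <- rep(NA_character_, length(sig_norm))
  out[sig_norm %in% c("pathogenic", "likely pathogenic",
                      "pathogenic/likely pathogenic")] <- "P/LP"
  out[sig_norm %in% c("benign", "likely benign", "benign/likely benign")] <- "B/LB"
  out[sig_norm %in% "uncertain significance"] <- "VUS"
  out
}

#' Classify copy-number variants
#'
#' Only large deletions are considered pathogenic: a deletion passing the
#' CNV QC filter and overlapping at least one protein-coding exon of the
#' MANE transcript is P/LP; non-PASS calls are excluded; duplications and
#' non-exonic deletions are not_pathogenic.
#'
#' @param cnvs `data.frame` with `variant_id`, `gene`, `cnv_kind`
#'   (`"deletion"`/`"duplication"`), `cnv_pass` (logical) and
#'   `overlaps_coding_exon` (logical).
#' @return Input with `label` and `rule_fired` appended.
#' @export
classify_cnvs <- function(cnvs) {
  .check_panel_genes(cnvs$gene)
  if (any(is.na(cnvs$cnv_kind) | cnvs$cnv_kind == "none")) {
    stop("classify_cnvs() requires cnv_kind 'deletion' or 'duplication'")
  }
  n <- nrow(cnvs)
  label <- character(n); rule <- character(n)
  for (i in seq_len(n)) {
    if (!isTRUE(cnvs$cnv_pass[i])) {
      label[i] <- "excluded"; rule[i] <- "cnv_filter"
    } else if (cnvs$cnv_kind[i] == "deletion" &&
               isTRUE(cnvs$overlaps_coding_exon[i])) {
      label[i] <- "P/LP"; rule[i] <- "cnv_exonic_deletion"
    } else {
      label[i] <- "not_pathogenic"; rule[i] <- "cnv_benign_kind"
    }
  }
  cnvs$label <- label
  cnvs$rule_fired <- rule
  cnvs
}

#' Per-participant carrier table from classified variants and genotypes
#'
#' A participant carries a gene iff she has at least one heterozygous or
#' homozygous genotype for a P/LP variant in it. Excluded variants never
#' contribute. Multi-gene carriers retain all genes; the single analysis
#' group follows the precedence BRCA1 > BRCA2 > PALB2 > ATM > CHEK2.
#'
#' @param classified Output of [classify_variants()] (and/or
#'   [classify_cnvs()]), i.e. variants with a `label` column.
#' @param genotypes `data.frame` with `participant_id`, `variant_id`, `GT`
#'   (`"0/0"`, `"0/1"`, `"1/1"`, `/`-or-`|`-separated).
#' @param participant_ids Optional full roster so non-carriers without any
#'   genotype row appear in the output.
#' @return `data.frame` with `participant_id`, `carrier_genes`
#'   (semicolon-joined, "" if none) and `analysis_group`.
#' @export
carrier_table <- function(classified, genotypes, participant_ids = NULL) {
  unknown <- setdiff(unique(genotypes$variant_id), classified$variant_id)
  if (length(unknown)) {
    stop("genotype references unknown variant(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  plp <- classified[classified$label == "P/LP", c("variant_id", "gene")]
  g <- merge(genotypes, plp, by = "variant_id")
  alt_count <- vapply(strsplit(g$GT, "[/|]"), function(a) sum(a == "1"), integer(1))
  g <- g[alt_count >= 1L, ]
  ids <- unique(c(participant_ids, genotypes$participant_id))
  carrier_sets <- lapply(split(g$gene, factor(g$participant_id, levels = ids)),
                         function(x) sort(unique(x)))
  carrier_genes <- vapply(ids, function(id) {
    s <- carrier_sets[[id]]
    if (is.null(s)) "" else
      paste(PANEL_GENES[sort(match(s, PANEL_GENES))], collapse = ";")
  }, character(1))
  data.frame(
    participant_id = ids,
    carrier_genes = unname(carrier_genes),
    analysis_group = carrier_analysis_group(unname(carrier_genes)),
    stringsAsFactors = FALSE
  )
}

#' Allele-frequency sanity report for P/LP calls
#'
#' Pathogenic calls in a population-screening panel are expected to be rare
#' (cohort allele frequency below 0.1%), the well-known CHEK2 c.1100del
#' (rs555607708) being the stated exception. This report flags any other
#' P/LP variant at or above the threshold for manual review; it never
#' reclassifies.
#'
#' @param classified Output of [classify_variants()].
#' @param af_threshold Cohort allele-frequency threshold (default 0.001).
#' @return `data.frame` of flagged variants (possibly zero rows) with the
#'   offending frequency.
#' @export
af_sanity_report <- function(classified, af_threshold = 0.001) {
  if (!nrow(classified)) {
    return(data.frame(variant_id = character(), gene = character(),
                      af_cohort = numeric(), stringsAsFactors = FALSE))
  }
  flag <- classified$label == "P/LP" &
    !(!is.na(classified$rsid) & classified$rsid == "rs555607708") &
    !is.na(classified$af_cohort) & classified$af_cohort >= af_threshold
  out <- classified[flag, c("variant_id", "gene", "af_cohort")]
  rownames(out) <- NULL
  out
}

#' Simulate an annotated variant table and genotype calls for a cohort
#'
#' Produces a small synthetic annotation set (per gene: an expert-panel
#' pathogenic variant, a LOFTEE-HC-only loss-of-function variant, a
#' multi-submitter benign variant, a VUS, and a gnomAD-filtered call, plus
#' the CHEK2 rs555607708 deletion) together with genotype rows that are
#' consistent with the cohort's `carrier_genes`: each carrier receives one
#' heterozygous P/LP genotype in her gene, and a sprinkling of benign/VUS
#' and hom-ref genotypes is added so classification actually filters
#' something. Running [classify_variants()] + [carrier_table()] on the
#' output reproduces the cohort's carrier sets exactly.
#'
#' @param cohort Cohort `data.frame`.
#' @param seed Integer seed (independent of the cohort's).
#' @return `list(variants = ..., genotypes = ...)`.
#' @export
simulate_variant_annotations <- function(cohort, seed = 1L) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  mk <- function(gene, tag, rsid, clnsig, clnrevstat, loftee, pass, af) {
    data.frame(variant_id = paste0(gene, "_", tag), gene = gene, rsid = rsid,
               consequence = if (loftee == "none") "missense_variant" else
                 "frameshift_variant",
               clnsig = clnsig, clnrevstat = clnrevstat, loftee = loftee,
               gnomad_filter_pass = pass, af_gnomad = af, af_cohort = af,
               stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, lapply(PANEL_GENES, function(g) {
    rbind(
      mk(g, "expert_p", NA, "Pathogenic", "reviewed by expert panel", "HC", TRUE, 2e-4),
      mk(g, "lof_hc", NA, NA, NA, "HC", TRUE, 1.5e-4),
      mk(g, "benign", NA, "Benign",
         "criteria provided, multiple submitters, no conflicts", "none", TRUE, 0.01),
      mk(g, "vus", NA, "Uncertain significance",
         "criteria provided, multiple submitters, no conflicts", "none", TRUE, 5e-4),
      mk(g, "filtered", NA, NA, NA, "HC", FALSE, 1e-4)
    )
  }))
  chek2_del <- mk("CHEK2", "del1100C", "rs555607708", NA, NA, "LC", TRUE, 0.0048)
  variants <- rbind(variants, chek2_del)

  plp_by_gene <- list()
  for (g in PANEL_GENES) {
    plp_by_gene[[g]] <- c(paste0(g, "_expert_p"), paste0(g, "_lof_hc"))
  }
  plp_by_gene$CHEK2 <- c(plp_by_gene$CHEK2, "CHEK2_del1100C", "CHEK2_del1100C")

  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    genes <- strsplit(cohort$carrier_genes[i], ";", fixed = TRUE)[[1]]
    for (g in genes) {
      vid <- sample(plp_by_gene[[g]], 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = cohort$participant_id[i], variant_id = vid,
        GT = "0/1", stringsAsFactors = FALSE)
    }
  }
  # benign/VUS het calls and hom-ref records for ~2% of the cohort
  n_noise <- max(1L, round(0.02 * nrow(cohort)))
  noise_ids <- sample(cohort$participant_id, n_noise)
  noise_vids <- sample(c(paste0(PANEL_GENES, "_benign"), paste0(PANEL_GENES, "_vus"),
                         paste0(PANEL_GENES, "_expert_p")), n_noise, replace = TRUE)
  noise_gt <- ifelse(grepl("_expert_p$", noise_vids), "0/0",
                     sample(c("0/1", "1/1"), n_noise, replace = TRUE))
  rows[[length(rows) + 1L]] <- data.frame(participant_id = noise_ids,
                                          variant_id = noise_vids,
                                          GT = noise_gt, stringsAsFactors = FALSE)
  genotypes <- do.call(rbind, rows)
  rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}
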