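#' Read a PGS-Catalog-format scoring file
#'
#' Flat tab-separated format with `#` metadata headers tolerated; requires
#' at least a variant identifier, `effect_allele` and `effect_weight`
#' column. Variant identifiers must be unique and weights finite.
#'
#' @param path Path to the scoring file.
#' @return `data.frame` with columns `variant_id`, `effect_allele`,
#'   `other_allele` (NA if absent) and `effect_weight`.
#' @export
read_pgs_model <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  id_col <- intersect(c("rsID", "rsid", "variant_id", "ID"), names(tab))[1]
  if (is.na(id_col)) {
    if (all(c("chr_name", "chr_position") %in% names(tab))) {
      tab$variant_id <- paste(tab$chr_name, tab$chr_position, sep = ":")
    } else stop("scoring file lacks a variant identifier column")
  } else {
    tab$variant_id <- as.character(tab[[id_col]])
  }
  if (!all(c("effect_allele", "effect_weight") %in% names(tab))) {
    stop("scoring file lacks effect_allele/effect_weight columns")
  }
  model <- data.frame(
    variant_id = tab$variant_id,
    effect_allele = tab$effect_allele,
    other_allele = if ("other_allele" %in% names(tab)) tab$other_allele else NA,
    effect_weight = as.numeric(tab$effect_weight),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(model$variant_id)) stop("duplicate variant_id in scoring file")
  if (any(!is.finite(model$effect_weight))) stop("non-finite effect weight")
  model
}

#' Effect-allele dosage with genotype-probability and frequency fallback
#'
#' Dosage (expected effect-allele count in \[0, 2\]) per observation:
#' when genotype probabilities are present, `0*GP0 + 1*GP1 + 2*GP2`;
#' otherwise the hard-call allele count `GT`; otherwise `2 * af_reference`
#' (the Hardy-Weinberg expectation under the gnomAD frequency of the
#' participant's closest genetic-similarity group).
#'
#' @param gp0,gp1,gp2 Genotype probabilities (hom-ref, het, hom-alt), NA
#'   when unavailable; must be non-negative and sum to 1 within 1e-6.
#' @param gt Hard-call effect-allele count (0, 1, 2), NA when unavailable.
#' @param af_reference Reference allele frequency of the effect allele.
#' @return Numeric dosages.
#' @examples
#' dosage(gp0 = 0.1, gp1 = 0.8, gp2 = 0.1)          # 1.0
#' dosage(gp0 = NA, gp1 = NA, gp2 = NA, gt = 2)     # 2
#' dosage(af_reference = 0.25)                      # 0.5
#' @export
dosage <- function(gp0 = NA_real_, gp1 = NA_real_, gp2 = NA_real_,
                   gt = NA_real_, af_reference = NA_real_) {
  n <- max(length(gp0), length(gp1), length(gp2), length(gt), length(af_reference))
  gp0 <- rep_len(gp0, n); gp1 <- rep_len(gp1, n); gp2 <- rep_len(gp2, n)
  gt <- rep_len(gt, n); af_reference <- rep_len(af_reference, n)
  has_gp <- !is.na(gp0) & !is.na(gp1) & !is.na(gp2)
  if (any(has_gp)) {
    tot <- gp0[has_gp] + gp1[has_gp] + gp2[has_gp]
    if (any(abs(tot - 1) > 1e-6) ||
        any(gp0[has_gp] < 0 | gp1[has_gp] < 0 | gp2[has_gp] < 0)) {
      stop("genotype probabilities must be non-negative and sum to 1")
    }
  }
  out <- ifelse(has_gp, gp1 + 2 * gp2,
                ifelse(!is.na(gt), gt, 2 * af_reference))
  if (any(is.na(out))) {
    stop("observation(s) with no GP, no GT and no reference allele frequency")
  }
  if (any(out < -1e-9 | out > 2 + 1e-9)) stop("dosage outside [0, 2]")
  out
}

#' Raw polygenic score per participant
#'
#' Linear score: sum over model variants of `effect_weight * dosage`.
#' Observed variants absent from the model are ignored with a warning.
#' Missingness in GP/GT falls back per [dosage()]; a variant with no
#' observation row at all for a participant contributes nothing (upstream
#' callability QC is expected to have dropped sparse variants, see
#' [prs_callability_filter()]).
#'
#' @param model Scoring model from [read_pgs_model()].
#' @param observations `data.frame` with `participant_id`, `variant_id` and
#'   any of `gp0`, `gp1`, `gp2`, `gt`, `af_reference`.
#' @return `data.frame` with `participant_id`, `raw_score`.
#' @export
prs_score <- function(model, observations) {
  extra <- setdiff(unique(observations$variant_id), model$variant_id)
  if (length(extra)) {
    warning("ignoring ", length(extra), " observed variant(s) absent from the model")
    observations <- observations[!observations$variant_id %in% extra, ]
  }
  get0 <- function(col) {
    if (col %in% names(observations)) observations[[col]] else
      rep(NA_real_, nrow(observations))
  }
  d <- dosage(get0("gp0"), get0("gp1"), get0("gp2"), get0("gt"),
              get0("af_reference"))
  w <- model$effect_weight[match(observations$variant_id, model$variant_id)]
  contrib <- w * d
  agg <- tapply(contrib, observations$participant_id, sum)
  data.frame(participant_id = names(agg), raw_score = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drop model variants with poor callability
#'
#' Mirrors the "strong overall callability" SNV QC: variants for which more
#' than `max_missing` of participants lack both GP and GT are removed from
#' the model before scoring.
#'
#' @param model Scoring model.
#' @param observations Observation table (see [prs_score()]).
#' @param n_participants Number of participants expected per variant.
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @return The filtered model.
#' @export
prs_callability_filter <- function(model, observations, n_participants,
                                   max_missing = 0.10) {
  has_call <- rep(FALSE, nrow(observations))
  if (all(c("gp0", "gp1", "gp2") %in% names(observations))) {
    has_call <- !is.na(observations$gp0) & !is.na(observations$gp1) &
      !is.na(observations$gp2)
  }
  if ("gt" %in% names(observations)) has_call <- has_call | !is.na(observations$gt)
  called <- tapply(has_call, observations$variant_id, sum)
  frac_missing <- 1 - (unlist(called)[model$variant_id] / n_participants)
  frac_missing[is.na(frac_missing)] <- 1
  model[frac_missing <= max_missing, , drop = FALSE]
}

#' Within-group PRS percentiles and standard scores
#'
#' Participants are ranked within their genetic-similarity group; ascending
#' average rank `r` of `N` gives percentile `100 * r / N` (so a one-person
#' group is 100 and ties share the average). Groups are then concatenated,
#' leaving each participant's percentile unchanged. The optional z-score is
#' standardized against the within-group mean/SD, by default computed on
#' undiagnosed women only (`exclude` flags diagnosed women, matching the
#' correlation analyses that drop breast-cancer cases).
#'
#' @param scores `data.frame` with `participant_id`, `raw_score`,
#'   `genetic_group`.
#' @param exclude Optional logical vector (same length): rows excluded from
#'   the z-score reference mean/SD, still receiving percentiles/z values.
#' @return Input with `percentile` (in (0, 100\]) and `z_score` appended.
#' @export
assign_percentiles <- function(scores, exclude = NULL) {
  stopifnot(all(c("participant_id", "raw_score", "genetic_group") %in% names(scores)))
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(scores))
  scores$percentile <- NA_real_
  scores$z_score <- NA_real_
  for (g in unique(scores$genetic_group)) {
    idx <- which(scores$genetic_group == g)
    if (!length(idx)) {
      warning("empty genetic-similarity group skipped: ", g)
      next
    }
    x <- scores$raw_score[idx]
    scores$percentile[idx] <- 100 * rank(x, ties.method = "average") / length(idx)
    ref <- x[!exclude[idx]]
    if (length(ref) >= 2L && stats::sd(ref) > 0) {
      scores$z_score[idx] <- (x - mean(ref)) / stats::sd(ref)
    }
  }
  scores
}

#' Rank-based AUC of a score against case labels
#'
#' Equal to the probability that a random case outscores a random control,
#' counting ties as one half (the Mann-Whitney U statistic normalized by
#' `n_case * n_control`).
#'
#' @param score Numeric scores.
#' @param is_case Logical case indicator.
#' @return AUC in \[0, 1\].
#' @export
prs_auc <- function(score, is_case) {
  is_case <- as.logical(is_case)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("AUC requires at least one case and one control")
  r <- rank(score, ties.method = "average")
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Top-fraction PRS flag
#'
#' `TRUE` when the within-group percentile is strictly above
#' `100 * (1 - top_fraction)`; the boundary percentile itself is excluded.
#'
#' @param percentile Percentiles from [assign_percentiles()].
#' @param top_fraction Fraction in (0, 1), e.g. 0.10 for the top decile.
#' @return Logical flags.
#' @export
prs_top_flag <- function(percentile, top_fraction) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be a single number in (0, 1)")
  }
  percentile > 100 * (1 - top_fraction)
}
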