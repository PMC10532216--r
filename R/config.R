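#' Run configuration for the effector-candidate pipeline
#'
#' Collects every tunable threshold used across the pipeline in one
#' validated list. Defaults follow the two-biotype aphid study design this
#' package models: differential expression is called at BH-adjusted
#' q <= 0.05 with an at-least-two-fold change (inclusive), salivary protein
#' groups are differential at p < 0.05 OR fold change > 2 OR < 0.5 (the
#' permissive literal rule; switch `prot_rule = "and"` for the conservative
#' conjunction), peptides of 7+ amino acids count as identified, and
#' theoretically observable tryptic peptides are those of 5--30 residues.
#'
#' @param q_max Maximum BH-adjusted q value for a gene to be a DEG.
#' @param min_fold Minimum fold change (>= 1) for a gene to be a DEG; the
#'   comparison is inclusive (exactly `min_fold` qualifies).
#' @param prot_p_max Maximum Welch-test p value in the differential-protein
#'   rule.
#' @param prot_fc_hi,prot_fc_lo Upper/lower fold-change bounds in the
#'   differential-protein rule; by default `prot_fc_lo = 1/prot_fc_hi`.
#' @param prot_rule `"or"` (literal published rule: any clause suffices) or
#'   `"and"` (p value and fold change must both pass).
#' @param peptide_min_len,peptide_max_len Length window (amino acids) of a
#'   theoretically observable tryptic peptide.
#' @param peptide_id_min_len Minimum peptide length to count as identified.
#' @param missed_cleavages Missed tryptic cleavages allowed in digestion
#'   (observable-peptide counting always uses zero).
#' @param tm_window Odd sliding-window width (aa) for the hydropathy scan.
#' @param tm_threshold Mean Kyte--Doolittle hydropathy above which a window
#'   is transmembrane-like.
#' @param sp_score_min Minimum weight-matrix log-odds score (bits) for a
#'   signal-peptide call.
#' @param detection_min_reps Detections required in one biotype (with zero
#'   in the other) to call a protein biotype-unique; `NULL` means half the
#'   replicates, rounded up.
#' @param min_align_score Minimum Smith--Waterman score for a homology hit.
#' @param strict_consistency Drop combined candidates whose proteome and
#'   transcriptome directions disagree instead of flagging them.
#' @param pseudo_count Pseudo-count added to normalized group means before
#'   the log2 fold change, keeping it finite for zero-count groups.
#' @param pseudo_reference Fall back to a pseudo-reference built from genes
#'   expressed in at least half the samples when no gene is expressed in
#'   every sample (median-of-ratios normalization).
#' @param seed Integer seed recorded with reports.
#'
#' @return A list of class `effector_config`.
#' @examples
#' cfg <- effector_config(q_max = 0.01)
#' cfg$min_fold
#' @export
effector_config <- function(q_max = 0.05,
                            min_fold = 2,
                            prot_p_max = 0.05,
                            prot_fc_hi = 2,
                            prot_fc_lo = 1 / prot_fc_hi,
                            prot_rule = c("or", "and"),
                            peptide_min_len = 5L,
                            peptide_max_len = 30L,
                            peptide_id_min_len = 7L,
                            missed_cleavages = 0L,
                            tm_window = 19L,
                            tm_threshold = 1.6,
                            sp_score_min = 3.5,
                            detection_min_reps = NULL,
                            min_align_score = 50,
                            strict_consistency = FALSE,
                            pseudo_count = 0.5,
                            pseudo_reference = FALSE,
                            seed = 1L) {
  prot_rule <- match.arg(prot_rule)
  stopifnot(
    q_max > 0, q_max < 1,
    min_fold >= 1,
    prot_p_max > 0, prot_p_max < 1,
    prot_fc_hi > 1, prot_fc_lo < 1, prot_fc_lo > 0,
    peptide_min_len <= peptide_id_min_len,
    peptide_id_min_len <= peptide_max_len,
    missed_cleavages >= 0, missed_cleavages <= 2,
    tm_window %% 2 == 1,
    pseudo_count >= 0
  )
  structure(
    list(
      q_max = q_max, min_fold = min_fold,
      prot_p_max = prot_p_max, prot_fc_hi = prot_fc_hi,
      prot_fc_lo = prot_fc_lo, prot_rule = prot_rule,
      peptide_min_len = as.integer(peptide_min_len),
      peptide_max_len = as.integer(peptide_max_len),
      peptide_id_min_len = as.integer(peptide_id_min_len),
      missed_cleavages = as.integer(missed_cleavages),
      tm_window = as.integer(tm_window), tm_threshold = tm_threshold,
      sp_score_min = sp_score_min,
      detection_min_reps = detection_min_reps,
      min_align_score = min_align_score,
      strict_consistency = strict_consistency,
      pseudo_count = pseudo_count,
      pseudo_reference = pseudo_reference,
      seed = as.integer(seed)
    ),
    class = "effector_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file whose keys are `effector_config()`
#'   arguments.
#' @return An `effector_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(effector_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(effector_config, vals)
}

#' @export
print.effector_config <- function(x, ...) {
  cat("<effector_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Resolve detection_min_reps against an actual replicate count.
min_detect_reps <- function(config, n_reps) {
  config$detection_min_reps %||% as.integer(ceiling(n_reps / 2))
}
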