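# The combined proteome-by-transcriptome strategy: salivary protein groups
# whose genes are head-transcriptome DEGs are the effector candidates,
# with qPCR (2^-ddCt) validation and a cross-species presence tally.

#' Combined proteome-by-transcriptome effector candidates
#'
#' Every salivary protein group contributes one candidate per mapped gene
#' that is a head-transcriptome DEG. Direction and fold change are the
#' gene's (RNA, A/B); the proteome class is attached (`detected_only` when
#' the group was detected but not differential), and direction consistency
#' between the two layers is computed where a proteome fold change exists.
#' Inconsistent candidates are retained and flagged unless
#' `config$strict_consistency` is set. The signal-peptide flag is
#' informational, not a filter, at this stage.
#'
#' @param groups Protein-group tibble from [infer_protein_groups()].
#' @param calls Differential-protein calls from
#'   [call_differential_proteins()] (may be `NULL`: all groups become
#'   `detected_only`).
#' @param head_degs `deg_result` or DEG tibble from head-tissue samples.
#' @param map Gene-to-protein map tibble.
#' @param annotations Optional secretion annotation tibble for the
#'   signal-peptide flag.
#' @param config `effector_config`.
#' @return EffectorCandidate tibble sorted by gene id: `protein_group_id`,
#'   `gene_id`, `rna_log2fc`, `rna_q`, `fold_change` (RNA, ratio A/B),
#'   `direction`, `prot_class`, `prot_fold_change`, `consistent`,
#'   `multi_gene`, `has_signal_peptide`.
#' @export
combined_candidates <- function(groups, calls, head_degs, map,
                                annotations = NULL,
                                config = effector_config()) {
  deg_tbl <- if (inherits(head_degs, "deg_result")) head_degs$table
             else head_degs
  deg_tbl <- deg_tbl[deg_tbl$is_deg, , drop = FALSE]
  call_by_group <- if (is.null(calls)) NULL else
    calls[match(groups$group_id, calls$group_id), ]
  sp_by_prot <- if (is.null(annotations)) NULL else
    setNames(annotations$has_signal_peptide, annotations$protein_id)

  rows <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    members <- groups$member_protein_ids[[i]]
    gene_ids <- sort(unique(
      map$gene_id[map$protein_id %in% members]
    ))
    deg_hit <- deg_tbl[deg_tbl$gene_id %in% gene_ids, , drop = FALSE]
    if (nrow(deg_hit) == 0) return(NULL)
    prot_class <- "detected_only"
    prot_fc <- NA_real_
    if (!is.null(call_by_group)) {
      cl <- call_by_group$class[i]
      if (!is.na(cl) && cl != "none") {
        prot_class <- cl
        prot_fc <- call_by_group$fold_change[i]
      }
    }
    has_sp <- if (is.null(sp_by_prot)) NA else
      any(sp_by_prot[members], na.rm = TRUE)
    consistent <- consistency_verdict(prot_class, prot_fc, deg_hit$log2fc)
    tibble(
      protein_group_id = groups$group_id[i],
      gene_id = deg_hit$gene_id,
      rna_log2fc = deg_hit$log2fc,
      rna_q = deg_hit$q_value,
      fold_change = 2^deg_hit$log2fc,
      direction = deg_hit$direction,
      prot_class = prot_class,
      prot_fold_change = prot_fc,
      consistent = consistent,
      multi_gene = nrow(deg_hit) > 1,
      has_signal_peptide = has_sp
    )
  })
  if (nrow(rows) == 0) {
    return(tibble(
      protein_group_id = character(), gene_id = character(),
      rna_log2fc = numeric(), rna_q = numeric(), fold_change = numeric(),
      direction = character(), prot_class = character(),
      prot_fold_change = numeric(), consistent = logical(),
      multi_gene = logical(), has_signal_peptide = logical()
    ))
  }
  if (config$strict_consistency) {
    rows <- rows[rows$consistent, , drop = FALSE]
  }
  dplyr::arrange(rows, .data$gene_id, .data$protein_group_id)
}

# consistent <=> no proteome direction to contradict, or the proteome and
# RNA fold changes point the same way
consistency_verdict <- function(prot_class, prot_fc, rna_log2fc) {
  vapply(seq_along(rna_log2fc), function(k) {
    if (prot_class %in% c("detected_only", "none")) return(TRUE)
    if (prot_class == "unique_A") return(rna_log2fc[k] > 0)
    if (prot_class == "unique_B") return(rna_log2fc[k] < 0)
    if (is.na(prot_fc)) return(TRUE)
    sign(log2(prot_fc)) == sign(rna_log2fc[k])
  }, logical(1))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean dCt(A) - mean dCt(B)` and relative expression (A vs B) is
#' `2^-ddCt`. The p value is a two-sided independent t-test on the dCt
#' values. Samples missing either Ct are dropped with a warning; fewer than
#' two remaining replicates per biotype is an error. Adding a constant to
#' every Ct leaves the result unchanged.
#'
#' @param ct_table Tibble with `sample_id`, `biotype` (A/B), `gene_id`,
#'   `ct_target`, `ct_reference` (see [read_ct_table()]).
#' @return Tibble per gene: `gene_id`, `delta_delta_ct`,
#'   `relative_expression`, `p_value`, `n_A`, `n_B`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = paste0("s", 1:6), biotype = rep(c("A", "B"), each = 3),
#'   gene_id = "g1", ct_target = c(20, 20.1, 19.9, 22, 22.1, 21.9),
#'   ct_reference = 18
#' )
#' ddct(ct)
#' @export
ddct <- function(ct_table) {
  ct <- as_tibble(ct_table)
  drop <- is.na(ct$ct_target) | is.na(ct$ct_reference)
  if (any(drop)) {
    warn(paste0(sum(drop), " sample(s) missing a Ct value were dropped"))
    ct <- ct[!drop, , drop = FALSE]
  }
  ct$delta_ct <- ct$ct_target - ct$ct_reference
  out <- lapply(split(ct, ct$gene_id), function(g) {
    da <- g$delta_ct[g$biotype == "A"]
    db <- g$delta_ct[g$biotype == "B"]
    if (length(da) < 2 || length(db) < 2) {
      abort(paste0("gene ", g$gene_id[1],
                   ": fewer than 2 replicates per biotype"))
    }
    ddct_val <- mean(da) - mean(db)
    p <- if (var(da) == 0 && var(db) == 0) {
      if (ddct_val == 0) 1 else 0
    } else {
      t.test(da, db)$p.value
    }
    tibble(
      gene_id = g$gene_id[1],
      delta_delta_ct = ddct_val,
      relative_expression = 2^(-ddct_val),
      p_value = p,
      n_A = length(da), n_B = length(db)
    )
  })
  dplyr::bind_rows(out)
}

#' Tally a salivary-protein presence/absence matrix across species
#'
#' @param presence Tibble from [read_presence_matrix()] (`protein` column
#'   plus one logical column per species).
#' @return List with `protein_counts` (per-protein species count),
#'   `species_counts` (per-species protein count) and `n_proteins_shared`
#'   (proteins present in at least one species).
#' @export
cross_species_tally <- function(presence) {
  species <- setdiff(names(presence), "protein")
  m <- as.matrix(presence[, species, drop = FALSE])
  if (!is.logical(m)) abort("presence matrix must be logical")
  row_counts <- rowSums(m)
  list(
    protein_counts = tibble(protein = presence$protein,
                            n_species = as.integer(row_counts)),
    species_counts = tibble(species = species,
                            n_proteins = as.integer(colSums(m))),
    n_proteins_shared = sum(row_counts >= 1)
  )
}

#' Plot the combined candidate set
#'
#' Candidate genes by RNA fold change, coloured by direction, shaped by
#' signal-peptide status.
#'
#' @param candidates Tibble from [combined_candidates()].
#' @return A ggplot object.
#' @export
plot_candidates <- function(candidates) {
  ggplot2::ggplot(candidates, ggplot2::aes(
    x = .data$rna_log2fc,
    y = stats::reorder(.data$gene_id, .data$rna_log2fc),
    colour = .data$direction, shape = .data$has_signal_peptide
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up_in_A = "#c0392b", down_in_A = "#2980b9")
    ) +
    ggplot2::labs(x = "RNA log2 fold change (A/B)", y = NULL,
                  colour = NULL, shape = "signal peptide") +
    ggplot2::theme_minimal()
}
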