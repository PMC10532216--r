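# Salivary proteome quantification: in-silico tryptic digestion, iBAQ-style
# LFQ (intensity divided by the count of theoretically observable tryptic
# peptides of 5-30 aa), Occam-parsimony protein grouping with razor-peptide
# assignment, and the biotype-unique / biotype-differential classification.

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P. With
#' zero missed cleavages the peptides are a partition of the input: their
#' concatenation reproduces the sequence. With `missed > 0` the result
#' additionally contains every join of up to `missed + 1` adjacent
#' fragments.
#'
#' @param sequence One protein sequence.
#' @param missed Number of missed cleavages (0--2).
#' @return Character vector of peptides, N- to C-terminal.
#' @examples
#' tryptic_digest("MKTAYIAKQR")
#' @export
tryptic_digest <- function(sequence, missed = 0L) {
  if (nchar(sequence) == 0) abort("empty sequence")
  base <- strsplit(sequence, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
  if (missed == 0) return(base)
  out <- base
  n <- length(base)
  for (k in seq_len(missed)) {
    if (n <= k) break
    joined <- vapply(seq_len(n - k), function(i) {
      paste(base[i:(i + k)], collapse = "")
    }, character(1))
    out <- c(out, joined)
  }
  out
}

#' Count theoretically observable tryptic peptides
#'
#' Fully tryptic peptides (zero missed cleavages) whose length falls in the
#' observable window (default 5--30 aa). Used as the iBAQ divisor.
#'
#' @param sequence One protein sequence.
#' @param config `effector_config` (`peptide_min_len`, `peptide_max_len`).
#' @return Non-negative integer count.
#' @export
count_observable_peptides <- function(sequence, config = effector_config()) {
  lens <- nchar(tryptic_digest(sequence, missed = 0L))
  sum(lens >= config$peptide_min_len & lens <= config$peptide_max_len)
}

#' iBAQ-style LFQ value
#'
#' Divides a protein's summed intensity by its count of theoretically
#' observable tryptic peptides. Missing intensities stay missing; a positive
#' intensity with zero observable peptides is unquantifiable (`NA` with the
#' `unquantifiable` attribute set by callers).
#'
#' @param total_intensity Numeric vector of per-sample intensities.
#' @param observable_count Observable-peptide count for the protein.
#' @return Per-sample LFQ values (all `NA` when `observable_count` is 0).
#' @export
compute_lfq <- function(total_intensity, observable_count) {
  if (observable_count < 1) {
    return(rep(NA_real_, length(total_intensity)))
  }
  total_intensity / observable_count
}

split_parents <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Parsimony protein-group inference
#'
#' MaxQuant-style Occam grouping: proteins with identical peptide sets
#' merge; a protein whose peptide set is a strict subset of another's joins
#' that protein's group; remaining shared (razor) peptides are assigned to
#' the group with the most peptides (ties broken by the lexicographically
#' smallest leading accession), so every identified peptide quantifies
#' exactly one group. Peptides shorter than `peptide_id_min_len` do not
#' count as identified. Group ids (the leading accession) are stable under
#' permutation of the input rows.
#'
#' @param evidence Evidence tibble (`peptide`, `protein_ids`
#'   semicolon-separated, plus intensity columns).
#' @param config `effector_config`.
#' @return Tibble with `group_id`, `member_protein_ids` (list, leading
#'   first), `n_members`, `supporting_peptides` (list of razor-assigned
#'   peptides), `n_peptides`, sorted by `group_id`.
#' @export
infer_protein_groups <- function(evidence, config = effector_config()) {
  ev <- evidence[nchar(evidence$peptide) >= config$peptide_id_min_len, ,
                 drop = FALSE]
  ev <- ev[!duplicated(ev$peptide), , drop = FALSE]
  if (nrow(ev) == 0) {
    return(tibble(group_id = character(), member_protein_ids = list(),
                  n_members = integer(), supporting_peptides = list(),
                  n_peptides = integer()))
  }
  parents <- split_parents(ev$protein_ids)
  if (any(lengths(parents) == 0)) abort("peptide with empty parent list")
  long <- tibble(
    peptide = rep(ev$peptide, lengths(parents)),
    protein_id = unlist(parents)
  )
  pepsets <- split(long$peptide, long$protein_id)
  pepsets <- lapply(pepsets, function(p) sort(unique(p)))
  prot_ids <- names(pepsets)

  # 1) identical peptide sets merge into one entity
  sig <- vapply(pepsets, paste, character(1), collapse = "\x1f")
  entities <- split(prot_ids, sig)
  ent <- lapply(entities, function(members) {
    members <- sort(members)
    list(members = members, peptides = pepsets[[members[1]]])
  })
  names(ent) <- vapply(ent, function(e) e$members[1], character(1))

  # 2) subset entities are absorbed by the superset entity with the most
  #    peptides (tie: lexicographically smallest leading accession)
  npep <- vapply(ent, function(e) length(e$peptides), integer(1))
  ord <- names(ent)[order(-npep, names(ent))]
  absorbed_into <- setNames(rep(NA_character_, length(ent)), names(ent))
  for (nm in names(ent)) {
    candidates <- character(0)
    for (other in ord) {
      if (other == nm) next
      if (length(ent[[other]]$peptides) <= length(ent[[nm]]$peptides)) break
      if (all(ent[[nm]]$peptides %in% ent[[other]]$peptides)) {
        candidates <- other   # ord is already preference-sorted
        break
      }
    }
    if (length(candidates) == 1) absorbed_into[nm] <- candidates
  }
  root <- function(nm) {
    while (!is.na(absorbed_into[nm])) nm <- absorbed_into[nm]
    nm
  }
  groups <- list()
  for (nm in names(ent)) {
    r <- root(nm)
    groups[[r]] <- c(groups[[r]], ent[[nm]]$members)
  }
  group_members <- lapply(names(groups), function(r) {
    c(ent[[r]]$members, sort(setdiff(groups[[r]], ent[[r]]$members)))
  })
  names(group_members) <- names(groups)

  # peptides mapped to each group via any member
  prot_to_group <- setNames(
    rep(names(group_members), lengths(group_members)),
    unlist(group_members)
  )
  long$group_id <- unname(prot_to_group[long$protein_id])
  pep_groups <- lapply(split(long$group_id, long$peptide), unique)
  group_size <- vapply(
    split(long$peptide, long$group_id),
    function(p) length(unique(p)), integer(1)
  )

  # 3) razor assignment: shared peptides go to the group with the most
  #    peptides, ties to the smallest leading accession
  assign_group <- vapply(pep_groups, function(gs) {
    gs[order(-group_size[gs], gs)][1]
  }, character(1))
  assigned <- split(names(assign_group), assign_group)

  out <- tibble(
    group_id = names(group_members),
    member_protein_ids = unname(group_members),
    n_members = unname(lengths(group_members)),
    supporting_peptides = lapply(names(group_members), function(g) {
      sort(assigned[[g]] %||% character(0))
    }),
    n_peptides = unname(vapply(names(group_members), function(g) {
      length(assigned[[g]] %||% character(0))
    }, integer(1)))
  )
  dplyr::arrange(out, .data$group_id)
}

#' Quantify protein groups
#'
#' Sums razor-assigned peptide intensities per sample and divides by the
#' leading protein's observable-peptide count (iBAQ-style LFQ). A sample
#' with no detected assigned peptide stays missing. Groups whose leading
#' protein has zero observable peptides are flagged `unquantifiable`.
#'
#' @param groups Group tibble from [infer_protein_groups()].
#' @param evidence The evidence tibble the groups were inferred from.
#' @param proteins Protein tibble (`id`, `sequence`) for observable counts.
#' @param design Saliva sample design.
#' @param config `effector_config`.
#' @return `groups` with added per-sample LFQ columns (named by sample),
#'   `observable_peptides` and `unquantifiable`.
#' @export
quantify_protein_groups <- function(groups, evidence, proteins, design,
                                    config = effector_config()) {
  design <- validate_design(design)
  samples <- design$sample_id
  ev <- evidence[!duplicated(evidence$peptide), , drop = FALSE]
  pep_idx <- setNames(seq_len(nrow(ev)), ev$peptide)
  seqs <- setNames(proteins$sequence, proteins$id)
  obs <- vapply(groups$group_id, function(g) {
    if (!g %in% names(seqs)) return(NA_integer_)
    as.integer(count_observable_peptides(seqs[[g]], config))
  }, integer(1))
  lfq_cols <- lapply(samples, function(s) {
    ints <- ev[[s]]
    vapply(seq_len(nrow(groups)), function(i) {
      idx <- pep_idx[groups$supporting_peptides[[i]]]
      v <- ints[idx]
      if (all(is.na(v))) return(NA_real_)
      total <- sum(v, na.rm = TRUE)
      if (is.na(obs[i]) || obs[i] < 1) return(NA_real_)
      compute_lfq(total, obs[i])
    }, numeric(1))
  })
  names(lfq_cols) <- samples
  out <- dplyr::bind_cols(groups, as_tibble(lfq_cols))
  out$observable_peptides <- obs
  detected_any <- rowSums(!is.na(as.matrix(out[, samples, drop = FALSE]))) > 0
  raw_detect <- vapply(seq_len(nrow(groups)), function(i) {
    any(!is.na(unlist(ev[pep_idx[groups$supporting_peptides[[i]]], samples])))
  }, logical(1))
  out$unquantifiable <- (is.na(obs) | obs < 1) & raw_detect
  out
}

#' Classify protein groups as biotype-unique or biotype-differential
#'
#' Detection is a non-missing LFQ. A group is `unique_A` when detected in at
#' least `detection_min_reps` samples of biotype A and in none of B (mirror
#' for `unique_B`). Otherwise, for groups detected in both biotypes, the
#' fold change is the ratio of mean LFQs (A/B over detected samples) and the
#' p value a two-sided Welch t-test on log LFQ; the group is differential
#' when `p < prot_p_max` OR `FC > prot_fc_hi` OR `FC < prot_fc_lo` (the
#' literal published rule; `prot_rule = "and"` requires p value and fold
#' change jointly). Unquantifiable groups are `none` with their flag kept.
#'
#' @param quant Quantified group tibble from [quantify_protein_groups()].
#' @param design Saliva sample design (>= 2 replicates per biotype).
#' @param config `effector_config`.
#' @return Tibble: `group_id`, `class` (unique_A/unique_B/up_in_A/down_in_A/
#'   none), `fold_change` (A/B), `p_value`, `n_detected_A`, `n_detected_B`,
#'   `unquantifiable`.
#' @export
call_differential_proteins <- function(quant, design,
                                       config = effector_config()) {
  design <- validate_design(design)
  check_two_replicates(design)
  a_cols <- design$sample_id[design$biotype == "A"]
  b_cols <- design$sample_id[design$biotype == "B"]
  min_a <- min_detect_reps(config, length(a_cols))
  min_b <- min_detect_reps(config, length(b_cols))
  la <- as.matrix(quant[, a_cols, drop = FALSE])
  lb <- as.matrix(quant[, b_cols, drop = FALSE])
  rows <- lapply(seq_len(nrow(quant)), function(i) {
    va <- la[i, ][!is.na(la[i, ])]
    vb <- lb[i, ][!is.na(lb[i, ])]
    nA <- length(va)
    nB <- length(vb)
    fc <- NA_real_
    p <- NA_real_
    class <- "none"
    if (!isTRUE(quant$unquantifiable[i])) {
      if (nA >= min_a && nB == 0) {
        class <- "unique_A"
      } else if (nB >= min_b && nA == 0) {
        class <- "unique_B"
      } else if (nA > 0 && nB > 0) {
        fc <- mean(va) / mean(vb)
        if (nA >= 2 && nB >= 2 && (var(log(va)) > 0 || var(log(vb)) > 0)) {
          p <- tryCatch(t.test(log(va), log(vb))$p.value,
                        error = function(e) NA_real_)
        }
        p_hit <- !is.na(p) && p < config$prot_p_max
        fc_hit <- fc > config$prot_fc_hi || fc < config$prot_fc_lo
        hit <- if (config$prot_rule == "or") p_hit || fc_hit
               else p_hit && fc_hit
        if (hit && fc != 1) {
          class <- if (fc > 1) "up_in_A" else "down_in_A"
        }
      }
    }
    tibble(group_id = quant$group_id[i], class = class, fold_change = fc,
           p_value = p, n_detected_A = nA, n_detected_B = nB,
           unquantifiable = isTRUE(quant$unquantifiable[i]))
  })
  dplyr::bind_rows(rows)
}

#' Write a protein-group table
#' @param quant Quantified group tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(quant, path) {
  out <- quant
  out$member_protein_ids <- vapply(out$member_protein_ids, paste,
                                   character(1), collapse = ";")
  out$supporting_peptides <- vapply(out$supporting_peptides, paste,
                                    character(1), collapse = ";")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
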