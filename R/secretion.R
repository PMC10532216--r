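# Classical stand-in predictors for classical secretion: a von Heijne-style
# position weight matrix for signal peptides and a Kyte-Doolittle sliding
# window for transmembrane segments. External predictions can override both
# (read_secretion_table()).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Kyte--Doolittle hydropathy values
#'
#' Named vector over the 20 amino acids; unknown residues (X) contribute 0.
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

kd_values <- function(residues) {
  v <- unname(KD_HYDROPATHY[residues])
  v[is.na(v)] <- 0
  v
}

# Per-position residue frequency profile of a classical signal peptide
# around the cleavage site: a long hydrophobic h-region (-13..-6), a short
# transition (-5..-4), the small-residue -3/-1 rule, and a mildly polar
# mature start. Log-odds are against a uniform 1/20 background.
sp_position_profile <- function(position) {
  f <- setNames(rep(0, 20), AA20)
  fill_rest <- function(f, total) {
    rest <- names(f)[f == 0]
    f[rest] <- (1 - total) / length(rest)
    f
  }
  if (position <= -6) {              # hydrophobic core
    f[c("L", "A", "V", "I", "F", "M", "W", "C", "S", "T", "G", "P")] <-
      c(.38, .11, .11, .08, .07, .04, .02, .03, .04, .04, .03, .01)
    f <- fill_rest(f, .96)
  } else if (position <= -4) {       # c-region transition
    f[c("A", "S", "G", "T", "P", "V", "L", "Q")] <-
      c(.15, .12, .10, .10, .08, .08, .08, .05)
    f <- fill_rest(f, .76)
  } else if (position == -3) {       # small residue (-3 rule)
    f[c("A", "V", "S", "G", "T", "C", "L", "I")] <-
      c(.40, .14, .10, .08, .08, .06, .04, .04)
    f <- fill_rest(f, .94)
  } else if (position == -2) {
    f[c("Q", "H", "S", "A", "E", "Y")] <- c(.08, .07, .07, .07, .06, .06)
    f <- fill_rest(f, .41)
  } else if (position == -1) {       # small residue (-1 rule)
    f[c("A", "G", "S", "C", "T", "Q")] <- c(.50, .16, .13, .06, .06, .03)
    f <- fill_rest(f, .94)
  } else {                           # +1, +2: mature start, mildly polar
    f[c("A", "S", "D", "E", "Q")] <- c(.09, .08, .08, .08, .08)
    f <- fill_rest(f, .41)
  }
  f
}

#' Signal-peptide position weight matrix
#'
#' Log-odds scores in bits (base-2, uniform background) for positions
#' -13..+2 relative to the cleavage site (cleavage falls between -1 and +1).
#'
#' @return A 20 x 16 matrix, rows amino acids, columns positions.
#' @export
sp_weight_matrix <- function() {
  positions <- c(-13:-1, 1:2)
  pwm <- vapply(positions, function(p) log2(sp_position_profile(p) / 0.05),
                numeric(20))
  dimnames(pwm) <- list(AA20, as.character(positions))
  pwm
}

#' Score a protein N-terminus for a signal peptide
#'
#' Scans candidate cleavage sites at positions 10--40 (cleavage after the
#' scanned residue) with the weight matrix and keeps the best-scoring site.
#' A positive call requires both the weight-matrix score to reach
#' `sp_score_min` and a hydrophobic core: a run of >= 6 residues with mean
#' Kyte--Doolittle hydropathy > 1.5 inside positions 2..(site - 6).
#'
#' @param sequence One protein sequence (character scalar).
#' @param model Weight matrix from [sp_weight_matrix()].
#' @param config `effector_config` (uses `sp_score_min`).
#' @return One-row tibble: `has_signal_peptide`, `sp_score` (bits),
#'   `cleavage_site` (NA when negative), `too_short`. Sequences shorter than
#'   15 aa are a negative call flagged `too_short`, not an error.
#' @export
score_signal_peptide <- function(sequence, model = sp_weight_matrix(),
                                 config = effector_config()) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 15) {
    return(tibble(has_signal_peptide = FALSE, sp_score = NA_real_,
                  cleavage_site = NA_integer_, too_short = TRUE))
  }
  positions <- as.integer(colnames(model))
  sites <- 10:min(40, n - 2)
  scores <- vapply(sites, function(site) {
    # position -k is residue site-k+1; +k is residue site+k
    idx <- ifelse(positions > 0, site + positions, site + positions + 1L)
    ok <- idx >= 1 & idx <= n
    aa <- res[idx[ok]]
    known <- aa %in% rownames(model)
    sum(model[cbind(aa[known], as.character(positions[ok][known]))])
  }, numeric(1))
  best <- which.max(scores)
  site <- sites[best]
  score <- scores[best]
  has_core <- hydrophobic_stretch(res, from = 2, to = site - 6,
                                  min_run = 6, min_mean = 1.5)
  has_sp <- score >= config$sp_score_min && has_core
  tibble(
    has_signal_peptide = has_sp,
    sp_score = score,
    cleavage_site = if (has_sp) as.integer(site) else NA_integer_,
    too_short = FALSE
  )
}

# any run of min_run consecutive residues in [from, to] with mean KD above
# min_mean
hydrophobic_stretch <- function(res, from, to, min_run, min_mean) {
  to <- min(to, length(res))
  if (to - from + 1 < min_run) return(FALSE)
  kd <- kd_values(res[from:to])
  cs <- cumsum(c(0, kd))
  w <- min_run
  means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  any(means > min_mean)
}

#' Scan a protein for transmembrane-like segments
#'
#' Mean Kyte--Doolittle hydropathy in a sliding window; maximal runs of
#' window centres above the threshold are merged and reported as full
#' window extents. Unknown residues (X) contribute hydropathy 0, with one
#' warning per protein. Sequences shorter than the window yield no segments.
#'
#' @param sequence One protein sequence.
#' @param window Odd window width (aa), default 19.
#' @param threshold Mean hydropathy threshold, default 1.6.
#' @return Integer matrix with columns `start`, `end` (1-based inclusive),
#'   sorted, non-overlapping.
#' @export
scan_transmembrane <- function(sequence, window = 19L, threshold = 1.6) {
  if (window %% 2 != 1) abort("window must be odd")
  res <- strsplit(sequence, "")[[1]]
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  n <- length(res)
  if (n < window) return(empty)
  if (any(!res %in% names(KD_HYDROPATHY))) {
    warn(paste0("unknown residue(s) treated as hydropathy 0"))
  }
  kd <- kd_values(res)
  cs <- cumsum(c(0, kd))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  half <- (window - 1L) %/% 2L
  centers <- which(means > threshold) + half   # center positions
  if (length(centers) == 0) return(empty)
  breaks <- which(diff(centers) > 1)
  starts <- centers[c(1, breaks + 1)] - half
  ends <- centers[c(breaks, length(centers))] + half
  cbind(start = as.integer(starts), end = as.integer(ends))
}

# candidate iff signal peptide present and no TM segment outside it
# (segments entirely inside the signal peptide, end <= cleavage site,
# are excused: signal peptides are themselves hydrophobic)
secreted_verdict <- function(has_sp, cleavage_site, tm_segments) {
  if (!isTRUE(has_sp)) return(FALSE)
  if (is.null(tm_segments) || nrow(tm_segments) == 0) return(TRUE)
  all(tm_segments[, "end"] <= cleavage_site)
}

#' Annotate proteins with secretion features
#'
#' Runs the signal-peptide and transmembrane stand-ins over a protein set
#' and derives the classical-secretion verdict used by the effector filter.
#'
#' @param proteins Tibble with `id`, `sequence` (from [read_fasta()]).
#' @param config `effector_config`.
#' @return Tibble with `protein_id`, `has_signal_peptide`, `sp_score`,
#'   `cleavage_site`, `tm_segments` (list of start/end matrices),
#'   `n_tm_segments`, `is_secreted_candidate`.
#' @export
annotate_secretion <- function(proteins, config = effector_config()) {
  model <- sp_weight_matrix()
  rows <- purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    sp <- score_signal_peptide(seq, model, config)
    tm <- scan_transmembrane(seq, config$tm_window, config$tm_threshold)
    tibble(
      protein_id = id,
      has_signal_peptide = sp$has_signal_peptide,
      sp_score = sp$sp_score,
      cleavage_site = sp$cleavage_site,
      tm_segments = list(tm),
      n_tm_segments = nrow(tm),
      is_secreted_candidate = secreted_verdict(
        sp$has_signal_peptide, sp$cleavage_site, tm
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a secretion annotation table
#' @param annotations Tibble from [annotate_secretion()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_secretion_table <- function(annotations, path) {
  out <- annotations
  out$tm_segments <- vapply(out$tm_segments, format_segments, character(1))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter DEGs down to secretion-competent effector candidates
#'
#' The transcriptome-route rule: a gene is an effector candidate iff it is a
#' DEG and at least one of its protein isoforms carries a signal peptide
#' with no transmembrane segment outside it. DEG genes with no protein in
#' the map are excluded with a message.
#'
#' @param degs `deg_result` or DEG tibble.
#' @param annotations Secretion annotation tibble.
#' @param map Gene-to-protein map tibble.
#' @return Candidate tibble: `gene_id`, `log2fc`, `q_value`, `direction`,
#'   `secreted_proteins` (semicolon-joined passing isoforms).
#' @export
filter_effector_candidates <- function(degs, annotations, map) {
  tbl <- if (inherits(degs, "deg_result")) degs$table else degs
  deg_tbl <- tbl[tbl$is_deg, , drop = FALSE]
  unmapped <- setdiff(deg_tbl$gene_id, map$gene_id)
  if (length(unmapped) > 0) {
    inform(paste0(length(unmapped),
                  " DEG gene(s) with no protein in the map were excluded"))
  }
  ann <- annotations[annotations$is_secreted_candidate, , drop = FALSE]
  hits <- map[map$protein_id %in% ann$protein_id, c("gene_id", "protein_id")]
  secreted <- hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      secreted_proteins = paste(sort(.data$protein_id), collapse = ";")
    )
  out <- dplyr::inner_join(
    deg_tbl[, c("gene_id", "log2fc", "q_value", "direction")],
    secreted, by = "gene_id"
  )
  dplyr::arrange(out, .data$gene_id)
}
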