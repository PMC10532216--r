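# Translated homology screen of published effectors: six-frame translation
# of a nucleotide gene set plus exhaustive Smith-Waterman alignment (no
# seeding heuristics; identity is reported rather than E-values).

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#' @return The BLOSUM62 matrix shipped with Biostrings.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Six-frame translation
#'
#' Frames +1..+3 read the sequence, -1..-3 its reverse complement, under the
#' standard codon table; stop codons become `*`, codons containing N become
#' `X`, trailing partial codons are dropped.
#'
#' @param sequence One nucleotide sequence (A/C/G/T/N).
#' @return Tibble with columns `frame` (+1,+2,+3,-1,-2,-3) and `protein`.
#' @examples
#' six_frame_translate("ATGAAA")
#' @export
six_frame_translate <- function(sequence) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  if (nchar(sequence) < 3) {
    warn("sequence shorter than one codon: empty translations")
    return(tibble(frame = frames, protein = rep("", 6)))
  }
  code <- Biostrings::GENETIC_CODE
  fwd <- strsplit(toupper(sequence), "")[[1]]
  rev <- rev(chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", fwd))
  one <- function(chars, off) {
    n <- length(chars) - off
    n <- (n %/% 3L) * 3L
    if (n < 3) return("")
    i <- off + seq.int(1L, n, 3L)
    codons <- paste0(chars[i], chars[i + 1L], chars[i + 2L])
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"   # N-containing / ambiguous codons
    paste(aa, collapse = "")
  }
  tibble(
    frame = frames,
    protein = c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
                one(rev, 0L), one(rev, 1L), one(rev, 2L))
  )
}

#' Optimal local protein alignment (Smith--Waterman, affine gaps)
#'
#' A gap of length L costs `gap_open + L * gap_extend`. Percent identity is
#' identical columns over aligned columns (gap columns included) times 100.
#'
#' @param query,subject Protein sequences (character scalars).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return One-row tibble: `score`, `percent_identity`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `aligned_cols`.
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")
#' @export
local_align <- function(query, subject, matrix = blosum62(),
                        gap_open = 11, gap_extend = 1) {
  if (nchar(query) == 0 || nchar(subject) == 0) abort("empty sequence")
  qi <- seq_to_index(query, matrix)
  sj <- seq_to_index(subject, matrix)
  r <- sw_align_cpp(qi, sj, matrix, gap_open, gap_extend)
  pid <- if (r$aligned_cols > 0) 100 * r$identical_cols / r$aligned_cols
         else NA_real_
  tibble(
    score = r$score, percent_identity = pid,
    q_start = r$q_start, q_end = r$q_end,
    s_start = r$s_start, s_end = r$s_end,
    aligned_cols = r$aligned_cols
  )
}

seq_to_index <- function(sequence, matrix) {
  idx <- match(strsplit(sequence, "")[[1]], rownames(matrix))
  if (anyNA(idx)) {
    abort("sequence contains residue(s) absent from the substitution matrix")
  }
  idx
}

#' Screen published effectors against a gene set
#'
#' For every query protein, aligns against all six translation frames of
#' every gene (stop-codon-separated stretches are aligned as-is; `*` scores
#' as itself under BLOSUM62), keeps hits at or above `min_align_score`, and
#' joins the best hit per query (or all gene hits with `all_hits = TRUE`) to
#' its gene's differential-expression status.
#'
#' @param queries Protein tibble (`id`, `sequence`) of published effectors.
#' @param genes Nucleotide tibble (`id`, `sequence`).
#' @param deg_table DEG tibble or `deg_result` covering the gene set; genes
#'   absent from it get status `n.s.` with a warning.
#' @param map Optional gene-to-protein map to report a subject protein id.
#' @param config `effector_config` (`min_align_score`).
#' @param all_hits Keep every gene hit above threshold per query instead of
#'   only the best.
#' @return HomologHit tibble sorted by query: `query_id`, `subject_gene_id`,
#'   `subject_protein_id`, `frame`, `score`, `percent_identity`,
#'   `deg_status` (`n.s.`, `up_in_A`, `down_in_A`).
#' @export
screen_published_effectors <- function(queries, genes, deg_table = NULL,
                                       map = NULL,
                                       config = effector_config(),
                                       all_hits = FALSE) {
  if (nrow(queries) == 0) {
    return(tibble(query_id = character(), subject_gene_id = character(),
                  subject_protein_id = character(), frame = integer(),
                  score = numeric(), percent_identity = numeric(),
                  deg_status = character()))
  }
  mat <- blosum62()
  translations <- lapply(genes$sequence, six_frame_translate)
  frame_idx <- lapply(translations, function(tr) {
    lapply(tr$protein, function(p) {
      if (nchar(p) == 0) NULL else seq_to_index(p, mat)
    })
  })
  query_idx <- lapply(queries$sequence, seq_to_index, matrix = mat)
  hits <- purrr::map_dfr(seq_len(nrow(queries)), function(k) {
    qidx <- query_idx[[k]]
    n_genes <- nrow(genes)
    score <- numeric(n_genes)
    pid <- numeric(n_genes)
    frame <- integer(n_genes)
    for (gi in seq_len(n_genes)) {
      best <- NULL
      for (f in seq_len(6)) {
        sidx <- frame_idx[[gi]][[f]]
        if (is.null(sidx)) next
        a <- sw_align_cpp(qidx, sidx, mat, 11, 1)
        if (is.null(best) || a$score > best$score) {
          best <- a
          frame[gi] <- translations[[gi]]$frame[f]
        }
      }
      if (is.null(best)) next
      score[gi] <- best$score
      pid[gi] <- if (best$aligned_cols > 0) {
        100 * best$identical_cols / best$aligned_cols
      } else NA_real_
    }
    keep <- which(score >= config$min_align_score)
    if (length(keep) == 0) return(NULL)
    if (!all_hits) keep <- keep[which.max(score[keep])]
    tibble(
      query_id = queries$id[k], subject_gene_id = genes$id[keep],
      frame = frame[keep], score = score[keep],
      percent_identity = pid[keep]
    )
  })
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), subject_gene_id = character(),
                  subject_protein_id = character(), frame = integer(),
                  score = numeric(), percent_identity = numeric(),
                  deg_status = character()))
  }
  hits$subject_protein_id <- NA_character_
  if (!is.null(map)) {
    first_prot <- map |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(protein_id = sort(.data$protein_id)[1])
    hits$subject_protein_id <-
      first_prot$protein_id[match(hits$subject_gene_id, first_prot$gene_id)]
  }
  hits$deg_status <- "n.s."
  if (!is.null(deg_table)) {
    tbl <- if (inherits(deg_table, "deg_result")) deg_table$table
           else deg_table
    miss <- setdiff(hits$subject_gene_id, tbl$gene_id)
    if (length(miss) > 0) {
      warn(paste0("gene(s) missing from the DEG table reported n.s.: ",
                  paste(head(miss, 5), collapse = ", ")))
    }
    dirn <- tbl$direction[match(hits$subject_gene_id, tbl$gene_id)]
    hits$deg_status <- ifelse(is.na(dirn) | dirn == "none", "n.s.", dirn)
  }
  cols <- c("query_id", "subject_gene_id", "subject_protein_id", "frame",
            "score", "percent_identity", "deg_status")
  dplyr::arrange(hits[, cols], .data$query_id, .data$subject_gene_id)
}
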