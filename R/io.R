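# Readers/writers for the pipeline's external tables and sequence sets.
# All tables are UTF-8, tab-delimited, "." decimal mark; a missing intensity
# is an empty field and is read as "not detected" (NA).

FEATURECOUNTS_ANNOT <- c("Chr", "Start", "End", "Strand", "Length")

#' Read a sample design table
#'
#' The design maps each sequencing or proteomics sample to a biotype role:
#' `A` is the numerator biotype of every fold change (the study's
#' Cucurbitaceae-specialized CU biotype), `B` the denominator (the
#' Malvaceae-specialized MA biotype). Free-text biotype labels are mapped to
#' the two roles via `biotype_a`.
#'
#' @param path Tab-delimited file with columns `sample_id`, `biotype`,
#'   `replicate` and optionally `tissue` (one of whole/head/saliva).
#' @param biotype_a Label in the `biotype` column to treat as role A; the
#'   single remaining label becomes role B. `NULL` keeps literal `A`/`B`.
#' @return A tibble with columns `sample_id`, `biotype` (factor A/B),
#'   `replicate`, `tissue`.
#' @export
read_design <- function(path, biotype_a = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "biotype", "replicate") %in% names(d))) {
    abort("design table needs columns sample_id, biotype, replicate")
  }
  if (!"tissue" %in% names(d)) d$tissue <- "whole"
  design <- tibble(
    sample_id = as.character(d$sample_id),
    biotype = as.character(d$biotype),
    replicate = as.integer(d$replicate),
    tissue = as.character(d$tissue)
  )
  if (!is.null(biotype_a)) {
    labs <- unique(design$biotype)
    if (!biotype_a %in% labs) {
      abort(paste0("biotype_a '", biotype_a, "' absent from design"))
    }
    other <- setdiff(labs, biotype_a)
    if (length(other) != 1) abort("design must contain exactly two biotypes")
    design$biotype <- ifelse(design$biotype == biotype_a, "A", "B")
  }
  validate_design(design)
}

validate_design <- function(design) {
  design <- as_tibble(design)
  if (anyDuplicated(design$sample_id)) {
    abort("duplicate sample_id in design")
  }
  if (!all(design$biotype %in% c("A", "B"))) {
    abort("biotype labels must be A/B (use biotype_a= to map free text)")
  }
  if (any(design$replicate < 1)) abort("replicate must be a positive integer")
  if (!all(design$tissue %in% c("whole", "head", "saliva"))) {
    abort("tissue must be one of whole, head, saliva")
  }
  design$biotype <- factor(design$biotype, levels = c("A", "B"))
  design
}

# Require >= 2 replicates in both biotypes for any statistical test.
check_two_replicates <- function(design) {
  n <- table(design$biotype)
  if (length(n) < 2 || any(n < 2)) {
    abort("each biotype needs at least 2 replicates for testing")
  }
  invisible(design)
}

#' Read a gene-by-sample fragment count matrix
#'
#' Accepts a plain TSV with gene ids in the first column and one count
#' column per sample, or featureCounts output (the `Chr`, `Start`, `End`,
#' `Strand`, `Length` annotation columns are auto-detected and dropped).
#'
#' @param path Tab-delimited count file.
#' @param design Design tibble from [read_design()]; every designed sample
#'   must have a column.
#' @return A tibble with `gene_id` first and one integer column per designed
#'   sample, in design order.
#' @export
read_count_matrix <- function(path, design) {
  design <- validate_design(design)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  names(d)[1] <- "gene_id"
  annot <- intersect(FEATURECOUNTS_ANNOT, names(d))
  if (length(annot) > 0) d <- d[, setdiff(names(d), annot)]
  missing <- setdiff(design$sample_id, names(d))
  if (length(missing) > 0) {
    abort(paste0("count file lacks column(s) for designed sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- unique(d$gene_id[duplicated(d$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated gene id(s): ", paste(dup, collapse = ", ")))
  }
  counts <- d[, c("gene_id", design$sample_id)]
  for (s in design$sample_id) {
    v <- counts[[s]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "sample %s: negative or non-integer count at line %d", s, bad[1] + 1L
      ))
    }
    counts[[s]] <- as.integer(v)
  }
  counts$gene_id <- as.character(counts$gene_id)
  counts
}

# tibble (gene_id + samples) -> integer matrix with rownames
counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

PROTEIN_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
NUCLEOTIDE_LETTERS <- strsplit("ACGTUNRYSWKMBDHV", "")[[1]]

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`. Ambiguity codes are
#'   allowed for nucleotide records, `X` (and `*`) for protein.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for record: ", ids[nchar(seqs) == 0][1]))
  }
  allowed <- if (alphabet == "protein") PROTEIN_LETTERS else NUCLEOTIDE_LETTERS
  for (i in seq_along(seqs)) {
    letters_i <- unique(strsplit(seqs[i], "")[[1]])
    bad <- setdiff(letters_i, allowed)
    if (length(bad) > 0) {
      abort(sprintf("record %s: character(s) %s not in %s alphabet",
                    ids[i], paste(bad, collapse = ""), alphabet))
    }
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write a tibble of sequences as FASTA
#' @param seqs Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", seqs$id, "\n", seqs$sequence), path)
  invisible(path)
}

#' Read a gene-to-protein map
#'
#' @param path TSV with columns `gene_id`, `protein_id`, `exonic_length_bp`.
#' @return A tibble; each protein maps to exactly one gene and exonic
#'   lengths are positive.
#' @export
read_gene_protein_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "protein_id", "exonic_length_bp") %in% names(m))) {
    abort("map needs columns gene_id, protein_id, exonic_length_bp")
  }
  m <- as_tibble(m[, c("gene_id", "protein_id", "exonic_length_bp")])
  if (anyDuplicated(m$protein_id)) {
    abort("a protein_id maps to more than one gene")
  }
  if (any(m$exonic_length_bp < 1)) abort("exonic_length_bp must be >= 1")
  m
}

#' Read a peptide evidence table
#'
#' @param path TSV with columns `peptide`, `protein_ids`
#'   (semicolon-separated parent accessions) and one intensity column per
#'   saliva sample; empty intensity fields read as not detected (`NA`).
#' @param design Saliva sample design (validated against column names).
#' @return A tibble with `peptide`, `protein_ids` and numeric sample columns.
#' @export
read_peptide_evidence <- function(path, design) {
  design <- validate_design(design)
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("peptide", "protein_ids") %in% names(ev))) {
    abort("evidence needs columns peptide, protein_ids")
  }
  missing <- setdiff(design$sample_id, names(ev))
  if (length(missing) > 0) {
    abort(paste0("evidence lacks intensity column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ev <- ev[, c("peptide", "protein_ids", design$sample_id)]
  for (s in design$sample_id) ev[[s]] <- as.numeric(ev[[s]])
  as_tibble(ev)
}

#' Read a salivary-protein presence/absence matrix
#'
#' @param path TSV whose first column is a protein label and remaining
#'   columns are species; `1`/`x`/check marks count as present, empty or `0`
#'   as absent.
#' @return A tibble with `protein` and one logical column per species.
#' @export
read_presence_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  names(d)[1] <- "protein"
  if (anyDuplicated(d$protein)) abort("duplicate protein row label")
  if (anyDuplicated(names(d))) abort("duplicate species column label")
  for (sp in names(d)[-1]) {
    v <- d[[sp]]
    d[[sp]] <- !(is.na(v) | v %in% c("", "0", "no", "FALSE"))
  }
  d
}

#' Read an externally computed DEG table
#'
#' Drop-in for published differential-expression tools: a table with
#' `gene_id`, `log2fc`, `p_value` and optionally `q_value` (recomputed by
#' BH when absent) is accepted wherever this package's own test output is.
#'
#' @param path TSV file.
#' @param config `effector_config` supplying the DEG thresholds.
#' @return A DEG tibble with `is_deg` and `direction` columns filled in.
#' @export
read_deg_table <- function(path, config = effector_config()) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "log2fc", "p_value") %in% names(d))) {
    abort("DEG table needs columns gene_id, log2fc, p_value")
  }
  if (!"q_value" %in% names(d)) d$q_value <- bh_adjust(d$p_value)
  call_degs(as_tibble(d), config)
}

#' Read external secretion predictions
#'
#' Loads per-protein predictions from external tools, overriding the
#' built-in weight-matrix/hydropathy stand-ins.
#'
#' @param path TSV with columns `protein_id`, `has_signal_peptide`,
#'   `cleavage_site` (empty when no signal peptide) and `tm_segments`
#'   (semicolon-separated `start-end` pairs, empty for none).
#' @return A secretion annotation tibble as from [annotate_secretion()].
#' @export
read_secretion_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("protein_id", "has_signal_peptide", "cleavage_site", "tm_segments")
  if (!all(need %in% names(d))) {
    abort(paste0("secretion table needs columns ",
                 paste(need, collapse = ", ")))
  }
  segs <- lapply(as.character(d$tm_segments), parse_segments)
  tibble(
    protein_id = as.character(d$protein_id),
    has_signal_peptide = as.logical(d$has_signal_peptide),
    sp_score = NA_real_,
    cleavage_site = ifelse(d$has_signal_peptide,
                           as.integer(d$cleavage_site), NA_integer_),
    tm_segments = segs,
    is_secreted_candidate = vapply(seq_len(nrow(d)), function(i) {
      secreted_verdict(as.logical(d$has_signal_peptide[i]),
                       if (as.logical(d$has_signal_peptide[i]))
                         as.integer(d$cleavage_site[i]) else NA_integer_,
                       segs[[i]])
    }, logical(1))
  )
}

parse_segments <- function(x) {
  if (is.na(x) || x == "") {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(x, ";")[[1]], "-")
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
  colnames(m) <- c("start", "end")
  m
}

format_segments <- function(m) {
  if (is.null(m) || nrow(m) == 0) return("")
  paste(paste0(m[, 1], "-", m[, 2]), collapse = ";")
}

#' Write the final effector-candidate report
#'
#' One row per candidate, sorted by gene id, with a machine-readable JSON
#' sidecar (`<path>.json`) recording the run configuration and summary
#' counts (total, up/down in biotype A, with/without signal peptide).
#'
#' @param candidates Candidate tibble from [combined_candidates()] (or any
#'   tibble with `protein_group_id`, `gene_id`, `direction`, `fold_change`,
#'   `has_signal_peptide`; a `description` column is carried through).
#' @param path Output TSV path.
#' @param config `effector_config` echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path,
                                   config = effector_config()) {
  need <- c("protein_group_id", "gene_id", "direction", "fold_change",
            "has_signal_peptide")
  miss <- setdiff(need, names(candidates))
  if (length(miss) > 0) {
    abort(paste0("candidates lack column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"description" %in% names(candidates)) {
    candidates$description <- NA_character_
  }
  out <- candidates[order(candidates$gene_id), , drop = FALSE]
  keep <- c("protein_group_id", "gene_id", "description", "direction",
            "fold_change", "has_signal_peptide")
  extra <- setdiff(names(out), keep)
  out <- out[, c(keep, extra), drop = FALSE]
  out <- out[, !vapply(out, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  sidecar <- list(
    n_candidates = nrow(out),
    n_up_in_A = sum(out$direction == "up_in_A"),
    n_down_in_A = sum(out$direction == "down_in_A"),
    n_signal_peptide = sum(out$has_signal_peptide, na.rm = TRUE),
    n_no_signal_peptide = sum(!out$has_signal_peptide, na.rm = TRUE),
    config = unclass(config)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a candidate report back
#' @param path Report TSV written by [write_candidate_report()].
#' @return The report tibble.
#' @export
read_candidate_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `sample_id`, `biotype`, `gene_id`,
#'   `ct_target`, `ct_reference`.
#' @return A tibble with those columns.
#' @export
read_ct_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "biotype", "gene_id", "ct_target", "ct_reference")
  if (!all(need %in% names(d))) {
    abort(paste0("Ct table needs columns ", paste(need, collapse = ", ")))
  }
  as_tibble(d[, need])
}
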