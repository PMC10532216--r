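# Seeded generator of a complete two-biotype multi-omics study with known
# ground truth: NB counts for whole-aphid and head tissues with planted
# DEGs, protein sequences with planted signal peptides and TM segments, a
# salivary subset with log-normal peptide intensities carrying planted
# biotype-unique and biotype-differential proteins, planted homologs of
# query effectors, and qPCR Ct tables. A "distortion" mode decouples
# proteome differences from transcript differences.

BG_AA_FREQ <- local({
  f <- c(A = 6, R = 7, N = 5, D = 7, C = 1, Q = 5, E = 8, G = 7, H = 3,
         I = 3, L = 5, K = 8, M = 2, F = 3, P = 5, S = 8, T = 6, W = 1,
         Y = 3, V = 4)
  f / sum(f)
})

random_protein <- function(len, exclude_n_terminal_met = FALSE) {
  aa <- sample(names(BG_AA_FREQ), len, replace = TRUE, prob = BG_AA_FREQ)
  paste(aa, collapse = "")
}

# standard-table codons per amino acid (no stops)
CODON_CHOICES <- local({
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
})

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    choices <- CODON_CHOICES[[a]]
    choices[sample.int(length(choices), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

mutate_protein <- function(protein, keep_identity) {
  aa <- strsplit(protein, "")[[1]]
  n_mut <- round((1 - keep_identity) * length(aa))
  if (n_mut > 0) {
    pos <- sample(seq_along(aa), n_mut)
    for (p in pos) {
      aa[p] <- sample(setdiff(names(BG_AA_FREQ), aa[p]), 1)
    }
  }
  paste(aa, collapse = "")
}

plant_signal_peptide <- function(mature, hard = FALSE) {
  core_len <- if (hard) 7L else 10L
  core_pool <- if (hard) c("L", "A", "V", "T", "S") else
    c("L", "L", "A", "A", "V", "I", "F")
  core <- paste(sample(core_pool, core_len, replace = TRUE), collapse = "")
  sp <- paste0("MK", core, "A", "AQA")
  # acidic mature start keeps hydropathy windows that straddle the cleavage
  # site below the TM threshold, so the h-region is not mistaken for a TM
  list(sequence = paste0(sp, "DDESS", mature), cleavage_site = nchar(sp))
}

plant_tm_segment <- function(sequence, at, hard = FALSE) {
  len <- if (hard) 19L else 21L
  pool <- c("I", "I", "L", "L", "V", "F", "A")
  seg <- paste(sample(pool, len, replace = TRUE), collapse = "")
  pre <- substr(sequence, 1, at - 1)
  post <- substr(sequence, at + len, nchar(sequence))
  list(sequence = paste0(pre, seg, post),
       start = at, end = at + len - 1L)
}

make_design <- function(prefix, n_reps, tissue) {
  tibble(
    sample_id = c(paste0(prefix, "A", seq_len(n_reps)),
                  paste0(prefix, "B", seq_len(n_reps))),
    biotype = rep(c("A", "B"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2),
    tissue = tissue
  )
}

nb_counts <- function(mu_a, mu_b, design, dispersion, depth) {
  n_genes <- length(mu_a)
  cols <- lapply(seq_len(nrow(design)), function(j) {
    mu <- if (design$biotype[j] == "A") mu_a else mu_b
    as.integer(rnbinom(n_genes, mu = mu * depth[j], size = 1 / dispersion))
  })
  names(cols) <- design$sample_id
  as_tibble(cols)
}

#' Simulate qPCR Ct values for a planted expression ratio
#'
#' Plants a true A-vs-B expression ratio on the log2 scale: each sample's
#' dCt is the gene's baseline minus its biotype's log2 expression, plus
#' Normal(0, `sigma_ct`) noise, so the expected `2^-ddCt` equals `fold`.
#'
#' @param gene_id Gene label.
#' @param fold True relative expression of biotype A vs B.
#' @param n_reps Replicates per biotype.
#' @param sigma_ct Ct noise standard deviation (cycles).
#' @return Ct tibble as accepted by [ddct()].
#' @export
simulate_ct <- function(gene_id, fold, n_reps = 5L, sigma_ct = 0.2) {
  l2 <- log2(fold)
  base_dct <- runif(1, 2, 8)
  rows <- lapply(c("A", "B"), function(bt) {
    shift <- if (bt == "A") l2 / 2 else -l2 / 2
    ref <- 18 + rnorm(n_reps, 0, sigma_ct / 2)
    tibble(
      sample_id = paste0("qpcr", bt, seq_len(n_reps)),
      biotype = bt,
      gene_id = gene_id,
      ct_target = ref + base_dct - shift + rnorm(n_reps, 0, sigma_ct),
      ct_reference = ref
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a complete two-biotype multi-omics effector study
#'
#' Generates, from a single seeded stream, every input the pipeline
#' consumes plus the planted truth: whole-aphid and head count matrices
#' (negative-binomial, shared DEG truth, salivary genes boosted in heads),
#' protein and gene sequences with planted signal peptides, transmembrane
#' segments and query-effector homologs, salivary peptide evidence with
#' log-normal intensities carrying planted biotype-unique and
#' biotype-differential proteins, and qPCR Ct tables for the planted
#' effectors. Identical seeds give identical output.
#'
#' Default replication mirrors the clonal-line design this package models
#' (3 biological replicates per biotype for the omics layers, 5 for qPCR).
#' With `distortion = TRUE`, proteome differences are planted independently
#' of transcript differences, emulating saliva collected from an artificial
#' diet whose composition is decoupled from head transcription.
#'
#' @param n_genes Number of genes (>= 50); one protein per gene.
#' @param n_reps Replicates per biotype for both RNA tissues and saliva.
#' @param n_qpcr_reps Replicates per biotype for Ct tables.
#' @param dispersion NB dispersion of counts.
#' @param deg_fraction Fraction of genes planted as DEGs.
#' @param planted_l2fc Absolute log2 fold change of planted DEGs.
#' @param saliva_size Number of salivary proteins.
#' @param n_effectors Planted effectors: salivary proteins whose genes are
#'   DEGs with a direction-consistent proteome fold (ignored under
#'   distortion).
#' @param n_unique,n_differential Planted biotype-unique and
#'   biotype-differential salivary proteins (on non-DEG genes unless
#'   `distortion`).
#' @param prot_fc Planted proteome fold change of differential proteins.
#' @param sp_fraction,tm_fraction Fractions of proteins with planted signal
#'   peptides / TM segments.
#' @param n_queries Query effector proteins emitted; the first
#'   `n_homologs` get a planted homolog gene at `homolog_identity`.
#' @param n_homologs,homolog_identity Homolog planting controls.
#' @param distortion Decouple proteome truth from transcript truth.
#' @param sigma_ct Ct noise (cycles).
#' @param intensity_cv Log-normal sdlog of protein intensities.
#' @param head_boost Head-tissue expression multiplier for salivary genes.
#' @param hard Narrow the planted SP/TM margins for robustness testing.
#' @param seed Integer seed; the single source of randomness.
#' @return An `effector_sim` list: `counts_whole`, `counts_head`,
#'   `design_rna`, `design_head`, `design_saliva`, `proteins`, `genes`,
#'   `map`, `evidence`, `ct`, `queries`, `truth`, `params`.
#' @export
simulate_effector_study <- function(n_genes = 200L,
                                    n_reps = 3L,
                                    n_qpcr_reps = 5L,
                                    dispersion = 0.05,
                                    deg_fraction = 0.1,
                                    planted_l2fc = 3,
                                    saliva_size = 30L,
                                    n_effectors = 8L,
                                    n_unique = 4L,
                                    n_differential = 6L,
                                    prot_fc = 4,
                                    sp_fraction = 0.35,
                                    tm_fraction = 0.2,
                                    n_queries = 5L,
                                    n_homologs = 3L,
                                    homolog_identity = 0.6,
                                    distortion = FALSE,
                                    sigma_ct = 0.2,
                                    intensity_cv = 0.2,
                                    head_boost = 4,
                                    hard = FALSE,
                                    seed = 1L) {
  if (n_genes < 50) abort("n_genes must be >= 50")
  if (n_reps < 2) abort("n_reps must be >= 2")
  if (saliva_size > n_genes) abort("saliva_size exceeds the protein set")
  n_deg <- round(deg_fraction * n_genes)
  n_effectors <- min(n_effectors, n_deg, saliva_size)
  if (n_unique + n_differential + (if (distortion) 0 else n_effectors) >
      saliva_size) {
    abort("planted salivary classes exceed saliva_size")
  }
  set.seed(seed, kind = "Mersenne-Twister")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  protein_ids <- sprintf("p%04d", seq_len(n_genes))
  map <- tibble(
    gene_id = gene_ids, protein_id = protein_ids,
    exonic_length_bp = sample(500:3000, n_genes, replace = TRUE)
  )

  salivary_idx <- sort(sample.int(n_genes, saliva_size))

  # --- transcript truth -----------------------------------------------
  if (distortion || n_effectors == 0) {
    deg_idx <- sort(sample.int(n_genes, n_deg))
    effector_idx <- integer(0)
  } else {
    effector_idx <- sort(sample(salivary_idx, n_effectors))
    pool <- setdiff(seq_len(n_genes), salivary_idx)
    deg_idx <- sort(c(effector_idx,
                      sample(pool, max(n_deg - n_effectors, 0))))
  }
  l2fc <- setNames(rep(0, n_genes), gene_ids)
  if (length(deg_idx) > 0) {
    signs <- sample(c(-1, 1), length(deg_idx), replace = TRUE)
    l2fc[deg_idx] <- signs * planted_l2fc
  }

  base_mu <- exp(runif(n_genes, log(50), log(500)))
  mu_a <- base_mu * 2^(l2fc / 2)
  mu_b <- base_mu * 2^(-l2fc / 2)
  design_rna <- make_design("whole", n_reps, "whole")
  design_head <- make_design("head", n_reps, "head")
  design_saliva <- make_design("sal", n_reps, "saliva")
  depth_whole <- runif(2 * n_reps, 0.8, 1.25)
  depth_head <- runif(2 * n_reps, 0.8, 1.25)
  counts_whole <- dplyr::bind_cols(
    tibble(gene_id = gene_ids),
    nb_counts(mu_a, mu_b, design_rna, dispersion, depth_whole)
  )
  boost <- rep(1, n_genes)
  boost[salivary_idx] <- head_boost
  counts_head <- dplyr::bind_cols(
    tibble(gene_id = gene_ids),
    nb_counts(mu_a * boost, mu_b * boost, design_head, dispersion,
              depth_head)
  )

  # --- protein sequences with planted secretion features ---------------
  n_sp <- round(sp_fraction * n_genes)
  n_tm <- round(tm_fraction * n_genes)
  sp_idx <- sort(sample.int(n_genes, n_sp))
  tm_idx <- sort(sample.int(n_genes, n_tm))
  seqs <- character(n_genes)
  cleavage <- rep(NA_integer_, n_genes)
  tm_start <- rep(NA_integer_, n_genes)
  tm_end <- rep(NA_integer_, n_genes)
  for (i in seq_len(n_genes)) {
    mature <- random_protein(sample(120:260, 1))
    if (i %in% sp_idx) {
      sp <- plant_signal_peptide(mature, hard)
      seqs[i] <- sp$sequence
      cleavage[i] <- sp$cleavage_site
    } else {
      seqs[i] <- paste0("M", mature)
    }
    if (i %in% tm_idx) {
      at <- if (i %in% sp_idx) cleavage[i] + 15L else 40L
      tm <- plant_tm_segment(seqs[i], at, hard)
      seqs[i] <- tm$sequence
      tm_start[i] <- tm$start
      tm_end[i] <- tm$end
    }
  }

  # --- queries and planted homologs ------------------------------------
  query_ids <- sprintf("effq%02d", seq_len(n_queries))
  n_homologs <- min(n_homologs, n_queries)
  homolog_genes <- if (n_homologs > 0) {
    sort(sample(setdiff(seq_len(n_genes), c(deg_idx, salivary_idx)),
                n_homologs))
  } else integer(0)
  queries <- character(n_queries)
  for (k in seq_len(n_queries)) {
    if (k <= n_homologs) {
      queries[k] <- mutate_protein(seqs[homolog_genes[k]], homolog_identity)
    } else {
      queries[k] <- paste0("M", random_protein(sample(140:200, 1)))
    }
  }
  genes_nt <- vapply(seqs, reverse_translate, character(1), USE.NAMES = FALSE)

  # --- salivary proteome truth -----------------------------------------
  remaining <- if (distortion) salivary_idx else
    setdiff(salivary_idx, effector_idx)
  unique_idx <- sort(sample(remaining, n_unique))
  remaining <- setdiff(remaining, unique_idx)
  diff_idx <- sort(sample(remaining, n_differential))
  unique_side <- sample(c("A", "B"), n_unique, replace = TRUE)
  diff_sign <- sample(c(-1, 1), n_differential, replace = TRUE)

  prot_l2 <- setNames(rep(0, n_genes), protein_ids)
  prot_l2[diff_idx] <- diff_sign * log2(prot_fc)
  # effectors: proteome fold consistent with the RNA direction
  if (!distortion && length(effector_idx) > 0) {
    prot_l2[effector_idx] <- sign(l2fc[effector_idx]) * 1
  }

  ev_rows <- list()
  for (i in salivary_idx) {
    peps <- tryptic_digest(seqs[i])
    peps <- unique(peps[nchar(peps) >= 7 & nchar(peps) <= 30])
    if (length(peps) == 0) next
    abundance <- rlnorm(1, meanlog = log(2e5), sdlog = 1)
    obs <- count_observable_peptides(seqs[i])
    share <- runif(length(peps))
    share <- share / sum(share)
    ints <- lapply(seq_len(nrow(design_saliva)), function(j) {
      bt <- design_saliva$biotype[j]
      uq <- match(i, unique_idx)
      if (!is.na(uq) && bt != unique_side[uq]) {
        return(rep(NA_real_, length(peps)))
      }
      fold <- 2^(if (bt == "A") prot_l2[i] / 2 else -prot_l2[i] / 2)
      total <- abundance * max(obs, 1) * fold *
        rlnorm(1, 0, intensity_cv)
      total * share * rlnorm(length(peps), 0, 0.05)
    })
    names(ints) <- design_saliva$sample_id
    ev_rows[[length(ev_rows) + 1]] <- dplyr::bind_cols(
      tibble(peptide = peps, protein_ids = protein_ids[i]),
      as_tibble(ints)
    )
  }
  evidence <- dplyr::bind_rows(ev_rows)

  # --- planted effectors by the combined rule --------------------------
  head_deg_salivary <- intersect(salivary_idx, deg_idx)
  consistent <- vapply(head_deg_salivary, function(i) {
    if (prot_l2[i] == 0) TRUE else sign(prot_l2[i]) == sign(l2fc[i])
  }, logical(1))
  planted_effector_idx <- head_deg_salivary[consistent]

  # --- qPCR Ct for the planted effectors -------------------------------
  ct <- if (length(planted_effector_idx) > 0) {
    dplyr::bind_rows(lapply(planted_effector_idx, function(i) {
      simulate_ct(gene_ids[i], 2^l2fc[i], n_qpcr_reps, sigma_ct)
    }))
  } else {
    tibble(sample_id = character(), biotype = character(),
           gene_id = character(), ct_target = numeric(),
           ct_reference = numeric())
  }

  truth <- list(
    deg_genes = tibble(gene_id = gene_ids[deg_idx],
                       l2fc = unname(l2fc[deg_idx])),
    sp_proteins = tibble(protein_id = protein_ids[sp_idx],
                         cleavage_site = cleavage[sp_idx]),
    tm_proteins = tibble(protein_id = protein_ids[tm_idx],
                         start = tm_start[tm_idx], end = tm_end[tm_idx]),
    salivary_proteins = protein_ids[salivary_idx],
    unique_proteins = tibble(protein_id = protein_ids[unique_idx],
                             biotype = unique_side),
    differential_proteins = tibble(
      protein_id = protein_ids[diff_idx],
      fold = 2^(unname(prot_l2[diff_idx]))
    ),
    planted_effectors = protein_ids[planted_effector_idx],
    homologs = tibble(query_id = query_ids[seq_len(n_homologs)],
                      gene_id = gene_ids[homolog_genes],
                      identity = homolog_identity * 100),
    seed = seed
  )

  structure(
    list(
      counts_whole = counts_whole, counts_head = counts_head,
      design_rna = design_rna, design_head = design_head,
      design_saliva = design_saliva,
      proteins = tibble(id = protein_ids, sequence = seqs),
      genes = tibble(id = gene_ids, sequence = genes_nt),
      map = map, evidence = evidence, ct = ct,
      queries = tibble(id = query_ids, sequence = queries),
      truth = truth,
      params = list(
        n_genes = n_genes, n_reps = n_reps, dispersion = dispersion,
        deg_fraction = deg_fraction, planted_l2fc = planted_l2fc,
        saliva_size = saliva_size, distortion = distortion,
        sigma_ct = sigma_ct, seed = seed
      )
    ),
    class = "effector_sim"
  )
}

#' @export
print.effector_sim <- function(x, ...) {
  cat(sprintf(
    "<effector_sim> %d genes x %d reps/biotype, %d planted DEGs, %d salivary proteins, %d planted effectors (seed %d)\n",
    x$params$n_genes, x$params$n_reps, nrow(x$truth$deg_genes),
    length(x$truth$salivary_proteins), length(x$truth$planted_effectors),
    x$params$seed
  ))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits every file the pipeline reads: count TSVs for both tissues, design
#' TSVs, protein and gene FASTA, the gene-protein map, peptide evidence, Ct
#' CSV, query FASTA, and the planted truth as JSON. Output is byte-stable
#' for a fixed seed.
#'
#' @param sim An `effector_sim` from [simulate_effector_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_count_matrix(sim$counts_whole, p("counts_whole.tsv"))
  write_count_matrix(sim$counts_head, p("counts_head.tsv"))
  readr::write_tsv(sim$design_rna, p("design_whole.tsv"), progress = FALSE)
  readr::write_tsv(sim$design_head, p("design_head.tsv"), progress = FALSE)
  readr::write_tsv(sim$design_saliva, p("design_saliva.tsv"),
                   progress = FALSE)
  write_fasta(sim$proteins, p("proteins.faa"))
  write_fasta(sim$genes, p("genes.fna"))
  write_fasta(sim$queries, p("query_effectors.faa"))
  readr::write_tsv(sim$map, p("gene_protein_map.tsv"), progress = FALSE)
  readr::write_tsv(sim$evidence, p("peptide_evidence.tsv"), na = "",
                   progress = FALSE)
  readr::write_csv(sim$ct, p("ct_values.csv"), progress = FALSE)
  truth <- sim$truth
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Score pipeline outputs against planted truth
#'
#' Confusion counts per pipeline stage plus an exact-set flag. Stages with
#' no supplied output are skipped.
#'
#' @param truth Truth list from an `effector_sim`.
#' @param deg `deg_result` or DEG tibble on the simulated counts.
#' @param annotations Secretion annotation tibble on the simulated proteins.
#' @param calls Differential-protein calls on the simulated evidence.
#' @param candidates Combined-candidate tibble.
#' @return Tibble: `stage`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `exact`.
#' @export
evaluate_recovery <- function(truth, deg = NULL, annotations = NULL,
                              calls = NULL, candidates = NULL) {
  score <- function(stage, called, pos, universe) {
    if (!all(called %in% universe) || !all(pos %in% universe)) {
      abort(paste0(stage, ": ids do not match the truth's universe"))
    }
    tp <- length(intersect(called, pos))
    fp <- length(setdiff(called, pos))
    fn <- length(setdiff(pos, called))
    tn <- length(universe) - tp - fp - fn
    tibble(
      stage = stage, tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (length(pos) > 0) tp / length(pos) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      exact = fp == 0 && fn == 0
    )
  }
  out <- list()
  if (!is.null(deg)) {
    tbl <- if (inherits(deg, "deg_result")) deg$table else deg
    out$deg <- score("deg", tbl$gene_id[tbl$is_deg],
                     truth$deg_genes$gene_id, tbl$gene_id)
  }
  if (!is.null(annotations)) {
    out$sp <- score(
      "signal_peptide",
      annotations$protein_id[annotations$has_signal_peptide],
      truth$sp_proteins$protein_id, annotations$protein_id
    )
    out$tm <- score(
      "transmembrane",
      annotations$protein_id[annotations$n_tm_segments > 0],
      truth$tm_proteins$protein_id, annotations$protein_id
    )
  }
  if (!is.null(calls)) {
    called <- calls$group_id[calls$class != "none"]
    pos <- c(truth$unique_proteins$protein_id,
             truth$differential_proteins$protein_id)
    out$prot <- score("differential_protein", called,
                      intersect(pos, calls$group_id), calls$group_id)
  }
  if (!is.null(candidates)) {
    prot_of_group <- unique(candidates$protein_group_id)
    out$comb <- score(
      "combined_candidates", prot_of_group,
      truth$planted_effectors,
      unique(c(truth$salivary_proteins, prot_of_group))
    )
  }
  dplyr::bind_rows(out)
}
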