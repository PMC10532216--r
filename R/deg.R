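# Two-biotype negative-binomial differential expression.
#
# The test is a deliberately compact NB Wald test: median-of-ratios
# normalization, gene-wise method-of-moments dispersion shrunk halfway
# toward a fitted mean-dispersion trend, and a delta-method standard error
# for the log ratio of group means under Var = m + phi * m^2.

#' Median-of-ratios size factors
#'
#' @param counts Count tibble (`gene_id` + sample columns) or numeric matrix.
#' @return Named positive scale factor per sample: the median, over genes
#'   with a positive geometric mean, of each sample's count divided by that
#'   geometric mean.
#' @param pseudo_reference When no gene is expressed in every sample, fall
#'   back to a reference built from genes expressed in at least half the
#'   samples (zeros ignored in the geometric mean) instead of erroring.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"),
#'                          s1 = c(10L, 100L), s2 = c(20L, 200L))
#' size_factors(counts)
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  if (any(m < 0)) abort("negative counts")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      abort(paste0("no gene expressed in all samples; set ",
                   "pseudo_reference = TRUE to use a pseudo-reference"))
    }
    use <- rowSums(m > 0) >= ncol(m) / 2
    if (!any(use)) abort("no gene expressed in half the samples")
    ref <- apply(m[use, , drop = FALSE], 1, function(x) {
      exp(mean(log(x[x > 0])))
    })
    sub <- m[use, , drop = FALSE]
  } else {
    sub <- m[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
  }
  sf <- apply(sub, 2, function(col) median((col / ref)[col > 0]))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    abort("could not compute positive size factors")
  }
  sf
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `fpkm = count * 1e9 / (exonic_length_bp * column_total)`, on raw column
#' totals (FPKM is defined on mapped fragments, not size-factored counts).
#'
#' @param counts Count tibble.
#' @param map Gene map tibble with `gene_id`, `exonic_length_bp` (from
#'   [read_gene_protein_map()]); every gene in `counts` must appear.
#' @return Tibble of the same shape with FPKM values.
#' @export
fpkm <- function(counts, map) {
  m <- counts_to_matrix(counts)
  lens <- map$exonic_length_bp[match(rownames(m), map$gene_id)]
  if (anyNA(lens)) {
    abort(paste0("no exonic length for gene(s): ",
                 paste(head(rownames(m)[is.na(lens)], 5), collapse = ", ")))
  }
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("zero column total, FPKM undefined for sample(s): ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  f <- m * 1e9 / outer(lens, totals)
  out <- as_tibble(f)
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

#' Benjamini--Hochberg step-up adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j`, capped at 1:
#' the classic step-up transform, monotone in p and idempotent.
#'
#' @param p_values Numeric vector of p values in \[0, 1\]; `NA`/`NaN`
#'   propagate with a warning.
#' @return q values in input order.
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p)) warn("NA p-values propagated as NA q-values")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    qv <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
    q[ok] <- qv
  }
  q
}

# Fit a mean-dispersion trend phi(mu) = a0 + a1/mu on moment estimates,
# excluding genes at the floor; falls back to the median dispersion when
# the fit degenerates.
fit_dispersion_trend <- function(mu, phi, floor = 1e-8) {
  use <- is.finite(phi) & phi > floor * 10 & mu > 0
  if (sum(use) >= 10) {
    fit <- tryCatch(lm(phi[use] ~ I(1 / mu[use])), error = function(e) NULL)
    if (!is.null(fit)) {
      a <- coef(fit)
      a[is.na(a)] <- 0
      a <- pmax(a, 0)
      return(pmax(a[1] + a[2] / pmax(mu, 1e-8), floor))
    }
  }
  med <- if (any(use)) median(phi[use]) else floor
  rep(max(med, floor), length(mu))
}

#' Negative-binomial differential expression between two biotypes
#'
#' For each gene, normalized group means `m_A`, `m_B` are compared with a
#' Wald test on `ln((m_A + c)/(m_B + c))` (pseudo-count `c`, default 0.5),
#' whose delta-method variance uses the NB relation `Var = m + phi * m^2`.
#' The gene-wise dispersion `phi` is a pooled within-group method-of-moments
#' estimate, floored at 1e-8 and shrunk halfway toward a fitted
#' mean-dispersion trend. P values are two-sided normal; all-zero genes get
#' `p = 1`, `log2fc = 0` by convention.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param design Design tibble mapping samples to biotypes A/B; at least two
#'   replicates per biotype.
#' @param config `effector_config` (pseudo-count, DEG thresholds).
#' @param map Optional gene map for FPKM columns (`mean_fpkm_A/B`); skipped
#'   when `NULL`.
#' @return An object of class `deg_result`: a list with `table` (one
#'   DegRecord tibble row per gene: `gene_id`, `base_mean`, `log2fc`,
#'   `p_value`, `q_value`, `is_deg`, `direction`, optionally FPKM means),
#'   `size_factors`, `config`. Use [tidy()] / [glance()] / [autoplot()].
#' @examples
#' sim <- simulate_effector_study(n_genes = 60, seed = 1)
#' res <- deg_test(sim$counts_whole, sim$design_rna)
#' glance(res)
#' @export
deg_test <- function(counts, design, config = effector_config(), map = NULL) {
  design <- validate_design(design)
  check_two_replicates(design)
  m <- counts_to_matrix(counts)
  if (!setequal(colnames(m), design$sample_id)) {
    m <- m[, design$sample_id, drop = FALSE]
  }
  if (all(m == 0)) abort("no expressed genes")
  sf <- size_factors(m, pseudo_reference = config$pseudo_reference)
  norm <- sweep(m, 2, sf, "/")
  a_cols <- design$sample_id[design$biotype == "A"]
  b_cols <- design$sample_id[design$biotype == "B"]
  nA <- length(a_cols)
  nB <- length(b_cols)
  normA <- norm[, a_cols, drop = FALSE]
  normB <- norm[, b_cols, drop = FALSE]
  mA <- rowMeans(normA)
  mB <- rowMeans(normB)
  pc <- config$pseudo_count
  log2fc <- log2((mA + pc) / (mB + pc))

  # pooled within-group moment dispersion
  vA <- apply(normA, 1, var)
  vB <- apply(normB, 1, var)
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mbar <- (nA * mA + nB * mB) / (nA + nB)
  floor_phi <- 1e-8
  phi_gene <- pmax((s2 - mbar) / pmax(mbar, 1e-8)^2, floor_phi)
  phi_trend <- fit_dispersion_trend(mbar, phi_gene, floor_phi)
  phi <- pmax((phi_gene + phi_trend) / 2, floor_phi)

  var_lnA <- (mA + phi * mA^2) / (nA * (mA + pc)^2)
  var_lnB <- (mB + phi * mB^2) / (nB * (mB + pc)^2)
  se_ln <- sqrt(var_lnA + var_lnB)
  stat <- ifelse(se_ln > 0, log(2) * log2fc / se_ln, 0)
  p <- 2 * pnorm(-abs(stat))
  zero <- mA == 0 & mB == 0
  p[zero] <- 1
  log2fc[zero] <- 0
  tbl <- tibble(
    gene_id = rownames(m),
    base_mean = unname(mbar),
    log2fc = unname(log2fc),
    dispersion = unname(phi),
    stat = unname(stat),
    p_value = unname(p),
    q_value = bh_adjust(unname(p))
  )
  if (!is.null(map)) {
    fp <- fpkm(counts, map)
    fm <- counts_to_matrix(fp)
    tbl$mean_fpkm_A <- rowMeans(fm[, a_cols, drop = FALSE])[tbl$gene_id]
    tbl$mean_fpkm_B <- rowMeans(fm[, b_cols, drop = FALSE])[tbl$gene_id]
  }
  tbl <- call_degs(tbl, config)
  structure(
    list(table = tbl, size_factors = sf, config = config,
         n_reps = c(A = nA, B = nB)),
    class = "deg_result"
  )
}

#' Flag differentially expressed genes
#'
#' `is_deg` is true iff `q_value <= q_max` and `|log2fc| >= log2(min_fold)`
#' (both comparisons inclusive); `direction` follows the sign of `log2fc`.
#'
#' @param records DEG tibble with `log2fc` and `q_value`.
#' @param config `effector_config`.
#' @return The tibble with `is_deg` and `direction` columns (re)computed.
#' @export
call_degs <- function(records, config = effector_config()) {
  lfc_min <- log2(config$min_fold)
  records$is_deg <- !is.na(records$q_value) &
    records$q_value <= config$q_max & abs(records$log2fc) >= lfc_min
  records$direction <- dplyr::case_when(
    records$is_deg & records$log2fc > 0 ~ "up_in_A",
    records$is_deg & records$log2fc < 0 ~ "down_in_A",
    .default = "none"
  )
  records
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("<deg_result> %d genes, %d DEGs (%d up_in_A, %d down_in_A)\n",
              nrow(x$table), sum(x$table$is_deg),
              sum(x$table$direction == "up_in_A"),
              sum(x$table$direction == "down_in_A")))
  invisible(x)
}

#' @rdname deg_test
#' @param x,object A `deg_result`.
#' @param ... Unused.
#' @method tidy deg_result
#' @export
tidy.deg_result <- function(x, ...) x$table

#' @rdname deg_test
#' @method glance deg_result
#' @export
glance.deg_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_deg = sum(x$table$is_deg),
    n_up_in_A = sum(x$table$direction == "up_in_A"),
    n_down_in_A = sum(x$table$direction == "down_in_A"),
    q_max = x$config$q_max,
    min_fold = x$config$min_fold
  )
}

#' @rdname deg_test
#' @method autoplot deg_result
#' @export
autoplot.deg_result <- function(object, ...) {
  tbl <- object$table
  tbl$status <- factor(tbl$direction, c("up_in_A", "down_in_A", "none"))
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$q_value, 1e-300)),
    colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(object$config$min_fold),
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::geom_hline(yintercept = -log10(object$config$q_max),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up_in_A = "#c0392b", down_in_A = "#2980b9", none = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change (A/B)", y = "-log10 q",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a DEG table
#' @param result `deg_result` or DEG tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(result, path) {
  tbl <- if (inherits(result, "deg_result")) result$table else result
  tbl <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
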