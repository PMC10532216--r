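test_that("size factors obey symmetry, scaling and permutation invariance", {
  design <- two_group_design(1)
  counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           sA1 = c(10L, 100L, 7L), sB1 = c(10L, 100L, 7L))
  expect_equal(unname(size_factors(counts)), c(1, 1))

  doubled <- counts
  doubled$sB1 <- 2L * counts$sA1
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)))

  perm <- counts[c(3, 1, 2), ]
  expect_equal(size_factors(perm), size_factors(counts))
})

test_that("size factors error without a common reference unless told not to", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(10L, 0L), s2 = c(0L, 10L))
  expect_error(size_factors(counts), "pseudo_reference")
  sf <- size_factors(counts, pseudo_reference = TRUE)
  expect_true(all(sf > 0))
})

test_that("FPKM matches its closed form and scaling law", {
  design <- two_group_design(1)
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           sA1 = c(10L, 1999990L), sB1 = c(0L, 4000000L))
  map <- tibble::tibble(gene_id = c("g1", "g2"), protein_id = c("p1", "p2"),
                        exonic_length_bp = c(2000L, 1000L))
  f <- fpkm(counts, map)
  expect_equal(f$sA1[1], 10 * 1e9 / (2000 * 2e6))   # 2.5
  expect_equal(f$sB1[1], 0)                          # zeros map to zeros
  # doubling the column total with this gene's count fixed halves its FPKM
  counts2 <- counts
  counts2$sA1 <- c(10L, 3999990L)
  f2 <- fpkm(counts2, map)
  expect_equal(f2$sA1[1], f$sA1[1] / 2)

  zero <- tibble::tibble(gene_id = "g1", sA1 = 0L, sB1 = 1L)
  expect_error(fpkm(zero, map), "zero column total")
})

test_that("BH adjustment reproduces the hand step-up and its edge cases", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_warning(q <- bh_adjust(c(0.01, NA, 0.5)), "NA")
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], suppressWarnings(bh_adjust(c(0.01, 0.5))))
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")
})

test_that("BH agrees with a brute-force tail-minimum oracle and p.adjust", {
  brute_bh <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "max")
    vapply(seq_len(m), function(i) {
      min(1, min(p[p >= p[i]] * m / r[p >= p[i]]))
    }, numeric(1))
  }
  set.seed(17)
  for (k in 1:20) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-12 & q <= 1))  # step-up bounds
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("a flat gene is a clean null and all-zero genes use the convention", {
  design <- two_group_design(3)
  counts <- tiny_counts(c(rep(100L, 6), rep(0L, 6), rep(20L, 6)), design)
  counts <- tibble::as_tibble(counts)
  r <- tidy(deg_test(counts, design))
  expect_equal(r$log2fc[1], 0)
  expect_gt(r$p_value[1], 0.9)
  expect_equal(r$log2fc[2], 0)             # all-zero gene
  expect_equal(r$p_value[2], 1)
})

test_that("a planted 8-fold gene is called up in biotype A", {
  set.seed(42)
  design <- two_group_design(5)
  n <- 400
  mu <- rep(100, n)
  muA <- mu
  muA[1] <- 100 * sqrt(8)
  muB <- mu
  muB[1] <- 100 / sqrt(8)
  counts <- tibble::tibble(gene_id = sprintf("g%03d", 1:n))
  for (j in seq_len(nrow(design))) {
    m <- if (design$biotype[j] == "A") muA else muB
    counts[[design$sample_id[j]]] <-
      as.integer(rnbinom(n, mu = m, size = 1 / 0.05))
  }
  r <- tidy(deg_test(counts, design))
  expect_lt(r$q_value[1], 0.05)
  expect_equal(r$direction[1], "up_in_A")
  expect_true(r$is_deg[1])
})

test_that("size factors and log2fc are invariant to global count rescaling", {
  sim <- simulate_effector_study(n_genes = 60, seed = 3)
  # negligible pseudo-count isolates the scaling behaviour itself
  cfg <- effector_config(pseudo_count = 1e-6)
  r1 <- deg_test(sim$counts_whole, sim$design_rna, cfg)
  scaled <- sim$counts_whole
  for (s in sim$design_rna$sample_id) scaled[[s]] <- 3L * scaled[[s]]
  r2 <- deg_test(scaled, sim$design_rna, cfg)
  expect_equal(r2$table$log2fc, r1$table$log2fc, tolerance = 1e-6)
  # factors are relative to the geometric-mean reference: scale-free
  expect_equal(unname(r2$size_factors), unname(r1$size_factors),
               tolerance = 1e-8)
})

test_that("DEG calling applies the inclusive q and two-fold rules", {
  tbl <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    log2fc = c(1.2, 0.8, 3.0, 1.0, -1.0),
    q_value = c(0.04, 0.04, 0.06, 0.05, 0.05)
  )
  out <- call_degs(tbl, effector_config())
  expect_equal(out$is_deg, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$direction,
               c("up_in_A", "none", "none", "up_in_A", "down_in_A"))
})

test_that("the DEG set shrinks as thresholds tighten", {
  sim <- simulate_effector_study(n_genes = 100, n_reps = 4, seed = 8,
                                 dispersion = 0.2, planted_l2fc = 1.5)
  r <- deg_test(sim$counts_whole, sim$design_rna)
  sets <- lapply(c(0.1, 0.05, 0.01), function(q) {
    t <- call_degs(r$table, effector_config(q_max = q))
    t$gene_id[t$is_deg]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  folds <- lapply(c(1.5, 2, 4), function(f) {
    t <- call_degs(r$table, effector_config(min_fold = f))
    t$gene_id[t$is_deg]
  })
  expect_true(all(folds[[2]] %in% folds[[1]]))
  expect_true(all(folds[[3]] %in% folds[[2]]))
})

test_that("externally computed DEG tables drop in", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("g1", "g2"), log2fc = c(2.5, 0.1),
    p_value = c(0.001, 0.8)
  ), path)
  d <- read_deg_table(path)
  expect_equal(d$q_value, bh_adjust(c(0.001, 0.8)))
  expect_equal(d$is_deg, c(TRUE, FALSE))
})

test_that("tidy, glance and autoplot work on a deg_result", {
  sim <- simulate_effector_study(n_genes = 60, seed = 2)
  r <- deg_test(sim$counts_whole, sim$design_rna, map = sim$map)
  expect_s3_class(tidy(r), "tbl_df")
  expect_true(all(c("mean_fpkm_A", "mean_fpkm_B") %in% names(tidy(r))))
  g <- glance(r)
  expect_equal(g$n_deg, sum(tidy(r)$is_deg))
  expect_s3_class(autoplot(r), "ggplot")
})
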