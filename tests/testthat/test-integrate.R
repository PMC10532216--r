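make_group <- function(id, members) {
  tibble::tibble(
    group_id = id, member_protein_ids = list(members),
    n_members = length(members), supporting_peptides = list(character(0)),
    n_peptides = 0L
  )
}

test_that("combined candidates follow the head-DEG join rules", {
  groups <- dplyr::bind_rows(
    make_group("p1", "p1"), make_group("p2", "p2"), make_group("p3", "p3")
  )
  calls <- tibble::tibble(
    group_id = c("p1", "p2", "p3"),
    class = c("up_in_A", "down_in_A", "none"),
    fold_change = c(3, 0.3, 1), p_value = 0.01,
    n_detected_A = 3L, n_detected_B = 3L, unquantifiable = FALSE
  )
  head_degs <- tibble::tibble(
    gene_id = c("g1", "g2"), log2fc = c(2, 2), q_value = 0.01,
    is_deg = TRUE, direction = "up_in_A"
  )
  map <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        protein_id = c("p1", "p2", "p3"),
                        exonic_length_bp = 1000L)
  cand <- combined_candidates(groups, calls, head_degs, map)
  # p3 maps to g3 which is not a DEG: no candidate (proteome-only
  # differentials never enter the combined set)
  expect_equal(cand$protein_group_id, c("p1", "p2"))
  expect_equal(cand$consistent, c(TRUE, FALSE))  # p2 contradicts: flagged
  expect_equal(cand$direction, rep("up_in_A", 2))
  expect_equal(cand$fold_change, c(4, 4))        # RNA fold change

  strict <- combined_candidates(groups, calls, head_degs, map,
                                config = effector_config(
                                  strict_consistency = TRUE
                                ))
  expect_equal(strict$protein_group_id, "p1")
})

test_that("detected-only groups are consistent and unique classes use sign", {
  groups <- make_group("p1", "p1")
  head_degs <- tibble::tibble(gene_id = "g1", log2fc = -2, q_value = 0.01,
                              is_deg = TRUE, direction = "down_in_A")
  map <- tibble::tibble(gene_id = "g1", protein_id = "p1",
                        exonic_length_bp = 1000L)
  cand <- combined_candidates(groups, NULL, head_degs, map)
  expect_equal(cand$prot_class, "detected_only")
  expect_true(cand$consistent)

  calls <- tibble::tibble(group_id = "p1", class = "unique_A",
                          fold_change = NA_real_, p_value = NA_real_,
                          n_detected_A = 3L, n_detected_B = 0L,
                          unquantifiable = FALSE)
  cand <- combined_candidates(groups, calls, head_degs, map)
  expect_false(cand$consistent)    # unique in A but RNA down in A
})

test_that("multi-gene groups expand to one flagged candidate per DEG gene", {
  groups <- make_group("p1", c("p1", "p2"))
  head_degs <- tibble::tibble(gene_id = c("g1", "g2"), log2fc = 2,
                              q_value = 0.01, is_deg = TRUE,
                              direction = "up_in_A")
  map <- tibble::tibble(gene_id = c("g1", "g2"),
                        protein_id = c("p1", "p2"),
                        exonic_length_bp = 1000L)
  cand <- combined_candidates(groups, NULL, head_degs, map)
  expect_equal(cand$gene_id, c("g1", "g2"))
  expect_true(all(cand$multi_gene))
})

test_that("candidates are contained in head DEGs joined to salivary genes", {
  sim <- simulate_effector_study(n_genes = 100, seed = 19)
  hd <- deg_test(sim$counts_head, sim$design_head)
  g <- infer_protein_groups(sim$evidence)
  q <- quantify_protein_groups(g, sim$evidence, sim$proteins,
                               sim$design_saliva)
  calls <- call_differential_proteins(q, sim$design_saliva)
  cand <- combined_candidates(g, calls, hd, sim$map)
  deg_genes <- hd$table$gene_id[hd$table$is_deg]
  salivary_genes <- sim$map$gene_id[
    sim$map$protein_id %in% unlist(g$member_protein_ids)
  ]
  expect_true(all(cand$gene_id %in% intersect(deg_genes, salivary_genes)))
})

test_that("ddct reproduces closed-form cases and is shift-invariant", {
  base <- tibble::tibble(
    sample_id = paste0("s", 1:6), biotype = rep(c("A", "B"), each = 3),
    gene_id = "g1",
    ct_target = c(20, 20, 20, 22, 22, 22), ct_reference = 18
  )
  same <- base
  same$ct_target <- 20
  r <- ddct(same)
  expect_equal(r$delta_delta_ct, 0)
  expect_equal(r$relative_expression, 1)

  r <- ddct(base)                      # ddCt = 2 - 4 = -2
  expect_equal(r$delta_delta_ct, -2)
  expect_equal(r$relative_expression, 4)

  shifted <- base
  shifted$ct_target <- base$ct_target + 5
  shifted$ct_reference <- base$ct_reference + 5
  expect_equal(ddct(shifted)$relative_expression, r$relative_expression)
})

test_that("ddct drops incomplete samples and errors below 2 replicates", {
  ct <- tibble::tibble(
    sample_id = paste0("s", 1:6), biotype = rep(c("A", "B"), each = 3),
    gene_id = "g1",
    ct_target = c(20, 20, NA, 22, 22, 22), ct_reference = 18
  )
  expect_warning(r <- ddct(ct), "dropped")
  expect_equal(r$n_A, 2L)
  ct$ct_target[c(2, 3)] <- NA
  expect_warning(expect_error(ddct(ct), "fewer than 2"))
})

test_that("a planted 2.42-fold expression difference is recovered by qPCR", {
  set.seed(77)
  ct <- simulate_ct("target", fold = 2.42, n_reps = 5, sigma_ct = 0.2)
  r <- ddct(ct)
  expect_lt(abs(r$relative_expression - 2.42) / 2.42, 0.2)
  expect_lt(r$p_value, 0.05)
})

test_that("cross-species tallies count rows, columns and shared proteins", {
  pm <- tibble::tibble(
    protein = c("a", "b", "c"),
    sp1 = c(TRUE, FALSE, FALSE),
    sp2 = c(TRUE, TRUE, FALSE)
  )
  t <- cross_species_tally(pm)
  expect_equal(t$protein_counts$n_species, c(2L, 1L, 0L))
  expect_equal(t$species_counts$n_proteins, c(1L, 2L))
  expect_equal(t$n_proteins_shared, 2)
})
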