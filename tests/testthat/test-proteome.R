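test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("MKTAYIAKQR"), c("MK", "TAYIAK", "QR"))
  expect_equal(tryptic_digest("AKPLR"), "AKPLR")     # K-P suppressed
  expect_equal(tryptic_digest("RRR"), c("R", "R", "R"))
  expect_error(tryptic_digest(""), "empty")
  # one missed cleavage adds every adjacent join
  expect_setequal(tryptic_digest("MKTAYIAKQR", missed = 1),
                  c("MK", "TAYIAK", "QR", "MKTAYIAK", "TAYIAKQR"))
})

test_that("digestion is a partition with no internal cleavage sites", {
  set.seed(23)
  for (k in 1:200) {
    s <- random_aa(sample(10:300, 1))
    peps <- tryptic_digest(s)
    expect_equal(paste(peps, collapse = ""), s)
    internal <- substr(peps, 1, nchar(peps) - 1)
    bad <- grepl("[KR](?!P)", internal, perl = TRUE)
    expect_false(any(bad))
  }
})

test_that("observable-peptide counting uses the 5-30 aa window", {
  expect_equal(count_observable_peptides("MKTAYIAKQR"), 1)  # only TAYIAK
  expect_equal(count_observable_peptides(strrep("K", 12)), 0)
  expect_equal(count_observable_peptides(strrep("A", 40)), 0) # 40-mer > 30
  expect_equal(count_observable_peptides(strrep("A", 25)), 1)
})

test_that("LFQ is intensity over observable count with missing preserved", {
  expect_equal(compute_lfq(c(1e6, NA, 2e6), 4), c(2.5e5, NA, 5e5))
  expect_true(all(is.na(compute_lfq(c(1e6, 2e6), 0))))
})

test_that("parsimony grouping merges subsets and identical sets", {
  ev <- tibble::tibble(
    peptide = c("AAAAAAAK", "CCCCCCCK"),
    protein_ids = c("pA;pB", "pA"),
    s1 = c(1, 1)
  )
  g <- infer_protein_groups(ev)
  expect_equal(nrow(g), 1)
  expect_equal(g$group_id, "pA")
  expect_equal(g$member_protein_ids[[1]], c("pA", "pB"))
  expect_equal(g$n_peptides, 2L)

  ev2 <- tibble::tibble(
    peptide = c("AAAAAAAK", "CCCCCCCK"),
    protein_ids = c("pA", "pB"), s1 = c(1, 1)
  )
  expect_equal(nrow(infer_protein_groups(ev2)), 2)

  # identical peptide sets: 2 proteins, 1 group (the 177-in-105 structure)
  ev3 <- tibble::tibble(
    peptide = c("AAAAAAAK", "CCCCCCCK"),
    protein_ids = c("pA;pB", "pA;pB"), s1 = c(1, 1)
  )
  g3 <- infer_protein_groups(ev3)
  expect_equal(nrow(g3), 1)
  expect_equal(g3$n_members, 2L)
})

test_that("razor peptides go to the group with the most evidence", {
  ev <- tibble::tibble(
    peptide = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK", "EEEEEEEK", "FFFFFFFK"),
    protein_ids = c("pA", "pA", "pA;pB", "pB", "pB"),
    s1 = 1
  )
  g <- infer_protein_groups(ev)
  expect_equal(nrow(g), 2)
  a <- g[g$group_id == "pA", ]
  # pA and pB both explain 3 peptides; the tie goes to the smaller accession
  expect_true("DDDDDDDK" %in% a$supporting_peptides[[1]])
  # every peptide quantifies exactly one group
  expect_equal(sort(unlist(g$supporting_peptides)), sort(ev$peptide))
})

test_that("sub-identification-length peptides are ignored", {
  ev <- tibble::tibble(
    peptide = c("AAAK", "CCCCCCCK"),
    protein_ids = c("pA", "pA"), s1 = 1
  )
  g <- infer_protein_groups(ev)
  expect_equal(g$n_peptides, 1L)
})

test_that("grouping is order-invariant and idempotent in structure", {
  sim <- simulate_effector_study(n_genes = 60, seed = 12)
  g1 <- infer_protein_groups(sim$evidence)
  perm <- sim$evidence[sample.int(nrow(sim$evidence)), ]
  g2 <- infer_protein_groups(perm)
  expect_equal(g1$group_id, g2$group_id)
  expect_equal(g1$member_protein_ids, g2$member_protein_ids)
  expect_equal(g1$supporting_peptides, g2$supporting_peptides)
  # group count <= protein count; members >= groups
  n_prot <- length(unique(unlist(strsplit(sim$evidence$protein_ids, ";"))))
  expect_lte(nrow(g1), n_prot)
  expect_gte(sum(g1$n_members), nrow(g1))
})

test_that("differential calling applies the unique and OR rules", {
  design <- two_group_design(3, tissue = "saliva")
  quant <- tibble::tibble(
    group_id = c("p1", "p2", "p3"),
    sA1 = c(4, 10, 5), sA2 = c(4, 12, 5), sA3 = c(4, 11, 5),
    sB1 = c(1, NA, 5), sB2 = c(1, NA, 5), sB3 = c(1, NA, 5),
    unquantifiable = FALSE
  )
  calls <- call_differential_proteins(quant, design)
  expect_equal(calls$class, c("up_in_A", "unique_A", "none"))
  expect_equal(calls$fold_change[1], 4)
  expect_equal(calls$n_detected_B[2], 0)
})

test_that("unquantifiable groups are never classified", {
  design <- two_group_design(2, tissue = "saliva")
  quant <- tibble::tibble(
    group_id = "p1", sA1 = 9, sA2 = 9, sB1 = 1, sB2 = 1,
    unquantifiable = TRUE
  )
  calls <- call_differential_proteins(quant, design)
  expect_equal(calls$class, "none")
  expect_true(calls$unquantifiable)
})

test_that("the literal OR rule is at least as permissive as AND", {
  sim <- simulate_effector_study(n_genes = 120, seed = 9)
  g <- infer_protein_groups(sim$evidence)
  q <- quantify_protein_groups(g, sim$evidence, sim$proteins,
                               sim$design_saliva)
  or_calls <- call_differential_proteins(q, sim$design_saliva,
                                         effector_config(prot_rule = "or"))
  and_calls <- call_differential_proteins(q, sim$design_saliva,
                                          effector_config(prot_rule = "and"))
  or_set <- or_calls$group_id[or_calls$class != "none"]
  and_set <- and_calls$group_id[and_calls$class != "none"]
  expect_true(all(and_set %in% or_set))
})

test_that("planted unique and differential proteins are recovered", {
  sim <- simulate_effector_study(n_genes = 150, n_reps = 3, seed = 14,
                                 prot_fc = 4)
  g <- infer_protein_groups(sim$evidence)
  q <- quantify_protein_groups(g, sim$evidence, sim$proteins,
                               sim$design_saliva)
  # AND mode: sensitivity on planted classes, low false positives on nulls
  calls <- call_differential_proteins(q, sim$design_saliva,
                                      effector_config(prot_rule = "and"))
  planted <- c(sim$truth$unique_proteins$protein_id,
               sim$truth$differential_proteins$protein_id)
  called <- calls$group_id[calls$class != "none"]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.9)
  null_groups <- setdiff(calls$group_id,
                         c(planted, sim$truth$planted_effectors))
  fp <- intersect(called, null_groups)
  expect_lte(length(fp) / max(length(null_groups), 1), 0.1)
  # unique calls land on the correct side
  uq <- calls[calls$group_id %in% sim$truth$unique_proteins$protein_id, ]
  side <- sim$truth$unique_proteins$biotype[
    match(uq$group_id, sim$truth$unique_proteins$protein_id)
  ]
  expect_true(all(uq$class == paste0("unique_", side)))
})
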