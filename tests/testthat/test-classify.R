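test_that("signature membership applies the padj and fold-change gates", {
  ct <- fake_contrast(
    paste0("g", 1:6),
    log2fc = c(1.0, 1.0, 0.5, -1.0, 2.0, 1.0),
    pvalue = c(1e-4, NA, 1e-5, 1e-4, 1e-4, 1e-4),
    tested = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  # overwrite padj directly to probe the gates
  ct$padj <- c(0.04, NA, 0.001, 0.01, 0.05, 0.8)
  sig <- define_age_signature(ct, alpha_adj = 0.05, fc_threshold = 1.5,
                              base_mean_min = 0)
  # g1: in, increased; g2: untested; g3: fold 1.41 fails the gate;
  # g4: in, decreased; g5: padj == 0.05 exactly fails the strict gate;
  # g6: padj too large
  expect_identical(sig$gene_id, c("g1", "g4"))
  expect_identical(sig$direction, c("increased", "decreased"))

  # baseMean prefilter
  ct2 <- fake_contrast(c("lo", "hi"), c(1, 1), c(1e-5, 1e-5),
                       base_mean = c(5, 50))
  sig2 <- define_age_signature(ct2, base_mean_min = 10)
  expect_identical(sig2$gene_id, "hi")

  expect_error(define_age_signature(ct, alpha_adj = 1), "alpha_adj")
  expect_error(define_age_signature(ct, fc_threshold = 1), "fc_threshold")
})

test_that("reversal calls reproduce the worked decision examples", {
  sig <- fake_signature(paste0("g", 1:4), c(1, 1, 1, -1))
  rva <- fake_contrast(
    paste0("g", 1:4),
    log2fc = c(-0.9, -0.5, 0.8, 0.2),
    pvalue = c(0.01, 0.02, 0.03, 0.30)
  )
  rvad <- fake_contrast(
    paste0("g", 1:4),
    log2fc = c(0.1, 0.5, 1.0, -0.8),
    pvalue = c(0.40, 0.01, 0.20, 0.01)
  )
  cls <- classify_reversal(sig, rva, rvad, alpha = 0.05)
  expect_identical(
    cls$category,
    c("reversed", "partially_reversed", "exacerbated", "unaffected")
  )
})

test_that("classifier output equals an independent truth table on a grid", {
  # independently coded reading of the published decision criteria
  oracle <- function(age_sign, rva_sign, p_rva, p_rvad, alpha = 0.05) {
    moved <- p_rva < alpha
    if (!moved) return("unaffected")
    if (rva_sign == age_sign) return("exacerbated")
    if (p_rvad >= alpha) return("reversed")
    "partially_reversed"
  }
  grid <- expand.grid(
    age_sign = c(1, -1), rva_sign = c(1, -1),
    p_rva = c(0.01, 0.049, 0.05, 0.5),
    p_rvad = c(0.01, 0.049, 0.05, 0.5)
  )
  genes <- sprintf("g%02d", seq_len(nrow(grid)))
  sig <- fake_signature(genes, grid$age_sign)
  rva <- fake_contrast(genes, 0.8 * grid$rva_sign, grid$p_rva)
  rvad <- fake_contrast(genes, 0.4 * grid$age_sign, grid$p_rvad)
  cls <- classify_reversal(sig, rva, rvad, alpha = 0.05)
  expected <- mapply(oracle, grid$age_sign, grid$rva_sign,
                     grid$p_rva, grid$p_rvad)
  expect_identical(cls$category, unname(expected))

  # boundary convention: p = 0.05 fails "P < 0.05", satisfies "P >= 0.05"
  at_boundary <- grid$p_rva == 0.05
  expect_true(all(cls$category[at_boundary] == "unaffected"))
  toward_adult <- grid$p_rva < 0.05 & grid$rva_sign != grid$age_sign
  expect_true(all(
    cls$category[toward_adult & grid$p_rvad == 0.05] == "reversed"
  ))
})

test_that("degenerate and missing classification inputs fall to unaffected", {
  sig <- fake_signature(c("g1", "g2", "g3"), c(1, 1, -1))
  # g1: zero repop log2fc despite small p; g2 missing from rva entirely;
  # g3 untested in rvad when step 3 is reached
  rva <- fake_contrast(c("g1", "g3"), c(0, 0.9), c(0.01, 0.01))
  rvad <- fake_contrast(c("g1", "g2", "g3"), c(0, 0, 0.5),
                        c(0.5, 0.5, NA), tested = c(TRUE, TRUE, FALSE))
  expect_warning(
    cls <- classify_reversal(sig, rva, rvad),
    "untested"
  )
  expect_identical(cls$category, c("unaffected", "unaffected", "unaffected"))
})

test_that("tightening alpha moves calls toward unaffected, never the reverse", {
  set.seed(31)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  age_sign <- sample(c(1, -1), n, TRUE)
  sig <- fake_signature(genes, age_sign)
  rva <- fake_contrast(genes, runif(n, -1, 1), runif(n))
  rvad <- fake_contrast(genes, runif(n, -1, 1), runif(n))
  loose <- classify_reversal(sig, rva, rvad, alpha = 0.05)$category
  tight <- classify_reversal(sig, rva, rvad, alpha = 0.01)$category

  expect_true(all(tight[loose == "unaffected"] == "unaffected"))
  expect_true(all(loose[tight == "exacerbated"] == "exacerbated"))
  # a gene reversed at the loose level can only stay or lose significance
  expect_true(all(tight[loose == "reversed"] %in%
                    c("reversed", "unaffected")))
})

test_that("reversal categories partition the signature", {
  cfg <- sim_config(n_genes = 300, category_counts = c(
    null = 200, up_reversed = 25, up_partial = 25, up_exacerbated = 25,
    down_unaffected = 25
  ), seed = 32)
  sim <- simulate_reversal_experiment(cfg)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sim$design, sf)
  cts <- repopsig:::reversal_contrasts(sim$counts, sim$design, sf, disp)
  sig <- define_age_signature(cts$age)
  cls <- classify_reversal(sig, cts$repop_vs_aged, cts$repop_vs_adult)
  expect_identical(sort(cls$gene_id), sort(sig$gene_id))
  smry <- summarize_categories(cls)
  expect_identical(sum(smry$n), nrow(sig))
  expect_true(all(cls$category %in%
    c("reversed", "partially_reversed", "exacerbated", "unaffected")))
})

test_that("LPS calls reproduce the worked taxonomy examples", {
  genes <- paste0("g", 1:4)
  adult <- fake_contrast(genes, c(1.2, 0.2, 0.3, 0.1),
                         c(0.01, 0.60, 0.70, 0.9))
  aged <- fake_contrast(genes, c(1.8, 1.5, 1.4, 0.2),
                        c(0.001, 0.003, 0.002, 0.8))
  ava <- fake_contrast(genes, c(0.8, 1.2, 1.0, 0.1),
                       c(0.02, 0.01, 0.04, 0.7))
  repop <- fake_contrast(genes, c(1.5, 1.4, 0.1, 0.1),
                         c(0.01, 0.01, 0.70, 0.9))
  cls <- classify_lps_response(adult, aged, ava, repop, alpha = 0.05)
  expect_identical(
    cls$category,
    c("exacerbated_by_age", "unique_to_aged", "unique_to_aged",
      "nonresponsive")
  )
  # only the aged-responsive gene whose repop induction failed is flagged
  expect_identical(cls$prevented_by_repop, c(FALSE, FALSE, TRUE, FALSE))

  expect_error(
    classify_lps_response(adult, aged, NULL, repop),
    "aged_vs_adult_lps"
  )
})

test_that("adult-only induction is kept apart from age-dependent classes", {
  genes <- c("adult_only_gene", "both_no_exacerbation")
  adult <- fake_contrast(genes, c(1.5, 1.2), c(0.001, 0.01))
  aged <- fake_contrast(genes, c(0.1, 1.2), c(0.9, 0.01))
  ava <- fake_contrast(genes, c(-1.2, 0.0), c(0.01, 0.99))
  repop <- fake_contrast(genes, c(0.1, 1.2), c(0.9, 0.01))
  cls <- classify_lps_response(adult, aged, ava, repop)
  expect_identical(cls$category, c("adult_only", "adult_only"))
  expect_false(any(cls$prevented_by_repop))
})

test_that("category summaries count every gene exactly once", {
  sig <- fake_signature(paste0("g", 1:10), rep(c(1, -1), 5))
  rva <- fake_contrast(paste0("g", 1:10), -rep(c(1, -1), 5),
                       rep(0.01, 10))
  rvad <- fake_contrast(paste0("g", 1:10), rep(0, 10), rep(0.5, 10))
  cls <- classify_reversal(sig, rva, rvad)
  expect_true(all(cls$category == "reversed"))
  smry <- summarize_categories(cls)
  expect_identical(sum(smry$n), 10L)
  expect_identical(smry$n[smry$category == "reversed"], c(5L, 5L))
  expect_error(summarize_categories(cls[0, ]), "Empty")
})
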