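test_that("a gene with identical counts in both groups is exactly null", {
  counts <- count_tbl(tibble::tibble(
    gene_id = "g1", a1 = 5, a2 = 7, a3 = 6, b1 = 5, b2 = 7, b3 = 6
  ))
  design <- repopsig:::as_sample_key(tibble::tibble(
    sample_id = sample_ids(counts),
    age = rep(c("adult", "aged"), each = 3), treatment = "control"
  ))
  res <- fit_contrast(counts, design, "age", "aged", "adult",
                      size_factors = unit_size_factors(counts),
                      dispersions = 0.1)
  expect_equal(res$log2fc, 0, tolerance = 1e-10)
  expect_equal(res$pvalue, 1, tolerance = 1e-10)
})

test_that("the dispersion -> 0 limit matches an independent Poisson GLM", {
  counts <- count_tbl(tibble::tibble(
    gene_id = paste0("g", 1:4),
    a1 = c(5, 40, 12, 3), a2 = c(8, 35, 15, 1),
    a3 = c(6, 50, 9, 2), a4 = c(7, 42, 11, 4),
    b1 = c(12, 20, 30, 6), b2 = c(9, 25, 28, 8),
    b3 = c(14, 22, 35, 5), b4 = c(11, 18, 33, 7)
  ))
  design <- make_two_group_design(counts)
  res <- fit_contrast(counts, design, "age", "aged", "adult",
                      size_factors = unit_size_factors(counts),
                      dispersions = rep(1e-12, 4))
  m <- as.matrix(counts[-1])
  grp <- rep(c(0, 1), each = 4)
  for (g in 1:4) {
    fit <- stats::glm(m[g, ] ~ grp, family = stats::poisson(),
                      control = stats::glm.control(epsilon = 1e-14))
    co <- summary(fit)$coefficients[2, ]
    expect_equal(res$log2fc[g] * log(2), unname(co[1]), tolerance = 1e-6)
    expect_equal(res$lfc_se[g] * log(2), unname(co[2]), tolerance = 1e-6)
    expect_equal(res$pvalue[g], 2 * pnorm(-abs(unname(co[3]))),
                 tolerance = 1e-6)
  }
})

test_that("swapping numerator and denominator negates the statistic", {
  counts <- make_counts(n_genes = 30, n_samples = 12, seed = 21, mean = 60)
  design <- make_two_group_design(counts)
  sf <- estimate_size_factors(counts)
  fwd <- fit_contrast(counts, design, "age", "aged", "adult",
                      size_factors = sf, dispersions = 0.05)
  rev <- fit_contrast(counts, design, "age", "adult", "aged",
                      size_factors = sf, dispersions = 0.05)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-10)
  expect_equal(fwd$stat, -rev$stat, tolerance = 1e-10)
  expect_equal(fwd$pvalue, rev$pvalue, tolerance = 1e-10)
})

test_that("size-factor normalization absorbs library-scale changes", {
  counts <- make_counts(n_genes = 40, n_samples = 8, seed = 22, mean = 50)
  design <- make_two_group_design(counts)
  sf <- estimate_size_factors(counts)
  base <- fit_contrast(counts, design, "age", "aged", "adult",
                       size_factors = sf, dispersions = 0.05)

  # scaling one sample's counts by c scales its factor by c relative to
  # every other sample's (the geometric-mean reference shifts all factors
  # by a common c^(1/n), which the GLM intercept absorbs)
  scaled <- counts
  scaled[[2]] <- scaled[[2]] * 3
  sf_scaled <- estimate_size_factors(scaled)
  rel <- unname(sf_scaled / sf)
  expect_equal(rel[1] / rel[2], 3, tolerance = 1e-12)
  expect_equal(rel[-1], rep(rel[2], 7), tolerance = 1e-12)
  # its normalized column is unchanged
  expect_equal(
    normalize_counts(scaled, sf_scaled)[[2]] * rel[2],
    normalize_counts(counts, sf)[[2]],
    tolerance = 1e-12
  )

  # rescaling all size factors by a common constant leaves every
  # downstream statistic unchanged
  res <- fit_contrast(counts, design, "age", "aged", "adult",
                      size_factors = sf * 2.7, dispersions = 0.05)
  expect_equal(res$log2fc, base$log2fc, tolerance = 1e-8)
  expect_equal(res$stat, base$stat, tolerance = 1e-8)
  expect_equal(res$pvalue, base$pvalue, tolerance = 1e-8)
})

test_that("a planted 4-fold age effect is detected in nearly every draw", {
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_genes = 1, n_per_group = 6,
      category_counts = c(up_unaffected = 1),
      age_lfc_magnitude = c(2, 2), dispersion = 0.05,
      baseline_mean_range = c(100, 100), libsize_sd = 0, seed = 1000 + s
    )
    sim <- simulate_reversal_experiment(cfg)
    res <- fit_contrast(sim$counts, sim$design, "group",
                        "aged_control", "adult_control",
                        size_factors = unit_size_factors(sim$counts),
                        dispersions = 0.05)
    if (isTRUE(res$pvalue < 1e-4)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("untested genes are flagged, not dropped, and excluded from BH", {
  counts <- make_counts(n_genes = 6, n_samples = 6, seed = 23)
  counts[2, -1] <- as.list(rep(0, 6)) # all-zero: untested
  counts[4, 2:4] <- as.list(rep(0, 3)) # one side all-zero: untested
  design <- make_two_group_design(counts)
  res <- fit_contrast(counts, design, "age", "aged", "adult",
                      size_factors = unit_size_factors(counts),
                      dispersions = 0.1)
  expect_identical(nrow(res), 6L)
  expect_false(res$tested[2])
  expect_false(res$tested[4])
  expect_true(all(is.na(res$pvalue[!res$tested])))
  expect_true(all(is.na(res$padj[!res$tested])))
  expect_equal(res$padj[res$tested],
               adjust_bh(res$pvalue[res$tested]))
  expect_true(all(res$padj >= res$pvalue, na.rm = TRUE))
})

test_that("stratum filtering and covariates are honoured", {
  cfg <- sim_config(arm = "lps", n_genes = 50,
                    category_counts = c(null = 40, lps_aged_unique = 10),
                    seed = 24)
  sim <- simulate_lps_experiment(cfg)
  res <- fit_contrast(sim$counts, sim$design, "stimulus", "lps", "saline",
                      stratum = c(group = "aged_control"),
                      size_factors = estimate_size_factors(sim$counts),
                      dispersions = 0.05)
  ct <- attr(res, "contrast")
  expect_identical(ct$n_numerator, 6L)
  expect_identical(ct$n_denominator, 6L)

  # a constant covariate is collinear with the intercept
  design <- sim$design
  design$flat <- 1
  expect_error(
    fit_contrast(sim$counts, design, "stimulus", "lps", "saline",
                 covariates = "flat",
                 size_factors = estimate_size_factors(sim$counts),
                 dispersions = 0.05),
    "collinear"
  )

  expect_error(
    fit_contrast(sim$counts, sim$design, "stimulus", "lps", "saline",
                 stratum = c(group = "nonexistent"),
                 size_factors = estimate_size_factors(sim$counts),
                 dispersions = 0.05),
    "absent"
  )
})

test_that("raw p-values are near-uniform when nothing is planted", {
  cfg <- sim_config(arm = "lps", n_genes = 2000,
                    category_counts = c(null = 2000),
                    dispersion = 0.1, seed = 25)
  sim <- simulate_lps_experiment(cfg)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sim$design, sf)
  res <- fit_contrast(sim$counts, sim$design, "stimulus", "lps", "saline",
                      stratum = c(group = "aged_control"),
                      size_factors = sf, dispersions = disp)
  p <- res$pvalue[res$tested]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  # 1% critical value of the KS statistic at n ~ 2000
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(p)))
})
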