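#' Evaluate recovery of planted truth
#'
#' Compares a reversal classification against the simulator's truth table:
#' a confusion matrix of planted vs called categories, per-category recall
#' and precision, signature-level sensitivity/specificity, and the
#' empirical false discovery rate of the signature (planted-null genes in
#' the signature over signature size). Per-category precision is computed
#' among genes genuinely planted in the signature, so cross-category
#' confusion (classifier error) is kept separate from signature false
#' positives (DE-engine error).
#'
#' @param truth Truth tibble from [simulate_reversal_experiment()].
#' @param classification A `reversal_classification` covering the
#'   signature; its gene set defines the called signature.
#' @param contrasts Optional named list of `contrast_result` objects whose
#'   raw-p calibration (fraction of tested genes with p < `alpha`) is
#'   reported.
#' @param alpha Cutoff used for the calibration summary.
#' @return A `recovery_report` list: `confusion`, `per_category`,
#'   `signature` (one row) and `calibration` tibbles.
#' @export
evaluate_recovery <- function(truth, classification, contrasts = NULL,
                              alpha = 0.05) {
  extra <- setdiff(classification$gene_id, truth$gene_id)
  if (length(extra) > 0) {
    abort(paste0(
      "Gene universe mismatch: classified gene(s) absent from the truth: ",
      toString(head(extra, 5))
    ))
  }
  planted <- truth |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      planted = collapse_category(.data$category)
    )
  called <- classification |>
    dplyr::select("gene_id", called = "category")
  joined <- planted |>
    dplyr::left_join(called, by = "gene_id") |>
    dplyr::mutate(called = dplyr::coalesce(.data$called, "not_called"))

  confusion <- joined |>
    dplyr::count(.data$planted, .data$called) |>
    tidyr::complete(
      planted = c(reversal_category_levels, "null"),
      called = c(reversal_category_levels, "not_called"),
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(
      match(.data$planted, c(reversal_category_levels, "null")),
      match(.data$called, c(reversal_category_levels, "not_called"))
    )

  in_sig_truth <- joined$planted != "null"
  in_sig_call <- joined$called != "not_called"
  per_category <- purrr::map_dfr(reversal_category_levels, function(cat) {
    n_planted <- sum(joined$planted == cat)
    n_called_sig <- sum(in_sig_truth & joined$called == cat)
    correct <- sum(joined$planted == cat & joined$called == cat)
    tibble::tibble(
      category = cat,
      n_planted = n_planted,
      recall = if (n_planted > 0) correct / n_planted else NA_real_,
      precision = if (n_called_sig > 0) correct / n_called_sig else NA_real_
    )
  })

  sig_size <- sum(in_sig_call)
  false_members <- sum(!in_sig_truth & in_sig_call)
  signature <- tibble::tibble(
    n_planted = sum(in_sig_truth),
    n_called = sig_size,
    sensitivity = if (any(in_sig_truth)) {
      sum(in_sig_truth & in_sig_call) / sum(in_sig_truth)
    } else {
      NA_real_
    },
    specificity = if (any(!in_sig_truth)) {
      sum(!in_sig_truth & !in_sig_call) / sum(!in_sig_truth)
    } else {
      NA_real_
    },
    empirical_fdr = false_members / max(1, sig_size)
  )

  calibration <- purrr::imap_dfr(contrasts %||% list(), function(ct, nm) {
    p <- ct$pvalue[ct$tested]
    tibble::tibble(
      contrast = nm, n_tested = length(p),
      frac_p_below = mean(p < alpha)
    )
  })

  structure(
    list(
      confusion = confusion, per_category = per_category,
      signature = signature, calibration = calibration, alpha = alpha
    ),
    class = "recovery_report"
  )
}

collapse_category <- function(category) {
  dplyr::case_when(
    category == "null" ~ "null",
    endsWith(category, "reversed") ~ "reversed",
    endsWith(category, "partial") ~ "partially_reversed",
    endsWith(category, "exacerbated") ~ "exacerbated",
    endsWith(category, "unaffected") ~ "unaffected",
    .default = category
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report\n")
  cat("  signature: planted", x$signature$n_planted,
      "| called", x$signature$n_called,
      "| sensitivity", signif(x$signature$sensitivity, 3),
      "| empirical FDR", signif(x$signature$empirical_fdr, 3), "\n")
  cat("  per-category recall:\n")
  for (i in seq_len(nrow(x$per_category))) {
    cat(sprintf(
      "    %-20s %s\n", x$per_category$category[i],
      signif(x$per_category$recall[i], 3)
    ))
  }
  invisible(x)
}

#' Null calibration of the DE engine
#'
#' Repeatedly simulates an all-null factorial experiment (no planted
#' effects), runs the three reversal contrasts, and records the fraction of
#' raw p-values below `alpha` and the size of the resulting age signature.
#' Under a calibrated engine the p fractions sit near `alpha` and the
#' signature stays essentially empty. Replicate `r` uses seed
#' `config$seed + r`, recorded in the output so failures are re-runnable.
#'
#' @param n_reps Number of replicates (0 gives an empty summary).
#' @param config A [sim_config()]; its `category_counts` must be all null.
#' @param alpha Raw-p threshold for the calibration fraction.
#' @return A `null_calibration` tibble: one row per replicate x contrast
#'   with `rep`, `seed`, `contrast`, `n_tested`, `frac_p_below`,
#'   `signature_size`. [glance()] averages over replicates.
#' @export
null_calibration <- function(n_reps, config = NULL, alpha = 0.05) {
  if (is.null(config)) {
    config <- sim_config(
      n_genes = 2000,
      category_counts = c(null = 2000),
      dispersion = 0.1
    )
  }
  if (any(config$category_counts[names(config$category_counts) != "null"] > 0)) {
    abort("null_calibration needs an all-null config.")
  }
  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_reversal_experiment(cfg)
    sf <- estimate_size_factors(sim$counts)
    disp <- estimate_dispersions(sim$counts, sim$design, sf)
    cts <- reversal_contrasts(sim$counts, sim$design, sf, disp)
    sig <- define_age_signature(cts$age)
    purrr::imap_dfr(cts, function(ct, nm) {
      p <- ct$pvalue[ct$tested]
      tibble::tibble(
        rep = r, seed = cfg$seed, contrast = nm,
        n_tested = length(p), frac_p_below = mean(p < alpha),
        signature_size = nrow(sig)
      )
    })
  })
  if (n_reps == 0) {
    rows <- tibble::tibble(
      rep = integer(), seed = integer(), contrast = character(),
      n_tested = integer(), frac_p_below = double(),
      signature_size = integer()
    )
  }
  structure(
    rows,
    class = c("null_calibration", class(tibble::tibble())),
    alpha = alpha
  )
}

# The three standard contrasts of the reversal design.
reversal_contrasts <- function(counts, design, size_factors, dispersions,
                               covariates = NULL) {
  defs <- list(
    age = c("aged_control", "adult_control"),
    repop_vs_aged = c("aged_repopulation", "aged_control"),
    repop_vs_adult = c("aged_repopulation", "adult_control")
  )
  purrr::map(defs, function(s) {
    fit_contrast(
      counts, design,
      factor = "group", numerator = s[1], denominator = s[2],
      covariates = covariates,
      size_factors = size_factors, dispersions = dispersions
    )
  })
}
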