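#' Negative-binomial Wald test for one contrast
#'
#' Fits, gene by gene, a negative-binomial GLM with log link and log size
#' factors as offsets on the samples belonging to the two contrast levels
#' (after optional stratum filtering), and tests the level coefficient with
#' a Wald test: `stat = coef / SE` (standard error from the observed
#' information), two-sided p-value against the standard normal. `log2fc` is
#' the coefficient for `numerator` over `denominator` on the log2 scale.
#' `base_mean` is the mean of normalized counts across *all* samples of the
#' table. Genes are tested when `base_mean > 0` and each contrast side has
#' at least one nonzero count; untested genes (including the rare
#' non-converged fit) carry `NA` statistics. `padj` is the
#' Benjamini-Hochberg adjustment over tested genes only.
#'
#' @param counts A [count_tbl()]. Raw counts are the expected input; for
#'   tables already normalized upstream, pass `size_factors = 1` semantics
#'   by supplying a vector of ones (the pipeline runners do this when
#'   `scale = "normalized"`).
#' @param design Sample key covering the count columns.
#' @param factor Name of the design column to contrast (e.g. `"group"`,
#'   `"stimulus"`).
#' @param numerator,denominator Levels of `factor` being compared
#'   (numerator over denominator).
#' @param stratum Optional named character vector fixing levels of other
#'   design columns before the comparison, e.g.
#'   `c(group = "adult_control")` to test LPS within adult controls.
#' @param covariates Optional names of numeric design columns to adjust for.
#' @param size_factors Optional per-sample size factors (estimated from the
#'   raw counts when `NULL`).
#' @param dispersions Optional per-gene dispersions (estimated via
#'   [estimate_dispersions()] when `NULL`).
#' @return A `contrast_result` tibble: `gene_id`, `base_mean`, `log2fc`,
#'   `lfc_se`, `stat`, `pvalue`, `padj`, `tested`; the contrast definition
#'   is carried in attributes and surfaced by [glance()].
#' @export
fit_contrast <- function(counts, design, factor, numerator, denominator,
                         stratum = NULL, covariates = NULL,
                         size_factors = NULL, dispersions = NULL) {
  stopifnot(inherits(counts, "count_tbl"))
  if (identical(numerator, denominator)) {
    abort("numerator and denominator must differ.")
  }
  samples <- sample_ids(counts)
  design <- align_design(design, samples)
  if (!factor %in% names(design)) {
    abort(paste0("Design has no column '", factor, "'."))
  }
  if (is.null(size_factors)) {
    size_factors <- if (count_scale(counts) == "raw") {
      estimate_size_factors(counts)
    } else {
      setNames(rep(1, length(samples)), samples)
    }
  }
  if (is.null(names(size_factors))) names(size_factors) <- samples
  size_factors <- size_factors[samples]
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, design, size_factors)
  }
  dispersions <- rep_len(dispersions, nrow(counts))

  keep <- rep(TRUE, nrow(design))
  for (nm in names(stratum)) {
    if (!nm %in% names(design)) {
      abort(paste0("Stratum column '", nm, "' not in the design."))
    }
    keep <- keep & design[[nm]] == stratum[[nm]]
  }
  lev <- design[[factor]]
  missing_lev <- setdiff(c(numerator, denominator), unique(lev[keep]))
  if (length(missing_lev) > 0) {
    abort(paste0(
      "Level(s) ", toString(sQuote(missing_lev)), " of '", factor,
      "' absent after stratum filtering."
    ))
  }
  use <- keep & lev %in% c(numerator, denominator)

  m_all <- count_matrix(counts)
  base_mean <- rowMeans(sweep(m_all, 2, size_factors, "/"))
  m <- m_all[, use, drop = FALSE]
  sf <- size_factors[use]
  is_num <- lev[use] == numerator

  X <- matrix(1, nrow = sum(use), ncol = 1,
              dimnames = list(NULL, "intercept"))
  for (cv in covariates) {
    if (!cv %in% names(design)) {
      abort(paste0("Covariate '", cv, "' not in the design."))
    }
    X <- cbind(X, as.numeric(design[[cv]][use]))
    colnames(X)[ncol(X)] <- cv
  }
  X <- cbind(X, level = as.numeric(is_num))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("Singular design; collinear column(s): ", toString(drop)))
  }

  tested <- base_mean > 0 &
    rowSums(m[, is_num, drop = FALSE] > 0) >= 1 &
    rowSums(m[, !is_num, drop = FALSE] > 0) >= 1

  n_genes <- nrow(m)
  log2fc <- lfc_se <- stat <- pvalue <- rep(NA_real_, n_genes)
  if (any(tested)) {
    fit <- nb_glm_fit(
      m[tested, , drop = FALSE], X, log(sf),
      pmax(dispersions[tested], 1e-12),
      tol = 1e-8, maxit = 100L
    )
    conv <- fit$converged == 1L
    p <- ncol(X)
    b <- fit$beta[, p]
    s <- fit$se[, p]
    idx <- which(tested)
    ok <- idx[conv]
    log2fc[ok] <- b[conv] / log(2)
    lfc_se[ok] <- s[conv] / log(2)
    stat[ok] <- b[conv] / s[conv]
    pvalue[ok] <- 2 * pnorm(-abs(stat[ok]))
    tested[idx[!conv]] <- FALSE
  }

  out <- tibble::tibble(
    gene_id = counts$gene_id,
    base_mean = unname(base_mean),
    log2fc = log2fc,
    lfc_se = lfc_se,
    stat = stat,
    pvalue = pvalue,
    padj = adjust_bh(pvalue),
    tested = tested
  )
  structure(
    out,
    class = c("contrast_result", class(out)),
    contrast = list(
      factor = factor, numerator = numerator, denominator = denominator,
      stratum = stratum, covariates = covariates,
      n_numerator = sum(is_num), n_denominator = sum(!is_num)
    )
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values `padj_i = min_{j >= rank_i} m * p_(j) / j`, capped at 1,
#' where `m` counts the non-missing entries (the testing family). Missing
#' values pass through untouched and do not enter `m`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, possibly with `NA`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_bh <- function(pvalues) {
  obs <- !is.na(pvalues)
  p <- pvalues[obs]
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(pvalues))
  m <- length(p)
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
    out[obs][o] <- adj
  }
  out
}

#' Comparative-CT fold changes
#'
#' The delta-delta-CT method: per sample,
#' `dCT = ct_target - ct_reference`, `ddCT = dCT - mean(dCT | control group)`
#' (arithmetic mean), and `fold_change = 2^-ddCT`, expressing each sample's
#' target expression relative to the control group. The mean log2 fold
#' change within the control group is 0 by construction.
#'
#' @param table A tibble with `sample_id`, `group`, `ct_target`,
#'   `ct_reference` (see [read_ddct_table()]).
#' @param control_group Label of the reference group.
#' @return The input with `delta_ct`, `delta_delta_ct` and `fold_change`
#'   columns appended.
#' @examples
#' tbl <- simulate_ddct_table(4, delta_ct_control = 5, delta_delta_ct = -2)
#' ddct_fold_change(tbl, "control")
#' @export
ddct_fold_change <- function(table, control_group) {
  required <- c("sample_id", "group", "ct_target", "ct_reference")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", toString(missing)))
  }
  if (!any(table$group == control_group)) {
    abort(paste0("Control group '", control_group, "' is empty."))
  }
  dct <- table$ct_target - table$ct_reference
  ddct <- dct - mean(dct[table$group == control_group])
  dplyr::mutate(
    tibble::as_tibble(table),
    delta_ct = dct, delta_delta_ct = ddct, fold_change = 2^(-ddct)
  )
}
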