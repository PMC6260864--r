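#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making libraries comparable: each sample's
#' factor is the median, over reference genes, of the ratio of its count to
#' the gene's geometric mean across samples. Reference genes are those with
#' no zero count in any sample; appending all-zero (or any zero-containing)
#' genes therefore leaves the factors unchanged. When no zero-free gene
#' exists, set `pseudo_reference = TRUE` to fall back to geometric means
#' computed over the positive counts of each gene.
#'
#' @param counts A raw-scale [count_tbl()].
#' @param pseudo_reference Use the positive-count fallback when no gene is
#'   zero-free.
#' @return A named numeric vector of positive size factors, one per sample.
#' @examples
#' counts <- count_tbl(tibble::tibble(
#'   gene_id = c("g1", "g2"), s1 = c(10, 20), s2 = c(20, 40)
#' ))
#' estimate_size_factors(counts) # c(1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(inherits(counts, "count_tbl"))
  if (count_scale(counts) != "raw") {
    abort("Size factors are estimated from raw counts.")
  }
  m <- count_matrix(counts)
  logm <- log(m)
  if (pseudo_reference) {
    loggeo <- apply(logm, 1, function(r) mean(r[is.finite(r)]))
    ref <- is.finite(loggeo)
  } else {
    ref <- rowSums(m > 0) == ncol(m)
    if (!any(ref)) {
      abort(paste0(
        "No gene has all-positive counts, so there is no median-of-ratios ",
        "reference set; rerun with pseudo_reference = TRUE to use ",
        "geometric means over positive counts."
      ))
    }
    loggeo <- rowMeans(logm)
  }
  sf <- apply(logm[ref, , drop = FALSE], 2, function(col) {
    exp(median((col - loggeo[ref])[is.finite(col)]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    abort("Size-factor estimation produced a non-positive factor.")
  }
  setNames(sf, sample_ids(counts))
}

#' Normalize counts by size factors
#'
#' Divides each sample column by its size factor and flips the table's scale
#' flag to `"normalized"`.
#'
#' @param counts A raw-scale [count_tbl()].
#' @param size_factors Positive per-sample factors, in column order or named
#'   by sample.
#' @return A normalized-scale [count_tbl()].
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  stopifnot(inherits(counts, "count_tbl"))
  samples <- sample_ids(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (!is.null(names(size_factors))) {
    if (!setequal(names(size_factors), samples)) {
      abort("Size-factor names do not match the sample identifiers.")
    }
    size_factors <- size_factors[samples]
  }
  if (length(size_factors) != length(samples)) {
    abort("Need one size factor per sample.")
  }
  if (any(!is.finite(size_factors) | size_factors <= 0)) {
    abort("Size factors must be positive and finite.")
  }
  m <- sweep(count_matrix(counts), 2, size_factors, "/")
  set_count_values(counts, m, scale = "normalized")
}

#' Gene-wise NB dispersion estimates
#'
#' Method-of-moments estimate of the dispersion `alpha` in
#' `var = mu + alpha * mu^2`, computed on normalized counts pooled within
#' design cells (unique combinations of age, treatment and, when present,
#' stimulus), then shrunk 50/50 in log space toward a log-linear
#' mean--dispersion trend fitted across genes, and clamped to
#' `[1e-8, 10]`. Genes whose counts show no variance in any cell carry no
#' overdispersion information and clamp to the lower bound.
#'
#' @param counts A raw-scale [count_tbl()].
#' @param design Sample key covering the count columns.
#' @param size_factors Optional precomputed size factors.
#' @param cells Optional name of a design column defining the pooling cells;
#'   defaults to the interaction of the factor columns present.
#' @return A named per-gene numeric vector of dispersions.
#' @export
estimate_dispersions <- function(counts, design, size_factors = NULL,
                                 cells = NULL) {
  stopifnot(inherits(counts, "count_tbl"))
  samples <- sample_ids(counts)
  design <- align_design(design, samples)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(count_matrix(counts), 2, size_factors[samples], "/")

  cell_id <- if (!is.null(cells)) {
    design[[cells]]
  } else {
    fac <- intersect(c("age", "treatment", "stimulus"), names(design))
    do.call(paste, c(design[fac], sep = "."))
  }
  tab <- table(cell_id)
  if (all(tab < 2)) {
    abort("Dispersion is unidentifiable: no design cell has >= 2 replicates.")
  }

  num <- 0
  den <- 0
  any_var <- rep(FALSE, nrow(norm))
  for (cell in names(tab)[tab >= 2]) {
    sub <- norm[, cell_id == cell, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (ncol(sub) - 1)
    w <- ncol(sub) - 1
    ok <- m > 0
    contrib <- ifelse(ok, (v - m) / m^2, 0)
    num <- num + w * contrib * ok
    den <- den + w * ok
    any_var <- any_var | (v > 0)
  }
  raw <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  raw_pos <- pmax(raw, 1e-8)

  base_mean <- rowMeans(norm)
  use <- !is.na(raw) & raw > 1e-8 & base_mean > 0 & any_var
  log_trend <- if (sum(use) >= 10) {
    fit <- lm(log(raw_pos[use]) ~ log(base_mean[use]))
    cf <- coef(fit)
    cf[1] + cf[2] * log(pmax(base_mean, min(base_mean[use])))
  } else if (any(use)) {
    rep(median(log(raw_pos[use])), length(raw))
  } else {
    rep(log(1e-8), length(raw))
  }
  if (any(use)) {
    # regressing log(raw) understates the mean dispersion (Jensen);
    # recalibrate the trend to the arithmetic mean of the raw estimates
    shift <- mean(raw_pos[use] / exp(log_trend[use]))
    if (is.finite(shift) && shift > 0) log_trend <- log_trend + log(shift)
  }

  shrunk <- exp(0.5 * log(raw_pos) + 0.5 * log_trend)
  if (any(use)) {
    # geometric blending shrinks the first moment; rescale so the mean of
    # the blended estimates matches the mean of the unbiased raw estimates
    scale <- mean(raw_pos[use]) / mean(shrunk[use])
    if (is.finite(scale) && scale > 0) shrunk <- shrunk * scale
  }
  shrunk[!any_var | is.na(raw)] <- 1e-8
  out <- pmin(pmax(shrunk, 1e-8), 10)
  setNames(as.numeric(out), counts$gene_id)
}

align_design <- function(design, samples) {
  design <- tibble::as_tibble(design)
  if (!"sample_id" %in% names(design)) abort("Design needs a sample_id column.")
  missing <- setdiff(samples, design$sample_id)
  if (length(missing) > 0) {
    abort(paste0(
      "Sample(s) missing from the design: ", toString(head(missing, 5))
    ))
  }
  design[match(samples, design$sample_id), , drop = FALSE]
}
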