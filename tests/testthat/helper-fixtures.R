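# Small programmatic fixtures shared across test files.

# gene x sample count table with deterministic Poisson-ish values
make_counts <- function(n_genes = 20, n_samples = 8, seed = 1, mean = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, mean), n_genes, n_samples)
  storage.mode(m) <- "double"
  tbl <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)))
  for (j in seq_len(n_samples)) tbl[[paste0("s", j)]] <- m[, j]
  count_tbl(tbl)
}

# two-group design (adult vs aged controls) over the columns of `counts`
make_two_group_design <- function(counts) {
  ids <- sample_ids(counts)
  n <- length(ids)
  repopsig:::as_sample_key(tibble::tibble(
    sample_id = ids,
    age = rep(c("adult", "aged"), each = n / 2),
    treatment = "control"
  ))
}

unit_size_factors <- function(counts) {
  stats::setNames(rep(1, length(sample_ids(counts))), sample_ids(counts))
}

# hand-built contrast result, for classifier tests
fake_contrast <- function(gene_id, log2fc, pvalue, base_mean = 100,
                          tested = TRUE) {
  n <- length(gene_id)
  out <- tibble::tibble(
    gene_id = gene_id,
    base_mean = rep_len(base_mean, n),
    log2fc = ifelse(rep_len(tested, n), log2fc, NA_real_),
    lfc_se = ifelse(rep_len(tested, n), 0.1, NA_real_),
    stat = ifelse(rep_len(tested, n), log2fc / 0.1, NA_real_),
    pvalue = ifelse(rep_len(tested, n), pvalue, NA_real_),
    padj = adjust_bh(ifelse(rep_len(tested, n), pvalue, NA_real_)),
    tested = rep_len(tested, n)
  )
  structure(out, class = c("contrast_result", class(tibble::tibble())))
}

# a signature whose genes have the given age-effect directions
fake_signature <- function(gene_id, age_log2fc) {
  ct <- fake_contrast(gene_id, age_log2fc, pvalue = 1e-6)
  define_age_signature(ct, alpha_adj = 0.05, fc_threshold = 1.5,
                       base_mean_min = 0)
}

# independent brute-force BH step-up oracle (definition-level, O(n^2))
bh_oracle <- function(p) {
  obs <- which(!is.na(p))
  q <- p[obs]
  n <- length(q)
  out <- rep(NA_real_, length(p))
  if (n > 0) {
    rank_of <- vapply(q, function(t) sum(q <= t), 0)
    cand <- n / rank_of * q
    out[obs] <- vapply(q, function(t) min(1, min(cand[q >= t])), 0)
  }
  out
}
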