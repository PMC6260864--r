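#' Simulation configuration
#'
#' Describes a factorial negative-binomial count experiment with planted
#' per-gene category structure. Counts are drawn as
#' `NB(mean = baseline * 2^(group LFC) * library factor, var = mu + alpha * mu^2)`.
#' Defaults emulate the reference microglial-turnover design: four groups
#' (adult/aged x control/repopulation) of 6 biological replicates, 10,000
#' genes of which ~500 form an age signature split across the four reversal
#' categories in proportions echoing a bulk microglia aging study
#' (reversed 117 up / 10 down, partially reversed 48/5, exacerbated 14/5,
#' unaffected 271/36), age effects of 1.5--2.5 log2 units, gene-wise
#' dispersion 0.05, baseline means log-uniform on \[20, 2000\] and log-normal
#' library-size variation with sd 0.2 on the natural-log scale.
#'
#' For the LPS arm (`arm = "lps"`) the design is adult-control, aged-control
#' and aged-repopulation groups each under saline or LPS, and the categories
#' plant the LPS-response taxonomy: `lps_adult_up` (equal LPS induction at
#' both ages), `lps_age_exacerbated` (induced in adults, induced more
#' strongly in aged), `lps_aged_unique` (induced only in aged) and
#' `lps_prevented_by_repop` (induced in aged controls but not after
#' repopulation). LPS defaults echo a 248-gene inflammation panel.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Biological replicates per design cell (>= 2).
#' @param baseline_mean_range Interval for log-uniform baseline-mean sampling.
#' @param dispersion NB dispersion `alpha` (scalar, or per-gene vector).
#' @param libsize_sd SD of the log-normal library-size factor (natural log).
#' @param category_counts Named integer vector over the planted categories;
#'   must sum to `n_genes`. Defaults depend on `arm` as described above.
#' @param age_lfc_magnitude Interval for |planted log2 fold change| of the
#'   age (or LPS) effect.
#' @param partial_fraction Fraction of the age effect undone in
#'   `*_partial` genes, in (0, 1).
#' @param exacerbation_increment Extra log2 units added in the age-effect
#'   direction for `*_exacerbated` genes (and for the aged-vs-adult LPS
#'   increment in `lps_age_exacerbated` genes).
#' @param seed Integer root seed; every generated artifact is a pure
#'   function of the config including this seed.
#' @param arm `"reversal"` (2x2 design) or `"lps"` (3-group x stimulus).
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' sim <- simulate_reversal_experiment(cfg)
#' names(sim)
#' @export
sim_config <- function(n_genes = NULL,
                       n_per_group = 6,
                       baseline_mean_range = c(20, 2000),
                       dispersion = 0.05,
                       libsize_sd = 0.2,
                       category_counts = NULL,
                       age_lfc_magnitude = c(1.5, 2.5),
                       partial_fraction = 0.5,
                       exacerbation_increment = 0.75,
                       seed = 1,
                       arm = c("reversal", "lps")) {
  arm <- match.arg(arm)
  if (is.null(n_genes)) n_genes <- if (arm == "reversal") 10000L else 248L
  n_genes <- as.integer(n_genes)
  if (is.null(category_counts)) {
    category_counts <- default_category_counts(n_genes, arm)
  }
  # tolerate YAML-style nested lists; YAML parses an unquoted `null` key to
  # an empty name, so restore it
  category_counts <- unlist(category_counts)
  if (!is.null(names(category_counts))) {
    names(category_counts)[is.na(names(category_counts)) |
                             names(category_counts) == ""] <- "null"
  }
  baseline_mean_range <- as.numeric(unlist(baseline_mean_range))
  age_lfc_magnitude <- as.numeric(unlist(age_lfc_magnitude))
  dispersion <- as.numeric(unlist(dispersion))
  cfg <- structure(
    list(
      n_genes = n_genes, n_per_group = as.integer(n_per_group),
      baseline_mean_range = baseline_mean_range, dispersion = dispersion,
      libsize_sd = libsize_sd, category_counts = category_counts,
      age_lfc_magnitude = age_lfc_magnitude,
      partial_fraction = partial_fraction,
      exacerbation_increment = exacerbation_increment,
      seed = as.integer(seed), arm = arm
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

reversal_categories <- c(
  "null",
  "up_reversed", "up_partial", "up_exacerbated", "up_unaffected",
  "down_reversed", "down_partial", "down_exacerbated", "down_unaffected"
)

lps_categories <- c(
  "null", "lps_adult_up", "lps_age_exacerbated", "lps_aged_unique",
  "lps_prevented_by_repop"
)

default_category_counts <- function(n_genes, arm) {
  planted <- if (arm == "reversal") {
    c(
      up_reversed = 117, down_reversed = 10,
      up_partial = 48, down_partial = 5,
      up_exacerbated = 14, down_exacerbated = 5,
      up_unaffected = 271, down_unaffected = 36
    )
  } else {
    c(
      lps_adult_up = 20, lps_age_exacerbated = 11,
      lps_aged_unique = 29, lps_prevented_by_repop = 3
    )
  }
  if (sum(planted) > n_genes) {
    abort(paste0(
      "n_genes = ", n_genes, " is smaller than the default planted-category ",
      "total (", sum(planted), "); supply category_counts explicitly."
    ))
  }
  c(null = n_genes - sum(planted), planted)
}

validate_sim_config <- function(cfg) {
  valid <- if (cfg$arm == "reversal") reversal_categories else lps_categories
  bad <- setdiff(names(cfg$category_counts), valid)
  if (length(bad) > 0) {
    abort(paste0("Unknown category label(s): ", toString(bad)))
  }
  if (sum(cfg$category_counts) != cfg$n_genes) {
    abort(paste0(
      "category_counts sum to ", sum(cfg$category_counts),
      " but n_genes = ", cfg$n_genes
    ))
  }
  if (any(cfg$category_counts < 0)) abort("category_counts must be >= 0.")
  if (cfg$n_per_group < 2) abort("n_per_group must be >= 2.")
  stopifnot(
    length(cfg$baseline_mean_range) == 2, all(cfg$baseline_mean_range > 0),
    all(cfg$dispersion > 0), cfg$libsize_sd >= 0,
    length(cfg$age_lfc_magnitude) == 2, all(cfg$age_lfc_magnitude > 0),
    cfg$partial_fraction > 0, cfg$partial_fraction < 1,
    cfg$exacerbation_increment > 0
  )
  invisible(cfg)
}

#' Simulate a factorial repopulation experiment
#'
#' Draws a raw count table for the 2x2 adult/aged x control/repopulation
#' design with planted per-gene log2 fold changes realizing each reversal
#' category, together with the sample key and a truth table. Adult groups
#' sit at the baseline mean; aged-control means are shifted by the planted
#' age effect `lfc_age` and aged-repopulation means by
#' `lfc_age + lfc_repop`, where `lfc_repop` is `-lfc_age` for reversed
#' genes, `-partial_fraction * lfc_age` for partially reversed genes,
#' `sign(lfc_age) * exacerbation_increment` for exacerbated genes and 0 for
#' unaffected and null genes. Identical configs (including seed) give
#' bit-identical output.
#'
#' @param config A [sim_config()] with `arm = "reversal"`.
#' @return A list with elements `counts` ([count_tbl()], raw scale),
#'   `design` (sample key tibble) and `truth` (tibble: `gene_id`,
#'   `category`, `lfc_age`, `lfc_repop`, `baseline_mean`,
#'   `dispersion_used`).
#' @export
simulate_reversal_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), config$arm == "reversal")
  validate_sim_config(config)
  set.seed(config$seed)

  truth <- plant_reversal_truth(config)
  design <- factorial_design(
    groups = c(
      "adult_control", "adult_repopulation",
      "aged_control", "aged_repopulation"
    ),
    n_per_group = config$n_per_group
  )
  # planted log2 offsets per group, genes x groups
  lfc <- cbind(
    adult_control = 0, adult_repopulation = 0,
    aged_control = truth$lfc_age,
    aged_repopulation = truth$lfc_age + truth$lfc_repop
  )
  counts <- draw_nb_counts(truth, lfc[, design$group, drop = FALSE], config)
  colnames(counts) <- design$sample_id
  list(
    counts = count_tbl(
      dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                       tibble::as_tibble(counts)),
      scale = "raw"
    ),
    design = as_sample_key(design),
    truth = truth
  )
}

#' Simulate an LPS-challenge inflammation panel
#'
#' Draws a raw count table for the LPS arm: adult-control, aged-control and
#' aged-repopulation groups each receiving saline or LPS. Planted LPS log2
#' fold changes realize the LPS-response taxonomy (see [sim_config()]).
#' The generator derives its stream from `seed + 1` so the reversal and LPS
#' arms of one root seed are independent substreams.
#'
#' @param config A [sim_config()] with `arm = "lps"`.
#' @return A list with `counts`, `design` (including `stimulus`) and
#'   `truth` (tibble: `gene_id`, `category`, `lfc_lps_adult`,
#'   `lfc_lps_aged`, `lfc_lps_repop`, `baseline_mean`, `dispersion_used`).
#' @export
simulate_lps_experiment <- function(config = sim_config(arm = "lps")) {
  stopifnot(inherits(config, "sim_config"), config$arm == "lps")
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  truth <- plant_lps_truth(config)
  groups <- c("adult_control", "aged_control", "aged_repopulation")
  design <- factorial_design(
    groups = rep(groups, each = 2),
    stimulus = rep(c("saline", "lps"), times = length(groups)),
    n_per_group = config$n_per_group
  )
  lps_lfc <- cbind(
    adult_control = truth$lfc_lps_adult,
    aged_control = truth$lfc_lps_aged,
    aged_repopulation = truth$lfc_lps_repop
  )
  cell_lfc <- lps_lfc[, design$group, drop = FALSE] *
    rep(design$stimulus == "lps", each = nrow(truth))
  counts <- draw_nb_counts(truth, cell_lfc, config)
  colnames(counts) <- design$sample_id
  list(
    counts = count_tbl(
      dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                       tibble::as_tibble(counts)),
      scale = "raw"
    ),
    design = as_sample_key(design),
    truth = truth
  )
}

#' Simulate a comparative-CT (qPCR) table
#'
#' Control samples get `delta CT = delta_ct_control + noise`; treated
#' samples get `delta CT = delta_ct_control + delta_delta_ct + noise`, with
#' independent Gaussian noise of sd `noise_sd`. The reference CT is fixed at
#' 20 cycles and the target CT set to carry the delta, so
#' [ddct_fold_change()] on noise-free output returns exactly
#' `2^-delta_delta_ct` for every treated sample.
#'
#' @param n_per_group Samples per group (>= 1).
#' @param delta_ct_control Control-group mean delta CT (cycles).
#' @param delta_delta_ct Planted treated-vs-control delta CT shift (cycles;
#'   negative means higher target expression).
#' @param noise_sd SD of per-sample Gaussian CT noise (cycles).
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `group` (`control`/`treated`),
#'   `ct_target`, `ct_reference`.
#' @export
simulate_ddct_table <- function(n_per_group, delta_ct_control,
                                delta_delta_ct, noise_sd = 0, seed = 1) {
  stopifnot(n_per_group >= 1, noise_sd >= 0)
  set.seed(seed)
  n <- as.integer(n_per_group)
  delta <- c(
    delta_ct_control + rnorm(n, 0, noise_sd),
    delta_ct_control + delta_delta_ct + rnorm(n, 0, noise_sd)
  )
  tibble::tibble(
    sample_id = paste0(rep(c("ctl", "trt"), each = n), seq_len(n)),
    group = rep(c("control", "treated"), each = n),
    ct_target = 20 + delta,
    ct_reference = 20
  )
}

# ---- internals --------------------------------------------------------------

plant_reversal_truth <- function(cfg) {
  counts <- cfg$category_counts[intersect(reversal_categories,
                                          names(cfg$category_counts))]
  category <- rep(names(counts), times = counts)
  n <- cfg$n_genes
  sign <- ifelse(startsWith(category, "up"), 1,
    ifelse(startsWith(category, "down"), -1, 0)
  )
  mag <- runif(n, cfg$age_lfc_magnitude[1], cfg$age_lfc_magnitude[2])
  lfc_age <- sign * mag
  base <- substring(category, regexpr("_", category) + 1L)
  lfc_repop <- dplyr::case_when(
    base == "reversed" ~ -lfc_age,
    base == "partial" ~ -cfg$partial_fraction * lfc_age,
    base == "exacerbated" ~ sign * cfg$exacerbation_increment,
    .default = 0
  )
  tibble::tibble(
    gene_id = gene_ids(n),
    category = category,
    lfc_age = lfc_age,
    lfc_repop = lfc_repop,
    baseline_mean = draw_baselines(cfg),
    dispersion_used = rep_len(cfg$dispersion, n)
  )
}

plant_lps_truth <- function(cfg) {
  counts <- cfg$category_counts[intersect(lps_categories,
                                          names(cfg$category_counts))]
  category <- rep(names(counts), times = counts)
  n <- cfg$n_genes
  mag <- runif(n, cfg$age_lfc_magnitude[1], cfg$age_lfc_magnitude[2])
  adult <- ifelse(category %in% c("lps_adult_up", "lps_age_exacerbated"),
    mag, 0
  )
  aged <- dplyr::case_when(
    category == "lps_adult_up" ~ mag,
    category == "lps_age_exacerbated" ~ mag + cfg$exacerbation_increment,
    category %in% c("lps_aged_unique", "lps_prevented_by_repop") ~ mag,
    .default = 0
  )
  repop <- ifelse(category == "lps_prevented_by_repop", 0, aged)
  tibble::tibble(
    gene_id = gene_ids(n),
    category = category,
    lfc_lps_adult = adult,
    lfc_lps_aged = aged,
    lfc_lps_repop = repop,
    baseline_mean = draw_baselines(cfg),
    dispersion_used = rep_len(cfg$dispersion, n)
  )
}

gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

draw_baselines <- function(cfg) {
  r <- log(cfg$baseline_mean_range)
  exp(runif(cfg$n_genes, r[1], r[2]))
}

factorial_design <- function(groups, n_per_group, stimulus = NULL) {
  cells <- tibble::tibble(group = groups)
  if (!is.null(stimulus)) cells$stimulus <- stimulus
  design <- tidyr::uncount(cells, n_per_group)
  parts <- strsplit(design$group, "_", fixed = TRUE)
  design$age <- vapply(parts, `[`, "", 1L)
  design$treatment <- vapply(parts, `[`, "", 2L)
  key <- paste0(design$group,
    if (is.null(stimulus)) "" else paste0("_", design$stimulus)
  )
  design$sample_id <- paste0(
    key, "_", stats::ave(seq_along(key), key, FUN = seq_along)
  )
  design[c("sample_id", "age", "treatment",
           if (!is.null(stimulus)) "stimulus", "group")]
}

# counts ~ NB(mean = baseline * 2^lfc * library factor, var = mu + a mu^2);
# lfc is a genes x samples matrix of planted log2 offsets.
draw_nb_counts <- function(truth, lfc, cfg) {
  n_samples <- ncol(lfc)
  lib <- exp(rnorm(n_samples, 0, cfg$libsize_sd))
  mu <- truth$baseline_mean * 2^lfc *
    matrix(lib, nrow(lfc), n_samples, byrow = TRUE)
  size <- 1 / rep_len(cfg$dispersion, nrow(lfc))
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = rep(size, n_samples)),
    nrow = nrow(lfc), ncol = n_samples
  )
  storage.mode(counts) <- "double"
  counts
}
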