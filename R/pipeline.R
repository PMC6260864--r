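#' Run configuration
#'
#' The pipeline runners ([run_simulate()], [run_de()],
#' [run_classify_reversal()], [run_classify_lps()], [run_ddct()],
#' [run_evaluate()]) all consume one hierarchical run configuration, read
#' from YAML or given as a named list. Recognised keys:
#'
#' * `seed`: integer root seed;
#' * `out_dir`: output directory (created if needed);
#' * `counts`, `sample_key`, `truth`, `classification`, `ddct`: input paths;
#' * `scale`: `"raw"` (default) or `"normalized"`; normalized input skips
#'   size-factor estimation and fixes all factors at 1 (inference from
#'   already-normalized counts is approximate and flagged in the log);
#' * `thresholds`: `alpha_adj`, `alpha`, `fc_threshold`, `base_mean_min`;
#' * `covariates`: design columns to adjust for;
#' * `control_group`: reference group for the comparative-CT runner;
#' * `simulation`: fields of [sim_config()].
#'
#' Direct arguments to the runners override config keys. Every runner
#' writes a `provenance.json` (config echo, seed, md5 checksum per written
#' file -- deliberately no timestamps, so identical runs are byte-identical)
#' and logs to standard error.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) return(cfg)
  stopifnot(is.list(cfg))
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    alpha_adj = th$alpha_adj %||% 0.05,
    alpha = th$alpha %||% 0.05,
    fc_threshold = th$fc_threshold %||% 1.5,
    base_mean_min = th$base_mean_min %||% 10
  )
  stopifnot(
    cfg$thresholds$alpha_adj > 0, cfg$thresholds$alpha_adj < 1,
    cfg$thresholds$alpha > 0, cfg$thresholds$alpha < 1,
    cfg$thresholds$fc_threshold > 1, cfg$thresholds$base_mean_min >= 0
  )
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$scale <- cfg$scale %||% "raw"
  structure(cfg, class = c("run_config", "list"))
}

#' Pipeline runners
#'
#' Thin orchestration over the package verbs, for scripted and
#' command-line use. Each runner reads its inputs through the package
#' readers, executes one stage, writes CSV outputs plus a
#' `provenance.json` into `out_dir`, and returns the written paths
#' invisibly. Stage failures propagate as errors naming the stage.
#'
#' * `run_simulate()`: factorial simulation -> `counts.csv`,
#'   `sample_key.csv`, `truth.csv`.
#' * `run_de()`: one Wald contrast table per entry of `config$contrasts`
#'   (each a list with `factor`, `numerator`, `denominator`, optional
#'   `stratum`) -> `<name>.csv`.
#' * `run_classify_reversal()`: the full age-signature procedure (three
#'   contrasts, signature, four-way classification, category summary).
#' * `run_classify_lps()`: the LPS-response taxonomy from the four LPS
#'   contrasts.
#' * `run_ddct()`: comparative-CT fold changes.
#' * `run_evaluate()`: recovery report from a truth table and a
#'   classification table.
#'
#' @param config A `run_config`, plain list, or YAML path.
#' @param out_dir Output directory, overriding `config$out_dir`.
#' @return The written file paths, invisibly.
#' @name runners
NULL

#' @rdname runners
#' @export
run_simulate <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out <- prepare_out_dir(out_dir %||% cfg$out_dir)
  sim_args <- cfg$simulation %||% list()
  sim_args$seed <- sim_args$seed %||% cfg$seed
  arm <- sim_args$arm %||% "reversal"
  scfg <- do.call(sim_config, sim_args)
  inform(paste0(
    "[simulate] arm=", arm, " n_genes=", scfg$n_genes,
    " n_per_group=", scfg$n_per_group, " seed=", scfg$seed
  ))
  sim <- if (arm == "lps") {
    simulate_lps_experiment(scfg)
  } else {
    simulate_reversal_experiment(scfg)
  }
  paths <- c(
    counts = file.path(out, "counts.csv"),
    sample_key = file.path(out, "sample_key.csv"),
    truth = file.path(out, "truth.csv")
  )
  write_count_matrix(sim$counts, paths[["counts"]])
  write_sample_key(sim$design, paths[["sample_key"]])
  write_delim_auto(sim$truth, paths[["truth"]])
  write_provenance(cfg, out, paths)
  invisible(paths)
}

#' @rdname runners
#' @export
run_de <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out <- prepare_out_dir(out_dir %||% cfg$out_dir)
  inputs <- load_experiment(cfg)
  if (is.null(cfg$contrasts) || length(cfg$contrasts) == 0) {
    abort("[de] config$contrasts is empty.")
  }
  paths <- character(0)
  for (nm in names(cfg$contrasts)) {
    ct <- cfg$contrasts[[nm]]
    res <- fit_contrast(
      inputs$counts, inputs$design,
      factor = ct$factor %||% "group",
      numerator = ct$numerator, denominator = ct$denominator,
      stratum = unlist(ct$stratum), covariates = cfg$covariates,
      size_factors = inputs$size_factors, dispersions = inputs$dispersions
    )
    inform(paste0(
      "[de] ", nm, ": ", sum(res$tested), "/", nrow(res), " genes tested"
    ))
    p <- file.path(out, paste0(nm, ".csv"))
    write_results_table(res, p)
    paths[nm] <- p
  }
  write_provenance(cfg, out, paths)
  invisible(paths)
}

#' @rdname runners
#' @export
run_classify_reversal <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out <- prepare_out_dir(out_dir %||% cfg$out_dir)
  th <- cfg$thresholds
  inputs <- load_experiment(cfg)
  cts <- reversal_contrasts(
    inputs$counts, inputs$design, inputs$size_factors, inputs$dispersions,
    covariates = cfg$covariates
  )
  sig <- define_age_signature(
    cts$age,
    alpha_adj = th$alpha_adj, fc_threshold = th$fc_threshold,
    base_mean_min = th$base_mean_min
  )
  inform(paste0(
    "[classify-reversal] thresholds: alpha_adj=", th$alpha_adj,
    " fc=", th$fc_threshold, " base_mean_min=", th$base_mean_min,
    "; tested=", sum(cts$age$tested), "; signature=", nrow(sig)
  ))
  cls <- classify_reversal(
    sig, cts$repop_vs_aged, cts$repop_vs_adult, alpha = th$alpha
  )
  smry <- summarize_categories(cls)
  inform(paste0(
    "[classify-reversal] ",
    paste(smry$category, smry$n, sep = "=", collapse = " ")
  ))
  paths <- c(
    age_contrast = file.path(out, "age_contrast.csv"),
    repop_vs_aged = file.path(out, "repop_vs_aged.csv"),
    repop_vs_adult = file.path(out, "repop_vs_adult.csv"),
    classification = file.path(out, "classification.csv"),
    category_summary = file.path(out, "category_summary.csv")
  )
  write_results_table(cts$age, paths[["age_contrast"]])
  write_results_table(cts$repop_vs_aged, paths[["repop_vs_aged"]])
  write_results_table(cts$repop_vs_adult, paths[["repop_vs_adult"]])
  if (nrow(cls) > 0) {
    write_results_table(cls, paths[["classification"]])
  } else {
    readr::write_csv(
      data.frame(gene_id = character(), direction = character(),
                 category = character()),
      paths[["classification"]]
    )
  }
  write_delim_auto(smry, paths[["category_summary"]])
  write_provenance(cfg, out, paths)
  invisible(paths)
}

#' @rdname runners
#' @export
run_classify_lps <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out <- prepare_out_dir(out_dir %||% cfg$out_dir)
  th <- cfg$thresholds
  inputs <- load_experiment(cfg)
  fit <- function(factor, numerator, denominator, stratum = NULL) {
    fit_contrast(
      inputs$counts, inputs$design, factor, numerator, denominator,
      stratum = stratum, covariates = cfg$covariates,
      size_factors = inputs$size_factors, dispersions = inputs$dispersions
    )
  }
  cts <- list(
    adult_lps = fit("stimulus", "lps", "saline",
                    c(group = "adult_control")),
    aged_lps = fit("stimulus", "lps", "saline",
                   c(group = "aged_control")),
    aged_vs_adult_lps = fit("group", "aged_control", "adult_control",
                            c(stimulus = "lps")),
    repop_lps = fit("stimulus", "lps", "saline",
                    c(group = "aged_repopulation"))
  )
  cls <- classify_lps_response(
    cts$adult_lps, cts$aged_lps, cts$aged_vs_adult_lps, cts$repop_lps,
    alpha = th$alpha
  )
  smry <- summarize_categories(cls)
  inform(paste0(
    "[classify-lps] alpha=", th$alpha, "; ",
    paste(smry$category, smry$n, sep = "=", collapse = " ")
  ))
  paths <- c(
    adult_lps = file.path(out, "adult_lps.csv"),
    aged_lps = file.path(out, "aged_lps.csv"),
    aged_vs_adult_lps = file.path(out, "aged_vs_adult_lps.csv"),
    repop_lps = file.path(out, "repop_lps.csv"),
    classification = file.path(out, "lps_classification.csv"),
    category_summary = file.path(out, "lps_category_summary.csv")
  )
  for (nm in names(cts)) write_results_table(cts[[nm]], paths[[nm]])
  write_results_table(cls, paths[["classification"]])
  write_delim_auto(smry, paths[["category_summary"]])
  write_provenance(cfg, out, paths)
  invisible(paths)
}

#' @rdname runners
#' @export
run_ddct <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out <- prepare_out_dir(out_dir %||% cfg$out_dir)
  tbl <- read_ddct_table(cfg$ddct)
  fc <- ddct_fold_change(tbl, cfg$control_group %||% "control")
  inform(paste0("[ddct] ", nrow(fc), " samples, control group '",
                cfg$control_group %||% "control", "'"))
  paths <- c(fold_changes = file.path(out, "fold_changes.csv"))
  write_delim_auto(fc, paths[["fold_changes"]])
  write_provenance(cfg, out, paths)
  invisible(paths)
}

#' @rdname runners
#' @export
run_evaluate <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out <- prepare_out_dir(out_dir %||% cfg$out_dir)
  truth <- readr::read_csv(
    cfg$truth, show_col_types = FALSE, progress = FALSE
  )
  cls <- read_results_table(cfg$classification)
  report <- evaluate_recovery(truth, cls)
  paths <- c(
    confusion = file.path(out, "confusion.csv"),
    per_category = file.path(out, "per_category.csv"),
    signature_metrics = file.path(out, "signature_metrics.csv"),
    summary = file.path(out, "recovery_summary.txt")
  )
  write_delim_auto(report$confusion, paths[["confusion"]])
  write_delim_auto(report$per_category, paths[["per_category"]])
  write_delim_auto(report$signature, paths[["signature_metrics"]])
  writeLines(utils::capture.output(print(report)), paths[["summary"]])
  write_provenance(cfg, out, paths)
  invisible(paths)
}

# ---- internals --------------------------------------------------------------

load_config <- function(config) {
  if (is.character(config)) read_run_config(config) else as_run_config(config)
}

prepare_out_dir <- function(out_dir) {
  if (is.null(out_dir)) abort("No output directory configured.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create out_dir: ", out_dir))
  out_dir
}

load_experiment <- function(cfg) {
  if (is.null(cfg$counts) || is.null(cfg$sample_key)) {
    abort("Config must name 'counts' and 'sample_key' files.")
  }
  counts <- read_count_matrix(cfg$counts, scale = cfg$scale)
  design <- read_sample_key(cfg$sample_key)
  if (count_scale(counts) == "normalized") {
    inform(paste0(
      "[input] normalized counts: size factors fixed at 1 ",
      "(raw-count inference is approximate)"
    ))
    sf <- setNames(rep(1, length(sample_ids(counts))), sample_ids(counts))
  } else {
    sf <- estimate_size_factors(counts)
  }
  disp <- estimate_dispersions(counts, design, sf)
  list(counts = counts, design = design, size_factors = sf,
       dispersions = disp)
}

write_provenance <- function(cfg, out_dir, paths) {
  record <- list(
    package = "repopsig",
    version = as.character(utils::packageVersion("repopsig")),
    seed = cfg$seed,
    config = unclass(cfg),
    files = as.list(setNames(
      unname(tools::md5sum(unname(paths))), basename(unname(paths))
    ))
  )
  jsonlite::write_json(
    record, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(record)
}
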