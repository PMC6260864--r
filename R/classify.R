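#' Define the age signature
#'
#' The age signature is the set of genes differentially expressed between
#' aged-control and adult-control samples: adjusted p-value strictly below
#' `alpha_adj` and absolute fold change strictly above `fc_threshold`
#' (i.e. `|log2fc| > log2(fc_threshold)`), split by direction of the age
#' effect. An expression prefilter on the mean of normalized counts
#' (`base_mean > base_mean_min`, default 10) screens out near-silent genes;
#' set `base_mean_min = 0` to disable it. Untested genes never enter.
#'
#' @param age_contrast A `contrast_result` for the aged-control vs
#'   adult-control comparison (or any designated condition contrast).
#' @param alpha_adj Adjusted-p cutoff, in (0, 1).
#' @param fc_threshold Fold-change cutoff, > 1.
#' @param base_mean_min Expression prefilter on `base_mean`.
#' @return An `age_signature` tibble: `gene_id`, `direction`
#'   (`increased`/`decreased`), `log2fc`, `pvalue`, `padj`, `base_mean`.
#' @export
define_age_signature <- function(age_contrast, alpha_adj = 0.05,
                                 fc_threshold = 1.5, base_mean_min = 10) {
  stopifnot(inherits(age_contrast, "contrast_result"))
  if (alpha_adj <= 0 || alpha_adj >= 1) abort("alpha_adj must lie in (0, 1).")
  if (fc_threshold <= 1) abort("fc_threshold must exceed 1.")
  out <- age_contrast |>
    dplyr::filter(
      .data$tested,
      !is.na(.data$padj), .data$padj < alpha_adj,
      abs(.data$log2fc) > log2(fc_threshold),
      .data$base_mean > base_mean_min
    ) |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      direction = ifelse(.data$log2fc > 0, "increased", "decreased"),
      log2fc = .data$log2fc,
      pvalue = .data$pvalue,
      padj = .data$padj,
      base_mean = .data$base_mean
    )
  out <- tibble::as_tibble(out)
  structure(
    out,
    class = c("age_signature", class(tibble::tibble())),
    thresholds = list(
      alpha_adj = alpha_adj, fc_threshold = fc_threshold,
      base_mean_min = base_mean_min
    )
  )
}

#' Classify reversal of the age signature
#'
#' Assigns each age-signature gene one of four mutually exclusive
#' categories describing how forced repopulation moved its expression,
#' using nominal (unadjusted) p-values of two contrasts. Decision order per
#' gene:
#' 1. repopulation-vs-aged p >= `alpha`, or gene untested there, or its
#'    log2 fold change exactly 0 -> `unaffected`;
#' 2. else, repopulation-vs-aged change in the *same* direction as the age
#'    effect (conserved directionality) -> `exacerbated`;
#' 3. else, repopulation-vs-adult p >= `alpha` (expression no longer
#'    distinguishable from adult controls) -> `reversed`;
#' 4. else -> `partially_reversed`.
#'
#' A signature gene missing or untested in the repopulation-vs-adult
#' contrast when step 3 is reached is called `unaffected` with a warning
#' (absence of evidence of change).
#'
#' @param signature An [define_age_signature()] result.
#' @param repop_vs_aged `contrast_result`, aged-repopulation vs
#'   aged-control.
#' @param repop_vs_adult `contrast_result`, aged-repopulation vs
#'   adult-control.
#' @param alpha Nominal p cutoff for both gates.
#' @return A `reversal_classification` tibble: `gene_id`, `direction`,
#'   `category`, and the statistics used (`age_log2fc`, `rva_log2fc`,
#'   `rva_pvalue`, `rvad_log2fc`, `rvad_pvalue`).
#' @export
classify_reversal <- function(signature, repop_vs_aged, repop_vs_adult,
                              alpha = 0.05) {
  stopifnot(inherits(signature, "age_signature"))
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  rva <- contrast_lookup(repop_vs_aged, signature$gene_id)
  rvad <- contrast_lookup(repop_vs_adult, signature$gene_id)

  age_lfc <- signature$log2fc
  rva_sig <- rva$tested & !is.na(rva$pvalue) & rva$pvalue < alpha
  conserved <- sign(rva$log2fc) == sign(age_lfc) & rva$log2fc != 0
  rvad_known <- rvad$tested & !is.na(rvad$pvalue)

  category <- character(nrow(signature))
  for (i in seq_along(category)) {
    category[i] <- if (!rva_sig[i] || rva$log2fc[i] == 0) {
      "unaffected"
    } else if (conserved[i]) {
      "exacerbated"
    } else if (!rvad_known[i]) {
      warn(paste0(
        "Gene '", signature$gene_id[i], "' is untested in the ",
        "repopulation-vs-adult contrast; calling it unaffected."
      ))
      "unaffected"
    } else if (rvad$pvalue[i] >= alpha) {
      "reversed"
    } else {
      "partially_reversed"
    }
  }

  out <- tibble::tibble(
    gene_id = signature$gene_id,
    direction = signature$direction,
    category = category,
    age_log2fc = age_lfc,
    rva_log2fc = rva$log2fc,
    rva_pvalue = rva$pvalue,
    rvad_log2fc = rvad$log2fc,
    rvad_pvalue = rvad$pvalue
  )
  structure(
    out,
    class = c("reversal_classification", class(tibble::tibble())),
    alpha = alpha
  )
}

reversal_category_levels <- c(
  "reversed", "partially_reversed", "exacerbated", "unaffected"
)

lps_category_levels <- c(
  "exacerbated_by_age", "unique_to_aged", "adult_only", "nonresponsive"
)

#' Classify the LPS response taxonomy
#'
#' Classifies genes of an inflammation panel by how their LPS induction
#' depends on age, from four contrasts (all nominal p, no fold-change gate
#' unless `fc_threshold` is supplied):
#' * `exacerbated_by_age`: increased by LPS in adults (p < `alpha`,
#'   log2fc > 0) and further increased with age (aged-LPS vs adult-LPS
#'   p < `alpha`, log2fc > 0);
#' * `unique_to_aged`: increased by LPS in aged (p < `alpha`, log2fc > 0)
#'   but not in adults (p >= `alpha` or log2fc <= 0);
#' * `adult_only`: increased by LPS in adults only;
#' * `nonresponsive`: everything else.
#'
#' `prevented_by_repop` flags genes of the two aged-responsive categories
#' whose LPS induction fails in aged-repopulation mice
#' (p >= `alpha` or log2fc <= 0).
#'
#' @param adult_lps `contrast_result`, LPS vs saline within adult controls.
#' @param aged_lps `contrast_result`, LPS vs saline within aged controls.
#' @param aged_vs_adult_lps `contrast_result`, aged-LPS vs adult-LPS.
#' @param repop_lps `contrast_result`, LPS vs saline within
#'   aged-repopulation.
#' @param alpha Nominal p cutoff.
#' @param fc_threshold Optional fold-change gate applied to every "up" call
#'   (off by default).
#' @return An `lps_classification` tibble: `gene_id`, `direction`,
#'   `category`, `prevented_by_repop`, plus the four (log2fc, p) pairs.
#' @export
classify_lps_response <- function(adult_lps, aged_lps, aged_vs_adult_lps,
                                  repop_lps, alpha = 0.05,
                                  fc_threshold = NULL) {
  contrasts <- list(
    adult_lps = adult_lps, aged_lps = aged_lps,
    aged_vs_adult_lps = aged_vs_adult_lps, repop_lps = repop_lps
  )
  for (nm in names(contrasts)) {
    if (is.null(contrasts[[nm]])) {
      abort(paste0("Missing contrast: ", nm))
    }
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  genes <- adult_lps$gene_id
  lfc_min <- if (is.null(fc_threshold)) 0 else log2(fc_threshold)

  up <- purrr::map(contrasts, function(ct) {
    ct <- contrast_lookup(ct, genes)
    ct$tested & !is.na(ct$pvalue) & ct$pvalue < alpha & ct$log2fc > lfc_min
  })
  category <- dplyr::case_when(
    up$adult_lps & up$aged_vs_adult_lps ~ "exacerbated_by_age",
    up$aged_lps & !up$adult_lps ~ "unique_to_aged",
    up$adult_lps ~ "adult_only",
    .default = "nonresponsive"
  )
  prevented <- category %in% c("exacerbated_by_age", "unique_to_aged") &
    !up$repop_lps

  out <- tibble::tibble(
    gene_id = genes,
    direction = "increased",
    category = category,
    prevented_by_repop = prevented,
    adult_lps_log2fc = contrast_lookup(adult_lps, genes)$log2fc,
    adult_lps_pvalue = contrast_lookup(adult_lps, genes)$pvalue,
    aged_lps_log2fc = contrast_lookup(aged_lps, genes)$log2fc,
    aged_lps_pvalue = contrast_lookup(aged_lps, genes)$pvalue,
    aged_vs_adult_log2fc = contrast_lookup(aged_vs_adult_lps, genes)$log2fc,
    aged_vs_adult_pvalue = contrast_lookup(aged_vs_adult_lps, genes)$pvalue,
    repop_lps_log2fc = contrast_lookup(repop_lps, genes)$log2fc,
    repop_lps_pvalue = contrast_lookup(repop_lps, genes)$pvalue
  )
  structure(
    out,
    class = c("lps_classification", class(tibble::tibble())),
    alpha = alpha, fc_threshold = fc_threshold
  )
}

#' Count genes per classification category
#'
#' Tallies a reversal or LPS classification by direction and category in a
#' fixed, deterministic order; counts always sum to the number of
#' classified genes.
#'
#' @param classification A `reversal_classification` or
#'   `lps_classification`.
#' @return A tibble: `direction`, `category`, `n` (plus `n_prevented` for
#'   LPS classifications).
#' @export
summarize_categories <- function(classification) {
  if (nrow(classification) == 0) abort("Empty classification.")
  levels <- if (inherits(classification, "lps_classification")) {
    lps_category_levels
  } else {
    reversal_category_levels
  }
  grid <- tidyr::expand_grid(
    direction = intersect(c("increased", "decreased"),
                          unique(classification$direction)),
    category = levels
  )
  counts <- classification |>
    dplyr::count(.data$direction, .data$category)
  out <- grid |>
    dplyr::left_join(counts, by = c("direction", "category")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  if (inherits(classification, "lps_classification")) {
    prev <- classification |>
      dplyr::group_by(.data$direction, .data$category) |>
      dplyr::summarise(
        n_prevented = sum(.data$prevented_by_repop), .groups = "drop"
      )
    out <- out |>
      dplyr::left_join(prev, by = c("direction", "category")) |>
      dplyr::mutate(n_prevented = dplyr::coalesce(.data$n_prevented, 0L))
  }
  out
}

# Align a contrast result to a gene list; genes absent from the table come
# back with tested = FALSE and NA statistics.
contrast_lookup <- function(contrast, genes) {
  stopifnot(inherits(contrast, "contrast_result"))
  idx <- match(genes, contrast$gene_id)
  out <- contrast[idx, , drop = FALSE]
  out$gene_id <- genes
  out$tested[is.na(idx)] <- FALSE
  out
}
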