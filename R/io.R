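#' Read and write count tables
#'
#' Count tables are stored genes-as-rows, samples-as-columns, the layout used
#' for normalized bulk RNA-seq supplements. Delimiter is chosen by extension:
#' comma for `.csv`, tab for `.tsv`/`.tab`/`.txt`. On read the first column is
#' taken as gene identifiers whatever its header; on write it is always named
#' `gene_id`. Files that violate the count-table invariants (duplicate
#' identifiers, negative, non-numeric, or -- for raw counts -- non-integer
#' cells) are rejected with the offending coordinates; nothing is silently
#' dropped or reordered.
#'
#' @param path File path.
#' @param scale Scale flag to record on the table: `"raw"` or `"normalized"`.
#' @param x A [count_tbl()].
#' @return `read_count_matrix()` returns a [count_tbl()]; `write_count_matrix()`
#'   returns `path` invisibly.
#' @export
read_count_matrix <- function(path, scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  raw <- read_delim_chr(path)
  if (ncol(raw) < 2) abort("Count file needs a gene column and >= 1 sample column.")
  genes <- raw[[1]]
  samples <- names(raw)[-1]
  num <- purrr::imap(raw[-1], function(col, nm) {
    vals <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(vals) & !is.na(col))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-numeric value '", col[bad[1]], "' at gene '", genes[bad[1]],
        "', sample '", nm, "' in ", path
      ))
    }
    vals
  })
  out <- dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(num))
  count_tbl(out, scale = scale)
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_tbl"))
  write_delim_auto(x, path)
}

#' Read and write sample keys
#'
#' A sample key maps each sample to its factor levels: `age` (`adult`/`aged`),
#' `treatment` (`control`/`repopulation`) and optionally `stimulus`
#' (`saline`/`lps`). Unrecognized levels are rejected, never coerced. Any
#' additional numeric column is attached as a per-sample covariate (for
#' example user-supplied unwanted-variation factors) and listed in the
#' `covariates` attribute. A derived `group` column (`age` and `treatment`
#' pasted with `_`) is added if absent so cross-factor comparisons such as
#' aged-repopulation vs adult-control can be expressed as one factor.
#'
#' @param path File path.
#' @param design A sample-key tibble.
#' @return A tibble with columns `sample_id`, `age`, `treatment`, `group`,
#'   optional `stimulus` and covariates; attribute `covariates` names the
#'   covariate columns.
#' @export
read_sample_key <- function(path) {
  raw <- read_delim_chr(path)
  as_sample_key(raw, context = path)
}

#' @rdname read_sample_key
#' @export
write_sample_key <- function(design, path) {
  write_delim_auto(design, path)
}

design_levels <- list(
  age = c("adult", "aged"),
  treatment = c("control", "repopulation"),
  stimulus = c("saline", "lps")
)

as_sample_key <- function(x, context = "sample key") {
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "age", "treatment")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", context, ": ", toString(missing)))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(paste0(
      "Duplicate sample_id in ", context, ": ",
      toString(unique(x$sample_id[duplicated(x$sample_id)]))
    ))
  }
  for (f in intersect(names(design_levels), names(x))) {
    allowed <- design_levels[[f]]
    bad <- setdiff(unique(x[[f]]), allowed)
    if (length(bad) > 0) {
      abort(paste0(
        "Unknown ", f, " level(s) ", toString(sQuote(bad)),
        "; allowed: ", toString(allowed)
      ))
    }
  }
  extra <- setdiff(names(x), c(required, "stimulus", "group"))
  covars <- character(0)
  for (nm in extra) {
    vals <- suppressWarnings(as.numeric(x[[nm]]))
    if (!anyNA(vals)) {
      x[[nm]] <- vals
      covars <- c(covars, nm)
    }
  }
  if (!"group" %in% names(x)) {
    x$group <- paste(x$age, x$treatment, sep = "_")
  }
  x <- dplyr::relocate(
    x, "sample_id", "age", "treatment",
    dplyr::any_of(c("stimulus", "group"))
  )
  structure(x, covariates = covars)
}

#' Read and write per-gene results tables
#'
#' One writer serves contrast tables (`gene_id`, `baseMean`, `log2FC`,
#' `lfcSE`, `stat`, `pvalue`, `padj`), reversal classification tables
#' (`gene_id`, `direction`, `category`) and LPS classification tables
#' (`gene_id`, `direction`, `category`, `prevented_by_repop`). Column order
#' is fixed, missing statistics are written as the literal token `NA`, and
#' gene order is preserved as given. `read_results_table()` restores the
#' matching object class from the columns it finds.
#'
#' @param x A `contrast_result`, `reversal_classification` or
#'   `lps_classification`.
#' @param path File path (`.csv` or `.tsv`).
#' @return `read_results_table()` returns a tibble of the matching class;
#'   `write_results_table()` returns `path` invisibly.
#' @export
write_results_table <- function(x, path) {
  if (nrow(x) == 0) abort("Refusing to write an empty results table.")
  if (inherits(x, "contrast_result")) {
    out <- tibble::tibble(
      gene_id = x$gene_id, baseMean = x$base_mean, log2FC = x$log2fc,
      lfcSE = x$lfc_se, stat = x$stat, pvalue = x$pvalue, padj = x$padj
    )
  } else if (inherits(x, "lps_classification")) {
    out <- tibble::tibble(
      gene_id = x$gene_id, direction = x$direction, category = x$category,
      prevented_by_repop = x$prevented_by_repop
    )
  } else if (inherits(x, "reversal_classification")) {
    out <- tibble::tibble(
      gene_id = x$gene_id, direction = x$direction, category = x$category
    )
  } else {
    abort("Unsupported results object.")
  }
  write_delim_auto(out, path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  raw <- read_delim_chr(path)
  if (all(c("baseMean", "log2FC", "pvalue") %in% names(raw))) {
    out <- tibble::tibble(
      gene_id = raw$gene_id,
      base_mean = num_or_na(raw$baseMean),
      log2fc = num_or_na(raw$log2FC),
      lfc_se = num_or_na(raw$lfcSE),
      stat = num_or_na(raw$stat),
      pvalue = num_or_na(raw$pvalue),
      padj = num_or_na(raw$padj)
    )
    out$tested <- !is.na(out$pvalue)
    class(out) <- c("contrast_result", class(out))
  } else if ("prevented_by_repop" %in% names(raw)) {
    out <- tibble::tibble(
      gene_id = raw$gene_id, direction = raw$direction,
      category = raw$category,
      prevented_by_repop = as.logical(raw$prevented_by_repop)
    )
    class(out) <- c("lps_classification", class(out))
  } else if ("category" %in% names(raw)) {
    out <- tibble::tibble(
      gene_id = raw$gene_id, direction = raw$direction, category = raw$category
    )
    class(out) <- c("reversal_classification", class(out))
  } else {
    abort(paste0("Unrecognized results table layout in ", path))
  }
  out
}

#' Read and write comparative-CT (qPCR) tables
#'
#' Each row is one sample: its group label and the cycle-threshold values of
#' the target and reference (housekeeping) amplicons.
#'
#' @param path File path.
#' @param x A tibble with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @export
read_ddct_table <- function(path) {
  raw <- read_delim_chr(path)
  required <- c("sample_id", "group", "ct_target", "ct_reference")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ", toString(missing)))
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id, group = raw$group,
    ct_target = num_or_na(raw$ct_target),
    ct_reference = num_or_na(raw$ct_reference)
  )
  if (anyNA(out$ct_target) || anyNA(out$ct_reference) ||
    any(!is.finite(out$ct_target)) || any(!is.finite(out$ct_reference))) {
    abort(paste0("CT values in ", path, " must be finite numbers."))
  }
  out
}

#' @rdname read_ddct_table
#' @export
write_ddct_table <- function(x, path) {
  write_delim_auto(x, path)
}

# ---- shared dialect helpers -------------------------------------------------

num_or_na <- function(v) suppressWarnings(as.numeric(v))

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

read_delim_chr <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_delim(
    path,
    delim = delim_for(path),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
}

write_delim_auto <- function(x, path) {
  readr::write_delim(as.data.frame(x), path, delim = delim_for(path), na = "NA")
  invisible(path)
}
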