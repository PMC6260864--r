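#' Count tables
#'
#' A count table is a tibble whose first column, `gene_id`, holds unique gene
#' identifiers and whose remaining columns hold one sample each. The table
#' carries a `scale` attribute, either `"raw"` (integer sequencing counts)
#' or `"normalized"` (counts divided by per-sample size factors). All
#' downstream verbs ([estimate_size_factors()], [fit_contrast()], ...) take
#' the table as their first argument so calls chain with the pipe.
#'
#' @param x A data frame with a `gene_id` column followed by one numeric
#'   column per sample.
#' @param scale `"raw"` or `"normalized"`.
#' @return A `count_tbl`: a tibble with a `scale` attribute.
#' @examples
#' counts <- count_tbl(
#'   tibble::tibble(gene_id = c("g1", "g2"), s1 = c(5, 0), s2 = c(7, 1))
#' )
#' count_scale(counts)
#' @export
count_tbl <- function(x, scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    names(x)[1] <- "gene_id"
  }
  x <- dplyr::relocate(x, "gene_id")
  validate_count_tbl(x, scale)
  structure(x, scale = scale, class = c("count_tbl", class(tibble::tibble())))
}

validate_count_tbl <- function(x, scale) {
  genes <- x$gene_id
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("Duplicate gene identifier(s): ", toString(head(dup, 5))))
  }
  samples <- setdiff(names(x), "gene_id")
  if (length(samples) == 0) abort("Count table has no sample columns.")
  if (anyDuplicated(samples)) {
    abort(paste0(
      "Duplicate sample identifier(s): ",
      toString(unique(samples[duplicated(samples)]))
    ))
  }
  m <- as.matrix(x[samples])
  if (!is.numeric(m)) abort("All sample columns must be numeric.")
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Negative or non-finite count at gene '", genes[bad[1, 1]],
      "', sample '", samples[bad[1, 2]], "'."
    ))
  }
  if (scale == "raw") {
    nonint <- which(m != round(m), arr.ind = TRUE)
    if (nrow(nonint) > 0) {
      abort(paste0(
        "Raw counts must be integers; non-integer value at gene '",
        genes[nonint[1, 1]], "', sample '", samples[nonint[1, 2]], "'."
      ))
    }
  }
  invisible(x)
}

#' @rdname count_tbl
#' @export
count_scale <- function(x) attr(x, "scale") %||% "raw"

#' @rdname count_tbl
#' @export
sample_ids <- function(x) setdiff(names(x), "gene_id")

# gene x sample numeric matrix with dimnames
count_matrix <- function(x) {
  m <- as.matrix(x[sample_ids(x)])
  rownames(m) <- x$gene_id
  m
}

set_count_values <- function(x, m, scale) {
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = x$gene_id),
    tibble::as_tibble(m)
  )
  structure(out, scale = scale, class = class(x))
}
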