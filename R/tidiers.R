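#' Tidiers for repopsig result objects
#'
#' broom-style accessors: `tidy()` returns the per-gene (or per-replicate)
#' table as a plain tibble; `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy contrast_result
#' @export
tidy.contrast_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidiers
#' @method glance contrast_result
#' @export
glance.contrast_result <- function(x, ...) {
  ct <- attr(x, "contrast") %||% list()
  tibble::tibble(
    factor = ct$factor %||% NA_character_,
    numerator = ct$numerator %||% NA_character_,
    denominator = ct$denominator %||% NA_character_,
    n_genes = nrow(x),
    n_tested = sum(x$tested),
    n_signif = sum(x$padj < 0.05, na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @method tidy age_signature
#' @export
tidy.age_signature <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidiers
#' @method glance age_signature
#' @export
glance.age_signature <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_genes = nrow(x),
    n_increased = sum(x$direction == "increased"),
    n_decreased = sum(x$direction == "decreased"),
    alpha_adj = th$alpha_adj,
    fc_threshold = th$fc_threshold,
    base_mean_min = th$base_mean_min
  )
}

#' @rdname tidiers
#' @method tidy reversal_classification
#' @export
tidy.reversal_classification <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidiers
#' @method glance reversal_classification
#' @export
glance.reversal_classification <- function(x, ...) {
  counts <- table(factor(x$category, levels = reversal_category_levels))
  out <- tibble::as_tibble(as.list(counts))
  out$n_genes <- nrow(x)
  out$alpha <- attr(x, "alpha")
  out
}

#' @rdname tidiers
#' @method tidy lps_classification
#' @export
tidy.lps_classification <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidiers
#' @method glance lps_classification
#' @export
glance.lps_classification <- function(x, ...) {
  counts <- table(factor(x$category, levels = lps_category_levels))
  out <- tibble::as_tibble(as.list(counts))
  out$n_prevented <- sum(x$prevented_by_repop)
  out$n_genes <- nrow(x)
  out$alpha <- attr(x, "alpha")
  out
}

#' @rdname tidiers
#' @method tidy null_calibration
#' @export
tidy.null_calibration <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidiers
#' @method glance null_calibration
#' @export
glance.null_calibration <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(
      n_reps = 0L, mean_frac_p_below = NA_real_,
      mean_signature_size = NA_real_
    ))
  }
  tibble::tibble(
    n_reps = dplyr::n_distinct(x$rep),
    mean_frac_p_below = mean(x$frac_p_below),
    mean_signature_size = mean(x$signature_size[!duplicated(x$rep)])
  )
}

#' @rdname tidiers
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  x$per_category
}

#' @rdname tidiers
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  x$signature
}
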