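#' Interactor classification thresholds from wild-type controls
#'
#' The screen calls a genotype an interactor when its mean normalized
#' dumping index moves far enough from the wild-type reference, measured in
#' units of the aggregate wild-type variability: sigma is the sample SD of
#' the pooled, QC-passing, non-normalized wild-type control dumping indices
#' across all experiments. The weak band starts at 1 sigma and the strong
#' band at 3 sigma.
#'
#' @param control_dis Numeric vector of at least two QC-passing wild-type
#'   control dumping indices.
#' @return A `threshold_spec` object: list with `sigma`, `weak_bound`
#'   (= sigma), `strong_bound` (= 3 sigma), `n_controls`, `source`.
#' @examples
#' thresholds_from_controls(c(0.45, 0.50, 0.55, 0.52))
#' @export
thresholds_from_controls <- function(control_dis) {
  control_dis <- control_dis[!is.na(control_dis)]
  if (length(control_dis) < 2) {
    abort("at least two control dumping indices are required (SD undefined)")
  }
  sigma <- sd(control_dis)
  if (sigma == 0) {
    warn("all control dumping indices identical: sigma = 0, every nonzero effect will be called strong")
  }
  new_threshold_spec(sigma, n_controls = length(control_dis), source = "computed")
}

#' Thresholds from a supplied aggregate control SD
#'
#' Builds the same 1x/3x classification bands as
#' [thresholds_from_controls()] from an externally supplied sigma — for
#' example, to classify new data against a previously published aggregate
#' control SD rather than the input's own controls.
#'
#' @param sigma Aggregate wild-type control dumping-index sample SD (> 0
#'   or 0 with a degeneracy warning).
#' @param n_controls Optional count of controls behind the supplied sigma.
#' @return A `threshold_spec` object.
#' @examples
#' thresholds_from_sigma(0.054) # weak 0.054, strong 0.162
#' @export
thresholds_from_sigma <- function(sigma, n_controls = NA_integer_) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  if (sigma == 0) warn("sigma = 0: degenerate thresholds")
  new_threshold_spec(sigma, n_controls = n_controls, source = "supplied")
}

new_threshold_spec <- function(sigma, n_controls, source) {
  structure(
    list(
      sigma = sigma,
      weak_bound = sigma,
      strong_bound = 3 * sigma,
      n_controls = n_controls,
      source = source
    ),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("Interactor classification thresholds (", x$source, ")\n", sep = "")
  cat(sprintf("  sigma (aggregate control DI SD): %.6g\n", x$sigma))
  cat(sprintf("  weak band  (1 sigma): |mean normalized index| >= %.6g\n", x$weak_bound))
  cat(sprintf("  strong band (3 sigma): |mean normalized index| >= %.6g\n", x$strong_bound))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_spec <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma, weak_bound = x$weak_bound, strong_bound = x$strong_bound,
    n_controls = x$n_controls, source = x$source
  )
}

band_levels <- c("non_interactor", "weak", "strong")
direction_levels <- c("none", "enhancer", "suppressor")

#' Classify a mean normalized dumping index into interactor bands
#'
#' Partition of the real line by effect magnitude in aggregate-control SD
#' units: `|x| < sigma` is a non-interactor, `sigma <= |x| < 3 sigma` a weak
#' interactor, and `|x| >= 3 sigma` a strong interactor. Direction follows
#' the sign convention of within-experiment normalization: negative means
#' enhanced sensitivity to COX inhibition (enhancer), positive means
#' suppressed sensitivity (suppressor); non-interactors have direction
#' `none`.
#'
#' @param mean_norm Mean normalized dumping index (vectorized).
#' @param spec A `threshold_spec`.
#' @return A tibble with columns `band` and `direction` (factors).
#' @examples
#' classify(c(-0.275, 0.0, -0.10), thresholds_from_sigma(0.054))
#' @export
classify <- function(mean_norm, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  mag <- abs(mean_norm)
  band <- dplyr::case_when(
    mag >= spec$strong_bound ~ "strong",
    mag >= spec$weak_bound ~ "weak",
    TRUE ~ "non_interactor"
  )
  direction <- dplyr::case_when(
    band == "non_interactor" ~ "none",
    mean_norm < 0 ~ "enhancer",
    TRUE ~ "suppressor"
  )
  tibble::tibble(
    band = factor(band, levels = band_levels),
    direction = factor(direction, levels = direction_levels)
  )
}

#' Classify every genotype of an aggregated screen
#'
#' Joins interactor calls onto the per-genotype summary table. The control
#' genotype, whose normalized index is 0 by construction, is always a
#' non-interactor. Single-replicate genotypes keep their call but remain
#' flagged provisional.
#'
#' @param summaries Output of [aggregate_genotypes()].
#' @param spec A `threshold_spec`.
#' @return `summaries` with added `band`, `direction`, and a human-readable
#'   `class` label (e.g. `"strong enhancer"`).
#' @export
classify_genotypes <- function(summaries, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (nrow(summaries) == 0) {
    return(dplyr::mutate(
      summaries,
      band = factor(character(), levels = band_levels),
      direction = factor(character(), levels = direction_levels),
      class = character()
    ))
  }
  calls <- classify(summaries$mean_norm, spec)
  out <- dplyr::bind_cols(summaries, calls)
  out$class <- ifelse(
    out$band == "non_interactor", "non-interactor",
    paste(as.character(out$band), as.character(out$direction))
  )
  out
}

#' Machine-readable classification report
#'
#' Serializes a classified screen (per-genotype calls plus the thresholds
#' used) to JSON, the audit-friendly twin of the screen's classification
#' chart.
#'
#' @param classified Output of [classify_genotypes()].
#' @param spec The `threshold_spec` used for the calls.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
classification_report <- function(classified, spec, path = NULL) {
  payload <- list(
    thresholds = tidy(spec),
    genotypes = dplyr::mutate(
      classified,
      band = as.character(.data$band),
      direction = as.character(.data$direction)
    )
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
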