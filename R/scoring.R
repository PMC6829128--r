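#' Fraction of follicles completing nurse cell dumping
#'
#' A cultured Stage-10B follicle is scored as having completed nurse cell
#' dumping when it progresses to Stage 12 or 13/14 overnight; follicles
#' remaining in S10B or S11 have not dumped. The dumping fraction of a well
#' is the dumped count over the total scored.
#'
#' All arguments are vectorized and recycled by the usual rules.
#'
#' @param n_s10b,n_s11,n_s12,n_s13_14 Non-negative integer follicle counts
#'   per stage bucket.
#' @return Numeric vector of dumping fractions in \[0, 1\].
#' @examples
#' dumping_fraction(2, 0, 5, 18) # 23/25
#' @export
dumping_fraction <- function(n_s10b, n_s11, n_s12, n_s13_14) {
  counts <- cbind(n_s10b, n_s11, n_s12, n_s13_14)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("stage counts must be non-negative integers")
  }
  total <- rowSums(counts)
  if (any(total < 1)) abort("no follicles scored in at least one well")
  as.numeric((counts[, 3L] + counts[, 4L]) / total)
}

#' Dumping index: aspirin-to-vehicle ratio of dumping fractions
#'
#' The per-replicate statistic of the screen: the fraction of follicles
#' completing dumping in aspirin medium divided by the fraction completing
#' dumping in vehicle medium for the same genotype in the same experiment.
#' At the screening dose (1.5 mM aspirin, calibrated to block half of
#' wild-type maturation) wild-type controls are expected near 0.5.
#'
#' @param f_aspirin Dumping fraction in aspirin medium, in \[0, 1\].
#' @param f_vehicle Dumping fraction in vehicle medium, in (0, 1\].
#' @return `f_aspirin / f_vehicle`. A vehicle fraction of zero makes the
#'   index undefined and is an error — the replicate is unusable, never
#'   silently 0 or infinite.
#' @examples
#' dumping_index(0.46, 0.92) # 0.5
#' @export
dumping_index <- function(f_aspirin, f_vehicle) {
  stopifnot(all(f_aspirin >= 0 & f_aspirin <= 1), all(f_vehicle >= 0 & f_vehicle <= 1))
  if (any(f_vehicle == 0)) {
    abort("dumping index undefined: vehicle dumping fraction is 0 (experiment unusable)")
  }
  f_aspirin / f_vehicle
}

#' Wild-type quality-control rule for an experiment
#'
#' An experiment is kept only when its wild-type control dumping index lies
#' inside the QC band; the band defaults to \[0.4, 0.6\] with inclusive
#' endpoints (experiments are excluded when the control index is strictly
#' below 0.4 or strictly above 0.6). QC is evaluated on the control genotype
#' only; experimental genotypes never trigger exclusion.
#'
#' @param control_di Control dumping index (vectorized, non-negative).
#' @param qc_band Length-two numeric, lower and upper inclusive bounds.
#' @return Logical vector: `TRUE` when the experiment passes QC.
#' @examples
#' qc_experiment(c(0.505, 0.39, 0.40))
#' @export
qc_experiment <- function(control_di, qc_band = c(0.4, 0.6)) {
  stopifnot(length(qc_band) == 2, qc_band[1] < qc_band[2],
            all(control_di >= 0, na.rm = TRUE))
  control_di >= qc_band[1] & control_di <= qc_band[2]
}

#' Normalized dumping index
#'
#' Subtracts the same experiment's wild-type control dumping index from a
#' genotype's dumping index, removing shared batch effects (e.g. aspirin
#' potency drift between experiments). Negative values indicate enhanced
#' sensitivity to COX inhibition (enhancer), positive values suppressed
#' sensitivity (suppressor); the control normalizes to exactly 0.
#'
#' @param di_experimental Dumping index of the experimental genotype.
#' @param di_control Dumping index of the wild-type control from the same
#'   experiment.
#' @return `di_experimental - di_control` (vectorized).
#' @export
normalize_index <- function(di_experimental, di_control) {
  di_experimental - di_control
}

#' Score a screen table into per-experiment dumping indices
#'
#' For every (experiment, genotype) with both treatment arms present,
#' computes the vehicle and aspirin dumping fractions, the dumping index,
#' and the normalized dumping index against that experiment's wild-type
#' control; applies the wild-type QC rule, carrying the experiment's QC
#' status onto every genotype scored in it.
#'
#' Experiments whose control has a vehicle dumping fraction of zero (index
#' undefined) or lacks a paired control arm are marked unusable
#' (`qc_pass = NA`) with a diagnostic attached as the `dropped` attribute.
#'
#' @param table A `screen_tbl` (or data frame with canonical columns).
#' @param control_genotype Control label; defaults to the label recorded on
#'   the table, else `"yw"`.
#' @param qc_band Inclusive QC band for the control dumping index.
#' @return A tibble with one row per (experiment_id, genotype):
#'   `f_vehicle`, `f_aspirin`, `dumping_index`, `normalized_index`,
#'   `is_control`, `qc_pass`.
#' @export
score_screen <- function(table, control_genotype = NULL, qc_band = c(0.4, 0.6)) {
  ctrl <- control_genotype %||% attr(table, "control_genotype") %||% "yw"
  empty <- tibble::tibble(
    experiment_id = character(), genotype = character(),
    f_vehicle = double(), f_aspirin = double(),
    dumping_index = double(), normalized_index = double(),
    is_control = logical(), qc_pass = logical()
  )
  tbl <- tibble::as_tibble(table)
  if (nrow(tbl) == 0) return(empty)

  wells <- tbl |>
    dplyr::mutate(.f = dumping_fraction(.data$n_s10b, .data$n_s11, .data$n_s12, .data$n_s13_14)) |>
    dplyr::select("experiment_id", "genotype", "treatment", ".f") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = ".f",
                       names_prefix = "f_")
  if (!"f_vehicle" %in% names(wells)) wells$f_vehicle <- NA_real_
  if (!"f_aspirin" %in% names(wells)) wells$f_aspirin <- NA_real_

  dropped <- character()
  incomplete <- !complete.cases(wells[c("f_vehicle", "f_aspirin")])
  if (any(incomplete)) {
    dropped <- c(dropped, paste0(
      "unpaired wells (missing treatment arm): ",
      paste(wells$experiment_id[incomplete], wells$genotype[incomplete],
            sep = "/", collapse = ", ")
    ))
  }

  scores <- wells |>
    dplyr::mutate(
      dumping_index = dplyr::if_else(
        !is.na(.data$f_vehicle) & .data$f_vehicle > 0,
        .data$f_aspirin / .data$f_vehicle, NA_real_
      ),
      is_control = .data$genotype == ctrl
    )
  zero_ctrl <- scores$is_control & !is.na(scores$f_vehicle) & scores$f_vehicle == 0
  if (any(zero_ctrl)) {
    dropped <- c(dropped, paste0(
      "control vehicle dumping fraction is 0; experiment unusable: ",
      paste(scores$experiment_id[zero_ctrl], collapse = ", ")
    ))
  }

  ctrl_di <- scores |>
    dplyr::filter(.data$is_control) |>
    dplyr::select("experiment_id", control_di = "dumping_index")
  out <- scores |>
    dplyr::left_join(ctrl_di, by = "experiment_id") |>
    dplyr::mutate(
      normalized_index = normalize_index(.data$dumping_index, .data$control_di),
      qc_pass = dplyr::if_else(
        is.na(.data$control_di), NA,
        qc_experiment(.data$control_di, qc_band)
      )
    ) |>
    dplyr::select(
      "experiment_id", "genotype", "f_vehicle", "f_aspirin",
      "dumping_index", "normalized_index", "is_control", "qc_pass"
    )
  no_ctrl <- unique(out$experiment_id[is.na(out$qc_pass)])
  if (length(no_ctrl)) {
    dropped <- c(dropped, paste0(
      "experiments without a usable control dumping index: ",
      paste(no_ctrl, collapse = ", ")
    ))
  }
  attr(out, "dropped") <- dropped
  attr(out, "control_genotype") <- ctrl
  out
}

#' Aggregate per-experiment scores into per-genotype summaries
#'
#' Averages the dumping index and the normalized dumping index over the
#' QC-passing replicates of each genotype. SDs use the sample (n - 1)
#' definition and are reported as missing — never 0 — for single-replicate
#' genotypes, which are flagged `provisional`.
#'
#' @param scores Output of [score_screen()].
#' @param genotype Optional label(s) to restrict aggregation to; by default
#'   all genotypes with at least one usable replicate are summarized.
#' @param include_qc_fail Keep replicates from QC-failing experiments
#'   (default `FALSE`, matching the screen's exclusion rule).
#' @return A tibble with `genotype`, `n`, `mean_di`, `sd_di`, `mean_norm`,
#'   `sd_norm`, `provisional`.
#' @export
aggregate_genotypes <- function(scores, genotype = NULL, include_qc_fail = FALSE) {
  usable <- scores |>
    dplyr::filter(!is.na(.data$dumping_index), !is.na(.data$qc_pass)) |>
    dplyr::filter(include_qc_fail | .data$qc_pass)
  if (!is.null(genotype)) {
    usable <- dplyr::filter(usable, .data$genotype %in% !!genotype)
    if (nrow(usable) == 0) {
      abort(paste0(
        "no usable (QC-passing) replicates for genotype(s): ",
        paste(genotype, collapse = ", ")
      ))
    }
  }
  usable |>
    dplyr::group_by(genotype = .data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_di = mean(.data$dumping_index),
      sd_di = if (dplyr::n() > 1) sd(.data$dumping_index) else NA_real_,
      mean_norm = mean(.data$normalized_index),
      sd_norm = if (dplyr::n() > 1) sd(.data$normalized_index) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(provisional = .data$n == 1L)
}
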