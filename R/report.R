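#' Full screen analysis: score, QC, aggregate, classify
#'
#' One-call pipeline over a validated screen table: per-experiment scoring
#' and QC ([score_screen()]), replicate aggregation
#' ([aggregate_genotypes()]), threshold derivation, and interactor
#' classification ([classify_genotypes()]).
#'
#' Sigma — the aggregate control dumping-index SD defining the
#' classification bands — is either computed from the input's own
#' QC-passing controls (the default) or supplied, e.g. to reuse a
#' previously published aggregate band on new data. The result records
#' which.
#'
#' @param table A `screen_tbl` (see [read_screen_table()],
#'   [simulate_screen()]).
#' @param control_genotype Control label; defaults to the table's.
#' @param qc_band Inclusive QC band for the control dumping index.
#' @param sigma Optional externally supplied aggregate control SD.
#' @return A `screen_analysis` object: list with `scores`, `summaries`,
#'   `thresholds`, `classified`, `qc_excluded` (experiment ids),
#'   `control_genotype`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
analyze_screen <- function(table, control_genotype = NULL,
                           qc_band = c(0.4, 0.6), sigma = NULL) {
  ctrl <- control_genotype %||% attr(table, "control_genotype") %||% "yw"
  scores <- score_screen(table, control_genotype = ctrl, qc_band = qc_band)
  ctrl_di <- scores$dumping_index[scores$is_control & scores$qc_pass %in% TRUE]
  spec <- if (is.null(sigma)) {
    if (length(ctrl_di) < 2) {
      abort("fewer than 2 QC-passing controls: supply `sigma` explicitly")
    }
    thresholds_from_controls(ctrl_di)
  } else {
    thresholds_from_sigma(sigma)
  }
  summaries <- aggregate_genotypes(scores)
  classified <- classify_genotypes(summaries, spec)
  qc_excluded <- unique(scores$experiment_id[scores$qc_pass %in% FALSE])
  structure(
    list(
      scores = scores, summaries = summaries, thresholds = spec,
      classified = classified, qc_excluded = qc_excluded,
      control_genotype = ctrl
    ),
    class = "screen_analysis"
  )
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("Pharmaco-genetic screen analysis\n")
  cat("  control genotype:", x$control_genotype, "\n")
  cat("  experiments:", length(unique(x$scores$experiment_id)),
      "| QC-excluded:", length(x$qc_excluded), "\n")
  cat(sprintf("  sigma = %.4g (%s); bands at %.4g / %.4g\n",
              x$thresholds$sigma, x$thresholds$source,
              x$thresholds$weak_bound, x$thresholds$strong_bound))
  counts <- table(x$classified$class)
  cat("  calls:", paste(names(counts), counts, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.screen_analysis <- function(x, ...) {
  tibble::as_tibble(x$classified)
}

#' @exportS3Method generics::glance
glance.screen_analysis <- function(x, ...) {
  tibble::tibble(
    n_experiments = length(unique(x$scores$experiment_id)),
    n_qc_excluded = length(x$qc_excluded),
    n_genotypes = nrow(x$classified),
    sigma = x$thresholds$sigma,
    weak_bound = x$thresholds$weak_bound,
    strong_bound = x$thresholds$strong_bound,
    sigma_source = x$thresholds$source
  )
}

#' Classification chart of a screen analysis
#'
#' Per-genotype mean normalized dumping index with SD error bars, dashed
#' lines at +/- 1 sigma and solid lines at +/- 3 sigma — the standard
#' presentation of a modifier screen's classification.
#'
#' @param object A `screen_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.screen_analysis <- function(object, ...) {
  d <- object$classified
  d$genotype <- stats::reorder(d$genotype, d$mean_norm)
  s <- object$thresholds
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$mean_norm)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = c(-s$weak_bound, s$weak_bound),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = c(-s$strong_bound, s$strong_bound),
                        colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_norm - dplyr::coalesce(.data$sd_norm, 0),
      ymax = .data$mean_norm + dplyr::coalesce(.data$sd_norm, 0),
      colour = .data$direction
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean normalized dumping index",
                  colour = "direction") +
    ggplot2::theme_minimal()
}

pg_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Simulate a screen from a configuration and write it to CSV
#'
#' Configuration-driven front end to [simulate_screen()]. A seed is
#' mandatory: re-running the same configuration must reproduce the same
#' table byte for byte.
#'
#' @param config A [sim_screen_config()], or a path to a YAML/JSON file
#'   whose fields match its arguments (genotypes as a list of records).
#' @param output Output CSV path.
#' @return The output path, invisibly.
#' @export
run_simulate <- function(config, output) {
  if (is.character(config)) {
    cfg <- read_run_config(config)
    genotypes <- NULL
    if (!is.null(cfg$genotypes)) {
      genotypes <- purrr::map_dfr(cfg$genotypes, function(g) {
        do.call(sim_genotype, g)
      })
    }
    if (is.null(cfg$seed)) abort("simulation config must contain a seed")
    config <- sim_screen_config(
      genotypes = genotypes,
      control_label = cfg$control_label %||% "yw",
      control_p_vehicle = cfg$control_p_vehicle %||% 0.92,
      control_p_aspirin = cfg$control_p_aspirin %||% 0.50,
      tau = cfg$tau %||% 0,
      n_experiments = cfg$n_experiments %||% 5,
      follicles_range = unlist(cfg$follicles_range %||% c(20L, 30L)),
      dumped_split = cfg$dumped_split %||% 0.5,
      undumped_split = cfg$undumped_split %||% 0.5,
      aspirin_mM = cfg$aspirin_mM %||% 1.5,
      seed = cfg$seed
    )
  }
  tbl <- simulate_screen(config)
  write_screen_table(tbl, output)
  pg_log("simulated ", config$n_experiments, " experiment(s) to ", output)
  invisible(output)
}

#' Score a screen CSV and write score, summary, and QC tables
#'
#' Reads, validates and scores a screen table, then writes three TSVs to
#' `output_dir`: `scores.tsv` (per experiment x genotype), `summary.tsv`
#' (per genotype, QC-passing replicates only), and `qc_report.tsv` (one row
#' per experiment with its control dumping index and QC outcome). QC
#' exclusions and structural problems are logged.
#'
#' @param input Path to a screen CSV/TSV.
#' @param output_dir Output directory (created if missing).
#' @param control_genotype Control label.
#' @param qc_band Inclusive QC band.
#' @param dialect Column dialect for [read_screen_table()].
#' @return Named character vector of output paths, invisibly.
#' @export
run_score <- function(input, output_dir, control_genotype = "yw",
                      qc_band = c(0.4, 0.6), dialect = screen_dialect()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- read_screen_table(input, dialect = dialect,
                           control_genotype = control_genotype)
  probs <- screen_problems(tbl)
  for (m in probs$message) pg_log(m, level = "WARN")
  scores <- score_screen(tbl, control_genotype = control_genotype, qc_band = qc_band)
  qc <- scores |>
    dplyr::filter(.data$is_control) |>
    dplyr::transmute(.data$experiment_id, control_di = .data$dumping_index,
                     .data$qc_pass)
  for (eid in qc$experiment_id[qc$qc_pass %in% FALSE]) {
    pg_log("experiment ", eid, " excluded by QC (control dumping index ",
           format(qc$control_di[qc$experiment_id == eid]), ")", level = "WARN")
  }
  paths <- c(
    scores = file.path(output_dir, "scores.tsv"),
    summary = file.path(output_dir, "summary.tsv"),
    qc = file.path(output_dir, "qc_report.tsv")
  )
  readr::write_tsv(scores, paths[["scores"]])
  summaries <- aggregate_genotypes(scores)
  if (nrow(summaries)) {
    out <- summaries
    out$class <- ifelse(out$provisional, "provisional", NA_character_)
    out$provisional <- NULL
    write_summary_table(out, paths[["summary"]])
  } else {
    readr::write_tsv(
      tibble::tibble(genotype = character(), n = integer(), mean_di = double(),
                     sd_di = double(), mean_norm = double(), sd_norm = double(),
                     class = character()),
      paths[["summary"]]
    )
    pg_log("no QC-passing experiments; summary table is empty", level = "WARN")
  }
  readr::write_tsv(qc, paths[["qc"]])
  invisible(paths)
}

#' Classify a screen and write the report artifacts
#'
#' Runs [analyze_screen()] on a screen CSV and writes the JSON
#' classification report plus `chart_table.tsv`, the machine-readable twin
#' of the classification chart (per-genotype mean normalized index, SD, and
#' the threshold values). The log records the QC exclusions, the sigma used
#' and whether it was computed or supplied.
#'
#' @inheritParams run_score
#' @param sigma Optional supplied aggregate control SD; when `NULL` sigma
#'   is computed from the input's own QC-passing controls.
#' @return Named character vector of output paths, invisibly.
#' @export
run_report <- function(input, output_dir, control_genotype = "yw",
                       qc_band = c(0.4, 0.6), sigma = NULL,
                       dialect = screen_dialect()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- read_screen_table(input, dialect = dialect,
                           control_genotype = control_genotype)
  ana <- analyze_screen(tbl, control_genotype = control_genotype,
                        qc_band = qc_band, sigma = sigma)
  for (eid in ana$qc_excluded) pg_log("experiment ", eid, " excluded by QC", level = "WARN")
  pg_log("sigma = ", format(ana$thresholds$sigma), " (", ana$thresholds$source,
         "); bands at ", format(ana$thresholds$weak_bound), " / ",
         format(ana$thresholds$strong_bound))
  paths <- c(
    classification = file.path(output_dir, "classification.json"),
    chart = file.path(output_dir, "chart_table.tsv")
  )
  classification_report(ana$classified, ana$thresholds, paths[["classification"]])
  chart <- ana$classified |>
    dplyr::transmute(
      .data$genotype, .data$n, .data$mean_norm, .data$sd_norm,
      weak_bound = ana$thresholds$weak_bound,
      strong_bound = ana$thresholds$strong_bound,
      band = as.character(.data$band), direction = as.character(.data$direction)
    )
  readr::write_tsv(chart, paths[["chart"]])
  invisible(paths)
}

#' Dunnett comparison report for a scored screen
#'
#' Tests every experimental genotype's QC-passing dumping indices against
#' the pooled wild-type control with one-way ANOVA plus Dunnett many-to-one
#' comparisons, the family being all experimental genotypes in the call.
#' Genotypes with fewer than two usable replicates are skipped with a log
#' note (their test is undefined).
#'
#' @param scores Output of [score_screen()].
#' @param control_genotype Control label (defaults to the scores' own).
#' @return A tibble: one row per tested genotype with group sizes, means,
#'   `statistic`, `df`, `p_raw`, `p_adj`, `method`, plus the ANOVA F and p
#'   as attributes `anova_f`, `anova_p`.
#' @export
screen_stats <- function(scores, control_genotype = NULL) {
  ctrl <- control_genotype %||% attr(scores, "control_genotype") %||% "yw"
  usable <- dplyr::filter(scores, .data$qc_pass %in% TRUE, !is.na(.data$dumping_index))
  ctrl_di <- usable$dumping_index[usable$genotype == ctrl]
  if (length(ctrl_di) < 2) abort("need >= 2 QC-passing control replicates for testing")
  exp_split <- split(usable$dumping_index[usable$genotype != ctrl],
                     usable$genotype[usable$genotype != ctrl])
  small <- names(exp_split)[lengths(exp_split) < 2]
  for (g in small) pg_log("genotype ", g, " has < 2 usable replicates; skipped", level = "WARN")
  exp_split <- exp_split[lengths(exp_split) >= 2]
  if (length(exp_split) == 0) abort("no experimental genotype has >= 2 usable replicates")
  fam <- c(list(control = ctrl_di), exp_split)
  aov_res <- one_way_anova(setNames(fam, make.unique(names(fam))))
  dn <- dunnett_many_to_one(ctrl_di, exp_split)
  out <- dplyr::mutate(dn, control_mean = mean(ctrl_di), control_n = length(ctrl_di),
                       .after = "label")
  attr(out, "anova_f") <- aov_res$statistic
  attr(out, "anova_p") <- aov_res$p_value
  out
}

#' Quantify corrected membrane intensity for a batch of image stacks
#'
#' For each job, reads (or takes) an image stack, maximum-projects the
#' requested slices, and measures the background-corrected membrane
#' intensity; results are written as one TSV row per image.
#'
#' @param jobs A list of jobs, each a list with fields `image` (path to a
#'   TIFF, or an in-memory list of matrices), `membrane` (a [line_probe()]
#'   or a path readable by [read_line_probe()]), `cytoplasm` (a
#'   [region_probe()]), and optionally `slices` (indices to project,
#'   default all) and `id`.
#' @param output Optional TSV output path.
#' @return A tibble with one row per job: `id`, `membrane_mean`,
#'   `cytoplasm_mean`, `corrected`, `flagged_negative`.
#' @export
run_quantify_images <- function(jobs, output = NULL) {
  res <- purrr::imap_dfr(jobs, function(job, i) {
    stack <- if (is.character(job$image)) read_image_stack(job$image) else job$image
    img <- max_project(stack, job$slices %||% seq_along(stack))
    mem <- if (is.character(job$membrane)) read_line_probe(job$membrane) else job$membrane
    ci <- corrected_membrane_intensity(img, mem, job$cytoplasm)
    dplyr::mutate(ci, id = as.character(job$id %||% i), .before = 1)
  })
  if (!is.null(output)) readr::write_tsv(res, output)
  res
}
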