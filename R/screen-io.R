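#' Column-name dialect for screen tables
#'
#' Screens exported from different lab notebooks rarely agree on headers. A
#' dialect maps the canonical column names used throughout pgscreen to the
#' names found in a particular file. Any canonical name not remapped keeps
#' its default.
#'
#' Canonical columns: `experiment_id`, `genotype`, `treatment` (one of
#' `"vehicle"` or `"aspirin"`), `aspirin_mM`, and the four stage-bucket
#' counts `n_s10b`, `n_s11`, `n_s12`, `n_s13_14`. The optional `allele_note`
#' column carries free text and is never validated.
#'
#' @param ... Named character scalars, e.g. `genotype = "strain"` meaning the
#'   file stores the genotype under a column called `strain`.
#' @return A named character vector mapping canonical names to file names.
#' @examples
#' screen_dialect()
#' screen_dialect(genotype = "strain", n_s13_14 = "n_s13.14")
#' @export
screen_dialect <- function(...) {
  default <- c(
    experiment_id = "experiment_id", genotype = "genotype",
    treatment = "treatment", aspirin_mM = "aspirin_mM",
    n_s10b = "n_s10b", n_s11 = "n_s11", n_s12 = "n_s12",
    n_s13_14 = "n_s13_14", allele_note = "allele_note"
  )
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(default))
    if (length(bad)) {
      abort(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")))
    }
    default[names(override)] <- override
  }
  default
}

count_cols <- c("n_s10b", "n_s11", "n_s12", "n_s13_14")

#' Read a follicle-maturation screen table
#'
#' Reads a delimited file with one culture well per row and validates it into
#' the canonical screen layout. Each well records the experiment it belongs
#' to, the genotype, the treatment arm (vehicle or aspirin), and follicle
#' counts in the four developmental-stage buckets scored in the maturation
#' assay (S10B, S11, S12, S13/14).
#'
#' Validation is total: every malformed count yields a diagnostic naming the
#' offending row, and no row is ever silently dropped. Experiments missing a
#' paired wild-type control in either treatment arm are flagged as structural
#' problems (retrievable with [screen_problems()]) but the table is still
#' returned, since such experiments may be deliberately incomplete.
#'
#' @param path Path to a CSV or TSV file with a header row. Tab separation is
#'   assumed for `.tsv`/`.tab` extensions, comma otherwise.
#' @param dialect Column-name mapping from [screen_dialect()].
#' @param control_genotype Label of the wild-type control genotype run in
#'   every experiment. Defaults to `"yw"`.
#' @return A tibble of class `screen_tbl` with canonical columns, row order
#'   preserved. Attributes: `control_genotype`, and `problems` (a tibble of
#'   structural warnings).
#' @seealso [as_screen_table()] for validating an in-memory data frame,
#'   [screen_problems()] for the collected diagnostics.
#' @export
read_screen_table <- function(path, dialect = screen_dialect(),
                              control_genotype = "yw") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  required <- setdiff(names(screen_dialect()), "allele_note")
  missing <- required[!(dialect[required] %in% names(raw))]
  # aspirin_mM may be absent entirely (vehicle-only default handling)
  missing <- setdiff(missing, "aspirin_mM")
  if (length(missing)) {
    abort(paste0(
      "screen table is missing required column(s): ",
      paste(dialect[missing], collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    experiment_id = as.character(raw[[dialect[["experiment_id"]]]]),
    genotype = as.character(raw[[dialect[["genotype"]]]]),
    treatment = tolower(trimws(as.character(raw[[dialect[["treatment"]]]])))
  )
  if (dialect[["aspirin_mM"]] %in% names(raw)) {
    out$aspirin_mM <- suppressWarnings(as.numeric(raw[[dialect[["aspirin_mM"]]]]))
  } else {
    out$aspirin_mM <- ifelse(out$treatment == "aspirin", 1.5, 0)
  }
  for (col in count_cols) {
    vals <- raw[[dialect[[col]]]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      abort(paste0(
        "column '", dialect[[col]], "' must hold non-negative integer counts; ",
        "offending row(s): ", paste(head(bad, 10), collapse = ", ")
      ))
    }
    out[[col]] <- as.integer(num)
  }
  if ("allele_note" %in% names(dialect) && dialect[["allele_note"]] %in% names(raw)) {
    out$allele_note <- as.character(raw[[dialect[["allele_note"]]]])
  }
  as_screen_table(out, control_genotype = control_genotype)
}

#' Validate an in-memory data frame as a screen table
#'
#' Applies the same validation as [read_screen_table()] to a data frame that
#' already uses canonical column names (for example, the output of
#' [simulate_screen()] or a table assembled by hand).
#'
#' @param x A data frame with canonical screen columns.
#' @inheritParams read_screen_table
#' @return A `screen_tbl` tibble; see [read_screen_table()].
#' @export
as_screen_table <- function(x, control_genotype = "yw") {
  x <- tibble::as_tibble(x)
  required <- c("experiment_id", "genotype", "treatment", count_cols)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  bad_trt <- which(!(x$treatment %in% c("vehicle", "aspirin")))
  if (length(bad_trt)) {
    abort(paste0(
      "treatment must be 'vehicle' or 'aspirin'; offending row(s): ",
      paste(head(bad_trt, 10), collapse = ", ")
    ))
  }
  for (col in count_cols) {
    v <- x[[col]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(paste0(
        "column '", col, "' must hold non-negative integer counts; ",
        "offending row(s): ", paste(head(bad, 10), collapse = ", ")
      ))
    }
    x[[col]] <- as.integer(v)
  }
  if (!"aspirin_mM" %in% names(x)) {
    x$aspirin_mM <- ifelse(x$treatment == "aspirin", 1.5, 0)
  }
  dup <- duplicated(x[c("experiment_id", "genotype", "treatment")])
  if (any(dup)) {
    abort(paste0(
      "duplicate (experiment_id, genotype, treatment) key(s) at row(s): ",
      paste(head(which(dup), 10), collapse = ", ")
    ))
  }
  problems <- collect_problems(x, control_genotype)
  structure(
    x,
    class = c("screen_tbl", class(tibble::tibble())),
    control_genotype = control_genotype,
    problems = problems
  )
}

# Structural diagnostics: every experiment must carry the wild-type control
# in both treatment arms; vehicle wells should not report an aspirin dose.
collect_problems <- function(x, control_genotype) {
  probs <- list()
  for (eid in unique(x$experiment_id)) {
    sub <- x[x$experiment_id == eid & x$genotype == control_genotype, ]
    missing_arms <- setdiff(c("vehicle", "aspirin"), sub$treatment)
    if (length(missing_arms)) {
      probs[[length(probs) + 1L]] <- tibble::tibble(
        experiment_id = eid, type = "missing_control",
        message = paste0(
          "experiment '", eid, "' lacks a paired control ('", control_genotype,
          "') well in arm(s): ", paste(missing_arms, collapse = ", ")
        )
      )
    }
  }
  dosed_vehicle <- which(x$treatment == "vehicle" & !is.na(x$aspirin_mM) & x$aspirin_mM != 0)
  for (i in dosed_vehicle) {
    probs[[length(probs) + 1L]] <- tibble::tibble(
      experiment_id = x$experiment_id[i], type = "dosed_vehicle",
      message = paste0("row ", i, ": vehicle well reports nonzero aspirin_mM")
    )
  }
  if (length(probs)) dplyr::bind_rows(probs) else {
    tibble::tibble(experiment_id = character(), type = character(), message = character())
  }
}

#' Structural problems collected during screen validation
#'
#' @param x A `screen_tbl` from [read_screen_table()] or [as_screen_table()].
#' @return A tibble with columns `experiment_id`, `type`, `message`; zero rows
#'   when the table is structurally complete.
#' @export
screen_problems <- function(x) {
  attr(x, "problems") %||%
    tibble::tibble(experiment_id = character(), type = character(), message = character())
}

#' Control genotype recorded for a screen table
#' @param x A `screen_tbl`.
#' @return The control genotype label (length-one character).
#' @export
control_genotype <- function(x) attr(x, "control_genotype") %||% "yw"

#' Write a screen table to CSV
#'
#' Inverse of [read_screen_table()] with the default dialect: the written
#' file round-trips all counts and labels exactly.
#'
#' @param x A `screen_tbl` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Write per-genotype summaries to TSV
#'
#' Writes the aggregate table produced by [aggregate_genotypes()] (optionally
#' after [classify_genotypes()]): one row per genotype with replicate count,
#' mean and SD of the dumping index and of the normalized dumping index, and
#' the interactor class when present. Values round-trip through
#' [read_summary_table()] to at least six decimal places.
#'
#' @param summaries A non-empty data frame of genotype summaries.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    abort("no summaries to write")
  }
  cols <- c("genotype", "n", "mean_di", "sd_di", "mean_norm", "sd_norm", "class")
  out <- summaries
  if (!"class" %in% names(out)) out$class <- NA_character_
  missing <- setdiff(cols, names(out))
  if (length(missing)) {
    abort(paste0("summary table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(out[cols], path)
  invisible(path)
}

#' Read a per-genotype summary table written by [write_summary_table()]
#' @param path Path to the TSV file.
#' @return A tibble with the summary columns.
#' @export
read_summary_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    genotype = readr::col_character(),
    n = readr::col_integer(),
    mean_di = readr::col_double(),
    sd_di = readr::col_double(),
    mean_norm = readr::col_double(),
    sd_norm = readr::col_double(),
    class = readr::col_character()
  ), progress = FALSE)
}
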