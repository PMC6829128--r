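#' Genotype entry for a simulated screen
#'
#' @param label Genotype label.
#' @param p_vehicle Maturation (dumping) probability in vehicle medium,
#'   in (0, 1].
#' @param beta Aspirin-sensitivity shift on the log-odds scale, >= 0.
#'   0 means the genotype responds to aspirin exactly like wild type.
#' @param direction `"enhancer"` (shift increases aspirin sensitivity,
#'   lowering maturation), `"suppressor"` (shift decreases sensitivity), or
#'   `"none"`.
#' @return One-row tibble usable in [sim_screen_config()].
#' @export
sim_genotype <- function(label, p_vehicle = 0.92, beta = 0,
                         direction = c("none", "enhancer", "suppressor")) {
  direction <- match.arg(direction)
  stopifnot(p_vehicle > 0, p_vehicle <= 1, beta >= 0)
  tibble::tibble(label = label, p_vehicle = p_vehicle, beta = beta,
                 direction = direction)
}

#' Configuration for a simulated pharmaco-genetic screen
#'
#' Encodes the generative model the analysis assumes: each culture well of
#' 20-30 follicles yields a binomial dumped count; vehicle wells dump with
#' the genotype's `p_vehicle`; aspirin wells dump with probability
#' `plogis(qlogis(p_vehicle) - beta_control - s * beta + delta_e)`, where
#' `beta_control` calibrates the wild-type aspirin response, `s` is +1 for
#' enhancers, -1 for suppressors and 0 otherwise, and `delta_e ~ N(0, tau)`
#' is an experiment-level potency jitter (solvent evaporation, batch
#' effects) shared by every well of experiment `e` — the very structure
#' that makes within-experiment normalization against the control
#' meaningful.
#'
#' Defaults encode the screen's design: wild-type (`"yw"`) vehicle dumping
#' of 92% and a drug dose calibrated so about half of wild-type follicles
#' mature in aspirin (so `beta_control = qlogis(0.92) - qlogis(0.5)`),
#' giving an expected control dumping index near 0.5/0.92 = 0.543.
#'
#' @param genotypes Tibble of experimental genotypes from [sim_genotype()]
#'   (bind rows for several), or `NULL` for a control-only screen.
#' @param control_label Wild-type control label.
#' @param control_p_vehicle Control vehicle dumping probability.
#' @param control_p_aspirin Target control dumping probability in aspirin;
#'   fixes `beta_control` on the log-odds scale.
#' @param tau SD of the per-experiment jitter on the aspirin log-odds
#'   shift, >= 0. See [calibrate_tau()].
#' @param n_experiments Number of experiments (each contains every genotype
#'   plus the control, in both treatment arms).
#' @param follicles_range Integer range of follicles per well, inclusive.
#' @param dumped_split Probability a dumped follicle is scored S13/14
#'   rather than S12 (cosmetic bucket detail; never affects the score).
#' @param undumped_split Likewise for S10B vs S11.
#' @param aspirin_mM Nominal dose recorded on aspirin wells.
#' @param seed Mandatory random seed; a fixed seed makes the simulated
#'   screen fully reproducible.
#' @return A `sim_screen_config` list.
#' @export
sim_screen_config <- function(genotypes = NULL,
                              control_label = "yw",
                              control_p_vehicle = 0.92,
                              control_p_aspirin = 0.50,
                              tau = 0,
                              n_experiments = 5,
                              follicles_range = c(20L, 30L),
                              dumped_split = 0.5,
                              undumped_split = 0.5,
                              aspirin_mM = 1.5,
                              seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is required for reproducible simulation")
  stopifnot(
    control_p_vehicle > 0, control_p_vehicle <= 1,
    control_p_aspirin > 0, control_p_aspirin < 1,
    tau >= 0, n_experiments >= 1,
    length(follicles_range) == 2, follicles_range[1] >= 1,
    follicles_range[1] <= follicles_range[2],
    dumped_split >= 0, dumped_split <= 1,
    undumped_split >= 0, undumped_split <= 1
  )
  if (!is.null(genotypes)) {
    stopifnot(all(c("label", "p_vehicle", "beta", "direction") %in% names(genotypes)))
    if (control_label %in% genotypes$label) {
      abort("the control genotype must not appear in `genotypes`")
    }
  }
  structure(list(
    genotypes = genotypes,
    control_label = control_label,
    control_p_vehicle = control_p_vehicle,
    control_p_aspirin = control_p_aspirin,
    beta_control = qlogis(control_p_vehicle) - qlogis(control_p_aspirin),
    tau = tau,
    n_experiments = n_experiments,
    follicles_range = as.integer(follicles_range),
    dumped_split = dumped_split,
    undumped_split = undumped_split,
    aspirin_mM = aspirin_mM,
    seed = as.integer(seed)
  ), class = "sim_screen_config")
}

clamp_prob <- function(p) {
  out <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (any(out != p)) warn("degenerate well probability clamped to [1e-6, 1 - 1e-6]")
  out
}

split_counts <- function(total, dumped, dumped_split, undumped_split) {
  n_s13_14 <- rbinom(length(dumped), dumped, dumped_split)
  undumped <- total - dumped
  n_s10b <- rbinom(length(undumped), undumped, undumped_split)
  tibble::tibble(
    n_s10b = n_s10b, n_s11 = undumped - n_s10b,
    n_s12 = dumped - n_s13_14, n_s13_14 = n_s13_14
  )
}

#' Simulate a pharmaco-genetic interaction screen
#'
#' Draws a full screen table under the generative model described in
#' [sim_screen_config()]: one jitter draw per experiment shared by all its
#' wells, binomial dumped counts per well, uniform well sizes on the
#' configured range, and stage buckets filled by the split probabilities.
#' The same config (same seed) always reproduces the identical table.
#'
#' @param config A [sim_screen_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A validated `screen_tbl` (see [as_screen_table()]).
#' @export
simulate_screen <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_screen_config"))
  seed <- seed %||% config$seed
  geno <- dplyr::bind_rows(
    sim_genotype(config$control_label, config$control_p_vehicle, 0, "none"),
    config$genotypes
  )
  sgn <- c(none = 0, enhancer = 1, suppressor = -1)[geno$direction]
  n_e <- config$n_experiments
  n_g <- nrow(geno)
  withr::with_seed(seed, {
    # fully vectorized over the experiment x genotype grid; the jitter is
    # drawn once per experiment and shared by all of its wells
    delta <- rnorm(n_e, 0, config$tau)
    eidx <- rep(seq_len(n_e), each = n_g)
    gidx <- rep(seq_len(n_g), times = n_e)
    nw <- length(eidx)
    sizes <- seq(config$follicles_range[1], config$follicles_range[2])
    n_veh <- sample(sizes, nw, replace = TRUE)
    n_asp <- sample(sizes, nw, replace = TRUE)
    p_veh <- clamp_prob(geno$p_vehicle[gidx])
    p_asp <- clamp_prob(plogis(
      qlogis(geno$p_vehicle[gidx]) - config$beta_control -
        sgn[gidx] * geno$beta[gidx] + delta[eidx]
    ))
    d_veh <- rbinom(nw, n_veh, p_veh)
    d_asp <- rbinom(nw, n_asp, p_asp)
    eid <- sprintf("E%03d", eidx)
    out <- dplyr::bind_rows(
      dplyr::bind_cols(
        tibble::tibble(experiment_id = eid, genotype = geno$label[gidx],
                       treatment = "vehicle", aspirin_mM = 0),
        split_counts(n_veh, d_veh, config$dumped_split, config$undumped_split)
      ),
      dplyr::bind_cols(
        tibble::tibble(experiment_id = eid, genotype = geno$label[gidx],
                       treatment = "aspirin", aspirin_mM = config$aspirin_mM),
        split_counts(n_asp, d_asp, config$dumped_split, config$undumped_split)
      )
    )
    out <- dplyr::arrange(out, .data$experiment_id)
    as_screen_table(out, control_genotype = config$control_label)
  })
}

# SD of QC-passing control dumping indices under a config, at a given tau,
# estimated from a dedicated control-only simulation.
control_sd_at_tau <- function(config, tau, n_experiments, seed) {
  cfg <- config
  cfg$genotypes <- NULL
  cfg$tau <- tau
  cfg$n_experiments <- n_experiments
  tbl <- simulate_screen(structure(cfg, class = "sim_screen_config"), seed = seed)
  scores <- score_screen(tbl, control_genotype = cfg$control_label)
  keep <- scores$is_control & !is.na(scores$qc_pass) & scores$qc_pass
  sd(scores$dumping_index[keep])
}

#' Calibrate the experiment-level jitter to a target control variability
#'
#' Finds the jitter SD `tau` at which the simulated aggregate wild-type
#' control dumping-index SD — computed, like the screen's sigma, over the
#' pooled QC-passing controls — matches a target. Uses bisection with
#' common random numbers (fixed seed batches), since the QC-passing SD is
#' monotone non-decreasing in tau.
#'
#' Two boundary regimes are reported honestly rather than hidden:
#' \itemize{
#' \item The binomial sampling floor: at `tau = 0` the wells' binomial noise
#'   alone already produces a positive control SD. A target below the floor
#'   is returned as `tau = 0` when the floor is within the calibration
#'   tolerance of the target, and is an error otherwise (the requested
#'   variability is below the irreducible sampling variance).
#' \item The truncation ceiling: because QC restricts control indices to
#'   \[0.4, 0.6\], their SD cannot exceed that of a uniform on the band
#'   (about 0.0577) however large tau grows; a target above the ceiling
#'   saturates at `tau_max` with a warning.
#' }
#'
#' @param target_control_sd Desired aggregate QC-passing control DI SD.
#' @param config A [sim_screen_config()]; its `tau` is ignored.
#' @param tol Relative calibration tolerance (default 0.10).
#' @param n_experiments Simulated experiments per SD evaluation.
#' @param tau_max Upper search bound.
#' @return `tau` (numeric scalar) with attributes `achieved_sd` and
#'   `floor_sd`.
#' @export
calibrate_tau <- function(target_control_sd, config, tol = 0.10,
                          n_experiments = 4000, tau_max = 5) {
  stopifnot(target_control_sd > 0)
  seed <- config$seed
  f <- function(tau) control_sd_at_tau(config, tau, n_experiments, seed)
  floor_sd <- f(0)
  if (target_control_sd <= floor_sd) {
    if (floor_sd <= target_control_sd * (1 + tol)) {
      tau <- 0
      attr(tau, "achieved_sd") <- floor_sd
      attr(tau, "floor_sd") <- floor_sd
      return(tau)
    }
    abort(paste0(
      "target SD ", format(target_control_sd), " is below the binomial sampling floor ",
      format(floor_sd), " at the configured well sizes; the requested variability ",
      "is smaller than the irreducible sampling variance"
    ))
  }
  hi_sd <- f(tau_max)
  if (target_control_sd >= hi_sd) {
    warn(paste0(
      "target SD ", format(target_control_sd), " exceeds the QC-truncation ceiling (",
      format(hi_sd), " at tau = ", tau_max, "); returning the saturated tau"
    ))
    tau <- tau_max
    attr(tau, "achieved_sd") <- hi_sd
    attr(tau, "floor_sd") <- floor_sd
    return(tau)
  }
  lo <- 0; hi <- tau_max
  mid_sd <- NA_real_
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    mid_sd <- f(mid)
    if (abs(mid_sd - target_control_sd) <= tol * target_control_sd) break
    if (mid_sd < target_control_sd) lo <- mid else hi <- mid
  }
  tau <- (lo + hi) / 2
  attr(tau, "achieved_sd") <- mid_sd
  attr(tau, "floor_sd") <- floor_sd
  tau
}

#' Monte-Carlo recovery of planted interactors
#'
#' Runs the full simulate - score - aggregate - classify pipeline
#' `n_repetitions` times and tabulates, per genotype, how often each
#' (band, direction) call was made. Thresholds are re-derived from each
#' repetition's own QC-passing controls, exactly as a real screen would.
#'
#' @param config A [sim_screen_config()] with the planted effects.
#' @param n_repetitions Number of independent screen repetitions.
#' @param seed Base seed; repetition r uses `seed + r`.
#' @param extra_control_experiments Number of additional control-only
#'   experiments per repetition whose QC-passing dumping indices enlarge
#'   the sigma pool (they never contribute genotype scores). Screens
#'   typically derive their bands from a wild-type aggregate pooled over
#'   the whole campaign — far more experiments than any one genotype was
#'   run in — and this argument reproduces that structure.
#' @return A tibble: `genotype`, `direction_planted`, `band`, `direction`,
#'   `n_calls`, `prop` (of repetitions in which the genotype was scorable).
#'   Zero repetitions give a zero-row tibble.
#' @export
recovery_experiment <- function(config, n_repetitions, seed,
                                extra_control_experiments = 0) {
  stopifnot(inherits(config, "sim_screen_config"), n_repetitions >= 0)
  empty <- tibble::tibble(
    genotype = character(), direction_planted = character(),
    band = character(), direction = character(),
    n_calls = integer(), prop = double()
  )
  if (n_repetitions == 0) return(empty)
  planted <- dplyr::bind_rows(
    tibble::tibble(genotype = config$control_label, direction_planted = "none"),
    if (!is.null(config$genotypes)) {
      tibble::tibble(genotype = config$genotypes$label,
                     direction_planted = config$genotypes$direction)
    }
  )
  calls <- purrr::map_dfr(seq_len(n_repetitions), function(r) {
    tbl <- simulate_screen(config, seed = seed + r)
    scores <- score_screen(tbl, control_genotype = config$control_label)
    ctrl_di <- scores$dumping_index[scores$is_control & scores$qc_pass %in% TRUE]
    if (extra_control_experiments > 0) {
      pool_cfg <- config
      pool_cfg$genotypes <- NULL
      pool_cfg$n_experiments <- extra_control_experiments
      pool_tbl <- simulate_screen(structure(pool_cfg, class = "sim_screen_config"),
                                  seed = seed + n_repetitions + r)
      pool_sc <- score_screen(pool_tbl, control_genotype = config$control_label)
      ctrl_di <- c(ctrl_di,
                   pool_sc$dumping_index[pool_sc$is_control & pool_sc$qc_pass %in% TRUE])
    }
    if (length(ctrl_di) < 2) return(NULL)
    spec <- thresholds_from_controls(ctrl_di)
    summaries <- aggregate_genotypes(scores)
    classified <- classify_genotypes(summaries, spec)
    tibble::tibble(
      rep = r, genotype = classified$genotype,
      band = as.character(classified$band),
      direction = as.character(classified$direction)
    )
  })
  if (nrow(calls) == 0) return(empty)
  scorable <- calls |> dplyr::count(.data$genotype, name = "n_scorable")
  calls |>
    dplyr::count(.data$genotype, .data$band, .data$direction, name = "n_calls") |>
    dplyr::left_join(scorable, by = "genotype") |>
    dplyr::mutate(prop = .data$n_calls / .data$n_scorable) |>
    dplyr::left_join(planted, by = "genotype") |>
    dplyr::select("genotype", "direction_planted", "band", "direction",
                  "n_calls", "prop")
}
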