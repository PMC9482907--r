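# Gradient-elution simulator (linear-solvent-strength retention model).
#
# Retention is modelled as log10 k = log_kw - S * phi, with phi the organic
# fraction at the column inlet. A compound migrates until the fundamental
# gradient-elution condition
#     integral_0^(tR - t0)  dt / ( t0 * k(phi(t)) )  =  1
# is met, where t0 = dead_volume / flow_rate and the programmed gradient
# reaches the column delayed by dwell_volume / flow_rate. The integral has a
# closed form on each linear gradient segment, so elution times are exact to
# machine precision and the isocratic limit tR = t0 * (1 + k) is recovered
# for a flat program.

#' Describe an LC system
#'
#' @param flow_rate Flow rate in mL/min (> 0).
#' @param dead_volume Column dead (void) volume in mL; t0 =
#'   dead_volume / flow_rate.
#' @param dwell_volume Gradient dwell volume in mL (mixer to column inlet);
#'   the programmed gradient reaches the column after
#'   dwell_volume / flow_rate minutes.
#' @param gradient data.frame with columns `time` (min, strictly
#'   increasing, starting at 0) and `phi` (fraction organic, 0..1). The
#'   first phi is held before the program starts and the last one after it
#'   ends.
#' @param label Free-text system label.
#' @return An `lc_system` list.
#' @export
lc_system <- function(flow_rate, dead_volume, dwell_volume, gradient,
                      label = "system") {
  stopifnot(flow_rate > 0, dead_volume > 0, dwell_volume >= 0,
            is.data.frame(gradient),
            all(c("time", "phi") %in% names(gradient)))
  if (any(diff(gradient$time) <= 0))
    stop("gradient times must be strictly increasing")
  if (any(gradient$phi < 0 | gradient$phi > 1))
    stop("phi must be within [0, 1]")
  structure(list(flow_rate = flow_rate, dead_volume = dead_volume,
                 dwell_volume = dwell_volume, gradient = gradient,
                 label = label),
            class = "lc_system")
}

#' @export
print.lc_system <- function(x, ...) {
  cat("LC system '", x$label, "': ", x$flow_rate, " mL/min, V0 ",
      x$dead_volume, " mL (t0 ", format(x$dead_volume / x$flow_rate,
      digits = 3), " min), dwell ", x$dwell_volume, " mL\n", sep = "")
  cat("  gradient: phi ", paste(x$gradient$phi, collapse = " -> "),
      " at t ", paste(x$gradient$time, collapse = ", "), " min\n", sep = "")
  invisible(x)
}

#' Reference LC system
#'
#' A UHPLC reversed-phase setup typical for polar metabolomics: 0.3 mL/min
#' on a 100 x 2.1 mm column (dead volume 0.21 mL), dwell volume 0.12 mL,
#' 2 min hold at 5% organic then a linear ramp to 99.9% over 15 min and a
#' 3 min hold. The flow-rate panel for cross-condition experiments is
#' derived from this system by changing only the flow rate.
#'
#' @param flow_rate Flow rate in mL/min (default 0.3).
#' @return An [lc_system()].
#' @export
reference_system <- function(flow_rate = 0.3) {
  lc_system(
    flow_rate = flow_rate,
    dead_volume = 0.21,
    dwell_volume = 0.12,
    gradient = data.frame(time = c(0, 2, 17, 20),
                          phi = c(0.05, 0.05, 0.999, 0.999)),
    label = sprintf("ref_%.2f", flow_rate)
  )
}

# gradient phi at the column inlet as piecewise-linear breakpoints
.column_program <- function(system, max_time) {
  td <- system$dwell_volume / system$flow_rate
  g <- system$gradient
  t <- td + g$time
  phi <- g$phi
  if (t[1] > 0) { t <- c(0, t); phi <- c(phi[1], phi) }
  if (t[length(t)] < max_time) {
    t <- c(t, max_time); phi <- c(phi, phi[length(phi)])
  }
  list(t = t, phi = phi)
}

#' Gradient-elution retention time
#'
#' Solves the gradient-elution integral for a compound with LSS parameters
#' (`log_kw`, `S`) on a given system. Exact closed-form integration per
#' linear gradient segment; reduces to tR = t0 (1 + k) for a flat program.
#'
#' @param log_kw log10 retention factor extrapolated to pure aqueous eluent
#'   (vectorised).
#' @param S Solvent-strength slope (> 0), same length as `log_kw` or
#'   length 1.
#' @param system An [lc_system()].
#' @param max_time Maximum simulated time in minutes; compounds not eluted
#'   by then get `NA` (non-eluting).
#' @return Retention time(s) in minutes; `NA` for non-eluting compounds.
#' @examples
#' iso <- lc_system(1, 1, 0, data.frame(time = 0, phi = 0.5))
#' gradient_rt(log10(9) + 0.5 * 1, S = 1, iso)  # k = 9 -> tR = 10
#' @export
gradient_rt <- function(log_kw, S, system, max_time = 60) {
  stopifnot(inherits(system, "lc_system"), all(S > 0))
  if (length(S) == 1L) S <- rep(S, length(log_kw))
  stopifnot(length(S) == length(log_kw))
  prog <- .column_program(system, max_time)
  t0 <- system$dead_volume / system$flow_rate
  ln10 <- log(10)
  vapply(seq_along(log_kw), function(i) {
    lkw <- log_kw[i]; s <- S[i]
    acc <- 0
    for (seg in seq_len(length(prog$t) - 1L)) {
      a <- prog$t[seg]; b <- prog$t[seg + 1L]
      pa <- prog$phi[seg]; pb <- prog$phi[seg + 1L]
      m <- (pb - pa) / (b - a)
      # integrand 10^(s*phi(t) - lkw) / t0
      if (abs(m) < 1e-12) {
        rate <- 10^(s * pa - lkw) / t0
        contrib <- rate * (b - a)
        if (acc + contrib >= 1) {
          te <- a + (1 - acc) / rate
          return(te + t0)
        }
      } else {
        xa <- 10^(s * pa - lkw)
        xb <- 10^(s * pb - lkw)
        denom <- t0 * s * m * ln10
        contrib <- (xb - xa) / denom
        if (acc + contrib >= 1) {
          x_end <- xa + (1 - acc) * denom
          phi_e <- (lkw + log10(x_end)) / s
          te <- a + (phi_e - pa) / m
          return(te + t0)
        }
      }
      acc <- acc + contrib
    }
    NA_real_
  }, numeric(1))
}

#' LSS parameters of the NAPS homologous series
#'
#' Default retention parameters for the C1-C20 standards:
#' `log_kw = -2.9 + 0.5 n` (a methylene increment of 0.5 log units) and
#' `S = 2.5 + 0.25 n` (solvent-strength slope growing with chain length).
#' On the [reference_system()] these reproduce the characteristic elution
#' pattern: C1-C3 pile up at the void volume during the initial hold while
#' C4-C20 spread over the gradient up to ~17 min.
#'
#' @param n Integer vector of homologue chain lengths (default 1:20).
#' @return data.frame with columns `n`, `log_kw`, `S`.
#' @export
naps_lss_params <- function(n = 1:20) {
  data.frame(n = n, log_kw = -2.9 + 0.5 * n, S = 2.5 + 0.25 * n)
}

#' Simulate a NAPS anchor run
#'
#' Deterministic apex retention times of the homologous series on a system
#' (add jitter separately if a noisy bracketing run is wanted).
#'
#' @param system An [lc_system()].
#' @param params LSS parameters as from [naps_lss_params()].
#' @param rt_jitter_sd Optional retention-time jitter; see
#'   [rt_jitter()] for the noise model. Default 0 (deterministic).
#' @return data.frame with columns `n_carbons`, `rt_min`.
#' @export
simulate_naps_series <- function(system, params = naps_lss_params(),
                                 rt_jitter_sd = 0) {
  rt <- gradient_rt(params$log_kw, params$S, system)
  if (any(is.na(rt))) stop("non-eluting NAPS homologue; check parameters")
  if (rt_jitter_sd > 0) rt <- rt_jitter(rt, rt_jitter_sd)
  data.frame(n_carbons = params$n, rt_min = rt)
}

#' Retention-time jitter model
#'
#' Run-to-run retention variability grows with retention: weakly retained
#' void-volume peaks reproduce to a few thousandths of a minute while
#' mid-gradient peaks drift more. Jitter is Gaussian with standard
#' deviation `sd_frac * rt`, floored at `sd_min` minutes — at a typical
#' mid-run retention time of 8 min the default fraction gives an absolute
#' sd of 0.02 min.
#'
#' @param rt Retention times (minutes).
#' @param sd_frac Fractional sd (default 0.0025, i.e. 0.25% of RT).
#' @param sd_min Absolute sd floor in minutes (default 0.002).
#' @return Jittered retention times.
#' @export
rt_jitter <- function(rt, sd_frac = 0.0025, sd_min = 0.002) {
  rt + stats::rnorm(length(rt), 0, pmax(sd_min, sd_frac * rt))
}

#' Simulate an analyte panel
#'
#' Draws a panel of hypothetical analytes with LSS retention parameters
#' skewed towards polar (early-eluting) compounds, as is typical for a
#' metabolite standard collection on reversed phase: `log_kw` follows a
#' Beta(1.2, 1.8) distribution rescaled to [-1, 5.5] and
#' `S = 3.5 + 0.4 log_kw`. Each analyte gets a random m/z (100-900 Da),
#' polarity and base intensity (10^4..10^7).
#'
#' @param n_analytes Panel size (default 50).
#' @return data.frame with columns `compound_id`, `log_kw`, `S`, `mz`,
#'   `polarity`, `base_intensity`. Uses the current RNG state; call
#'   `set.seed()` first for reproducibility.
#' @export
simulate_analyte_panel <- function(n_analytes = 50) {
  log_kw <- -1 + 6.5 * stats::rbeta(n_analytes, 1.2, 1.8)
  data.frame(
    compound_id = sprintf("A%03d", seq_len(n_analytes)),
    log_kw = log_kw,
    S = 3.5 + 0.4 * log_kw,
    mz = round(stats::runif(n_analytes, 100, 900), 4),
    polarity = sample(c("pos", "neg"), n_analytes, replace = TRUE),
    base_intensity = 10^stats::runif(n_analytes, 4, 7),
    stringsAsFactors = FALSE
  )
}

#' Simulate one feature-table run of an analyte panel
#'
#' Deterministic LSS retention times plus retention jitter and log-normal
#' intensity noise.
#'
#' @param panel Panel from [simulate_analyte_panel()].
#' @param system An [lc_system()].
#' @param rt_sd_frac,rt_sd_min Jitter model, see [rt_jitter()]; set
#'   `rt_sd_frac = 0, rt_sd_min = 0` for a noise-free run.
#' @param intensity_sd_log10 Log-normal intensity noise sd in log10 units
#'   (default 0.1).
#' @return Feature data.frame: `feature_id`, `compound_id`, `mz`, `rt_min`,
#'   `intensity`, `polarity`.
#' @export
simulate_run <- function(panel, system, rt_sd_frac = 0.0025,
                         rt_sd_min = 0.002, intensity_sd_log10 = 0.1) {
  rt <- gradient_rt(panel$log_kw, panel$S, system)
  keep <- !is.na(rt)
  rt <- rt[keep]; panel <- panel[keep, , drop = FALSE]
  if (rt_sd_frac > 0 || rt_sd_min > 0)
    rt <- rt_jitter(rt, rt_sd_frac, rt_sd_min)
  intensity <- panel$base_intensity *
    10^stats::rnorm(nrow(panel), 0, intensity_sd_log10)
  data.frame(
    feature_id = sprintf("F_%s_%s", system$label, panel$compound_id),
    compound_id = panel$compound_id,
    mz = panel$mz,
    rt_min = rt,
    intensity = intensity,
    polarity = panel$polarity,
    stringsAsFactors = FALSE
  )
}

#' Simulate a flow-rate variation study
#'
#' Runs the same analyte panel and NAPS series on systems differing only in
#' flow rate, with per-run NAPS anchors so each condition can be indexed
#' against its own calibration — the in-silico analogue of a systematic
#' flow-rate comparison on one instrument.
#'
#' @param flow_rates Panel of flow rates in mL/min (default
#'   `c(0.20, 0.25, 0.35, 0.40)`).
#' @param reference_flow Reference flow rate (default 0.30).
#' @param n_analytes Panel size (default 50).
#' @param seed Integer seed; all randomness derives from it.
#' @param rt_sd_frac,rt_sd_min,intensity_sd_log10 Noise model, see
#'   [simulate_run()].
#' @return List with `panel`, `systems`, per-system `naps` anchor tables
#'   and `runs` feature tables (named by flow rate, reference included),
#'   and `reference` (the reference label).
#' @export
simulate_flow_study <- function(flow_rates = c(0.20, 0.25, 0.35, 0.40),
                                reference_flow = 0.30, n_analytes = 50,
                                seed = 1, rt_sd_frac = 0.0025,
                                rt_sd_min = 0.002,
                                intensity_sd_log10 = 0.1) {
  set.seed(seed)
  panel <- simulate_analyte_panel(n_analytes)
  flows <- c(reference_flow, flow_rates)
  systems <- lapply(flows, reference_system)
  names(systems) <- vapply(systems, `[[`, character(1), "label")
  naps <- list(); runs <- list()
  for (nm in names(systems)) {
    sys <- systems[[nm]]
    naps[[nm]] <- simulate_naps_series(sys, rt_jitter_sd = 0)
    if (rt_sd_frac > 0 || rt_sd_min > 0)
      naps[[nm]]$rt_min <- rt_jitter(naps[[nm]]$rt_min, rt_sd_frac,
                                     rt_sd_min)
    runs[[nm]] <- simulate_run(panel, sys, rt_sd_frac, rt_sd_min,
                               intensity_sd_log10)
  }
  list(panel = panel, systems = systems, naps = naps, runs = runs,
       reference = names(systems)[1])
}

#' Simulate a NAPS spike-in suppression experiment
#'
#' Generates an unspiked matrix run (features uniform in time over the
#' elution window, log-uniform intensities) and spiked runs at several NAPS
#' dilutions. Spiking imposes a Gaussian suppression kernel centred at each
#' NAPS apex: at dilution 1:f the spiked intensity is multiplied by
#' `1 - amplitude * (20 / f) * exp(-d^2 / (2 width^2))` with `d` the
#' distance to the nearest apex, so a 1:20 spike suppresses `amplitude`
#' (default 50%) at the apex and more dilute spikes proportionally less.
#' Spiked and unspiked runs are back-to-back technical injections of the
#' same extract, so they share feature intensities up to a small run-to-run
#' log-normal noise (`run_sd_log10`).
#'
#' @param system An [lc_system()].
#' @param dilutions Character spike levels (default
#'   `c("1:20", "1:40", "1:80")`).
#' @param n_features Number of matrix features (default 1200).
#' @param amplitude Fractional suppression at the apex for a 1:20 spike
#'   (default 0.5).
#' @param width Gaussian kernel sd in minutes (default 0.08; NAPS peaks
#'   span about 0.2 min).
#' @param run_sd_log10 Run-to-run intensity noise between technical
#'   injections, log10 sd (default 0.03).
#' @param rt_sd_frac,rt_sd_min Retention jitter between injections, see
#'   [rt_jitter()].
#' @param seed Integer seed.
#' @return List with `unspiked` (feature data.frame), `spiked` (named list
#'   of feature data.frames per dilution), `naps_apexes` (deterministic
#'   apex table) and `truth` (kernel parameters actually applied).
#' @export
simulate_suppression_experiment <- function(system = reference_system(),
                                            dilutions = c("1:20", "1:40",
                                                          "1:80"),
                                            n_features = 1200,
                                            amplitude = 0.5, width = 0.08,
                                            run_sd_log10 = 0.03,
                                            rt_sd_frac = 0.0025,
                                            rt_sd_min = 0.002, seed = 1) {
  set.seed(seed)
  apexes <- simulate_naps_series(system)
  t0 <- system$dead_volume / system$flow_rate
  rt_max <- max(apexes$rt_min) + 1
  base <- data.frame(
    feature_id = sprintf("M%05d", seq_len(n_features)),
    mz = round(stats::runif(n_features, 100, 900), 4),
    rt_min = stats::runif(n_features, t0, rt_max),
    intensity = 10^stats::runif(n_features, 4, 7),
    polarity = "pos",
    stringsAsFactors = FALSE
  )
  unspiked <- base
  unspiked$intensity <- base$intensity *
    10^stats::rnorm(n_features, 0, run_sd_log10)

  amp_of <- function(d) amplitude * 20 / as.numeric(sub("^1:", "", d))
  spiked <- lapply(dilutions, function(dil) {
    a <- amp_of(dil)
    d_apex <- vapply(base$rt_min,
                     function(rt) min(abs(rt - apexes$rt_min)), numeric(1))
    supp <- 1 - a * exp(-d_apex^2 / (2 * width^2))
    out <- base
    out$rt_min <- rt_jitter(base$rt_min, rt_sd_frac, rt_sd_min)
    out$intensity <- base$intensity * supp *
      10^stats::rnorm(n_features, 0, run_sd_log10)
    out
  })
  names(spiked) <- dilutions
  list(unspiked = unspiked, spiked = spiked, naps_apexes = apexes,
       truth = list(amplitude_by_dilution =
                      stats::setNames(vapply(dilutions, amp_of, numeric(1)),
                                      dilutions),
                    width = width))
}

#' Simulate replicate standard runs for library building
#'
#' Emulates pooled-standard library construction: the same panel measured
#' in several replicate runs, each bracketed by its own (jittered) NAPS
#' injections before and after.
#'
#' @param panel Analyte panel (default a fresh [simulate_analyte_panel()]).
#' @param system An [lc_system()].
#' @param replicates Number of replicate runs (default 3).
#' @param seed Integer seed.
#' @inheritParams simulate_run
#' @return List of [standard_run()] objects.
#' @export
simulate_standard_runs <- function(panel = NULL,
                                   system = reference_system(),
                                   replicates = 3, seed = 1,
                                   rt_sd_frac = 0.0025, rt_sd_min = 0.002,
                                   intensity_sd_log10 = 0.1) {
  set.seed(seed)
  if (is.null(panel)) panel <- simulate_analyte_panel()
  lapply(seq_len(replicates), function(r) {
    feats <- simulate_run(panel, system, rt_sd_frac, rt_sd_min,
                          intensity_sd_log10)
    meas <- data.frame(compound_id = feats$compound_id,
                       adduct = ifelse(feats$polarity == "pos",
                                       "[M+H]+", "[M-H]-"),
                       polarity = feats$polarity,
                       rt_min = feats$rt_min,
                       stringsAsFactors = FALSE)
    naps <- simulate_naps_series(system)
    before <- naps; before$rt_min <- rt_jitter(naps$rt_min, rt_sd_frac,
                                               rt_sd_min)
    after <- naps; after$rt_min <- rt_jitter(naps$rt_min, rt_sd_frac,
                                             rt_sd_min)
    standard_run(meas, before, after, run_id = sprintf("rep%02d", r))
  })
}

#' Read a simulator configuration (YAML or JSON)
#'
#' The configuration mirrors the arguments of [simulate_study()]: fields
#' `flow_rates`, `reference_flow`, `n_analytes`, `replicates`, noise
#' (`rt_sd_frac`, `rt_sd_min`, `intensity_sd_log10`) and suppression
#' (`dilutions`, `n_features`, `amplitude`, `width`, `run_sd_log10`).
#' Unknown fields raise an error naming them.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return Named list of configuration values.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("flow_rates", "reference_flow", "n_analytes", "replicates",
             "rt_sd_frac", "rt_sd_min", "intensity_sd_log10", "dilutions",
             "n_features", "amplitude", "width", "run_sd_log10")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown simulator config field(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Simulate a complete in-silico study
#'
#' Orchestrates the generators: a flow-rate panel with per-run NAPS anchors,
#' replicate standard runs for library building, and a spike-in suppression
#' experiment, all derived deterministically from one seed.
#'
#' @param config Named list as returned by [read_sim_config()]; missing
#'   fields fall back to the documented defaults.
#' @param seed Integer seed (< 2^28; sub-seeds are derived from it).
#' @return List with elements `flow`, `standard_runs`, `suppression` and
#'   `config` (the completed configuration).
#' @export
simulate_study <- function(config = list(), seed = 1) {
  stopifnot(is.list(config), seed == as.integer(seed), abs(seed) < 2^28)
  defaults <- list(flow_rates = c(0.20, 0.25, 0.35, 0.40),
                   reference_flow = 0.30, n_analytes = 50, replicates = 3,
                   rt_sd_frac = 0.0025, rt_sd_min = 0.002,
                   intensity_sd_log10 = 0.1,
                   dilutions = c("1:20", "1:40", "1:80"),
                   n_features = 1200, amplitude = 0.5, width = 0.08,
                   run_sd_log10 = 0.03)
  cfg <- utils::modifyList(defaults, config)
  flow <- simulate_flow_study(
    flow_rates = cfg$flow_rates, reference_flow = cfg$reference_flow,
    n_analytes = cfg$n_analytes, seed = seed,
    rt_sd_frac = cfg$rt_sd_frac, rt_sd_min = cfg$rt_sd_min,
    intensity_sd_log10 = cfg$intensity_sd_log10)
  runs <- simulate_standard_runs(
    panel = flow$panel, system = reference_system(cfg$reference_flow),
    replicates = cfg$replicates, seed = seed + 1L,
    rt_sd_frac = cfg$rt_sd_frac, rt_sd_min = cfg$rt_sd_min,
    intensity_sd_log10 = cfg$intensity_sd_log10)
  supp <- simulate_suppression_experiment(
    system = reference_system(cfg$reference_flow),
    dilutions = cfg$dilutions, n_features = cfg$n_features,
    amplitude = cfg$amplitude, width = cfg$width,
    run_sd_log10 = cfg$run_sd_log10, rt_sd_frac = cfg$rt_sd_frac,
    rt_sd_min = cfg$rt_sd_min, seed = seed + 2L)
  list(flow = flow, standard_runs = runs, suppression = supp, config = cfg)
}
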