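#' Ground-truth scenario for synthetic dilution-potential experiments
#'
#' Bundles every parameter of the forward model used by
#' [simulate_dilution_trace()]: the two-pathway circuit (epithelium +
#' drug-formed channels), the protocol timing, the current-pulse schedule
#' and the noise model. Conductances are on the megaohm scale implied by
#' +/- 0.5 nA pulses producing millivolt deflections across a 0.33 cm^2
#' insert.
#'
#' @param true_p_cl_na True P_Cl/P_Na of the drug pathway.
#' @param g_frt Untreated epithelial conductance, mS/cm^2.
#' @param g_drug_max Saturating drug-pathway conductance, mS/cm^2 (0 allowed,
#'   to simulate an inactive compound).
#' @param drug_onset_s Logistic time constant of the drug-conductance rise
#'   after compound addition, seconds.
#' @param p_frt The epithelium's own (paracellular) P_Cl/P_Na; 1 = non-
#'   selective.
#' @param junction_mV Liquid-junction potential present while the baths are
#'   asymmetric, mV.
#' @param noise_sd_mV Gaussian voltage noise s.d. per sample, mV.
#' @param drift_mV_min Linear baseline drift, mV/min.
#' @param pulse_period_s,pulse_dur_s,pulse_gap_s,pulse_amp_nA Bipolar pulse
#'   schedule: one +amp then one -amp pulse of `pulse_dur_s` each, separated
#'   by `pulse_gap_s`, repeating every `pulse_period_s`.
#' @param sample_hz Sampling rate, Hz.
#' @param area_cm2 Membrane area, cm^2.
#' @param baseline_s,dilution_s,compound_s Durations of the three protocol
#'   segments (symmetric baths; post apical dilution; post compound).
#' @param slope Slope mode for the forward GHK model (see [ghk_slope()]).
#' @param high_solution,low_solution Bath compositions.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return Object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(true_p_cl_na = 3,
                               g_frt = 1.0e-3,
                               g_drug_max = 4.0e-3,
                               drug_onset_s = 10,
                               p_frt = 1,
                               junction_mV = 1.2,
                               noise_sd_mV = 0.02,
                               drift_mV_min = 0,
                               pulse_period_s = 15,
                               pulse_dur_s = 2,
                               pulse_gap_s = 1,
                               pulse_amp_nA = 0.5,
                               sample_hz = 5,
                               area_cm2 = 0.33,
                               baseline_s = 120,
                               dilution_s = 240,
                               compound_s = 360,
                               slope = c("paper", "exact"),
                               high_solution = ringer_high(),
                               low_solution = ringer_low(),
                               seed = 1L) {
  slope <- match.arg(slope)
  stopifnot(g_frt > 0, g_drug_max >= 0, noise_sd_mV >= 0, area_cm2 > 0,
            true_p_cl_na >= 0, p_frt >= 0, sample_hz > 0,
            pulse_dur_s > 0, pulse_period_s > 2 * pulse_dur_s + pulse_gap_s)
  structure(as.list(environment()), class = "synthetic_scenario")
}

# drug-pathway conductance at time t (s) after compound addition
.g_drug_t <- function(t_after, g_max, tau) {
  if (g_max <= 0) return(rep(0, length(t_after)))
  ifelse(t_after < 0, 0, g_max * stats::plogis((t_after - 4 * tau) / tau))
}

#' Simulate one current-clamp dilution-potential recording
#'
#' Forward model: the open-circuit voltage is the conductance-weighted
#' average of the two pathways' GHK dilution potentials. The drug pathway's
#' conductance rises logistically after the `"compound_added"` event; the
#' junction offset applies while the baths are asymmetric (after
#' `"dilution"`); linear drift and Gaussian noise are added throughout.
#' Current pulses deflect the voltage by `I / (G_total * area)` (Ohm's
#' law). A ground-truth sidecar accompanies the trace so recovery tests
#' never have to trust the analysis output.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List of class `"synthetic_dilution"`: `trace` (a
#'   [recording_trace()] with `"dilution"` and `"compound_added"` events)
#'   and `truth` (true P, pathway potentials and conductances, junction,
#'   seed).
#' @export
simulate_dilution_trace <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  set.seed(s$seed)
  slope_mV <- ghk_slope(s$slope, temperature_K = s$high_solution$temperature_K)
  act <- selectivity_activities(s$high_solution, s$low_solution)
  v_frt <- ghk_potential(s$p_frt, act["na_baso"], act["cl_baso"],
                         act["na_api"], act["cl_api"], slope_mV = slope_mV)
  v_drug <- if (s$true_p_cl_na >= 0 && s$g_drug_max > 0)
    ghk_potential(s$true_p_cl_na, act["na_baso"], act["cl_baso"],
                  act["na_api"], act["cl_api"], slope_mV = slope_mV)
  else NA_real_

  total_s <- s$baseline_s + s$dilution_s + s$compound_s
  t_dil <- s$baseline_s
  t_cmp <- s$baseline_s + s$dilution_s
  time_s <- seq(0, total_s, by = 1 / s$sample_hz)

  g_d <- .g_drug_t(time_s - t_cmp, s$g_drug_max, s$drug_onset_s)
  g_tot <- s$g_frt + g_d

  v <- numeric(length(time_s))
  asym <- time_s >= t_dil
  pre_cmp <- asym & time_s < t_cmp
  post_cmp <- time_s >= t_cmp
  v[pre_cmp] <- v_frt + s$junction_mV
  if (s$g_drug_max > 0) {
    v[post_cmp] <- (s$g_frt * v_frt + g_d[post_cmp] * v_drug) /
      g_tot[post_cmp] + s$junction_mV
  } else {
    v[post_cmp] <- v_frt + s$junction_mV
  }

  # bipolar pulse schedule, offset so no pulse straddles an event
  current <- numeric(length(time_s))
  pair_starts <- seq(s$pulse_period_s / 2, total_s - 2 * s$pulse_dur_s -
                       s$pulse_gap_s, by = s$pulse_period_s)
  for (t0 in pair_starts) {
    pos <- time_s >= t0 & time_s < t0 + s$pulse_dur_s
    neg <- time_s >= t0 + s$pulse_dur_s + s$pulse_gap_s &
      time_s < t0 + 2 * s$pulse_dur_s + s$pulse_gap_s
    current[pos] <- s$pulse_amp_nA
    current[neg] <- -s$pulse_amp_nA
  }
  v <- v + current / (g_tot * s$area_cm2) / 1000   # Ohmic deflection, mV
  v <- v + s$drift_mV_min / 60 * time_s
  if (s$noise_sd_mV > 0) v <- v + stats::rnorm(length(v), 0, s$noise_sd_mV)

  trace <- recording_trace(
    time_s, v, current,
    events = data.frame(time_s = c(t_dil, t_cmp),
                        label = c("dilution", "compound_added"),
                        stringsAsFactors = FALSE),
    area_cm2 = s$area_cm2)
  truth <- list(p_cl_na = s$true_p_cl_na, p_frt = s$p_frt,
                v_frt_mV = v_frt, v_drug_mV = v_drug,
                g_frt = s$g_frt, g_total = s$g_frt + s$g_drug_max,
                junction_mV = s$junction_mV, slope_mV = slope_mV,
                seed = s$seed)
  structure(list(trace = trace, truth = truth, scenario = s),
            class = "synthetic_dilution")
}

#' Simulate a replicate series of dilution-potential measurements
#'
#' Runs [simulate_dilution_trace()] `n` times (seeds `seed, seed + 1, ...`)
#' and reduces each recording with the package's own trace pipeline
#' ([trace_to_measurement()]), yielding the measurement table consumed by
#' [fit_selectivity()] plus the shared ground truth.
#'
#' @param scenario A [synthetic_scenario()]; its `seed` seeds the first
#'   replicate.
#' @param n Number of replicates.
#' @param window_s Plateau window passed to the trace reduction.
#' @return List: `measurements` (data frame, one row per replicate) and
#'   `truth`.
#' @export
simulate_dilution_replicates <- function(scenario, n = 6, window_s = 60) {
  stopifnot(inherits(scenario, "synthetic_scenario"), n >= 1)
  rows <- vector("list", n)
  truth <- NULL
  for (i in seq_len(n)) {
    sc <- scenario
    sc$seed <- scenario$seed + i - 1L
    sim <- simulate_dilution_trace(sc)
    truth <- sim$truth
    rows[[i]] <- trace_to_measurement(sim$trace, sim$truth$junction_mV,
                                      replicate_id = sprintf("rep%02d", i),
                                      window_s = window_s)
  }
  list(measurements = do.call(rbind, rows), truth = truth)
}

#' Write a simulated recording (and its truth sidecar) to CSV files
#'
#' Emits `<stem>_trace.csv` (`time_s`, `voltage_mV`, `current_nA`),
#' `<stem>_events.csv` (`time_s`, `label`) and `<stem>_truth.txt`
#' (flat `key = value` lines), the same dialects the package's readers
#' consume.
#'
#' @param sim A `"synthetic_dilution"` from [simulate_dilution_trace()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the three paths.
#' @export
write_dilution_trace <- function(sim, dir, stem = "sim") {
  stopifnot(inherits(sim, "synthetic_dilution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_trace <- file.path(dir, paste0(stem, "_trace.csv"))
  p_ev <- file.path(dir, paste0(stem, "_events.csv"))
  p_truth <- file.path(dir, paste0(stem, "_truth.txt"))
  utils::write.csv(data.frame(time_s = sim$trace$time_s,
                              voltage_mV = sim$trace$voltage_mV,
                              current_nA = sim$trace$current_nA),
                   p_trace, row.names = FALSE)
  utils::write.csv(sim$trace$events, p_ev, row.names = FALSE)
  tr <- sim$truth
  writeLines(sprintf("%s = %s", names(tr),
                     vapply(tr, function(x) format(x, digits = 15),
                            character(1))),
             p_truth)
  invisible(c(trace = p_trace, events = p_ev, truth = p_truth))
}

#' Simulate an ion-selective-electrode chloride efflux trace
#'
#' Phase structure of the liposome assay: 2 min flat baseline, compound
#' addition with an exponential approach to `efflux_fraction` of the total
#' releasable chloride over 10 min, Triton step to the 100% level, 3 min
#' tail. Gaussian noise throughout.
#'
#' @param efflux_fraction True fraction of total chloride released by the
#'   compound, in `[0, 1]`.
#' @param baseline_ppm,triton_ppm Baseline and fully lysed chloride levels,
#'   ppm.
#' @param tau_min Exponential time constant of compound-induced efflux,
#'   minutes.
#' @param noise_sd_ppm Gaussian noise s.d., ppm.
#' @param compound_time_min,triton_time_min,total_min Protocol timing,
#'   minutes.
#' @param samples_per_min Sampling density.
#' @param seed Integer seed.
#' @return List of class `"synthetic_ise"`: `trace` (an [ise_trace()]) and
#'   `truth` (`efflux_fraction`, levels, seed).
#' @export
simulate_ise_trace <- function(efflux_fraction, baseline_ppm = 2,
                               triton_ppm = 100, tau_min = 1.5,
                               noise_sd_ppm = 0.3,
                               compound_time_min = 2, triton_time_min = 12,
                               total_min = 15, samples_per_min = 60,
                               seed = 1L) {
  if (!is.finite(efflux_fraction) || efflux_fraction < 0 || efflux_fraction > 1)
    stop("efflux_fraction must be in [0, 1]")
  set.seed(seed)
  t <- seq(0, total_min, by = 1 / samples_per_min)
  span <- triton_ppm - baseline_ppm
  y <- rep(baseline_ppm, length(t))
  mid <- t >= compound_time_min & t < triton_time_min
  y[mid] <- baseline_ppm + efflux_fraction * span *
    (1 - exp(-(t[mid] - compound_time_min) / tau_min))
  y[t >= triton_time_min] <- triton_ppm
  if (noise_sd_ppm > 0) y <- y + stats::rnorm(length(y), 0, noise_sd_ppm)
  structure(list(trace = ise_trace(t, y, compound_time_min, triton_time_min),
                 truth = list(efflux_fraction = efflux_fraction,
                              baseline_ppm = baseline_ppm,
                              triton_ppm = triton_ppm, seed = seed)),
            class = "synthetic_ise")
}

#' Simulate a yeast rescue growth table
#'
#' The mutant/WT growth ratio follows a Hill-type rescue multiplied by a
#' high-dose rolloff (toxicity) term, rescaled so its maximum over the dose
#' grid equals `max_rescue` exactly; WT wells sit near `wt_od`. Noise is
#' Gaussian on OD600.
#'
#' @param basal_ratio Mutant/WT growth ratio with vehicle only.
#' @param max_rescue Programmed peak mutant/WT ratio over the dose grid.
#' @param ec50,hill Hill rescue parameters (dose units, exponent).
#' @param rolloff_ic50,rolloff_hill High-dose rolloff parameters.
#' @param doses Dose grid (> 0), in the compound's concentration units.
#' @param replicates Replicates per condition.
#' @param noise_sd_od Gaussian OD600 noise s.d.
#' @param wt_od Mean WT OD600.
#' @param compound Compound label.
#' @param seed Integer seed.
#' @return List of class `"synthetic_growth"`: `table` (a [growth_table()])
#'   and `truth` (`max_percent`, `dose_at_max`, `basal_percent`, seed).
#' @export
simulate_growth_table <- function(basal_ratio = 0.05, max_rescue = 0.52,
                                  ec50 = 5, hill = 2,
                                  rolloff_ic50 = 60, rolloff_hill = 4,
                                  doses = c(1.25, 2.5, 5, 10, 20, 40, 80),
                                  replicates = 3, noise_sd_od = 0.01,
                                  wt_od = 1, compound = "cmpd",
                                  seed = 1L) {
  stopifnot(all(doses > 0), max_rescue >= basal_ratio, basal_ratio >= 0)
  set.seed(seed)
  g <- (doses^hill / (ec50^hill + doses^hill)) /
    (1 + (doses / rolloff_ic50)^rolloff_hill)
  ratio <- basal_ratio + (max_rescue - basal_ratio) * g / max(g)
  mk <- function(strain, cmp, dose, mu) {
    data.frame(strain = strain, compound = cmp, dose = dose,
               replicate = seq_len(replicates),
               od600 = pmax(0, mu + stats::rnorm(replicates, 0, noise_sd_od)),
               stringsAsFactors = FALSE)
  }
  rows <- list(mk("WT", "vehicle", 0, wt_od),
               mk("mutant", "vehicle", 0, basal_ratio * wt_od))
  for (i in seq_along(doses)) {
    rows <- c(rows, list(mk("WT", compound, doses[i], wt_od),
                         mk("mutant", compound, doses[i], ratio[i] * wt_od)))
  }
  structure(list(table = growth_table(do.call(rbind, rows)),
                 truth = list(max_percent = 100 * max_rescue,
                              dose_at_max = doses[which.max(ratio)],
                              basal_percent = 100 * basal_ratio,
                              seed = seed)),
            class = "synthetic_growth")
}

#' Simulate an alamarBlue plate
#'
#' Well fluorescence is an affine map of true viability,
#' `F = offset + gain * (viability + noise)`, with blank controls at
#' viability 1 and Triton controls at 0. Because the noise lives on the
#' viability scale, the derived viability percentages are exactly invariant
#' to the gain/offset choice at a fixed seed.
#'
#' @param true_viability Vector of true viabilities in `[0, 1]`, one per
#'   compound well.
#' @param gain,offset Affine map from viability to fluorescence.
#' @param noise_sd Gaussian noise s.d. on the viability scale.
#' @param n_blank,n_triton Numbers of control wells.
#' @param seed Integer seed.
#' @return List of class `"synthetic_plate"`: `plate` (a
#'   [plate_readings()]) and `truth` (`viability_percent` vector, seed).
#' @export
simulate_plate <- function(true_viability, gain = 1000, offset = 50,
                           noise_sd = 0.02, n_blank = 3, n_triton = 3,
                           seed = 1L) {
  if (any(!is.finite(true_viability)) || any(true_viability < 0) ||
      any(true_viability > 1))
    stop("true_viability must be in [0, 1]")
  set.seed(seed)
  v <- c(rep(1, n_blank), rep(0, n_triton), true_viability)
  role <- c(rep("blank", n_blank), rep("triton", n_triton),
            rep("compound", length(true_viability)))
  f <- offset + gain * (v + stats::rnorm(length(v), 0, noise_sd))
  plate <- plate_readings(data.frame(
    well = sprintf("w%02d", seq_along(v)), role = role, fluorescence = f,
    compound = ifelse(role == "compound", "cmpd", ""),
    dose = NA_real_, stringsAsFactors = FALSE))
  structure(list(plate = plate,
                 truth = list(viability_percent = 100 * true_viability,
                              seed = seed)),
            class = "synthetic_plate")
}
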