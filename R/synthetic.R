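## Seeded synthetic-data generators.
##
## Every analysis stage in the package has a generator producing inputs
## with the statistical structure that stage assumes, so the whole
## pipeline is testable without instrument data.  Study-condition
## parameter sets live in one registry (`hc_presets()`); generators are
## pure functions of (configuration, seed).

#' Registry of study-condition presets
#'
#' Named parameter sets reproducing the measurement conditions of the
#' half-calcified-CaM study, used by the `gen_*()` generators:
#'
#' * `itc_ca_camiq_27c` -- Ca2+ titrated into 10 uM CaM12'-IQ complex at
#'   27 C (0.23 mM CaCl2, 35 x 10 ul, 1.5 ml cell); biphasic isotherm,
#'   two-independent-classes parameters (minor nonstoichiometric class
#'   n1 = 0.2, ka1 = 6e8; major class n2 = 1.7, ka2 = 1.7e7,
#'   dh2 = -7.5 kcal/mol, apparent KD ~60 nM).
#' * `itc_ca_camiq_37c` -- same titration at 37 C (8 uM cell, 0.30 mM
#'   CaCl2); monophasic one-site parameters n = 1.8, ka = 1.4e7
#'   (KDapp ~72 nM), dh = -7.7 kcal/mol.
#' * `itc_iq_wt_27c` / `itc_iq_wt_37c` -- Ca2/CaM12' titrated into the
#'   wild-type IQ peptide (10 uM or 7 uM cell, 0.1 mM syringe);
#'   one-site, KD 16 nM at 27 C (dh = -10) and 37 nM at 37 C (dh = -15).
#' * `itc_iq_y1657d_27c` -- the weakened Y1657D IQ variant (50 uM cell,
#'   0.5 mM syringe, KD 8 uM, dh = -5.6).
#' * `fp_apocam_y1657d` -- FP titration of 100 nM labelled Y1657D
#'   peptide with apoCaM: KD 60 uM, maximal polarization 0.2, 12 titrant
#'   points log-spaced 0.5-500 uM, noise SD 5% of the maximum.
#' * `fp_ca2cam_iqwt` -- depletion-regime FP titration of 100 nM
#'   labelled wild-type IQ with Ca2/CaM12': true KD 16 nM, grid
#'   10-1000 nM, noise SD 3% of the plateau.
#' * `sc_cell_attached` -- single-channel protocol: 2 s depolarizations
#'   sampled at 10 kHz, 2 kHz low-pass filter, unitary Ba2+ current
#'   -1 pA, noise 0.2 pA.
#' * `wc_strong_cdi` / `wc_no_cdi` -- whole-cell families: 900 ms steps,
#'   -60..+50 mV in 10 mV increments, bi-exponential inactivation with
#'   Ca2+ faster than Ba2+ (or identical, for the no-CDI control).
#'
#' ITC presets carry a default per-injection heat noise of 0.1 kcal per
#' mole of injectant.
#'
#' @return a named list of preset parameter sets.
#' @export
hc_presets <- function() {
  itc_noise <- 0.1
  list(
    itc_ca_camiq_27c = list(
      kind = "itc",
      params = two_site_params(0.2, 6e8, -10, 1.7, 1.7e7, -7.5),
      schedule = titration_schedule(1.5e-3, 10e-6, 0.23e-3, 35, 10e-6,
                                    celsius_to_kelvin(27)),
      noise_sd = itc_noise),
    itc_ca_camiq_37c = list(
      kind = "itc",
      params = one_site_params(1.8, 1.4e7, -7.7),
      schedule = titration_schedule(1.5e-3, 8e-6, 0.30e-3, 35, 10e-6,
                                    celsius_to_kelvin(37)),
      noise_sd = itc_noise),
    itc_iq_wt_27c = list(
      kind = "itc",
      params = one_site_params(0.77, 1 / 16e-9, -10),
      schedule = titration_schedule(1.5e-3, 10e-6, 0.1e-3, 35, 10e-6,
                                    celsius_to_kelvin(27)),
      noise_sd = itc_noise),
    itc_iq_wt_37c = list(
      kind = "itc",
      params = one_site_params(0.76, 1 / 37e-9, -15),
      schedule = titration_schedule(1.5e-3, 7e-6, 0.1e-3, 35, 10e-6,
                                    celsius_to_kelvin(37)),
      noise_sd = itc_noise),
    itc_iq_y1657d_27c = list(
      kind = "itc",
      params = one_site_params(0.72, 1 / 8e-6, -5.6),
      schedule = titration_schedule(1.5e-3, 50e-6, 0.5e-3, 35, 10e-6,
                                    celsius_to_kelvin(27)),
      noise_sd = itc_noise),
    fp_apocam_y1657d = list(
      kind = "fp",
      kd = 60e-6, b_max = 0.2, labeled_conc = 100e-9,
      grid = exp(seq(log(0.5e-6), log(500e-6), length.out = 12)),
      noise_sd = 0.05 * 0.2),
    fp_ca2cam_iqwt = list(
      kind = "fp",
      kd = 16e-9, b_max = 0.2, labeled_conc = 100e-9,
      grid = exp(seq(log(10e-9), log(1000e-9), length.out = 12)),
      noise_sd = 0.03 * 0.2),
    sc_cell_attached = list(
      kind = "singlechannel",
      duration = 2, sampling_rate = 10000, filter_cutoff = 2000,
      unitary_current = -1, noise_sd = 0.2),
    wc_strong_cdi = list(
      kind = "wholecell",
      tau_ba = list(w_fast = 0.3, tau_fast = 0.150, tau_slow = 2.0),
      tau_ca = list(w_fast = 0.7, tau_fast = 0.040, tau_slow = 0.500),
      capacitance = 20, noise_sd = 5),
    wc_no_cdi = list(
      kind = "wholecell",
      tau_ba = list(w_fast = 0.3, tau_fast = 0.150, tau_slow = 2.0),
      tau_ca = list(w_fast = 0.3, tau_fast = 0.150, tau_slow = 2.0),
      capacitance = 20, noise_sd = 5)
  )
}

.get_preset <- function(name, kind) {
  p <- hc_presets()[[name]]
  if (is.null(p)) stop("unknown preset '", name, "'", call. = FALSE)
  if (p$kind != kind) {
    stop("preset '", name, "' is not a ", kind, " preset", call. = FALSE)
  }
  p
}

#' Generate an ITC isotherm from a preset or explicit parameters
#'
#' Thin wrapper over [simulate_isotherm()] bundling the study-condition
#' presets of [hc_presets()].
#'
#' @param preset preset name (see [hc_presets()]), or `NULL` to supply
#'   `params` and `schedule` directly.
#' @param seed integer RNG seed.
#' @param params,schedule,noise_sd overrides of the preset values.
#' @return an `isotherm`.
#' @examples
#' iso <- gen_itc("itc_ca_camiq_37c", seed = 1)
#' fit <- fit_one_site(delete_first_injection(iso))
#' @export
gen_itc <- function(preset = NULL, seed = NULL, params = NULL,
                    schedule = NULL, noise_sd = NULL) {
  if (!is.null(preset)) {
    p <- .get_preset(preset, "itc")
    if (is.null(params)) params <- p$params
    if (is.null(schedule)) schedule <- p$schedule
    if (is.null(noise_sd)) noise_sd <- p$noise_sd
  }
  if (is.null(params) || is.null(schedule)) {
    stop("supply a preset name or both 'params' and 'schedule'",
         call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- 0
  simulate_isotherm(params, schedule, noise_sd = noise_sd, seed = seed)
}

#' Generate a fluorescence-polarization titration
#'
#' Forward model is the depletion-exact quadratic saturation of the
#' labelled peptide (which reduces to the hyperbola when
#' `labeled_conc` is much smaller than `kd`), scaled by `b_max`, with
#' seeded Gaussian noise.
#'
#' @param preset preset name, or `NULL` for explicit parameters.
#' @param seed integer RNG seed.
#' @param kd,b_max,labeled_conc,grid,noise_sd overrides: true
#'   dissociation constant (M), maximal polarization, labelled-peptide
#'   concentration (M), titrant grid (M), and noise SD.
#' @return an [fp_titration()].
#' @examples
#' t <- gen_fp("fp_apocam_y1657d", seed = 1)
#' fit_fp(t)$kd * 1e6 # ~60 uM
#' @export
gen_fp <- function(preset = NULL, seed = NULL, kd = NULL, b_max = NULL,
                   labeled_conc = NULL, grid = NULL, noise_sd = NULL) {
  if (!is.null(preset)) {
    p <- .get_preset(preset, "fp")
    if (is.null(kd)) kd <- p$kd
    if (is.null(b_max)) b_max <- p$b_max
    if (is.null(labeled_conc)) labeled_conc <- p$labeled_conc
    if (is.null(grid)) grid <- p$grid
    if (is.null(noise_sd)) noise_sd <- p$noise_sd
  }
  .check_positive(kd, "kd")
  .check_positive(b_max, "b_max")
  y <- b_max * .depletion_saturation(grid, labeled_conc, kd)
  if (!is.null(noise_sd) && noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  fp_titration(grid, y, labeled_conc)
}

## bi-exponential decay normalised to 1 at t = 0
.biexp <- function(t, w_fast, tau_fast, tau_slow) {
  w_fast * exp(-t / tau_fast) + (1 - w_fast) * exp(-t / tau_slow)
}

#' Generate a paired Ba2+/Ca2+ whole-cell recording family
#'
#' 900 ms depolarizations from -60 to +50 mV in 10 mV steps.  Peak
#' amplitude across voltage follows a Boltzmann-activated linear driving
#' force; inactivation is bi-exponential with the Ca2+ carrier faster
#' than Ba2+ (CDI).  Optionally a capacitive spike blanked over the
#' first 2 ms tests robustness of downstream metrics.
#'
#' @param preset preset name (`"wc_strong_cdi"`, `"wc_no_cdi"`), or
#'   `NULL` for explicit parameters.
#' @param seed integer RNG seed.
#' @param tau_ba,tau_ca inactivation settings per carrier: lists with
#'   `w_fast`, `tau_fast`, `tau_slow` (seconds).
#' @param capacitance cell capacitance, pF.
#' @param noise_sd current noise SD, pA.
#' @param gmax peak conductance scale, nS.
#' @param erev,vhalf,slope I/V shape: reversal potential, half-activation
#'   and slope, mV.
#' @param sampling_rate sampling rate, Hz.
#' @param cap_spike logical; inject a capacitive transient blanked over
#'   the first 2 ms.
#' @return a list with elements `ba` and `ca`, each a
#'   [wholecell_recording()], plus `tau_ba`/`tau_ca` echoing the
#'   generating settings.
#' @export
gen_wholecell <- function(preset = NULL, seed = NULL, tau_ba = NULL,
                          tau_ca = NULL, capacitance = NULL,
                          noise_sd = NULL, gmax = 10, erev = 60,
                          vhalf = -10, slope = 6, sampling_rate = 10000,
                          cap_spike = FALSE) {
  if (!is.null(preset)) {
    p <- .get_preset(preset, "wholecell")
    if (is.null(tau_ba)) tau_ba <- p$tau_ba
    if (is.null(tau_ca)) tau_ca <- p$tau_ca
    if (is.null(capacitance)) capacitance <- p$capacitance
    if (is.null(noise_sd)) noise_sd <- p$noise_sd
  }
  if (is.null(noise_sd)) noise_sd <- 0
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  potentials <- seq(-60, 50, by = 10)
  dur <- 0.9
  t <- seq(0, dur - 1 / sampling_rate, by = 1 / sampling_rate)
  peak <- gmax * (potentials - erev) /
    (1 + exp(-(potentials - vhalf) / slope)) # pA, inward negative
  make_rec <- function(tau, carrier) {
    sw <- vapply(seq_along(potentials), function(i) {
      y <- peak[i] * .biexp(t, tau$w_fast, tau$tau_fast, tau$tau_slow)
      if (cap_spike) {
        spike <- -500 * exp(-t / 2e-4)
        y <- y + spike
        y[t < 2e-3] <- 0 # blanked
      }
      if (noise_sd > 0) y <- y + stats::rnorm(length(t), sd = noise_sd)
      y
    }, numeric(length(t)))
    colnames(sw) <- potentials
    wholecell_recording(sw, capacitance, carrier, sampling_rate,
                        pulse_duration = dur * 1000)
  }
  list(ba = make_rec(tau_ba, "Ba"), ca = make_rec(tau_ca, "Ca"),
       tau_ba = tau_ba, tau_ca = tau_ca)
}

#' Generate single-channel sweeps under the cell-attached protocol
#'
#' Delegates to [simulate_sweeps()] with the cell-attached protocol
#' preset (2 s depolarizations, 10 kHz sampling, 2 kHz Bessel filter).
#'
#' @param model a [gating_model()].
#' @param n_sweeps number of sweeps.
#' @param seed integer RNG seed.
#' @param preset protocol preset name (default `"sc_cell_attached"`).
#' @return a [sweep_set()].
#' @export
gen_singlechannel <- function(model, n_sweeps, seed = NULL,
                              preset = "sc_cell_attached") {
  p <- .get_preset(preset, "singlechannel")
  simulate_sweeps(model, n_sweeps, duration = p$duration,
                  sampling_rate = p$sampling_rate,
                  noise_sd = p$noise_sd,
                  filter_cutoff = p$filter_cutoff, seed = seed)
}

#' Generate a synthetic structural ensemble
#'
#' A rigid backbone scaffold (ideal alpha-helical geometry) is copied
#' `n_models` times with independent Gaussian coordinate jitter, giving a
#' known expected coordinate precision (to-mean RMSD ~= jitter_sd *
#' sqrt(3), slightly reduced by the superposition fit).
#'
#' @param n_models number of models (>= 2).
#' @param jitter_sd per-coordinate Gaussian jitter SD, angstroms.
#' @param seed integer RNG seed.
#' @param n_residues scaffold length, residues.
#' @param first_residue residue numbering offset of the scaffold.
#' @return a list of model data frames (see [ensemble_rmsd()]).
#' @export
gen_ensemble <- function(n_models, jitter_sd, seed = NULL,
                         n_residues = 30, first_residue = 85L) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  ## ideal helix: 100 degrees twist and 1.5 A rise per residue, CA at
  ## 2.3 A radius; N, C, O placed at fixed offsets from CA
  i <- seq_len(n_residues)
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  offsets <- list(
    N = c(-1.0, -0.7, -0.6), CA = c(0, 0, 0),
    C = c(1.1, 0.5, 0.4), O = c(1.4, 1.5, 0.9)
  )
  scaffold <- do.call(rbind, lapply(i, function(r) {
    do.call(rbind, lapply(names(offsets), function(a) {
      data.frame(residue = first_residue + r - 1L, atom = a,
                 x = ca[r, 1] + offsets[[a]][1],
                 y = ca[r, 2] + offsets[[a]][2],
                 z = ca[r, 3] + offsets[[a]][3])
    }))
  }))
  lapply(seq_len(n_models), function(m) {
    out <- scaffold
    jit <- matrix(stats::rnorm(3 * nrow(out), sd = jitter_sd),
                  ncol = 3)
    out$x <- out$x + jit[, 1]
    out$y <- out$y + jit[, 2]
    out$z <- out$z + jit[, 3]
    out
  })
}
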