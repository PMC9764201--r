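## Cell-attached single-channel analysis.
##
## Forward model: each of k channels is an independent continuous-time
## two-state Markov chain (closed <-> open) with exact exponential dwell
## sampling; the superposed open count is scaled by the unitary current,
## broadband Gaussian noise is added, and the sum passes through a
## digital 4-pole Bessel filter -- the order of the physical recording
## chain, where patch noise enters upstream of the amplifier's low-pass
## filter (so the output noise SD is below the nominal `noise_sd` by the
## filter's noise-bandwidth factor).  Analysis: half-amplitude multi-level idealization,
## channel-count estimation from the maximum simultaneous opening,
## NPo / Po, and mean ensemble averages.

#' Two-state gating model
#'
#' @param open_rate closed-to-open rate, s^-1.
#' @param close_rate open-to-closed rate, s^-1.
#' @param unitary_current single-channel current, pA (negative for inward
#'   Ba2+ current).
#' @param n_channels number of channels in the patch (k >= 1).
#' @return an object of class `"gating_model"`; the stationary open
#'   probability `open_rate / (open_rate + close_rate)` is stored as
#'   `$p_open`.
#' @examples
#' gating_model(open_rate = 31.25, close_rate = 125,
#'              unitary_current = -1) # true Po = 0.2
#' @export
gating_model <- function(open_rate, close_rate, unitary_current,
                         n_channels = 1L) {
  .check_positive(open_rate, "open_rate")
  .check_positive(close_rate, "close_rate")
  stopifnot(is.numeric(unitary_current), is.finite(unitary_current))
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("'n_channels' must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(open_rate = open_rate, close_rate = close_rate,
         unitary_current = unitary_current, n_channels = n_channels,
         p_open = open_rate / (open_rate + close_rate)),
    class = "gating_model"
  )
}

#' Sweep-set container
#'
#' @param sweeps numeric matrix of currents in pA: one column per sweep,
#'   rows are samples.
#' @param sampling_rate sampling rate, Hz.
#' @param filter_cutoff low-pass filter cutoff, Hz; must satisfy
#'   `sampling_rate >= 2 * filter_cutoff`.
#' @return an object of class `"sweep_set"` with `sweep_duration` in
#'   seconds derived from the dimensions.
#' @export
sweep_set <- function(sweeps, sampling_rate, filter_cutoff) {
  sweeps <- as.matrix(sweeps)
  .check_positive(sampling_rate, "sampling_rate")
  .check_positive(filter_cutoff, "filter_cutoff")
  if (sampling_rate < 2 * filter_cutoff) {
    stop("'sampling_rate' must be at least twice 'filter_cutoff'",
         call. = FALSE)
  }
  structure(
    list(sweeps = sweeps, sampling_rate = sampling_rate,
         filter_cutoff = filter_cutoff,
         sweep_duration = nrow(sweeps) / sampling_rate),
    class = "sweep_set"
  )
}

## ---- Bessel filter ----------------------------------------------------

## 4th-order analog Bessel low-pass prototype, -3 dB at 1 rad/s
## (pole constants to 8 decimals; DC gain is unity by construction)
.BESSEL4_POLES <- c(
  complex(real = -1.37006783, imaginary =  0.41024972),
  complex(real = -1.37006783, imaginary = -0.41024972),
  complex(real = -0.99520876, imaginary =  1.25710574),
  complex(real = -0.99520876, imaginary = -1.25710574)
)

## digital 4-pole Bessel low-pass via pre-warped bilinear transform
.bessel4_lowpass <- function(x, sampling_rate, cutoff) {
  wc <- 2 * sampling_rate * tan(pi * cutoff / sampling_rate)
  sp <- .BESSEL4_POLES * wc
  sg <- Re(prod(-sp))
  zp <- signal::bilinear(Sz = numeric(0), Sp = sp, Sg = sg,
                         T = 1 / sampling_rate)
  ar <- signal::as.Arma(zp)
  as.numeric(signal::filter(ar$b, ar$a, x))
}

## ---- simulation -------------------------------------------------------

## open (0/1) state of one channel sampled on the grid, from exact
## exponential dwells; initial state drawn from the stationary law
.simulate_channel_states <- function(open_rate, close_rate, n_samples,
                                     sampling_rate) {
  duration <- n_samples / sampling_rate
  state <- as.integer(stats::runif(1) <
                        open_rate / (open_rate + close_rate))
  t_grid <- (seq_len(n_samples) - 1) / sampling_rate
  ## draw dwells in blocks until the sweep is covered
  times <- numeric(0)
  states <- integer(0)
  t <- 0
  s <- state
  mean_cycle <- 1 / open_rate + 1 / close_rate
  while (t < duration) {
    n_draw <- max(16L, ceiling(2 * (duration - t) / mean_cycle) * 2L)
    rates <- ifelse(rep(c(s, 1 - s), length.out = n_draw) == 1L,
                    close_rate, open_rate)
    dw <- stats::rexp(n_draw, rate = rates)
    times <- c(times, t + cumsum(dw))
    states <- c(states, rep(c(s, 1 - s), length.out = n_draw))
    t <- times[length(times)]
    s <- 1L - states[length(states)]
  }
  ## state at each sample instant: states[j] holds on [times[j-1], times[j])
  idx <- findInterval(t_grid, times) + 1L
  states[idx]
}

#' Simulate single-channel current sweeps
#'
#' k independent two-state channels are simulated with exact exponential
#' dwell sampling, superposed, scaled by the unitary current, corrupted
#' with broadband Gaussian noise and low-pass filtered (digital 4-pole
#' Bessel), in that order -- the order of the physical recording chain.
#' Fully reproducible for a given seed.
#'
#' @param model a [gating_model()].
#' @param n_sweeps number of sweeps.
#' @param duration sweep duration, s.
#' @param sampling_rate sampling rate, Hz (default 10 kHz).
#' @param noise_sd broadband (pre-filter) Gaussian noise SD, pA.
#' @param filter_cutoff Bessel filter cutoff, Hz (default 2 kHz).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return a [sweep_set()]; the generating true level matrix (open counts
#'   per sample) is attached as `attr(, "true_levels")` for validation.
#' @export
simulate_sweeps <- function(model, n_sweeps, duration,
                            sampling_rate = 10000, noise_sd = 0.2,
                            filter_cutoff = 2000, seed = NULL) {
  stopifnot(inherits(model, "gating_model"))
  .check_positive(n_sweeps, "n_sweeps")
  .check_positive(duration, "duration")
  .check_nonnegative(noise_sd, "noise_sd")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  n_samples <- round(duration * sampling_rate)
  sweeps <- matrix(0, n_samples, n_sweeps)
  levels <- matrix(0L, n_samples, n_sweeps)
  for (j in seq_len(n_sweeps)) {
    lv <- integer(n_samples)
    for (ch in seq_len(model$n_channels)) {
      lv <- lv + .simulate_channel_states(model$open_rate,
                                          model$close_rate,
                                          n_samples, sampling_rate)
    }
    levels[, j] <- lv
    y <- lv * model$unitary_current
    if (noise_sd > 0) y <- y + stats::rnorm(n_samples, sd = noise_sd)
    sweeps[, j] <- .bessel4_lowpass(y, sampling_rate, filter_cutoff)
  }
  out <- sweep_set(sweeps, sampling_rate, filter_cutoff)
  attr(out, "true_levels") <- levels
  out
}

## ---- idealization -----------------------------------------------------

## run-length encode a level vector into an event data frame
.levels_to_events <- function(lv, sampling_rate) {
  r <- rle(lv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(level = r$values,
             start_s = starts / sampling_rate,
             duration_s = r$lengths / sampling_rate)
}

## merge events shorter than min_len samples into their longer neighbour
.merge_short_events <- function(lv, min_len) {
  repeat {
    r <- rle(lv)
    short <- which(r$lengths < min_len)
    if (!length(short) || length(r$lengths) == 1L) return(lv)
    i <- short[which.min(r$lengths[short])]
    nb <- if (i == 1L) 2L
    else if (i == length(r$lengths)) i - 1L
    else if (r$lengths[i + 1L] >= r$lengths[i - 1L]) i + 1L
    else i - 1L
    r$values[i] <- r$values[nb]
    lv <- inverse.rle(r)
  }
}

#' Half-amplitude idealization of single-channel sweeps
#'
#' Assigns to every sample the open-channel count whose ideal amplitude
#' is nearest, i.e. thresholds at `(m - 1/2) * unitary_current` for
#' `m = 1..k_max` (the half-height criterion extended to stacked
#' openings).  Events shorter than the filter risetime
#' `0.3321 / filter_cutoff` cannot be resolved by the recording filter
#' and are merged into their longer neighbour.
#'
#' @param sweeps a [sweep_set()].
#' @param unitary_current unitary current, pA (sign as recorded).
#' @param k_max maximum number of simultaneously open channels to
#'   resolve.
#' @return an object of class `"event_list"`: a list with one data frame
#'   per sweep (columns `level`, `start_s`, `duration_s`, tiling the
#'   sweep), with the sweep duration as an attribute.
#' @export
idealize_half_height <- function(sweeps, unitary_current, k_max = 4L) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (unitary_current == 0) {
    stop("'unitary_current' must be nonzero", call. = FALSE)
  }
  noise_sd <- stats::mad(diff(sweeps$sweeps[, 1])) / sqrt(2)
  if (is.finite(noise_sd) && abs(unitary_current) < 3 * noise_sd) {
    warning("unitary current below 3x estimated noise SD; idealization ",
            "will be unreliable", call. = FALSE)
  }
  min_len <- max(1L, ceiling(0.3321 / sweeps$filter_cutoff *
                               sweeps$sampling_rate))
  events <- lapply(seq_len(ncol(sweeps$sweeps)), function(j) {
    y <- sweeps$sweeps[, j] / unitary_current # open level is positive
    lv <- pmin(pmax(floor(y + 0.5), 0), k_max)
    lv <- .merge_short_events(as.integer(lv), min_len)
    .levels_to_events(lv, sweeps$sampling_rate)
  })
  structure(events, class = "event_list",
            sweep_duration = sweeps$sweep_duration,
            filter_cutoff = sweeps$filter_cutoff)
}

#' Estimate the number of channels in the patch
#'
#' The channel count k is the maximum simultaneous open level observed
#' across all sweeps, counting only *resolved* events: a level counts
#' when it is held for at least `min_duration` (default twice the filter
#' risetime when the event list carries its filter cutoff, 0 otherwise),
#' which rejects threshold-grazing noise blips.  The estimator is
#' reliable for small k (< 4) and reasonable open probability; genuine
#' stacked openings dwell far longer than the risetime, so the duration
#' gate can only underestimate the true count.
#'
#' @param events an `"event_list"`.
#' @param min_duration minimum duration (s) for an event to count;
#'   `NULL` for the default above.
#' @return integer channel count (>= 1 when any opening was seen, 0 for
#'   an all-closed record).
#' @export
estimate_channel_count <- function(events, min_duration = NULL) {
  stopifnot(inherits(events, "event_list"))
  if (!length(events)) stop("empty event list", call. = FALSE)
  if (is.null(min_duration)) {
    fc <- attr(events, "filter_cutoff")
    min_duration <- if (is.null(fc)) 0 else 2 * 0.3321 / fc
  }
  max(vapply(events, function(e) {
    ok <- e$duration_s >= min_duration
    if (any(ok)) max(e$level[ok]) else 0
  }, 0))
}

#' Open probability from an event list
#'
#' `NPo` is the time-averaged open level over all sweeps; `Po = NPo / k`
#' after correcting by the channel count.
#'
#' @param events an `"event_list"`.
#' @param k channel count (>= 1), e.g. from [estimate_channel_count()].
#' @return a list with `npo` and `po`.
#' @export
open_probability <- function(events, k) {
  stopifnot(inherits(events, "event_list"))
  if (!is.numeric(k) || k < 1) stop("'k' must be >= 1", call. = FALSE)
  open_time <- sum(vapply(events, function(e) sum(e$level * e$duration_s),
                          0))
  total_time <- sum(vapply(events, function(e) sum(e$duration_s), 0))
  npo <- open_time / total_time
  list(npo = npo, po = npo / k)
}

#' Mean ensemble average of single-channel sweeps
#'
#' Pointwise mean current across all sweeps.  For stationary gating the
#' plateau converges to `k * Po * unitary_current`.
#'
#' @param sweeps a [sweep_set()].
#' @return numeric trace, pA, one value per sample.
#' @export
mean_ensemble_average <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (ncol(sweeps$sweeps) < 1L) stop("no sweeps", call. = FALSE)
  rowMeans(sweeps$sweeps)
}

#' Write an event list as CSV
#'
#' Columns `sweep`, `level`, `start_s`, `dur_s`.
#'
#' @param events an `"event_list"`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_event_list <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  df <- do.call(rbind, lapply(seq_along(events), function(j) {
    data.frame(sweep = j, level = events[[j]]$level,
               start_s = events[[j]]$start_s,
               dur_s = events[[j]]$duration_s)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
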