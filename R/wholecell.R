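## Whole-cell current analysis: I/V curves, peak current density, and the
## inactivation metrics r300 (fraction of peak current remaining 300 ms
## after depolarization onset), f300 = r300(Ba) - r300(Ca) (the CDI
## readout) and VDI = 1 - r300(Ba).
##
## Sign convention: inward current is negative in stored traces; metrics
## are computed on magnitudes.  Leak and capacitance transients are
## assumed already subtracted.

#' Whole-cell recording container
#'
#' @param sweeps numeric matrix of current traces in pA, one column per
#'   test potential, rows sampled at `sampling_rate`; column names are
#'   the test potentials in mV.
#' @param capacitance cell capacitance, pF (> 0).
#' @param carrier charge carrier, `"Ba"` or `"Ca"`.
#' @param sampling_rate sampling rate, Hz.
#' @param pulse_duration depolarization duration, ms.
#' @param holding holding potential, mV.
#' @return an object of class `"wholecell_recording"`.
#' @export
wholecell_recording <- function(sweeps, capacitance, carrier,
                                sampling_rate, pulse_duration = 900,
                                holding = -80) {
  sweeps <- as.matrix(sweeps)
  if (is.null(colnames(sweeps))) {
    stop("'sweeps' must have column names giving test potentials in mV",
         call. = FALSE)
  }
  .check_positive(capacitance, "capacitance")
  .check_positive(sampling_rate, "sampling_rate")
  .check_positive(pulse_duration, "pulse_duration")
  carrier <- match.arg(carrier, c("Ba", "Ca"))
  structure(
    list(sweeps = sweeps, capacitance = capacitance, carrier = carrier,
         sampling_rate = sampling_rate, pulse_duration = pulse_duration,
         holding = holding,
         potentials = as.numeric(colnames(sweeps))),
    class = "wholecell_recording"
  )
}

#' Peak current density I/V curve
#'
#' For each test potential, the peak inward current (most negative value
#' within the pulse) divided by the cell capacitance.  The potential of
#' the largest-magnitude density is reported as `imax_potential`.
#'
#' @param rec a [wholecell_recording()].
#' @return an object of class `"iv_curve"`: data frame with columns
#'   `potential_mV` and `peak_density_pA_pF`, with `imax_potential` as an
#'   attribute.
#' @export
peak_current_density <- function(rec) {
  stopifnot(inherits(rec, "wholecell_recording"))
  if (ncol(rec$sweeps) < 1L || nrow(rec$sweeps) < 1L) {
    stop("recording contains no sweeps", call. = FALSE)
  }
  peaks <- apply(rec$sweeps, 2, min)
  dens <- peaks / rec$capacitance
  out <- data.frame(potential_mV = rec$potentials,
                    peak_density_pA_pF = unname(dens))
  attr(out, "imax_potential") <- rec$potentials[which.max(abs(dens))]
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Normalize peak currents (or an I/V curve) to the current maximum
#'
#' Divides by the magnitude of the largest peak so the normalized curve
#' has magnitude 1 at the potential of Imax.
#'
#' @param x an `"iv_curve"` or a numeric vector of peak currents.
#' @return the normalized object, same shape as the input.
#' @export
normalize_to_imax <- function(x) {
  if (inherits(x, "iv_curve")) {
    imax <- max(abs(x$peak_density_pA_pF))
    if (imax == 0) stop("all-zero I/V curve", call. = FALSE)
    x$peak_density_pA_pF <- x$peak_density_pA_pF / imax
    return(x)
  }
  imax <- max(abs(x))
  if (imax == 0) stop("all-zero input", call. = FALSE)
  x / imax
}

#' Fraction of current remaining 300 ms after depolarization onset
#'
#' `r300 = |I(300 ms)| / |I_peak|`, with the clock starting at
#' depolarization onset (the first sample of the trace).  The peak is
#' the activation peak, located within the first `peak_window` ms of the
#' pulse (channel activation at these potentials completes within tens
#' of milliseconds, and restricting the search keeps the peak estimate
#' off the late, noise-dominated part of the trace).  The 300 ms current
#' is averaged over a short window (default 5 ms) centred on 300 ms to
#' suppress sampling noise.  Values above 1 (facilitating traces) are
#' permitted and flagged with a warning.
#'
#' @param trace numeric current trace, pA, starting at depolarization
#'   onset.
#' @param sampling_rate sampling rate, Hz.
#' @param at time of the remaining-current measurement, ms (default 300).
#' @param window averaging window, ms (default 5).
#' @param peak_window activation-peak search window from onset, ms
#'   (default 100).
#' @return fraction of the peak current remaining.
#' @examples
#' fs <- 10000; t <- seq(0, 0.9, by = 1 / fs)
#' r300(-exp(-t / 0.3), fs) # ~ exp(-1)
#' @export
r300 <- function(trace, sampling_rate, at = 300, window = 5,
                 peak_window = 100) {
  .check_positive(sampling_rate, "sampling_rate")
  n <- length(trace)
  if (n / sampling_rate * 1000 < at) {
    stop("trace shorter than ", at, " ms", call. = FALSE)
  }
  np <- min(n, round(peak_window / 1000 * sampling_rate) + 1L)
  peak <- max(abs(trace[seq_len(np)]))
  if (peak == 0) stop("zero peak current", call. = FALSE)
  i0 <- max(1L, round((at - window / 2) / 1000 * sampling_rate) + 1L)
  i1 <- min(n, round((at + window / 2) / 1000 * sampling_rate) + 1L)
  r <- mean(abs(trace[i0:i1])) / peak
  if (r > 1) {
    warning("remaining current exceeds the peak (facilitating trace)",
            call. = FALSE)
  }
  r
}

#' Calcium-dependent inactivation metric f300
#'
#' `f300 = r300(Ba) - r300(Ca)`: the extra inactivation seen with Ca2+ as
#' the charge carrier, the standard CDI readout.  A negative value (Ca2+
#' decaying slower than Ba2+) is non-physical for this channel and is
#' flagged.
#'
#' @param r_ba300 fraction remaining with Ba2+.
#' @param r_ca300 fraction remaining with Ca2+.
#' @return f300.
#' @export
cdi_f300 <- function(r_ba300, r_ca300) {
  f <- r_ba300 - r_ca300
  if (any(f < 0)) {
    warning("negative f300: Ca2+ decays slower than Ba2+", call. = FALSE)
  }
  f
}

#' Voltage-dependent inactivation from the Ba2+ trace
#'
#' `VDI = 1 - r300(Ba)`: the inactivation that occurs without permeant
#' Ca2+.
#'
#' @param r_ba300 fraction remaining with Ba2+.
#' @return VDI.
#' @export
vdi <- function(r_ba300) 1 - r_ba300

#' Write / read a whole-cell recording as columnar text
#'
#' First column `time_s`, one column per test potential labelled by mV;
#' `#` header lines carry capacitance, carrier, sampling rate, pulse
#' duration and holding potential.
#'
#' @param rec a [wholecell_recording()].
#' @param path file path.
#' @return `write_wholecell()` returns `path` invisibly;
#'   `read_wholecell()` returns a [wholecell_recording()].
#' @export
write_wholecell <- function(rec, path) {
  stopifnot(inherits(rec, "wholecell_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# capacitance_pF=%.12g", rec$capacitance),
    sprintf("# carrier=%s", rec$carrier),
    sprintf("# sampling_rate_Hz=%.12g", rec$sampling_rate),
    sprintf("# pulse_duration_ms=%.12g", rec$pulse_duration),
    sprintf("# holding_mV=%.12g", rec$holding),
    "# sign_convention=inward_negative"
  ), con)
  df <- data.frame(
    time_s = (seq_len(nrow(rec$sweeps)) - 1) / rec$sampling_rate,
    rec$sweeps, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_wholecell
#' @export
read_wholecell <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  kv <- strsplit(hdr, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2),
                          vapply(kv, `[`, "", 1))
  df <- utils::read.table(
    textConnection(grep("^#", lines, value = TRUE, invert = TRUE)),
    header = TRUE, sep = "\t", check.names = FALSE)
  sweeps <- as.matrix(df[, -1, drop = FALSE])
  wholecell_recording(
    sweeps,
    capacitance = as.numeric(vals[["capacitance_pF"]]),
    carrier = vals[["carrier"]],
    sampling_rate = as.numeric(vals[["sampling_rate_Hz"]]),
    pulse_duration = as.numeric(vals[["pulse_duration_ms"]]),
    holding = as.numeric(vals[["holding_mV"]]))
}
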