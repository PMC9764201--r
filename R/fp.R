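## Fluorescence-polarization binding analysis.
##
## A fixed concentration of fluorescein-labelled peptide is titrated with
## a binding partner; polarization rises as the labelled peptide is bound.
## Two saturation models are provided: the simple hyperbola
## Y = B X / (Kd + X) (the conventional fit), and the depletion-exact
## quadratic that accounts for the labelled peptide consuming titrant
## when its concentration is comparable to Kd.

#' Fluorescence-polarization titration container
#'
#' @param titrant_total total titrant concentrations, molar, strictly
#'   increasing and non-negative.
#' @param polarization polarization readings (dimensionless), same length.
#' @param labeled_conc fixed labelled-peptide concentration, molar.
#' @param replicate_sd optional per-point SD of the polarization values.
#' @return an object of class `"fp_titration"`.
#' @export
fp_titration <- function(titrant_total, polarization, labeled_conc,
                         replicate_sd = NULL) {
  .check_nonnegative(titrant_total, "titrant_total")
  .check_positive(labeled_conc, "labeled_conc")
  if (length(titrant_total) != length(polarization)) {
    stop("'titrant_total' and 'polarization' lengths differ",
         call. = FALSE)
  }
  if (is.unsorted(titrant_total, strictly = TRUE)) {
    stop("'titrant_total' must be strictly increasing", call. = FALSE)
  }
  if (!is.null(replicate_sd) &&
      length(replicate_sd) != length(polarization)) {
    stop("'replicate_sd' length differs from data", call. = FALSE)
  }
  structure(
    list(titrant_total = titrant_total, polarization = polarization,
         labeled_conc = labeled_conc, replicate_sd = replicate_sd),
    class = "fp_titration"
  )
}

#' Polarization from vertical and horizontal intensities
#'
#' `P = (Iv - g Ih) / (Iv + g Ih)` with `g` the instrument correction
#' factor for the fluorophore.
#'
#' @param iv,ih vertical and horizontal fluorescence intensities.
#' @param g correction factor (> 0), default 1.
#' @return polarization in `(-1, 1]`.
#' @examples
#' polarization(3, 1) # 0.5
#' @export
polarization <- function(iv, ih, g = 1) {
  .check_positive(g, "g")
  denom <- iv + g * ih
  if (any(denom <= 0)) {
    stop("'iv + g*ih' must be > 0", call. = FALSE)
  }
  (iv - g * ih) / denom
}

## fractional saturation of the labelled peptide under ligand depletion:
## exact solution of  complex^2 - (L0 + X + Kd) complex + L0 X = 0
.depletion_saturation <- function(x_total, labeled_conc, kd) {
  s <- labeled_conc + x_total + kd
  disc <- s * s - 4 * labeled_conc * x_total
  complex <- (s - sqrt(pmax(disc, 0))) / 2
  complex / labeled_conc
}

## baseline handling: if the titration includes a zero-titrant point its
## polarization is the free-peptide baseline and is subtracted
.fp_baseline_subtract <- function(t) {
  y <- t$polarization
  x <- t$titrant_total
  if (x[1] == 0) {
    y <- y - y[1]
    list(x = x[-1], y = y[-1])
  } else {
    list(x = x, y = y)
  }
}

#' Fit a saturation binding curve to an FP titration
#'
#' `fit_hyperbolic()` fits `Y = B X / (Kd + X)` to the
#' baseline-subtracted polarization (the conventional analysis; when the
#' labelled-peptide concentration is comparable to Kd the fitted Kd is an
#' apparent, depletion-biased value).  `fit_fp()` with
#' `depletion = TRUE` instead fits the exact quadratic saturation that
#' accounts for titrant consumed by the labelled peptide, recovering the
#' true Kd in the tight-binding regime.
#'
#' @param t an [fp_titration()].
#' @param depletion logical; fit the depletion-exact quadratic model
#'   instead of the hyperbola.
#' @return a list of class `"fp_fit"` with `b_max`, `kd`, standard errors
#'   `se` (named `b_max`, `kd`), `converged`, `depletion` and `fitted`
#'   values.
#' @examples
#' x <- c(1, 3, 10, 30, 100, 300) * 1e-6
#' y <- 0.2 * x / (60e-6 + x)
#' fit_hyperbolic(fp_titration(x, y, 100e-9))
#' @export
fit_fp <- function(t, depletion = FALSE) {
  stopifnot(inherits(t, "fp_titration"))
  d <- .fp_baseline_subtract(t)
  if (length(d$x) < 4L) {
    stop("need at least 4 titrant points", call. = FALSE)
  }
  if (stats::cor(d$x, d$y) < 0) {
    stop("polarization decreases with titrant; wrong assay orientation",
         call. = FALSE)
  }
  b0 <- max(d$y)
  kd0 <- d$x[which.min(abs(d$y - b0 / 2))]
  kd0 <- max(kd0, min(d$x[d$x > 0]) / 10)
  model <- if (depletion) {
    function(th) th[1] * .depletion_saturation(d$x, t$labeled_conc,
                                               exp(th[2]))
  } else {
    function(th) th[1] * d$x / (exp(th[2]) + d$x)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(b0, log(kd0)),
      fn = function(th) d$y - model(th),
      lower = c(0, log(1e-13)), upper = c(10 * b0 + 1, log(1)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(b_max = NA_real_, kd = NA_real_,
                          se = c(b_max = NA_real_, kd = NA_real_),
                          converged = FALSE, depletion = depletion),
                     class = "fp_fit"))
  }
  b_max <- fit$par[1]
  kd <- exp(fit$par[2])
  dev <- sum(fit$fvec^2)
  dof <- max(length(fit$fvec) - 2L, 1L)
  vc <- tryCatch(solve(fit$hessian) * dev / dof, error = function(e) NULL)
  se <- if (is.null(vc)) c(NA_real_, NA_real_) else
    sqrt(pmax(diag(vc), 0))
  structure(
    list(b_max = b_max, kd = kd,
         se = c(b_max = se[1], kd = se[2] * kd),
         converged = fit$info %in% 1:4, depletion = depletion,
         fitted = model(fit$par), x = d$x, y = d$y),
    class = "fp_fit"
  )
}

#' @rdname fit_fp
#' @export
fit_hyperbolic <- function(t) fit_fp(t, depletion = FALSE)

#' @export
print.fp_fit <- function(x, ...) {
  cat("FP saturation fit (",
      if (x$depletion) "depletion-exact quadratic" else "hyperbolic",
      ")\n", sep = "")
  cat(sprintf("  b_max = %.4g +- %.2g\n", x$b_max, x$se["b_max"]))
  cat(sprintf("  kd    = %.4g M +- %.2g\n", x$kd, x$se["kd"]))
  invisible(x)
}

#' Free titrant concentration under ligand depletion
#'
#' `free = total - labeled_conc * fractional_saturation`, floored at zero
#' (with a warning when the bound amount nominally exceeds the total).
#'
#' @param total total titrant concentration, molar.
#' @param labeled_conc labelled-peptide concentration, molar.
#' @param fractional_saturation fraction of labelled peptide bound.
#' @return free titrant concentration, molar.
#' @examples
#' free_titrant(150e-9, 100e-9, 0.5) # 100 nM
#' @export
free_titrant <- function(total, labeled_conc, fractional_saturation) {
  .check_nonnegative(total, "total")
  .check_nonnegative(labeled_conc, "labeled_conc")
  .check_nonnegative(fractional_saturation, "fractional_saturation")
  free <- total - labeled_conc * fractional_saturation
  if (any(free < 0)) {
    warning("bound titrant exceeds total; clipping free concentration ",
            "at 0", call. = FALSE)
    free <- pmax(free, 0)
  }
  free
}

#' Saturation-based upper bound on the dissociation constant
#'
#' Implements the visual saturation argument as a testable rule.  A
#' plateau exists when the last three points agree with each other
#' within `saturation_tol` (relative); the plateau level is the fitted
#' maximal polarization when those points also agree with it, and
#' otherwise the mean of the last three points (the extrapolated
#' hyperbolic maximum systematically overshoots the observed plateau in
#' the ligand-depletion regime, where the saturation knee is sharper
#' than any hyperbola).  The Kd upper bound is the smallest titrant
#' concentration from which the curve stays within `saturation_tol` of
#' the plateau: if a titration is saturated at concentration c, the Kd
#' must be below c.
#'
#' @param t an [fp_titration()].
#' @param saturation_tol relative tolerance defining "at plateau"
#'   (default 0.05).
#' @return the upper bound in molar, or `Inf` (unbounded) when no plateau
#'   is reached.
#' @export
kd_upper_bound <- function(t, saturation_tol = 0.05) {
  stopifnot(inherits(t, "fp_titration"))
  d <- .fp_baseline_subtract(t)
  if (length(d$x) < 4L) {
    stop("need at least 4 titrant points", call. = FALSE)
  }
  fit <- tryCatch(fit_fp(t, depletion = FALSE), error = function(e) NULL)
  n <- length(d$y)
  last3 <- d$y[(n - 2):n]
  level <- mean(last3)
  if (level <= 0 || stats::sd(last3) > saturation_tol * abs(level)) {
    return(Inf) # still rising (or too scattered): no plateau
  }
  if (!is.null(fit) && is.finite(fit$b_max) && fit$b_max > 0 &&
      all(abs(last3 - fit$b_max) <= saturation_tol * fit$b_max)) {
    level <- fit$b_max
  }
  at_plateau <- abs(d$y - level) <= saturation_tol * level
  ## smallest concentration from which the curve stays at plateau
  stays <- rev(cumprod(rev(at_plateau))) > 0
  if (!any(stays)) return(Inf)
  d$x[which(stays)[1]]
}
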