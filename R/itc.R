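## Isothermal titration calorimetry: forward model and fitting.
##
## The forward model reproduces the per-injection heats of a
## perfusion-cell instrument (constant cell volume; each injection
## displaces an equal volume of cell content).  Concentrations of both
## the titrand and the accumulated injectant are diluted by
## (1 - v_inj / V_cell) per injection, and the measured heat of injection
## i is the change in total bound-ligand enthalpy content corrected for
## the enthalpy carried out with the displaced volume:
##
##   Q_i  = V_cell * sum_c dH_c * [bound]_c,i            (kcal)
##   dq_i = Q_i - Q_{i-1} + (v/V) * (Q_i + Q_{i-1}) / 2
##
## normalised by the moles of injectant delivered.  Binding classes are
## independent; free ligand is the root of the (monotone) conservation
## equation -- closed form for one class, bracketed root-find for two.

#' ITC titration schedule
#'
#' @param cell_volume calorimeter cell volume, litres.
#' @param cell_conc titrand concentration in the cell, molar.
#' @param syringe_conc injectant concentration in the syringe, molar.
#' @param n_injections number of injections (>= 2).
#' @param injection_volume volume per injection, litres.
#' @param temperature bath temperature, kelvin.
#' @return an object of class `"titration_schedule"`.
#' @examples
#' # 8 uM complex in 1.5 ml titrated with 0.30 mM CaCl2, 35 x 10 ul, 37 C
#' titration_schedule(1.5e-3, 8e-6, 0.30e-3, 35, 10e-6,
#'                    celsius_to_kelvin(37))
#' @export
titration_schedule <- function(cell_volume, cell_conc, syringe_conc,
                               n_injections, injection_volume,
                               temperature) {
  .check_positive(cell_volume, "cell_volume")
  .check_positive(cell_conc, "cell_conc")
  .check_positive(syringe_conc, "syringe_conc")
  .check_positive(injection_volume, "injection_volume")
  .check_positive(temperature, "temperature")
  n_injections <- as.integer(n_injections)
  if (is.na(n_injections) || n_injections < 2L) {
    stop("'n_injections' must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc, n_injections = n_injections,
         injection_volume = injection_volume, temperature = temperature),
    class = "titration_schedule"
  )
}

#' One-site ITC binding parameters
#'
#' @param n stoichiometry, sites per titrand molecule.
#' @param ka association constant, M^-1.
#' @param dh binding enthalpy, kcal per mole of injectant bound.
#' @return an object of class `c("one_site_params", "itc_params")`.
#' @export
one_site_params <- function(n, ka, dh) {
  .check_positive(n, "n")
  .check_positive(ka, "ka")
  stopifnot(is.numeric(dh), is.finite(dh))
  structure(list(n = n, ka = ka, dh = dh),
            class = c("one_site_params", "itc_params"))
}

#' Two-independent-classes ITC binding parameters
#'
#' Two classes of independent sites on the titrand, each with its own
#' stoichiometry, association constant and enthalpy (the parameterisation
#' of the classic instrument-software "two sets of sites" model).
#'
#' @param n1,ka1,dh1 stoichiometry, association constant (M^-1) and
#'   enthalpy (kcal/mol) of the first class.
#' @param n2,ka2,dh2 same for the second class.
#' @return an object of class `c("two_site_params", "itc_params")`.
#' @export
two_site_params <- function(n1, ka1, dh1, n2, ka2, dh2) {
  .check_positive(c(n1, n2), "n")
  .check_positive(c(ka1, ka2), "ka")
  stopifnot(is.numeric(c(dh1, dh2)), all(is.finite(c(dh1, dh2))))
  structure(list(n1 = n1, ka1 = ka1, dh1 = dh1,
                 n2 = n2, ka2 = ka2, dh2 = dh2),
            class = c("two_site_params", "itc_params"))
}

## ---- forward model ----------------------------------------------------

## total and titrand concentrations in the cell after each injection,
## perfusion (overflow) convention
.itc_totals <- function(schedule) {
  ni <- schedule$n_injections
  f <- schedule$injection_volume / schedule$cell_volume
  d <- 1 - f
  i <- seq_len(ni)
  mt <- schedule$cell_conc * d^i
  xt <- schedule$syringe_conc * (1 - d^i)
  list(mt = mt, xt = xt, f = f)
}

## bound-ligand concentration per class given totals; one class closed
## form, two classes bracketed root-find on the monotone free-ligand
## conservation equation
.bound_conc <- function(params, mt, xt) {
  if (inherits(params, "one_site_params")) {
    s <- params$n * mt
    ka <- params$ka
    b <- 1 + ka * (s - xt)
    xf <- (-b + sqrt(b * b + 4 * ka * xt)) / (2 * ka)
    list(total = s * ka * xf / (1 + ka * xf), dh_weighted = NULL,
         per_class = NULL, params = params)
  } else {
    s1 <- params$n1 * mt; s2 <- params$n2 * mt
    k1 <- params$ka1;     k2 <- params$ka2
    xf <- numeric(length(xt))
    b1 <- numeric(length(xt))
    b2 <- numeric(length(xt))
    for (i in seq_along(xt)) {
      if (xt[i] <= 0) next
      fn <- function(x) {
        x + s1[i] * k1 * x / (1 + k1 * x) +
          s2[i] * k2 * x / (1 + k2 * x) - xt[i]
      }
      r <- tryCatch(
        stats::uniroot(fn, lower = 0, upper = xt[i],
                       tol = max(xt[i] * 1e-14, 1e-22)),
        error = function(e) {
          stop("free-ligand root-find failed (xt = ", xt[i], "): ",
               conditionMessage(e), call. = FALSE)
        }
      )
      xf[i] <- r$root
      b1[i] <- s1[i] * k1 * xf[i] / (1 + k1 * xf[i])
      b2[i] <- s2[i] * k2 * xf[i] / (1 + k2 * xf[i])
    }
    list(total = b1 + b2, per_class = cbind(b1, b2), params = params)
  }
}

## noise-free normalised heats (kcal per mole of injectant) for every
## injection in the schedule
.itc_model_heats <- function(params, schedule) {
  tot <- .itc_totals(schedule)
  v0 <- schedule$cell_volume
  if (inherits(params, "one_site_params")) {
    bc <- .bound_conc(params, tot$mt, tot$xt)
    q <- v0 * params$dh * bc$total
  } else {
    bc <- .bound_conc(params, tot$mt, tot$xt)
    q <- v0 * (params$dh1 * bc$per_class[, 1] +
                 params$dh2 * bc$per_class[, 2])
  }
  qprev <- c(0, q[-length(q)])
  dq <- q - qprev + tot$f * (q + qprev) / 2
  dq / (schedule$syringe_conc * schedule$injection_volume)
}

#' Simulate an ITC isotherm
#'
#' Computes the noise-free per-injection heats for a binding model and a
#' titration schedule under the perfusion-cell convention (see the file
#' header for the exact bookkeeping), then adds seeded Gaussian noise.
#'
#' @param params a [one_site_params()] or [two_site_params()] object.
#' @param schedule a [titration_schedule()].
#' @param noise_sd Gaussian noise SD on the normalised heats, kcal per
#'   mole of injectant (default 0).
#' @param seed integer RNG seed used when `noise_sd > 0`; `NULL` uses the
#'   current RNG state.
#' @return an object of class `"isotherm"`: a data frame with columns
#'   `injection`, `molar_ratio` (total injectant / total titrand in the
#'   cell) and `heat_kcal_per_mol`, with the schedule stored in
#'   `attr(, "schedule")`.
#' @examples
#' sch <- titration_schedule(1.5e-3, 8e-6, 0.3e-3, 35, 10e-6, 310.15)
#' iso <- simulate_isotherm(one_site_params(1.8, 1.4e7, -7.7), sch,
#'                          noise_sd = 0.1, seed = 1)
#' head(iso)
#' @export
simulate_isotherm <- function(params, schedule, noise_sd = 0,
                              seed = NULL) {
  stopifnot(inherits(params, "itc_params"),
            inherits(schedule, "titration_schedule"))
  .check_nonnegative(noise_sd, "noise_sd")
  heats <- .itc_model_heats(params, schedule)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    heats <- heats + stats::rnorm(length(heats), sd = noise_sd)
  }
  tot <- .itc_totals(schedule)
  out <- data.frame(
    injection = seq_len(schedule$n_injections),
    molar_ratio = tot$xt / tot$mt,
    heat_kcal_per_mol = heats
  )
  attr(out, "schedule") <- schedule
  class(out) <- c("isotherm", "data.frame")
  out
}

## save/restore of the global RNG state so seeded generators do not
## perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Delete the first injection of an isotherm
#'
#' The first injection of a titration carries a systematic under-delivery
#' error from the syringe dead volume, so its point is removed before
#' fitting.  Injection indices and molar ratios of the remaining points
#' are preserved.
#'
#' @param iso an `isotherm` from [simulate_isotherm()] or
#'   [read_isotherm()].
#' @return the isotherm without its first retained injection.
#' @export
delete_first_injection <- function(iso) {
  stopifnot(inherits(iso, "isotherm"))
  if (nrow(iso) < 2L) {
    stop("cannot delete the first injection of a single-point isotherm",
         call. = FALSE)
  }
  out <- iso[-1L, , drop = FALSE]
  attr(out, "schedule") <- attr(iso, "schedule")
  class(out) <- class(iso)
  out
}

## ---- fitting ----------------------------------------------------------

## residuals of observed heats vs the noise-free forward model restricted
## to the retained injection indices
.itc_residuals <- function(make_params, theta, iso) {
  schedule <- attr(iso, "schedule")
  p <- make_params(theta)
  heats <- .itc_model_heats(p, schedule)
  iso$heat_kcal_per_mol - heats[iso$injection]
}

## crude starting values: enthalpy from the early plateau, stoichiometry
## from the half-drop point of |heat|, ka from a mid-range c-value
.itc_init_one <- function(iso) {
  schedule <- attr(iso, "schedule")
  h <- iso$heat_kcal_per_mol
  dh0 <- mean(h[seq_len(min(3, length(h)))])
  amax <- max(abs(h))
  past <- which(abs(h) < amax / 2)
  n0 <- if (length(past)) iso$molar_ratio[past[1]] else
    iso$molar_ratio[length(h)] / 2
  n0 <- min(max(n0, 0.05), 20)
  ka0 <- 50 / (n0 * schedule$cell_conc)
  one_site_params(n0, ka0, if (abs(dh0) > 1e-8) dh0 else -1)
}

.itc_fit_core <- function(iso, theta0, make_params, lower, upper,
                          par_names) {
  res_fn <- function(theta) .itc_residuals(make_params, theta, iso)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = res_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(theta = theta0, se = rep(NA_real_, length(theta0)),
                converged = FALSE, deviance = NA_real_))
  }
  theta <- unname(fit$par)
  dev <- sum(fit$fvec^2)
  dof <- max(length(fit$fvec) - length(theta), 1L)
  vc <- tryCatch(solve(fit$hessian) * dev / dof, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(theta)) else
    sqrt(pmax(diag(vc), 0))
  conv <- fit$info %in% 1:4 &&
    !any(abs(theta - lower) < 1e-10) && !any(abs(theta - upper) < 1e-10)
  names(theta) <- names(se) <- par_names
  list(theta = theta, se = se, converged = conv, deviance = dev)
}

#' Fit a one-site binding model to an ITC isotherm
#'
#' Least-squares fit of the noise-free forward model, with the
#' association constant fitted on the log scale for conditioning across
#' the 1e6--1e9 M^-1 range.  Non-convergence is flagged, not raised.
#'
#' @param iso an `isotherm` (normally after [delete_first_injection()]).
#' @param init optional [one_site_params()] starting values; a data-driven
#'   heuristic is used when omitted.
#' @return an object of class `"itc_fit"` with elements `params`
#'   (fitted [one_site_params()]), `se` (standard errors for `n`, `ka`,
#'   `dh`; the `ka` error is delta-method transformed from the log scale),
#'   `converged`, `deviance` and `model = "one_site"`.
#' @examples
#' sch <- titration_schedule(1.5e-3, 8e-6, 0.3e-3, 35, 10e-6, 310.15)
#' iso <- simulate_isotherm(one_site_params(1.8, 1.4e7, -7.7), sch,
#'                          noise_sd = 0.1, seed = 1)
#' fit <- fit_one_site(delete_first_injection(iso))
#' apparent_kd(fit) * 1e9 # nM
#' @export
fit_one_site <- function(iso, init = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  if (nrow(iso) < 5L) {
    stop("need at least 5 points to fit a one-site model", call. = FALSE)
  }
  if (is.null(init)) init <- .itc_init_one(iso)
  stopifnot(inherits(init, "one_site_params"))
  make <- function(th) {
    th <- unname(th)
    one_site_params(th[1], exp(th[2]), th[3])
  }
  core <- .itc_fit_core(
    iso, c(init$n, log(init$ka), init$dh), make,
    lower = c(1e-3, log(1e2), -1e4), upper = c(1e3, log(1e15), 1e4),
    par_names = c("n", "log_ka", "dh")
  )
  params <- make(core$theta)
  se <- c(n = unname(core$se["n"]),
          ka = unname(core$se["log_ka"]) * params$ka,
          dh = unname(core$se["dh"]))
  structure(list(params = params, se = se, converged = core$converged,
                 deviance = core$deviance, model = "one_site",
                 isotherm = iso),
            class = "itc_fit")
}

#' Fit a two-independent-classes model to an ITC isotherm
#'
#' As [fit_one_site()] with two classes of sites.  The fitted classes are
#' returned in canonical descending-`ka` order to remove the label-swap
#' degeneracy, and a warning is attached when the two association
#' constants are within a factor of 3 (poor identifiability).
#'
#' @param iso an `isotherm` (normally after [delete_first_injection()]).
#' @param init [two_site_params()] starting values.
#' @return an `"itc_fit"` with `params` a [two_site_params()], standard
#'   errors for all six parameters, `converged`, and
#'   `identifiability_warning` (logical).
#' @export
fit_two_site <- function(iso, init) {
  stopifnot(inherits(iso, "isotherm"), inherits(init, "two_site_params"))
  if (nrow(iso) < 8L) {
    stop("need at least 8 points to fit a two-site model", call. = FALSE)
  }
  make <- function(th) {
    th <- unname(th)
    two_site_params(th[1], exp(th[2]), th[3], th[4], exp(th[5]), th[6])
  }
  core <- .itc_fit_core(
    iso,
    c(init$n1, log(init$ka1), init$dh1, init$n2, log(init$ka2), init$dh2),
    make,
    lower = rep(c(1e-3, log(1e2), -1e4), 2),
    upper = rep(c(1e3, log(1e15), 1e4), 2),
    par_names = c("n1", "log_ka1", "dh1", "n2", "log_ka2", "dh2")
  )
  params <- make(core$theta)
  se <- c(n1 = unname(core$se["n1"]),
          ka1 = unname(core$se["log_ka1"]) * params$ka1,
          dh1 = unname(core$se["dh1"]),
          n2 = unname(core$se["n2"]),
          ka2 = unname(core$se["log_ka2"]) * params$ka2,
          dh2 = unname(core$se["dh2"]))
  ## canonical ordering: class 1 is the tighter (larger ka) class
  if (params$ka2 > params$ka1) {
    params <- two_site_params(params$n2, params$ka2, params$dh2,
                              params$n1, params$ka1, params$dh1)
    se <- se[c("n2", "ka2", "dh2", "n1", "ka1", "dh1")]
    names(se) <- c("n1", "ka1", "dh1", "n2", "ka2", "dh2")
  }
  ident <- params$ka1 / params$ka2 < 3
  if (ident) {
    warning("the two site classes have association constants within a ",
            "factor of 3; parameters may not be identifiable",
            call. = FALSE)
  }
  structure(list(params = params, se = se, converged = core$converged,
                 deviance = core$deviance, model = "two_site",
                 identifiability_warning = ident, isotherm = iso),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC fit (", x$model, " model), ",
      if (isTRUE(x$converged)) "converged" else "NOT converged", "\n",
      sep = "")
  p <- unlist(x$params[!vapply(x$params, is.null, TRUE)])
  for (nm in names(p)) {
    cat(sprintf("  %-4s = %.4g", nm, p[[nm]]))
    if (!is.na(x$se[nm])) cat(sprintf(" +- %.2g", x$se[nm]))
    cat("\n")
  }
  cat(sprintf("  apparent KD = %.4g nM\n", apparent_kd(x) * 1e9))
  invisible(x)
}

#' Apparent dissociation constant from fitted ITC parameters
#'
#' One-site: `1/ka`.  Two classes: `1/ka` of the stoichiometric (major)
#' class, i.e. the class whose `n` is nearest `expected_n` -- for Ca2+
#' binding to the CaM C-lobe the expected stoichiometry is 2 per protein.
#'
#' @param x an `"itc_fit"` or an `itc_params` object.
#' @param expected_n expected stoichiometry of the major class (default 2).
#' @return apparent dissociation constant, molar.
#' @export
apparent_kd <- function(x, expected_n = 2) {
  if (inherits(x, "itc_fit")) x <- x$params
  stopifnot(inherits(x, "itc_params"))
  if (inherits(x, "one_site_params")) return(1 / x$ka)
  if (abs(x$n1 - expected_n) <= abs(x$n2 - expected_n)) 1 / x$ka1
  else 1 / x$ka2
}

## ---- i/o --------------------------------------------------------------

#' Write / read an isotherm as columnar CSV
#'
#' Columns `injection`, `molar_ratio`, `heat_kcal_per_mol`; the titration
#' schedule is carried in `#`-prefixed header comments so a round trip
#' preserves it.
#'
#' @param iso an `isotherm`.
#' @param path file path.
#' @return `write_isotherm()` returns `path` invisibly; `read_isotherm()`
#'   returns an `isotherm`.
#' @export
write_isotherm <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  sch <- attr(iso, "schedule")
  hdr <- sprintf(
    "# %s=%.12g",
    c("cell_volume_L", "cell_conc_M", "syringe_conc_M", "n_injections",
      "injection_volume_L", "temperature_K"),
    c(sch$cell_volume, sch$cell_conc, sch$syringe_conc, sch$n_injections,
      sch$injection_volume, sch$temperature))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(iso), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "="))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  sch <- titration_schedule(vals[["cell_volume_L"]], vals[["cell_conc_M"]],
                            vals[["syringe_conc_M"]],
                            vals[["n_injections"]],
                            vals[["injection_volume_L"]],
                            vals[["temperature_K"]])
  attr(df, "schedule") <- sch
  class(df) <- c("isotherm", "data.frame")
  df
}
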