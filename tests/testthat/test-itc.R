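# study-condition helpers used across the ITC tests
sched_37 <- function() titration_schedule(1.5e-3, 8e-6, 0.30e-3, 35,
                                          10e-6, celsius_to_kelvin(37))
par_37 <- function() one_site_params(1.8, 1.4e7, -7.7)

test_that("zero-enthalpy titrations release no heat", {
  iso <- simulate_isotherm(one_site_params(1, 1e7, 0), sched_37())
  expect_true(all(iso$heat_kcal_per_mol == 0))
  iso2 <- simulate_isotherm(two_site_params(1, 1e8, 0, 1, 1e6, 0),
                            sched_37())
  expect_true(all(abs(iso2$heat_kcal_per_mol) < 1e-14))
})

test_that("cumulative heat conserves the total binding enthalpy", {
  # strong binding: total raw heat ~ n * M0 * V0 * dh (~ -166 ucal for
  # the 37 C conditions), brute-force summation over injections
  sch <- sched_37()
  iso <- simulate_isotherm(par_37(), sch)
  raw_kcal <- sum(iso$heat_kcal_per_mol) * sch$syringe_conc *
    sch$injection_volume
  expect_equal(raw_kcal, 1.8 * 8e-6 * 1.5e-3 * (-7.7), tolerance = 0.02)
  # the final injections approach the zero-heat asymptote
  expect_lt(abs(iso$heat_kcal_per_mol[35]),
            abs(iso$heat_kcal_per_mol[1]) / 50)
})

test_that("two-class forward model matches a bisection oracle", {
  h <- simulate_isotherm(
    two_site_params(0.2, 6e8, -10, 1.7, 1.7e7, -7.5),
    titration_schedule(1.5e-3, 10e-6, 0.23e-3, 35, 10e-6,
                       celsius_to_kelvin(27)))$heat_kcal_per_mol
  h_or <- oracle_itc_two_site(0.2, 6e8, -10, 1.7, 1.7e7, -7.5,
                              1.5e-3, 10e-6, 0.23e-3, 35, 10e-6)
  expect_equal(h, h_or, tolerance = 1e-10)
})

test_that("forward model is invariant to joint concentration rescaling", {
  # concentrations x s with ka / s leaves normalised heats unchanged
  s <- 1e3
  sch2 <- titration_schedule(1.5e-3, 8e-6 * s, 0.30e-3 * s, 35, 10e-6,
                             310.15)
  h1 <- simulate_isotherm(par_37(), sched_37())$heat_kcal_per_mol
  h2 <- simulate_isotherm(one_site_params(1.8, 1.4e7 / s, -7.7),
                          sch2)$heat_kcal_per_mol
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("first-injection deletion drops one point, keeps molar ratios", {
  iso <- simulate_isotherm(par_37(), sched_37(), noise_sd = 0.1,
                           seed = 4)
  expect_equal(nrow(iso), 35)
  d1 <- delete_first_injection(iso)
  expect_equal(nrow(d1), 34)
  expect_equal(d1$molar_ratio, iso$molar_ratio[-1])
  expect_equal(d1$heat_kcal_per_mol, iso$heat_kcal_per_mol[-1])
  d2 <- delete_first_injection(d1)
  expect_equal(nrow(d2), 33)
  tiny <- iso[1, , drop = FALSE]
  class(tiny) <- class(iso)
  expect_error(delete_first_injection(tiny), "single-point")
})

test_that("one-site fit recovers exact synthetic parameters", {
  iso <- delete_first_injection(simulate_isotherm(par_37(), sched_37()))
  fit <- fit_one_site(iso)
  expect_true(fit$converged)
  expect_equal(fit$params$n, 1.8, tolerance = 1e-6)
  expect_equal(fit$params$ka, 1.4e7, tolerance = 1e-6)
  expect_equal(fit$params$dh, -7.7, tolerance = 1e-6)
})

test_that("flat isotherms are flagged rather than fitted", {
  iso <- delete_first_injection(
    simulate_isotherm(one_site_params(1, 1e7, 0), sched_37(),
                      noise_sd = 0.05, seed = 11))
  fit <- fit_one_site(iso)
  # degenerate input: either flagged as non-converged, or the fitted
  # enthalpy is negligible with an unbounded association-constant error
  ka_rel_err <- fit$se[["ka"]] / fit$params$ka
  expect_true(!fit$converged ||
                (abs(fit$params$dh) < 0.2 &&
                   (is.na(ka_rel_err) || ka_rel_err > 1)))
})

test_that("two-site fit recovers exact parameters in canonical order", {
  truth <- two_site_params(0.2, 6e8, -10, 1.7, 1.7e7, -7.5)
  sch <- titration_schedule(1.5e-3, 10e-6, 0.23e-3, 35, 10e-6, 300.15)
  iso <- delete_first_injection(simulate_isotherm(truth, sch))
  # start away from the truth, with the class labels swapped
  init <- two_site_params(1.5, 1e7, -6, 0.3, 1e9, -12)
  fit <- fit_two_site(iso, init)
  expect_true(fit$converged)
  expect_gt(fit$params$ka1, fit$params$ka2) # descending-ka order
  expect_equal(fit$params$n1, 0.2, tolerance = 1e-4)
  expect_equal(fit$params$ka1, 6e8, tolerance = 1e-3)
  expect_equal(fit$params$n2, 1.7, tolerance = 1e-4)
  expect_equal(fit$params$ka2, 1.7e7, tolerance = 1e-4)
  expect_equal(fit$params$dh2, -7.5, tolerance = 1e-4)
})

test_that("overlapping site classes trigger an identifiability warning", {
  truth <- two_site_params(1, 2e7, -8, 1, 1.2e7, -6)
  sch <- titration_schedule(1.5e-3, 10e-6, 0.23e-3, 35, 10e-6, 300.15)
  iso <- delete_first_injection(simulate_isotherm(truth, sch))
  expect_warning(fit_two_site(iso, truth), "factor of 3")
})

test_that("apparent KD picks the stoichiometric class", {
  expect_equal(apparent_kd(one_site_params(1.8, 1.4e7, -7.7)) * 1e9,
               71.43, tolerance = 1e-3)
  expect_equal(apparent_kd(one_site_params(1, 1e9, -5)), 1e-9)
  # two classes: the class with n nearest 2 defines KDapp (~59 nM),
  # not the tighter nonstoichiometric class
  p2 <- two_site_params(0.2, 6e8, -10, 1.7, 1.7e7, -7.5)
  expect_equal(apparent_kd(p2) * 1e9, 1e9 / 1.7e7, tolerance = 1e-9)
})

test_that("one-site KD recovery is unbiased across seeds", {
  # 50 seeded replicates of the wild-type IQ titration (KD 16 nM)
  kd <- vapply(1:50, function(s) {
    iso <- delete_first_injection(
      simulate_isotherm(one_site_params(0.77, 1 / 16e-9, -10),
                        titration_schedule(1.5e-3, 10e-6, 0.1e-3, 35,
                                           10e-6, 300.15),
                        noise_sd = 0.1, seed = s))
    apparent_kd(fit_one_site(iso))
  }, 0)
  expect_lt(abs(stats::median(kd) - 16e-9) / 16e-9, 0.25)
})

test_that("isotherms survive a CSV round trip", {
  iso <- simulate_isotherm(par_37(), sched_37(), noise_sd = 0.1,
                           seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotherm(iso, path)
  back <- read_isotherm(path)
  expect_equal(back$heat_kcal_per_mol, iso$heat_kcal_per_mol,
               tolerance = 1e-10)
  expect_equal(attr(back, "schedule")$cell_conc, 8e-6)
})
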