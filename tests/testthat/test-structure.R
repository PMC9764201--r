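toy_model <- function(xyz, residue = seq_len(nrow(xyz))) {
  data.frame(residue = residue, atom = "CA",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

rotmat <- function(a, b, c) {
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  rz %*% ry %*% rx
}

test_that("superposition nulls rigid transforms and matches the grid oracle", {
  set.seed(41)
  ref <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_equal(superpose(toy_model(ref), toy_model(ref))$rmsd, 0,
               tolerance = 1e-12)
  # rigid-rotated + translated copy superposes exactly
  mob <- sweep(ref %*% rotmat(0.8, -0.4, 1.1), 2, c(5, -2, 7), `+`)
  expect_equal(superpose(toy_model(mob), toy_model(ref))$rmsd, 0,
               tolerance = 1e-9)
  # symmetric in (mobile, reference)
  mob2 <- mob + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(superpose(toy_model(mob2), toy_model(ref))$rmsd,
               superpose(toy_model(ref), toy_model(mob2))$rmsd,
               tolerance = 1e-9)
  # 4-atom toys against the brute-force rotation-grid oracle
  a4 <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0, 0.5, 0.5, 1.8), 4, 3,
               byrow = TRUE)
  b4 <- a4 %*% rotmat(0.5, 0.3, -0.7) +
    matrix(c(0.2, -0.1, 0.05, 0.15, -0.2, 0.1, 0, 0.1, -0.15, 0.05,
             0.2, -0.05), 4, 3, byrow = TRUE)
  expect_equal(superpose(toy_model(a4), toy_model(b4))$rmsd,
               oracle_superpose_rmsd(a4, b4), tolerance = 1e-3)
  # independent cross-check against bio3d's coordinate fitting
  mob3 <- ref + matrix(rnorm(30, sd = 0.4), 10, 3)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                           mobile = as.vector(t(mob3)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(superpose(toy_model(mob3), toy_model(ref))$rmsd,
               bio3d::rmsd(as.vector(t(ref)), fitted),
               tolerance = 1e-3)
  expect_error(superpose(toy_model(a4[1:2, ]), toy_model(b4[1:2, ])),
               "3 matched atoms")
  lin <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, 3,
                byrow = TRUE)
  expect_error(superpose(toy_model(lin), toy_model(lin)), "collinear")
})

test_that("ensemble RMSD matches the analytic one-atom displacement", {
  # 6 atoms on the coordinate axes; model 2 displaces atom 1 by delta
  # along its own (radial) axis, so the optimal rotation is the
  # identity by symmetry.  Centering spreads the displacement as
  # (1 - 1/N) on atom 1 and -1/N elsewhere, giving inter-model
  # RMSD = delta * sqrt(N - 1) / N and to-mean RMSD of half that.
  delta <- 1
  base <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                   0, 0, 1, 0, 0, -1), 6, 3, byrow = TRUE)
  shifted <- base
  shifted[1, 1] <- shifted[1, 1] + delta
  ens <- list(toy_model(base), toy_model(shifted))
  r <- ensemble_rmsd(ens)
  n <- 6
  expect_equal(r$mean_pairwise_rmsd, delta * sqrt(n - 1) / n,
               tolerance = 1e-9)
  expect_equal(r$rmsd_to_mean, delta * sqrt(n - 1) / n / 2,
               tolerance = 1e-9)
  # identical models: both conventions are zero
  r0 <- ensemble_rmsd(list(toy_model(base), toy_model(base)))
  expect_equal(r0$rmsd_to_mean, 0, tolerance = 1e-12)
  expect_equal(r0$mean_pairwise_rmsd, 0, tolerance = 1e-12)
})

test_that("to-mean RMSD never exceeds the mean pairwise RMSD", {
  for (seed in 1:3) {
    ens <- gen_ensemble(8, jitter_sd = 0.5, seed = seed)
    r <- ensemble_rmsd(ens, select_backbone(85:114))
    expect_lte(r$rmsd_to_mean, r$mean_pairwise_rmsd)
  }
})

test_that("alignment tensor fit recovers a known Saupe matrix", {
  set.seed(17)
  u <- matrix(rnorm(60), 20, 3)
  u <- u / sqrt(rowSums(u^2))
  saupe <- c(2, -5, 1, 0.5, -1)
  design <- cbind(u[, 2]^2 - u[, 1]^2, u[, 3]^2 - u[, 1]^2,
                  2 * u[, 1] * u[, 2], 2 * u[, 1] * u[, 3],
                  2 * u[, 2] * u[, 3])
  d <- drop(design %*% saupe)
  fit <- fit_alignment_tensor(rdc_set(1:20, d, u))
  expect_equal(fit$saupe, saupe, tolerance = 1e-10)
  expect_equal(fit$d_calc, d, tolerance = 1e-10)
  expect_equal(sum(diag(fit$tensor)), 0, tolerance = 1e-10) # traceless
  # matches the normal-equations oracle on noisy data
  d_noisy <- d + rnorm(20, sd = 0.5)
  fit_n <- fit_alignment_tensor(rdc_set(1:20, d_noisy, u))
  oracle <- drop(solve(crossprod(design), crossprod(design, d_noisy)))
  expect_equal(fit_n$saupe, oracle, tolerance = 1e-10)
  # isotropic data fit to the zero tensor
  fit0 <- fit_alignment_tensor(rdc_set(1:20, rep(0, 20), u))
  expect_equal(max(abs(fit0$d_calc)), 0, tolerance = 1e-12)
  # degenerate vector sets are refused
  expect_error(
    fit_alignment_tensor(rdc_set(1:6, rnorm(6),
                                 matrix(rep(c(1, 0, 0), 6), 6, 3,
                                        byrow = TRUE))),
    "rank-deficient")
  expect_error(fit_alignment_tensor(rdc_set(1:4, rnorm(4), u[1:4, ])),
               "at least 5")
})

test_that("Q-factor is the RMS misfit over the RMS coupling", {
  u <- diag(3)
  perfect <- rdc_set(1:3, c(3, -1, 2), u, d_calc = c(3, -1, 2))
  expect_equal(q_factor(perfect), 0)
  null_calc <- rdc_set(1:3, c(3, -1, 2), u, d_calc = c(0, 0, 0))
  expect_equal(q_factor(null_calc), 1)
  direct <- rdc_set(1:2, c(5, -5), u[1:2, ], d_calc = c(4, -4))
  expect_equal(q_factor(direct), 0.2)
  # invariant to joint rescaling of measured and calculated couplings
  scaled <- rdc_set(1:2, 7 * c(5, -5), u[1:2, ], d_calc = 7 * c(4, -4))
  expect_equal(q_factor(scaled), q_factor(direct), tolerance = 1e-12)
  zero <- rdc_set(1:2, c(0, 0), u[1:2, ], d_calc = c(1, 1))
  expect_error(q_factor(zero), "all-zero")
})

test_that("PDB ensembles round-trip through the fixed-column format", {
  ens <- gen_ensemble(5, jitter_sd = 0.3, seed = 9, n_residues = 12)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, path)
  back <- read_pdb_ensemble(path)
  expect_length(back, 5)
  expect_equal(back[[3]]$residue, ens[[3]]$residue)
  expect_equal(back[[3]]$atom, ens[[3]]$atom)
  # coordinates quantised to the 0.001 A PDB precision
  expect_equal(back[[3]]$x, ens[[3]]$x, tolerance = 1e-3)
  # precision metrics agree before and after the round trip
  r1 <- ensemble_rmsd(ens, select_backbone())
  r2 <- ensemble_rmsd(back, select_backbone())
  expect_equal(r2$rmsd_to_mean, r1$rmsd_to_mean, tolerance = 1e-2)
})
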