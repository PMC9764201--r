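## Coupled Ca2+ / CaM / IQ equilibria.
##
## The IQ-bound CaM is modelled as a two-step macroscopic Ca2+-binding
## ladder: the C-lobe loads first (association constant k1_app), then the
## N-lobe (k2_app).  Each macroscopic step binds `n_per_step` Ca2+ ions
## (default 2: the two EF-hands of a lobe act as one cooperative unit).
## Apparent affinities follow from thermodynamic linkage between Ca2+ and
## peptide binding.

#' Two-step Ca2+-binding scheme for IQ-bound calmodulin
#'
#' Constructs the macroscopic binding scheme used by
#' [species_fractions()]: apoCaM-IQ -> Ca2/CaM-IQ (C-lobe loading, `k1_app`)
#' -> Ca4/CaM-IQ (N-lobe loading, `k2_app`).
#'
#' @param k1_app apparent association constant of the first (C-lobe) step,
#'   in M^-n where n = `n_per_step`.
#' @param k2_app apparent association constant of the second (N-lobe) step,
#'   same units.
#' @param n_per_step integer number of Ca2+ ions bound per macroscopic step
#'   (default 2, i.e. both EF-hands of a lobe load together).
#' @return an object of class `"binding_scheme"`.
#' @examples
#' binding_scheme(k1_app = 1e14, k2_app = 1e12)
#' @export
binding_scheme <- function(k1_app, k2_app, n_per_step = 2L) {
  .check_positive(k1_app, "k1_app")
  .check_positive(k2_app, "k2_app")
  n_per_step <- as.integer(n_per_step)
  if (is.na(n_per_step) || n_per_step < 1L) {
    stop("'n_per_step' must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(k1_app = k1_app, k2_app = k2_app, n_per_step = n_per_step),
    class = "binding_scheme"
  )
}

#' @export
print.binding_scheme <- function(x, ...) {
  cat("Two-step Ca2+-binding scheme (", x$n_per_step, " Ca2+ per step)\n",
      sep = "")
  cat(sprintf("  step 1 (C-lobe): k1_app = %.4g M^-%d\n",
              x$k1_app, x$n_per_step))
  cat(sprintf("  step 2 (N-lobe): k2_app = %.4g M^-%d\n",
              x$k2_app, x$n_per_step))
  invisible(x)
}

#' Thermodynamic linkage cycle between Ca2+ and IQ binding
#'
#' Holds the three dissociation constants of the square linkage cycle:
#' Ca2+ binding to a lobe of free CaM, and IQ binding to the Ca2+-free and
#' Ca2+-loaded states of that lobe.
#'
#' @param kd_ca_free dissociation constant of Ca2+ for the lobe of free
#'   CaM, molar.
#' @param kd_iq_apo dissociation constant of the IQ peptide for the
#'   Ca2+-free lobe, molar.
#' @param kd_iq_loaded dissociation constant of the IQ peptide for the
#'   Ca2+-loaded lobe, molar.
#' @return an object of class `"linkage_cycle"`.
#' @seealso [apparent_kd_linkage()]
#' @export
linkage_cycle <- function(kd_ca_free, kd_iq_apo, kd_iq_loaded) {
  .check_positive(kd_ca_free, "kd_ca_free")
  .check_positive(kd_iq_apo, "kd_iq_apo")
  .check_positive(kd_iq_loaded, "kd_iq_loaded")
  structure(
    list(kd_ca_free = kd_ca_free, kd_iq_apo = kd_iq_apo,
         kd_iq_loaded = kd_iq_loaded),
    class = "linkage_cycle"
  )
}

#' Hyperbolic Ca2+ occupancy of a CaM lobe
#'
#' Fractional saturation `Y = ca_free / (ca_free + kd_app)` of one lobe at
#' a given free Ca2+ concentration.  With the apparent C-lobe affinity of
#' IQ-bound CaM (~72 nM at 37 C) and basal Ca2+ (~100 nM) this exceeds
#' one half, which is the quantitative basis for Ca2/CaM preassociation.
#'
#' @param ca_free free Ca2+ concentration, molar (vectorised, >= 0).
#' @param kd_app apparent dissociation constant, molar (> 0).
#' @return fractional occupancy in `[0, 1)`.
#' @examples
#' lobe_occupancy(100e-9, 72e-9) # > 0.5 at basal calcium
#' @export
lobe_occupancy <- function(ca_free, kd_app) {
  .check_nonnegative(ca_free, "ca_free")
  .check_positive(kd_app, "kd_app")
  ca_free / (ca_free + kd_app)
}

#' Species fractions of IQ-bound CaM along the Ca2+ ladder
#'
#' Fractions of apoCaM-IQ, Ca2/CaM-IQ and Ca4/CaM-IQ at a given free Ca2+
#' concentration, from the two-step partition function
#' `Z = 1 + k1 c^n + k1 k2 c^(2n)`.
#'
#' @param ca_free free Ca2+ concentration, molar (vectorised, >= 0).
#' @param scheme a [binding_scheme()].
#' @return a data frame with columns `ca_free`, `f_apo`, `f_ca2`, `f_ca4`;
#'   the three fractions sum to 1 row-wise.
#' @examples
#' sch <- binding_scheme(1e14, 1e12)
#' species_fractions(100e-9, sch)
#' @export
species_fractions <- function(ca_free, scheme) {
  stopifnot(inherits(scheme, "binding_scheme"))
  .check_nonnegative(ca_free, "ca_free")
  n <- scheme$n_per_step
  ## work in log space: k1 c^n can overflow/underflow across a wide grid
  lc <- ifelse(ca_free > 0, log(ca_free), -Inf)
  l1 <- log(scheme$k1_app) + n * lc
  l2 <- log(scheme$k1_app) + log(scheme$k2_app) + 2 * n * lc
  lmax <- pmax(0, l1, l2)
  w0 <- exp(0 - lmax)
  w1 <- exp(l1 - lmax)
  w2 <- exp(l2 - lmax)
  z <- w0 + w1 + w2
  data.frame(
    ca_free = ca_free,
    f_apo = w0 / z,
    f_ca2 = w1 / z,
    f_ca4 = w2 / z
  )
}

#' Apparent Ca2+ affinity from the thermodynamic linkage cycle
#'
#' Cycle identity: the apparent Ca2+ dissociation constant of a lobe in
#' the presence of saturating IQ peptide is
#' `kd_ca_free * kd_iq_loaded / kd_iq_apo`.  When peptide binding is
#' tighter to the Ca2+-loaded state (ratio < 1) the apparent Ca2+ affinity
#' increases by the same factor -- the >10-fold enhancement observed for
#' the C-lobe upon IQ binding.
#'
#' @param cycle a [linkage_cycle()].
#' @return apparent Ca2+ dissociation constant, molar.
#' @examples
#' # 10-fold coupling: 1 uM free-CaM affinity becomes 100 nM on the IQ
#' apparent_kd_linkage(linkage_cycle(1e-6, 10e-6, 1e-6))
#' @export
apparent_kd_linkage <- function(cycle) {
  stopifnot(inherits(cycle, "linkage_cycle"))
  cycle$kd_ca_free * cycle$kd_iq_loaded / cycle$kd_iq_apo
}

#' van't Hoff temperature scaling of a dissociation constant
#'
#' Ratio `KD(t2)/KD(t1) = exp[(dH/R) (1/t2 - 1/t1)]` under a
#' temperature-independent binding enthalpy.  For exothermic binding
#' (negative `delta_h`) and `t2 > t1` the ratio exceeds 1: affinity
#' weakens on warming.
#'
#' @param delta_h binding enthalpy, kcal/mol.
#' @param t1,t2 temperatures, kelvin.
#' @return dimensionless ratio `KD(t2)/KD(t1)`.
#' @examples
#' # -15 kcal/mol predicts a 2.3-fold weaker KD from 27 C to 37 C
#' vant_hoff_kd_ratio(-15, celsius_to_kelvin(27), celsius_to_kelvin(37))
#' @export
vant_hoff_kd_ratio <- function(delta_h, t1, t2) {
  .check_positive(t1, "t1")
  .check_positive(t2, "t2")
  exp((delta_h * 1000 / .R_CAL) * (1 / t2 - 1 / t1))
}

#' Binding heat-capacity change from enthalpies at two temperatures
#'
#' Finite-difference estimate `dCp = (dH(t2) - dH(t1)) / (t2 - t1)`.
#' A negative value is the signature of hydrophobic surface burial on
#' complex formation.
#'
#' @param delta_h_t1,delta_h_t2 binding enthalpies at `t1` and `t2`,
#'   kcal/mol.
#' @param t1,t2 temperatures, kelvin; must differ.
#' @return heat-capacity change, kcal mol^-1 K^-1.
#' @examples
#' delta_cp(-10, -15, celsius_to_kelvin(27), celsius_to_kelvin(37)) # -0.5
#' @export
delta_cp <- function(delta_h_t1, delta_h_t2, t1, t2) {
  .check_positive(t1, "t1")
  .check_positive(t2, "t2")
  if (isTRUE(all.equal(t1, t2))) {
    stop("'t1' and 't2' must differ", call. = FALSE)
  }
  (delta_h_t2 - delta_h_t1) / (t2 - t1)
}
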