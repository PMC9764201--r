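## Light structural metrics: rigid-body (Kabsch) superposition, NMR
## ensemble coordinate precision, and RDC alignment-tensor fitting with
## the Q-factor agreement measure.
##
## A structural model is a data frame with columns `residue` (integer),
## `atom` (character, e.g. "CA") and `x`, `y`, `z` (angstroms); an
## ensemble is an ordered list of such models sharing an atom set.

.model_coords <- function(model, selection = NULL) {
  stopifnot(all(c("residue", "atom", "x", "y", "z") %in% names(model)))
  if (!is.null(selection)) model <- selection(model)
  as.matrix(model[, c("x", "y", "z")])
}

#' Atom selection helpers
#'
#' `select_backbone()` builds a selection function for backbone atoms of
#' an inclusive residue range; `atoms` defaults to N, CA, C, O (set
#' `c("N", "CA", "C")` for the heavy-backbone convention).
#'
#' @param residues inclusive residue range, e.g. `85:149`; `NULL` keeps
#'   all residues.
#' @param atoms atom names to keep.
#' @return a function mapping a model data frame to its selected rows.
#' @export
select_backbone <- function(residues = NULL,
                            atoms = c("N", "CA", "C", "O")) {
  force(residues); force(atoms)
  function(model) {
    keep <- model$atom %in% atoms
    if (!is.null(residues)) keep <- keep & model$residue %in% residues
    model[keep, , drop = FALSE]
  }
}

## Kabsch: rotation R such that x %*% R best fits y (both centred),
## with the reflection guard on the SVD determinant
.kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` by the Kabsch algorithm on the
#' selected atoms and reports the post-fit RMSD over that selection.  The
#' returned model has the fitted transform applied to *all* its atoms.
#'
#' @param mobile,reference structural models (data frames with columns
#'   `residue`, `atom`, `x`, `y`, `z`).
#' @param selection optional selection function (see
#'   [select_backbone()]); `NULL` uses all atoms.  The two models must
#'   yield matched atom lists under the selection.
#' @return a list with `model` (transformed mobile) and `rmsd`
#'   (angstroms).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  xm <- .model_coords(mobile, selection)
  xr <- .model_coords(reference, selection)
  if (nrow(xm) != nrow(xr)) {
    stop("selections of mobile and reference differ in size",
         call. = FALSE)
  }
  if (nrow(xm) < 3L) {
    stop("need at least 3 matched atoms to superpose", call. = FALSE)
  }
  cm <- colMeans(xm); cr <- colMeans(xr)
  xm0 <- sweep(xm, 2, cm); xr0 <- sweep(xr, 2, cr)
  if (qr(xm0)$rank < 2L) {
    stop("selection is collinear; superposition is degenerate",
         call. = FALSE)
  }
  rot <- .kabsch_rotation(xm0, xr0)
  fitted_sel <- xm0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted_sel - xr0)^2)))
  all_xyz <- .model_coords(mobile)
  new_xyz <- sweep(sweep(all_xyz, 2, cm) %*% rot, 2, cr, `+`)
  out <- mobile
  out[, c("x", "y", "z")] <- new_xyz
  list(model = out, rmsd = rmsd)
}

#' Coordinate precision of a structural ensemble
#'
#' Each model is superposed on the iteratively refined mean structure
#' over the selection; reported are the mean (+- SD) RMSD of the models
#' to the mean structure (the common deposition convention) and the mean
#' pairwise inter-model RMSD.
#'
#' @param ensemble list of >= 2 structural models.
#' @param selection selection function, e.g.
#'   `select_backbone(85:149)` for the C-lobe backbone.
#' @param max_iter,tol iteration control for the mean-structure
#'   refinement.
#' @return a list with `rmsd_to_mean`, `rmsd_to_mean_sd`,
#'   `mean_pairwise_rmsd` and the per-model `per_model` RMSDs.
#' @export
ensemble_rmsd <- function(ensemble, selection = NULL, max_iter = 20,
                          tol = 1e-8) {
  stopifnot(is.list(ensemble), length(ensemble) >= 2L)
  sel_coords <- lapply(ensemble, .model_coords, selection = selection)
  n_atoms <- unique(vapply(sel_coords, nrow, 0L))
  if (length(n_atoms) != 1L || n_atoms == 0L) {
    stop("selection is empty or inconsistent across models",
         call. = FALSE)
  }
  centred <- lapply(sel_coords, function(x) sweep(x, 2, colMeans(x)))
  ref <- centred[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(centred, function(x) x %*% .kabsch_rotation(x, ref))
    new_ref <- Reduce(`+`, fitted) / length(fitted)
    if (sqrt(mean((new_ref - ref)^2)) < tol) { ref <- new_ref; break }
    ref <- new_ref
  }
  fitted <- lapply(centred, function(x) x %*% .kabsch_rotation(x, ref))
  per_model <- vapply(fitted, function(x) {
    sqrt(mean(rowSums((x - ref)^2)))
  }, 0)
  nm <- length(fitted)
  pw <- numeric(0)
  for (i in seq_len(nm - 1)) {
    for (j in seq(i + 1, nm)) {
      rot <- .kabsch_rotation(fitted[[i]], fitted[[j]])
      pw <- c(pw, sqrt(mean(rowSums((fitted[[i]] %*% rot -
                                       fitted[[j]])^2))))
    }
  }
  list(rmsd_to_mean = mean(per_model),
       rmsd_to_mean_sd = stats::sd(per_model),
       mean_pairwise_rmsd = mean(pw),
       per_model = per_model)
}

## ---- RDC -------------------------------------------------------------

#' RDC restraint set
#'
#' @param residue residue index per restraint.
#' @param d_meas measured residual dipolar coupling, Hz.
#' @param vectors n x 3 matrix of internuclear unit vectors (rows are
#'   normalised internally).
#' @param d_calc optional back-calculated couplings, Hz.
#' @return an object of class `"rdc_set"`.
#' @export
rdc_set <- function(residue, d_meas, vectors, d_calc = NULL) {
  vectors <- as.matrix(vectors)
  stopifnot(length(residue) == length(d_meas),
            nrow(vectors) == length(d_meas), ncol(vectors) == 3L)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length internuclear vector",
                          call. = FALSE)
  vectors <- vectors / nrm
  structure(list(residue = residue, d_meas = d_meas, vectors = vectors,
                 d_calc = d_calc),
            class = "rdc_set")
}

## design matrix for the 5 independent Saupe elements
## (Syy, Szz, Sxy, Sxz, Syz), traceless symmetric tensor absorbed scale
.rdc_design <- function(u) {
  cbind(u[, 2]^2 - u[, 1]^2,
        u[, 3]^2 - u[, 1]^2,
        2 * u[, 1] * u[, 2],
        2 * u[, 1] * u[, 3],
        2 * u[, 2] * u[, 3])
}

#' Fit the molecular alignment tensor to measured RDCs
#'
#' Linear least-squares (SVD) solution for the five independent elements
#' of the Saupe order matrix, in coupling units (the dipolar interaction
#' constant is absorbed into the tensor).  Requires >= 5 restraints with
#' a non-degenerate set of bond vectors.
#'
#' @param rdc an [rdc_set()].
#' @return the input `rdc_set` with `d_calc` filled in and the tensor
#'   attached: `saupe` (5-vector), `tensor` (3x3 traceless symmetric
#'   matrix, Hz).
#' @export
fit_alignment_tensor <- function(rdc) {
  stopifnot(inherits(rdc, "rdc_set"))
  if (length(rdc$d_meas) < 5L) {
    stop("need at least 5 RDC restraints", call. = FALSE)
  }
  a <- .rdc_design(rdc$vectors)
  s <- svd(a)
  if (min(s$d) < max(s$d) * 1e-10) {
    stop("rank-deficient RDC design matrix (degenerate vector set)",
         call. = FALSE)
  }
  coef <- s$v %*% ((t(s$u) %*% rdc$d_meas) / s$d)
  coef <- drop(coef)
  syy <- coef[1]; szz <- coef[2]
  sxx <- -(syy + szz)
  tensor <- matrix(c(sxx, coef[3], coef[4],
                     coef[3], syy, coef[5],
                     coef[4], coef[5], szz), 3, 3)
  rdc$d_calc <- drop(a %*% coef)
  rdc$saupe <- coef
  rdc$tensor <- tensor
  rdc
}

#' RDC Q-factor
#'
#' `Q = RMS(d_meas - d_calc) / RMS(d_meas)`: 0 for perfect agreement;
#' about 0.3 corresponds to ~2 angstrom structural resolution.
#'
#' @param rdc an [rdc_set()] with `d_calc` present (e.g. from
#'   [fit_alignment_tensor()]).
#' @return dimensionless Q-factor.
#' @export
q_factor <- function(rdc) {
  stopifnot(inherits(rdc, "rdc_set"))
  if (is.null(rdc$d_calc)) {
    stop("'d_calc' missing; run fit_alignment_tensor() first",
         call. = FALSE)
  }
  rms_meas <- sqrt(mean(rdc$d_meas^2))
  if (rms_meas == 0) stop("all-zero measured RDCs", call. = FALSE)
  sqrt(mean((rdc$d_meas - rdc$d_calc)^2)) / rms_meas
}

## ---- PDB i/o ---------------------------------------------------------

#' Read / write a multi-model PDB ensemble
#'
#' Minimal fixed-column ATOM/MODEL/ENDMDL handling, sufficient for NMR
#' ensembles: the first altloc of an atom is kept, HETATM records are
#' ignored and no chain remapping is performed.
#'
#' @param path PDB file path.
#' @param ensemble list of structural models (see [ensemble_rmsd()]).
#' @return `read_pdb_ensemble()` returns a list of model data frames;
#'   `write_pdb_ensemble()` returns `path` invisibly.
#' @export
read_pdb_ensemble <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      cur <- character(0)
    } else if (tag == "ENDMDL") {
      models[[length(models) + 1L]] <- cur
      cur <- NULL
    } else if (substr(ln, 1, 4) == "ATOM") {
      if (is.null(cur)) cur <- character(0) # single-model file
      cur <- c(cur, ln)
    }
  }
  if (!is.null(cur) && length(cur)) models[[length(models) + 1L]] <- cur
  parse_model <- function(lns) {
    altloc <- substr(lns, 17, 17)
    keep <- altloc %in% c(" ", "A")
    lns <- lns[keep]
    data.frame(
      residue = as.integer(substr(lns, 23, 26)),
      atom = trimws(substr(lns, 13, 16)),
      x = as.numeric(substr(lns, 31, 38)),
      y = as.numeric(substr(lns, 39, 46)),
      z = as.numeric(substr(lns, 47, 54))
    )
  }
  lapply(models, parse_model)
}

#' @rdname read_pdb_ensemble
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    mod <- ensemble[[m]]
    lines <- sprintf(
      "ATOM  %5d %-4s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(mod)),
      ifelse(nchar(mod$atom) < 4, paste0(" ", mod$atom), mod$atom),
      "ALA", "A", mod$residue, mod$x, mod$y, mod$z, 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
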