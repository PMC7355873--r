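#' Harmonic normal-mode analysis in dimensionless coordinates
#'
#' Diagonalizes the mass-weighted Cartesian Hessian after projecting out the
#' rigid-body subspace built from analytic translation/rotation generators
#' (not from an eigenvalue threshold alone, which is fragile for floppy
#' systems).  Vibrational displacement vectors are scaled to dimensionless
#' normal coordinates: the Cartesian displacement is `dx = sum_i l_i q_i` with
#' `l_i = m^(-1/2) e_i / sqrt(omega_i)` in atomic units (hbar = 1), so the
#' harmonic ground state has `<q_i^2> = 1/2`.  The three translational and
#' three (two, for collinear geometries) rotational modes along the principal
#' axes of inertia are appended; rotations are angle-parameterized
#' (displacement per radian about the principal axes, so the rigid
#' "dimensionless coordinate" is the rotation angle) and translations have
#' unit mass-weighted norm.  The rigid-mode scaling is arbitrary -- reported
#' results are invariant to it -- and can be changed through `rot_scale` /
#' `trans_scale`.
#'
#' @param system a [mol_system()].
#' @param iso an [isotopologue()].
#' @param hessian 3N x 3N Cartesian Hessian, hartree/bohr^2 (atom-major
#'   ordering).  Must be symmetric to 1e-8; small asymmetry is symmetrized.
#' @param zero_gap_cm1 warn if the smallest vibrational frequency is within
#'   this many cm^-1 of zero (near-degenerate zero/vibration separation).
#' @param basis_id identifier recorded on the mode set; derivative containers
#'   refuse to combine across different ids.
#' @param rot_scale,trans_scale multiplicative rescaling of the rigid modes
#'   (for invariance checks; defaults 1).
#' @return An object of class `normal_modes`: `omega` (vibrational
#'   frequencies, hartree), `freq_cm1`, `L` (3N x 3N matrix whose columns are
#'   the Cartesian mode vectors in bohr per unit dimensionless coordinate,
#'   vibrations first, then rotations, then translations), `kind` (per-column
#'   "v"/"r"/"t"), `n_vib`, `masses_au`, and the inputs.
#' @export
normal_modes <- function(system, iso, hessian,
                         zero_gap_cm1 = 1, basis_id = NULL,
                         rot_scale = 1, trans_scale = 1) {
  stopifnot(inherits(system, "mol_system"), inherits(iso, "isotopologue"))
  n <- system$n_atoms
  n3 <- 3L * n
  hessian <- as.matrix(hessian)
  stopifnot(nrow(hessian) == n3, ncol(hessian) == n3)
  asym <- max(abs(hessian - t(hessian)))
  if (asym > 1e-8) stop("Hessian asymmetry ", format(asym), " exceeds 1e-8")
  hessian <- (hessian + t(hessian)) / 2

  m_au <- amu_to_au(iso$masses)
  sqm <- rep(sqrt(m_au), each = 3L)
  Hmw <- hessian / outer(sqm, sqm)

  rig <- rigid_basis(system, iso, rot_scale, trans_scale)
  n_rig <- ncol(rig$mw)
  P <- diag(n3) - tcrossprod(rig$mw)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  eg <- eigen(Hp, symmetric = TRUE)

  # vibrational eigenpairs: those orthogonal to the rigid space
  rig_w <- colSums((crossprod(rig$mw, eg$vectors))^2)
  is_vib <- rig_w < 0.5
  n_vib <- n3 - n_rig
  if (sum(is_vib) != n_vib)
    stop("failed to separate ", n_vib, " vibrations from the rigid space")
  lam <- eg$values[is_vib]
  vec <- eg$vectors[, is_vib, drop = FALSE]
  if (any(lam < -1e-10))
    stop("negative vibrational eigenvalue: geometry is a saddle point, not a minimum")
  ord <- order(lam)                    # ascending omega, canonical order
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
  omega <- sqrt(pmax(lam, 0))
  if (au_to_cm1(omega[1]) < zero_gap_cm1)
    warning("smallest vibrational frequency within ", zero_gap_cm1,
            " cm^-1 of the rigid-mode space")

  vec <- fix_eigenvectors(vec, lam)

  Lv <- (vec / sqm) / rep(sqrt(omega), each = n3)
  L <- cbind(Lv, rig$cart_r, rig$cart_t)
  kind <- c(rep("v", n_vib), rep("r", ncol(rig$cart_r)), rep("t", 3L))
  structure(list(omega = omega, freq_cm1 = au_to_cm1(omega), L = L,
                 kind = kind, n_vib = n_vib, masses_au = m_au,
                 system = system, iso = iso,
                 basis_id = basis_id %||% paste0("nm:", iso$label)),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes> ", x$n_vib, " vibrations (",
      paste(sprintf("%.1f", x$freq_cm1), collapse = ", "), " cm^-1), ",
      sum(x$kind == "r"), " rotations, 3 translations\n", sep = "")
  invisible(x)
}

# deterministic phase/degeneracy fixing: within each (near-)degenerate block,
# rotate the eigenvector block onto the canonical Cartesian axes (LQ of the
# block's component matrix, with pivoting), then make the largest-magnitude
# component of every column positive.  Repeated runs and permuted inputs then
# give identical mode vectors.
fix_eigenvectors <- function(vec, lam) {
  if (!ncol(vec)) return(vec)
  grp <- cumsum(c(TRUE, abs(diff(lam)) > 1e-8 * (abs(lam[-1]) + 1)))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) > 1) {
      B <- vec[, cols, drop = FALSE]
      comp <- t(B)                              # k x 3N components on axes
      piv <- qr(comp, LAPACK = TRUE)$pivot[seq_along(cols)]
      Qrot <- qr.Q(qr(comp[, piv, drop = FALSE]))
      vec[, cols] <- B %*% Qrot
    }
  }
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  vec
}

#' Principal axes of inertia and rigid-body mode vectors
#'
#' @inheritParams normal_modes
#' @return List with `com` (center of mass, bohr), `axes` (columns are the
#'   principal axes), `moments` (principal moments, a.u.), `rotations` and
#'   `translations` (Cartesian mode vectors with unit mass-weighted norm; two
#'   rotations only for collinear geometries).
#' @export
principal_axes <- function(system, iso) {
  rig <- rigid_basis(system, iso)
  list(com = rig$com, axes = rig$axes, moments = rig$moments,
       rotations = rig$cart_r, translations = rig$cart_t)
}

rigid_basis <- function(system, iso, rot_scale = 1, trans_scale = 1) {
  x <- system$coords_e
  n <- nrow(x)
  m <- amu_to_au(iso$masses)
  com <- colSums(x * m) / sum(m)
  xc <- sweep(x, 2, com)
  I3 <- diag(c(sum(m * rowSums(xc^2))), 3) - crossprod(sqrt(m) * xc)
  # note: crossprod(sqrt(m)*xc) = sum_a m_a x_a x_a^T
  eI <- eigen((I3 + t(I3)) / 2, symmetric = TRUE)
  axes <- eI$vectors
  sqm <- rep(sqrt(m), each = 3L)

  trans <- sapply(1:3, function(a) rep(axes[, a], n))   # atom-major x1 y1 z1 ...
  rots <- lapply(1:3, function(a) {
    w <- t(apply(xc, 1, function(r) c(axes[2, a] * r[3] - axes[3, a] * r[2],
                                      axes[3, a] * r[1] - axes[1, a] * r[3],
                                      axes[1, a] * r[2] - axes[2, a] * r[1])))
    as.vector(t(w))
  })
  rot_norm <- vapply(rots, function(v) sqrt(sum((sqm * v)^2)), 0)
  scale_ref <- sqrt(sum(m)) * max(abs(xc))
  keep <- rot_norm > 1e-8 * max(scale_ref, 1)
  if (!any(keep)) stop("all atoms coincident: no rotational modes")
  cart_t <- trans / sqrt(sum(m)) * trans_scale
  # rotations are angle-parameterized: displacement per unit rotation angle
  # (radians), so the rigid "dimensionless coordinate" is the angle itself,
  # consistent with the dimensionless vibrational coordinates.  An overall
  # rescaling (rot_scale) leaves every reported result unchanged.
  cart_r <- sapply(which(keep), function(a) rots[[a]] * rot_scale)
  mw <- cbind(sqm * cart_r, sqm * cart_t)
  # orthonormal rigid-space basis for projections only (scaling-free)
  mw_on <- qr.Q(qr(mw))
  list(com = com, axes = axes, moments = eI$values,
       cart_t = cart_t, cart_r = cart_r, mw = mw_on)
}

# remove rigid-body (translation + infinitesimal rotation) components from a
# Cartesian displacement vector, in the mass metric of the given masses
eckart_project <- function(system, masses_au, vec) {
  iso_like <- list(masses = masses_au / vib_constants$amu_to_me)
  class(iso_like) <- "isotopologue"
  rig <- rigid_basis(system, iso_like)
  sqm <- rep(sqrt(masses_au), each = 3L)
  v_mw <- sqm * vec
  (v_mw - rig$mw %*% crossprod(rig$mw, v_mw))[, 1] / sqm
}

#' Eckart-condition residuals of vibrational modes
#'
#' Every vibrational mode must carry no net translation
#' (`sum_a m_a l_ia = 0`) and no net infinitesimal rotation
#' (`sum_a m_a R_ea x l_ia = 0`).
#'
#' @param modes a [normal_modes()] set.
#' @return List with `translation` and `rotation`: the largest absolute
#'   residual over all vibrational modes (mass-weighted units).
#' @export
check_eckart <- function(modes) {
  x <- modes$system$coords_e
  m <- modes$masses_au
  Lv <- modes$L[, modes$kind == "v", drop = FALSE]
  tr_res <- rot_res <- 0
  for (k in seq_len(ncol(Lv))) {
    d <- matrix(Lv[, k], ncol = 3, byrow = TRUE)
    tr <- colSums(m * d)
    rot <- colSums(m * cbind(x[, 2] * d[, 3] - x[, 3] * d[, 2],
                             x[, 3] * d[, 1] - x[, 1] * d[, 3],
                             x[, 1] * d[, 2] - x[, 2] * d[, 1]))
    # scale out the dimensionless-mode normalization so residuals are
    # comparable across modes
    nrm <- sqrt(sum(m * rowSums(d^2)))
    tr_res <- max(tr_res, max(abs(tr)) / nrm)
    rot_res <- max(rot_res, max(abs(rot)) / nrm / max(abs(x)))
  }
  list(translation = tr_res, rotation = rot_res)
}
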