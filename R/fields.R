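#' Semi-diagonal cubic force fields and shielding-surface derivatives
#'
#' Numerical differentiation along mode vectors produces the two derivative
#' containers every averaging formula consumes: the semi-diagonal cubic force
#' constants in dimensionless coordinates, and the per-nucleus first/second
#' directional derivatives of the shielding surface.  Displacements are applied
#' in dimensionless coordinates (geometry `R_e + h * l`), with central
#' two-point stencils; the default step widths are `h_ff = 0.005` for force
#' fields and `h_nmr = 0.05` for shieldings.
#'
#' @name cubic_field
NULL

# Accept a normal_modes object (vibrational columns), a dd_basis (retained
# difference-dedicated columns) or a bare list(x_e, B, omega?, basis_id).
extract_basis <- function(modes, vibrational_only = TRUE) {
  vib_norm <- function(L, kind) {
    nv <- sqrt(colSums(L[, kind == "v", drop = FALSE]^2))
    if (length(nv)) max(nv) else Inf
  }
  if (inherits(modes, "normal_modes")) {
    cols <- if (vibrational_only) which(modes$kind == "v") else seq_len(ncol(modes$L))
    list(x_e = modes$system$coords_e, B = modes$L[, cols, drop = FALSE],
         basis_id = modes$basis_id, step_ref = vib_norm(modes$L, modes$kind))
  } else if (inherits(modes, "dd_basis")) {
    mA <- modes$modesA
    list(x_e = modes$system$coords_e,
         B = modes$dd_L[, modes$retained, drop = FALSE],
         basis_id = modes$basis_id, step_ref = vib_norm(mA$L, mA$kind))
  } else if (is.list(modes) && !is.null(modes$B)) {
    list(x_e = modes$x_e, B = as.matrix(modes$B),
         basis_id = modes$basis_id %||% "custom",
         step_ref = modes$step_ref %||% Inf)
  } else stop("unsupported mode-basis object")
}

displace <- function(x_e, lvec, h) x_e + h * matrix(lvec, ncol = 3, byrow = TRUE)

# Per-direction step: the dimensionless step h as prescribed, capped so the
# Cartesian displacement norm never exceeds what the largest vibrational mode
# vector of the generating basis would produce.  Vibrational modes are
# unaffected by construction; the cap only engages for rigid-dominated
# difference-dedicated directions (Cartesian norms of several bohr, arising
# at cutoff 0), where a raw dimensionless step would inflate the central-
# stencil error by the cube of the direction norm.
dir_step <- function(h, lvec, step_ref = Inf) {
  h * min(1, step_ref / sqrt(sum(lvec^2)))
}

check_step <- function(h) if (!is.numeric(h) || length(h) != 1 || h <= 0)
  stop("step width must be a positive scalar")

#' Semi-diagonal cubic force constants (Hessian-difference scheme)
#'
#' Central differences of the mode-projected Hessian along each mode
#' direction: `S[i, k] = d/dq_k (l_i^T H l_i)` is the semi-diagonal constant
#' with two derivatives along mode `i` and one along mode `k` (hartree, all
#' coordinates dimensionless).  Costs `2 * n_modes` Hessian evaluations.
#'
#' @param hessian_fun evaluator mapping an N x 3 geometry (bohr) to the
#'   3N x 3N Cartesian Hessian (hartree/bohr^2).
#' @param modes a [normal_modes()] (vibrational block), a [dd_modes()] basis
#'   (retained modes), or `list(x_e=, B=)` with explicit direction vectors.
#' @param h_ff dimensionless step width.
#' @return A `cubic_field` object: `S` (n x n matrix, `S[i,k]` = third
#'   derivative twice along mode i and once along mode k) and `basis_id`.
#' @export
cubic_semidiagonal <- function(hessian_fun, modes, h_ff = 0.005) {
  check_step(h_ff)
  bb <- extract_basis(modes)
  nb <- ncol(bb$B)
  S <- matrix(0, nb, nb)
  for (k in seq_len(nb)) {
    hk <- dir_step(h_ff, bb$B[, k], bb$step_ref)
    Hp <- hessian_fun(displace(bb$x_e, bb$B[, k], +hk))
    Hm <- hessian_fun(displace(bb$x_e, bb$B[, k], -hk))
    Tk <- crossprod(bb$B, (Hp - Hm) %*% bb$B) / (2 * hk)
    S[, k] <- diag(Tk)
  }
  structure(list(S = S, basis_id = bb$basis_id, scheme = "delta_k", h = h_ff),
            class = "cubic_field")
}

#' Semi-diagonal cubic force constants (force-difference scheme)
#'
#' Second differences of the mode-projected gradient: displacing along mode
#' `i` gives `S[i, k] = d^2/dq_i^2 (dV/dq_k)` for all `k`, which by symmetry
#' of the third-derivative tensor is the same semi-diagonal slice as
#' [cubic_semidiagonal()].  Costs `2 * n_modes + 1` gradient evaluations.
#'
#' @param gradient_fun evaluator mapping a geometry to the 3N Cartesian
#'   gradient (hartree/bohr).
#' @inheritParams cubic_semidiagonal
#' @return A `cubic_field` object as for [cubic_semidiagonal()].
#' @export
cubic_semidiagonal_forces <- function(gradient_fun, modes, h_ff = 0.005) {
  check_step(h_ff)
  bb <- extract_basis(modes)
  nb <- ncol(bb$B)
  g0 <- crossprod(bb$B, gradient_fun(bb$x_e))
  S <- matrix(0, nb, nb)
  for (i in seq_len(nb)) {
    hi <- dir_step(h_ff, bb$B[, i], bb$step_ref)
    gp <- crossprod(bb$B, gradient_fun(displace(bb$x_e, bb$B[, i], +hi)))
    gm <- crossprod(bb$B, gradient_fun(displace(bb$x_e, bb$B[, i], -hi)))
    S[i, ] <- drop(gp - 2 * g0 + gm) / hi^2
  }
  structure(list(S = S, basis_id = bb$basis_id, scheme = "delta2_F", h = h_ff),
            class = "cubic_field")
}

#' Directional shielding derivatives along mode vectors
#'
#' Central first and second differences of the per-nucleus shielding surface
#' along each mode: `Dsigma[l] = (s(+h l) - s(-h l)) / 2h` and
#' `D2sigma[l] = (s(+h l) - 2 s(0) + s(-h l)) / h^2`.  Costs
#' `2 * n_modes + 1` shielding evaluations.
#'
#' @param sigma_fun evaluator mapping a geometry to a named numeric vector of
#'   per-nucleus shieldings (ppm).
#' @inheritParams cubic_semidiagonal
#' @param h_nmr dimensionless step width.
#' @return A `property_surface` object: `sigma_e` (ppm), `grad` and `curv`
#'   (nucleus x mode matrices, ppm per unit dimensionless coordinate), and
#'   `basis_id`.
#' @export
property_derivatives <- function(sigma_fun, modes, h_nmr = 0.05) {
  check_step(h_nmr)
  bb <- extract_basis(modes)
  nb <- ncol(bb$B)
  s0 <- sigma_fun(bb$x_e)
  grad <- curv <- matrix(0, length(s0), nb,
                         dimnames = list(names(s0), NULL))
  for (k in seq_len(nb)) {
    hk <- dir_step(h_nmr, bb$B[, k], bb$step_ref)
    sp <- sigma_fun(displace(bb$x_e, bb$B[, k], +hk))
    sm <- sigma_fun(displace(bb$x_e, bb$B[, k], -hk))
    grad[, k] <- (sp - sm) / (2 * hk)
    curv[, k] <- (sp - 2 * s0 + sm) / hk^2
  }
  structure(list(sigma_e = s0, grad = grad, curv = curv,
                 basis_id = bb$basis_id, h = h_nmr),
            class = "property_surface")
}

check_same_basis <- function(...) {
  ids <- vapply(list(...), function(o) o$basis_id %||% "", "")
  if (length(unique(ids)) != 1L)
    stop("basis mismatch: objects built on different mode sets (",
         paste(ids, collapse = " vs "), ")")
  invisible(ids[1])
}

#' Cubic slice for the difference-dedicated geometry formula
#'
#' Central differences of the Hessian along the *retained*
#' difference-dedicated directions, projected onto the full v+r dd basis:
#' `S[k, i] = phi(l_i; l_k, l_k)` (one derivative along dd mode i, two along
#' retained mode k).  Only the retained directions are displaced -- the
#' projections onto the remaining modes come from the same evaluations -- so
#' the cost stays `2 * n_retained` Hessian calls while the inner sums of the
#' geometry-relaxation formula run over the complete basis.
#'
#' @param hessian_fun evaluator mapping a geometry to the Cartesian Hessian.
#' @param dd a [dd_modes()] basis.
#' @param h_ff dimensionless step width.
#' @return A `cubic_field` with `S` of dimension `n_retained x n_modes` and
#'   `slice = "dd"`.
#' @export
cubic_dd_slice <- function(hessian_fun, dd, h_ff = 0.005) {
  check_step(h_ff)
  stopifnot(inherits(dd, "dd_basis"))
  x_e <- dd$system$coords_e
  mA <- dd$modesA
  step_ref <- max(sqrt(colSums(mA$L[, mA$kind == "v", drop = FALSE]^2)))
  r <- dd$retained
  S <- matrix(0, length(r), ncol(dd$dd_L))
  for (j in seq_along(r)) {
    lk <- dd$dd_L[, r[j]]
    hk <- dir_step(h_ff, lk, step_ref)
    Hp <- hessian_fun(displace(x_e, lk, +hk))
    Hm <- hessian_fun(displace(x_e, lk, -hk))
    S[j, ] <- drop(crossprod(dd$dd_L, (Hp - Hm) %*% lk)) / (2 * hk)
  }
  structure(list(S = S, basis_id = dd$basis_id, scheme = "delta_k",
                 slice = "dd", h = h_ff),
            class = "cubic_field")
}
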