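#' Difference-dedicated vibration modes (DD-VPT2)
#'
#' The isotopologue difference of the vibrational averaging is re-expressed in
#' a small set of non-canonic "difference-dedicated" modes.  The expansion
#' coefficients of B's modes in A's complete mode basis give a weight matrix
#' whose eigenvalues kappa measure how much each direction contributes to the
#' vibration hole; for a single substitution only a handful of |kappa| are
#' non-negligible, so cubic and shielding derivatives are needed along a few
#' directions only, instead of along every normal mode of both isotopologues.
#'
#' @name ddvpt2
NULL

#' Expansion of one isotopologue's modes in the other's full mode basis
#'
#' Solves `l_i(B) = sum_i' J[i, i'] l_i'(A)` exactly in the full
#' 3N-dimensional space (vibrations + rotations + translations of A).
#'
#' @param modesA,modesB [normal_modes()] of the two isotopologues; they must
#'   share the equilibrium geometry.
#' @return A `mode_jacobian` object: `J` (rows index B's modes, columns A's
#'   modes, both in v/r/t column order), `kindA`, `kindB`.
#' @export
mode_jacobian <- function(modesA, modesB) {
  stopifnot(inherits(modesA, "normal_modes"), inherits(modesB, "normal_modes"))
  if (!isTRUE(all.equal(modesA$system$coords_e, modesB$system$coords_e)))
    stop("isotopologues do not share an equilibrium geometry")
  LA <- modesA$L; LB <- modesB$L
  kap <- kappa(LA)
  if (!is.finite(kap) || kap > 1e10)
    stop("singular mode basis (condition number ", format(kap), ")")
  Jt <- solve(LA, LB)
  res <- max(abs(LA %*% Jt - LB))
  if (res > 1e-10 * max(abs(LB)))
    stop("mode expansion residual ", format(res), " too large")
  structure(list(J = t(Jt), kindA = modesA$kind, kindB = modesB$kind,
                 modesA = modesA, modesB = modesB),
            class = "mode_jacobian")
}

#' Difference-dedicated weight matrix M
#'
#' `M[k, k'] = sum_i J[i, k] J[i, k'] - theta_v(k) delta_kk'`, with the
#' outer sum over B's vibrational modes and k, k' running over A's
#' vibrational and rotational modes.  For identical isotopologues M vanishes
#' identically; its trace equals the sum of the kappa eigenvalues.
#'
#' @param jac a [mode_jacobian()].
#' @return Symmetric matrix M over A's v+r index range.
#' @export
dd_weight_matrix <- function(jac) {
  stopifnot(inherits(jac, "mode_jacobian"))
  rows <- jac$kindB == "v"
  cols <- jac$kindA %in% c("v", "r")
  Jvr <- jac$J[rows, cols, drop = FALSE]
  M <- crossprod(Jvr) - diag(as.numeric(jac$kindA[cols] == "v"))
  (M + t(M)) / 2
}

#' Difference-dedicated modes, weights and curvature matrix
#'
#' Diagonalizes M; eigenvalues kappa are ordered by decreasing magnitude
#' (they are negative for substitution with a heavier isotope, so monotone
#' decay is in |kappa|).  The difference-dedicated Cartesian mode vectors are
#' `l_i^(D) = sum_k K[k, i] l_k(A)` over A's v+r modes, and the
#' curvature-weight matrix is `G[i, i'] = sum_j^v K[j, i] K[j, i'] / omega_j`.
#' Modes with `|kappa| < cutoff` are dropped from the retained set.
#'
#' @param M weight matrix from [dd_weight_matrix()].
#' @param modesA the unsubstituted isotopologue's [normal_modes()].
#' @param cutoff retained-|kappa| threshold (contextual values in use are
#'   1e-2, 1e-3 and 1e-4; default 1e-3).  `cutoff = 0` retains every mode.
#' @param substituted set `TRUE` (default) to warn when the cutoff retains no
#'   modes although a substitution exists.
#' @return A `dd_basis` object: `kappa`, `K`, `dd_L` (3N x (v+r) Cartesian
#'   difference-dedicated mode vectors), `G`, `retained` (indices kept),
#'   `cutoff`, `basis_id`.
#' @export
dd_modes <- function(M, modesA, cutoff = 1e-3, substituted = TRUE) {
  stopifnot(inherits(modesA, "normal_modes"))
  if (max(abs(M - t(M))) > 1e-10) stop("M must be symmetric")
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  kappa_v <- eg$values[ord]
  K <- fix_eigenvectors(eg$vectors[, ord, drop = FALSE], seq_along(ord))
  vr <- modesA$kind %in% c("v", "r")
  dd_L <- modesA$L[, vr, drop = FALSE] %*% K
  Kv <- K[seq_len(modesA$n_vib), , drop = FALSE]
  G <- crossprod(Kv, Kv / modesA$omega)
  retained <- which(abs(kappa_v) >= cutoff)
  if (cutoff > 0 && !length(retained) && substituted)
    warning("cutoff ", cutoff, " retains no difference-dedicated modes")
  if (cutoff == 0) retained <- seq_along(kappa_v)
  structure(list(kappa = kappa_v, K = K, dd_L = dd_L, G = G,
                 retained = retained, cutoff = cutoff,
                 omegaA = modesA$omega, system = modesA$system,
                 modesA = modesA,
                 basis_id = paste0("dd:", modesA$basis_id, ":c", cutoff)),
            class = "dd_basis")
}

#' @export
print.dd_basis <- function(x, ...) {
  cat("<dd_basis> ", length(x$kappa), " modes, ", length(x$retained),
      " retained (|kappa| >= ", format(x$cutoff), ")\n", sep = "")
  cat("leading kappa:",
      paste(sprintf("%.5f", utils::head(x$kappa, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' DD-VPT2 isotope shifts from derivatives along retained modes
#'
#' \deqn{{}^n\Delta\delta_{harm} = -\tfrac14 \sum_k \kappa_k D^2\sigma[l_k^{(\Delta)}],}
#' \deqn{{}^n\Delta R = -\tfrac14 \sum_k \kappa_k \sum_{ii'} G_{ii'}
#'        \phi(l_i^{(\Delta)}; l_k^{(\Delta)}, l_k^{(\Delta)})\, l_{i'}^{(\Delta)},}
#' \deqn{{}^n\Delta\delta_{anh} = -D\sigma[{}^n\Delta R],}
#' with cubic and shielding derivatives evaluated along the retained
#' difference-dedicated directions only.  With `cutoff = 0` this reproduces
#' the explicit-difference VPT2 result exactly.
#'
#' @param dd a [dd_modes()] basis.
#' @param cubic a [cubic_dd_slice()] (displacements along retained modes,
#'   projections on the full v+r dd basis) or, for backward compatibility,
#'   a [cubic_semidiagonal()] along the retained modes only.
#' @param prop [property_derivatives()] along the retained dd modes.
#' @param sigma_fun the shielding evaluator; when given, the anharmonic part
#'   is computed as a central difference along the assembled `nDR` direction
#'   (two extra evaluations), which stays exact when the inner sums extend
#'   beyond the retained set.  Without it the gradient table restricted to
#'   retained modes is used.
#' @param report_nuclei optional data frame (`label`, `atom`).
#' @param sub_atoms substitution-site atom indices (for the bond count n).
#' @param h_nmr step width for the `nDR` directional derivative.
#' @param labels isotopologue labels recorded on the report.
#' @return An `iso_shift_report` (see [standard_isotope_shift()]).
#' @export
dd_isotope_shift <- function(dd, cubic, prop, sigma_fun = NULL,
                             report_nuclei = NULL, sub_atoms = integer(),
                             h_nmr = 0.05, labels = NULL) {
  stopifnot(inherits(dd, "dd_basis"), inherits(cubic, "cubic_field"),
            inherits(prop, "property_surface"))
  check_same_basis(dd, cubic, prop)
  r <- dd$retained
  if (!length(r)) stop("retained difference-dedicated mode set is empty")
  kap <- dd$kappa[r]
  harm <- -0.25 * drop(prop$curv %*% kap) * 1000
  # w[i] = sum_k kappa_k phi(l_i; l_k, l_k), i over the cubic field's basis
  w <- drop(kap %*% cubic$S)
  if (identical(cubic$slice, "dd")) {
    # inner sums over the complete v+r basis (free projections)
    coef <- -0.25 * drop(dd$G %*% w)
    dR <- drop(dd$dd_L %*% coef)
  } else {
    Gr <- dd$G[r, r, drop = FALSE]
    coef <- -0.25 * drop(Gr %*% w)
    dR <- drop(dd$dd_L[, r, drop = FALSE] %*% coef)
  }
  if (!is.null(sigma_fun)) {
    mA <- dd$modesA
    step_ref <- max(sqrt(colSums(mA$L[, mA$kind == "v", drop = FALSE]^2)))
    hh <- dir_step(h_nmr, dR, step_ref)
    x_e <- dd$system$coords_e
    anh <- -(sigma_fun(displace(x_e, dR, +hh)) -
               sigma_fun(displace(x_e, dR, -hh))) / (2 * hh) * 1000
  } else if (identical(cubic$slice, "dd")) {
    anh <- -drop(prop$grad %*% coef[r]) * 1000
  } else {
    anh <- -drop(prop$grad %*% coef) * 1000
  }
  dR <- eckart_project(dd$system, dd$modesA$masses_au, dR)
  new_shift_report(dd$system, names(harm), harm, anh, dR, sub_atoms,
                   report_nuclei, method = "DD-VPT2",
                   labels = labels %||% c(dd$modesA$iso$label, "substituted"))
}

#' Isotope effects on geometry parameters and visualization structures
#'
#' Evaluates the isotope effect on r_z geometry parameters as
#' `f(R_e + dR) - f(R_e)` and emits the exaggerated structure
#' `R_e + lambda * dR` used to visualize the vibration hole (`lambda` about
#' 400 for localized holes, about 80 for strongly delocalized ones).
#'
#' @param system a [mol_system()].
#' @param dR Cartesian isotope-effect vector on the r_z geometry (bohr),
#'   e.g. `attr(report, "dR")`.
#' @param coords list of internal coordinates.
#' @param lambda_viz dimensionless exaggeration factor.
#' @return List with `table` (tibble: coordinate, f_e, delta_f_z in bohr/rad)
#'   and `viz_geometry` (N x 3, bohr).
#' @export
dd_geometry_report <- function(system, dR, coords, lambda_viz = 400) {
  x_e <- system$coords_e
  x_z <- x_e + matrix(dR, ncol = 3, byrow = TRUE)
  tab <- tibble::tibble(
    coordinate = unname(vapply(coords, function(cc) cc$label, "")),
    kind = unname(vapply(coords, function(cc) cc$kind, "")),
    f_e = unname(vapply(coords, evaluate_coordinate, 0, x = x_e)),
    delta_f_z = unname(vapply(coords, evaluate_coordinate, 0, x = x_z) -
      vapply(coords, evaluate_coordinate, 0, x = x_e)))
  list(table = tab,
       viz_geometry = x_e + lambda_viz * matrix(dR, ncol = 3, byrow = TRUE))
}
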