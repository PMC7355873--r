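#' Vibration-hole descriptors: r_z / r_g parameters, amplitudes, covariances
#'
#' The effective geometry of a vibrating molecule is described in two ways:
#' the r_z geometry (the geometry of the vibrationally averaged Cartesian
#' coordinates, `R_z = R_e + dR`) and the r_g parameters (each geometry
#' parameter averaged individually, `f_g = <f(R)>`).  To second order in the
#' displacements,
#' \deqn{f_z = f(R_e + \Delta R),\qquad
#'       f_g = f_z + \tfrac14 \sum_i^{v} l_i^T (\nabla^2 f)\, l_i,}
#' using `<q_i^2> = 1/2` for the zero-point amplitude of every vibrational
#' mode.  Harmonic mean-square amplitudes and amplitude covariances relative
#' to the r_e geometry are
#' \deqn{\langle\Delta f^2\rangle = \tfrac12 \sum_i^{v} (Df[l_i])^2,\qquad
#'       \langle\Delta f \Delta g\rangle = \tfrac12 \sum_i^{v} Df[l_i]\, Dg[l_i].}
#' Isotope effects come either from the explicit difference of two
#' isotopologue tables (full channel) or from kappa-weighted sums over the
#' difference-dedicated modes (DD channel); the two channels agree at
#' cutoff 0.
#'
#' @name geometry_stats
NULL

coord_tables <- function(coords, x_e) {
  ders <- lapply(coords, coordinate_derivatives, x = x_e)
  list(label = unname(vapply(coords, function(cc) cc$label, "")),
       kind = unname(vapply(coords, function(cc) cc$kind, "")),
       f_e = unname(vapply(ders, `[[`, 0, "value")),
       grads = lapply(ders, `[[`, "grad"),
       hesses = lapply(ders, `[[`, "hess"))
}

#' r_z geometry parameters
#'
#' @param coords list of internal coordinates.
#' @param x_e equilibrium geometry (N x 3, bohr).
#' @param dR Cartesian r_z shift vector (length 3N, bohr), e.g. `$dR` of a
#'   [vib_correction()] or `attr(report, "dR")`.
#' @return Tibble with `coordinate`, `kind`, `f_e`, `f_z` (bohr / rad).
#' @export
rz_parameters <- function(coords, x_e, dR) {
  x_z <- x_e + matrix(dR, ncol = 3, byrow = TRUE)
  tibble::tibble(
    coordinate = unname(vapply(coords, function(cc) cc$label, "")),
    kind = unname(vapply(coords, function(cc) cc$kind, "")),
    f_e = unname(vapply(coords, evaluate_coordinate, 0, x = x_e)),
    f_z = unname(vapply(coords, evaluate_coordinate, 0, x = x_z)))
}

#' Per-isotopologue geometry statistics
#'
#' @inheritParams rz_parameters
#' @param modes a [normal_modes()] set (vibrational block used).
#' @param reference internal coordinate against which amplitude covariances
#'   are taken (conventionally the substituted bond); `NULL` for none.
#' @return A tibble: `coordinate`, `kind`, `f_e`, `f_z`, `f_g`, `msa`
#'   (mean-square amplitude), `cov` (amplitude covariance with `reference`),
#'   in bohr/rad units.
#' @export
geometry_statistics <- function(coords, modes, dR = NULL, reference = NULL) {
  stopifnot(inherits(modes, "normal_modes"))
  x_e <- modes$system$coords_e
  if (is.null(dR)) dR <- numeric(3 * nrow(x_e))
  Lv <- modes$L[, modes$kind == "v", drop = FALSE]
  ct <- coord_tables(coords, x_e)
  x_z <- x_e + matrix(dR, ncol = 3, byrow = TRUE)
  f_z <- unname(vapply(coords, evaluate_coordinate, 0, x = x_z))
  curv <- vapply(seq_along(coords), function(j)
    0.25 * sum(colSums(Lv * (ct$hesses[[j]] %*% Lv))), 0)
  D <- do.call(rbind, unname(lapply(ct$grads, function(g) drop(crossprod(Lv, g)))))
  msa <- 0.5 * rowSums(D^2)
  cov <- rep(NA_real_, length(coords))
  if (!is.null(reference)) {
    gr <- coordinate_derivatives(reference, x_e)$grad
    Dref <- drop(crossprod(Lv, gr))
    cov <- 0.5 * drop(D %*% Dref)
  }
  out <- tibble::tibble(coordinate = ct$label, kind = ct$kind,
                        f_e = ct$f_e, f_z = f_z, f_g = f_z + curv,
                        msa = msa, cov = cov)
  class(out) <- c("geometry_stats", class(out))
  out
}

#' Isotope effects on geometry statistics (explicit-difference channel)
#'
#' @param statsA,statsB [geometry_statistics()] tables of the two
#'   isotopologues (same coordinates).
#' @return Tibble of per-coordinate differences B - A (`delta_f_z`,
#'   `delta_f_g`, `delta_msa`, `delta_cov`).
#' @export
geometry_isotope_effect <- function(statsA, statsB) {
  stopifnot(identical(statsA$coordinate, statsB$coordinate))
  tibble::tibble(coordinate = statsA$coordinate, kind = statsA$kind,
                 f_e = statsA$f_e,
                 delta_f_z = statsB$f_z - statsA$f_z,
                 delta_f_g = statsB$f_g - statsA$f_g,
                 delta_msa = statsB$msa - statsA$msa,
                 delta_cov = statsB$cov - statsA$cov)
}

#' Isotope effects on geometry statistics (difference-dedicated channel)
#'
#' Kappa-weighted sums over the retained difference-dedicated modes replace
#' the explicit isotopologue difference:
#' `delta_msa = 1/2 sum_k kappa_k (Df[l_k^D])^2` and analogously for the
#' covariance and the `f_g` curvature term, while `delta_f_z` follows the
#' DD r_z isotope-effect vector.
#'
#' @param coords list of internal coordinates.
#' @param dd a [dd_modes()] basis.
#' @param dR the DD r_z isotope-effect vector (`attr(report, "dR")`).
#' @param reference covariance reference coordinate (conventionally the
#'   substituted bond).
#' @return Tibble as in [geometry_isotope_effect()].
#' @export
dd_geometry_isotope_effect <- function(coords, dd, dR, reference = NULL) {
  stopifnot(inherits(dd, "dd_basis"))
  x_e <- dd$system$coords_e
  r <- dd$retained
  Ld <- dd$dd_L[, r, drop = FALSE]
  kap <- dd$kappa[r]
  ct <- coord_tables(coords, x_e)
  x_z <- x_e + matrix(dR, ncol = 3, byrow = TRUE)
  delta_f_z <- unname(vapply(coords, evaluate_coordinate, 0, x = x_z)) - ct$f_e
  dcurv <- vapply(seq_along(coords), function(j)
    0.25 * sum(kap * colSums(Ld * (ct$hesses[[j]] %*% Ld))), 0)
  D <- do.call(rbind, unname(lapply(ct$grads, function(g) drop(crossprod(Ld, g)))))
  delta_msa <- 0.5 * drop(D^2 %*% kap)
  delta_cov <- rep(NA_real_, length(coords))
  if (!is.null(reference)) {
    gr <- coordinate_derivatives(reference, x_e)$grad
    Dref <- drop(crossprod(Ld, gr))
    delta_cov <- 0.5 * drop((D * rep(Dref, each = nrow(D))) %*% kap)
  }
  tibble::tibble(coordinate = ct$label, kind = ct$kind, f_e = ct$f_e,
                 delta_f_z = delta_f_z, delta_f_g = delta_f_z + dcurv,
                 delta_msa = delta_msa, delta_cov = delta_cov)
}

#' Vibration-hole decay profile by topological distance
#'
#' Groups per-bond isotope effects by the number of bonds between each bond
#' and the substitution site (0 for the substituted bond itself, 1 for
#' geminal bonds, 2 for vicinal bonds, ...).  Magnitudes are reported with
#' the sign kept as a separate flag, matching the usual presentation of
#' hole-decay plots.
#'
#' @param effects tibble from [geometry_isotope_effect()] or
#'   [dd_geometry_isotope_effect()], restricted to its bond rows.
#' @param coords the internal coordinates the rows refer to (bond kind).
#' @param system the [mol_system()] (bond topology required).
#' @param sub_atoms substitution-site atom index (or indices).
#' @return A `hole_profile` tibble: `coordinate`, `distance`, one
#'   `abs_*`/`sign_*` column pair per effect column.
#' @export
hole_profile <- function(effects, coords, system, sub_atoms) {
  if (is.null(system$bonds)) stop("hole_profile needs a bond topology")
  d_atom <- topo_atom_distances(system$bonds, system$n_atoms, sub_atoms)
  if (any(!is.finite(d_atom)))
    warning("disconnected topology: distances computed per component")
  is_bond <- vapply(coords, function(cc) cc$kind %in% c("bond"), TRUE)
  coords <- coords[is_bond]
  rows <- match(vapply(coords, function(cc) cc$label, ""), effects$coordinate)
  dist <- vapply(coords, function(cc)
    min(d_atom[cc$atom_indices]), 0)
  out <- tibble::tibble(coordinate = effects$coordinate[rows],
                        distance = as.integer(dist))
  for (col in intersect(c("delta_f_z", "delta_f_g", "delta_msa", "delta_cov"),
                        names(effects))) {
    v <- effects[[col]][rows]
    out[[paste0("abs_", col)]] <- abs(v)
    out[[paste0("sign_", col)]] <- sign(v)
  }
  out <- out[order(out$distance), ]
  class(out) <- c("hole_profile", class(out))
  out
}

#' Plot a vibration-hole decay profile
#'
#' Log-scale magnitudes against topological distance; filled and hollow
#' markers distinguish positive and negative effects.
#'
#' @param object a [hole_profile()] tibble.
#' @param column which effect column to plot (without the `abs_` prefix).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hole_profile <- function(object, column = "delta_msa", ...) {
  acol <- paste0("abs_", column); scol <- paste0("sign_", column)
  df <- data.frame(distance = object$distance,
                   value = object[[acol]],
                   sign = factor(ifelse(object[[scol]] >= 0, "positive",
                                        "negative")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$value,
                                   shape = .data$sign)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(positive = 16, negative = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "topological distance (bonds)",
                  y = paste0("|", column, "|"), shape = NULL)
}

#' @rdname autoplot.hole_profile
#' @export
plot_hole_profile <- function(object, column = "delta_msa", ...)
  autoplot.hole_profile(object, column = column, ...)

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
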