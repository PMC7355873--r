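#' Molecular systems and isotopologues
#'
#' A `mol_system` bundles the element labels, the equilibrium Cartesian
#' geometry (the r_e geometry, stored in bohr) and an optional bond topology
#' shared by every isotopologue.  Isotopologues differ only in their per-atom
#' masses; the potential-energy and shielding surfaces are mass-independent.
#'
#' @param atom_symbols character vector of element labels.
#' @param coords_e N x 3 numeric matrix of equilibrium positions, bohr.
#' @param bonds optional integer matrix (two columns) of bonded atom pairs,
#'   used only for topological-distance reporting (bonds are user-supplied,
#'   never perceived from distances).
#' @return An object of class `mol_system`.
#' @examples
#' sys <- mol_system(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 1.81)),
#'                   bonds = rbind(c(1L, 2L)))
#' @export
mol_system <- function(atom_symbols, coords_e, bonds = NULL) {
  coords_e <- as.matrix(coords_e)
  n <- length(atom_symbols)
  stopifnot(n >= 2, nrow(coords_e) == n, ncol(coords_e) == 3)
  if (!all(is.finite(coords_e))) stop("coordinates must be finite")
  dmin <- min(stats::dist(coords_e))
  if (dmin < 1e-6) stop("two atoms coincide in the equilibrium geometry")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > n)) stop("bond indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("bond joins an atom to itself")
  }
  structure(list(atom_symbols = atom_symbols, coords_e = coords_e,
                 bonds = bonds, n_atoms = n),
            class = "mol_system")
}

#' @export
print.mol_system <- function(x, ...) {
  cat("<mol_system> ", x$n_atoms, " atoms: ",
      paste(x$atom_symbols, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Define an isotopologue of a molecular system
#'
#' @param system a [mol_system()].
#' @param masses per-atom masses in amu (length N).  Either `masses` or
#'   `substitutions` must be given.
#' @param substitutions named list or list of `list(atom, mass)` entries
#'   applied on top of `base_masses`.
#' @param base_masses starting masses when `substitutions` is used.
#' @param label text label for reports.
#' @return An object of class `isotopologue` with fields `masses` (amu),
#'   `label` and `substitutions` (data frame of atom index, old and new mass).
#' @export
isotopologue <- function(system, masses = NULL, substitutions = NULL,
                         base_masses = NULL, label = "") {
  stopifnot(inherits(system, "mol_system"))
  n <- system$n_atoms
  subs <- data.frame(atom = integer(), old_mass = numeric(), new_mass = numeric())
  if (is.null(masses)) {
    if (is.null(base_masses) || is.null(substitutions))
      stop("give either `masses` or both `base_masses` and `substitutions`")
    masses <- base_masses
    for (s in substitutions) {
      i <- as.integer(s$atom)
      stopifnot(i >= 1L, i <= n)
      subs <- rbind(subs, data.frame(atom = i, old_mass = masses[i],
                                     new_mass = s$mass))
      masses[i] <- s$mass
    }
  } else if (!is.null(base_masses)) {
    ch <- which(masses != base_masses)
    subs <- data.frame(atom = ch, old_mass = base_masses[ch],
                       new_mass = masses[ch])
  }
  if (length(masses) != n) stop("length of masses must equal the atom count")
  if (any(masses <= 0)) stop("all masses must be positive")
  structure(list(masses = masses, label = label, substitutions = subs),
            class = "isotopologue")
}

#' Internal (curvilinear) coordinates
#'
#' Constructors for the geometry parameters used to describe the vibration
#' hole: interatomic distances, interior angles, and the azimuth/altitude
#' bending angles of a bond about its apex atom.  The azimuth `phi_az` is the
#' signed angle between the apex->mobile direction and the plane containing
#' the bisector of the two adjacent bonds and the frame normal; the altitude
#' `phi_alt` is the signed angle between the apex->mobile direction and the
#' plane spanned by the two adjacent bonds.  Signs are fixed by the
#' right-handed frame built from (apex->partner1, apex->partner2); only
#' consistency between isotopologues matters.
#'
#' @param i,j,k atom indices (angle vertex is `j`).
#' @param mobile,apex,partner1,partner2 atom indices for the bending angles:
#'   `mobile` is the displaced atom (e.g. H), `apex` its bonded partner, and
#'   the partners are the two atoms adjacent to the apex defining the frame.
#' @param label optional coordinate label for reports.
#' @return An object of class `internal_coord`.
#' @export
ic_bond <- function(i, j, label = NULL) {
  new_ic("bond", c(i, j), label %||% paste0("r(", i, ",", j, ")"))
}

#' @rdname ic_bond
#' @export
ic_angle <- function(i, j, k, label = NULL) {
  new_ic("angle", c(i, j, k), label %||% paste0("ang(", i, ",", j, ",", k, ")"))
}

#' @rdname ic_bond
#' @export
ic_azimuth <- function(mobile, apex, partner1, partner2, label = NULL) {
  new_ic("azimuth", c(mobile, apex, partner1, partner2),
         label %||% paste0("phi_az(", mobile, ")"))
}

#' @rdname ic_bond
#' @export
ic_altitude <- function(mobile, apex, partner1, partner2, label = NULL) {
  new_ic("altitude", c(mobile, apex, partner1, partner2),
         label %||% paste0("phi_alt(", mobile, ")"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_ic <- function(kind, idx, label) {
  idx <- as.integer(idx)
  if (anyDuplicated(idx)) stop("coordinate atom indices must be distinct")
  structure(list(kind = kind, atom_indices = idx, label = label),
            class = "internal_coord")
}

#' @export
print.internal_coord <- function(x, ...) {
  cat("<internal_coord> ", x$label, " [", x$kind, "]\n", sep = "")
  invisible(x)
}

# ---- forward-mode jets for analytic coordinate gradients --------------------
# A "jet" carries a 3-vector value and its 3 x 3N Jacobian wrt all Cartesian
# positions (atom-major ordering x1 y1 z1 x2 ...).

jet_atom <- function(x, i, n) {
  J <- matrix(0, 3, 3 * n)
  J[, (3 * i - 2):(3 * i)] <- diag(3)
  list(v = x[i, ], J = J)
}
jet_sub <- function(a, b) list(v = a$v - b$v, J = a$J - b$J)
jet_add <- function(a, b) list(v = a$v + b$v, J = a$J + b$J)
skew3 <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
jet_cross <- function(a, b) {
  list(v = c(a$v[2] * b$v[3] - a$v[3] * b$v[2],
             a$v[3] * b$v[1] - a$v[1] * b$v[3],
             a$v[1] * b$v[2] - a$v[2] * b$v[1]),
       J = skew3(a$v) %*% b$J - skew3(b$v) %*% a$J)
}
jet_unit <- function(a, what = "vector") {
  n <- sqrt(sum(a$v^2))
  if (n < 1e-10) stop("degenerate coordinate: zero-length ", what)
  u <- a$v / n
  list(v = u, J = (diag(3) - tcrossprod(u)) %*% a$J / n)
}
# scalar jets: list(v = scalar, g = length-3N gradient)
jet_dot <- function(a, b) {
  list(v = sum(a$v * b$v), g = drop(crossprod(a$J, b$v) + crossprod(b$J, a$v)))
}
jet_norm <- function(a, what = "vector") {
  n <- sqrt(sum(a$v^2))
  if (n < 1e-10) stop("degenerate coordinate: zero-length ", what)
  list(v = n, g = drop(crossprod(a$J, a$v / n)))
}
jet_asin <- function(s) {
  if (abs(s$v) > 1 - 1e-10) stop("degenerate coordinate: angle at +/- pi/2")
  list(v = asin(s$v), g = s$g / sqrt(1 - s$v^2))
}
jet_atan2 <- function(y, x) {
  d <- x$v^2 + y$v^2
  if (d < 1e-20) stop("degenerate coordinate: undefined angle")
  list(v = atan2(y$v, x$v), g = (x$v * y$g - y$v * x$g) / d)
}

ic_value_grad <- function(coord, x) {
  n <- nrow(x)
  idx <- coord$atom_indices
  if (any(idx > n)) stop("coordinate atom index out of range")
  switch(coord$kind,
    bond = {
      d <- jet_sub(jet_atom(x, idx[1], n), jet_atom(x, idx[2], n))
      jet_norm(d, "bond")
    },
    angle = {
      u1 <- jet_sub(jet_atom(x, idx[1], n), jet_atom(x, idx[2], n))
      u2 <- jet_sub(jet_atom(x, idx[3], n), jet_atom(x, idx[2], n))
      cr <- jet_cross(u1, u2)
      s <- sqrt(sum(cr$v^2))
      if (s < 1e-8 * sqrt(sum(u1$v^2) * sum(u2$v^2)))
        stop("degenerate coordinate: collinear angle arms")
      jet_atan2(jet_norm(cr, "angle cross product"), jet_dot(u1, u2))
    },
    azimuth = ,
    altitude = {
      ap <- jet_atom(x, idx[2], n)
      u  <- jet_unit(jet_sub(jet_atom(x, idx[1], n), ap), "apex-mobile bond")
      b1 <- jet_unit(jet_sub(jet_atom(x, idx[3], n), ap), "frame bond 1")
      b2 <- jet_unit(jet_sub(jet_atom(x, idx[4], n), ap), "frame bond 2")
      nn <- jet_cross(b1, b2)
      if (sqrt(sum(nn$v^2)) < 1e-8)
        stop("degenerate coordinate: collinear azimuth/altitude frame")
      nh <- jet_unit(nn, "frame normal")
      if (coord$kind == "altitude") {
        jet_asin(jet_dot(u, nh))
      } else {
        dh <- jet_unit(jet_add(b1, b2), "frame bisector")
        mh <- jet_unit(jet_cross(nh, dh), "frame in-plane normal")
        jet_asin(jet_dot(u, mh))
      }
    },
    stop("unknown coordinate kind: ", coord$kind))
}

#' Evaluate an internal coordinate
#'
#' @param coord an [ic_bond()], [ic_angle()], [ic_azimuth()] or
#'   [ic_altitude()] coordinate.
#' @param x N x 3 Cartesian geometry, bohr.
#' @return Scalar value: bohr for distances, radians for angles.
#' @export
evaluate_coordinate <- function(coord, x) {
  stopifnot(inherits(coord, "internal_coord"))
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("geometry must be finite")
  ic_value_grad(coord, x)$v
}

#' Value, gradient and Hessian of an internal coordinate
#'
#' First derivatives are analytic (forward-mode propagation through the
#' defining vector algebra).  Second derivatives are analytic for bonds and
#' obtained by Richardson-extrapolated central differences of the analytic
#' gradient for the angle-type coordinates.
#'
#' @inheritParams evaluate_coordinate
#' @param h step (bohr) for the finite-difference Hessian of angle-type
#'   coordinates.
#' @return List with `value`, `grad` (length 3N) and `hess` (3N x 3N,
#'   symmetric).
#' @export
coordinate_derivatives <- function(coord, x, h = 1e-3) {
  stopifnot(inherits(coord, "internal_coord"))
  x <- as.matrix(x)
  vg <- ic_value_grad(coord, x)
  n3 <- 3 * nrow(x)
  if (coord$kind == "bond") {
    i <- coord$atom_indices[1]; j <- coord$atom_indices[2]
    d <- x[i, ] - x[j, ]
    r <- sqrt(sum(d^2))
    u <- d / r
    B <- (diag(3) - tcrossprod(u)) / r
    H <- matrix(0, n3, n3)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- B; H[jj, jj] <- B; H[ii, jj] <- -B; H[jj, ii] <- -B
  } else {
    grad_at <- function(y) ic_value_grad(coord, y)$g
    fd <- function(step) {
      G <- matrix(0, n3, n3)
      for (k in seq_len(n3)) {
        y <- x; y[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] <- y[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] + step
        gp <- grad_at(y)
        y <- x; y[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] <- y[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] - step
        gm <- grad_at(y)
        G[, k] <- (gp - gm) / (2 * step)
      }
      G
    }
    H <- (4 * fd(h / 2) - fd(h)) / 3
    H <- (H + t(H)) / 2
  }
  list(value = vg$v, grad = vg$g, hess = H)
}

# Bond-path (topological) distances from a set of source atoms, by BFS.
# Returns per-atom integer distance (Inf for disconnected atoms).
topo_atom_distances <- function(bonds, n_atoms, sources) {
  adj <- vector("list", n_atoms)
  if (!is.null(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- rep(Inf, n_atoms)
  d[sources] <- 0
  queue <- sources
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in adj[[a]]) if (d[b] > d[a] + 1) { d[b] <- d[a] + 1; queue <- c(queue, b) }
  }
  d
}
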