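#' Synthetic anharmonic model systems and exact grid oracles
#'
#' The model systems stand in for ab initio potential and shielding surfaces:
#' each fixture carries an analytic force field (harmonic, cubic and Morse
#' terms in internal coordinates) and per-nucleus shielding surfaces that are
#' low-order polynomials in the same internal coordinates, so every
#' directional derivative the package computes numerically is exactly
#' checkable.  Evaluators (energy, gradient, Hessian, shieldings) are pure
#' deterministic functions of the geometry and satisfy the contract expected
#' by [cubic_semidiagonal()] and [property_derivatives()].
#'
#' @name modelsystems
NULL

#' Reference isotope masses (amu)
#' @export
iso_masses <- c(H = 1.007825, D = 2.014102, C12 = 12.000000,
                C13 = 13.003355, O16 = 15.994915)

# ---- internal-coordinate force-field machinery ------------------------------

# term: list(coords = character, pow = integer, coef = numeric)  (polynomial in
# deviations), or list(morse = TRUE, coords = name, De =, a =)
term_value <- function(term, dev) {
  if (isTRUE(term$morse)) {
    e <- exp(-term$a * dev[term$coords])
    term$De * (1 - e)^2
  } else {
    term$coef * prod(dev[term$coords]^term$pow)
  }
}

term_d1 <- function(term, dev) {
  if (isTRUE(term$morse)) {
    d <- dev[term$coords]; a <- term$a; e <- exp(-a * d)
    out <- 2 * term$De * a * e * (1 - e)
    names(out) <- term$coords
    return(out)
  }
  d <- dev[term$coords]
  vapply(seq_along(term$coords), function(j) {
    p <- term$pow
    if (p[j] == 0) return(0)
    term$coef * p[j] * d[j]^(p[j] - 1) * prod(d[-j]^p[-j])
  }, 0) -> out
  names(out) <- term$coords
  out
}

term_d2 <- function(term, dev) {
  cs <- term$coords
  m <- matrix(0, length(cs), length(cs), dimnames = list(cs, cs))
  if (isTRUE(term$morse)) {
    d <- dev[cs]; a <- term$a; e <- exp(-a * d)
    m[1, 1] <- 2 * term$De * a^2 * (2 * e^2 - e)
    return(m)
  }
  d <- dev[cs]; p <- term$pow
  for (j in seq_along(cs)) for (k in seq_along(cs)) {
    if (j == k) {
      if (p[j] >= 2)
        m[j, j] <- term$coef * p[j] * (p[j] - 1) * d[j]^(p[j] - 2) *
          prod(d[-j]^p[-j])
    } else if (p[j] >= 1 && p[k] >= 1) {
      m[j, k] <- term$coef * p[j] * p[k] * d[j]^(p[j] - 1) * d[k]^(p[k] - 1) *
        prod(d[-c(j, k)]^p[-c(j, k)])
    }
  }
  m
}

ff_energy_at <- function(fix, x) {
  vals <- vapply(fix$ic_set, evaluate_coordinate, 0, x = x)
  dev <- vals - fix$ic_ref
  sum(vapply(fix$ff, term_value, 0, dev = dev))
}

ff_gradient_at <- function(fix, x) {
  need <- unique(unlist(lapply(fix$ff, `[[`, "coords")))
  jets <- lapply(fix$ic_set[need], ic_value_grad, x = x)
  dev <- vapply(jets, `[[`, 0, "v") - fix$ic_ref[need]
  g <- numeric(3 * nrow(x))
  for (term in fix$ff) {
    d1 <- term_d1(term, dev)
    for (cn in names(d1)) if (d1[cn] != 0) g <- g + d1[cn] * jets[[cn]]$g
  }
  g
}

ff_hessian_at <- function(fix, x) {
  need <- unique(unlist(lapply(fix$ff, `[[`, "coords")))
  der <- lapply(fix$ic_set[need], coordinate_derivatives, x = x)
  dev <- vapply(der, `[[`, 0, "value") - fix$ic_ref[need]
  n3 <- 3 * nrow(x)
  H <- matrix(0, n3, n3)
  for (term in fix$ff) {
    d1 <- term_d1(term, dev)
    d2 <- term_d2(term, dev)
    cs <- term$coords
    for (j in seq_along(cs)) {
      if (d1[j] != 0) H <- H + d1[j] * der[[cs[j]]]$hess
      for (k in seq_along(cs)) {
        if (d2[j, k] != 0)
          H <- H + d2[j, k] * tcrossprod(der[[cs[j]]]$grad, der[[cs[k]]]$grad)
      }
    }
  }
  (H + t(H)) / 2
}

sigma_at <- function(fix, x) {
  need <- unique(unlist(lapply(fix$sigma, function(s)
    unlist(lapply(s$terms, `[[`, "coords")))))
  vals <- vapply(fix$ic_set[need], evaluate_coordinate, 0, x = x)
  dev <- vals - fix$ic_ref[need]
  out <- vapply(fix$sigma, function(s)
    s$const + sum(vapply(s$terms, term_value, 0, dev = dev)), 0)
  names(out) <- names(fix$sigma)
  out
}

#' Evaluators with call counting
#'
#' Wraps a fixture's analytic surfaces into the evaluator contract used by
#' the differentiation machinery, with per-function call counters (the cost
#' model of VPT2 vs DD-VPT2 is asserted through these).
#'
#' @param fix a `vib_fixture` from [make_fixture()].
#' @return A `vib_evaluators` object: functions `energy`, `gradient`,
#'   `hessian`, `sigma`; see [evaluator_counts()].
#' @export
make_evaluators <- function(fix) {
  env <- new.env()
  env$counts <- c(energy = 0L, gradient = 0L, hessian = 0L, sigma = 0L)
  bump <- function(what) env$counts[what] <- env$counts[what] + 1L
  structure(list(
    energy   = function(x) { bump("energy");   ff_energy_at(fix, as.matrix(x)) },
    gradient = function(x) { bump("gradient"); ff_gradient_at(fix, as.matrix(x)) },
    hessian  = function(x) { bump("hessian");  ff_hessian_at(fix, as.matrix(x)) },
    sigma    = function(x) { bump("sigma");    sigma_at(fix, as.matrix(x)) },
    counts_env = env, report_nuclei = fix$report_nuclei),
    class = "vib_evaluators")
}

#' @rdname make_evaluators
#' @param ev a `vib_evaluators` object.
#' @return `evaluator_counts()`: named integer vector of calls so far.
#' @export
evaluator_counts <- function(ev) ev$counts_env$counts

#' @rdname make_evaluators
#' @export
evaluator_reset <- function(ev) {
  ev$counts_env$counts[] <- 0L
  invisible(ev)
}

# ---- named fixtures ---------------------------------------------------------

#' Build a synthetic model system
#'
#' Six named fixtures cover the scenarios the methods are exercised on:
#' `diatomic_morse` (X-H Morse oscillator with polynomial shieldings),
#' `xh_heavy` (bent Y-X-H with stretch-bend coupling and very heavy frame,
#' the limit in which all methods must coincide), `water_like` (bent
#' triatomic), `methane_like` (central atom with four equivalent bonds, the
#' multi-bond-substitution testbed), `chain_n` (an H-terminated heavy-atom
#' chain for topological-distance profiles) and `hbond_toy` (a three-center
#' O-H...O motif whose stretch-stretch coupling delocalizes the vibration
#' hole; `params$coupling` switches the sign of the coupling).
#'
#' A nonzero `jitter` parameter perturbs every force-field and shielding
#' coefficient by up to that relative amount, deterministically from `seed`,
#' to generate random variants; the defaults (`jitter = 0`) are the canonical
#' study conditions.
#'
#' @param name fixture name (see above).
#' @param params named list of overrides (fixture-specific; all have
#'   defaults).
#' @param seed integer seed for jittered variants.
#' @return A `vib_fixture`: `system`, `isoA`/`isoB` (default substitution),
#'   `ic_set`/`ic_ref` (internal coordinates and reference values), `ff`
#'   (force-field terms), `sigma` (shielding surfaces), `report_nuclei`,
#'   `mobile`/`apex`/`partners` (local-model frame), `coords` (bond
#'   coordinates for geometry reports).
#' @export
make_fixture <- function(name = c("diatomic_morse", "xh_heavy", "water_like",
                                  "methane_like", "chain_n", "hbond_toy"),
                         params = list(), seed = 1L) {
  name <- match.arg(name)
  fix <- switch(name,
    diatomic_morse = fixture_diatomic(params),
    xh_heavy = fixture_xh_heavy(params),
    water_like = fixture_water(params),
    methane_like = fixture_methane(params),
    chain_n = fixture_chain(params),
    hbond_toy = fixture_hbond(params))
  jitter <- params$jitter %||% 0
  if (jitter > 0) {
    rng <- local({ set.seed(seed); function(n) stats::runif(n, -1, 1) })
    fix$ff <- lapply(fix$ff, function(tm) {
      if (isTRUE(tm$morse)) tm$De <- tm$De * (1 + jitter * rng(1))
      else tm$coef <- tm$coef * (1 + jitter * rng(1))
      tm
    })
    fix$sigma <- lapply(fix$sigma, function(s) {
      s$terms <- lapply(s$terms, function(tm) {
        tm$coef <- tm$coef * (1 + jitter * rng(1)); tm })
      s
    })
  }
  # positive-definiteness of the harmonic part, checked at build time
  ev0 <- list(hessian = function(x) ff_hessian_at(fix, x))
  H <- ev0$hessian(fix$system$coords_e)
  m <- amu_to_au(fix$isoA$masses)
  sqm <- rep(sqrt(m), each = 3)
  ev_h <- eigen((H + t(H)) / 2 / outer(sqm, sqm), symmetric = TRUE,
                only.values = TRUE)$values
  if (sum(ev_h < -1e-10) > 0)
    stop("fixture harmonic force field is not positive semidefinite")
  fix$name <- name
  class(fix) <- "vib_fixture"
  fix
}

#' @export
print.vib_fixture <- function(x, ...) {
  cat("<vib_fixture> ", x$name, ": ", x$system$n_atoms, " atoms, ",
      length(x$ff), " force-field terms\n", sep = "")
  invisible(x)
}

fixture_core <- function(symbols, coords, bonds, masses, sub_atom, sub_mass,
                         ic_set, ff, sigma, report_atoms,
                         mobile, apex, partners, labelA, labelB) {
  sys <- mol_system(symbols, coords, bonds)
  ref <- vapply(ic_set, evaluate_coordinate, 0, x = sys$coords_e)
  names(ref) <- names(ic_set)
  isoA <- isotopologue(sys, masses = masses, label = labelA)
  mB <- masses; mB[sub_atom] <- sub_mass
  isoB <- isotopologue(sys, masses = mB, base_masses = masses, label = labelB)
  list(system = sys, isoA = isoA, isoB = isoB,
       ic_set = ic_set, ic_ref = ref, ff = ff, sigma = sigma,
       report_nuclei = data.frame(label = names(sigma),
                                  atom = report_atoms),
       mobile = mobile, apex = apex, partners = partners,
       coords = ic_set[vapply(ic_set, function(ic) ic$kind == "bond", TRUE)])
}

poly_term <- function(coords, pow, coef) list(coords = coords, pow = pow, coef = coef)
morse_term <- function(coord, De, a) list(morse = TRUE, coords = coord, De = De, a = a)

fixture_diatomic <- function(p) {
  De <- p$De %||% 0.18; a <- p$a %||% 1.1
  r0 <- p$r0 %||% 1.8324
  mX <- p$mX %||% iso_masses[["O16"]]
  ics <- list(r12 = ic_bond(1, 2, "r(X-H)"))
  # harmonic = TRUE takes the a -> 0 Morse limit at fixed curvature
  # 2 De a^2 analytically (avoids the catastrophic cancellation of
  # evaluating De (1 - exp(-a dr))^2 with a tiny a and huge De)
  ff <- if (isTRUE(p$harmonic)) list(poly_term("r12", 2, De * a^2))
        else list(morse_term("r12", De, a))
  sig <- list(
    X1 = list(const = 320, terms = list(poly_term("r12", 1, -60),
                                        poly_term("r12", 2, 25))),
    H2 = list(const = 30, terms = list(poly_term("r12", 1, -12),
                                       poly_term("r12", 2, 5))))
  fixture_core(c("X", "H"), rbind(c(0, 0, 0), c(0, 0, r0)), rbind(c(1L, 2L)),
               c(mX, iso_masses[["H"]]), 2L, iso_masses[["D"]],
               ics, ff, sig, c(1L, 2L), mobile = 2L, apex = 1L,
               partners = integer(), labelA = "X-H", labelB = "X-D")
}

fixture_xh_heavy <- function(p) {
  mheavy <- p$m_heavy %||% 1e6
  r_xh <- p$r_xh %||% 1.83; r_xy <- p$r_xy %||% 2.7
  th <- (p$angle_deg %||% 104) * pi / 180
  # Y and Z are heavy frame atoms bonded to X.  H points along the
  # anti-bisector of the two frame bonds, so its azimuth and altitude both
  # vanish at equilibrium and the two transverse directions are orthogonal:
  # the local problem is exactly harmonically separable in the polar frame.
  half <- pi - th                       # frame bonds at +/- half from -u
  coords <- rbind(r_xy * c(cos(half), sin(half), 0),           # Y
                  c(0, 0, 0),                                  # X
                  r_xh * c(-1, 0, 0),                          # H
                  r_xy * c(cos(half), -sin(half), 0))          # Z
  # the angular potential is written directly on the azimuth/altitude bending
  # coordinates of the mobile H, so the only coupling between the radial and
  # angular motions at the default (weak) cross term is the kinematic
  # (centrifugal) one -- the effect the local-model comparison isolates.  A
  # strongly bending-coupled variant is obtained through params$c_rtt.
  c_rtt <- p$c_rtt %||% -0.005
  ics <- list(r_xh = ic_bond(2, 3, "r(X-H)"),
              r_xy = ic_bond(2, 1, "r(X-Y)"),
              r_xz = ic_bond(2, 4, "r(X-Z)"),
              phi_az = ic_azimuth(3, 2, 1, 4, "phi_az(H)"),
              phi_alt = ic_altitude(3, 2, 1, 4, "phi_alt(H)"),
              th_yz = ic_angle(1, 2, 4, "ang(Y-X-Z)"))
  De <- p$De %||% 0.18; a_m <- p$a %||% 1.1
  ff <- c(
    if (isTRUE(p$harmonic)) list(poly_term("r_xh", 2, De * a_m^2))
    else list(morse_term("r_xh", De, a_m),
              poly_term("phi_az", 3, -0.010),
              poly_term("phi_alt", 3, -0.006),
              poly_term(c("r_xh", "phi_az"), c(1, 2), c_rtt),
              poly_term(c("r_xh", "phi_alt"), c(1, 2), 0.8 * c_rtt)),
    list(
      poly_term("r_xy", 2, 0.25),
      poly_term("r_xz", 2, 0.25),
      poly_term("phi_az", 2, 0.070),
      poly_term("phi_alt", 2, 0.055),
      poly_term("th_yz", 2, 0.10)))
  sig <- list(
    X2 = list(const = 200, terms = list(
      poly_term("r_xh", 1, -50), poly_term("r_xh", 2, 20),
      poly_term("phi_az", 1, -10), poly_term("phi_az", 2, 8),
      poly_term("phi_alt", 2, 5))),
    H3 = list(const = 30, terms = list(
      poly_term("r_xh", 1, -12), poly_term("r_xh", 2, 5),
      poly_term("phi_az", 1, 2), poly_term("phi_az", 2, 3),
      poly_term("phi_alt", 2, 2.2),
      poly_term(c("r_xh", "phi_az"), c(1, 1), -1.5))))
  fixture_core(c("Y", "X", "H", "Z"), coords,
               rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)),
               c(mheavy, mheavy, iso_masses[["H"]], mheavy),
               3L, iso_masses[["D"]],
               ics, ff, sig, c(2L, 3L), mobile = 3L, apex = 2L,
               partners = c(1L, 4L), labelA = "YX-H", labelB = "YX-D")
}

fixture_water <- function(p) {
  r0 <- p$r0 %||% 1.8088
  th <- (p$angle_deg %||% 104.52) * pi / 180
  coords <- rbind(c(0, 0, 0),
                  r0 * c(sin(th / 2), 0, cos(th / 2)),
                  r0 * c(-sin(th / 2), 0, cos(th / 2)))
  ics <- list(r1 = ic_bond(1, 2, "r(O-H1)"), r2 = ic_bond(1, 3, "r(O-H2)"),
              th = ic_angle(2, 1, 3, "ang(H-O-H)"))
  ff <- list(
    morse_term("r1", p$De %||% 0.18, p$a %||% 1.15),
    morse_term("r2", p$De %||% 0.18, p$a %||% 1.15),
    poly_term("th", 2, 0.075),
    poly_term("th", 3, -0.008),
    poly_term(c("r1", "r2"), c(1, 1), -0.010),
    poly_term(c("r1", "th"), c(1, 2), -0.040),
    poly_term(c("r2", "th"), c(1, 2), -0.040))
  sig <- list(
    O1 = list(const = 330, terms = list(
      poly_term("r1", 1, -55), poly_term("r2", 1, -55),
      poly_term("r1", 2, 18), poly_term("r2", 2, 18),
      poly_term("th", 1, -12), poly_term("th", 2, 6))),
    H2 = list(const = 30, terms = list(
      poly_term("r1", 1, -14), poly_term("r2", 1, -2),
      poly_term("r1", 2, 6), poly_term("th", 1, 1),
      poly_term("th", 2, 2.5), poly_term(c("r1", "th"), c(1, 1), -1.2))),
    H3 = list(const = 30, terms = list(
      poly_term("r2", 1, -14), poly_term("r1", 1, -2),
      poly_term("r2", 2, 6), poly_term("th", 1, 1),
      poly_term("th", 2, 2.5), poly_term(c("r2", "th"), c(1, 1), -1.2))))
  fixture_core(c("O", "H", "H"), coords, rbind(c(1L, 2L), c(1L, 3L)),
               c(iso_masses[["O16"]], iso_masses[["H"]], iso_masses[["H"]]),
               2L, iso_masses[["D"]],
               ics, ff, sig, c(1L, 2L, 3L), mobile = 2L, apex = 1L,
               partners = 3L, labelA = "H2O", labelB = "HDO")
}

fixture_methane <- function(p) {
  r0 <- p$r0 %||% 2.0598
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  coords <- rbind(c(0, 0, 0), r0 * dirs)
  bonds <- cbind(1L, 2:5)
  ics <- list()
  for (i in 2:5) ics[[paste0("r", i)]] <- ic_bond(1L, i, paste0("r(C-H", i, ")"))
  pairs <- utils::combn(2:5, 2)
  for (c_i in seq_len(ncol(pairs))) {
    a <- pairs[1, c_i]; b <- pairs[2, c_i]
    ics[[paste0("th", a, b)]] <- ic_angle(a, 1L, b, paste0("ang(H", a, "-C-H", b, ")"))
  }
  ff <- list()
  for (i in 2:5) ff <- c(ff, list(morse_term(paste0("r", i),
                                             p$De %||% 0.17, p$a %||% 1.0)))
  for (c_i in seq_len(ncol(pairs))) {
    a <- pairs[1, c_i]; b <- pairs[2, c_i]
    tn <- paste0("th", a, b)
    ff <- c(ff, list(
      poly_term(tn, 2, 0.060),
      poly_term(tn, 3, -0.005),
      poly_term(c(paste0("r", a), tn), c(1, 2), -0.030),
      poly_term(c(paste0("r", b), tn), c(1, 2), -0.030),
      poly_term(c(paste0("r", a), paste0("r", b)), c(1, 1), -0.008)))
  }
  sig <- list(C1 = list(const = 195, terms = c(
    lapply(2:5, function(i) poly_term(paste0("r", i), 1, -30)),
    lapply(2:5, function(i) poly_term(paste0("r", i), 2, 12)),
    lapply(seq_len(ncol(pairs)), function(c_i)
      poly_term(paste0("th", pairs[1, c_i], pairs[2, c_i]), 2, 3)))))
  for (i in 2:5) {
    others <- setdiff(2:5, i)
    angles_i <- apply(pairs, 2, function(pr) i %in% pr)
    tn_i <- paste0("th", pairs[1, angles_i], pairs[2, angles_i])
    sig[[paste0("H", i)]] <- list(const = 31, terms = c(
      list(poly_term(paste0("r", i), 1, -16),
           poly_term(paste0("r", i), 2, 5.5),
           poly_term(c(paste0("r", i), tn_i[1]), c(1, 1), -1.2)),
      lapply(others, function(j) poly_term(paste0("r", j), 1, -0.8)),
      lapply(tn_i, function(tn) poly_term(tn, 2, 2.0))))
  }
  masses <- c(iso_masses[["C12"]], rep(iso_masses[["H"]], 4))
  sub_atom <- p$sub_atom %||% 2L
  sub_mass <- p$sub_mass %||% iso_masses[["D"]]
  fixture_core(c("C", "H", "H", "H", "H"), coords, bonds, masses,
               sub_atom, sub_mass, ics, ff, sig, 1:5,
               mobile = 2L, apex = 1L, partners = c(3L, 4L),
               labelA = "CH4", labelB = if (sub_atom == 1L) "13CH4" else "CH3D")
}

fixture_chain <- function(p) {
  n <- p$n %||% 6L
  stopifnot(n >= 3L)
  th <- 109.47 * pi / 180
  r_hc <- 2.06; r_cc <- 2.90
  # gauche-helix backbone (non-planar, so weak 1-4 distance terms give every
  # torsion a restoring force)
  coords <- matrix(0, n, 3)
  coords[2, ] <- c(r_hc, 0, 0)
  if (n >= 3) coords[3, ] <- coords[2, ] +
      r_cc * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)[-(1:3)]) {
    b1 <- coords[i - 1, ] - coords[i - 2, ]
    b0 <- coords[i - 2, ] - coords[i - 3, ]
    e1 <- b1 / sqrt(sum(b1^2))
    nrm <- c(b0[2] * b1[3] - b0[3] * b1[2], b0[3] * b1[1] - b0[1] * b1[3],
             b0[1] * b1[2] - b0[2] * b1[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m1 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    dih <- 60 * pi / 180
    d <- -cos(pi - th) * e1 +
      sin(pi - th) * (cos(dih) * m1 + sin(dih) * nrm)
    coords[i, ] <- coords[i - 1, ] + r_cc * d
  }
  bonds <- cbind(seq_len(n - 1), 2:n)
  ics <- list(r1 = ic_bond(1L, 2L, "r(H-C2)"))
  for (i in 2:(n - 1))
    ics[[paste0("r", i)]] <- ic_bond(i, i + 1L, paste0("r(C", i, "-C", i + 1, ")"))
  for (i in 2:(n - 1))
    ics[[paste0("th", i)]] <- ic_angle(i - 1L, i, i + 1L, paste0("ang@C", i))
  ff <- list(morse_term("r1", 0.17, 1.0))
  for (i in 2:(n - 1))
    ff <- c(ff, list(poly_term(paste0("r", i), 2, 0.225),
                     poly_term(paste0("r", i), 3, -0.15)))
  for (i in 2:(n - 1))
    ff <- c(ff, list(poly_term(paste0("th", i), 2, 0.10),
                     poly_term(c(paste0("r", i - 1), paste0("th", i)),
                               c(1, 2), -0.03),
                     poly_term(c(paste0("r", i), paste0("th", i)),
                               c(1, 2), -0.03)))
  if (n >= 4) for (i in seq_len(n - 3)) {
    nm14 <- paste0("d14_", i)
    ics[[nm14]] <- ic_bond(i, i + 3L, paste0("r(1-4:", i, ",", i + 3, ")"))
    ff <- c(ff, list(poly_term(nm14, 2, 0.025)))
  }
  sig <- list(H1 = list(const = 30, terms = list(
    poly_term("r1", 1, -14), poly_term("r1", 2, 5))))
  for (i in 2:n) {
    tms <- list(poly_term(paste0("r", i - 1), 1, -20),
                poly_term(paste0("r", i - 1), 2, 6))
    if (i < n) tms <- c(tms, list(poly_term(paste0("r", i), 1, -10)))
    if (i > 2 && i < n)
      tms <- c(tms, list(poly_term(paste0("th", i), 1, 1.5)))
    sig[[paste0("C", i)]] <- list(const = 150 + 5 * i, terms = tms)
  }
  masses <- c(iso_masses[["H"]], rep(iso_masses[["C12"]], n - 1))
  fx <- fixture_core(c("H", rep("C", n - 1)), coords, bonds, masses,
                     1L, iso_masses[["D"]], ics, ff, sig, seq_len(n),
                     mobile = 1L, apex = 2L, partners = 3L,
                     labelA = "chain-H", labelB = "chain-D")
  # report only the topological bonds, not the auxiliary 1-4 distances
  fx$coords <- fx$ic_set[grep("^r[0-9]+$", names(fx$ic_set))]
  fx
}

fixture_hbond <- function(p) {
  r_oh <- 1.85; r_oo <- 5.2
  th0 <- (p$bend_deg %||% 8) * pi / 180
  coords <- rbind(c(0, 0, 0),
                  r_oh * c(1, 0, 0),
                  r_oo * c(cos(th0), sin(th0), 0))
  ics <- list(r_oh = ic_bond(1, 2, "r(O-H)"),
              r_oo = ic_bond(1, 3, "r(O,O)"),
              th = ic_angle(2, 1, 3, "ang(H-O-O)"))
  cpl <- p$coupling %||% -0.06
  ff <- list(
    morse_term("r_oh", p$De %||% 0.12, p$a %||% 1.3),
    poly_term("r_oo", 2, 0.040),
    poly_term("th", 2, 0.050),
    poly_term(c("r_oh", "r_oo"), c(1, 1), cpl),
    poly_term(c("r_oh", "th"), c(1, 2), -0.03),
    poly_term(c("r_oo", "th"), c(1, 1), p$theta_coupling %||% 0.02))
  sig <- list(
    O1 = list(const = 300, terms = list(
      poly_term("r_oh", 1, -60), poly_term("r_oo", 1, 25),
      poly_term("r_oh", 2, 20), poly_term("th", 1, -8))),
    H2 = list(const = 25, terms = list(
      poly_term("r_oh", 1, -30), poly_term("r_oo", 1, 10),
      poly_term("r_oh", 2, 12), poly_term("th", 1, -5),
      poly_term("th", 2, 4))),
    O3 = list(const = 280, terms = list(
      poly_term("r_oh", 1, 15), poly_term("r_oo", 1, -35),
      poly_term("r_oo", 2, 10))))
  fixture_core(c("O", "H", "O"), coords, rbind(c(1L, 2L), c(1L, 3L)),
               c(iso_masses[["O16"]], iso_masses[["H"]], iso_masses[["O16"]]),
               2L, iso_masses[["D"]], ics, ff, sig, 1:3,
               mobile = 2L, apex = 1L, partners = 3L,
               labelA = "OHO", labelB = "ODO")
}

# ---- sinc-DVR grid oracles --------------------------------------------------

sinc_kinetic <- function(n, dx, mass_au) {
  i <- seq_len(n)
  D <- outer(i, i, function(a, b) {
    out <- 2 / (a - b)^2
    out[a == b] <- pi^2 / 3
    out * (-1)^(a - b)
  })
  D / (2 * mass_au * dx^2)
}

dvr1d_solve <- function(V, mass_au, xlim, n) {
  x <- seq(xlim[1], xlim[2], length.out = n)
  dx <- x[2] - x[1]
  H <- sinc_kinetic(n, dx, mass_au)
  diag(H) <- diag(H) + vapply(x, V, 0)
  eg <- eigen(H, symmetric = TRUE)
  psi <- eg$vectors[, n]
  list(x = x, e0 = eg$values[n], psi = psi / sqrt(sum(psi^2)))
}

#' Exact ground-state vibrational averages by sinc-DVR
#'
#' Dense-grid (discrete variable representation) diagonalization for 1D or 2D
#' subsystem potentials; used as the exact oracle against which the VPT2
#' truncation is measured.  The grid is doubled until the ground-state energy
#' and the requested expectation change by less than `tol`, and the range is
#' widened automatically while the wavefunction leaks into the edges.
#'
#' @param V potential: function of one coordinate (1D, bohr -> hartree) or of
#'   two coordinates (2D).
#' @param mass_amu particle mass(es), amu (length 1 or 2).
#' @param observable function of the same coordinates to average.
#' @param xlim,ylim coordinate ranges (bohr).
#' @param tol convergence tolerance on E0 and the average.
#' @param n_start,n_max initial and maximal number of grid points per
#'   dimension.
#' @return List with `energy` (hartree), `mean` (ground-state expectation of
#'   `observable`), `n` (final grid size).
#' @export
dvr_average <- function(V, mass_amu, observable, xlim, ylim = NULL,
                        tol = 1e-8, n_start = 64L, n_max = 2048L) {
  if (is.null(ylim)) {
    m <- amu_to_au(mass_amu[1])
    widen <- 0L
    repeat {
      sol <- dvr1d_solve(V, m, xlim, n_start)
      edge <- max(abs(sol$psi[1]), abs(sol$psi[length(sol$psi)]))
      if (edge < 1e-7) break
      if (V(xlim[1]) < sol$e0 || V(xlim[2]) < sol$e0)
        stop("non-confining potential on the DVR range")
      xlim <- xlim + c(-0.25, 0.25) * diff(xlim)
      widen <- widen + 1L
      if (widen > 6L) stop("DVR range failed to confine the ground state")
    }
    prev <- NULL
    n <- n_start
    repeat {
      sol <- dvr1d_solve(V, m, xlim, n)
      mean_obs <- sum(sol$psi^2 * vapply(sol$x, observable, 0))
      if (!is.null(prev) &&
          abs(prev$e0 - sol$e0) < tol && abs(prev$m - mean_obs) < tol)
        return(list(energy = sol$e0, mean = mean_obs, n = n))
      prev <- list(e0 = sol$e0, m = mean_obs)
      n <- 2L * n
      if (n > n_max) {
        warning("DVR grid not converged to ", tol, " at n = ", n_max)
        return(list(energy = sol$e0, mean = mean_obs, n = n %/% 2L))
      }
    }
  } else {
    if (length(mass_amu) == 1L) mass_amu <- rep(mass_amu, 2L)
    mx <- amu_to_au(mass_amu[1]); my <- amu_to_au(mass_amu[2])
    solve2d <- function(n) {
      x <- seq(xlim[1], xlim[2], length.out = n)
      y <- seq(ylim[1], ylim[2], length.out = n)
      Tx <- sinc_kinetic(n, x[2] - x[1], mx)
      Ty <- sinc_kinetic(n, y[2] - y[1], my)
      Vg <- outer(x, y, Vectorize(V))
      H <- kronecker(Tx, diag(n)) + kronecker(diag(n), Ty) + diag(as.vector(t(Vg)))
      # state ordering: index = (ix - 1) * n + iy  (x-major, y fastest)
      eg <- eigen(H, symmetric = TRUE)
      psi <- eg$vectors[, n * n]
      og <- outer(x, y, Vectorize(observable))
      list(e0 = eg$values[n * n],
           mean = sum(psi^2 * as.vector(t(og))))
    }
    n <- max(24L, n_start %/% 2L)
    prev <- solve2d(n)
    repeat {
      n2 <- n + n %/% 2L
      cur <- solve2d(n2)
      if (abs(cur$e0 - prev$e0) < tol * 10 && abs(cur$mean - prev$mean) < tol * 10)
        return(list(energy = cur$e0, mean = cur$mean, n = n2))
      prev <- cur; n <- n2
      if (n > 96L) {
        warning("2D DVR not fully converged at n = ", n)
        return(list(energy = cur$e0, mean = cur$mean, n = n))
      }
    }
  }
}
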