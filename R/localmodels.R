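#' A-priori local comparator methods: loc-VPT2 and LMZL
#'
#' loc-VPT2 treats only the nucleus at the substitution site as in standard
#' VPT2 while every other nucleus stays frozen at its r_e position: the 3x3
#' block of the Cartesian Hessian at the mobile atom is mass-weighted with
#' that atom's mass alone and diagonalized without any translation/rotation
#' projection (the frozen environment fixes the frame), and the VPT2 formulas
#' are applied with three local modes.  Harmonic couplings between the local
#' stretching and bending motions are thereby retained.
#'
#' LMZL (local-mode zero-point level) goes one step further and treats the
#' three polar coordinates of the mobile atom about its bonded partner --
#' bond length r and the two bending arcs (azimuth, altitude) -- as
#' *independent* 1D oscillators, ignoring both harmonic and anharmonic
#' couplings.  Coordinate shifts and amplitudes are obtained perturbatively
#' from the 1D harmonic and cubic constants, which makes the results directly
#' comparable to the VPT2-family numbers.  The optional centrifugal
#' correction augments the radial potential with the angular zero-point
#' term `V_cent(r) = <L^2> / (2 mu r^2)`, `<L^2> = mu r_e^2
#' (omega_az + omega_alt) / 2`, restoring the bond stretch induced by the
#' angular zero-point motion that the separable treatment misses.
#'
#' @name localmodels
NULL

local_mode_set <- function(system, iso, hessian, mobile, basis_id = NULL) {
  n <- system$n_atoms
  idx <- (3 * mobile - 2):(3 * mobile)
  block <- as.matrix(hessian)[idx, idx]
  block <- (block + t(block)) / 2
  m_au <- amu_to_au(iso$masses[mobile])
  eg <- eigen(block / m_au, symmetric = TRUE)
  if (any(eg$values <= 0))
    stop("restricted force-constant block is not positive definite")
  ord <- order(eg$values)   # ascending, as in normal_modes
  omega <- sqrt(eg$values[ord])
  vec <- fix_eigenvectors(eg$vectors[, ord, drop = FALSE], eg$values[ord])
  L <- matrix(0, 3 * n, 3)
  L[idx, ] <- vec / sqrt(m_au) / rep(sqrt(omega), each = 3)
  structure(list(omega = omega, freq_cm1 = au_to_cm1(omega), L = L,
                 kind = rep("v", 3), n_vib = 3L, masses_au = amu_to_au(iso$masses),
                 system = system, iso = iso, local = TRUE, mobile = mobile,
                 basis_id = basis_id %||% paste0("loc:", iso$label)),
            class = "normal_modes")
}

#' loc-VPT2 isotope shift
#'
#' @inheritParams vpt2_shift
#' @param mobile index of the (single) mobile atom; the substitution must be
#'   confined to it.
#' @return An `iso_shift_report` with method `"loc-VPT2"`.
#' @export
loc_vpt2_shift <- function(system, isoA, isoB, ev, mobile,
                           h_ff = 0.005, h_nmr = 0.05) {
  subs <- isoB$substitutions$atom
  if (length(subs) && !all(subs == mobile))
    stop("loc-VPT2: substitution is not confined to the mobile atom")
  H0 <- ev$hessian(system$coords_e)
  corr <- lapply(list(isoA, isoB), function(iso) {
    modes <- local_mode_set(system, iso, H0, mobile)
    cub <- cubic_semidiagonal(ev$hessian, modes, h_ff)
    prop <- property_derivatives(ev$sigma, modes, h_nmr)
    vib_correction(modes, cub, prop)
  })
  rep <- standard_isotope_shift(corr[[1]], corr[[2]], system,
                                report_nuclei = ev$report_nuclei,
                                method = "loc-VPT2")
  attr(rep, "details") <- list(corrA = corr[[1]], corrB = corr[[2]])
  rep
}

# polar frame about the apex: radial unit vector and the two transverse
# (azimuth / altitude) directions, fixed by the adjacent-partner geometry
lmzl_frame <- function(system, mobile, apex, partners) {
  x <- system$coords_e
  u <- x[mobile, ] - x[apex, ]
  r_e <- sqrt(sum(u^2)); u <- u / r_e
  if (length(partners) >= 2) {
    b1 <- x[partners[1], ] - x[apex, ]; b1 <- b1 / sqrt(sum(b1^2))
    b2 <- x[partners[2], ] - x[apex, ]; b2 <- b2 / sqrt(sum(b2^2))
    nn <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    if (sqrt(sum(nn^2)) < 1e-8) stop("degenerate azimuth/altitude frame")
    nn <- nn / sqrt(sum(nn^2))
    dd <- b1 + b2; dd <- dd / sqrt(sum(dd^2))
    mm <- c(nn[2] * dd[3] - nn[3] * dd[2], nn[3] * dd[1] - nn[1] * dd[3],
            nn[1] * dd[2] - nn[2] * dd[1])
  } else if (length(partners) == 1) {
    b1 <- x[partners[1], ] - x[apex, ]; b1 <- b1 / sqrt(sum(b1^2))
    nn <- c(u[2] * b1[3] - u[3] * b1[2], u[3] * b1[1] - u[1] * b1[3],
            u[1] * b1[2] - u[2] * b1[1])
    if (sqrt(sum(nn^2)) < 1e-8) stop("collinear local frame")
    nn <- nn / sqrt(sum(nn^2))
    mm <- c(nn[2] * u[3] - nn[3] * u[2], nn[3] * u[1] - nn[1] * u[3],
            nn[1] * u[2] - nn[2] * u[1])
  } else stop("LMZL frame needs at least one adjacent partner atom")
  # transverse directions orthogonal to u
  e_az <- mm - sum(mm * u) * u; e_az <- e_az / sqrt(sum(e_az^2))
  e_alt <- nn - sum(nn * u) * u; e_alt <- e_alt / sqrt(sum(e_alt^2))
  list(u = u, e_az = e_az, e_alt = e_alt, r_e = r_e)
}

fd_123 <- function(f, h) {
  # value, first, second, third derivative of f at 0 from a 5-point stencil
  v <- vapply(c(-2, -1, 0, 1, 2) * h, f, 0)
  list(d1 = (v[1] - 8 * v[2] + 8 * v[4] - v[5]) / (12 * h),
       d2 = (-v[1] + 16 * v[2] - 30 * v[3] + 16 * v[4] - v[5]) / (12 * h^2),
       d3 = (v[5] - 2 * v[4] + 2 * v[2] - v[1]) / (2 * h^3))
}

#' LMZL isotope shift with optional centrifugal correction
#'
#' @inheritParams loc_vpt2_shift
#' @param apex bonded partner of the mobile atom (polar-coordinate origin).
#' @param partners one or two atoms adjacent to the apex fixing the
#'   azimuth/altitude directions.
#' @param centrifugal add the centrifugal radial potential (method label
#'   `"LMZL+cent"`).
#' @param radial_mass `"mobile"` (default; consistent with the frozen
#'   environment) or `"reduced"` (two-body reduced mass of the bond) for the
#'   radial oscillator.
#' @param h_disp displacement step (bohr, along the radial direction and the
#'   bending arcs) for the 1D finite differences.
#' @return List with `report` (an `iso_shift_report`) and `geometry`
#'   (a tibble of per-coordinate 1D frequencies, zero-point shifts and
#'   mean-square amplitudes for both isotopologues plus their isotope
#'   effects; lengths bohr, from the polar treatment these are r_g-type
#'   averages).
#' @export
lmzl_shift <- function(system, isoA, isoB, ev, mobile, apex, partners,
                       centrifugal = FALSE, radial_mass = c("mobile", "reduced"),
                       h_disp = 0.02) {
  radial_mass <- match.arg(radial_mass)
  subs <- isoB$substitutions$atom
  if (length(subs) && !all(subs == mobile))
    stop("LMZL: substitution is not confined to the mobile atom")
  if (!is.null(system$bonds)) {
    nb <- sum(system$bonds == mobile)
    if (nb > 1)
      stop("LMZL is not applicable: the substitution site is bonded to ",
           nb, " atoms")
  }
  fr <- lmzl_frame(system, mobile, apex, partners)
  x_e <- system$coords_e
  path <- function(dirvec) function(s) {
    y <- x_e; y[mobile, ] <- y[mobile, ] + s * dirvec; y
  }
  arc <- function(evec) function(s) {
    phi <- s / fr$r_e
    y <- x_e
    y[mobile, ] <- x_e[apex, ] + fr$r_e * (cos(phi) * fr$u + sin(phi) * evec)
    y
  }
  paths <- list(r = path(fr$u), az = arc(fr$e_az), alt = arc(fr$e_alt))

  vder <- lapply(paths, function(pp) fd_123(function(s) ev$energy(pp(s)), h_disp))
  nuc <- names(ev$sigma(x_e))
  sder <- lapply(paths, function(pp) {
    d <- lapply(nuc, function(q) fd_123(function(s) ev$sigma(pp(s))[q], h_disp))
    names(d) <- nuc
    d
  })

  one_iso <- function(iso) {
    m_mob <- amu_to_au(iso$masses[mobile])
    mu <- c(r = if (radial_mass == "reduced") {
      mp <- amu_to_au(iso$masses[apex]); m_mob * mp / (m_mob + mp)
    } else m_mob, az = m_mob, alt = m_mob)
    k <- vapply(vder, `[[`, 0, "d2")
    c3 <- vapply(vder, `[[`, 0, "d3")
    names(k) <- names(c3) <- names(paths)
    if (any(k <= 0)) stop("negative 1D force constant in the LMZL frame")
    omega <- sqrt(k / mu)
    g <- c(r = 0, az = 0, alt = 0)
    if (centrifugal) {
      L2 <- mu[["az"]] * fr$r_e^2 * (omega[["az"]] + omega[["alt"]]) / 2
      g[["r"]] <- g[["r"]] - L2 / (mu[["r"]] * fr$r_e^3)
      k[["r"]] <- k[["r"]] + 3 * L2 / (mu[["r"]] * fr$r_e^4)
      c3[["r"]] <- c3[["r"]] - 12 * L2 / (mu[["r"]] * fr$r_e^5)
      omega <- sqrt(k / mu)
    }
    shift <- -g / k - c3 / (4 * mu^2 * omega^3)
    msa <- 1 / (2 * mu * omega)
    harm <- vapply(nuc, function(q)
      -0.25 * sum(vapply(names(paths), function(cc)
        sder[[cc]][[q]]$d2 / (mu[[cc]] * omega[[cc]]), 0)), 0)
    anh <- vapply(nuc, function(q)
      -sum(vapply(names(paths), function(cc)
        sder[[cc]][[q]]$d1 * shift[[cc]], 0)), 0)
    list(omega = omega, shift = shift, msa = msa,
         harm = harm * 1000, anh = anh * 1000)
  }
  A <- one_iso(isoA); B <- one_iso(isoB)
  dR_cart <- (B$shift[["r"]] - A$shift[["r"]]) * fr$u  # radial part only
  dR <- numeric(3 * system$n_atoms)
  dR[(3 * mobile - 2):(3 * mobile)] <- dR_cart
  rep <- new_shift_report(system, nuc, B$harm - A$harm, B$anh - A$anh, dR,
                          sub_atoms = mobile,
                          report_nuclei = ev$report_nuclei,
                          method = if (centrifugal) "LMZL+cent" else "LMZL",
                          labels = c(isoA$label, isoB$label))
  geo <- tibble::tibble(
    coordinate = names(paths),
    omega_cm1_A = au_to_cm1(A$omega), omega_cm1_B = au_to_cm1(B$omega),
    shift_A = unname(A$shift), shift_B = unname(B$shift),
    delta_shift = unname(B$shift - A$shift),
    msa_A = unname(A$msa), msa_B = unname(B$msa),
    delta_msa = unname(B$msa - A$msa))
  list(report = rep, geometry = geo, r_e = fr$r_e)
}
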