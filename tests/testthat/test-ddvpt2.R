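test_that("mode expansion is exact and reduces to the identity for A = A", {
  fix <- fix_of("water_like")
  ev <- make_evaluators(fix)
  H0 <- ev$hessian(fix$system$coords_e)
  mA <- normal_modes(fix$system, fix$isoA, H0, basis_id = "A")
  mB <- normal_modes(fix$system, fix$isoB, H0, basis_id = "B")
  jac_same <- mode_jacobian(mA, mA)
  nv <- mA$n_vib
  expect_equal(jac_same$J[1:nv, 1:nv], diag(nv), tolerance = 1e-10)
  jac <- mode_jacobian(mA, mB)
  expect_lt(max(abs(mA$L %*% t(jac$J) - mB$L)), 1e-10)
})

test_that("the 1D heavy-partner expansion coefficient is (muH/muD)^(1/4)", {
  fix <- fix_of("diatomic_morse", mX = 1e6)
  ev <- make_evaluators(fix)
  H0 <- ev$hessian(fix$system$coords_e)
  mA <- normal_modes(fix$system, fix$isoA, H0, basis_id = "A")
  mB <- normal_modes(fix$system, fix$isoB, H0, basis_id = "B")
  jac <- mode_jacobian(mA, mB)
  muH <- 1.007825 * 1e6 / (1e6 + 1.007825)
  muD <- 2.014102 * 1e6 / (1e6 + 2.014102)
  expect_equal(abs(jac$J[1, 1]), (muH / muD)^(1 / 4), tolerance = 1e-4)
  M <- dd_weight_matrix(jac)
  expect_equal(M[1, 1], sqrt(muH / muD) - 1, tolerance = 1e-4)
})

test_that("M vanishes for identical isotopologues and traces to sum(kappa)", {
  fix <- fix_of("methane_like")
  ev <- make_evaluators(fix)
  H0 <- ev$hessian(fix$system$coords_e)
  mA <- normal_modes(fix$system, fix$isoA, H0, basis_id = "A")
  M0 <- dd_weight_matrix(mode_jacobian(mA, mA))
  expect_lt(max(abs(M0)), 1e-10)
  mB <- normal_modes(fix$system, fix$isoB, H0, basis_id = "B")
  M <- dd_weight_matrix(mode_jacobian(mA, mB))
  dd <- dd_modes(M, mA, cutoff = 1e-3)
  expect_equal(sum(diag(M)), sum(dd$kappa), tolerance = 1e-10)
  expect_true(all(diff(abs(dd$kappa)) < 1e-12))   # |kappa| non-increasing
})

test_that("heavy-frame kappas reach the printed mass-ratio limits", {
  # H/D against an effectively infinite-mass frame: three leading kappa at
  # -1 + sqrt(m_H/m_D) = -0.29262
  run <- runs_of("xh_heavy", .cutoff = 1e-3)
  dd <- attr(run$dd, "details")$dd
  expect_equal(unname(dd$kappa[1:3]),
               rep(-1 + sqrt(1.007825 / 2.014102), 3), tolerance = 1e-4)
  expect_lt(max(abs(dd$kappa[-(1:3)])), 1e-4)
  # finite-mass environments dilute the limit to the reduced-mass value:
  # C-H stretch kappa for a 12 amu partner
  run_m <- runs_of("methane_like")
  ddm <- attr(run_m$dd, "details")$dd
  muH <- 1.007825 * 12 / 13.007825
  muD <- 2.014102 * 12 / 14.014102
  expect_lt(abs(ddm$kappa[1] - (sqrt(muH / muD) - 1)), 0.01)
  # single substitution: no more than ten weights above 1e-3
  expect_lte(sum(abs(ddm$kappa) > 1e-3), 10L)
})

test_that("a single 13C substitution shows one leading reduced-mass weight", {
  run <- runs_of("methane_like", sub_atom = 1L, sub_mass = 13.003355)
  dd <- attr(run$dd, "details")$dd
  # the central atom vibrates against the 4 x 1.008 amu hydrogen cage
  muA <- 12 * 4.0313 / 16.0313
  muB <- 13.003355 * 4.0313 / 17.034655
  expect_lt(abs(dd$kappa[1] - (sqrt(muA / muB) - 1)), 0.001)
  expect_lt(abs(dd$kappa[1]), abs(-1 + sqrt(12 / 13.003355)))  # diluted limit
})

test_that("a double substitution roughly doubles the leading-mode count", {
  fix <- fix_of("methane_like")
  ev <- make_evaluators(fix)
  H0 <- ev$hessian(fix$system$coords_e)
  mA <- normal_modes(fix$system, fix$isoA, H0, basis_id = "A")
  iso2 <- isotopologue(fix$system,
                       masses = replace(fix$isoA$masses, c(2, 3), 2.014102),
                       base_masses = fix$isoA$masses, label = "CH2D2")
  mB2 <- normal_modes(fix$system, iso2, H0, basis_id = "B2")
  dd2 <- dd_modes(dd_weight_matrix(mode_jacobian(mA, mB2)), mA, cutoff = 1e-3)
  dd1 <- attr(runs_of("methane_like")$dd, "details")$dd
  n1 <- sum(abs(dd1$kappa) > 0.05)
  n2 <- sum(abs(dd2$kappa) > 0.05)
  expect_equal(n2, 2L * n1)
})

test_that("DD-VPT2 at cutoff 0 reproduces explicit-difference VPT2", {
  run <- runs_of("water_like")
  expect_lt(max(abs(run$dd$shift_ppb - run$vpt2$shift_ppb)), 1)
  # the Delta-R identity is exact in exact arithmetic; at the default step
  # width the residual is the O(h^2) stencil floor (its h^2 decay is
  # asserted in the stencil-convergence test below)
  expect_lt(max(abs(attr(run$dd, "dR") - attr(run$vpt2, "dR"))), 1e-7)
  expect_lt(max(abs(run$dd$harm_ppb - run$vpt2$harm_ppb)), 1)
})

test_that("no substitution gives an identically zero DD shift", {
  fix <- fix_of("water_like")
  ev <- make_evaluators(fix)
  rep0 <- suppressWarnings(
    ddvpt2_shift(fix$system, fix$isoA, fix$isoA, ev, cutoff = 0))
  expect_lt(max(abs(rep0$shift_ppb)), 1e-8)
})

test_that("the truncation self-converges between cutoffs 1e-3 and 1e-4", {
  fix <- fix_of("methane_like")
  ev <- make_evaluators(fix)
  s3 <- ddvpt2_shift(fix$system, fix$isoA, fix$isoB, ev, cutoff = 1e-3)
  s4 <- ddvpt2_shift(fix$system, fix$isoA, fix$isoB, ev, cutoff = 1e-4)
  expect_lt(max(abs(s3$shift_ppb - s4$shift_ppb)), 0.01 * max(abs(s4$shift_ppb)))
})

test_that("results do not depend on the arbitrary rigid-mode scaling", {
  fix <- fix_of("water_like")
  ev <- make_evaluators(fix)
  H0 <- ev$hessian(fix$system$coords_e)
  run_scaled <- function(rs) {
    mA <- normal_modes(fix$system, fix$isoA, H0, basis_id = "A", rot_scale = rs,
                       trans_scale = rs)
    mB <- normal_modes(fix$system, fix$isoB, H0, basis_id = "B", rot_scale = rs,
                       trans_scale = rs)
    dd <- dd_modes(dd_weight_matrix(mode_jacobian(mA, mB)), mA, cutoff = 0)
    cub <- cubic_semidiagonal(ev$hessian, dd); cub$basis_id <- dd$basis_id
    prop <- property_derivatives(ev$sigma, dd); prop$basis_id <- dd$basis_id
    list(rep = dd_isotope_shift(dd, cub, prop, sub_atoms = 2L), dd = dd)
  }
  r1 <- run_scaled(1); r2 <- run_scaled(3.7)
  # invariance is exact in exact arithmetic; the residual is finite-
  # difference noise from displacing along the re-mixed dd directions
  expect_lt(max(abs(r1$rep$shift_ppb - r2$rep$shift_ppb)) /
              max(abs(r1$rep$shift_ppb)), 5e-5)
  expect_lt(max(abs(attr(r1$rep, "dR") - attr(r2$rep, "dR"))), 1e-8)
  # the leading (vibration-dominated) weight is stable; rotation-admixed
  # trailing weights re-mix with the scaling
  expect_lt(abs(r1$dd$kappa[1] - r2$dd$kappa[1]), 1e-4)
})

test_that("the evaluation budget follows the retained-mode count", {
  fix <- fix_of("methane_like")
  ev <- make_evaluators(fix)
  H0 <- ev$hessian(fix$system$coords_e)
  mA <- normal_modes(fix$system, fix$isoA, H0, basis_id = "A")
  mB <- normal_modes(fix$system, fix$isoB, H0, basis_id = "B")
  dd <- dd_modes(dd_weight_matrix(mode_jacobian(mA, mB)), mA, cutoff = 1e-3)
  n_ret <- length(dd$retained)
  evaluator_reset(ev)
  cubic_semidiagonal(ev$hessian, dd)
  expect_identical(unname(evaluator_counts(ev)[["hessian"]]), 2L * n_ret)
  expect_lt(n_ret, mA$n_vib)           # fewer than 3N-6 directions
})

test_that("geometry reports evaluate the r_z isotope effect and viz structures", {
  run <- runs_of("diatomic_morse", .cutoff = 1e-3, mX = 1e6)
  dR <- attr(run$dd, "dR")
  geo0 <- dd_geometry_report(run$fix$system, dR, run$fix$coords, lambda_viz = 0)
  expect_equal(geo0$viz_geometry, run$fix$system$coords_e, tolerance = 1e-14)
  # deuteration contracts the X-H bond (Morse anharmonicity)
  geo <- dd_geometry_report(run$fix$system, dR, run$fix$coords, lambda_viz = 400)
  expect_lt(geo$table$delta_f_z[1], 0)
  # independent oracle for the sign: exact Morse ground-state averages
  De <- 0.18; a <- 1.1; r0 <- 1.8324
  mean_r <- function(m_amu) {
    mu <- m_amu * 1e6 / (m_amu + 1e6)
    dvr_average(function(r) De * (1 - exp(-a * (r - r0)))^2, mu,
                function(r) r, xlim = c(0.9, 4.5))$mean
  }
  expect_lt(mean_r(2.014102) - mean_r(1.007825), 0)
  # Taylor consistency: f(Re + dR) - f(Re) matches the gradient contraction
  d <- coordinate_derivatives(run$fix$coords[[1]], run$fix$system$coords_e)
  expect_equal(unname(geo$table$delta_f_z[1] / sum(d$grad * dR)), 1,
               tolerance = 1e-3)
})

test_that("the equivalence residual is pure second-order stencil error", {
  # the cutoff-0 identity is exact in exact arithmetic; the finite-difference
  # residual between the two displacement bases must fall as h^2
  fix <- fix_of("water_like")
  ev <- make_evaluators(fix)
  res_at <- function(h) {
    r1 <- vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, h_ff = h)
    r2 <- ddvpt2_shift(fix$system, fix$isoA, fix$isoB, ev, cutoff = 0, h_ff = h)
    max(abs(attr(r1, "dR") - attr(r2, "dR")))
  }
  r5 <- res_at(0.005); r1 <- res_at(0.001)
  expect_equal(r5 / r1, 25, tolerance = 0.25)
  expect_lt(r1, 1e-9)
})
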