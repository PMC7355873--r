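test_that("loc-VPT2 equals standard VPT2 in the frozen-frame limit", {
  run <- runs_of("xh_heavy")
  fix <- run$fix
  loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, run$ev, fix$mobile)
  expect_lt(max(abs(loc$shift_ppb - run$vpt2$shift_ppb)), 0.1)
})

test_that("loc-VPT2 has no anharmonic part on a Cartesian-harmonic surface", {
  fix <- fix_of("xh_heavy")
  ev0 <- make_evaluators(fix)
  H0 <- ev0$hessian(fix$system$coords_e)
  x0 <- as.vector(t(fix$system$coords_e))
  ev <- list(hessian = function(x) H0,
             sigma = ev0$sigma, report_nuclei = ev0$report_nuclei)
  loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile)
  expect_lt(max(abs(loc$anh_ppb)), 1e-8)
  expect_lt(max(abs(attr(loc, "dR"))), 1e-12)
})

test_that("loc-VPT2 tracks DD-VPT2 qualitatively on the methane-like system", {
  run <- runs_of("methane_like", .cutoff = 1e-3)
  fix <- run$fix
  loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, run$ev, fix$mobile)
  dd <- run$dd
  # same sign and same order of magnitude at the substituted nucleus, but
  # not identical (the locality restriction is an approximation)
  i <- which(dd$nucleus == "H2")
  expect_identical(sign(loc$shift_ppb[i]), sign(dd$shift_ppb[i]))
  expect_lt(abs(loc$shift_ppb[i] / dd$shift_ppb[i] - 1), 1)
  expect_gt(abs(loc$shift_ppb[i] - dd$shift_ppb[i]), 1e-6)
})

test_that("substitution away from the mobile atom is rejected", {
  fix <- fix_of("methane_like")
  ev <- make_evaluators(fix)
  expect_error(loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, mobile = 3L),
               "not confined")
  expect_error(lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, mobile = 3L,
                          apex = 1L, partners = c(4L, 5L)), "not confined")
})

test_that("LMZL refuses multiply-bonded substitution sites", {
  fix <- fix_of("methane_like", sub_atom = 1L, sub_mass = 13.003355)
  ev <- make_evaluators(fix)
  expect_error(lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, mobile = 1L,
                          apex = 2L, partners = c(3L, 4L)), "bonded to")
})

test_that("LMZL amplitudes equal loc-VPT2 amplitudes for a separable harmonic potential", {
  fix <- fix_of("xh_heavy", harmonic = TRUE)
  ev <- make_evaluators(fix)
  loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile)
  lm <- lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile, fix$apex,
                   fix$partners, centrifugal = FALSE)
  det <- attr(loc, "details")
  # mean-square Cartesian amplitudes of the mobile atom per local mode:
  # loc modes are the polar axes here, so sorted amplitude sets must agree
  msa_loc_A <- sort(0.5 * colSums(det$corrA$modes$L^2))
  msa_lmzl_A <- sort(lm$geometry$msa_A)
  expect_equal(msa_loc_A, msa_lmzl_A, tolerance = 1e-8)
  msa_loc_B <- sort(0.5 * colSums(det$corrB$modes$L^2))
  expect_equal(msa_loc_B, sort(lm$geometry$msa_B), tolerance = 1e-8)
})

test_that("the centrifugal correction recovers the missing bond stretch", {
  # bending-coupled variant: plain LMZL underestimates |dr_g|, the
  # centrifugal correction closes most of the gap to loc-VPT2
  fix <- fix_of("xh_heavy", c_rtt = -0.05)
  ev <- make_evaluators(fix)
  loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile)
  lm <- lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile, fix$apex,
                   fix$partners, centrifugal = FALSE)
  lmc <- lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile, fix$apex,
                    fix$partners, centrifugal = TRUE)
  det <- attr(loc, "details")
  gA <- geometry_statistics(fix$coords["r_xh"], det$corrA$modes, det$corrA$dR)
  gB <- geometry_statistics(fix$coords["r_xh"], det$corrB$modes, det$corrB$dR)
  drg_loc <- gB$f_g - gA$f_g
  drg_lm <- lm$geometry$delta_shift[1]
  drg_lmc <- lmc$geometry$delta_shift[1]
  expect_lte(abs(drg_lm), abs(drg_lmc))
  expect_lte(abs(drg_lmc), abs(drg_loc))
  # "considerably closer": the correction removes most of the deficit
  expect_lt(abs(drg_lmc - drg_loc), 0.5 * abs(drg_lm - drg_loc))
  # same ordering pattern for the shifts at the substituted nucleus
  i <- which(loc$nucleus == "H3")
  expect_lt(abs(lmc$report$shift_ppb[i] - loc$shift_ppb[i]),
            abs(lm$report$shift_ppb[i] - loc$shift_ppb[i]))
})

test_that("LMZL systematically underestimates the bond-length isotope effect", {
  for (cc in c(-0.02, -0.05, -0.08)) {
    fix <- fix_of("xh_heavy", c_rtt = cc)
    ev <- make_evaluators(fix)
    loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile)
    lm <- lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile, fix$apex,
                     fix$partners, centrifugal = FALSE)
    det <- attr(loc, "details")
    gA <- geometry_statistics(fix$coords["r_xh"], det$corrA$modes, det$corrA$dR)
    gB <- geometry_statistics(fix$coords["r_xh"], det$corrB$modes, det$corrB$dR)
    expect_lte(abs(lm$geometry$delta_shift[1]), abs(gB$f_g - gA$f_g))
  }
})

test_that("LMZL with centrifugal correction approaches the exact 2D average", {
  # planar (r, phi) model: Morse radial potential plus harmonic angular
  # restoring; exact ground state by 2D sinc-DVR
  De <- 0.16; a <- 1.15; re <- 1.83; kphi <- 0.065
  V2 <- function(x, y) {
    r <- sqrt((re + x)^2 + y^2)
    phi <- atan2(y, re + x)
    De * (1 - exp(-a * (r - re)))^2 + 0.5 * kphi * phi^2
  }
  robs <- function(x, y) sqrt((re + x)^2 + y^2)
  exact_mean <- function(m_amu)
    dvr_average(V2, rep(m_amu, 2), robs, xlim = c(-0.75, 1.6),
                ylim = c(-1.4, 1.4), tol = 1e-7)$mean
  lmzl_mean <- function(m_amu, cent) {
    mu <- m_amu * vib_constants$amu_to_me
    kr <- 2 * De * a^2; c3r <- -6 * De * a^3
    kang <- kphi / re^2                  # arc-coordinate constant
    wr <- sqrt(kr / mu); wa <- sqrt(kang / mu)
    g <- 0
    if (cent) {
      # single angular mode in 2D: <L^2> = mu re^2 w_a / 2
      L2 <- mu * re^2 * wa / 2
      g <- -L2 / (mu * re^3)
      kr_c <- kr + 3 * L2 / (mu * re^4)
      c3r_c <- c3r - 12 * L2 / (mu * re^5)
      wr_c <- sqrt(kr_c / mu)
      re - g / kr_c - c3r_c / (4 * mu^2 * wr_c^3)
    } else re - c3r / (4 * mu^2 * wr^3)
  }
  dr_exact <- exact_mean(2.014102) - exact_mean(1.007825)
  dr_cent <- lmzl_mean(2.014102, TRUE) - lmzl_mean(1.007825, TRUE)
  dr_plain <- lmzl_mean(2.014102, FALSE) - lmzl_mean(1.007825, FALSE)
  expect_lt(abs(dr_cent / dr_exact - 1), 0.25)
  expect_lt(abs(dr_plain), abs(dr_exact))    # plain LMZL biased low
  expect_lt(abs(dr_cent / dr_exact - 1), abs(dr_plain / dr_exact - 1))
})
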