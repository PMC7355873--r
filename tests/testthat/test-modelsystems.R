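test_that("the harmonic limit of the Morse bond has no cubic constants", {
  # the a -> 0 limit at fixed curvature is taken analytically by the
  # harmonic fixture variant
  fix <- fix_of("diatomic_morse", harmonic = TRUE)
  ev <- make_evaluators(fix)
  modes <- normal_modes(fix$system, fix$isoA, ev$hessian(fix$system$coords_e))
  cub <- cubic_semidiagonal(ev$hessian, modes)
  expect_lt(max(abs(cub$S)), 1e-10)
})

test_that("fixtures have the expected mode counts and deterministic evaluators", {
  fix <- fix_of("methane_like")
  ev <- make_evaluators(fix)
  modes <- normal_modes(fix$system, fix$isoA, ev$hessian(fix$system$coords_e))
  expect_identical(modes$n_vib, 9L)          # 3N - 6 with N = 5
  # same seed, fresh build: bit-identical evaluator outputs
  f1 <- make_fixture("methane_like", params = list(jitter = 0.1), seed = 42L)
  f2 <- make_fixture("methane_like", params = list(jitter = 0.1), seed = 42L)
  e1 <- make_evaluators(f1); e2 <- make_evaluators(f2)
  x <- fix$system$coords_e
  x[2, 1] <- x[2, 1] + 0.05; x[3, 2] <- x[3, 2] - 0.04   # non-rigid distortion
  expect_identical(e1$energy(x), e2$energy(x))
  expect_identical(e1$sigma(x), e2$sigma(x))
  f3 <- make_fixture("methane_like", params = list(jitter = 0.1), seed = 43L)
  expect_false(identical(make_evaluators(f3)$energy(x), e1$energy(x)))
})

test_that("every fixture's derivatives are internally consistent", {
  for (name in c("diatomic_morse", "xh_heavy", "water_like", "methane_like",
                 "hbond_toy")) {
    fix <- fix_of(name)
    ev <- make_evaluators(fix)
    x <- fix$system$coords_e + 0.013   # off-equilibrium probe point
    g_ana <- ev$gradient(x)
    g_num <- num_grad(ev$energy, x)
    expect_lt(max(abs(g_ana - g_num)), 1e-8)
    H_ana <- ev$hessian(x)
    n3 <- length(g_ana)
    H_num <- matrix(0, n3, n3)
    for (k in seq_len(n3)) {
      y <- x; y[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] <-
        y[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] + 1e-5
      y2 <- x; y2[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] <-
        y2[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] - 1e-5
      H_num[, k] <- (ev$gradient(y) - ev$gradient(y2)) / 2e-5
    }
    expect_lt(max(abs(H_ana - H_num)), 1e-6)
    # the stored geometry is a stationary point
    expect_lt(max(abs(ev$gradient(fix$system$coords_e))), 1e-10)
  }
})

test_that("the hydrogen-bond toy switches its hole morphology with the coupling", {
  # the O-H ... O stretch-stretch coupling controls whether deuteration
  # contracts or expands the O,O distance
  for (cpl in c(-0.06, 0.06)) {
    fix <- fix_of("hbond_toy", coupling = cpl)
    ev <- make_evaluators(fix)
    rep <- vpt2_shift(fix$system, fix$isoA, fix$isoB, ev)
    geo <- dd_geometry_report(fix$system, attr(rep, "dR"), fix$coords, 80)
    doo <- geo$table$delta_f_z[geo$table$coordinate == "r(O,O)"]
    if (cpl < 0) expect_lt(doo, 0) else expect_gt(doo, 0)
  }
})

test_that("the 1D grid oracle reproduces closed forms", {
  # harmonic oscillator: E0 = w/2 and <q^2> = 1/2
  mu_amu <- 1
  mu <- amu_to_au(1)
  w <- cm1_to_au(1000)
  k <- mu * w^2
  l <- 1 / sqrt(mu * w)
  res <- dvr_average(function(x) 0.5 * k * x^2, mu_amu,
                     function(x) (x / l)^2, xlim = c(-1.5, 1.5))
  expect_equal(res$energy, w / 2, tolerance = 1e-9)
  expect_equal(res$mean, 0.5, tolerance = 1e-9)
  # Morse: closed-form ground-state energy
  De <- 0.17; a <- 1.05
  resM <- dvr_average(function(r) De * (1 - exp(-a * r))^2, 1.2,
                      function(r) r, xlim = c(-1, 3.5))
  expect_equal(resM$energy, morse_e0(De, a, amu_to_au(1.2)), tolerance = 1e-8)
  # non-confining potential is rejected
  expect_error(dvr_average(function(x) -x^2, 1, function(x) x, xlim = c(-9, 9)),
               "confin")
})

test_that("VPT2 converges quadratically in the anharmonicity to the grid oracle", {
  # scale the Morse cubic strength at fixed harmonic curvature; the scan
  # sits in the asymptotic regime (small s) where the quadratic error term
  # dominates the next order
  svals <- c(0.4, 0.2, 0.1)
  scan <- sapply(svals, function(s) {
    De0 <- 0.18; a0 <- 1.1
    a <- a0 * s; De <- De0 / s^2
    fix <- fix_of("diatomic_morse", De = De, a = a)
    ev <- make_evaluators(fix)
    modes <- normal_modes(fix$system, fix$isoA, ev$hessian(fix$system$coords_e))
    corr <- vib_correction(modes, cubic_semidiagonal(ev$hessian, modes),
                           property_derivatives(ev$sigma, modes))
    r0 <- 1.8324
    dr_vpt2 <- evaluate_coordinate(fix$ic_set$r12, fix$system$coords_e +
                                     matrix(corr$dR, ncol = 3, byrow = TRUE)) - r0
    mu_amu <- prod(fix$isoA$masses) / sum(fix$isoA$masses)
    Vfun <- function(r) De * (1 - exp(-a * (r - r0)))^2
    dvr_r <- dvr_average(Vfun, mu_amu, function(r) r - r0, xlim = c(0.9, 4.5))
    dvr_s <- dvr_average(Vfun, mu_amu,
                         function(r) 30 - 12 * (r - r0) + 5 * (r - r0)^2,
                         xlim = c(0.9, 4.5))
    dsig_vpt2 <- (corr$delta_harm[["H2"]] + corr$delta_anh[["H2"]]) / 1000
    exact_s <- -(dvr_s$mean - 30)        # delta scale
    c(rel_r = abs(dr_vpt2 / dvr_r$mean - 1),
      err_s = abs(dsig_vpt2 - exact_s))
  })
  slope_r <- stats::coef(stats::lm(log(scan["rel_r", ]) ~ log(svals)))[2]
  slope_s <- stats::coef(stats::lm(log(scan["err_s", ]) ~ log(svals)))[2]
  expect_equal(unname(slope_r), 2, tolerance = 0.15)
  expect_equal(unname(slope_s), 2, tolerance = 0.2)
})

test_that("all four methods coincide in the infinite-frame-mass limit", {
  run <- runs_of("xh_heavy", .cutoff = 1e-3)
  fix <- run$fix
  loc <- loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, run$ev, fix$mobile)
  lmc <- lmzl_shift(fix$system, fix$isoA, fix$isoB, run$ev, fix$mobile,
                    fix$apex, fix$partners, centrifugal = TRUE)
  m <- cbind(run$vpt2$shift_ppb, run$dd$shift_ppb, loc$shift_ppb)
  spread3 <- apply(m, 1, function(x) (max(x) - min(x)) / max(abs(x)))
  expect_lt(max(spread3), 1e-3)        # VPT2 family: essentially exact overlap
  # the separable local model with centrifugal correction joins within the
  # second-order margin measured for this comparison (a few percent; cf. the
  # published local-model benchmarks)
  m4 <- cbind(m, lmc$report$shift_ppb)
  spread4 <- apply(m4, 1, function(x) (max(x) - min(x)) / max(abs(x)))
  expect_lt(max(spread4), 0.05)
})
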