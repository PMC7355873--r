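#' End-to-end isotope-shift drivers
#'
#' Convenience pipelines tying the modules together for one isotopologue pair
#' over one set of evaluators: standard VPT2 by explicit difference, and
#' DD-VPT2 through the difference-dedicated modes.  Both return the same
#' tibble-based report so methods can be compared row by row.
#'
#' @name drivers
NULL

#' @rdname drivers
#' @param system a [mol_system()].
#' @param isoA,isoB the unsubstituted and substituted [isotopologue()]s.
#' @param ev evaluators (e.g. [make_evaluators()]): functions `hessian` and
#'   `sigma`, plus `report_nuclei`.
#' @param h_ff,h_nmr dimensionless step widths for the cubic force field and
#'   the shielding derivatives.
#' @return An `iso_shift_report`; details (mode sets, corrections or the
#'   dd basis) are attached as attribute `"details"`.
#' @export
vpt2_shift <- function(system, isoA, isoB, ev, h_ff = 0.005, h_nmr = 0.05) {
  H0 <- ev$hessian(system$coords_e)
  corr <- lapply(list(isoA, isoB), function(iso) {
    modes <- normal_modes(system, iso, H0,
                          basis_id = paste0("nm:", iso$label))
    cub <- cubic_semidiagonal(ev$hessian, modes, h_ff)
    prop <- property_derivatives(ev$sigma, modes, h_nmr)
    vib_correction(modes, cub, prop)
  })
  rep <- standard_isotope_shift(corr[[1]], corr[[2]], system,
                                report_nuclei = ev$report_nuclei)
  attr(rep, "details") <- list(corrA = corr[[1]], corrB = corr[[2]])
  rep
}

#' @rdname drivers
#' @param cutoff retained-|kappa| threshold for the difference-dedicated
#'   modes (0 retains all).
#' @export
ddvpt2_shift <- function(system, isoA, isoB, ev, cutoff = 1e-3,
                         h_ff = 0.005, h_nmr = 0.05) {
  H0 <- ev$hessian(system$coords_e)
  modesA <- normal_modes(system, isoA, H0, basis_id = paste0("nm:", isoA$label))
  modesB <- normal_modes(system, isoB, H0, basis_id = paste0("nm:", isoB$label))
  jac <- mode_jacobian(modesA, modesB)
  M <- dd_weight_matrix(jac)
  dd <- dd_modes(M, modesA, cutoff = cutoff,
                 substituted = nrow(isoB$substitutions) > 0)
  cub <- cubic_dd_slice(ev$hessian, dd, h_ff)
  prop <- property_derivatives(ev$sigma, dd, h_nmr)
  prop$basis_id <- dd$basis_id
  rep <- dd_isotope_shift(dd, cub, prop, sigma_fun = ev$sigma,
                          report_nuclei = ev$report_nuclei,
                          sub_atoms = isoB$substitutions$atom, h_nmr = h_nmr,
                          labels = c(isoA$label, isoB$label))
  attr(rep, "details") <- list(dd = dd, modesA = modesA, modesB = modesB)
  rep
}

#' Method comparison table
#'
#' Runs several methods on the same system/evaluators and lines their
#' per-nucleus shifts up side by side, with mean signed (MSgD) and
#' root-mean-square deviations against a designated reference method.
#'
#' @inheritParams vpt2_shift
#' @param methods character subset of `c("vpt2", "ddvpt2", "locvpt2",
#'   "lmzl", "lmzl_cent")`.
#' @param reference method name the deviation columns refer to.
#' @param mobile,apex,partners local-model frame (defaults from `fix` if
#'   given).
#' @param fix optional `vib_fixture` supplying system, isotopologues,
#'   evaluators and frame in one go.
#' @param cutoff DD-VPT2 cutoff.
#' @return A tibble: one row per nucleus, one shift column per method, plus a
#'   `glance`-style attribute `"deviations"` (method, MSgD, RMS vs reference).
#' @export
compare_methods <- function(system = fix$system, isoA = fix$isoA,
                            isoB = fix$isoB, ev = NULL,
                            methods = c("vpt2", "ddvpt2", "locvpt2"),
                            reference = methods[1], cutoff = 1e-3,
                            mobile = fix$mobile, apex = fix$apex,
                            partners = fix$partners, fix = NULL,
                            h_ff = 0.005, h_nmr = 0.05) {
  if (is.null(ev)) {
    stopifnot(inherits(fix, "vib_fixture"))
    ev <- make_evaluators(fix)
  }
  runs <- list()
  for (m in methods) {
    runs[[m]] <- switch(m,
      vpt2 = vpt2_shift(system, isoA, isoB, ev, h_ff, h_nmr),
      ddvpt2 = ddvpt2_shift(system, isoA, isoB, ev, cutoff, h_ff, h_nmr),
      locvpt2 = loc_vpt2_shift(system, isoA, isoB, ev, mobile, h_ff, h_nmr),
      lmzl = lmzl_shift(system, isoA, isoB, ev, mobile, apex, partners,
                        centrifugal = FALSE)$report,
      lmzl_cent = lmzl_shift(system, isoA, isoB, ev, mobile, apex, partners,
                             centrifugal = TRUE)$report,
      stop("unknown method: ", m))
  }
  out <- tidy(runs[[1]])[, c("nucleus", "atom", "n_bonds")]
  for (m in methods) out[[m]] <- runs[[m]]$shift_ppb
  devs <- do.call(rbind, lapply(methods, function(m) {
    d <- out[[m]] - out[[reference]]
    tibble::tibble(method = m, MSgD = mean(d), RMS = sqrt(mean(d^2)))
  }))
  attr(out, "deviations") <- devs
  attr(out, "reference") <- reference
  attr(out, "reports") <- runs
  out
}
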