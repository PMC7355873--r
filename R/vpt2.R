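#' Standard VPT2 vibrational corrections
#'
#' Zero-point (T = 0) second-order vibrational corrections to per-nucleus
#' shieldings and to the geometry for one isotopologue.  The harmonic part
#' averages the curvature of the shielding surface over the harmonic ground
#' state; the anharmonic part follows the cubic-force-field displacement of
#' the average geometry (the r_z shift vector) through the shielding gradient:
#' \deqn{\Delta\delta_{harm} = -\tfrac14 \sum_i^{v} D^2\sigma[l_i],\qquad
#'       \Delta R = -\tfrac14 \sum_k^{v} \frac{1}{\omega_k}
#'                  \sum_i^{v} \phi_{iik}\, l_k,\qquad
#'       \Delta\delta_{anh} = -D\sigma[\Delta R],}
#' with \eqn{\phi_{iik}} the semi-diagonal cubic constants in dimensionless
#' coordinates.  The directional derivative in the anharmonic part is
#' decomposed into per-mode components of the gradient table, so it costs no
#' additional evaluator calls.
#'
#' @param modes a [normal_modes()] set.
#' @param cubic a [cubic_semidiagonal()] field in the same (vibrational) basis.
#' @param prop a [property_derivatives()] surface in the same basis.
#' @return A `vib_correction` object: `delta_harm`, `delta_anh` (named, ppb),
#'   `dR` (3N Cartesian r_z shift, bohr), `q_shift` (per-mode expansion
#'   coefficients of `dR`), `label`.
#' @export
vib_correction <- function(modes, cubic, prop) {
  stopifnot(inherits(modes, "normal_modes"), inherits(cubic, "cubic_field"),
            inherits(prop, "property_surface"))
  check_same_basis(modes, cubic, prop)
  nv <- modes$n_vib
  if (nrow(cubic$S) != nv) stop("cubic field dimension does not match n_vib")
  Lv <- modes$L[, modes$kind == "v", drop = FALSE]
  delta_harm <- -0.25 * rowSums(prop$curv) * 1000           # ppm -> ppb
  q_shift <- -0.25 * colSums(cubic$S) / modes$omega         # <q_k>
  dR <- drop(Lv %*% q_shift)
  delta_anh <- -drop(prop$grad %*% q_shift) * 1000
  structure(list(delta_harm = delta_harm, delta_anh = delta_anh,
                 dR = dR, q_shift = q_shift, label = modes$iso$label,
                 modes = modes),
            class = "vib_correction")
}

#' @export
print.vib_correction <- function(x, ...) {
  cat("<vib_correction> ", x$label, "\n", sep = "")
  print(round(cbind(harm_ppb = x$delta_harm, anh_ppb = x$delta_anh), 2))
  invisible(x)
}

#' Isotope shift by explicit difference of two VPT2 corrections
#'
#' Per-nucleus difference substituted-minus-unsubstituted,
#' `n-Delta-delta = Delta-delta(B) - Delta-delta(A)` (which equals
#' `sigma(A) - sigma(B)` in the usual shielding convention), together with the
#' isotope effect on the r_z geometry `Delta R(B) - Delta R(A)`.  The bond
#' count `n` of each reporting nucleus is the shortest bond-path distance from
#' the substitution site.
#'
#' @param corrA,corrB [vib_correction()]s of the unsubstituted (A) and
#'   substituted (B) isotopologues of the same system.
#' @param system the shared [mol_system()] (for bond topology).
#' @param report_nuclei data frame with columns `label` and `atom` mapping the
#'   shielding entries to atom indices; defaults to the nuclei on the
#'   correction objects.
#' @param method method label recorded on the report.
#' @return An `iso_shift_report`: a tibble with columns `nucleus`, `atom`,
#'   `n_bonds`, `shift_ppb`, `harm_ppb`, `anh_ppb`, plus attributes `dR`
#'   (Cartesian isotope effect on the r_z geometry, bohr) and `method`.
#' @export
standard_isotope_shift <- function(corrA, corrB, system,
                                   report_nuclei = NULL, method = "VPT2") {
  stopifnot(inherits(corrA, "vib_correction"), inherits(corrB, "vib_correction"))
  if (!identical(names(corrA$delta_harm), names(corrB$delta_harm)))
    stop("mismatched reporting nuclei between isotopologues")
  harm <- corrB$delta_harm - corrA$delta_harm
  anh <- corrB$delta_anh - corrA$delta_anh
  dR <- corrB$dR - corrA$dR
  # report the r_z isotope effect in a canonical (Eckart) gauge: the
  # difference of two isotopologues' dR vectors carries a rigid-body
  # component from the differing Eckart frames, invisible to any
  # rotation/translation-invariant property.  (Local-mode corrections have a
  # frozen environment and are left untouched.)
  if (!isTRUE(corrA$modes$local))
    dR <- eckart_project(system, corrA$modes$masses_au, dR)
  sub_atoms <- unique(c(corrA$modes$iso$substitutions$atom,
                        corrB$modes$iso$substitutions$atom))
  new_shift_report(system, names(harm), harm, anh, dR, sub_atoms,
                   report_nuclei, method,
                   labels = c(corrA$label, corrB$label))
}

new_shift_report <- function(system, nuclei, harm, anh, dR, sub_atoms,
                             report_nuclei = NULL, method, labels = c("A", "B")) {
  if (is.null(report_nuclei)) {
    atom <- suppressWarnings(as.integer(gsub("[^0-9]", "", nuclei)))
  } else {
    atom <- report_nuclei$atom[match(nuclei, report_nuclei$label)]
  }
  n_bonds <- rep(NA_integer_, length(nuclei))
  if (!is.null(system$bonds) && length(sub_atoms)) {
    d <- topo_atom_distances(system$bonds, system$n_atoms, sub_atoms)
    n_bonds <- ifelse(is.na(atom), NA_integer_, as.integer(d[atom]))
  }
  out <- tibble::tibble(nucleus = nuclei, atom = atom, n_bonds = n_bonds,
                        shift_ppb = harm + anh, harm_ppb = harm, anh_ppb = anh)
  attr(out, "dR") <- dR
  attr(out, "method") <- method
  attr(out, "isotopologues") <- labels
  class(out) <- c("iso_shift_report", class(out))
  out
}

#' @export
print.iso_shift_report <- function(x, ...) {
  cat("# Isotope-shift report [", attr(x, "method"), "] ",
      paste(attr(x, "isotopologues"), collapse = " -> "), "\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an isotope-shift report into a plain tibble
#'
#' @param x an `iso_shift_report`.
#' @param ... unused.
#' @return A tibble with one row per reporting nucleus.
#' @export
tidy.iso_shift_report <- function(x, ...) {
  out <- x
  attr(out, "dR") <- NULL
  class(out) <- setdiff(class(out), "iso_shift_report")
  tibble::as_tibble(out)
}

#' One-row summary of an isotope-shift report
#'
#' @inheritParams tidy.iso_shift_report
#' @return A one-row tibble: method, number of nuclei, largest-magnitude
#'   shift, and the norm of the r_z isotope-effect vector (bohr).
#' @export
glance.iso_shift_report <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 n_nuclei = nrow(x),
                 max_abs_shift_ppb = max(abs(x$shift_ppb)),
                 dR_norm_bohr = sqrt(sum(attr(x, "dR")^2)))
}
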