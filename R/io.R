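#' Vibrational job files, Molden and XYZ export
#'
#' Jobs are plain versioned YAML ("vibhole-job/1"): diffable metadata plus the
#' (desk-scale) numeric content inline.  A job either names a built-in
#' fixture (`source: {type: fixture}`) or spells out an explicit model --
#' geometry, internal-coordinate force-field terms and shielding surfaces --
#' in the same vocabulary the fixtures use (`source: {type: model}`).
#' Unknown keys are rejected with their location; omitted numeric options
#' get the package defaults (`h_ff` 0.005, `h_nmr` 0.05, `cutoff` 1e-3,
#' `lambda_viz` 400).
#'
#' @name io_job
NULL

job_defaults <- list(h_ff = 0.005, h_nmr = 0.05, cutoff = 1e-3,
                     lambda_viz = 400)

job_known_keys <- list(
  top = c("schema", "method", "source", "isotopologues", "options",
          "local_frame", "output"),
  source = c("type", "name", "params", "seed", "system", "force_field",
             "sigma", "internal_coords", "report_nuclei"),
  isotopologues = c("labels", "masses_a", "masses_b"),
  options = c("h_ff", "h_nmr", "cutoff", "lambda_viz"),
  local_frame = c("mobile", "apex", "partners"),
  output = c("report", "molden", "xyz"))

check_keys <- function(x, where) {
  unknown <- setdiff(names(x), job_known_keys[[where]])
  if (length(unknown))
    stop("unknown key(s) at job ", where, ": ", paste(unknown, collapse = ", "))
}

#' Read and validate a vibrational job file
#'
#' @param path YAML file path.
#' @return A validated `vib_job` list with defaults filled in.
#' @export
read_vib_job <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, "top")
  if (!identical(raw$schema, "vibhole-job/1"))
    stop("unsupported schema at job schema: ", raw$schema %||% "<missing>")
  if (!raw$method %in% c("vpt2", "ddvpt2", "locvpt2", "lmzl", "lmzl_cent"))
    stop("unknown method at job method: ", raw$method)
  check_keys(raw$source, "source")
  if (!is.null(raw$options)) check_keys(raw$options, "options")
  if (!is.null(raw$isotopologues)) check_keys(raw$isotopologues, "isotopologues")
  if (!is.null(raw$local_frame)) check_keys(raw$local_frame, "local_frame")
  if (!is.null(raw$output)) check_keys(raw$output, "output")
  if (!is.null(raw$isotopologues)) {
    for (mm in c("masses_a", "masses_b")) {
      m <- raw$isotopologues[[mm]]
      if (!is.null(m) && any(unlist(m) <= 0))
        stop("non-positive mass at job isotopologues/", mm)
    }
  }
  opts <- utils::modifyList(job_defaults, raw$options %||% list())
  raw$options <- opts
  class(raw) <- "vib_job"
  raw
}

#' @rdname read_vib_job
#' @param job a `vib_job`.
#' @export
write_vib_job <- function(job, path) {
  out <- unclass(job)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

job_model <- function(job) {
  src <- job$source
  if (identical(src$type, "fixture")) {
    fix <- make_fixture(src$name, params = src$params %||% list(),
                        seed = src$seed %||% 1L)
  } else if (identical(src$type, "model")) {
    ics <- lapply(src$internal_coords, function(ic) {
      at <- as.integer(unlist(ic$atoms))
      switch(ic$kind,
             bond = ic_bond(at[1], at[2], ic$label %||% NULL),
             angle = ic_angle(at[1], at[2], at[3], ic$label %||% NULL),
             azimuth = ic_azimuth(at[1], at[2], at[3], at[4], ic$label %||% NULL),
             altitude = ic_altitude(at[1], at[2], at[3], at[4], ic$label %||% NULL),
             stop("unknown coordinate kind in job model: ", ic$kind))
    })
    ff <- lapply(src$force_field, function(tm) {
      if (isTRUE(tm$morse)) morse_term(tm$coords, tm$De, tm$a)
      else poly_term(unlist(tm$coords), unlist(tm$pow), tm$coef)
    })
    sig <- lapply(src$sigma, function(s)
      list(const = s$const, terms = lapply(s$terms, function(tm)
        poly_term(unlist(tm$coords), unlist(tm$pow), tm$coef))))
    sys <- mol_system(unlist(src$system$symbols),
                      do.call(rbind, src$system$coords_bohr),
                      bonds = if (!is.null(src$system$bonds))
                        do.call(rbind, src$system$bonds))
    rn <- if (!is.null(src$report_nuclei))
      data.frame(label = vapply(src$report_nuclei, `[[`, "", "label"),
                 atom = vapply(src$report_nuclei, function(x)
                   as.integer(x$atom), 0L))
    else data.frame(label = names(sig), atom = seq_along(sig))
    masses <- unlist(job$isotopologues$masses_a)
    fix <- list(system = sys,
                isoA = isotopologue(sys, masses = masses,
                                    label = job$isotopologues$labels[[1]] %||% "A"),
                isoB = isotopologue(sys,
                                    masses = unlist(job$isotopologues$masses_b),
                                    base_masses = masses,
                                    label = job$isotopologues$labels[[2]] %||% "B"),
                ic_set = ics,
                ic_ref = {
                  r <- vapply(ics, evaluate_coordinate, 0, x = sys$coords_e)
                  names(r) <- names(ics); r
                },
                ff = ff, sigma = sig, report_nuclei = rn,
                mobile = job$local_frame$mobile,
                apex = job$local_frame$apex,
                partners = unlist(job$local_frame$partners),
                coords = ics[vapply(ics, function(ic) ic$kind == "bond", TRUE)],
                name = "job-model")
    class(fix) <- "vib_fixture"
  } else stop("unknown source type at job source/type: ", src$type %||% "<missing>")
  if (!is.null(job$isotopologues) && identical(src$type, "fixture")) {
    ma <- job$isotopologues$masses_a; mb <- job$isotopologues$masses_b
    if (!is.null(ma))
      fix$isoA <- isotopologue(fix$system, masses = unlist(ma),
                               label = job$isotopologues$labels[[1]] %||% "A")
    if (!is.null(mb))
      fix$isoB <- isotopologue(fix$system, masses = unlist(mb),
                               base_masses = unlist(ma) %||% fix$isoA$masses,
                               label = job$isotopologues$labels[[2]] %||% "B")
  }
  if (!is.null(job$local_frame)) {
    fix$mobile <- job$local_frame$mobile %||% fix$mobile
    fix$apex <- job$local_frame$apex %||% fix$apex
    fix$partners <- unlist(job$local_frame$partners) %||% fix$partners
  }
  fix
}

#' Run a vibrational job
#'
#' @param job a `vib_job` (from [read_vib_job()]) or a path to one.
#' @return List: `report` (an `iso_shift_report`), `fixture`, `counts`
#'   (evaluator call counts), and for DD runs the dd basis.  Requested output
#'   files (report table, Molden modes, exaggerated XYZ structure) are
#'   written as side effects.
#' @export
run_vib_job <- function(job) {
  if (is.character(job)) job <- read_vib_job(job)
  fix <- job_model(job)
  ev <- make_evaluators(fix)
  o <- job$options
  res <- switch(job$method,
    vpt2 = vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, o$h_ff, o$h_nmr),
    ddvpt2 = ddvpt2_shift(fix$system, fix$isoA, fix$isoB, ev, o$cutoff,
                          o$h_ff, o$h_nmr),
    locvpt2 = loc_vpt2_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile,
                             o$h_ff, o$h_nmr),
    lmzl = lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile,
                      fix$apex, fix$partners, centrifugal = FALSE)$report,
    lmzl_cent = lmzl_shift(fix$system, fix$isoA, fix$isoB, ev, fix$mobile,
                           fix$apex, fix$partners, centrifugal = TRUE)$report)
  out <- list(report = res, fixture = fix, counts = evaluator_counts(ev))
  if (!is.null(job$output$report))
    write_report_table(res, job$output$report)
  if (!is.null(job$output$molden)) {
    dd <- attr(res, "details")$dd
    if (!is.null(dd)) write_molden(dd, job$output$molden)
    else {
      H0 <- ev$hessian(fix$system$coords_e)
      write_molden(normal_modes(fix$system, fix$isoA, H0), job$output$molden)
    }
  }
  if (!is.null(job$output$xyz)) {
    dR <- attr(res, "dR")
    viz <- fix$system$coords_e +
      (job$options$lambda_viz) * matrix(dR, ncol = 3, byrow = TRUE)
    write_xyz(fix$system$atom_symbols, viz, job$output$xyz,
              comment = paste0("R_e + ", job$options$lambda_viz, " * dR (",
                               attr(res, "method"), ")"))
  }
  out
}

write_report_table <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(report, "method")), con)
  writeLines(paste0("# isotopologues: ",
                    paste(attr(report, "isotopologues"), collapse = " -> ")), con)
  utils::write.table(as.data.frame(tidy(report)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

element_number <- function(sym) {
  tab <- c(H = 1, D = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
           F = 9, Ne = 10, Na = 11, Mg = 12, Si = 14, P = 15, S = 16,
           Cl = 17, Ar = 18)
  out <- unname(tab[sym])
  out[is.na(out)] <- 0
  out
}

#' Write modes to a Molden frequency file
#'
#' Standard `[FREQ]` / `[FR-COORD]` / `[FR-NORM-COORD]` blocks.  For a
#' difference-dedicated basis the retained modes are written with their
#' kappa weights in an extra `[DD-KAPPA]` block (ignored by standard
#' viewers) and the `[FREQ]` entries carry the kappa values, since dd modes
#' have no frequency of their own.
#'
#' @param modes a [normal_modes()] set or a [dd_modes()] basis.
#' @param path output file.
#' @export
write_molden <- function(modes, path) {
  if (inherits(modes, "dd_basis")) {
    sys <- modes$system
    L <- modes$dd_L[, modes$retained, drop = FALSE]
    freq <- modes$kappa[modes$retained]
    kap <- modes$kappa[modes$retained]
  } else {
    stopifnot(inherits(modes, "normal_modes"))
    sys <- modes$system
    L <- modes$L[, modes$kind == "v", drop = FALSE]
    freq <- modes$freq_cm1
    kap <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[Molden Format]", con)
  writeLines("[Atoms] AU", con)
  z <- element_number(sys$atom_symbols)
  for (i in seq_len(sys$n_atoms))
    writeLines(sprintf("%-3s %4d %4d %18.10f %18.10f %18.10f",
                       sys$atom_symbols[i], i, z[i],
                       sys$coords_e[i, 1], sys$coords_e[i, 2],
                       sys$coords_e[i, 3]), con)
  writeLines("[FREQ]", con)
  writeLines(sprintf("%18.10f", freq), con)
  writeLines("[FR-COORD]", con)
  for (i in seq_len(sys$n_atoms))
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", sys$atom_symbols[i],
                       sys$coords_e[i, 1], sys$coords_e[i, 2],
                       sys$coords_e[i, 3]), con)
  writeLines("[FR-NORM-COORD]", con)
  for (k in seq_len(ncol(L))) {
    writeLines(paste("vibration", k), con)
    m <- matrix(L[, k], ncol = 3, byrow = TRUE)
    for (i in seq_len(nrow(m)))
      writeLines(sprintf(" %18.10f %18.10f %18.10f", m[i, 1], m[i, 2], m[i, 3]),
                 con)
  }
  if (!is.null(kap)) {
    writeLines("[DD-KAPPA]", con)
    writeLines(sprintf("%18.10e", kap), con)
  }
  invisible(path)
}

#' Parse a Molden frequency file written by [write_molden()]
#'
#' @param path file path.
#' @return List with `freq`, `coords` (N x 3, bohr), `modes` (3N x n) and
#'   `kappa` (or NULL).
#' @export
read_molden <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i <- grep(paste0("^\\[", name, "\\]"), ln)
    if (!length(i)) return(NULL)
    j <- grep("^\\[", ln)
    j <- j[j > i[1]]
    ln[(i[1] + 1):(if (length(j)) j[1] - 1 else length(ln))]
  }
  freq <- as.numeric(sec("FREQ"))
  crd <- do.call(rbind, lapply(strsplit(trimws(sec("FR-COORD")), "\\s+"),
                               function(p) as.numeric(p[2:4])))
  body <- sec("FR-NORM-COORD")
  starts <- grep("vibration", body)
  modes <- sapply(seq_along(starts), function(s) {
    from <- starts[s] + 1
    to <- if (s < length(starts)) starts[s + 1] - 1 else length(body)
    as.vector(t(do.call(rbind, lapply(strsplit(trimws(body[from:to]), "\\s+"),
                                      as.numeric))))
  })
  kap <- sec("DD-KAPPA")
  list(freq = freq, coords = crd, modes = matrix(modes, nrow = 3 * nrow(crd)),
       kappa = if (!is.null(kap)) as.numeric(kap))
}

#' Write an XYZ structure file
#'
#' @param symbols element labels.
#' @param geometry_bohr N x 3 geometry, bohr (written in angstrom).
#' @param path output file.
#' @param comment second-line comment.
#' @export
write_xyz <- function(symbols, geometry_bohr, path, comment = "") {
  g <- bohr_to_ang(as.matrix(geometry_bohr))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(symbols)), con)
  writeLines(comment, con)
  for (i in seq_along(symbols))
    writeLines(sprintf("%-3s %15.8f %15.8f %15.8f", symbols[i],
                       g[i, 1], g[i, 2], g[i, 3]), con)
  invisible(path)
}
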