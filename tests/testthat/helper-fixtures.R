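options(testthat.progress.max_fails = 1000L)

# shared fixtures and slow pipeline results, built once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fix_of <- function(.fixture, ...) {
  params <- list(...)
  key <- paste0("fix:", .fixture, ":", paste(deparse(params), collapse = ""))
  cached(key, make_fixture(.fixture, params = params))
}

# full VPT2 / DD pipeline results for a fixture (heaviest shared objects)
runs_of <- function(.fixture, .cutoff = 0, ...) {
  params <- list(...)
  key <- paste0("run:", .fixture, ":", .cutoff, ":", paste(deparse(params), collapse = ""))
  cached(key, {
    fix <- do.call(fix_of, c(list(.fixture), params))
    ev <- make_evaluators(fix)
    list(fix = fix, ev = ev,
         vpt2 = vpt2_shift(fix$system, fix$isoA, fix$isoB, ev),
         dd = ddvpt2_shift(fix$system, fix$isoA, fix$isoB, ev, cutoff = .cutoff))
  })
}

# Morse level formula: E_n = w (n + 1/2) - w x_e (n + 1/2)^2, atomic units
morse_e0 <- function(De, a, mu_au) {
  w <- a * sqrt(2 * De / mu_au)
  wxe <- a^2 / (2 * mu_au)
  w / 2 - wxe / 4
}

# central-difference gradient of a scalar function of an N x 3 geometry
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (k in seq_along(g)) {
    xp <- x; xp[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] <-
      xp[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] + h
    xm <- x; xm[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] <-
      xm[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# 7-point central difference for one partial derivative
fd7 <- function(f, x, atom, comp, h = 1e-3) {
  shift <- function(s) { y <- x; y[atom, comp] <- y[atom, comp] + s; y }
  ( -f(shift(-3 * h)) + 9 * f(shift(-2 * h)) - 45 * f(shift(-h)) +
     45 * f(shift(h)) - 9 * f(shift(2 * h)) + f(shift(3 * h))) / (60 * h)
}

rand_rotation <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3])), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
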