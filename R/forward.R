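#' Free-space 2-D Helmholtz Green's function
#'
#' Outgoing-wave fundamental solution `-(i/4) H0^(1)(k d)` with
#' `H0^(1) = J0 + i Y0`. Vectorized over `d`.
#'
#' @param k wavenumber in rad/m, positive.
#' @param d source-observer distance in m, strictly positive (self terms are
#'   handled by the cell quadrature in [assemble_green_operators()], not
#'   here).
#' @return complex value(s).
#' @export
green0 <- function(k, d) {
  if (any(k <= 0)) stop("wavenumber k must be positive", call. = FALSE)
  if (any(d <= 0)) stop("green0 requires d > 0 (no self terms)", call. = FALSE)
  x <- k * d
  -0.25i * (besselJ(x, 0) + 1i * besselY(x, 0))   # preserves dim attributes
}

# hankel functions of order 1 (first kind), used by the cell quadrature
hankel1_1 <- function(x) complex(real = besselJ(x, 1), imaginary = besselY(x, 1))

#' Discretized Green's operators for one grid and wavenumber
#'
#' Method-of-moments assembly of the pixel-to-pixel operator `C` (symmetric,
#' `N^2 x N^2`) and pixel-to-receiver operator `B` (`Nr x N^2`).
#'
#' Two quadratures are provided for the cell integrals. The default
#' `"midpoint"` point-matching rule weights each source cell by its area:
#' entries are `green0(k, d) * h^2`. The `"disk"` rule replaces each square
#' cell by the equal-area disk of radius `a = h/sqrt(pi)` and integrates the
#' Green's function exactly over it, giving the cell factor
#' `(2 pi a / k) J1(k a)` (which tends to `h^2` as `k h -> 0`).
#'
#' The singular self-cell `C_ii` is either excluded (`self_cell = "zero"`,
#' default -- the point-matching convention of the reconstruction algorithm
#' this package implements) or set to the analytic equal-area-disk
#' self-integral `-(i/4)(2 pi a / k) H1^(1)(k a) + 1/k^2`
#' (`self_cell = "disk"`).
#'
#' Sampling coarser than one pixel per wavelength (`k h >= 2 pi`) is
#' refused; at least two pixels per wavelength (`k h < pi`) is recommended
#' when the operators feed the exact forward solve.
#'
#' @param grid a `uct_grid`.
#' @param layout a `uct_layout` (receivers used for `B`).
#' @param k wavenumber rad/m.
#' @param quadrature cell quadrature for all entries, see above.
#' @param self_cell treatment of the singular self term, see above.
#' @return object of class `uct_green`: list with `k`, `C`, `B`.
#' @export
assemble_green_operators <- function(grid, layout, k,
                                     quadrature = c("midpoint", "disk"),
                                     self_cell = c("zero", "disk")) {
  quadrature <- match.arg(quadrature)
  self_cell <- match.arg(self_cell)
  if (k <= 0) stop("wavenumber k must be positive", call. = FALSE)
  if (k * grid$h >= 2 * pi) {
    stop(sprintf(
      "grid too coarse for wavenumber: k*h = %.3g >= 2*pi (under one pixel per wavelength)",
      k * grid$h), call. = FALSE)
  }
  a <- grid$h / sqrt(pi)
  w <- switch(quadrature,
              midpoint = grid$h^2,
              disk = (2 * pi * a / k) * besselJ(k * a, 1))
  gx <- grid$centers[, 1]; gy <- grid$centers[, 2]
  D <- sqrt(outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2)
  C <- matrix(0i, grid$N^2, grid$N^2)
  off <- D > 0
  C[off] <- w * green0(k, D[off])
  diag(C) <- switch(self_cell,
                    zero = 0i,
                    disk = -0.25i * (2 * pi * a / k) * hankel1_1(k * a) +
                           1 / k^2)
  DB <- point_grid_distances(layout$receiver_positions, grid)
  B <- w * green0(k, DB)
  structure(list(k = k, C = C, B = B), class = "uct_green")
}

#' Incident field of one transmitter on the grid
#'
#' Zero-order Bessel beam: pixel `j` receives `J0(k0 * |r_j - r_t|)` where
#' `r_t` is the transmitter position. Real-valued, magnitude at most 1.
#'
#' @param layout a `uct_layout`.
#' @param grid a `uct_grid`.
#' @param k0 background wavenumber rad/m.
#' @param transmitter_index 1-based index into the layout.
#' @return real vector of length `N^2`.
#' @export
incident_field <- function(layout, grid, k0, transmitter_index) {
  nt <- nrow(layout$transmitter_positions)
  if (transmitter_index < 1 || transmitter_index > nt) {
    stop("transmitter index out of range", call. = FALSE)
  }
  d <- point_grid_distances(
    layout$transmitter_positions[transmitter_index, , drop = FALSE], grid)
  besselJ(as.vector(d) * k0, 0)
}

# incident fields of all transmitters, as an N^2 x Nt matrix
incident_matrix <- function(layout, grid, k0) {
  d <- point_grid_distances(layout$transmitter_positions, grid)
  t(besselJ(d * k0, 0))
}

#' Total field inside the ROI by method of moments
#'
#' Solves the discretized Lippmann-Schwinger system
#' `(I - C D(G)) Gamma = Gamma_inc` for the total pressure on the grid, where
#' `D(G)` is the diagonal matrix of object-function values. `incident` may be
#' a vector (one transmitter) or an `N^2 x Nt` matrix (all transmitters share
#' one LU factorization).
#'
#' @param ops a `uct_green`.
#' @param G complex/numeric object-function vector of length `N^2`.
#' @param incident complex/numeric vector or matrix of incident field(s).
#' @return total field(s), same shape as `incident`.
#' @export
solve_total_field <- function(ops, G, incident) {
  n <- ncol(ops$C)
  if (length(G) != n) stop("object function has wrong length", call. = FALSE)
  A <- diag(n) - ops$C * matrix(G, nrow = n, ncol = n, byrow = TRUE)
  sol <- tryCatch(solve(A, incident + 0i),
                  error = function(e) {
                    stop("total-field system is singular or ill-conditioned ",
                         "(reciprocal condition estimate ",
                         format(rcond(A), digits = 3), "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  sol
}

#' Total field by the first-order Born recursion
#'
#' Single-scattering approximation of the total pressure:
#' `Gamma = (I + C D(G)) Gamma_inc`, i.e. the incident field plus one pass
#' of scattering off the object function. This is the field convention of
#' the reconstruction algorithm itself (its forward equations are written in
#' the first-Born approximation); the exact alternative is
#' [solve_total_field()]. Agrees with the exact solve to second order in the
#' contrast.
#'
#' @param ops a `uct_green`.
#' @param G object-function vector of length `N^2`.
#' @param incident vector or `N^2 x Nt` matrix of incident field(s).
#' @return total field(s), same shape as `incident`.
#' @export
born_total_field <- function(ops, G, incident) {
  n <- ncol(ops$C)
  if (length(G) != n) stop("object function has wrong length", call. = FALSE)
  incident + ops$C %*% (G * (incident + 0i))
}

# field dispatcher shared by simulation and inversion
total_field <- function(ops, G, incident, field_mode) {
  switch(field_mode,
         born = born_total_field(ops, G, incident),
         full = solve_total_field(ops, G, incident),
         stop("unknown field_mode: ", field_mode, call. = FALSE))
}

#' Scattered field at the receivers
#'
#' Evaluates `Gamma_sc = B D(G) Gamma` for one transmitter's total field.
#'
#' @param ops a `uct_green`.
#' @param G object-function vector of length `N^2`.
#' @param total_field total field vector of length `N^2`.
#' @return complex vector of length `Nr`.
#' @export
predict_scattered <- function(ops, G, total_field) {
  if (length(G) != ncol(ops$B) || length(total_field) != ncol(ops$B)) {
    stop("shape mismatch between operators, G and total field", call. = FALSE)
  }
  as.vector(ops$B %*% (G * total_field))
}

# run RNG-consuming code under a local, restored seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Additive measurement noise
#'
#' Adds i.i.d. circular complex Gaussian noise whose per-element standard
#' deviation (square root of `E|n|^2`) equals `noise_pct` times the RMS
#' magnitude of the clean values. Deterministic under a fixed seed and leaves
#' the caller's RNG state untouched.
#'
#' @param values complex vector.
#' @param noise_pct noise fraction, `>= 0`.
#' @param seed integer seed.
#' @return complex vector of the same length.
#' @export
add_noise <- function(values, noise_pct, seed) {
  if (noise_pct < 0) stop("noise_pct must be >= 0", call. = FALSE)
  if (noise_pct == 0 || length(values) == 0) return(values)
  s <- noise_pct * sqrt(mean(Mod(values)^2))
  n <- length(values)
  with_seed(seed, {
    values + complex(real = stats::rnorm(n, 0, s / sqrt(2)),
                     imaginary = stats::rnorm(n, 0, s / sqrt(2)))
  })
}

#' Simulate one full measurement sweep
#'
#' For each transmitter in turn: incident Bessel beam, total field against
#' the phantom's object function at the given frequency (Born recursion or
#' exact solve per `config$field_mode`), scattered field at all receivers.
#' Values are stacked transmitter-major (all receivers of transmitter 1,
#' then transmitter 2, ...) and measurement noise is added last. This
#' mirrors the acquisition protocol in which a single transmitter fires at a
#' time while every receiver listens.
#'
#' The noise fraction is referenced to the mean measurement magnitude
#' (`config$noise_ref = "mean_abs"`, default) or to the RMS magnitude
#' (`"rms"`); [add_noise()] itself always works on the RMS scale, so the
#' fraction is rescaled accordingly before the call.
#'
#' @param map phantom `uct_map` (defined on the simulation grid).
#' @param config a `uct_config` (`c0` sets the background wavenumber;
#'   `field_mode` and `noise_ref` select the forward and noise conventions).
#' @param layout a `uct_layout`.
#' @param frequency operating frequency Hz.
#' @param noise_pct noise fraction; default taken from `config`.
#' @param seed noise seed; default derived from `config$seed` and the
#'   frequency's index so the two frequencies get independent noise.
#' @return object of class `uct_measurements`: list with `frequency`,
#'   `values` (complex, length `Nt*Nr`, transmitter-major), `Nt`, `Nr`,
#'   `noise_pct`, `seed`.
#' @export
simulate_measurements <- function(map, config, layout, frequency,
                                  noise_pct = config$noise_pct,
                                  seed = noise_seed(config$seed, frequency,
                                                    config)) {
  k0 <- 2 * pi * frequency / config$c0
  ops <- assemble_green_operators(map$grid, layout, k0)
  G <- object_function(map, frequency)
  inc <- incident_matrix(layout, map$grid, k0)
  tot <- total_field(ops, G, inc, config$field_mode)
  pred <- ops$B %*% (G * tot)               # Nr x Nt, one column per transmitter
  clean <- as.vector(pred)                  # transmitter-major stacking
  rms <- sqrt(mean(Mod(clean)^2))
  eff_pct <- if (config$noise_ref == "mean_abs" && rms > 0) {
    noise_pct * mean(Mod(clean)) / rms
  } else {
    noise_pct
  }
  structure(list(frequency = frequency,
                 values = add_noise(clean, eff_pct, seed),
                 Nt = nrow(layout$transmitter_positions),
                 Nr = nrow(layout$receiver_positions),
                 noise_pct = noise_pct, seed = seed),
            class = "uct_measurements")
}

# deterministic per-frequency noise seed: f1 and f2 sweeps must be
# independent draws while still flowing from the single scenario seed
noise_seed <- function(base_seed, frequency, config) {
  idx <- if (isTRUE(all.equal(frequency, config$f1))) 1L
         else if (isTRUE(all.equal(frequency, config$f2))) 2L
         else 3L
  as.integer((as.numeric(base_seed) * 7 + idx * 104729) %% 2147483647)
}

#' Write / read a measurement set as plain text
#'
#' CSV with columns `transmitter_index`, `receiver_index`, `real`, `imag`
#' (full 17-significant-digit precision, so the round trip is exact to
#' double precision), plus a JSON sidecar `<path>.json` with `frequency`,
#' `Nt`, `Nr`, `noise_pct` and `seed`.
#'
#' @param meas a `uct_measurements`.
#' @param path CSV file path.
#' @return `read_measurements()` returns a `uct_measurements`.
#' @export
write_measurements <- function(meas, path) {
  ti <- rep(seq_len(meas$Nt), each = meas$Nr)
  ri <- rep(seq_len(meas$Nr), times = meas$Nt)
  lines <- c("transmitter_index,receiver_index,real,imag",
             sprintf("%d,%d,%.17g,%.17g", ti, ri,
                     Re(meas$values), Im(meas$values)))
  writeLines(lines, path)
  meta <- list(frequency = meas$frequency, Nt = meas$Nt, Nr = meas$Nr,
               noise_pct = meas$noise_pct, seed = meas$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  ord <- order(tab$transmitter_index, tab$receiver_index)
  tab <- tab[ord, ]
  structure(list(frequency = meta$frequency,
                 values = complex(real = tab$real, imaginary = tab$imag),
                 Nt = meta$Nt, Nr = meta$Nr,
                 noise_pct = meta$noise_pct, seed = meta$seed),
            class = "uct_measurements")
}
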