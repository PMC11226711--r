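#' Scenario configuration for a tomography experiment
#'
#' Bundles every physical and algorithmic parameter of one circular-array
#' ultrasound tomography experiment: the two operating frequencies, background
#' sound speed, coarse and fine grid sides, transducer counts and radii, region
#' of interest (ROI) size, phantom geometry, noise level and regularization
#' policy. Defaults reproduce the single-disk benchmark scenario: a 7.3 mm
#' disk of 30% sound contrast imaged at 1 and 2 MHz by 8 transmitters on a
#' 50 mm circle and 59 receivers on a 60 mm circle, reconstructed on a 20x20
#' grid (coarse stage 10x10) over 8 iterations with 10% measurement noise.
#'
#' @param f1,f2 operating frequencies in Hz, `f2 > f1 > 0`. The low frequency
#'   is used by the frequency-hopping stages, the high one for the final
#'   resolution.
#' @param c0 background sound speed in m/s (soft-tissue convention 1540).
#' @param N1,N2 coarse and fine grid side pixel counts; the resolution-turning
#'   hop doubles the side, so `N2 = 2 * N1` is required.
#' @param Nt,Nr transmitter and receiver counts.
#' @param Rt,Rr transmitter/receiver circle radii in m; both must exceed
#'   `L/2` so all transducers sit outside the ROI.
#' @param L ROI side length in m. The default inscribes the benchmark disk.
#' @param disk_diameter phantom disk diameter in m.
#' @param contrast_pct sound contrast as a fraction: the inclusion speed is
#'   `c1 = c0 * (1 + contrast_pct)`.
#' @param noise_pct measurement noise level as a fraction of the signal RMS
#'   (circular complex Gaussian), `0 <= noise_pct < 1`.
#' @param seed integer seed; all randomness in an experiment flows from it.
#' @param gamma_mode `"auto"` to pick the Tikhonov parameter from the leading
#'   singular value and current residual each iteration, `"fixed"` to always
#'   use `gamma_fixed`.
#' @param gamma_fixed regularization parameter used when `gamma_mode="fixed"`
#'   (and as fallback when the measured norm is zero).
#' @param rre_mode normalization of the relative residual error metric, see
#'   [rre()].
#' @param rre_on which per-pixel quantity the RRE compares: the
#'   frequency-independent contrast `chi` (object-function scale, default) or
#'   the fractional sound-speed `contrast`.
#' @param field_mode forward/field model used for data synthesis and the
#'   per-iteration field refresh: `"born"` (first-order Born recursion,
#'   default -- the reconstruction algorithm's own convention) or `"full"`
#'   (exact method-of-moments solve).
#' @param noise_ref reference scale for the noise fraction: `"mean_abs"`
#'   (mean measurement magnitude, default) or `"rms"` (root-mean-square
#'   magnitude).
#' @return an object of class `uct_config` (a validated named list).
#' @seealso [build_layout()], [build_grid()], [run_scheme()]
#' @export
scenario_config <- function(f1 = 1e6, f2 = 2e6, c0 = 1540,
                            N1 = 10, N2 = 20, Nt = 8, Nr = 59,
                            Rt = 0.050, Rr = 0.060,
                            L = 7.3e-3, disk_diameter = 7.3e-3,
                            contrast_pct = 0.30, noise_pct = 0.10,
                            seed = 1L,
                            gamma_mode = c("auto", "fixed"),
                            gamma_fixed = 1.2e-12,
                            rre_mode = c("sum_normalized", "per_pixel_support"),
                            rre_on = c("chi", "contrast"),
                            field_mode = c("born", "full"),
                            noise_ref = c("mean_abs", "rms")) {
  cfg <- list(
    f1 = f1, f2 = f2, c0 = c0, N1 = as.integer(N1), N2 = as.integer(N2),
    Nt = as.integer(Nt), Nr = as.integer(Nr), Rt = Rt, Rr = Rr, L = L,
    disk_diameter = disk_diameter, contrast_pct = contrast_pct,
    noise_pct = noise_pct, seed = as.integer(seed),
    gamma_mode = match.arg(gamma_mode), gamma_fixed = gamma_fixed,
    rre_mode = match.arg(rre_mode), rre_on = match.arg(rre_on),
    field_mode = match.arg(field_mode), noise_ref = match.arg(noise_ref)
  )
  class(cfg) <- "uct_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid scenario configuration: ", msg,
                                 call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (key in c("f1", "f2", "c0", "N1", "N2", "Nt", "Nr", "Rt", "Rr", "L",
                "disk_diameter", "contrast_pct", "noise_pct", "seed",
                "gamma_fixed")) {
    if (is.null(cfg[[key]]) || !num1(cfg[[key]])) {
      stop_cfg(sprintf("field '%s' missing or not a finite scalar", key))
    }
  }
  if (!(cfg$f2 > cfg$f1 && cfg$f1 > 0)) stop_cfg("need f2 > f1 > 0")
  if (cfg$c0 <= 0) stop_cfg("c0 must be positive")
  if (cfg$N1 < 1 || cfg$N2 != 2L * cfg$N1) stop_cfg("need N2 = 2*N1, N1 >= 1")
  if (cfg$Nt < 1 || cfg$Nr < 1) stop_cfg("need Nt >= 1 and Nr >= 1")
  if (cfg$L <= 0) stop_cfg("L must be positive")
  if (!(cfg$Rt > cfg$L / 2 && cfg$Rr > cfg$L / 2)) {
    stop_cfg("transducer radii Rt, Rr must exceed L/2 (outside the ROI)")
  }
  if (cfg$noise_pct < 0 || cfg$noise_pct >= 1) stop_cfg("need 0 <= noise_pct < 1")
  if (cfg$contrast_pct <= -1) stop_cfg("contrast_pct must exceed -1")
  if (!cfg$gamma_mode %in% c("auto", "fixed")) stop_cfg("unknown gamma_mode")
  if (!cfg$rre_mode %in% c("sum_normalized", "per_pixel_support")) {
    stop_cfg("unknown rre_mode")
  }
  if (!cfg$rre_on %in% c("chi", "contrast")) stop_cfg("unknown rre_on")
  if (!cfg$field_mode %in% c("born", "full")) stop_cfg("unknown field_mode")
  if (!cfg$noise_ref %in% c("mean_abs", "rms")) stop_cfg("unknown noise_ref")
  invisible(cfg)
}

#' @export
print.uct_config <- function(x, ...) {
  cat("Ultrasound tomography scenario\n")
  cat(sprintf("  frequencies   : %.3g / %.3g MHz\n", x$f1 / 1e6, x$f2 / 1e6))
  cat(sprintf("  background c0 : %g m/s\n", x$c0))
  cat(sprintf("  grids         : %d x %d (coarse), %d x %d (fine)\n",
              x$N1, x$N1, x$N2, x$N2))
  cat(sprintf("  transducers   : %d Tx @ %g mm, %d Rx @ %g mm (%d measurements)\n",
              x$Nt, x$Rt * 1e3, x$Nr, x$Rr * 1e3, x$Nt * x$Nr))
  cat(sprintf("  ROI / disk    : %g mm / %g mm, contrast %g%%, noise %g%%\n",
              x$L * 1e3, x$disk_diameter * 1e3, 100 * x$contrast_pct,
              100 * x$noise_pct))
  invisible(x)
}

#' Read / write a scenario configuration file
#'
#' Scenario files are flat YAML mappings whose keys are exactly the
#' [scenario_config()] field names (lengths in meters, frequencies in Hz,
#' fractions for percentages). Schedule fields (`scheme`, `N_sum`, `N_N1`,
#' `N_f1`, `N_Nf1`, `N_Nf11`, `N_Nf12`) may be present in the same file; they
#' are ignored here and picked up by [read_schedule()].
#'
#' @param path file path of the YAML scenario file.
#' @return `read_config()` returns a validated `uct_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  fields <- names(formals(scenario_config))
  optional <- c("gamma_mode", "rre_mode", "rre_on", "field_mode", "noise_ref")
  missing <- setdiff(setdiff(fields, optional), names(raw))
  # mode-style keys fall back to their defaults when absent
  if (length(missing) > 0) {
    stop("config file ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(scenario_config, raw[intersect(fields, names(raw))])
}

#' @param config a `uct_config` to serialize.
#' @param extra named list merged into the YAML mapping (e.g. schedule fields).
#' @rdname read_config
#' @export
write_config <- function(config, path, extra = list()) {
  validate_config(config)
  out <- c(unclass(config), extra)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Circular transducer layout
#'
#' Places `Nt` transmitters on the circle of radius `Rt` and `Nr` receivers on
#' the circle of radius `Rr`, both centered on the ROI. Transmitters are
#' equispaced starting at 1 degree (for `Nt = 8` this yields the canonical
#' angles 1, 46, 91, ..., 316 degrees); receivers are equispaced starting at
#' 0 degrees. Angles are counter-clockwise from the +x axis.
#'
#' @param config a `uct_config`.
#' @return an object of class `uct_layout` with matrices
#'   `transmitter_positions` (`Nt` x 2) and `receiver_positions` (`Nr` x 2),
#'   in meters.
#' @export
build_layout <- function(config) {
  validate_config(config)
  if (config$Rt <= 0 || config$Rr <= 0) {
    stop("transducer radii must be positive", call. = FALSE)
  }
  tx_ang <- (1 + (seq_len(config$Nt) - 1) * 360 / config$Nt) * pi / 180
  rx_ang <- ((seq_len(config$Nr) - 1) * 360 / config$Nr) * pi / 180
  new_layout(
    tx = config$Rt * cbind(cos(tx_ang), sin(tx_ang)),
    rx = config$Rr * cbind(cos(rx_ang), sin(rx_ang))
  )
}

# direct constructor (used by tests for non-standard geometries)
new_layout <- function(tx, rx) {
  structure(list(transmitter_positions = tx, receiver_positions = rx),
            class = "uct_layout")
}

#' Regular pixel grid over the ROI
#'
#' Builds the square lattice of `N^2` pixel centers covering the ROI of side
#' `L`, centered at the origin. Pixels are ordered row-major with row 1 at
#' minimum y and columns left to right; this ordering is shared by every
#' vector and matrix in the package that is indexed by pixel.
#'
#' @param config a `uct_config` (only its `L` is used).
#' @param N side pixel count.
#' @return an object of class `uct_grid`: list with `N`, pixel side `h = L/N`,
#'   and `centers` (an `N^2` x 2 matrix of pixel-center coordinates in m).
#' @export
build_grid <- function(config, N) {
  N <- as.integer(N)
  if (N < 1) stop("grid side N must be >= 1", call. = FALSE)
  L <- config$L
  if (L <= 0) stop("ROI side L must be positive", call. = FALSE)
  h <- L / N
  ax <- (seq_len(N) - 0.5) * h - L / 2
  # row-major, row 1 at minimum y: index = (row-1)*N + col; x varies fastest
  xs <- rep(ax, times = N)
  ys <- rep(ax, each = N)
  structure(list(N = N, h = h, centers = cbind(x = xs, y = ys)),
            class = "uct_grid")
}

# Euclidean distances from a set of points (m x 2) to all grid centers;
# returns an m x N^2 matrix.
point_grid_distances <- function(points, grid) {
  px <- points[, 1]; py <- points[, 2]
  gx <- grid$centers[, 1]; gy <- grid$centers[, 2]
  sqrt(outer(px, gx, "-")^2 + outer(py, gy, "-")^2)
}

#' Two-way excess phase across the phantom diameter
#'
#' Diagnostic for how strongly the scenario violates the Born approximation:
#' the round-trip phase difference accumulated along the disk diameter between
#' propagation at the inclusion speed `c1 = c0 (1 + contrast)` and at the
#' background speed, evaluated at the high frequency `f2`. The default
#' scenario gives about `8.75 * pi`.
#'
#' @param config a `uct_config`.
#' @return phase shift in radians.
#' @export
phase_shift <- function(config) {
  c1 <- config$c0 * (1 + config$contrast_pct)
  2 * 2 * pi * config$f2 * config$disk_diameter * abs(1 / config$c0 - 1 / c1)
}
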