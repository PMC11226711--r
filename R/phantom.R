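#' Object maps: acoustic contrast on a pixel grid
#'
#' An object map stores the frequency-independent acoustic contrast
#' `chi(z) = 1/c1(z)^2 - 1/c0^2` (units s^2/m^2) for every pixel of a grid,
#' in the package's shared row-major order. Background pixels carry
#' `chi = 0`. Attenuation is taken as zero and density as constant, so `chi`
#' is real for ideal phantoms (reconstruction estimates may be complex).
#'
#' @param grid a `uct_grid`.
#' @param chi numeric or complex vector of length `grid$N^2`.
#' @param c0 background sound speed in m/s.
#' @return an object of class `uct_map`.
#' @export
object_map <- function(grid, chi, c0) {
  if (length(chi) != grid$N^2) {
    stop("chi must have exactly N^2 entries", call. = FALSE)
  }
  structure(list(grid = grid, chi = chi, c0 = c0), class = "uct_map")
}

#' @export
print.uct_map <- function(x, ...) {
  cat(sprintf("Object map %d x %d (h = %.3g mm), %d scatterer pixel(s)\n",
              x$grid$N, x$grid$N, x$grid$h * 1e3, sum(Mod(x$chi) > 0)))
  invisible(x)
}

#' Single-disk phantom
#'
#' Centered disk of the given diameter whose interior sound speed is
#' `c1 = c0 * (1 + contrast_pct)`; every pixel whose center lies inside the
#' disk receives the corresponding contrast `chi = 1/c1^2 - 1/c0^2`
#' (negative for a faster inclusion), background pixels stay zero.
#'
#' @param grid a `uct_grid`.
#' @param diameter disk diameter in m.
#' @param contrast_pct sound contrast fraction (`> -1`).
#' @param c0 background sound speed m/s.
#' @param center disk center (length-2, m); default the ROI center.
#' @return a `uct_map`.
#' @export
make_single_disk <- function(grid, diameter, contrast_pct, c0,
                             center = c(0, 0)) {
  if (contrast_pct <= -1) stop("contrast_pct must exceed -1", call. = FALSE)
  c1 <- c0 * (1 + contrast_pct)
  chi_in <- 1 / c1^2 - 1 / c0^2
  d <- sqrt((grid$centers[, 1] - center[1])^2 +
            (grid$centers[, 2] - center[2])^2)
  chi <- ifelse(d <= diameter / 2, chi_in, 0)
  object_map(grid, chi, c0)
}

#' Two-disk phantom
#'
#' Union of two disks, each with its own diameter and contrast; where the
#' disks overlap the second disk's value wins. The default geometry used by
#' the under-determined benchmark (two disks of diameter `L/4` at
#' `(+/- L/4, 0)`, equal contrast) is a synthetic stand-in: the reference
#' experiment shows but never tabulates its two-object phantom.
#'
#' @param grid a `uct_grid`.
#' @param centers list of two length-2 centers (m).
#' @param diameters numeric length-2 diameters (m).
#' @param contrasts numeric length-2 contrast fractions.
#' @param c0 background sound speed m/s.
#' @return a `uct_map`.
#' @export
make_two_disk <- function(grid, centers, diameters, contrasts, c0) {
  L <- grid$N * grid$h
  for (i in 1:2) {
    if (any(abs(centers[[i]]) + diameters[i] / 2 > L / 2 + 1e-12)) {
      stop("disk ", i, " extends outside the ROI", call. = FALSE)
    }
  }
  chi <- rep(0, grid$N^2)
  for (i in 1:2) {
    c1 <- c0 * (1 + contrasts[i])
    d <- sqrt((grid$centers[, 1] - centers[[i]][1])^2 +
              (grid$centers[, 2] - centers[[i]][2])^2)
    inside <- d <= diameters[i] / 2
    chi[inside] <- 1 / c1^2 - 1 / c0^2
  }
  object_map(grid, chi, c0)
}

#' Default two-disk stand-in phantom for the under-determined scenario
#'
#' @param grid a `uct_grid`.
#' @param config a `uct_config` (contrast and c0 are taken from it).
#' @return a `uct_map`.
#' @export
make_default_two_disk <- function(grid, config) {
  L <- config$L
  make_two_disk(grid,
                centers = list(c(-L / 4, 0), c(L / 4, 0)),
                diameters = c(L / 4, L / 4),
                contrasts = rep(config$contrast_pct, 2),
                c0 = config$c0)
}

#' Frequency-dependent object function
#'
#' Converts the frequency-independent contrast `chi` into the object function
#' `G(z) = omega^2 * chi(z)` (units 1/m^2) entering the scattering integral
#' equation at angular frequency `omega = 2 pi f`. Because `chi` does not
#' depend on frequency, `G` at one frequency is obtained from another by the
#' factor `(f2/f1)^2`; this is what makes estimates transferable across a
#' frequency hop.
#'
#' @param map a `uct_map`.
#' @param frequency in Hz, positive.
#' @return vector of length `N^2` (real for real `chi`).
#' @export
object_function <- function(map, frequency) {
  if (frequency <= 0) stop("frequency must be positive", call. = FALSE)
  (2 * pi * frequency)^2 * map$chi
}

#' Sound-contrast map from an object map
#'
#' Recovers the fractional sound-speed contrast `dc/c0 = c1/c0 - 1` per pixel
#' from the stored `chi` via `c1 = 1/sqrt(1/c0^2 + chi)`. Complex estimates
#' are projected onto their real part first; slownesses are floored at a tiny
#' positive value so overshooting estimates cannot produce NaN.
#'
#' @param map a `uct_map`.
#' @return numeric vector of length `N^2` of contrast fractions.
#' @export
contrast_map <- function(map) {
  s2 <- 1 / map$c0^2 + Re(map$chi)          # squared slowness
  s2 <- pmax(s2, .Machine$double.eps / map$c0^2)
  1 / (map$c0 * sqrt(s2)) - 1
}

# vector (package pixel order) <-> matrix [row, col], row 1 at min y
map_as_matrix <- function(values, N) matrix(values, nrow = N, ncol = N,
                                            byrow = TRUE)
matrix_as_map_vector <- function(m) as.vector(t(m))

#' Write / read an object map as plain text
#'
#' The map is stored as an `N x N` CSV matrix of `chi` values (row-major,
#' background 0) together with a JSON sidecar `<path>.json` holding the grid
#' metadata (`N`, `h`, `L`, `c0`).
#'
#' @param map a `uct_map`.
#' @param path CSV file path.
#' @return `read_map()` returns a `uct_map`.
#' @export
write_map <- function(map, path) {
  m <- map_as_matrix(Re(map$chi), map$grid$N)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  meta <- list(N = map$grid$N, h = map$grid$h, L = map$grid$N * map$grid$h,
               c0 = map$c0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  cfg_like <- list(L = meta$L)
  grid <- build_grid(cfg_like, meta$N)
  object_map(grid, matrix_as_map_vector(unname(m)), meta$c0)
}
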