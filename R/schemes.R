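#' Reconstruction schedule
#'
#' Describes how the total iteration budget `N_sum` is split across grids and
#' frequencies for one of the five schemes:
#' \describe{
#'   \item{dbi}{all `N_sum` iterations at `f2` on the fine `N2` grid;}
#'   \item{rt_dbi}{resolution turning: `N_N1` iterations at `f2` on the
#'     coarse `N1` grid, nearest-neighbor upsample, then the remainder on
#'     `N2`;}
#'   \item{fh_dbi}{frequency hopping: `N_f1` iterations at `f1` then the
#'     remainder at `f2`, fine grid throughout;}
#'   \item{rt_fh_dbi_1}{`N_Nf1` iterations at `f1` on `N1`, upsample, then
#'     the remainder at `f2` on `N2`;}
#'   \item{rt_fh_dbi_2}{`N_Nf11` iterations at `f1` on `N1`, upsample,
#'     `N_Nf12` iterations at `f1` on `N2`, then the remainder at `f2` on
#'     `N2`.}
#' }
#' Stage defaults are the tuned values of the benchmark study
#' (`N_N1 = 1`, `N_f1 = 2`, `N_Nf1 = 1`, `N_Nf11 = 1`, `N_Nf12 = 1`).
#'
#' @param scheme one of `"dbi"`, `"rt_dbi"`, `"fh_dbi"`, `"rt_fh_dbi_1"`,
#'   `"rt_fh_dbi_2"`.
#' @param N_sum total iteration count.
#' @param N_N1,N_f1,N_Nf1,N_Nf11,N_Nf12 stage iteration counts (see above);
#'   only those relevant to `scheme` are used.
#' @return object of class `uct_schedule`.
#' @export
schedule <- function(scheme = c("dbi", "rt_dbi", "fh_dbi", "rt_fh_dbi_1",
                                "rt_fh_dbi_2"),
                     N_sum = 8, N_N1 = 1, N_f1 = 2, N_Nf1 = 1,
                     N_Nf11 = 1, N_Nf12 = 1) {
  scheme <- match.arg(scheme)
  counts <- c(N_sum = N_sum, N_N1 = N_N1, N_f1 = N_f1, N_Nf1 = N_Nf1,
              N_Nf11 = N_Nf11, N_Nf12 = N_Nf12)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("schedule counts must be non-negative integers", call. = FALSE)
  }
  used <- switch(scheme,
                 dbi = 0, rt_dbi = N_N1, fh_dbi = N_f1, rt_fh_dbi_1 = N_Nf1,
                 rt_fh_dbi_2 = N_Nf11 + N_Nf12)
  if (used > N_sum) {
    stop("stage iteration counts exceed the total budget N_sum",
         call. = FALSE)
  }
  structure(as.list(c(list(scheme = scheme), as.list(counts))),
            class = "uct_schedule")
}

# stage table: one row per (frequency label, grid side label, iterations)
schedule_stages <- function(sched) {
  with(sched, switch(sched$scheme,
    dbi = data.frame(freq = "f2", res = "N2",
                     iters = N_sum),
    rt_dbi = data.frame(freq = c("f2", "f2"), res = c("N1", "N2"),
                        iters = c(N_N1, N_sum - N_N1)),
    fh_dbi = data.frame(freq = c("f1", "f2"), res = c("N2", "N2"),
                        iters = c(N_f1, N_sum - N_f1)),
    rt_fh_dbi_1 = data.frame(freq = c("f1", "f2"), res = c("N1", "N2"),
                             iters = c(N_Nf1, N_sum - N_Nf1)),
    rt_fh_dbi_2 = data.frame(freq = c("f1", "f1", "f2"),
                             res = c("N1", "N2", "N2"),
                             iters = c(N_Nf11, N_Nf12,
                                       N_sum - N_Nf11 - N_Nf12))
  ))
}

#' Nearest-neighbor upsampling by a factor of two
#'
#' Replaces each pixel by a constant 2x2 block of the same value, doubling
#' the grid side. No new values are created and all original information is
#' retained; the sum of the output is exactly four times the sum of the
#' input.
#'
#' @param m square numeric/complex matrix (or a vector in package pixel
#'   order, for which the side is inferred).
#' @return matrix with doubled side (or upsampled vector if a vector was
#'   given).
#' @export
nn_upsample <- function(m) {
  if (is.matrix(m)) {
    if (nrow(m) != ncol(m)) stop("nn_upsample needs a square matrix",
                                 call. = FALSE)
    return(kronecker(m, matrix(1, 2, 2)))
  }
  N <- sqrt(length(m))
  if (N != round(N)) stop("vector length is not a perfect square",
                          call. = FALSE)
  matrix_as_map_vector(kronecker(map_as_matrix(m, N), matrix(1, 2, 2)))
}

#' Relative residual error between an ideal and a reconstructed map
#'
#' Quality metric comparing a reconstructed map against the ideal phantom on
#' the same grid. The comparand is frequency-independent, so the metric is
#' the same at either operating frequency: by default the contrast `chi`
#' maps are compared (the object-function scale, `on = "chi"`); setting
#' `on = "contrast"` compares fractional sound-speed maps `dc/c0` instead.
#' Two normalizations are provided:
#' \describe{
#'   \item{sum_normalized}{`sum(|C - Chat|) / sum(|C|)` over all pixels
#'     (default); can exceed 1 when reconstruction artifacts outweigh the
#'     true support;}
#'   \item{per_pixel_support}{mean over the pixels with `C != 0` of
#'     `|C - Chat| / |C|`.}
#' }
#'
#' @param ideal,estimate `uct_map` objects on the same grid, or plain
#'   numeric vectors/matrices of already-comparable per-pixel values.
#' @param mode normalization mode (see above).
#' @param on per-pixel quantity compared when maps are given: `"chi"`
#'   (default) or `"contrast"`.
#' @return scalar error.
#' @export
rre <- function(ideal, estimate,
                mode = c("sum_normalized", "per_pixel_support"),
                on = c("chi", "contrast")) {
  mode <- match.arg(mode)
  on <- match.arg(on)
  if (inherits(ideal, "uct_map")) {
    if (!inherits(estimate, "uct_map") ||
        ideal$grid$N != estimate$grid$N) {
      stop("ideal and estimate must be maps on the same grid", call. = FALSE)
    }
    if (on == "chi") {
      ideal <- Re(ideal$chi)
      estimate <- Re(estimate$chi)
    } else {
      ideal <- contrast_map(ideal)
      estimate <- contrast_map(estimate)
    }
  }
  C <- as.vector(ideal); Chat <- as.vector(estimate)
  if (all(C == 0)) stop("RRE undefined for an all-zero ideal map",
                        call. = FALSE)
  if (mode == "sum_normalized") {
    sum(abs(C - Chat)) / sum(abs(C))
  } else {
    supp <- C != 0
    mean(abs(C[supp] - Chat[supp]) / abs(C[supp]))
  }
}

#' Run one reconstruction schedule
#'
#' Executes a full multi-stage distorted-Born reconstruction. Measurements
#' are the physical data: the same measurement vectors feed every stage,
#' while grid-dependent quantities (Green's operators, incident fields,
#' system matrix) are rebuilt per stage. The estimate is carried across
#' stages as frequency-independent contrast `chi`, so a frequency hop needs
#' no explicit rescaling of the object function, and a resolution hop is the
#' nearest-neighbor upsample of the chi image. The RRE against the ideal
#' fine-grid phantom is recorded after every iteration (coarse-stage
#' estimates are upsampled for scoring so traces are comparable across
#' schemes).
#'
#' @param config a `uct_config`.
#' @param phantom ideal `uct_map` on the fine (`N2`) grid.
#' @param sched a `uct_schedule`.
#' @param measurements optional named list with elements `f1` and/or `f2`
#'   (`uct_measurements`); any set the schedule needs that is missing is
#'   simulated from the phantom with the config's noise and seed. Pass a
#'   shared list to compare schemes on identical data.
#' @return object of class `uct_report`: list with `scheme`, `trace`
#'   (RRE per iteration), `stage_log` (data.frame with per-iteration
#'   frequency, grid side, gamma, sigma0, residual norm), `final_map`
#'   (`uct_map` on the fine grid), `seed`, `config`, `schedule`.
#' @export
run_scheme <- function(config, phantom, sched, measurements = NULL) {
  validate_config(config)
  if (!inherits(sched, "uct_schedule")) stop("sched must be a uct_schedule",
                                             call. = FALSE)
  stages <- schedule_stages(sched)
  if (any(stages$iters < 0)) {
    stop("inconsistent schedule: negative stage length", call. = FALSE)
  }
  layout <- build_layout(config)
  grids <- list(N1 = build_grid(config, config$N1),
                N2 = build_grid(config, config$N2))
  freqs <- list(f1 = config$f1, f2 = config$f2)
  if (phantom$grid$N != config$N2) {
    stop("phantom must live on the fine (N2) grid", call. = FALSE)
  }

  needed <- unique(stages$freq[stages$iters > 0])
  if (is.null(measurements)) measurements <- list()
  for (fl in needed) {
    if (is.null(measurements[[fl]])) {
      measurements[[fl]] <- simulate_measurements(phantom, config, layout,
                                                  freqs[[fl]])
    }
  }

  trace <- numeric(0)
  log_rows <- list()
  cur_res <- NULL                       # current grid label
  state <- NULL
  ops_cache <- list()
  get_ops <- function(res, fl) {
    key <- paste(res, fl)
    if (is.null(ops_cache[[key]])) {
      k0 <- 2 * pi * freqs[[fl]] / config$c0
      ops_cache[[key]] <<- assemble_green_operators(grids[[res]], layout, k0)
    }
    ops_cache[[key]]
  }
  score <- function(st, res) {
    est <- st$chi_estimate
    if (res == "N1") {
      est <- object_map(grids$N2, nn_upsample(est$chi), est$c0)
    }
    rre(phantom, est, mode = config$rre_mode, on = config$rre_on)
  }

  for (s in seq_len(nrow(stages))) {
    res <- stages$res[s]; fl <- stages$freq[s]
    if (stages$iters[s] == 0) next
    if (is.null(state)) {
      state <- new_state(object_map(grids[[res]],
                                    rep(0 + 0i, grids[[res]]$N^2),
                                    config$c0))
      cur_res <- res
    } else if (res != cur_res) {
      if (res != "N2" || cur_res != "N1") {
        stop("unsupported resolution transition", call. = FALSE)
      }
      state$chi_estimate <- object_map(grids$N2,
                                       nn_upsample(state$chi_estimate$chi),
                                       config$c0)
      cur_res <- res
    }
    ops <- get_ops(res, fl)
    for (i in seq_len(stages$iters[s])) {
      state <- dbi_iterate(state, measurements[[fl]], ops, layout, config)
      trace <- c(trace, score(state, res))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        iteration = length(trace), frequency = freqs[[fl]],
        grid_side = grids[[res]]$N, gamma = state$gamma,
        sigma0 = state$sigma0, residual_norm = state$residual_norm,
        diverged = state$diverged)
    }
  }

  if (is.null(state)) {                 # empty schedule
    final_map <- object_map(grids$N2, rep(0 + 0i, grids$N2$N^2), config$c0)
  } else if (cur_res == "N1") {
    final_map <- object_map(grids$N2, nn_upsample(state$chi_estimate$chi),
                            config$c0)
  } else {
    final_map <- state$chi_estimate
  }
  structure(list(scheme = sched$scheme, trace = trace,
                 stage_log = if (length(log_rows)) do.call(rbind, log_rows)
                             else data.frame(),
                 final_map = final_map,
                 final_rre = if (length(trace)) trace[length(trace)]
                             else rre(phantom, final_map,
                                      mode = config$rre_mode,
                                      on = config$rre_on),
                 seed = config$seed, config = config, schedule = sched),
            class = "uct_report")
}

#' @export
print.uct_report <- function(x, ...) {
  cat(sprintf("Reconstruction report: scheme %s, %d iteration(s), final RRE %.4g\n",
              x$scheme, length(x$trace), x$final_rre))
  invisible(x)
}

#' Compare reconstruction schedules on shared data
#'
#' Runs every schedule in `schedules` against the same phantom and, per seed,
#' the same simulated measurement sets (fair comparison: schemes see
#' identical data). Deterministic under fixed seeds.
#'
#' @param config a `uct_config`; its `seed` is overridden per element of
#'   `seeds`.
#' @param phantom ideal `uct_map` on the fine grid.
#' @param schedules list of `uct_schedule` objects.
#' @param seeds integer vector of scenario seeds (default: the config's).
#' @return data.frame with columns `scheme`, `seed`, `final_rre`, plus the
#'   full reports in attribute `"reports"` (a list indexed `[seed][scheme]`).
#' @export
compare_schemes <- function(config, phantom, schedules,
                            seeds = config$seed) {
  rows <- list(); reports <- list()
  for (sd in seeds) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    layout <- build_layout(cfg)
    meas <- list(
      f1 = simulate_measurements(phantom, cfg, layout, cfg$f1),
      f2 = simulate_measurements(phantom, cfg, layout, cfg$f2)
    )
    seed_reports <- list()
    for (sched in schedules) {
      rep_ <- run_scheme(cfg, phantom, sched, measurements = meas)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = sched$scheme, seed = as.integer(sd),
        final_rre = rep_$final_rre)
      seed_reports[[sched$scheme]] <- rep_
    }
    reports[[as.character(sd)]] <- seed_reports
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
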