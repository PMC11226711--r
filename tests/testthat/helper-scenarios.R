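# Reduced scenario used by unit tests: same geometry regime as the default
# benchmark (k*h just under pi on the fine grid) at a quarter of the size,
# so whole-pipeline tests run in well under a second each.
small_config <- function(...) {
  args <- utils::modifyList(list(f1 = 5e5, f2 = 1e6, N1 = 5, N2 = 10,
                                 Nt = 4, Nr = 12), list(...))
  do.call(scenario_config, args)
}

small_phantom <- function(cfg) {
  make_single_disk(build_grid(cfg, cfg$N2), cfg$disk_diameter,
                   cfg$contrast_pct, cfg$c0)
}

vnorm <- function(x) sqrt(sum(Mod(x)^2))
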