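#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: the synthetic
#' acquisition, the two-lumen phantom, the scenario list and the solver and
#' Windkessel settings. All scenarios share one inlet waveform so that the
#' comparative report isolates the effect of the tear configuration.
#'
#' @param seed Integer seed controlling every random component.
#' @param scenarios Scenario labels to run, in comparison order.
#' @param inlet List: `period_s`, `peak_L_min`, `systolic_fraction`,
#'   `frames` of the shared half-sine inlet waveform.
#' @param targets A [pressure_targets()] for outlet calibration.
#' @param dt,max_cycles Network solver settings.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L,
                               scenarios = c("S1-like", "S2mod-like", "S2-like"),
                               inlet = list(period_s = 0.78, peak_L_min = 10,
                                            systolic_fraction = 0.35,
                                            frames = 40L),
                               targets = pressure_targets(60, 30),
                               dt = 1e-3, max_cycles = 50) {
  stopifnot(length(scenarios) >= 1)
  structure(list(seed = as.integer(seed), scenarios = scenarios,
                 acquisition = acquisition_params(),
                 phantom = phantom_spec(kind = "two_lumen_dissection",
                                        rng_seed = seed),
                 inlet = inlet, targets = targets,
                 dt = dt, max_cycles = max_cycles),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `seed`, `scenarios`, `inlet` (period_s, peak_L_min,
#' systolic_fraction, frames), `targets` (mean_pressure, pulse_pressure),
#' `dt`, `max_cycles`; missing keys fall back to [default_run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$scenarios)) cfg$scenarios <- unlist(y$scenarios)
  if (!is.null(y$inlet)) cfg$inlet <- utils::modifyList(cfg$inlet, y$inlet)
  if (!is.null(y$targets))
    cfg$targets <- pressure_targets(y$targets$mean_pressure,
                                    y$targets$pulse_pressure)
  if (!is.null(y$dt)) cfg$dt <- y$dt
  if (!is.null(y$max_cycles)) cfg$max_cycles <- y$max_cycles
  cfg$phantom$rng_seed <- cfg$seed
  cfg
}

# polynomial rolling hash of a serialized R object (double arithmetic keeps
# every intermediate below 2^53), as provenance fingerprint
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Run the full comparative hemodynamic analysis
#'
#' Executes the full analysis arc on synthetic data: (1) generate the two-lumen
#' phantom acquisition and verify the flow metrics on it (plane flow, TL/FL
#' distribution, RFI); (2) calibrate Windkessel outlets from the inlet
#' waveform and pressure targets; (3) build and solve the 0D dissection
#' network for every scenario; (4) assemble a comparative report of
#' per-station flow distribution, RFI, mean FL pressure and peak cross-lumen
#' pressure difference. Deterministic given the seed.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param outdir Optional output directory; per-scenario station CSVs, a
#'   phantom-metrics CSV and a JSON summary are written there.
#' @param verbose Print stage progress.
#' @return An object of class `comparative_report`: `scenarios` (named list
#'   of station metric data.frames), `phantom_metrics`, `config`, `seed`,
#'   `config_hash`, `solutions` (the [solve_network()] objects).
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  hash <- config_hash(unclass(config))

  say("[synth] generating phantom acquisition")
  ph <- make_phantom_field(config$phantom, config$acquisition)
  mid_z <- config$phantom$length_mm / 2
  mk_plane <- function(lum) analysis_plane(c(0, 0, mid_z), c(0, 0, 1),
                                           pitch_mm = 0.5, lumen = lum,
                                           label = paste0("mid-", lum))
  q_tl <- plane_flow_rate(ph$field, mk_plane("TL"))
  q_fl <- plane_flow_rate(ph$field, mk_plane("FL"))
  fd <- flow_distribution(q_tl, q_fl)
  phantom_metrics <- data.frame(
    tl_pct = fd$tl_pct, fl_pct = fd$fl_pct,
    rfi_tl = rfi(q_tl), rfi_fl = rfi(q_fl),
    peak_velocity_cm_s = peak_velocity(ph$field, mk_plane("both"))$cycle_max_cm_s)

  inl <- config$inlet
  inlet_wave <- make_inlet_waveform(inl$period_s, inl$peak_L_min,
                                    inl$systolic_fraction, inl$frames)

  scen_tables <- list()
  solutions <- list()
  for (sc in config$scenarios) {
    say("[net] scenario %s: build + calibrate", sc)
    net <- build_network(make_case(sc), inlet_wave, targets = config$targets)
    say("[net] scenario %s: solve", sc)
    sim <- solve_network(net, dt = config$dt, max_cycles = config$max_cycles)
    scen_tables[[sc]] <- report_metrics(sim)
    solutions[[sc]] <- sim
  }

  report <- structure(list(scenarios = scen_tables,
                           phantom_metrics = phantom_metrics,
                           config = config, seed = config$seed,
                           config_hash = hash, solutions = solutions),
                      class = "comparative_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (sc in names(scen_tables)) {
      f <- file.path(outdir, paste0("stations_", gsub("[^A-Za-z0-9]", "", sc), ".csv"))
      con <- file(f, "w")
      writeLines(sprintf("# seed: %d  config: %s", config$seed, hash), con)
      utils::write.csv(format(scen_tables[[sc]], digits = 15), con,
                       row.names = FALSE)
      close(con)
    }
    con <- file(file.path(outdir, "phantom_metrics.csv"), "w")
    writeLines(sprintf("# seed: %d  config: %s", config$seed, hash), con)
    utils::write.csv(format(phantom_metrics, digits = 15), con,
                     row.names = FALSE)
    close(con)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           scenarios = lapply(scen_tables, function(d) as.list(d)),
           trends = as.list(validate_trends(report))),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("Comparative dissection report (seed", x$seed, ", config",
      x$config_hash, ")\n")
  cat("Phantom acquisition check: TL", sprintf("%.1f%%", x$phantom_metrics$tl_pct),
      "/ FL", sprintf("%.1f%%", x$phantom_metrics$fl_pct), "\n")
  for (sc in names(x$scenarios)) {
    cat("\n--", sc, "--\n")
    print(x$scenarios[[sc]], digits = 4, row.names = FALSE)
  }
  if (length(x$scenarios) >= 2) {
    cat("\nDirectional trends:\n")
    print(validate_trends(x), row.names = FALSE)
  }
  invisible(x)
}

#' Difference between two scenarios of a report
#'
#' Deltas are always recomputed from the per-scenario tables, never stored.
#'
#' @param report A `comparative_report`.
#' @param a,b Scenario labels; the result is `a - b` per station and metric.
#' @return A data.frame of metric differences.
#' @export
report_delta <- function(report, a, b) {
  stopifnot(inherits(report, "comparative_report"),
            a %in% names(report$scenarios), b %in% names(report$scenarios))
  ta <- report$scenarios[[a]]; tb <- report$scenarios[[b]]
  stopifnot(identical(ta$station, tb$station))
  num <- vapply(ta, is.numeric, logical(1))
  out <- ta
  out[num] <- ta[num] - tb[num]
  out
}

#' Validate the directional tear-configuration trends
#'
#' Checks the three directional claims of the tear-count experiment on a
#' comparative report containing the S1-like, S2mod-like and S2-like
#' scenarios: at the distal station the TL flow fraction is ordered
#' S2 >= S2mod >= S1; the station-averaged cycle-mean FL pressure is ordered
#' S2 <= S2mod <= S1; and the peak cross-lumen pressure difference satisfies
#' S2 <= S1. Directions only; no magnitudes are asserted. Exact equalities
#' are reported as ties and count as passes.
#'
#' @param report A `comparative_report` with at least the S1-like and
#'   S2-like scenarios (S2mod-like optional).
#' @param distal_station Station used for the TL-fraction check ("P6").
#' @return A data.frame: `check`, `pass`, `tie`, `detail`.
#' @export
validate_trends <- function(report, distal_station = "P6") {
  stopifnot(inherits(report, "comparative_report"))
  need <- c("S1-like", "S2-like")
  if (!all(need %in% names(report$scenarios)))
    stop("report must contain scenarios: ", paste(need, collapse = ", "))
  has_mod <- "S2mod-like" %in% names(report$scenarios)
  g <- function(sc, col, st = NULL) {
    d <- report$scenarios[[sc]]
    if (!is.null(st)) d[d$station == st, col] else d[[col]]
  }
  tl <- c(S1 = g("S1-like", "tl_pct", distal_station),
          S2mod = if (has_mod) g("S2mod-like", "tl_pct", distal_station) else NA,
          S2 = g("S2-like", "tl_pct", distal_station))
  pfl <- c(S1 = mean(g("S1-like", "mean_fl_pressure_mmHg")),
           S2mod = if (has_mod) mean(g("S2mod-like", "mean_fl_pressure_mmHg")) else NA,
           S2 = mean(g("S2-like", "mean_fl_pressure_mmHg")))
  clpd <- c(S1 = max(g("S1-like", "peak_clpd_mmHg")),
            S2 = max(g("S2-like", "peak_clpd_mmHg")))
  ord <- function(v, decreasing) {
    v <- v[!is.na(v)]
    dif <- diff(v)
    list(pass = all(if (decreasing) dif <= 0 else dif >= 0),
         tie = all(dif == 0))
  }
  c1 <- ord(tl[c("S1", if (has_mod) "S2mod", "S2")], decreasing = FALSE)
  c2 <- ord(pfl[c("S1", if (has_mod) "S2mod", "S2")], decreasing = TRUE)
  c3 <- ord(clpd[c("S1", "S2")], decreasing = TRUE)
  data.frame(
    check = c("TL flow fraction (distal) increases with tears",
              "mean FL pressure decreases with tears",
              "peak CLPD decreases with tears"),
    pass = c(c1$pass, c2$pass, c3$pass),
    tie = c(c1$tie, c2$tie, c3$tie),
    detail = c(paste(sprintf("%.2f", tl[!is.na(tl)]), collapse = " -> "),
               paste(sprintf("%.2f", pfl[!is.na(pfl)]), collapse = " -> "),
               paste(sprintf("%.2f", clpd), collapse = " -> ")),
    stringsAsFactors = FALSE)
}
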