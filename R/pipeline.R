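# End-to-end screening driver. A run configuration bundles the seed, the
# lattice, the dose design and the thresholds; run_screen() executes the
# high-content route (simulate volumes -> segment -> score -> Hill fit)
# and/or the high-throughput route (simulate well-scans -> gate -> corrected
# ratio -> Gaussian -> Hill fit) on the same ground truth and writes every
# table with the seed and a config hash in tow.

#' Screening run configuration
#'
#' @param seed Integer seed recorded in every output.
#' @param mode `"hc"`, `"ht"`, or `"both"`.
#' @param doses Dose series, uM.
#' @param hill A [hill_params()] row (ground truth for the simulations).
#' @param lattice_spec A [lattice_spec()] for the HC volumes.
#' @param diam_mean,diam_sd Spheroid diameter distribution, um.
#' @param voxel_size Voxel size, um.
#' @param noise Volume noise list (`gauss_sd`, `poisson_gain`).
#' @param green_gate Scaffold gate for the HT path, a.u.
#' @param threshold_method Contour threshold for the HC path.
#' @param wells_per_dose,points_per_well HT well-scan design.
#' @param output_dir Output directory, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, mode = c("both", "hc", "ht"),
                       doses = c(0, 10, 20, 50, 100, 200),
                       hill = hill_params(18.92, 2.807),
                       lattice_spec = spheroidscreen::lattice_spec(250, 760),
                       diam_mean = 179.2, diam_sd = 9.76,
                       voxel_size = 5,
                       noise = list(gauss_sd = 50, poisson_gain = 1),
                       green_gate = 2000, threshold_method = "otsu",
                       wells_per_dose = 4L, points_per_well = 36L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  structure(
    list(seed = as.integer(seed), mode = mode, doses = doses, hill = hill,
         lattice_spec = lattice_spec, diam_mean = diam_mean,
         diam_sd = diam_sd, voxel_size = voxel_size, noise = noise,
         green_gate = green_gate, threshold_method = threshold_method,
         wells_per_dose = wells_per_dose, points_per_well = points_per_well,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()]; `hill`
#' and `lattice_spec` are given as nested maps.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$hill)) {
    # YAML 1.1 parses a bare `n` key as the boolean FALSE; map it back
    names(y$hill)[names(y$hill) %in% c("FALSE", "false")] <- "n"
    args$hill <- do.call(hill_params, y$hill)
  }
  if (!is.null(y$lattice_spec)) args$lattice_spec <- do.call(lattice_spec, y$lattice_spec)
  do.call(run_config, args)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable rolling hash; enough to tie outputs to a config
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the screening pipeline
#'
#' Executes the configured route(s) on synthetic ground truth and, when
#' `output_dir` is set, writes the spheroid records, circle map, dose
#' summaries and Hill fits (CSV/JSON), each stamped with the seed and a
#' config hash. Per-stage counts are logged with `message()`.
#'
#' @param config A [run_config()].
#' @return A list with elements `hc` (records, circle map, per-dose
#'   viability, `hill_fit`) and/or `ht` (scan, summaries, `hill_fit`), plus
#'   `seed` and `config_hash`.
#' @export
run_screen <- function(config) {
  if (!inherits(config, "run_config")) abort_input("`config` must be a run_config")
  seeds <- derive_seeds(config$seed, 2L * length(config$doses) + 2L)
  out <- list(seed = config$seed, config_hash = config_hash(config))

  if (config$mode %in% c("hc", "both")) {
    records <- vector("list", length(config$doses))
    for (i in seq_along(config$doses)) {
      lattice <- build_void_lattice(config$lattice_spec, jitter_sd = 0,
                                    seed = seeds[i])
      sim <- simulate_volume(
        lattice, diam_mean = config$diam_mean, diam_sd = config$diam_sd,
        dose = config$doses[i], hill = config$hill,
        noise = config$noise, voxel_size = config$voxel_size,
        seed = seeds[i]
      )
      res <- process_volume(sim$volume, config$lattice_spec$void_diameter,
                            config$threshold_method)
      message(sprintf("[hc] dose %g uM: %d ROIs, %d spheroids scored",
                      config$doses[i], nrow(res$records),
                      sum(res$records$flags == "ok")))
      records[[i]] <- mutate(res$records, dose_um = config$doses[i])
    }
    records <- bind_rows(records)
    ok <- filter(records, .data$flags == "ok")
    hc_fit <- fit_hill(ok$dose_um, ok$viability, free_asymptotes = TRUE)
    out$hc <- list(records = records, circle_map = circle_map(records),
                   hill_fit = hc_fit)
  }

  if (config$mode %in% c("ht", "both")) {
    scan <- simulate_wellscan(
      config$doses, hill = config$hill,
      points_per_well = config$points_per_well,
      wells_per_dose = config$wells_per_dose,
      noise = list(gauss_sd = config$noise$gauss_sd %||% 50),
      seed = seeds[length(seeds)]
    )
    summaries <- build_dose_response(scan, config$green_gate)
    message(sprintf("[ht] %d doses, %d points gated in",
                    nrow(summaries), sum(summaries$n)))
    out$ht <- list(scan = scan, summaries = summaries,
                   hill_fit = fit_hill_ht(summaries))
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(seed = config$seed, config_hash = out$config_hash,
                  package_version = as.character(utils::packageVersion("spheroidscreen")))
    if (!is.null(out$hc)) {
      readr::write_csv(out$hc$records, file.path(config$output_dir, "spheroid_records.csv"))
      readr::write_csv(as_tibble(out$hc$circle_map), file.path(config$output_dir, "circle_map.csv"))
      jsonlite::write_json(
        c(stamp, list(hill = as.list(out$hc$hill_fit$params),
                      r_squared = out$hc$hill_fit$r_squared)),
        file.path(config$output_dir, "hc_hill_fit.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(out$ht)) {
      readr::write_csv(out$ht$summaries, file.path(config$output_dir, "dose_summaries.csv"))
      jsonlite::write_json(
        c(stamp, list(hill = as.list(out$ht$hill_fit$params),
                      r_squared = out$ht$hill_fit$r_squared)),
        file.path(config$output_dir, "ht_hill_fit.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(stamp, file.path(config$output_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
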