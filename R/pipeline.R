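# End-to-end orchestration: configuration, table IO with validation, and
# reproducible multi-treatment runs with a manifest.

#' Run configuration for a full multi-treatment experiment
#'
#' @param treatments Treatment presets to run (see [treatment_preset()]).
#' @param n_replicates Replicates per treatment, recycled to the number of
#'   treatments (the experiments used 20, 20, 20 and 22).
#' @param seed Master seed; all stage seeds derive from it.
#' @param detection_prob Detection probability used for thinning.
#' @param msd_window Half-window for MSD/quantile series (± min, default 7).
#' @param quantiles Quantile percentages for front series.
#' @param mixture_grid_by,mixture_window Grid spacing and window (min) for
#'   the component decomposition (defaults 15 and 10).
#' @param spread_B,mixture_B Bootstrap sizes for spread statistics (default
#'   2000) and mixture tracking (default 600).
#' @param piecewise_B Bootstrap size for changepoint significance
#'   (default 200).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param sim_overrides Named list of [sim_config()] overrides applied to
#'   every replicate (scale runs down with e.g.
#'   `list(duration = 240)`).
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(treatments = c("low", "high", "high_diffuse",
                                      "high_clumped"),
                       n_replicates = c(20, 20, 20, 22),
                       seed = 1,
                       detection_prob = 0.33,
                       msd_window = 7,
                       quantiles = c(50, 75, 90, 95, 98, 99),
                       mixture_grid_by = 15, mixture_window = 10,
                       spread_B = 2000, mixture_B = 600, piecewise_B = 200,
                       out_dir = NULL,
                       sim_overrides = list()) {
  n_replicates <- rep_len(n_replicates, length(treatments))
  if (any(n_replicates < 1))
    stop("every treatment needs at least one replicate", call. = FALSE)
  structure(
    list(treatments = treatments, n_replicates = n_replicates, seed = seed,
         detection_prob = detection_prob, msd_window = msd_window,
         quantiles = quantiles, mixture_grid_by = mixture_grid_by,
         mixture_window = mixture_window, spread_B = spread_B,
         mixture_B = mixture_B, piecewise_B = piecewise_B,
         out_dir = out_dir, sim_overrides = sim_overrides),
    class = "run_config"
  )
}

#' Run the full pipeline for every treatment
#'
#' Simulates each treatment, thins detections to the configured detection
#' probability, and runs the spread, distribution and (for host treatments)
#' parasitism analyses. All randomness derives from the master seed, so the
#' same configuration reproduces identical outputs. When `out_dir` is set,
#' tidy CSV/JSON outputs and a manifest are written per treatment.
#'
#' @param config A [run_config()] object.
#' @param verbose Print per-stage progress (default `TRUE`).
#'
#' @return A list of class `experiment_result` with one element per
#'   treatment (`detections`, `hosts`, `msd`, `quantiles`, `diffusion`,
#'   `piecewise`, `components`, and for host treatments `kernel`,
#'   `gain`, `metrics`) plus `manifest`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(config$treatments))
  say <- function(...) if (verbose) message(...)
  t_start <- Sys.time()
  results <- list()
  timing <- list()
  for (i in seq_along(config$treatments)) {
    tr <- config$treatments[i]
    t0 <- Sys.time()
    say("treatment ", tr, ": simulating ", config$n_replicates[i],
        " replicates")
    sim <- do.call(simulate_experiment,
                   c(list(preset = tr, n_replicates = config$n_replicates[i],
                          seed = stage_seeds[i]),
                     config$sim_overrides))
    set.seed(stage_seeds[i] %% 1000000L + 7L)
    obs <- thin_detections(sim$detections, config$detection_prob)

    say("treatment ", tr, ": spread statistics (", nrow(obs), " detections)")
    msd <- compute_msd(obs, window = config$msd_window)
    qs <- compute_quantiles(obs, p = config$quantiles,
                            window = config$msd_window)
    diff_fit <- fit_diffusion(msd)
    pw_fit <- fit_piecewise(msd, B = config$piecewise_B)

    say("treatment ", tr, ": component decomposition")
    comp <- suppressWarnings(
      track_components(obs, grid_by = config$mixture_grid_by,
                       window = config$mixture_window, B = 0)
    )

    res <- list(detections = obs, hosts = sim$hosts, msd = msd,
                quantiles = qs, diffusion = diff_fit, piecewise = pw_fit,
                components = comp)
    if (nrow(sim$hosts) > 0) {
      say("treatment ", tr, ": parasitism analyses")
      res$kernel <- dispersal_kernel(sim$hosts)
      res$gain <- gain_curve(sim$hosts)
      res$metrics <- replicate_metrics(obs, sim$hosts)
    }
    timing[[tr]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      n_detections = nrow(obs), n_hosts = nrow(sim$hosts)
    )
    results[[tr]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spiralspread")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    treatments = config$treatments,
    n_replicates = config$n_replicates,
    timing = timing,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  results$manifest <- manifest
  class(results) <- "experiment_result"
  if (!is.null(config$out_dir)) write_experiment(results, config$out_dir)
  results
}

write_experiment <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in setdiff(names(results), "manifest")) {
    res <- results[[tr]]
    pre <- file.path(out_dir, tr)
    write_detections(res$detections, paste0(pre, "_detections.csv"))
    if (nrow(res$hosts) > 0) write_hosts(res$hosts, paste0(pre, "_hosts.csv"))
    readr::write_csv(res$msd, paste0(pre, "_msd.csv"))
    readr::write_csv(res$quantiles, paste0(pre, "_quantiles.csv"))
    readr::write_csv(res$components, paste0(pre, "_components.csv"))
    jsonlite::write_json(
      list(linear = unclass(res$diffusion),
           piecewise = unclass(res$piecewise)),
      paste0(pre, "_diffusion.json"), auto_unbox = TRUE, digits = NA,
      na = "null"
    )
  }
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read and write detection and host tables
#'
#' CSV interchange with schema validation. Detections need columns
#' `replicate`, `treatment`, `t`, `s`; hosts need `replicate`, `treatment`,
#' `host_id`, `patch_id`, `s`, `first_discovery`, `total_visit`,
#' `parasitized`. Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param data Table to write.
#' @param tunnel_half_length When given, positions outside
#'   `± tunnel_half_length` are an error.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @export
read_detections <- function(path, tunnel_half_length = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("replicate", "treatment", "t", "s")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(d$t) | d$t < 1 | d$t != round(d$t) |
                 !is.finite(d$s))
  if (!is.null(tunnel_half_length))
    bad <- union(bad, which(abs(d$s) > tunnel_half_length))
  if (length(bad))
    stop("invalid detection rows (data line ", paste(utils::head(bad, 5),
         collapse = ", "), if (length(bad) > 5) ", ..." else "", ") in ",
         path, call. = FALSE)
  d$t <- as.integer(d$t)
  d
}

#' @rdname read_detections
#' @export
write_detections <- function(data, path) {
  data <- check_detections(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname read_detections
#' @export
read_hosts <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("replicate", "treatment", "host_id", "patch_id", "s",
           "first_discovery", "total_visit", "parasitized")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(d$total_visit < 0 |
                 (d$parasitized & is.na(d$first_discovery)) |
                 (d$total_visit == 0 & d$parasitized))
  if (length(bad))
    stop("invalid host rows (data line ", paste(utils::head(bad, 5),
         collapse = ", "), if (length(bad) > 5) ", ..." else "", ") in ",
         path, call. = FALSE)
  d
}

#' @rdname read_detections
#' @export
write_hosts <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`; the writer returns
#'   `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  obj$host_layout <- list(
    modality = attr(config$host_layout, "modality") %||% "none",
    host_id = config$host_layout$host_id,
    patch_id = config$host_layout$patch_id,
    s = config$host_layout$s
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  hl <- tibble::tibble(
    host_id = as.integer(obj$host_layout$host_id %||% integer()),
    patch_id = as.integer(obj$host_layout$patch_id %||% integer()),
    s = as.numeric(obj$host_layout$s %||% numeric())
  )
  attr(hl, "modality") <- obj$host_layout$modality %||% "none"
  class(hl) <- c("host_layout", class(hl))
  obj$host_layout <- hl
  do.call(sim_config, obj)
}
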