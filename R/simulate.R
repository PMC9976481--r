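# Agent-based simulator: switching heterogeneous diffusion in a linear
# tunnel with host encounter, saturating parasitism and imperfect detection.

#' Simulation configuration
#'
#' Bundles all parameters of the switching random-walk simulator. Individuals
#' move along the linear tunnel coordinate in discrete one-minute steps drawn
#' from a zero-mean Gaussian whose standard deviation depends on the current
#' movement mode: a slow "resident" mode and a fast "explorer" mode. Residents
#' convert to explorers with a hazard that increases linearly with the number
#' of neighbours within the perception radius (positive density dependence)
#' and is boosted by recent host contact; explorers revert to residents only
#' when locally isolated and without recent host contact. Agents boarding a
#' host egg stop moving, accrue visit time and parasitise the host with a
#' constant hazard \eqn{1/\tau} per occupant-minute, so that
#' \eqn{P(\mathrm{parasitised}\mid T) = 1 - e^{-T/\tau}} for cumulated visit
#' time \eqn{T}.
#'
#' @param n_agents Number of individuals released (low-density groups 25 ± 5,
#'   high-density groups 70 ± 10).
#' @param duration Experiment duration in minutes (default 480).
#' @param dt Time step in minutes (default 1, the observation cadence).
#' @param tunnel_half_length Half tunnel length in cm (default 315);
#'   reflecting boundaries at both tips.
#' @param release_spread Width in cm of the uniform initial scatter around
#'   the centre (default 10).
#' @param sigma_resident,sigma_explorer Per-step standard deviations in
#'   cm min^-1/2 for the two modes (defaults 0.5 and 7).
#' @param latency Minutes after release during which mode switching is
#'   suppressed (default 25); all agents start resident unless
#'   `initial_explorer_frac > 0`.
#' @param switch_re_base Baseline resident-to-explorer hazard per minute.
#' @param switch_re_density_coef Additional hazard per neighbour within
#'   `perception_radius`.
#' @param switch_re_host_boost Additional hazard while host contact is more
#'   recent than `host_memory`.
#' @param perception_radius Radius in cm defining "local" neighbours
#'   (default 5).
#' @param switch_er_hazard Explorer-to-resident hazard per minute, applied
#'   only when fewer than `density_threshold` neighbours are present and no
#'   host contact occurred within `host_memory` minutes.
#' @param density_threshold Neighbour count below which an explorer is
#'   considered isolated (default 3).
#' @param host_memory Memory window in minutes for host contact (default 30).
#' @param host_layout A [make_host_layout()] tibble; `NULL` or zero rows for
#'   host-free arenas.
#' @param reactive_distance Host detection radius in cm (default 0.4, the
#'   insects' reactive distance).
#' @param leave_host_prob Per-minute probability that an agent on a host
#'   leaves it (default 0.2, mean visit 5 min, the typical host-processing
#'   time).
#' @param host_refractory Minutes after leaving a host during which an agent
#'   does not board another (post-oviposition handling and travel;
#'   default 15). Boarding is independent of the host's parasitism status,
#'   so the closed-form gain function is preserved.
#' @param tau_parasitism Gain-function time constant \eqn{\tau} in minutes
#'   (default 60, saturating close to 1 near 200 min of cumulated visit).
#' @param detection_prob Probability that an individual present at a given
#'   minute is detected by the imaging pipeline (default 0.33).
#' @param initial_explorer_frac Fraction of agents starting in explorer mode
#'   (default 0).
#' @param seed Integer seed for this replicate, or `NULL` to use the current
#'   RNG state.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_agents = 70, duration = 480, dt = 1,
                       tunnel_half_length = 315, release_spread = 10,
                       sigma_resident = 0.5, sigma_explorer = 7,
                       latency = 25,
                       switch_re_base = 1.5e-3,
                       switch_re_density_coef = 3e-4,
                       switch_re_host_boost = 0.01,
                       perception_radius = 5,
                       switch_er_hazard = 0.01,
                       density_threshold = 3,
                       host_memory = 30,
                       host_layout = NULL,
                       reactive_distance = 0.4,
                       leave_host_prob = 0.2,
                       host_refractory = 15,
                       tau_parasitism = 60,
                       detection_prob = 0.33,
                       initial_explorer_frac = 0,
                       seed = NULL) {
  if (is.null(host_layout)) host_layout <- make_host_layout("none")
  cfg <- list(
    n_agents = as.integer(n_agents), duration = as.integer(duration), dt = dt,
    tunnel_half_length = tunnel_half_length, release_spread = release_spread,
    sigma_resident = sigma_resident, sigma_explorer = sigma_explorer,
    latency = latency, switch_re_base = switch_re_base,
    switch_re_density_coef = switch_re_density_coef,
    switch_re_host_boost = switch_re_host_boost,
    perception_radius = perception_radius,
    switch_er_hazard = switch_er_hazard,
    density_threshold = density_threshold,
    host_memory = host_memory, host_layout = host_layout,
    reactive_distance = reactive_distance,
    leave_host_prob = leave_host_prob, host_refractory = host_refractory,
    tau_parasitism = tau_parasitism,
    detection_prob = detection_prob,
    initial_explorer_frac = initial_explorer_frac, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_agents >= 0, cfg$duration >= 1, cfg$dt > 0,
    cfg$tunnel_half_length > 0, cfg$release_spread >= 0,
    cfg$sigma_resident >= 0, cfg$sigma_explorer >= 0,
    cfg$sigma_resident <= cfg$sigma_explorer,
    cfg$latency >= 0, cfg$switch_re_base >= 0,
    cfg$switch_re_density_coef >= 0, cfg$switch_re_host_boost >= 0,
    cfg$perception_radius >= 0, cfg$switch_er_hazard >= 0,
    cfg$host_memory >= 0, cfg$reactive_distance >= 0,
    cfg$host_refractory >= 0,
    cfg$leave_host_prob >= 0, cfg$leave_host_prob <= 1,
    cfg$tau_parasitism > 0,
    cfg$detection_prob >= 0, cfg$detection_prob <= 1,
    cfg$initial_explorer_frac >= 0, cfg$initial_explorer_frac <= 1
  )
  invisible(cfg)
}

# reflect positions into [-L, L]
reflect_positions <- function(x, L) {
  out <- abs(x + L) %% (4 * L)
  out <- ifelse(out > 2 * L, 4 * L - out, out)
  out - L
}

# neighbours within +/- r, excluding self; positions need not be sorted
count_neighbours <- function(x, r) {
  if (length(x) <= 1) return(rep(0L, length(x)))
  xs <- sort(x)
  hi <- findInterval(x + r, xs)
  lo <- findInterval(x - r, xs, left.open = TRUE)
  hi - lo - 1L
}

#' Simulate one replicate of the tunnel experiment
#'
#' Runs the agent-based switching random walk described in [sim_config()] and
#' returns ground-truth detection and host tables. Agents on hosts do not
#' move; every agent is recorded at every minute, so downstream analyses of
#' imperfect detection should pass the detection table through
#' [thin_detections()].
#'
#' @param config A [sim_config()] object.
#' @param replicate_id Identifier stored in the output tables (default 1).
#' @param treatment Treatment label stored in the output tables.
#'
#' @return A list with
#'   * `detections`: tibble (`replicate`, `treatment`, `t`, `s`, `agent_id`,
#'     `mode`, `on_host`) — one row per agent per minute (ground truth);
#'   * `hosts`: tibble (`replicate`, `treatment`, `host_id`, `patch_id`, `s`,
#'     `first_discovery`, `total_visit`, `parasitized`,
#'     `first_discoverer_mode`) — `first_discovery` is `NA` for undiscovered
#'     hosts; `first_discoverer_mode` is the ground-truth movement mode of
#'     the discovering agent;
#'   * `config`: the configuration used.
#' @export
simulate_replicate <- function(config, replicate_id = 1L,
                               treatment = "custom") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_agents
  Tm <- config$duration
  L <- config$tunnel_half_length
  hosts <- config$host_layout
  n_hosts <- nrow(hosts)

  if (n == 0) {
    return(list(
      detections = tibble::tibble(replicate = integer(), treatment = character(),
                                  t = integer(), s = numeric(),
                                  agent_id = integer(), mode = character(),
                                  on_host = integer()),
      hosts = empty_host_table(hosts, replicate_id, treatment),
      config = config
    ))
  }

  pos <- stats::runif(n, -config$release_spread / 2, config$release_spread / 2)
  explorer <- stats::runif(n) < config$initial_explorer_frac
  on_host <- rep(NA_integer_, n)
  t_since_host <- rep(Inf, n)

  host_visit <- numeric(n_hosts)
  host_first <- rep(NA_integer_, n_hosts)
  host_par <- logical(n_hosts)
  host_disc_mode <- rep(NA_character_, n_hosts)

  p_par_1 <- if (n_hosts) 1 - exp(-config$dt / config$tau_parasitism) else 0

  pos_rec <- matrix(NA_real_, n, Tm)
  mode_rec <- matrix(FALSE, n, Tm)
  onhost_rec <- matrix(NA_integer_, n, Tm)

  sig <- c(config$sigma_resident, config$sigma_explorer) * sqrt(config$dt)

  for (t in seq_len(Tm)) {
    free <- is.na(on_host)
    # 1. movement of free agents, reflecting at the tunnel tips
    if (any(free)) {
      step <- stats::rnorm(sum(free), 0, sig[explorer[free] + 1L])
      pos[free] <- reflect_positions(pos[free] + step, L)
    }
    # 2. host boarding within the reactive distance (not during the
    #    post-visit refractory period)
    if (n_hosts && any(free)) {
      idx <- which(free & t_since_host >= config$host_refractory)
      d <- abs(outer(pos[idx], hosts$s, "-"))
      nearest <- max.col(-d, ties.method = "first")
      near <- d[cbind(seq_along(idx), nearest)] <= config$reactive_distance
      if (any(near)) {
        boarded <- idx[near]
        hid <- nearest[near]
        on_host[boarded] <- hid
        pos[boarded] <- hosts$s[hid]
        newly <- unique(hid[is.na(host_first[hid])])
        if (length(newly)) {
          host_first[newly] <- t
          # discoverer = first boarding agent of that host this minute
          host_disc_mode[newly] <- vapply(newly, function(h) {
            a <- boarded[hid == h][1L]
            if (explorer[a]) "explorer" else "resident"
          }, character(1))
        }
      }
    }
    # 3. visit accrual, parasitism hazard, leaving
    if (n_hosts) {
      occ <- !is.na(on_host)
      if (any(occ)) {
        k <- tabulate(on_host[occ], nbins = n_hosts)
        host_visit <- host_visit + k * config$dt
        active <- which(k > 0 & !host_par)
        if (length(active)) {
          p_now <- 1 - (1 - p_par_1)^k[active]
          host_par[active] <- stats::runif(length(active)) < p_now
        }
        leavers <- which(occ)[stats::runif(sum(occ)) < config$leave_host_prob]
        on_host[leavers] <- NA_integer_
      }
      t_since_host <- ifelse(!is.na(on_host), 0, t_since_host + config$dt)
    }
    # 4. behavioural switching (suppressed during the latency phase)
    if (t > config$latency) {
      nb <- count_neighbours(pos, config$perception_radius)
      recent_host <- t_since_host <= config$host_memory
      res <- !explorer
      if (any(res)) {
        h_re <- config$switch_re_base +
          config$switch_re_density_coef * nb[res] +
          config$switch_re_host_boost * recent_host[res]
        explorer[res] <- stats::runif(sum(res)) < 1 - exp(-h_re * config$dt)
      }
      exp_idx <- which(explorer & is.na(on_host))
      if (length(exp_idx)) {
        can_revert <- nb[exp_idx] < config$density_threshold &
          !recent_host[exp_idx]
        p_er <- 1 - exp(-config$switch_er_hazard * config$dt)
        revert <- can_revert & stats::runif(length(exp_idx)) < p_er
        explorer[exp_idx[revert]] <- FALSE
      }
    }
    pos_rec[, t] <- pos
    mode_rec[, t] <- explorer
    onhost_rec[, t] <- on_host
  }

  detections <- tibble::tibble(
    replicate = as.integer(replicate_id),
    treatment = treatment,
    t = rep(seq_len(Tm), each = n),
    s = as.vector(pos_rec),
    agent_id = rep(seq_len(n), Tm),
    mode = ifelse(as.vector(mode_rec), "explorer", "resident"),
    on_host = as.vector(onhost_rec)
  )
  host_tab <- if (n_hosts) {
    tibble::tibble(
      replicate = as.integer(replicate_id), treatment = treatment,
      host_id = hosts$host_id, patch_id = hosts$patch_id, s = hosts$s,
      first_discovery = host_first, total_visit = host_visit,
      parasitized = host_par, first_discoverer_mode = host_disc_mode
    )
  } else {
    empty_host_table(hosts, replicate_id, treatment)
  }
  list(detections = detections, hosts = host_tab, config = config)
}

empty_host_table <- function(hosts, replicate_id, treatment) {
  tibble::tibble(
    replicate = integer(), treatment = character(), host_id = integer(),
    patch_id = integer(), s = numeric(), first_discovery = integer(),
    total_visit = numeric(), parasitized = logical(),
    first_discoverer_mode = character()
  )
}

#' Thin a ground-truth detection table to an observed one
#'
#' Emulates the imaging pipeline's imperfect detection: each (agent, minute)
#' row is kept independently with probability `detection_prob`, with no
#' spatial bias, and the ground-truth columns are dropped.
#'
#' @param detections Ground-truth detection tibble from
#'   [simulate_replicate()].
#' @param detection_prob Per-observation detection probability in `[0, 1]`.
#'
#' @return Tibble with columns `replicate`, `treatment`, `t`, `s`.
#' @export
thin_detections <- function(detections, detection_prob) {
  stopifnot(detection_prob >= 0, detection_prob <= 1)
  keep <- stats::runif(nrow(detections)) < detection_prob
  out <- detections[keep, c("replicate", "treatment", "t", "s")]
  tibble::as_tibble(out)
}

#' Treatment presets
#'
#' The four experimental treatments: `"low"` (25 ± 5 individuals, no hosts),
#' `"high"` (70 ± 10, no hosts), `"high_diffuse"` and `"high_clumped"`
#' (70 ± 10 with 120 host eggs laid out diffusely or in patches of six).
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()] object.
#' @export
treatment_preset <- function(preset = c("low", "high", "high_diffuse",
                                        "high_clumped"), ...) {
  preset <- match.arg(preset)
  layout <- switch(preset,
    low = , high = make_host_layout("none"),
    high_diffuse = make_host_layout("diffuse"),
    high_clumped = make_host_layout("clumped")
  )
  n_mean <- if (preset == "low") 25L else 70L
  args <- list(...)
  if (!"n_agents" %in% names(args)) args$n_agents <- n_mean
  if (!"host_layout" %in% names(args)) args$host_layout <- layout
  do.call(sim_config, args)
}

#' Simulate a batch of replicates for one treatment
#'
#' Replicate-level group sizes are drawn uniformly within the stated ranges
#' (25 ± 5 for low density, 70 ± 10 for high density), per-replicate seeds
#' are derived deterministically from the master seed, and arena chirality
#' alternates between replicates.
#'
#' @param preset One of `"low"`, `"high"`, `"high_diffuse"`,
#'   `"high_clumped"`.
#' @param n_replicates Number of replicates (the experiments used 20, or 22
#'   for the clumped treatment).
#' @param seed Master seed.
#' @param ... Overrides passed to [sim_config()] for every replicate.
#'
#' @return A list with `detections` and `hosts` tibbles (all replicates bound
#'   together, ground truth included), and `configs`, the per-replicate
#'   configurations.
#' @export
simulate_experiment <- function(preset, n_replicates = 20, seed = 1, ...) {
  stopifnot(n_replicates >= 0)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  n_range <- if (preset == "low") c(20L, 30L) else c(60L, 80L)
  n_agents <- sample(seq(n_range[1], n_range[2]), n_replicates, replace = TRUE)
  runs <- purrr::map(seq_len(n_replicates), function(i) {
    cfg <- treatment_preset(preset, n_agents = n_agents[i],
                            seed = rep_seeds[i], ...)
    run <- simulate_replicate(cfg, replicate_id = i, treatment = preset)
    run$detections$chirality <- if (i %% 2L == 1L) "levogyrous" else "dextrogyrous"
    run
  })
  list(
    detections = dplyr::bind_rows(purrr::map(runs, "detections")),
    hosts = dplyr::bind_rows(purrr::map(runs, "hosts")),
    configs = purrr::map(runs, "config")
  )
}
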