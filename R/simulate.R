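#' Stochastic simulation settings
#'
#' @param dt Time step (default `1e-3`, in units of `L/v`).
#' @param n_steps Number of steps (default `1e5`, i.e. 100 domain-crossing
#'   times of total simulated time).
#' @param n_iter Ensemble size: independent iterations averaged in the
#'   reported statistics (default 100).
#' @param seed Base RNG seed; each iteration uses a generator seeded
#'   deterministically from `(seed, iteration index)`.
#' @param fixed_M Recycling variant: a fixed population of `M` mitochondria
#'   is placed at the start and every mitochondrion reaching the soma is
#'   relaunched anterograde with health reset to 1; no production occurs.
#' @param forbid_retrograde_fusion SS only: retrograde motile mitochondria
#'   skip fusion attempts.
#' @param ss_placement SS only: `"uniform"` stations exactly `S` residents
#'   at every site; `"random"` distributes the `n * S` residents over sites
#'   uniformly at random at the start of each iteration.
#' @param record_stride Record per-site health and population counts every
#'   this many steps (0 disables; used by burn-in diagnostics and
#'   trajectory dumps).
#' @param record_trajectory Also record per-agent frames (position, state,
#'   health) at each recorded step.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 1e-3, n_steps = 1e5, n_iter = 100, seed = 1,
                       fixed_M = FALSE, forbid_retrograde_fusion = FALSE,
                       ss_placement = c("uniform", "random"),
                       record_stride = 0, record_trajectory = FALSE) {
  stopifnot(dt > 0, n_steps >= 1, n_iter >= 1, record_stride >= 0)
  ss_placement <- match.arg(ss_placement)
  if (record_trajectory && record_stride == 0)
    stop("record_trajectory requires record_stride > 0")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 fixed_M = fixed_M,
                 forbid_retrograde_fusion = forbid_retrograde_fusion,
                 ss_placement = ss_placement,
                 record_stride = as.integer(record_stride),
                 record_trajectory = record_trajectory),
            class = "sim_config")
}

.iter_seed <- function(seed, iter) {
  # per-iteration stream, reproducible and order-independent
  (as.double(seed) * 1000003 + iter * 7919) %% 2147483629
}

.run_kernel <- function(params, cfg, iter) {
  p <- params
  set.seed(.iter_seed(cfg$seed, iter))
  .sim_kernel(p$model, p$L, p$v, p$k_d, if (cfg$fixed_M) 0 else p$k_p,
              if (is.null(p$k_w)) 0 else p$k_w,
              if (is.null(p$p_s)) 0 else p$p_s,
              if (is.null(p$p_f)) 0 else p$p_f,
              if (is.null(p$S)) 0L else as.integer(p$S),
              p$phi, p$alpha * p$v / (2 * p$L), as.integer(p$n),
              cfg$dt, cfg$n_steps, cfg$fixed_M,
              as.integer(round(p$M)) -
                if (p$model == "ss") as.integer(p$n * p$S) else 0L,
              cfg$forbid_retrograde_fusion,
              identical(cfg$ss_placement, "random"),
              cfg$record_stride, cfg$record_trajectory)
}

.check_sim_args <- function(params, cfg) {
  g <- params$L / (params$n + 1)
  if (cfg$dt * params$v >= g)
    stop(sprintf("dt * v = %.3g reaches the inter-site gap %.3g: multi-site crossings per step are unsupported; reduce dt",
                 cfg$dt * params$v, g))
  if (params$k_d * cfg$dt * cfg$n_steps > 600)
    stop("k_d * dt * n_steps too large for the scaled-health representation (> 600 e-folds of decay)")
}

#' Run the stochastic Changing-of-the-Guard simulation
#'
#' Discrete agents move processively at speed `v`, stop at demand sites
#' with probability `p_s` per passage, restart at rate `k_w` (direction
#' equiprobable), decay in health at rate `k_d`, are engulfed when health
#' drops below `phi` (engulfed agents move retrograde only and are
#' excluded from all health metrics, though counted in the population),
#' and are produced at the soma with per-step probability
#' `1 - exp(-k_p dt)`. The reported statistics are final-step snapshots
#' averaged across `n_iter` independent iterations.
#'
#' @param params A CoG [mito_params()] object.
#' @param cfg A [sim_config()].
#' @return A `mito_ensemble` object; see [tidy.mito_ensemble()] and
#'   [glance.mito_ensemble()].
#' @export
run_cog <- function(params, cfg = sim_config()) {
  stopifnot(inherits(params, "mito_params"))
  if (params$model != "cog") stop("run_cog() requires a CoG parameter set")
  .run_ensemble(params, cfg)
}

#' Run the stochastic Space-Station simulation
#'
#' `S` permanently stationary agents are pre-placed at each site with
#' health 1. A motile agent crossing a site attempts transient fusion with
#' each resident in positional order (anterograde: proximal to distal;
#' retrograde: distal to proximal), each attempt succeeding with
#' probability `p_f` and setting both healths to their mean. Under
#' mitophagy, an engulfed resident leaves a vacant slot that is filled by
#' the next non-engulfed motile agent crossing the site (it stops with
#' probability 1 and becomes a permanent resident). All other rules as in
#' [run_cog()].
#'
#' @inheritParams run_cog
#' @export
run_ss <- function(params, cfg = sim_config()) {
  stopifnot(inherits(params, "mito_params"))
  if (params$model != "ss") stop("run_ss() requires an SS parameter set")
  if (params$S < 1) stop("run_ss() requires S >= 1")
  .run_ensemble(params, cfg)
}

#' Run the stochastic simulation for either model
#' @inheritParams run_cog
#' @export
simulate_model <- function(params, cfg = sim_config()) {
  if (params$model == "cog") run_cog(params, cfg) else run_ss(params, cfg)
}

.run_ensemble <- function(params, cfg) {
  .check_sim_args(params, cfg)
  n <- params$n
  it <- lapply(seq_len(cfg$n_iter), function(i) .run_kernel(params, cfg, i))
  H <- do.call(rbind, lapply(it, `[[`, "site_health"))     # n_iter x n
  cnt_site <- do.call(rbind, lapply(it, `[[`, "site_count"))
  M_final <- vapply(it, `[[`, numeric(1), "M_final")
  n_stat <- vapply(it, `[[`, numeric(1), "n_stationary")
  n_eng <- vapply(it, `[[`, numeric(1), "n_engulfed")
  n_mot <- vapply(it, function(x) x$n_anterograde + x$n_retrograde, numeric(1))
  # per-iteration normalizations: by realized total M and by the target M
  Hhat <- H / (pmax(M_final, 1) / n)
  Hhat0 <- H / (params$M / n)
  res <- structure(list(
    params = params, cfg = cfg, n_sites = n,
    H_sites = H,
    H_sites_mean = colMeans(H),
    H_sites_std = apply(H, 2, stats::sd),
    site_count_mean = colMeans(cnt_site),
    Hhat_sites_mean = colMeans(Hhat),
    Hhat_avg_mean = mean(rowMeans(Hhat)),
    Hhat_avg_sem = stats::sd(rowMeans(Hhat)) / sqrt(cfg$n_iter),
    Hhat_last_mean = mean(Hhat[, n]),
    Hhat_last_sem = stats::sd(Hhat[, n]) / sqrt(cfg$n_iter),
    Hhat0_avg_mean = mean(rowMeans(Hhat0)),
    Hhat0_last_mean = mean(Hhat0[, n]),
    sigma_over_mean = if (cfg$n_iter >= 2) variability(H) else NA_real_,
    counts = c(motile = mean(n_mot), stationary = mean(n_stat),
               engulfed = mean(n_eng), total = mean(M_final)),
    realized_fs = mean(n_stat / pmax(M_final, 1)),
    M_final = M_final),
    class = "mito_ensemble")
  if (cfg$record_stride > 0) {
    res$rec_site_health <- lapply(it, `[[`, "rec_site_health")
    res$rec_counts <- lapply(it, `[[`, "rec_counts")
  }
  if (cfg$record_trajectory)
    res$trajectory <- lapply(it, function(x) tibble::as_tibble(x$trajectory))
  res
}

#' @export
print.mito_ensemble <- function(x, ...) {
  cat(sprintf("<mito_ensemble> %s model, %d iterations, n = %d sites\n",
              toupper(x$params$model), x$cfg$n_iter, x$n_sites))
  cat(sprintf("  <H^> = %.4f (SEM %.4f)   H^_n = %.4f (SEM %.4f)\n",
              x$Hhat_avg_mean, x$Hhat_avg_sem, x$Hhat_last_mean, x$Hhat_last_sem))
  cat(sprintf("  counts: motile %.1f, stationary %.1f, engulfed %.1f, total %.1f (f_s = %.3f)\n",
              x$counts["motile"], x$counts["stationary"], x$counts["engulfed"],
              x$counts["total"], x$realized_fs))
  invisible(x)
}

#' Health variability statistic
#'
#' Normalized variability of regional mitochondrial health across
#' independent iterations: the across-iteration standard deviation of the
#' per-region health, averaged over regions, divided by the grand mean
#' per-region health (`mode = "per_region"`, the default). The alternative
#' `mode = "pooled"` takes the standard deviation of the region-averaged
#' health across iterations, divided by its mean.
#'
#' @param H Either a `mito_ensemble` or an iterations-by-regions numeric
#'   matrix of per-region health.
#' @param mode `"per_region"` or `"pooled"`.
#' @return The scalar variability `sigma_H / <H>`.
#' @export
variability <- function(H, mode = c("per_region", "pooled")) {
  mode <- match.arg(mode)
  if (inherits(H, "mito_ensemble")) H <- H$H_sites
  H <- as.matrix(H)
  if (nrow(H) < 2)
    stop("variability requires at least 2 iterations")
  if (mode == "per_region") {
    mean(apply(H, 2, stats::sd)) / mean(colMeans(H))
  } else {
    m <- rowMeans(H)
    stats::sd(m) / mean(m)
  }
}

#' Dump recorded trajectory frames to CSV
#'
#' Writes the per-frame agent records of a simulation run with
#' `record_trajectory = TRUE` as CSV with the fixed column order
#' `t, iteration, agent_id, x, state, health` (state coded
#' anterograde/retrograde/stationary/engulfed). Deterministic under a
#' fixed seed: identical runs produce byte-identical files.
#'
#' @param result A `mito_ensemble` run with trajectory recording on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_trajectory <- function(result, path) {
  stopifnot(inherits(result, "mito_ensemble"))
  if (is.null(result$trajectory))
    stop("no trajectory recorded; rerun with record_trajectory = TRUE")
  states <- c("anterograde", "retrograde", "stationary", "engulfed")
  frames <- purrr::imap_dfr(result$trajectory, function(tr, i) {
    tibble::tibble(t = tr$step * result$cfg$dt, iteration = i,
                   agent_id = as.integer(tr$id), x = tr$x,
                   state = states[tr$state + 1L], health = tr$health)
  })
  utils::write.csv(frames, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
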