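#' Define a parameter sweep grid
#'
#' Grids over the dimensionless control parameters: stationary fraction
#' `f_s`, protein stopping events per round trip `N_s`, and mitophagy
#' threshold `phi`, at fixed dimensionless decay `khat_d`, site count `n`
#' and population `M`.
#'
#' @param f_s_values,N_s_values,phi_values Strictly increasing grids.
#'   Defaults: `f_s` 10 points on (0.05, 0.95), `N_s` 10 log-spaced points
#'   on (0.2, 20), `phi = 0`.
#' @param khat_d Dimensionless decay rate.
#' @param n,M Site count and total mitochondria.
#' @param model `"cog"` or `"ss"`.
#' @param engine `"meanfield"` (deterministic, requires `phi = 0`) or
#'   `"stochastic"`.
#' @param objective Which health metric the optimizer targets:
#'   `"avg_health"` (`<H^>`) or `"last_site_health"` (`H^_n`).
#' @param normalization `"per_total_M"` (normalize by the realized total
#'   population; equivalent to holding total mitochondrial content fixed)
#'   or `"per_M0"` (normalize by the zero-mitophagy reference population,
#'   the fixed-production-rate reading).
#' @param cfg A [sim_config()] for the stochastic engine.
#' @return A `sweep_grid` list.
#' @export
sweep_grid <- function(f_s_values = seq(0.05, 0.95, length.out = 10),
                       N_s_values = exp(seq(log(0.2), log(20), length.out = 10)),
                       phi_values = 0,
                       khat_d = 0.6, n = 10, M = 300,
                       model = c("cog", "ss"),
                       engine = c("meanfield", "stochastic"),
                       objective = c("avg_health", "last_site_health"),
                       normalization = c("per_total_M", "per_M0"),
                       cfg = sim_config()) {
  model <- match.arg(model); engine <- match.arg(engine)
  objective <- match.arg(objective); normalization <- match.arg(normalization)
  chk <- function(x) length(x) >= 1 && !is.unsorted(x, strictly = TRUE)
  stopifnot(chk(f_s_values), chk(N_s_values), chk(phi_values))
  if (engine == "meanfield" && any(phi_values > 0))
    stop("the mean-field engine does not model mitophagy; use phi = 0 or the stochastic engine")
  structure(list(f_s_values = f_s_values, N_s_values = N_s_values,
                 phi_values = phi_values, khat_d = khat_d, n = n, M = M,
                 model = model, engine = engine, objective = objective,
                 normalization = normalization, cfg = cfg),
            class = "sweep_grid")
}

.eval_point <- function(grid, f_s, N_s, phi) {
  na_row <- tibble::tibble(avg_health = NA_real_, last_site_health = NA_real_,
                           avg_sem = NA_real_, last_sem = NA_real_,
                           realized_fs = NA_real_, note = NA_character_)
  pars <- tryCatch(
    params_from_targets(f_s, N_s, grid$khat_d, grid$M, grid$n,
                        model = grid$model, phi = phi),
    error = function(e) e)
  if (inherits(pars, "error")) {
    na_row$note <- conditionMessage(pars)
    return(na_row)
  }
  if (grid$engine == "meanfield") {
    sol <- tryCatch(solve_meanfield(pars), error = function(e) e)
    if (inherits(sol, "error")) { na_row$note <- conditionMessage(sol); return(na_row) }
    m <- health_metrics(sol)
    tibble::tibble(avg_health = m$Hhat_avg, last_site_health = m$Hhat_last,
                   avg_sem = 0, last_sem = 0,
                   realized_fs = attr(pars, "realized_f_s"), note = NA_character_)
  } else {
    sim <- simulate_model(pars, grid$cfg)
    if (grid$normalization == "per_total_M") {
      tibble::tibble(avg_health = sim$Hhat_avg_mean,
                     last_site_health = sim$Hhat_last_mean,
                     avg_sem = sim$Hhat_avg_sem, last_sem = sim$Hhat_last_sem,
                     realized_fs = sim$realized_fs, note = NA_character_)
    } else {
      tibble::tibble(avg_health = sim$Hhat0_avg_mean,
                     last_site_health = sim$Hhat0_last_mean,
                     avg_sem = sim$Hhat_avg_sem, last_sem = sim$Hhat_last_sem,
                     realized_fs = sim$realized_fs, note = NA_character_)
    }
  }
}

#' Evaluate the health landscape over a sweep grid
#'
#' Evaluates both health objectives at every `(f_s, N_s, phi)` grid point.
#' Points that are infeasible (e.g. an `N_s` beyond the SS fusion cap) are
#' recorded as `NA` rows with an explanatory `note`, never silently
#' dropped. Grid points are independent, stateless evaluations: any
#' evaluation order yields the identical table.
#'
#' @param grid A [sweep_grid()].
#' @return A tibble with columns `f_s`, `N_s`, `phi`, `avg_health`,
#'   `last_site_health`, the stochastic SEMs, `realized_fs` and `note`.
#' @export
sweep_landscape <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  pts <- tidyr::expand_grid(phi = grid$phi_values, f_s = grid$f_s_values,
                            N_s = grid$N_s_values)
  res <- purrr::pmap_dfr(pts, function(phi, f_s, N_s)
    .eval_point(grid, f_s, N_s, phi))
  dplyr::bind_cols(pts[, c("f_s", "N_s", "phi")], res)
}

#' Locate the optimum of a sweep landscape
#'
#' Takes the grid argmax of the configured objective; for the stochastic
#' engine the argmax point is then re-evaluated with `replicates`
#' independent ensembles (distinct seeds) and the mean and standard error
#' of the mean across replicates are reported.
#'
#' @param grid A [sweep_grid()].
#' @param replicates Number of re-evaluation replicates (stochastic
#'   engine; default 10).
#' @param landscape Optionally, a precomputed [sweep_landscape()] table
#'   for this grid.
#' @return A `sweep_optimum` list: `argmax_f_s`, `argmax_N_s`,
#'   `argmax_phi`, `max_value`, `sem`, and the full `landscape`.
#' @export
sweep_optimize <- function(grid, replicates = 10, landscape = NULL) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (is.null(landscape)) landscape <- sweep_landscape(grid)
  obj <- landscape[[grid$objective]]
  if (all(is.na(obj))) stop("all grid points infeasible or failed; nothing to optimize")
  k <- which.max(obj)
  best <- landscape[k, ]
  sem <- NA_real_
  max_value <- obj[k]
  if (grid$engine == "stochastic" && replicates >= 2) {
    vals <- vapply(seq_len(replicates), function(r) {
      g2 <- grid
      g2$cfg$seed <- as.integer((grid$cfg$seed + 104729 * r) %% 2147483629)
      .eval_point(g2, best$f_s, best$N_s, best$phi)[[grid$objective]]
    }, numeric(1))
    max_value <- mean(vals)
    sem <- stats::sd(vals) / sqrt(replicates)
  }
  structure(list(argmax_f_s = best$f_s, argmax_N_s = best$N_s,
                 argmax_phi = best$phi, max_value = max_value, sem = sem,
                 objective = grid$objective, landscape = landscape),
            class = "sweep_optimum")
}

#' @export
print.sweep_optimum <- function(x, ...) {
  cat(sprintf("<sweep_optimum> %s maximized at f_s = %.3g, N_s = %.3g, phi = %.3g\n",
              x$objective, x$argmax_f_s, x$argmax_N_s, x$argmax_phi))
  cat(sprintf("  max value %.4g%s\n", x$max_value,
              if (is.finite(x$sem)) sprintf(" (SEM %.3g)", x$sem) else ""))
  invisible(x)
}

#' Per-site health enhancement from local translation
#'
#' For a CoG mean-field configuration, compares the per-site stationary
#' health with local translation at each `alpha` against the
#' translation-free solution, returning the ratio `H_i(alpha) / H_i(0)`
#' per site. Local protein synthesis feeds health into stationary
#' mitochondria at rate `r = alpha v / (2 L)` per mitochondrion, so distal
#' sites -- whose soma-derived supply has decayed the most -- benefit the
#' most.
#'
#' @param params A CoG [mito_params()] object (its `alpha` is ignored).
#' @param alpha_values Local translation fractions to evaluate.
#' @return A tibble with columns `alpha`, `site`, `x`, `ratio`.
#' @export
translation_enhancement <- function(params, alpha_values) {
  stopifnot(inherits(params, "mito_params"))
  if (params$model != "cog")
    stop("local translation is modeled for the CoG mean-field system only")
  base <- params; base$alpha <- 0
  H0 <- solve_cog(base)$H_sites
  purrr::map_dfr(alpha_values, function(a) {
    p <- params; p$alpha <- a
    Ht <- solve_cog(p)$H_sites
    tibble::tibble(alpha = a, site = seq_along(Ht),
                   x = demand_site_positions(params$n, params$L),
                   ratio = Ht / H0)
  })
}
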