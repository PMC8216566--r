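#' Tidy a mean-field solution into a per-site tibble
#'
#' @param x A `meanfield_solution`.
#' @param M_ref Optional reference population for the normalization
#'   (see [health_metrics()]).
#' @param ... Unused.
#' @return A tibble with one row per demand site: `site`, `x`, `H`
#'   (stationary health) and `Hhat` (normalized by mitochondria per site).
#' @export
tidy.meanfield_solution <- function(x, M_ref = NULL, ...) {
  m <- health_metrics(x, M_ref)
  out <- tibble::tibble(site = seq_len(x$params$n), x = x$x_sites)
  out$H <- x$H_sites
  out$Hhat <- m$Hhat_sites
  out
}

#' One-row summary of a mean-field solution
#' @param x A `meanfield_solution`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `Hhat_avg`, `Hhat_last`, `rho`,
#'   `S`, `M_total`, `residual`.
#' @export
glance.meanfield_solution <- function(x, ...) {
  m <- health_metrics(x)
  tibble::tibble(model = x$params$model, Hhat_avg = m$Hhat_avg,
                 Hhat_last = m$Hhat_last, rho = x$rho, S = x$S,
                 M_total = x$M_total, residual = x$residual)
}

#' Tidy an ensemble result into a per-site tibble
#'
#' @param x A `mito_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per site: `site`, `x`, `H_mean`, `H_std`,
#'   `Hhat_mean` (normalized by realized mitochondria per site) and the
#'   mean stationary count.
#' @export
tidy.mito_ensemble <- function(x, ...) {
  out <- tibble::tibble(site = seq_len(x$n_sites),
                        x = demand_site_positions(x$n_sites, x$params$L))
  out$H_mean <- x$H_sites_mean
  out$H_std <- x$H_sites_std
  out$Hhat_mean <- x$Hhat_sites_mean
  out$count_mean <- x$site_count_mean
  out
}

#' One-row summary of an ensemble result
#' @param x A `mito_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble with the normalized health metrics (both
#'   normalizations), the variability statistic, population counts and the
#'   realized stationary fraction.
#' @export
glance.mito_ensemble <- function(x, ...) {
  tibble::tibble(model = x$params$model, n_iter = x$cfg$n_iter,
                 Hhat_avg = x$Hhat_avg_mean, Hhat_avg_sem = x$Hhat_avg_sem,
                 Hhat_last = x$Hhat_last_mean, Hhat_last_sem = x$Hhat_last_sem,
                 Hhat0_avg = x$Hhat0_avg_mean, Hhat0_last = x$Hhat0_last_mean,
                 sigma_over_mean = x$sigma_over_mean,
                 motile = x$counts[["motile"]],
                 stationary = x$counts[["stationary"]],
                 engulfed = x$counts[["engulfed"]],
                 M_total = x$counts[["total"]],
                 realized_fs = x$realized_fs)
}

#' Plot a mean-field solution
#'
#' Motile anterograde/retrograde health-density profiles (normalized by
#' the total population) with the normalized stationary site health
#' overlaid at the demand sites.
#'
#' @param object A `meanfield_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meanfield_solution
#' @export
autoplot.meanfield_solution <- function(object, ...) {
  prof <- sample_profile(object)
  prof_long <- tidyr::pivot_longer(prof, c("H_plus", "H_minus"),
                                   names_to = "direction", values_to = "H")
  prof_long$H <- prof_long$H / object$M_total
  sites <- tidy(object)
  ggplot2::ggplot(prof_long, ggplot2::aes(x = .data$x, y = .data$H,
                                          colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = sites, inherit.aes = FALSE,
                        ggplot2::aes(x = .data$x, y = .data$Hhat),
                        colour = "goldenrod", size = 2.5) +
    ggplot2::labs(x = "position x / L",
                  y = "health density / M (lines), site health per mito (points)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble per-site health with uncertainty ribbons
#' @param object A `mito_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mito_ensemble
#' @export
autoplot.mito_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$H_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$H_mean - .data$H_std,
                                      ymax = .data$H_mean + .data$H_std),
                         fill = "grey80") +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "position x / L", y = "stationary health per site") +
    ggplot2::theme_minimal()
}

#' Plot a sweep landscape as a heat map
#'
#' @param landscape A [sweep_landscape()] tibble.
#' @param objective Column to display (`"avg_health"` or
#'   `"last_site_health"`).
#' @param phi Mitophagy threshold slice to display (default: first).
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, objective = "avg_health", phi = NULL) {
  stopifnot(objective %in% c("avg_health", "last_site_health"))
  if (is.null(phi)) phi <- landscape$phi[1]
  d <- dplyr::filter(landscape, .data$phi == !!phi)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f_s, y = .data$N_s,
                                  fill = .data[[objective]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "stationary fraction f_s", y = "stopping events N_s",
                  fill = objective,
                  title = sprintf("phi = %.2g", phi)) +
    ggplot2::theme_minimal()
}
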