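#' Model parameters for axonal mitochondrial maintenance
#'
#' Construct and validate the raw kinetic parameter set for either
#' maintenance mechanism: `"cog"` (Changing of the Guard, whole mitochondria
#' interchange between the motile and stationary pools) or `"ss"`
#' (Space Station, permanently stationed mitochondria refreshed by transient
#' fusion/fission with passing motile ones).
#'
#' All internal computation is carried out in nondimensional units in which
#' the domain length and transport speed are 1; time is then measured in
#' units of `L/v`, the time for a motile mitochondrion to traverse the
#' domain once. Physical units can be used directly by supplying `L` and
#' `v` (e.g. cm and um/s) with rates in matching units.
#'
#' @param model `"cog"` or `"ss"`.
#' @param L Domain (axon) length. Default 1 (nondimensional).
#' @param v Processive transport speed of motile mitochondria. Default 1.
#' @param k_d Decay rate of mitochondrial health (1/time), `>= 0`.
#' @param M Target total number of mitochondria in the domain (used to
#'   derive production rates and normalizations).
#' @param n Number of discrete demand sites, integer `>= 1`.
#' @param k_p Somal production rate of new mitochondria (1/time).
#' @param k_w CoG only: restarting rate of stationary mitochondria (1/time).
#' @param p_s CoG only: probability that a motile mitochondrion stops when
#'   passing a demand site, in `[0, 1]`.
#' @param p_f SS only: probability of a transient fusion event with each
#'   stationary mitochondrion passed, in `[0, 1]`.
#' @param S SS only: number of permanently stationary mitochondria per
#'   demand site, integer `>= 0`.
#' @param phi Mitophagy threshold in `[0, 1)`: a mitochondrion whose health
#'   drops below `phi` is engulfed and carried back to the soma. `phi = 0`
#'   disables mitophagy.
#' @param alpha Local translation fraction in `[0, 1]`: distal protein
#'   synthesis rate per mitochondrion as a fraction of the maximal somal
#'   supply per mitochondrion, giving `r = alpha * v / (2 L)`.
#'
#' @return An object of class `mito_params` (a named list).
#' @seealso [derive_params()], [params_from_targets()]
#' @examples
#' p <- mito_params("cog", k_d = 0.6, M = 300, n = 10, k_p = 70,
#'                  k_w = 0.9, p_s = 0.1)
#' derive_params(p)
#' @export
mito_params <- function(model = c("cog", "ss"), L = 1, v = 1, k_d = 0,
                        M = NULL, n = 1, k_p = NULL, k_w = NULL, p_s = NULL,
                        p_f = NULL, S = NULL, phi = 0, alpha = 0) {
  model <- match.arg(model)
  stopifnot(L > 0, v > 0, k_d >= 0, n >= 1, n == round(n),
            phi >= 0, phi < 1, alpha >= 0, alpha <= 1)
  if (!is.null(k_p)) stopifnot(k_p >= 0)
  if (model == "cog") {
    if (!is.null(S)) stop("S is a Space Station parameter; unset it for the CoG model")
    if (is.null(p_s)) p_s <- 0
    if (is.null(k_w)) k_w <- 0
    stopifnot(p_s >= 0, p_s <= 1, k_w >= 0)
    p_f <- NULL
  } else {
    if (is.null(S)) stop("the SS model requires S (stationary mitochondria per site)")
    stopifnot(S >= 0, S == round(S))
    S <- as.integer(S)
    if (is.null(p_f)) p_f <- 0
    stopifnot(p_f >= 0, p_f <= 1)
    if (S == 0 && p_f > 0)
      stop("SS with S = 0 has no stationary partner to fuse with; set p_f = 0 or S >= 1")
    if (!is.null(M) && n * S > M)
      stop("SS requires n * S <= M (stationary pool cannot exceed the total)")
    p_s <- NULL; k_w <- NULL
  }
  if (is.null(k_p)) {
    if (is.null(M)) stop("supply either k_p or M")
    # production that sustains M total at steady state
    k_p <- if (model == "cog") {
      fs <- n * v * p_s / (L * k_w + n * v * p_s)
      if (p_s > 0 && k_w == 0) 0 else v * M * (1 - fs) / (2 * L)
    } else v * (M - n * S) / (2 * L)
  }
  if (is.null(M)) {
    M <- if (model == "cog") {
      if (p_s > 0 && k_w == 0) Inf
      else 2 * k_p * L / v + n * v * (2 * k_p / v) * p_s / max(k_w, .Machine$double.xmin)
    } else 2 * k_p * L / v + n * S
  }
  structure(list(model = model, L = L, v = v, k_d = k_d, M = M, n = n,
                 k_p = k_p, k_w = k_w, p_s = p_s, p_f = p_f, S = S,
                 phi = phi, alpha = alpha),
            class = "mito_params")
}

#' @export
print.mito_params <- function(x, ...) {
  cat(sprintf("<mito_params> %s model\n", toupper(x$model)))
  flds <- x[!vapply(x, is.null, logical(1))]
  flds$model <- NULL
  cat(paste0("  ", names(flds), " = ", signif(unlist(flds), 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Derived dimensionless control parameters
#'
#' Maps raw kinetic parameters to the dimensionless set that governs model
#' behaviour: the scaled decay rate `khat_d = k_d L / v`, the stationary
#' fraction `f_s`, the expected number of protein stopping events per round
#' trip `N_s = 2 * phat_s * n`, the effective per-site protein stopping
#' probability `phat_s` (equal to `p_s` for CoG and `1 - (1 - p_f/2)^S` for
#' SS), the SS effective restart rate `khat_w = p_f * v * rho / 2`, the
#' motile linear density `rho = 2 k_p / v`, and the local translation rate
#' per mitochondrion `r = alpha * v / (2 L)`.
#'
#' @param params A [mito_params()] object.
#' @return A one-row tibble of class `mito_derived`.
#' @export
derive_params <- function(params) {
  stopifnot(inherits(params, "mito_params"))
  p <- params
  rho <- 2 * p$k_p / p$v
  khat_d <- p$k_d * p$L / p$v
  r <- p$alpha * p$v / (2 * p$L)
  if (p$model == "cog") {
    phat_s <- p$p_s
    denom <- p$L * p$k_w + p$n * p$v * p$p_s
    f_s <- if (denom > 0) p$n * p$v * p$p_s / denom else 0
    khat_w <- p$k_w
  } else {
    if (p$S == 0 && p$p_f > 0) stop("SS with S = 0 cannot fuse")
    phat_s <- 1 - (1 - p$p_f / 2)^p$S
    f_s <- if (is.finite(p$M) && p$M > 0) p$n * p$S / p$M else NA_real_
    khat_w <- p$p_f * p$v * rho / 2
  }
  out <- tibble::tibble(khat_d = khat_d, f_s = f_s, N_s = 2 * phat_s * p$n,
                        phat_s = phat_s, khat_w = khat_w, rho = rho, r = r)
  class(out) <- c("mito_derived", class(out))
  out
}

#' Build raw parameters from dimensionless targets
#'
#' Inverse of [derive_params()]: given the dimensionless control set
#' (`f_s`, `N_s`, `khat_d`) together with `M` and `n`, construct the raw
#' kinetic parameters (in nondimensional units, `L = v = 1`) that realize
#' those targets. For the SS model the per-site count is rounded,
#' `S = round(f_s * M / n)`, and the realized stationary fraction
#' `n * S / M` is stored in the attribute `"realized_f_s"`.
#'
#' @param f_s Target stationary fraction, in `(0, 1)`.
#' @param N_s Target number of stopping events per protein round trip
#'   (`>= 0`); the per-site stopping probability is `phat_s = N_s / (2 n)`.
#' @param khat_d Dimensionless decay rate `k_d L / v`.
#' @param M Total mitochondria.
#' @param n Number of demand sites.
#' @param model `"cog"` or `"ss"`.
#' @param phi,alpha Passed to [mito_params()].
#' @return A [mito_params()] object (with attribute `realized_f_s`).
#' @details For CoG, `p_s = phat_s` and the restart rate follows from the
#'   stationary-fraction relation `f_s = n v p_s / (L k_w + n v p_s)`, i.e.
#'   `k_w = n v p_s (1 - f_s) / (L f_s)`. For SS,
#'   `p_f = 2 (1 - (1 - phat_s)^(1/S))`; the requested `phat_s` is rejected
#'   when it exceeds the cap reachable with `p_f = 1` at the given `S`
#'   (a motile protein always has a nonzero chance of staying with its
#'   carrier, so the SS model cannot realize arbitrarily large effective
#'   stopping probabilities).
#' @export
params_from_targets <- function(f_s, N_s, khat_d, M, n,
                                model = c("cog", "ss"), phi = 0, alpha = 0) {
  model <- match.arg(model)
  stopifnot(f_s > 0, f_s < 1, N_s >= 0, khat_d >= 0, M >= 1, n >= 1)
  phat_s <- N_s / (2 * n)
  if (phat_s > 1)
    stop(sprintf("N_s = %g requires per-site stopping probability %.3f > 1; reduce N_s or increase n",
                 N_s, phat_s))
  if (model == "cog") {
    p_s <- phat_s
    k_w <- n * p_s * (1 - f_s) / f_s  # L = v = 1
    k_p <- M * (1 - f_s) / 2
    out <- mito_params("cog", k_d = khat_d, M = M, n = n, k_p = k_p,
                       k_w = k_w, p_s = p_s, phi = phi, alpha = alpha)
    attr(out, "realized_f_s") <- if (p_s > 0) f_s else 0
    if (N_s == 0)
      attr(out, "degenerate") <- "N_s = 0: no exchange between pools ever occurs"
  } else {
    S <- round(f_s * M / n)
    if (S < 1)
      stop("f_s * M / n rounds to S = 0; the SS model needs at least one stationary mitochondrion per site")
    phat_cap <- 1 - (1 / 2)^S
    if (phat_s > phat_cap + 1e-12)
      stop(sprintf(paste0("requested phat_s = %.4f exceeds the SS cap 1 - 2^-S = %.4f ",
                          "at S = %d (even p_f = 1 cannot stop proteins that often)"),
                   phat_s, phat_cap, S))
    p_f <- 2 * (1 - (1 - phat_s)^(1 / S))
    k_p <- (M - n * S) / 2
    out <- mito_params("ss", k_d = khat_d, M = M, n = n, k_p = k_p,
                       p_f = min(p_f, 1), S = S, phi = phi, alpha = alpha)
    attr(out, "realized_f_s") <- n * S / M
  }
  out
}

#' Demand site positions
#'
#' Demand sites are placed at equal separations over the domain, strictly
#' in the interior: `x_i = i L / (n + 1)`, so the gap between consecutive
#' sites (and between the boundaries and the nearest site) is `L / (n+1)`.
#'
#' @param n Number of sites (`n = 0` gives an empty vector).
#' @param L Domain length.
#' @return Numeric vector of length `n`.
#' @export
demand_site_positions <- function(n, L = 1) {
  stopifnot(n >= 0, n == round(n), L > 0)
  if (n == 0) return(numeric(0))
  seq_len(n) * L / (n + 1)
}
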