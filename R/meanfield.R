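#' Steady-state mitochondrial density
#'
#' At steady state the motile mitochondria form a constant linear density
#' `rho = 2 k_p / v` over the whole domain, and each demand site holds
#' `S = v rho p_s / k_w` stationary mitochondria (CoG) or the fixed count
#' `S` (SS). The total population is `M = rho L + n S`.
#'
#' @param params A [mito_params()] object.
#' @return A list with `rho`, `S_per_site`, `M_total` and the stationary
#'   fraction `f_s = n S / M`.
#' @export
solve_density <- function(params) {
  stopifnot(inherits(params, "mito_params"))
  p <- params
  rho <- 2 * p$k_p / p$v
  if (p$model == "cog") {
    if (p$p_s > 0 && p$k_w == 0)
      stop("k_w = 0 with p_s > 0: stationary mitochondria accumulate without bound")
    S <- if (p$p_s == 0) 0 else p$v * rho * p$p_s / p$k_w
  } else {
    S <- p$S
  }
  M_total <- rho * p$L + p$n * S
  list(rho = rho, S_per_site = S, M_total = M_total,
       f_s = if (M_total > 0) p$n * S / M_total else 0)
}

# interval decay factor between consecutive sites (equal gaps)
.gap_decay <- function(params) {
  g <- params$L / (params$n + 1)
  exp(-params$k_d * g / params$v)
}

#' Steady-state mean-field solution, CoG model
#'
#' Assembles and solves (by one dense linear solve) the steady-state system
#' for the linear densities of anterograde/retrograde mitochondrial health
#' `H+`, `H-` and the per-site stationary health `H_i`: exponential decay of
#' the motile densities across each inter-site interval, flux jump
#' conditions at every demand site (stopping plus restarting), reflection
#' of anterograde into retrograde motion at the distal end, the somal
#' production boundary `v H+(0) = k_p`, and the site balance
#' `(k_d + k_w) H_i = v p_s [H+(x_i-) + H-(x_i+)] + r f_s M / n`, where the
#' last term is the local-translation source (zero when `alpha = 0`).
#'
#' @param params A CoG [mito_params()] object.
#' @return A `meanfield_solution` object; see [tidy.meanfield_solution()],
#'   [health_metrics()] and [sample_profile()].
#' @export
solve_cog <- function(params) {
  stopifnot(inherits(params, "mito_params"))
  if (params$model != "cog") stop("solve_cog() requires a CoG parameter set")
  p <- params
  dens <- solve_density(p)
  n <- p$n
  v <- p$v
  if (p$k_d == 0 && p$k_w == 0 && p$p_s > 0)
    stop("degenerate system: k_d = k_w = 0 with p_s > 0 has no unique steady state")
  E <- .gap_decay(p)
  r <- p$alpha * v / (2 * p$L)
  src <- r * dens$S_per_site  # r * f_s * M / n
  # unknowns per site i: HpL, HpR, HmL, HmR, H_i  (edge health densities and
  # stationary site health); column index helper
  ix <- function(i, k) (i - 1L) * 5L + k
  N <- 5L * n
  A <- matrix(0, N, N)
  b <- numeric(N)
  kw2v <- p$k_w / (2 * v)
  for (i in seq_len(n)) {
    # anterograde propagation into site i
    ri <- ix(i, 1L)
    A[ri, ix(i, 1L)] <- 1
    if (i == 1L) b[ri] <- E * p$k_p / v else A[ri, ix(i - 1L, 2L)] <- -E
    # anterograde jump at site i
    ri <- ix(i, 2L)
    A[ri, ix(i, 2L)] <- 1
    A[ri, ix(i, 1L)] <- -(1 - p$p_s)
    A[ri, ix(i, 5L)] <- -kw2v
    # retrograde propagation out of site i (toward the soma happens via HmL)
    ri <- ix(i, 4L)
    A[ri, ix(i, 4L)] <- 1
    if (i == n) A[ri, ix(n, 2L)] <- -E * E else A[ri, ix(i + 1L, 3L)] <- -E
    # retrograde jump at site i
    ri <- ix(i, 3L)
    A[ri, ix(i, 3L)] <- 1
    A[ri, ix(i, 4L)] <- -(1 - p$p_s)
    A[ri, ix(i, 5L)] <- -kw2v
    # site balance
    ri <- ix(i, 5L)
    A[ri, ix(i, 5L)] <- p$k_d + p$k_w
    A[ri, ix(i, 1L)] <- -v * p$p_s
    A[ri, ix(i, 4L)] <- -v * p$p_s
    b[ri] <- src
  }
  u <- tryCatch(solve(A, b), error = function(e)
    stop("singular mean-field system at the supplied parameters: ", conditionMessage(e)))
  sel <- function(k) u[ix(seq_len(n), k)]
  new_meanfield_solution(
    params = p,
    H_plus_edges = cbind(left = sel(1L), right = sel(2L)),
    H_minus_edges = cbind(left = sel(3L), right = sel(4L)),
    H_sites = sel(5L),
    H_site_mito = NULL,
    rho = dens$rho, S = dens$S_per_site, M_total = dens$M_total,
    residual = max(abs(A %*% u - b)))
}

#' Steady-state mean-field solution, SS model
#'
#' Solves the per-mitochondrion steady-state system of the Space Station
#' model: each of the `S` stationary mitochondria at a site exchanges
#' health with the passing motile streams through transient fusion (each
#' passage fuses with probability `p_f` and fully equilibrates the two
#' health levels), giving for mitochondrion `j` at site `i` the balance
#' `(v rho p_f / 2 + k_d) H_ij = (v p_f / 2) [H+_(i,j-1) + H-_(i,j+1)]`
#' with flux jumps `H+_(i,j) = (1 - p_f/2) H+_(i,j-1) + (p_f rho / 4) H_ij`
#' (and mirrored retrograde relations), exponential propagation between
#' sites, distal reflection and somal production. Within a (point-like)
#' site there is no propagation distance, hence no decay between
#' consecutive stationary mitochondria. The full per-mitochondrion system
#' is solved; no small-`p_f` approximation is used.
#'
#' @param params An SS [mito_params()] object with `S >= 1`.
#' @return A `meanfield_solution` object; `H_site_mito` holds the
#'   `n x S` matrix of per-mitochondrion health `H_ij` and
#'   `H_sites` its row sums.
#' @export
solve_ss <- function(params) {
  stopifnot(inherits(params, "mito_params"))
  if (params$model != "ss") stop("solve_ss() requires an SS parameter set")
  p <- params
  if (p$alpha > 0)
    stop("local translation is modeled for the CoG mean-field system only")
  if (p$S < 1) stop("solve_ss() requires S >= 1")
  if (p$k_d == 0 && p$p_f == 0)
    stop("degenerate system: k_d = 0 with p_f = 0 has no unique steady state")
  n <- p$n; S <- p$S; v <- p$v
  dens <- solve_density(p)
  rho <- dens$rho
  E <- .gap_decay(p)
  pf <- p$p_f
  # unknowns per site: a_j (j = 0..S, anterograde edges), b_j (j = 1..S+1,
  # retrograde edges), H_j (j = 1..S)
  per <- 3L * S + 2L
  ia <- function(i, j) (i - 1L) * per + j + 1L            # a_{i,j}, j in 0..S
  ib <- function(i, j) (i - 1L) * per + (S + 1L) + j      # b_{i,j}, j in 1..S+1
  ih <- function(i, j) (i - 1L) * per + (2L * S + 2L) + j # H_{i,j}, j in 1..S
  N <- n * per
  A <- matrix(0, N, N)
  b <- numeric(N)
  for (i in seq_len(n)) {
    # incoming anterograde edge
    ri <- ia(i, 0L)
    A[ri, ia(i, 0L)] <- 1
    if (i == 1L) b[ri] <- E * p$k_p / v else A[ri, ia(i - 1L, S)] <- -E
    # incoming retrograde edge (from the distal side)
    ri <- ib(i, S + 1L)
    A[ri, ib(i, S + 1L)] <- 1
    if (i == n) A[ri, ia(n, S)] <- -E * E else A[ri, ib(i + 1L, 1L)] <- -E
    for (j in seq_len(S)) {
      # anterograde jump across stationary mitochondrion j
      ri <- ia(i, j)
      A[ri, ia(i, j)] <- 1
      A[ri, ia(i, j - 1L)] <- -(1 - pf / 2)
      A[ri, ih(i, j)] <- -pf * rho / 4
      # retrograde jump
      ri <- ib(i, j)
      A[ri, ib(i, j)] <- 1
      A[ri, ib(i, j + 1L)] <- -(1 - pf / 2)
      A[ri, ih(i, j)] <- -pf * rho / 4
      # stationary balance
      ri <- ih(i, j)
      A[ri, ih(i, j)] <- v * rho * pf / 2 + p$k_d
      A[ri, ia(i, j - 1L)] <- -v * pf / 2
      A[ri, ib(i, j + 1L)] <- -v * pf / 2
    }
  }
  u <- tryCatch(solve(A, b), error = function(e)
    stop("singular mean-field system at the supplied parameters: ", conditionMessage(e)))
  Hm <- matrix(u[outer(seq_len(n), seq_len(S), ih)], n, S)
  new_meanfield_solution(
    params = p,
    H_plus_edges = cbind(left = u[ia(seq_len(n), 0L)], right = u[ia(seq_len(n), S)]),
    H_minus_edges = cbind(left = u[ib(seq_len(n), 1L)], right = u[ib(seq_len(n), S + 1L)]),
    H_sites = rowSums(Hm),
    H_site_mito = Hm,
    rho = dens$rho, S = S, M_total = dens$M_total,
    residual = max(abs(A %*% u - b)))
}

#' Solve the steady-state mean-field model
#'
#' Dispatches to [solve_cog()] or [solve_ss()] according to the model slot.
#' @param params A [mito_params()] object.
#' @return A `meanfield_solution` object.
#' @export
solve_meanfield <- function(params) {
  if (params$model == "cog") solve_cog(params) else solve_ss(params)
}

new_meanfield_solution <- function(params, H_plus_edges, H_minus_edges,
                                   H_sites, H_site_mito, rho, S, M_total,
                                   residual) {
  structure(list(params = params, x_sites = demand_site_positions(params$n, params$L),
                 H_plus_edges = H_plus_edges, H_minus_edges = H_minus_edges,
                 H_sites = H_sites, H_site_mito = H_site_mito, rho = rho,
                 S = S, M_total = M_total, residual = residual),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("<meanfield_solution> %s model, n = %d sites, M = %.4g\n",
              toupper(x$params$model), x$params$n, x$M_total))
  m <- health_metrics(x)
  cat(sprintf("  <H^> = %.4g   H^_n = %.4g   rho = %.4g   S = %.4g\n",
              m$Hhat_avg, m$Hhat_last, x$rho, x$S))
  invisible(x)
}

#' Normalized health metrics
#'
#' Per-site health normalized by the mitochondrial content per site:
#' `Hhat_i = H_i / (M_ref / n)`. With the default `M_ref` equal to the
#' solution's total population this is the health per mitochondrion
#' allocated to the site. Passing the zero-mitophagy reference population
#' as `M_ref` instead gives the fixed-production normalization
#' `Hhat_i^(0) = H_i / (M^(0)/n)` used when mitophagy depletes the
#' population at constant production rate.
#'
#' @param sol A `meanfield_solution`.
#' @param M_ref Reference population for the normalization; defaults to
#'   `sol$M_total`.
#' @return A list with `Hhat_sites`, `Hhat_avg` and `Hhat_last`.
#' @export
health_metrics <- function(sol, M_ref = NULL) {
  stopifnot(inherits(sol, "meanfield_solution"))
  if (is.null(M_ref)) M_ref <- sol$M_total
  if (!is.finite(M_ref) || M_ref <= 0) stop("M_ref must be a positive count")
  Hhat <- sol$H_sites / (M_ref / sol$params$n)
  list(Hhat_sites = Hhat, Hhat_avg = mean(Hhat), Hhat_last = Hhat[length(Hhat)])
}

#' Sample the motile health-density profiles on a grid
#'
#' Evaluates the piecewise-exponential steady-state profiles `H+(x)` and
#' `H-(x)` between demand sites for plotting or export.
#'
#' @param sol A `meanfield_solution`.
#' @param x Positions in `[0, L]` (default: 400 evenly spaced points).
#' @return A tibble with columns `x`, `H_plus`, `H_minus`.
#' @export
sample_profile <- function(sol, x = NULL) {
  p <- sol$params
  if (is.null(x)) x <- seq(0, p$L, length.out = 400L)
  stopifnot(all(x >= 0), all(x <= p$L))
  xs <- sol$x_sites
  n <- p$n
  kdv <- p$k_d / p$v
  # interval index: 0 = [0, x_1), i = [x_i, x_{i+1}), n = [x_n, L]
  iv <- findInterval(x, xs)
  Hp <- numeric(length(x)); Hm <- numeric(length(x))
  HpR <- c(p$k_p / p$v, unname(sol$H_plus_edges[, "right"]))  # interval left edges
  x0 <- c(0, xs)
  Hp <- HpR[iv + 1L] * exp(-kdv * (x - x0[iv + 1L]))
  # retrograde: value at the distal edge of each interval decays toward soma
  HL <- sol$H_plus_edges[n, "right"] * exp(-kdv * (p$L - xs[n]))  # H+(L) = H-(L)
  HmEnd <- unname(c(sol$H_minus_edges[, "left"], HL))  # interval right edges
  x1 <- c(xs, p$L)
  Hm <- HmEnd[iv + 1L] * exp(-kdv * (x1[iv + 1L] - x))
  tibble::tibble(x = x, H_plus = Hp, H_minus = Hm)
}
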