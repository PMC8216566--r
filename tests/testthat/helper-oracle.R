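# Independent steady-state oracle for the CoG mean-field system: first-order
# upwind discretization of the transport-decay equations on a K-point grid,
# solved by fixed-point iteration on the site healths (propagate the motile
# profiles left-to-right and right-to-left through the current site values,
# update the sites, repeat). Shares no code path with the package solver,
# which uses exact exponential interval propagation and one linear solve.
oracle_cog_fd <- function(params, K = 1e5, tol = 1e-13, max_iter = 5000) {
  p <- params
  stopifnot(p$model == "cog")
  xs <- demand_site_positions(p$n, p$L)
  dx <- p$L / K
  fac <- 1 - p$k_d * dx / p$v          # upwind decay per cell
  cell <- round(xs / dx)               # site locations on the grid
  r <- p$alpha * p$v / (2 * p$L)
  S <- if (p$p_s == 0) 0 else p$v * (2 * p$k_p / p$v) * p$p_s / p$k_w
  H <- rep(0, p$n)
  for (it in seq_len(max_iter)) {
    HpL <- numeric(p$n); HmR <- numeric(p$n)
    # anterograde sweep
    val <- p$k_p / p$v; prev <- 0
    for (i in seq_len(p$n)) {
      val <- val * fac^(cell[i] - prev)
      HpL[i] <- val
      val <- val * (1 - p$p_s) + p$k_w * H[i] / (2 * p$v)
      prev <- cell[i]
    }
    val <- val * fac^(K - cell[p$n])   # to the distal end; reflect
    # retrograde sweep
    prev <- K
    for (i in rev(seq_len(p$n))) {
      val <- val * fac^(prev - cell[i])
      HmR[i] <- val
      val <- val * (1 - p$p_s) + p$k_w * H[i] / (2 * p$v)
      prev <- cell[i]
    }
    Hn <- (p$v * p$p_s * (HpL + HmR) + r * S) / (p$k_d + p$k_w)
    if (max(abs(Hn - H)) <= tol * max(Hn, 1e-300)) {
      H <- Hn
      break
    }
    H <- Hn
  }
  H
}
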