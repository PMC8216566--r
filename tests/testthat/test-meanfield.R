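test_that("steady-state density follows rho = 2 k_p / v and S = v rho p_s / k_w", {
  p <- mito_params("cog", k_p = 1, v = 1, p_s = 0.2, k_w = 1, n = 5)
  d <- solve_density(p)
  expect_equal(d$rho, 2)
  expect_equal(d$S_per_site, 0.4)
  expect_equal(d$M_total, 2 + 5 * 0.4)

  expect_equal(solve_density(mito_params("cog", k_p = 1, p_s = 0, k_w = 1, n = 3))$S_per_site, 0)
  d0 <- solve_density(mito_params("cog", k_p = 0, p_s = 0.5, k_w = 1, n = 3))
  expect_equal(d0$rho, 0)
  expect_equal(d0$S_per_site, 0)
  expect_error(solve_density(mito_params("cog", k_p = 1, p_s = 0.5, k_w = 0, n = 3)),
               "k_w = 0")
})

test_that("without decay every mitochondrion keeps health 1, so Hhat_i = f_s", {
  for (model in c("cog", "ss")) {
    p <- params_from_targets(0.5, 4, 0, M = 40, n = 5, model = model)
    m <- health_metrics(solve_meanfield(p))
    expect_equal(m$Hhat_sites, rep(0.5, 5), tolerance = 1e-12)
  }
})

test_that("CoG solver matches an independent finite-difference oracle", {
  p <- params_from_targets(0.5, 2 * 0.1 * 2, 0.3, M = 10, n = 2, model = "cog")
  H <- solve_cog(p)$H_sites
  expect_equal(H, oracle_cog_fd(p), tolerance = 1e-4)
  # including the local-translation source term
  pt <- params_from_targets(0.5, 0.4, 0.6, M = 10, n = 5, model = "cog",
                            alpha = 0.3)
  expect_equal(solve_cog(pt)$H_sites, oracle_cog_fd(pt), tolerance = 1e-4)
})

test_that("the SS system at S = 1 is the CoG system under p_s -> p_f/2", {
  for (fs in c(0.2, 0.5, 0.8)) {
    n <- 5; M <- round(n / fs)  # S = 1 exactly
    fs_i <- n / M
    pc <- params_from_targets(fs_i, 1, 0.6, M = M, n = n, model = "cog")
    ps <- params_from_targets(fs_i, 1, 0.6, M = M, n = n, model = "ss")
    expect_identical(ps$S, 1L)
    hc <- health_metrics(solve_cog(pc))$Hhat_sites
    hs <- health_metrics(solve_ss(ps))$Hhat_sites
    expect_equal(hc, hs, tolerance = 1e-10)
  }
})

test_that("SS without fusion decays to zero site health and a bare exponential profile", {
  p <- mito_params("ss", k_d = 0.6, k_p = 2, n = 5, p_f = 0, S = 2)
  sol <- solve_ss(p)
  expect_equal(sol$H_sites, rep(0, 5), tolerance = 1e-12)
  prof <- sample_profile(sol, x = seq(0, 1, 0.05))
  expect_equal(prof$H_plus, 2 * exp(-0.6 * prof$x), tolerance = 1e-12)
  expect_equal(prof$H_minus, 2 * exp(-0.6 * (2 - prof$x)), tolerance = 1e-12)
})

test_that("normalized health is invariant under rescaling the population", {
  # CoG is exactly linear in k_p, so the invariance is exact; in SS a larger
  # population also means more residents per site (S = f_s M / n), which
  # perturbs the per-resident structure only weakly
  tol <- c(cog = 1e-10, ss = 1e-3)
  for (model in c("cog", "ss")) {
    p1 <- params_from_targets(0.4, 2, 0.6, M = 200, n = 5, model = model)
    p2 <- params_from_targets(0.4, 2, 0.6, M = 2000, n = 5, model = model)
    m1 <- health_metrics(solve_meanfield(p1))
    m2 <- health_metrics(solve_meanfield(p2))
    expect_equal(m1$Hhat_avg, m2$Hhat_avg, tolerance = tol[[model]])
    expect_equal(m1$Hhat_sites, m2$Hhat_sites, tolerance = tol[[model]])
  }
})

test_that("the assembled linear systems are solved to tight residuals", {
  p <- params_from_targets(0.5, 4, 0.6, M = 300, n = 5, model = "cog")
  expect_lt(solve_cog(p)$residual, 1e-10)
  ps <- params_from_targets(0.5, 2, 0.6, M = 300, n = 10, model = "ss")
  expect_lt(solve_ss(ps)$residual, 1e-10)
})

test_that("health depends on (f_s, N_s, khat_d), not separately on n", {
  m30 <- health_metrics(solve_cog(params_from_targets(0.5, 2, 0.06, M = 300,
                                                      n = 30, model = "cog")))
  m100 <- health_metrics(solve_cog(params_from_targets(0.5, 2, 0.06, M = 300,
                                                       n = 100, model = "cog")))
  expect_lt(abs(m30$Hhat_avg - m100$Hhat_avg) / m30$Hhat_avg, 0.05)
})

test_that("the no-decay limit of average health is the stationary fraction", {
  for (fs in c(0.3, 0.7)) {
    p <- params_from_targets(fs, 2, 1e-8, M = 100, n = 5, model = "cog")
    expect_equal(health_metrics(solve_cog(p))$Hhat_avg, fs, tolerance = 1e-4)
  }
})

test_that("fresh somal production keeps anterograde above retrograde health proximally", {
  p <- params_from_targets(0.5, 4, 0.6, M = 300, n = 5, model = "cog")
  prof <- sample_profile(solve_cog(p), x = 0)
  expect_gt(prof$H_plus, prof$H_minus)
})

test_that("site health decreases with distance from the soma at the reference parameters", {
  p <- params_from_targets(0.5, 4, 0.6, M = 300, n = 5, model = "cog")
  H <- health_metrics(solve_cog(p))$Hhat_sites
  expect_true(all(diff(H) < 0))
})

test_that("health metrics normalize by the chosen reference population", {
  p <- params_from_targets(0.5, 4, 0.6, M = 300, n = 5, model = "cog")
  sol <- solve_cog(p)
  m <- health_metrics(sol)
  expect_equal(m$Hhat_avg, mean(m$Hhat_sites))
  expect_equal(m$Hhat_last, m$Hhat_sites[5])
  m2 <- health_metrics(sol, M_ref = 2 * sol$M_total)
  expect_equal(m2$Hhat_avg, m$Hhat_avg / 2)
  expect_error(health_metrics(sol, M_ref = 0), "M_ref")
  # uniform site health c gives Hhat_avg = c n / M
  fake <- sol; fake$H_sites <- rep(2, 5)
  expect_equal(health_metrics(fake)$Hhat_avg, 2 * 5 / sol$M_total)
})

test_that("degenerate and unsupported configurations are rejected", {
  expect_error(solve_cog(mito_params("cog", k_d = 0, k_p = 1, n = 2,
                                     p_s = 0.5, k_w = 0)))
  expect_error(solve_ss(mito_params("ss", k_d = 0, k_p = 1, n = 2,
                                    p_f = 0, S = 1)), "degenerate")
  p <- mito_params("ss", k_d = 0.6, k_p = 1, n = 2, p_f = 0.5, S = 1,
                   alpha = 0.1)
  expect_error(solve_ss(p), "CoG")
})

test_that("tidy and glance expose the solution as tables", {
  p <- params_from_targets(0.5, 4, 0.6, M = 300, n = 5, model = "cog")
  sol <- solve_cog(p)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("site", "x", "H", "Hhat"))
  expect_equal(nrow(td), 5)
  gl <- glance(sol)
  expect_equal(gl$Hhat_avg, mean(td$Hhat))
})
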