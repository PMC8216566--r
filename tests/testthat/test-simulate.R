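# shared quick configurations: short runs are used where only relative or
# exact properties are checked; steady-state comparisons use longer runs
cfg_quick <- function(...) sim_config(n_steps = 2e4, n_iter = 5, seed = 99, ...)

test_that("identical parameters, settings and seed reproduce results bit for bit", {
  p <- params_from_targets(0.5, 2, 0.6, M = 150, n = 5, model = "cog", phi = 0.1)
  a <- run_cog(p, cfg_quick())
  b <- run_cog(p, cfg_quick())
  expect_identical(a$H_sites, b$H_sites)
  expect_identical(a$counts, b$counts)
  ps <- params_from_targets(0.5, 2, 0.6, M = 150, n = 5, model = "ss", phi = 0.1)
  expect_identical(run_ss(ps, cfg_quick())$H_sites, run_ss(ps, cfg_quick())$H_sites)
  # a different seed gives a different realization
  c2 <- run_cog(p, sim_config(n_steps = 2e4, n_iter = 5, seed = 100))
  expect_false(identical(a$H_sites, c2$H_sites))
})

test_that("nothing stops when the stopping probability is zero", {
  p <- mito_params("cog", k_d = 0.3, k_p = 40, n = 5, p_s = 0, k_w = 1)
  r <- run_cog(p, cfg_quick())
  expect_equal(r$H_sites_mean, rep(0, 5))
  expect_equal(r$realized_fs, 0)
})

test_that("without decay all health stays at 1 and site health counts mitochondria", {
  p <- params_from_targets(0.5, 2, 0, M = 200, n = 5, model = "cog")
  r <- run_cog(p, sim_config(n_steps = 4e4, n_iter = 10, seed = 3))
  # every stationary agent carries health exactly 1
  expect_equal(r$H_sites_mean, r$site_count_mean, tolerance = 1e-12)
  # normalized average health equals the realized stationary fraction
  expect_lt(abs(r$Hhat_avg_mean - r$realized_fs), 3 * max(r$Hhat_avg_sem, 1e-3))
})

test_that("SS sites decay as a bare exponential when fusion is disabled", {
  p <- mito_params("ss", k_d = 0.6, k_p = 10, n = 4, p_f = 0, S = 3, M = 52)
  r <- run_ss(p, sim_config(n_steps = 1e4, n_iter = 2, seed = 1))
  expect_equal(r$H_sites_mean, rep(3 * exp(-0.6 * 1e4 * 1e-3), 4),
               tolerance = 1e-10)
})

test_that("steady-state population matches the mean-field density", {
  p <- params_from_targets(0.5, 2, 0.6, M = 200, n = 5, model = "cog")
  cfg <- sim_config(n_steps = 1e5, n_iter = 8, seed = 17, record_stride = 1000)
  r <- run_cog(p, cfg)
  # birth saturation: at most one production event per step, so the realized
  # influx is 1 - exp(-k_p dt) per step rather than k_p dt
  q <- (1 - exp(-p$k_p * cfg$dt)) / cfg$dt
  expect_eff <- solve_density(mito_params("cog", k_d = p$k_d, k_p = q, n = 5,
                                          p_s = p$p_s, k_w = p$k_w))$M_total
  tail_M <- vapply(r$rec_counts, function(m) mean(m[91:100, 5]), numeric(1))
  expect_lt(abs(mean(tail_M) - expect_eff) / expect_eff, 0.1)
  # the last 10% of steps is trend-free: halves agree within noise
  h1 <- vapply(r$rec_counts, function(m) mean(m[91:95, 5]), numeric(1))
  h2 <- vapply(r$rec_counts, function(m) mean(m[96:100, 5]), numeric(1))
  expect_lt(abs(mean(h1) - mean(h2)),
            3 * sqrt(var(h1) / 8 + var(h2) / 8) + 1e-9)
})

test_that("the fixed-population variant conserves the count at every step", {
  for (model in c("cog", "ss")) {
    p <- params_from_targets(0.5, 2, 0.6, M = 100, n = 5, model = model,
                             phi = 0.15)
    r <- simulate_model(p, sim_config(n_steps = 2e4, n_iter = 3, seed = 8,
                                      fixed_M = TRUE, record_stride = 500))
    for (m in r$rec_counts) expect_true(all(m[, 5] == 100))
  }
})

test_that("engulfed mitochondria count toward the population but not site health", {
  p <- params_from_targets(0.53, 2, 0.6, M = 200, n = 10, model = "ss",
                           phi = 0.3)
  r <- run_ss(p, sim_config(n_steps = 4e4, n_iter = 5, seed = 2))
  expect_gt(r$counts[["engulfed"]], 0)
  expect_equal(r$counts[["total"]],
               r$counts[["motile"]] + r$counts[["stationary"]] +
                 r$counts[["engulfed"]])
  # stationary health never exceeds the count (health <= 1 per mitochondrion)
  expect_true(all(r$H_sites_mean <= r$site_count_mean + 1e-9))
})

test_that("infeasible simulation settings are rejected", {
  p <- params_from_targets(0.5, 2, 0.6, M = 100, n = 5, model = "cog")
  expect_error(run_cog(p, sim_config(dt = 0.2)), "gap")
  expect_error(run_cog(p, sim_config(dt = 1e-3, n_steps = 2e6)), "600")
  ps <- params_from_targets(0.5, 2, 0.6, M = 100, n = 5, model = "ss")
  expect_error(run_cog(ps, cfg_quick()), "CoG")
  expect_error(run_ss(p, cfg_quick()), "SS")
})

test_that("halving the time step leaves steady-state means within sampling error", {
  p <- params_from_targets(0.5, 2, 0.6, M = 200, n = 5, model = "cog")
  r1 <- run_cog(p, sim_config(dt = 1e-3, n_steps = 4e4, n_iter = 12, seed = 21))
  r2 <- run_cog(p, sim_config(dt = 5e-4, n_steps = 8e4, n_iter = 12, seed = 22))
  sem <- sqrt(r1$Hhat_avg_sem^2 + r2$Hhat_avg_sem^2)
  expect_lt(abs(r1$Hhat_avg_mean - r2$Hhat_avg_mean), 3 * sem)
})

test_that("local translation raises stationary health in the stochastic model", {
  p0 <- params_from_targets(0.5, 0.4, 0.6, M = 150, n = 5, model = "cog")
  pt <- p0; pt$alpha <- 0.3
  r0 <- run_cog(p0, sim_config(n_steps = 4e4, n_iter = 10, seed = 31))
  rt <- run_cog(pt, sim_config(n_steps = 4e4, n_iter = 10, seed = 31))
  expect_gt(rt$Hhat_avg_mean, r0$Hhat_avg_mean)
  # distal sites benefit most
  gain <- rt$H_sites_mean / pmax(r0$H_sites_mean, 1e-12)
  expect_gt(gain[5], gain[1])
})

test_that("variability statistic matches hand calculations", {
  # all iterations identical
  expect_equal(variability(matrix(2, 4, 3)), 0)
  # two iterations, one region, healths 1 and 3: sd = sqrt(2), mean = 2
  expect_equal(variability(matrix(c(1, 3), 2, 1)), sqrt(2) / 2)
  # pooled mode on the same input
  expect_equal(variability(matrix(c(1, 3), 2, 1), mode = "pooled"), sqrt(2) / 2)
  # region-averaged (pooled) differs once regions are heterogeneous
  H <- rbind(c(1, 5), c(3, 3))
  expect_equal(variability(H), (sd(c(1, 3)) + sd(c(5, 3))) / 2 / 3)
  expect_equal(variability(H, "pooled"), 0)
  expect_error(variability(matrix(1, 1, 3)), "2 iterations")
})

test_that("fusion lowers health variability in SS compared with CoG", {
  # content equilibration through kiss-and-run keeps SS site health much
  # quieter than whole-organelle exchange, across stationary fractions
  cfg <- sim_config(n_steps = 4e4, n_iter = 40, seed = 41)
  for (fs in c(0.35, 0.7)) {
    pc <- params_from_targets(fs, 2, 0.6, M = 300, n = 10, model = "cog")
    ps <- params_from_targets(fs, 2, 0.6, M = 300, n = 10, model = "ss")
    vc <- run_cog(pc, cfg)$sigma_over_mean
    vs <- run_ss(ps, cfg)$sigma_over_mean
    expect_gt(vc, vs)
  }
})

test_that("SS placement and retrograde-fusion options behave as documented", {
  ps <- params_from_targets(0.5, 2, 0.6, M = 120, n = 6, model = "ss")
  # random placement conserves the resident total but not the per-site split
  rr <- run_ss(ps, sim_config(n_steps = 1e4, n_iter = 6, seed = 55,
                              ss_placement = "random"))
  expect_equal(rr$counts[["stationary"]], 6 * ps$S)
  expect_gt(max(rr$site_count_mean) - min(rr$site_count_mean), 0)
  ru <- run_ss(ps, sim_config(n_steps = 1e4, n_iter = 6, seed = 55))
  expect_equal(ru$site_count_mean, rep(ps$S, 6))
  # forbidding retrograde fusion changes the realization but still runs
  rf <- run_ss(ps, sim_config(n_steps = 1e4, n_iter = 6, seed = 55,
                              forbid_retrograde_fusion = TRUE))
  expect_false(identical(rf$H_sites, ru$H_sites))
})

test_that("trajectory dumps are deterministic with a stable schema", {
  p <- params_from_targets(0.5, 2, 0.6, M = 30, n = 5, model = "cog")
  cfg <- sim_config(n_steps = 2000, n_iter = 1, seed = 5, record_stride = 200,
                    record_trajectory = TRUE)
  r <- run_cog(p, cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  dump_trajectory(r, f1)
  dump_trajectory(run_cog(p, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- utils::read.csv(f1)
  expect_named(d, c("t", "iteration", "agent_id", "x", "state", "health"))
  # one frame per stride, plus the initial frame when agents exist at t = 0
  ps <- params_from_targets(0.5, 2, 0.6, M = 30, n = 5, model = "ss")
  ds <- run_ss(ps, cfg)
  fs <- tempfile(fileext = ".csv"); dump_trajectory(ds, fs)
  expect_equal(length(unique(utils::read.csv(fs)$t)), 2000 / 200 + 1)
  expect_true(all(d$state %in% c("anterograde", "retrograde", "stationary",
                                 "engulfed")))
  # an empty system dumps a header-only file
  p0 <- mito_params("cog", k_d = 0.1, k_p = 0, n = 2, p_s = 0.1, k_w = 1)
  r0 <- run_cog(p0, cfg)
  f0 <- tempfile(fileext = ".csv")
  dump_trajectory(r0, f0)
  expect_equal(length(readLines(f0)), 1L)
  # asking for a dump without recording errors
  expect_error(dump_trajectory(run_cog(p, cfg_quick()), tempfile()), "record_trajectory")
})

test_that("ensemble results tidy into per-site and summary tables", {
  p <- params_from_targets(0.5, 2, 0.6, M = 100, n = 5, model = "cog")
  r <- run_cog(p, cfg_quick())
  td <- tidy(r)
  expect_equal(nrow(td), 5)
  expect_named(td, c("site", "x", "H_mean", "H_std", "Hhat_mean", "count_mean"))
  gl <- glance(r)
  expect_equal(gl$M_total, r$counts[["total"]])
})
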