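# Single-nephron model: algebraic closures, cubic solve, dynamics.

test_that("Henle flow and afferent resistance follow their closed forms", {
  p <- nephron_params()
  expect_equal(henle_flow(p$p_d, p), 0)
  expect_equal(henle_flow(1.79, p), (1.79 - 0.6) / 5.3)
  expect_equal(henle_flow(2.79, p) - henle_flow(1.79, p), 1 / 5.3)  # linear
  ar1 <- afferent_resistance(1, p)
  expect_equal(ar1$r_a, p$r_a0)           # beta + (1 - beta) = 1
  expect_equal(ar1$R, 1)
  expect_equal(afferent_resistance(0.9, p)$r_a,
               2.4 * (0.67 + 0.33 / 0.9^4))
  expect_equal(afferent_resistance(1e6, p)$r_a, p$beta * p$r_a0,
               tolerance = 1e-12)         # dilated limit
  expect_error(afferent_resistance(-0.1, p), "positive")
})

test_that("TGF activation hits its midpoint, limits and monotonicity", {
  p <- nephron_params()
  x3_eq <- p$t_delay * p$f_hen0 / 3
  expect_equal(tgf_activation(x3_eq, p), p$psi_eq, tolerance = 1e-14)
  expect_equal(tgf_activation(1e3, p), p$psi_max, tolerance = 1e-12)
  expect_lt(tgf_activation(0, p) - p$psi_min, 1e-8)
  xs <- seq(0, 3, by = 0.01)
  expect_true(all(diff(tgf_activation(xs, p)) >= 0))   # saturates in the tails
  mid <- seq(0.5, 1.5, by = 0.01)                      # strictly rising center
  expect_true(all(diff(tgf_activation(mid, p)) > 0))
})

test_that("equilibrium pressure components match their printed forms", {
  p <- nephron_params()
  eq <- equilibrium_pressure(1, 0.38, p)
  expect_equal(eq$p_el, 2.4 * exp(-4))
  expect_equal(eq$p_el, 0.0439, tolerance = 1e-2)
  expect_equal(equilibrium_pressure(1, 0, p)$p_eq,
               equilibrium_pressure(1, 0, p)$p_el)   # Psi = 0
  # P_act is monotone increasing on the physiological radius range
  rr <- seq(0.6, 1.6, by = 0.01)
  expect_true(all(diff(equilibrium_pressure(rr, 0.38, p)$p_act) > 0))
})

test_that("the protein cubic is solved to high accuracy and matches a scan oracle", {
  p <- nephron_params()
  st <- nephron_example_state()
  R <- afferent_resistance(st["r"], p)$R
  ce <- solve_ce(st["p_t"], 13.3, R, p)
  co <- ce_coefficients(st["p_t"], 13.3, R, p)
  resid <- abs(((co$A * ce + co$B) * ce + co$C) * ce + co$D)
  scale <- (abs(co$A) * ce + abs(co$B)) * ce^2 + abs(co$C) * ce + abs(co$D)
  expect_lt(resid / scale, 1e-10)
  expect_equal(ce, ce_scan_oracle(st["p_t"], 13.3, R, p), tolerance = 1e-8)
  expect_gt(ce, p$c_a)                  # filtration concentrates protein
  # residuals stay below 1e-10 across an operating sweep
  pts <- expand.grid(p_t = seq(0.8, 3, by = 0.2), p_a = seq(8, 16, by = 1))
  ces <- solve_ce(pts$p_t, pts$p_a, 1, p)
  cos <- ce_coefficients(pts$p_t, pts$p_a, 1, p)
  res <- abs(((cos$A * ces + cos$B) * ces + cos$C) * ces + cos$D) /
    ((abs(cos$A) * ces + abs(cos$B)) * ces^2 + abs(cos$C) * ces + abs(cos$D))
  expect_lt(max(res), 1e-10)
})

test_that("the cubic reduces to the quadratic closed form when b = 0", {
  p <- nephron_params(b = 0)
  co <- ce_coefficients(1.7923, 13.3, 1, p)
  expect_equal(co$A, 0)
  ce <- solve_ce(1.7923, 13.3, 1, p)
  # quadratic closed form: B x^2 + C x + D = 0, positive branch
  ce_quad <- (-co$C + sqrt(co$C^2 - 4 * co$B * co$D)) / (2 * co$B)
  expect_equal(ce, ce_quad, tolerance = 1e-10)
})

test_that("an out-of-regime state raises a classed, state-carrying error", {
  p <- nephron_params()
  # P_t far above P_a: all cubic coefficients positive, no positive root
  err <- tryCatch(solve_ce(20, 5, 1, p), error = identity)
  expect_s3_class(err, "nephronet_ce_error")
  expect_equal(err$state$p_t, 20)
})

test_that("glomerular block reproduces printed arithmetic and identities", {
  p <- nephron_params()
  gb <- glomerular_block(60, 1.79, 13.3, 2.4, p)
  expect_equal(gb$p_g, 0.39e-3 * 3600 + 21.7e-3 * 60 + 1.79)
  expect_equal(gb$p_g, 4.496, tolerance = 1e-3)
  # no protein concentration change, no filtration
  expect_equal(glomerular_block(p$c_a, 1.79, 13.3, 2.4, p)$f_filt, 0)
  # r = 1 substitution identity for the mean arteriolar pressure
  gb1 <- glomerular_block(60, 1.79, 13.3, p$r_a0, p)
  expect_equal(gb1$p_av, 0.5 * (13.3 - (13.3 - gb1$p_g) * p$beta + gb1$p_g))
  expect_equal(gb$f_eff, (gb$p_g - p$p_v) / p$r_e)
})

test_that("the full right-hand side matches an independent transcription", {
  p <- nephron_params()
  st <- nephron_example_state()
  mine <- nephron_derivatives(st, 13.3, p)$deriv
  oracle <- nephron_rhs_oracle(unname(st), 13.3, p)
  expect_lt(max(abs(unname(mine) - oracle)) / max(abs(oracle)), 1e-10)
  # a state constructed so that F_filt = F_reab + F_Hen has dP_t/dt = 0
  balance <- function(p_t) {
    s <- st; s["p_t"] <- p_t
    a <- nephron_derivatives(s, 13.3, p)$aux
    a$f_filt - p$f_reab - a$f_hen
  }
  p_t_star <- stats::uniroot(balance, c(0.5, 3), tol = 1e-12)$root
  st2 <- st; st2["p_t"] <- p_t_star
  expect_lt(abs(nephron_derivatives(st2, 13.3, p)$deriv["p_t"]), 1e-10)
  # equalized delay chain: the downstream stages are stationary
  st3 <- st; st3[c("x1", "x2", "x3")] <- 0.9
  d3 <- nephron_derivatives(st3, 13.3, p)$deriv
  expect_equal(unname(d3["x2"]), 0)
  expect_equal(unname(d3["x3"]), 0)
})

test_that("the nephron oscillates on a stable limit cycle inside its window", {
  sim <- simulate_nephron(12.25, t_end = 900)
  tr <- sim$trace[sim$trace$time >= 300, ]
  expect_gt(diff(range(tr$p_t)), 0.01)
  pk <- nephronet:::peak_times(tr$time, tr$p_t, 0.01)
  periods <- diff(pk)
  n <- length(periods)
  expect_gt(n, 10)
  # period and amplitude stabilize to < 1% between successive cycles
  late_periods <- periods[(n - 4):n]
  expect_lt(max(abs(diff(late_periods))) / mean(late_periods), 0.01)
  amp_of_cycle <- vapply(seq_len(length(pk) - 1), function(k) {
    seg <- tr$p_t[tr$time >= pk[k] & tr$time <= pk[k + 1]]
    diff(range(seg))
  }, numeric(1))
  la <- amp_of_cycle[(n - 4):n]
  expect_lt(max(abs(diff(la))) / mean(la), 0.01)
  # TGF period is of the order of half a minute
  expect_gt(mean(late_periods), 15)
  expect_lt(mean(late_periods), 60)
})

test_that("steady-state balances hold where the nephron is quiescent", {
  sim <- simulate_nephron(15, t_end = 800)
  tr <- sim$trace
  expect_lt(tail_amplitude(sim, 500), 1e-3)
  last <- tr[nrow(tr), ]
  expect_equal(last$f_filt, nephron_params()$f_reab + last$f_hen,
               tolerance = 1e-4)
  expect_equal(3 * last$x3 / nephron_params()$t_delay, last$f_hen,
               tolerance = 1e-4)
})

test_that("oscillations persist across the stated beta and alpha ranges", {
  for (b in c(0.4, 0.67)) for (al in c(12, 20)) {
    p <- nephron_params(beta = b, alpha = al)
    sim <- simulate_nephron(12, p, t_end = 600)
    expect_gt(tail_amplitude(sim, 300), 0.01)
  }
})

test_that("autoregulation sweep reports averages, amplitudes and activity", {
  sw <- autoregulation_sweep(c(6, 12.25), t_transient = 200, t_measure = 200)
  expect_s3_class(sw, "autoregulation_sweep")
  expect_false(sw$oscillating[1])
  expect_true(sw$oscillating[2])
  expect_false(sw$active[1] && sw$p_t_mean[1] < 0)
  expect_error(autoregulation_sweep(c(12, 6)), "increasing")
})
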