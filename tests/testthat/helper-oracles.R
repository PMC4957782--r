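# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths (plain loops, dense solves,
# polyroot, recursion) than the implementations they check.

# bottom-up recursive Strahler ordering (memoized through an environment)
strahler_brute <- function(tree) {
  v <- tree$vessels
  children <- split(seq_len(nrow(v)), v$parent_node)
  memo <- new.env()
  rec <- function(i) {
    key <- as.character(i)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    ch <- children[[as.character(v$child_node[i])]]
    val <- if (is.null(ch)) 1L else {
      co <- vapply(ch, rec, integer(1))
      m <- max(co)
      if (sum(co == m) >= 2L) m + 1L else m
    }
    assign(key, val, envir = memo)
    val
  }
  vapply(seq_len(nrow(v)), rec, integer(1))
}

# dense direct solve of the endothelial steady state, assembled by loops
dense_voltage_oracle <- function(net, units, currents) {
  n <- net$n_units
  A <- matrix(0, n, n)
  for (k in seq_along(net$links$g)) {
    i <- net$links$i[k]; j <- net$links$j[k]; g <- net$links$g[k]
    A[i, i] <- A[i, i] + g; A[j, j] <- A[j, j] + g
    A[i, j] <- A[i, j] - g; A[j, i] <- A[j, i] - g
  }
  diag(A) <- diag(A) + net$g_u + net$ground
  I <- numeric(n); I[units] <- currents
  net$v_rest + solve(A, I)
}

# positive root of the efferent-protein cubic by sign scan + uniroot
ce_scan_oracle <- function(p_t, p_a, R, params) {
  co <- ce_coefficients(p_t, p_a, R, params)
  f <- function(x) ((co$A * x + co$B) * x + co$C) * x + co$D
  xs <- seq(1e-6, 500, length.out = 1e6)
  fx <- f(xs)
  k <- which(fx[-1] * fx[-length(fx)] <= 0)[1]
  stopifnot(!is.na(k))
  stats::uniroot(f, c(xs[k], xs[k + 1]), tol = 1e-14)$root
}

# independent transcription of the six-ODE right-hand side (polyroot cubic)
nephron_rhs_oracle <- function(state, p_a, pp) {
  p_t <- state[1]; r <- state[2]; v_r <- state[3]
  x1 <- state[4]; x2 <- state[5]; x3 <- state[6]
  f_hen <- (p_t - pp$p_d) / pp$r_hen
  r_a <- pp$r_a0 * (pp$beta + (1 - pp$beta) / r^4)
  R <- pp$r_a0 / r_a
  A <- pp$b + R * pp$b * pp$h_a
  B <- pp$a + R * pp$b * pp$c_a * (1 - pp$h_a) + R * pp$a * pp$h_a
  C <- p_t - pp$p_v + R * pp$a * pp$c_a * (1 - pp$h_a) +
    R * (p_t - p_a) * pp$h_a
  D <- (p_t - p_a) * R * pp$c_a * (1 - pp$h_a)
  rts <- polyroot(c(D, C, B, A))
  real <- Re(rts[abs(Im(rts)) < 1e-8 * Mod(rts)])
  ce <- max(real[real > 0])
  p_g <- pp$b * ce^2 + pp$a * ce + p_t
  p_av <- 0.5 * (p_a - (p_a - p_g) * pp$beta * pp$r_a0 / r_a + p_g)
  f_filt <- (1 - pp$h_a) * (1 - pp$c_a / ce) * (p_a - p_g) / r_a
  q <- (pp$psi_eq - pp$psi_min) / (pp$psi_max - pp$psi_eq)
  psi <- pp$psi_max - (pp$psi_max - pp$psi_min) /
    (1 + q * exp(pp$alpha * (3 * x3 / (pp$t_delay * pp$f_hen0) - 1)))
  p_el <- 1.6 * (r - 1) + 2.4 * exp(10 * (r - 1.4))
  p_act <- 4.7 / (1 + exp(13 * (0.4 - r))) + 7.2 * r + 6.3
  p_eq <- p_el + psi * p_act
  c((f_filt - pp$f_reab - f_hen) / pp$c_tub,
    v_r,
    (p_av - p_eq) / pp$omega - pp$k_damp * v_r,
    f_hen - 3 / pp$t_delay * x1,
    3 / pp$t_delay * (x1 - x2),
    3 / pp$t_delay * (x2 - x3))
}

# per-node flow balance residuals of a pressure solution, by plain loops
flow_balance_oracle <- function(tree, p_root, state) {
  v <- tree$vessels
  art <- v[v$kind != "afferent_arteriole", ]
  P <- stats::setNames(state$pressure, state$node)
  getp <- function(node) {
    if (node %in% names(P)) unname(P[as.character(node)]) else p_root
  }
  res <- vessel_resistance(art$diameter, art$length)
  bal <- stats::setNames(numeric(length(state$node)), state$node)
  for (k in seq_len(nrow(art))) {
    up <- getp(art$parent_node[k]); dn <- getp(art$child_node[k])
    f <- (up - dn) / res[k]
    key <- as.character(art$child_node[k])
    bal[key] <- bal[key] + f
    pk <- as.character(art$parent_node[k])
    if (pk %in% names(bal)) bal[pk] <- bal[pk] - f
  }
  for (k in seq_along(state$aa_node)) {
    key <- as.character(state$aa_node[k])
    bal[key] <- bal[key] - state$f_neph[k]
  }
  bal
}

# quick amplitude of the tail of a trace
tail_amplitude <- function(sim, t_min = 300) {
  tr <- sim$trace[sim$trace$time >= t_min, ]
  diff(range(tr$p_t))
}
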