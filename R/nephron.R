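# Single-nephron model: six ODEs (proximal tubular pressure, afferent
# arteriolar radius and its rate of change, and a three-stage linear chain
# approximating the tubuloglomerular feedback delay) closed by algebraic
# relations, including a cubic equation for the efferent plasma protein
# concentration.
#
# State variables: P_t (kPa), r (dimensionless arteriolar radius), v_r (1/s),
# X1, X2, X3 (delay chain, nL). Units as in the parameter table below.

#' Nephron model parameters
#'
#' All constants of the single-nephron tubuloglomerular feedback model, with
#' their standard values. `beta` (non-variable fraction of the afferent
#' resistance) and `alpha` (feedback amplification) have stability ranges of
#' about 0.4-0.67 and 12-20.
#'
#' @param c_tub proximal tubule compliance (nL/kPa).
#' @param h_a arterial hematocrit (protein-free red cell fraction in the
#'   filtration balance).
#' @param p_v efferent arterial pressure (kPa).
#' @param p_d distal tubular hydrostatic pressure (kPa).
#' @param f_hen0 Henle-loop equilibrium flow (nL/s).
#' @param f_reab constant proximal reabsorption rate (nL/s).
#' @param r_hen hydrodynamic resistance of the loop of Henle (kPa*s/nL).
#' @param r_a0 afferent arteriolar equilibrium resistance (kPa*s/nL).
#' @param r_e efferent arteriolar resistance (kPa*s/nL).
#' @param omega mass-to-compliance coefficient of the arteriolar wall
#'   oscillator (kPa*s^2).
#' @param k_damp damping coefficient of the wall oscillator (1/s).
#' @param beta non-variable fraction of the afferent resistance.
#' @param psi_min,psi_max,psi_eq lower, upper and equilibrium values of the
#'   TGF activation.
#' @param c_a afferent plasma protein concentration (g/L).
#' @param a,b protein osmotic pressure coefficients (kPa*L/g, kPa*L^2/g^2).
#' @param t_delay transport delay in the loop of Henle (s).
#' @param alpha TGF amplification (sigmoid steepness).
#' @return An object of class `nephron_params`.
#' @export
nephron_params <- function(c_tub = 3.0, h_a = 0.5, p_v = 1.3, p_d = 0.6,
                           f_hen0 = 0.2, f_reab = 0.3, r_hen = 5.3,
                           r_a0 = 2.4, r_e = 1.9, omega = 20.0, k_damp = 0.04,
                           beta = 0.67, psi_min = 0.20, psi_max = 0.44,
                           psi_eq = 0.38, c_a = 54.0, a = 21.7e-3,
                           b = 0.39e-3, t_delay = 13.5, alpha = 20.0) {
  stopifnot(psi_min < psi_eq, psi_eq < psi_max, beta > 0, beta < 1,
            c_tub > 0, r_hen > 0, r_a0 > 0, r_e > 0, omega > 0, t_delay > 0)
  structure(list(c_tub = c_tub, h_a = h_a, p_v = p_v, p_d = p_d,
                 f_hen0 = f_hen0, f_reab = f_reab, r_hen = r_hen, r_a0 = r_a0,
                 r_e = r_e, omega = omega, k_damp = k_damp, beta = beta,
                 psi_min = psi_min, psi_max = psi_max, psi_eq = psi_eq,
                 c_a = c_a, a = a, b = b, t_delay = t_delay, alpha = alpha),
            class = "nephron_params")
}

#' @export
print.nephron_params <- function(x, ...) {
  cat("<nephron_params>\n")
  vals <- unlist(unclass(x))
  print(vals)
  invisible(x)
}

# canonical state order used throughout
nephron_state_names <- c("p_t", "r", "v_r", "x1", "x2", "x3")

#' Example nephron initial condition
#'
#' A convenience starting state near the oscillatory operating point
#' (`P_t = 1.7923` kPa, `r = 1.0221`, `v_r = -0.0149`, `X = 0.9177, 0.8903,
#' 0.8695`); not asserted to lie on the limit cycle.
#'
#' @return Named numeric vector of the six state variables.
#' @export
nephron_example_state <- function() {
  stats::setNames(c(1.7923, 1.0221, -0.0149, 0.9177, 0.8903, 0.8695),
                  nephron_state_names)
}

#' Flow into the loop of Henle
#'
#' `F_Hen = (P_t - P_d) / R_Hen`.
#'
#' @param p_t proximal tubular pressure (kPa).
#' @param params a [nephron_params()].
#' @return Flow (nL/s), vectorized.
#' @export
henle_flow <- function(p_t, params = nephron_params()) {
  (p_t - params$p_d) / params$r_hen
}

#' Afferent arteriolar resistance
#'
#' `R_a = R_a0 (beta + (1 - beta)/r^4)` and the resistance ratio
#' `R = R_a0 / R_a`. Only the fraction `1 - beta` of the equilibrium
#' resistance responds to the radius.
#'
#' @param r dimensionless arteriolar radius, > 0.
#' @param params a [nephron_params()].
#' @return List with `r_a` (kPa*s/nL) and `R` (dimensionless), vectorized.
#' @export
afferent_resistance <- function(r, params = nephron_params()) {
  if (any(r <= 0)) stop("arteriolar radius must be positive")
  r_a <- params$r_a0 * (params$beta + (1 - params$beta) / r^4)
  list(r_a = r_a, R = params$r_a0 / r_a)
}

#' Coefficients of the cubic for the efferent protein concentration
#'
#' The efferent arteriolar plasma protein concentration `C_e` satisfies
#' `A Ce^3 + B Ce^2 + C Ce + D = 0` with coefficients assembled from the
#' filtration balance across the glomerulus.
#'
#' @param p_t proximal tubular pressure (kPa).
#' @param p_a feed pressure at the arteriole origin (kPa).
#' @param R resistance ratio `R_a0 / R_a`.
#' @param params a [nephron_params()].
#' @return List of vectors `A`, `B`, `C`, `D`.
#' @export
ce_coefficients <- function(p_t, p_a, R, params = nephron_params()) {
  with(params, list(
    A = b + R * b * h_a,
    B = a + R * b * c_a * (1 - h_a) + R * a * h_a,
    C = p_t - p_v + R * a * c_a * (1 - h_a) + R * (p_t - p_a) * h_a,
    D = (p_t - p_a) * R * c_a * (1 - h_a)
  ))
}

# all real roots of a*x^3 + b*x^2 + c*x + d, one cubic per row (vectorized
# trigonometric/Cardano form); returns an n x 3 matrix padded with NA
cubic_real_roots <- function(a, b, c, d) {
  n <- length(a)
  p <- (3 * a * c - b^2) / (3 * a^2)
  q <- (2 * b^3 - 9 * a * b * c + 27 * a^2 * d) / (27 * a^3)
  shift <- b / (3 * a)
  disc <- (q / 2)^2 + (p / 3)^3
  out <- matrix(NA_real_, n, 3)
  one <- which(disc > 0)
  if (length(one)) {
    s <- sqrt(disc[one])
    u <- -q[one] / 2 + s
    w <- -q[one] / 2 - s
    out[one, 1] <- sign(u) * abs(u)^(1 / 3) + sign(w) * abs(w)^(1 / 3) -
      shift[one]
  }
  three <- which(disc <= 0)
  if (length(three)) {
    pp <- p[three]; qq <- q[three]
    mm <- 2 * sqrt(pmax(-pp / 3, 0))
    # clamp the cosine argument against rounding at the triple-root boundary
    arg <- pmin(pmax(ifelse(mm > 0, 3 * qq / (pp * mm), 0), -1), 1)
    th <- acos(arg) / 3
    for (k in 0:2)
      out[three, k + 1] <- mm * cos(th - 2 * pi * k / 3) - shift[three]
  }
  out
}

#' Efferent plasma protein concentration
#'
#' Solves the closure cubic analytically and returns its positive real root,
#' polished by a few Newton steps (the relative residual is below `1e-10` in
#' the operating regime). When several positive roots exist the largest is
#' returned; when none exists the state is out of the model's working regime
#' and an error of class `nephronet_ce_error` is signalled carrying the
#' offending state, so callers can mark the nephron inactive.
#'
#' @inheritParams ce_coefficients
#' @return `C_e` (g/L), vectorized over the inputs.
#' @export
solve_ce <- function(p_t, p_a, R, params = nephron_params()) {
  co <- ce_coefficients(p_t, p_a, R, params)
  n <- max(lengths(co))
  A <- rep_len(co$A, n); B <- rep_len(co$B, n)
  C <- rep_len(co$C, n); D <- rep_len(co$D, n)
  roots <- matrix(NA_real_, n, 3)
  cub <- A != 0
  if (any(cub))
    roots[cub, ] <- cubic_real_roots(A[cub], B[cub], C[cub], D[cub])
  if (any(!cub)) {
    # degenerate quadratic closure (b = 0): B x^2 + C x + D = 0
    q <- which(!cub)
    disc <- C[q]^2 - 4 * B[q] * D[q]
    ok <- disc >= 0 & B[q] != 0
    roots[q[ok], 1] <- (-C[q][ok] + sqrt(disc[ok])) / (2 * B[q][ok])
    roots[q[ok], 2] <- (-C[q][ok] - sqrt(disc[ok])) / (2 * B[q][ok])
    lin <- which(!cub & B == 0 & C != 0)
    roots[lin, 1] <- -D[lin] / C[lin]
  }
  roots[is.na(roots) | roots <= 0] <- -Inf
  ce <- pmax(roots[, 1], roots[, 2], roots[, 3])
  bad <- !is.finite(ce)
  if (any(bad)) {
    cond <- structure(
      class = c("nephronet_ce_error", "error", "condition"),
      list(message = paste0(
             "no positive efferent protein concentration (out-of-regime ",
             "state): P_t = ", paste(signif(rep_len(p_t, n)[bad], 5),
                                     collapse = ", "),
             ", P_a = ", paste(signif(rep_len(p_a, n)[bad], 5),
                               collapse = ", ")),
           call = sys.call(-1),
           state = list(p_t = rep_len(p_t, n)[bad],
                        p_a = rep_len(p_a, n)[bad], R = rep_len(R, n)[bad]))
    )
    stop(cond)
  }
  # Newton polish on the original cubic
  for (it in 1:3) {
    f <- ((A * ce + B) * ce + C) * ce + D
    fp <- (3 * A * ce + 2 * B) * ce + C
    step <- f / fp
    step[!is.finite(step)] <- 0
    ce <- ce - step
  }
  ce
}

#' Glomerular pressure, filtration and efferent flow
#'
#' From the efferent protein concentration: glomerular capillary pressure
#' `P_g = b Ce^2 + a Ce + P_t`, mean arteriolar pressure
#' `P_av = (P_a - (P_a - P_g) beta R_a0/R_a + P_g) / 2`, single-nephron
#' filtration rate `F_filt = (1 - H_a)(1 - C_a/C_e)(P_a - P_g)/R_a`, and
#' efferent flow `F_eff = (P_g - P_v)/R_e`.
#'
#' @param c_e efferent plasma protein concentration (g/L).
#' @param p_t proximal tubular pressure (kPa).
#' @param p_a feed pressure (kPa).
#' @param r_a afferent arteriolar resistance (kPa*s/nL).
#' @param params a [nephron_params()].
#' @return List with `p_g`, `p_av` (kPa), `f_filt`, `f_eff` (nL/s).
#' @export
glomerular_block <- function(c_e, p_t, p_a, r_a, params = nephron_params()) {
  if (any(c_e <= 0)) stop("protein concentration must be positive")
  with(params, {
    p_g <- b * c_e^2 + a * c_e + p_t
    p_av <- 0.5 * (p_a - (p_a - p_g) * beta * r_a0 / r_a + p_g)
    f_filt <- (1 - h_a) * (1 - c_a / c_e) * (p_a - p_g) / r_a
    f_eff <- (p_g - p_v) / r_e
    list(p_g = p_g, p_av = p_av, f_filt = f_filt, f_eff = f_eff)
  })
}

#' Tubuloglomerular feedback activation
#'
#' Sigmoidal activation of the afferent arteriolar smooth muscle by the
#' delayed Henle flow signal `X3`:
#' `Psi = Psi_max - (Psi_max - Psi_min) / (1 + q exp(alpha (3 X3/(T F_Hen0) - 1)))`
#' with `q = (Psi_eq - Psi_min)/(Psi_max - Psi_eq)`. At the equilibrium point
#' `3 X3/(T F_Hen0) = 1` it returns exactly `Psi_eq`; it is monotonically
#' increasing in `X3` and saturates at `Psi_min` and `Psi_max`.
#'
#' @param x3 third delay-chain state (nL).
#' @param params a [nephron_params()].
#' @return Activation value, vectorized.
#' @export
tgf_activation <- function(x3, params = nephron_params()) {
  with(params, {
    q <- (psi_eq - psi_min) / (psi_max - psi_eq)
    psi_max - (psi_max - psi_min) /
      (1 + q * exp(alpha * (3 * x3 / (t_delay * f_hen0) - 1)))
  })
}

#' Arteriolar equilibrium pressure
#'
#' Passive elastic component `P_el = 1.6 (r - 1) + 2.4 exp(10 (r - 1.4))`,
#' active (muscular) component
#' `P_act = 4.7/(1 + exp(13 (0.4 - r))) + 7.2 r + 6.3`, and the equilibrium
#' pressure `P_eq = P_el + Psi P_act` at activation `Psi`.
#'
#' @param r dimensionless arteriolar radius.
#' @param psi activation level.
#' @param params a [nephron_params()] (unused by the printed constants, kept
#'   for interface symmetry).
#' @return List with `p_el`, `p_act`, `p_eq` (kPa), vectorized.
#' @export
equilibrium_pressure <- function(r, psi, params = nephron_params()) {
  if (any(r <= 0)) stop("arteriolar radius must be positive")
  p_el <- 1.6 * (r - 1) + 2.4 * exp(10 * (r - 1.4))
  p_act <- 4.7 / (1 + exp(13 * (0.4 - r))) + 7.2 * r + 6.3
  list(p_el = p_el, p_act = p_act, p_eq = p_el + psi * p_act)
}

#' Right-hand side of the six nephron ODEs
#'
#' Evaluates all algebraic closures (cubic for `C_e`, glomerular block, TGF
#' activation, equilibrium pressure) and returns the six time derivatives:
#' `dP_t/dt = (F_filt - F_reab - F_Hen)/C_tub`; `dr/dt = v_r`;
#' `dv_r/dt = (P_av - P_eq)/omega - K v_r`; and the delay chain
#' `dX1/dt = F_Hen - (3/T) X1`, `dX2/dt = (3/T)(X1 - X2)`,
#' `dX3/dt = (3/T)(X2 - X3)`.
#'
#' @param state numeric vector of the six states (order `p_t, r, v_r, x1,
#'   x2, x3`) or an `n x 6` matrix for `n` nephrons.
#' @param p_a feed pressure (kPa), recycled over nephrons.
#' @param params a [nephron_params()].
#' @param psi_eff optional effective activation overriding the nephron's own
#'   TGF activation in the equilibrium pressure (used for electrotonic
#'   coupling in networks); defaults to the own activation.
#' @return List with `deriv` (same shape as `state`) and `aux`, a list of the
#'   algebraic quantities (`f_hen`, `r_a`, `R`, `c_e`, `p_g`, `p_av`,
#'   `f_filt`, `f_eff`, `f_neph`, `psi`, `psi_eff`, `p_eq`).
#' @export
nephron_derivatives <- function(state, p_a, params = nephron_params(),
                                psi_eff = NULL) {
  vec <- is.null(dim(state))
  S <- if (vec) matrix(state, nrow = 1) else as.matrix(state)
  p_t <- S[, 1]; r <- S[, 2]; v_r <- S[, 3]
  x1 <- S[, 4]; x2 <- S[, 5]; x3 <- S[, 6]
  p_a <- rep_len(p_a, nrow(S))

  f_hen <- henle_flow(p_t, params)
  ar <- afferent_resistance(r, params)
  c_e <- solve_ce(p_t, p_a, ar$R, params)
  gb <- glomerular_block(c_e, p_t, p_a, ar$r_a, params)
  psi <- tgf_activation(x3, params)
  psi_use <- if (is.null(psi_eff)) psi else rep_len(psi_eff, nrow(S))
  eq <- equilibrium_pressure(r, psi_use, params)

  k3 <- 3 / params$t_delay
  deriv <- cbind(
    (gb$f_filt - params$f_reab - f_hen) / params$c_tub,
    v_r,
    (gb$p_av - eq$p_eq) / params$omega - params$k_damp * v_r,
    f_hen - k3 * x1,
    k3 * (x1 - x2),
    k3 * (x2 - x3)
  )
  colnames(deriv) <- nephron_state_names
  aux <- list(f_hen = f_hen, r_a = ar$r_a, R = ar$R, c_e = c_e, p_g = gb$p_g,
              p_av = gb$p_av, f_filt = gb$f_filt, f_eff = gb$f_eff,
              f_neph = (p_a - gb$p_g) / ar$r_a, psi = psi,
              psi_eff = psi_use, p_eq = eq$p_eq)
  if (vec) deriv <- stats::setNames(drop(deriv), nephron_state_names)
  list(deriv = deriv, aux = aux)
}

#' Integrate a single nephron at fixed feed pressure
#'
#' Adaptive stiff-aware integration (lsoda) of the six-variable model with
#' `P_a` held constant.
#'
#' @param p_a feed pressure (kPa).
#' @param params a [nephron_params()].
#' @param t_end end time (s).
#' @param init initial state; defaults to [nephron_example_state()].
#' @param dt output sampling interval (s).
#' @param rtol,atol solver tolerances.
#' @return An object of class `nephron_sim`: data frame of time, the six
#'   states, and the auxiliary flows/pressures.
#' @export
simulate_nephron <- function(p_a = 13.3, params = nephron_params(),
                             t_end = 600, init = nephron_example_state(),
                             dt = 0.1, rtol = 1e-6, atol = 1e-8) {
  rhs <- function(t, y, parms) {
    list(as.numeric(nephron_derivatives(y, p_a, params)$deriv))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::lsoda(y = unname(init), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("time", nephron_state_names)
  aux <- nephron_derivatives(as.matrix(out[, nephron_state_names]),
                             p_a, params)$aux
  out$f_hen <- aux$f_hen; out$f_filt <- aux$f_filt; out$f_eff <- aux$f_eff
  out$p_g <- aux$p_g; out$psi <- aux$psi
  structure(list(trace = out, p_a = p_a, params = params),
            class = "nephron_sim")
}

#' @export
print.nephron_sim <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<nephron_sim> P_a = %g kPa, t = [0, %g] s (%d samples)\n",
              x$p_a, max(tr$time), nrow(tr)))
  late <- tr[tr$time >= max(tr$time) / 2, ]
  cat(sprintf("  late-half P_t: mean %.4g kPa, peak-to-peak %.4g kPa\n",
              mean(late$p_t), diff(range(late$p_t))))
  invisible(x)
}

#' @export
plot.nephron_sim <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$time, tr$p_t, type = "l", xlab = "time (s)",
                 ylab = "P_t (kPa)", ...)
  graphics::plot(tr$time, tr$r, type = "l", xlab = "time (s)",
                 ylab = "radius r", col = "red3", ...)
  invisible(x)
}

# peak-to-peak amplitude of the tail of a trace
p2p <- function(x) diff(range(x))

#' Single-nephron autoregulation sweep
#'
#' Integrates the nephron to (statistical) stationarity at each feed pressure
#' in an increasing grid, discarding a transient, and reports time-averaged
#' radius, efferent flow and filtration rate together with the peak-to-peak
#' tubular pressure amplitude. A grid point is classified inactive when the
#' integration fails, the mean tubular pressure is negative, or the
#' oscillation amplitude falls below `osc_threshold` (then the averages still
#' describe the steady state).
#'
#' @param p_a_grid increasing feed pressures (kPa).
#' @param params a [nephron_params()].
#' @param t_transient discarded initial interval (s).
#' @param t_measure measurement window (s).
#' @param osc_threshold peak-to-peak `P_t` amplitude (kPa) below which the
#'   nephron counts as non-oscillatory.
#' @param dt output sampling interval (s).
#' @return Data frame of class `autoregulation_sweep`: `p_a`, `r_mean`,
#'   `f_eff_mean`, `f_filt_mean`, `p_t_mean`, `p_t_amplitude`, `oscillating`,
#'   `active`.
#' @export
autoregulation_sweep <- function(p_a_grid, params = nephron_params(),
                                 t_transient = 300, t_measure = 300,
                                 osc_threshold = 0.01, dt = 0.1) {
  if (is.unsorted(p_a_grid)) stop("'p_a_grid' must be increasing")
  rows <- lapply(p_a_grid, function(pa) {
    sim <- tryCatch(
      simulate_nephron(pa, params, t_end = t_transient + t_measure, dt = dt),
      error = function(e) NULL)
    if (is.null(sim))
      return(data.frame(p_a = pa, r_mean = NA, f_eff_mean = NA,
                        f_filt_mean = NA, p_t_mean = NA, p_t_amplitude = NA,
                        oscillating = FALSE, active = FALSE))
    tr <- sim$trace[sim$trace$time >= t_transient, ]
    amp <- p2p(tr$p_t)
    data.frame(p_a = pa, r_mean = mean(tr$r), f_eff_mean = mean(tr$f_eff),
               f_filt_mean = mean(tr$f_filt), p_t_mean = mean(tr$p_t),
               p_t_amplitude = amp,
               oscillating = amp >= osc_threshold,
               active = amp >= osc_threshold && mean(tr$p_t) > 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("autoregulation_sweep", "data.frame")
  out
}

#' @export
plot.autoregulation_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$p_a, x$r_mean, type = "b", xlab = "P_a (kPa)",
                 ylab = "mean radius r", ...)
  graphics::plot(x$p_a, x$f_eff_mean, type = "b", xlab = "P_a (kPa)",
                 ylab = "mean F_eff (nL/s)", col = "red3", ...)
  invisible(x)
}

#' Flattest window of an autoregulation curve
#'
#' Finds the window of given width over the feed-pressure grid in which the
#' mean absolute slope of a response column is smallest -- the autoregulation
#' plateau.
#'
#' @param sweep an [autoregulation_sweep()] result (or any data frame with a
#'   `p_a` column).
#' @param column response column name.
#' @param width window width in kPa.
#' @return List with `from`, `to` (kPa) and `slope` (response units per kPa).
#' @export
flattest_window <- function(sweep, column = "f_eff_mean", width = 3) {
  ok <- is.finite(sweep[[column]])
  pa <- sweep$p_a[ok]; yy <- sweep[[column]][ok]
  if (length(pa) < 2) stop("not enough finite points in the sweep")
  starts <- pa[pa + width <= max(pa) + 1e-9]
  best <- NULL
  for (s in starts) {
    sel <- pa >= s - 1e-9 & pa <= s + width + 1e-9
    if (sum(sel) < 2) next
    slope <- abs(stats::coef(stats::lm(yy[sel] ~ pa[sel]))[2])
    if (is.null(best) || slope < best$slope)
      best <- list(from = s, to = s + width, slope = unname(slope))
  }
  best
}
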