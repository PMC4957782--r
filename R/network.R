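# Coupled nephro-arterial network: the pressure ODEs of the vascular tree,
# one six-variable nephron per afferent arteriole, and electrotonic coupling
# applied through the precomputed voltage-transfer matrix.

#' Assemble a coupled nephro-arterial network model
#'
#' Binds a vascular tree to the hemodynamic pressure network (one pressure
#' state per junction, vessels as Poiseuille resistances, lumped nodal
#' compliance), attaches one nephron model per afferent arteriole (the
#' nephron's feed pressure is the pressure of its origin node, and its inflow
#' `F_neph = (P_node - P_g)/R_a` drains that node), and precomputes the
#' electrotonic nephron-to-nephron coupling matrix. All nephrons share one
#' parameter set.
#'
#' Electrical coupling enters as an effective activation: nephron `m` uses
#' `Psi_m + g_md * sum_n K[m, n] (Psi_n - Psi_eq)` in its arteriolar
#' equilibrium pressure, where `K` is the voltage-transfer matrix and `g_md`
#' the macula-densa signal gain.
#'
#' @param tree a `vascular_tree` with at least one afferent arteriole.
#' @param params a [nephron_params()] shared by all nephrons.
#' @param epars an [endothelial_params()].
#' @param g_md dimensionless macula-densa coupling gain (0 disables
#'   electrical coupling).
#' @param p_root root perfusion pressure boundary (kPa).
#' @param c_hdr vessel compliance (nL/kPa), stable over about 0.3-5.
#' @param eq6_literal passed to [electrical_network()].
#' @return An object of class `nephro_network`.
#' @export
assemble_network <- function(tree, params = nephron_params(),
                             epars = endothelial_params(), g_md = 1,
                             p_root = 13.3, c_hdr = 3.0,
                             eq6_literal = FALSE) {
  stopifnot(inherits(tree, "vascular_tree"))
  net <- hemodynamic_network(tree)
  naa <- length(net$aa_node)
  if (naa < 1) stop("tree has no afferent arterioles: nothing to couple")
  lap <- hemodynamic_laplacian(net)
  K <- if (g_md != 0 && naa > 1) coupling_matrix(tree, epars,
                                                 eq6_literal = eq6_literal)
    else diag(naa)
  K_off <- K; diag(K_off) <- 0
  structure(list(
    tree = tree, params = params, epars = epars, g_md = g_md,
    p_root = p_root, c_hdr = c_hdr,
    n_nodes = net$n, n_nephrons = naa,
    nodes = net$nodes, aa_node_idx = net$aa_node, aa_id = net$aa_id,
    L = lap$L, broot = lap$broot, K = K, K_off = K_off,
    root_vessel = net$root_vessel, resistance = net$resistance,
    net = net
  ), class = "nephro_network")
}

#' @export
print.nephro_network <- function(x, ...) {
  cat(sprintf("<nephro_network> %d pressure nodes + %d nephrons (%s tree), P_root = %g kPa\n",
              x$n_nodes, x$n_nephrons, toupper(x$tree$meta$variant), x$p_root))
  cat(sprintf("  electrotonic gain g_md = %g; mean off-diagonal coupling %.4g\n",
              x$g_md, mean(x$K_off[x$K_off != 0])))
  invisible(x)
}

# effective activations under electrotonic coupling
effective_psi <- function(model, psi) {
  if (model$g_md == 0 || model$n_nephrons == 1) psi
  else psi + model$g_md * drop(model$K_off %*% (psi - model$params$psi_eq))
}

# initial condition: nephron example state everywhere, node pressures from
# the linear steady solve with the matching sinks
network_initial_state <- function(model, nephron_init = nephron_example_state()) {
  naa <- model$n_nephrons
  S <- matrix(rep(as.numeric(nephron_init), each = naa), nrow = naa)
  ar <- afferent_resistance(S[, 2], model$params)
  ce <- solve_ce(S[, 1], rep(model$p_root, naa), ar$R, model$params)
  p_g <- model$params$b * ce^2 + model$params$a * ce + S[, 1]
  st <- steady_pressures(model$tree, model$p_root, p_g = p_g, r_a = ar$r_a)
  c(st$pressure, as.vector(S))
}

network_rhs <- function(model) {
  n <- model$n_nodes; naa <- model$n_nephrons
  params <- model$params
  aa_idx <- model$aa_node_idx
  L <- model$L; broot_p <- model$broot * model$p_root
  c_hdr <- model$c_hdr
  function(t, y, parms) {
    P <- y[seq_len(n)]
    S <- matrix(y[-seq_len(n)], nrow = naa)
    psi <- tgf_activation(S[, 6], params)
    nd <- nephron_derivatives(S, P[aa_idx], params,
                              psi_eff = effective_psi(model, psi))
    dP <- broot_p - drop(L %*% P)
    f <- nd$aux$f_neph
    for (k in seq_len(naa)) dP[aa_idx[k]] <- dP[aa_idx[k]] - f[k]
    list(c(dP / c_hdr, as.vector(nd$deriv)))
  }
}

#' Integrate a coupled nephro-arterial network
#'
#' Stiff-aware adaptive integration of the full coupled system (junction
#' pressures + six states per nephron). Electrotonic coupling is applied at
#' every right-hand-side evaluation through the precomputed transfer matrix.
#'
#' @param model a [assemble_network()] result.
#' @param t_end end time (s).
#' @param init full initial state vector (nodes then nephron states) or NULL
#'   for the default (example nephron state, consistent steady pressures).
#' @param nephron_init per-network nephron initial state used when `init` is
#'   NULL; either a length-6 vector shared by all nephrons or an
#'   `n_nephrons x 6` matrix.
#' @param dt output sampling interval (s).
#' @param rtol,atol solver tolerances.
#' @return An object of class `network_sim`: `time`, per-nephron trace
#'   matrices `p_t`, `r`, `f_filt`, `f_eff`, `f_neph` (columns = arteriole
#'   vessel ids), node pressure matrix `node_pressure`, the model, and
#'   `completed` (FALSE when the solver stopped early; the partial trace is
#'   returned).
#' @export
simulate_network <- function(model, t_end = 600, init = NULL,
                             nephron_init = nephron_example_state(),
                             dt = 0.1, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(model, "nephro_network"))
  n <- model$n_nodes; naa <- model$n_nephrons
  if (is.null(init)) {
    if (is.matrix(nephron_init)) {
      stopifnot(nrow(nephron_init) == naa, ncol(nephron_init) == 6)
      ar <- afferent_resistance(nephron_init[, 2], model$params)
      ce <- solve_ce(nephron_init[, 1], rep(model$p_root, naa), ar$R,
                     model$params)
      p_g <- model$params$b * ce^2 + model$params$a * ce + nephron_init[, 1]
      st <- steady_pressures(model$tree, model$p_root, p_g = p_g, r_a = ar$r_a)
      init <- c(st$pressure, as.vector(nephron_init))
    } else {
      init <- network_initial_state(model, nephron_init)
    }
  }
  stopifnot(length(init) == n + 6 * naa)
  times <- seq(0, t_end, by = dt)
  # lsodes: the node-pressure relaxation times (C_hdr * R) are milliseconds
  # against TGF periods of ~30 s, so the system is stiff and the sparse
  # Jacobian structure pays off
  sol <- tryCatch(
    deSolve::lsodes(y = init, times = times, func = network_rhs(model),
                    parms = NULL, rtol = rtol, atol = atol),
    error = function(e) e)
  diagnostic <- NULL
  if (inherits(sol, "error")) stop(sol)
  completed <- nrow(sol) == length(times)
  if (!completed)
    diagnostic <- paste("integration stopped at t =", max(sol[, 1]), "s")
  tm <- sol[, 1]
  P <- sol[, 1 + seq_len(n), drop = FALSE]
  Sflat <- sol[, -(seq_len(n + 1)), drop = FALSE]
  pick <- function(block) {
    m <- Sflat[, (block - 1) * naa + seq_len(naa), drop = FALSE]
    colnames(m) <- model$aa_id
    m
  }
  p_t <- pick(1); r <- pick(2)
  # auxiliary flows, recomputed over the whole trace in one vectorized pass
  Sall <- cbind(as.vector(pick(1)), as.vector(pick(2)), as.vector(pick(3)),
                as.vector(pick(4)), as.vector(pick(5)), as.vector(pick(6)))
  pa_all <- as.vector(P[, model$aa_node_idx, drop = FALSE])
  aux <- tryCatch(nephron_derivatives(Sall, pa_all, model$params)$aux,
                  error = function(e) NULL)
  shape <- function(v) {
    m <- matrix(v, nrow = length(tm))
    colnames(m) <- model$aa_id
    m
  }
  structure(list(
    time = tm, p_t = p_t, r = r,
    f_filt = if (!is.null(aux)) shape(aux$f_filt),
    f_eff = if (!is.null(aux)) shape(aux$f_eff),
    f_neph = if (!is.null(aux)) shape(aux$f_neph),
    psi = if (!is.null(aux)) shape(aux$psi),
    node_pressure = P, model = model, completed = completed,
    diagnostic = diagnostic
  ), class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("<network_sim> %d nephrons, t = [0, %g] s%s\n",
              ncol(x$p_t), max(x$time),
              if (x$completed) "" else " (incomplete)"))
  late <- x$time >= max(x$time) / 2
  amp <- apply(x$p_t[late, , drop = FALSE], 2, function(z) diff(range(z)))
  cat(sprintf("  late-half P_t amplitude: %.4g to %.4g kPa\n",
              min(amp), max(amp)))
  invisible(x)
}

#' @export
plot.network_sim <- function(x, what = "p_t", ...) {
  m <- x[[what]]
  graphics::matplot(x$time, m, type = "l", lty = 1, xlab = "time (s)",
                    ylab = what, ...)
  invisible(x)
}

#' Operating diagram: tubular pressure extrema versus root pressure
#'
#' For each root pressure in an increasing grid, integrates the network to
#' stationarity (transient discarded) and records the per-nephron minimum and
#' maximum tubular pressure and the activity classification (oscillation
#' amplitude at least `osc_threshold` and positive mean tubular pressure).
#' Grid points where the integration fails are recorded as inactive.
#'
#' @param tree a `vascular_tree`.
#' @param p_root_grid increasing root pressures (kPa).
#' @param params,epars,g_md,c_hdr passed to [assemble_network()].
#' @param t_transient,t_measure transient and measurement windows (s).
#' @param osc_threshold peak-to-peak oscillation threshold (kPa).
#' @param dt output sampling interval (s).
#' @return Data frame of class `operating_diagram`: `p_root`, `aa_id`,
#'   `p_t_min`, `p_t_max`, `amplitude`, `oscillating`, `active`.
#' @export
operating_diagram <- function(tree, p_root_grid, params = nephron_params(),
                              epars = endothelial_params(), g_md = 1,
                              c_hdr = 3.0, t_transient = 300, t_measure = 300,
                              osc_threshold = 0.01, dt = 0.1) {
  if (is.unsorted(p_root_grid)) stop("'p_root_grid' must be increasing")
  rows <- lapply(p_root_grid, function(pr) {
    model <- assemble_network(tree, params, epars, g_md = g_md, p_root = pr,
                              c_hdr = c_hdr)
    sim <- tryCatch(simulate_network(model, t_end = t_transient + t_measure,
                                     dt = dt),
                    error = function(e) NULL)
    if (is.null(sim) || !sim$completed ||
        max(sim$time) < t_transient + t_measure) {
      return(data.frame(p_root = pr, aa_id = model$aa_id, p_t_min = NA_real_,
                        p_t_max = NA_real_, amplitude = NA_real_,
                        oscillating = FALSE, active = FALSE))
    }
    keep <- sim$time >= t_transient
    mn <- apply(sim$p_t[keep, , drop = FALSE], 2, min)
    mx <- apply(sim$p_t[keep, , drop = FALSE], 2, max)
    mean_pt <- colMeans(sim$p_t[keep, , drop = FALSE])
    data.frame(p_root = pr, aa_id = model$aa_id, p_t_min = mn, p_t_max = mx,
               amplitude = mx - mn,
               oscillating = (mx - mn) >= osc_threshold,
               active = (mx - mn) >= osc_threshold & mean_pt > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("operating_diagram", "data.frame")
  out
}

#' Network autoregulation curves
#'
#' Time-averaged per-nephron and net efferent flow and filtration rate as a
#' function of the root pressure, with the flattest-slope window of the net
#' curves (the autoregulation plateau).
#'
#' @inheritParams operating_diagram
#' @return List of class `network_autoregulation` with `per_nephron` (data
#'   frame: p_root, aa_id, f_eff, f_filt, active), `net` (data frame: p_root,
#'   f_eff_net, f_filt_net), and `plateau` (flattest 3-kPa windows of the two
#'   net curves).
#' @export
network_autoregulation <- function(tree, p_root_grid,
                                   params = nephron_params(),
                                   epars = endothelial_params(), g_md = 1,
                                   c_hdr = 3.0, t_transient = 300,
                                   t_measure = 300, osc_threshold = 0.01,
                                   dt = 0.1) {
  if (is.unsorted(p_root_grid)) stop("'p_root_grid' must be increasing")
  per <- lapply(p_root_grid, function(pr) {
    model <- assemble_network(tree, params, epars, g_md = g_md, p_root = pr,
                              c_hdr = c_hdr)
    sim <- tryCatch(simulate_network(model, t_end = t_transient + t_measure,
                                     dt = dt),
                    error = function(e) NULL)
    if (is.null(sim) || !sim$completed || is.null(sim$f_eff)) {
      return(data.frame(p_root = pr, aa_id = model$aa_id, f_eff = NA_real_,
                        f_filt = NA_real_, active = FALSE))
    }
    keep <- sim$time >= t_transient
    amp <- apply(sim$p_t[keep, , drop = FALSE], 2, function(z) diff(range(z)))
    mean_pt <- colMeans(sim$p_t[keep, , drop = FALSE])
    data.frame(p_root = pr, aa_id = model$aa_id,
               f_eff = colMeans(sim$f_eff[keep, , drop = FALSE]),
               f_filt = colMeans(sim$f_filt[keep, , drop = FALSE]),
               active = amp >= osc_threshold & mean_pt > 0)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  net <- stats::aggregate(cbind(f_eff, f_filt) ~ p_root, data = per, FUN = sum,
                          na.action = NULL)
  names(net) <- c("p_root", "f_eff_net", "f_filt_net")
  plateau <- list(
    f_eff = tryCatch(flattest_window(
      data.frame(p_a = net$p_root, f_eff_mean = net$f_eff_net)),
      error = function(e) NULL),
    f_filt = tryCatch(flattest_window(
      data.frame(p_a = net$p_root, f_eff_mean = net$f_filt_net)),
      error = function(e) NULL))
  structure(list(per_nephron = per, net = net, plateau = plateau),
            class = "network_autoregulation")
}

#' @export
print.network_autoregulation <- function(x, ...) {
  cat("<network_autoregulation>", nrow(x$net), "root pressures,",
      length(unique(x$per_nephron$aa_id)), "nephrons\n")
  if (!is.null(x$plateau$f_eff))
    cat(sprintf("  flattest net F_eff window: [%g, %g] kPa (|slope| %.4g nL/s/kPa)\n",
                x$plateau$f_eff$from, x$plateau$f_eff$to, x$plateau$f_eff$slope))
  invisible(x)
}

# -- phase extraction and synchronization ------------------------------------

# interpolated peak times of an oscillatory trace (quadratic fit around
# discrete local maxima)
peak_times <- function(t, x, min_amplitude = 0.01) {
  if (diff(range(x)) < min_amplitude) return(numeric(0))
  n <- length(x)
  lvl <- min(x) + 0.25 * diff(range(x))   # ignore sub-threshold wiggles
  im <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  im <- im[x[im] > lvl]
  if (!length(im)) return(numeric(0))
  dt <- t[2] - t[1]
  a <- x[im - 1]; b <- x[im]; c <- x[im + 1]
  den <- a - 2 * b + c
  off <- ifelse(abs(den) > 0, 0.5 * (a - c) / den, 0)
  t[im] + off * dt
}

# instantaneous phase by linear interpolation between successive peaks
phase_at <- function(tq, peaks) {
  k <- findInterval(tq, peaks)
  ok <- k >= 1 & k < length(peaks)
  ph <- rep(NA_real_, length(tq))
  ph[ok] <- 2 * pi * (k[ok] + (tq[ok] - peaks[k[ok]]) /
                        (peaks[k[ok] + 1] - peaks[k[ok]]))
  ph
}

#' Pairwise phase-locking statistics of tubular pressure oscillations
#'
#' Extracts instantaneous phases of the per-nephron tubular pressure traces
#' by peak interpolation and reports, for each pair, the circular mean and
#' circular variance of the phase difference. A pair is "in-phase locked"
#' when the circular variance is below 0.1 and the absolute circular mean
#' phase difference is below `pi/4`. Non-oscillatory traces (amplitude below
#' `min_amplitude`) make a pair not applicable (`locked = NA`).
#'
#' @param sim a `network_sim`.
#' @param pairs two-column matrix of arteriole vessel ids (default: all
#'   pairs).
#' @param t_min discard data before this time (s).
#' @param min_amplitude oscillation threshold (kPa).
#' @return Data frame: `aa_i`, `aa_j`, `mean_dphi`, `circ_var`, `n_cycles`,
#'   `locked`.
#' @export
synchronization_metrics <- function(sim, pairs = NULL, t_min = 0,
                                    min_amplitude = 0.01) {
  stopifnot(inherits(sim, "network_sim"))
  keep <- sim$time >= t_min
  t <- sim$time[keep]
  X <- sim$p_t[keep, , drop = FALSE]
  ids <- colnames(X)
  if (is.null(pairs)) {
    cmb <- utils::combn(ids, 2)
    pairs <- cbind(cmb[1, ], cmb[2, ])
  }
  pk <- lapply(seq_len(ncol(X)), function(j)
    peak_times(t, X[, j], min_amplitude))
  names(pk) <- ids
  rows <- apply(pairs, 1, function(pr) {
    p1 <- pk[[as.character(pr[1])]]; p2 <- pk[[as.character(pr[2])]]
    if (length(p1) < 3 || length(p2) < 3)
      return(data.frame(aa_i = pr[1], aa_j = pr[2], mean_dphi = NA_real_,
                        circ_var = NA_real_, n_cycles = 0, locked = NA))
    lo <- max(min(p1), min(p2)); hi <- min(max(p1), max(p2))
    tq <- seq(lo, hi, length.out = 200)
    dphi <- phase_at(tq, p1) - phase_at(tq, p2)
    dphi <- dphi[is.finite(dphi)]
    z <- mean(exp(1i * dphi))
    mean_dphi <- Arg(z)
    circ_var <- 1 - Mod(z)
    data.frame(aa_i = pr[1], aa_j = pr[2], mean_dphi = mean_dphi,
               circ_var = circ_var,
               n_cycles = min(length(p1), length(p2)) - 1,
               locked = circ_var < 0.1 & abs(mean_dphi) < pi / 4)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
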