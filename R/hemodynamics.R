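# Hemodynamics on a vascular tree: diameter-dependent in-vivo blood
# viscosity, Poiseuille resistances, nodal pressure dynamics and the linear
# steady-state pressure solve.
#
# Units: pressures kPa, flows nL/s, resistances kPa*s/nL, compliance nL/kPa,
# diameters and lengths um, viscosity cP. With these choices the Poiseuille
# formula needs no unit prefactor: 1 kPa*s/nL = 1e15 Pa*s/m^3 exactly cancels
# the 1e-3 (cP) * 1e-6 (um) / 1e-24 (um^4) factors.

#' In-vivo relative blood viscosity
#'
#' Diameter-dependent apparent viscosity of blood in small vessels at a fixed
#' hematocrit of 0.45 (Pries-type in-vivo relation):
#' `eta = [1 + 6 exp(-0.085 D) + 2.2 - 2.44 exp(-0.06 D^0.645)] * (D/(D-1.12))^2`
#' with `D` in micrometers and `eta` in centipoise. The large-diameter
#' asymptote is 3.2 cP.
#'
#' @param diam inner vessel diameter (um), must exceed 1.12 um.
#' @return Viscosity (cP), vectorized.
#' @export
blood_viscosity <- function(diam) {
  if (any(!is.finite(diam)) || any(diam <= 1.12))
    stop("viscosity law requires diameter > 1.12 um")
  (1 + 6 * exp(-0.085 * diam) + 2.2 - 2.44 * exp(-0.06 * diam^0.645)) *
    (diam / (diam - 1.12))^2
}

#' Poiseuille hemodynamic resistance of a vessel
#'
#' `R = 128 * eta(D) * L / (pi * D^4)`, returned directly in kPa*s/nL for
#' `D`, `L` in micrometers and viscosity in centipoise.
#'
#' @param diam inner diameter (um).
#' @param length vessel length (um).
#' @param viscosity viscosity (cP); defaults to [blood_viscosity()] at `diam`.
#' @return Resistance (kPa*s/nL), vectorized.
#' @export
vessel_resistance <- function(diam, length, viscosity = blood_viscosity(diam)) {
  if (any(diam <= 0) || any(length <= 0))
    stop("diameter and length must be positive")
  128 * viscosity * length / (pi * diam^4)
}

#' Nephron inflow through an afferent arteriole
#'
#' Flow from the arteriole-origin node into the nephron: the pressure
#' difference between that node and the glomerular capillaries divided by the
#' afferent arteriolar resistance. May be negative when the feed pressure
#' cannot sustain the glomerular pressure (reversed gradient).
#'
#' @param p_node pressure at the node giving rise to the arteriole (kPa).
#' @param p_g glomerular capillary pressure (kPa).
#' @param r_a afferent arteriolar hemodynamic resistance (kPa*s/nL), > 0.
#' @return Flow (nL/s), vectorized.
#' @export
nephron_inflow <- function(p_node, p_g, r_a) {
  if (any(r_a <= 0)) stop("afferent resistance must be positive")
  (p_node - p_g) / r_a
}

# Assemble the pressure-network structure of a tree: one pressure state per
# junction node (child node of every artery segment); arterioles are not
# resistors (their resistance lives in the nephron model) and appear only as
# nephron sinks at their origin node.
hemodynamic_network <- function(tree) {
  v <- tree$vessels
  art <- v[v$kind != "afferent_arteriole", ]
  aa <- v[v$kind == "afferent_arteriole", ]
  nodes <- art$child_node                 # pressure states, in this order
  node_index <- function(n) match(n, nodes)
  root_in <- art$parent_node[art$kind == "root"]
  res <- vessel_resistance(art$diameter, art$length)
  from <- node_index(art$parent_node)     # NA for the root vessel (inlet)
  to <- node_index(art$child_node)
  aa_node <- node_index(aa$parent_node)
  if (any(is.na(aa_node))) stop("arteriole attached to an unknown node")
  list(nodes = nodes, n = length(nodes), resistance = res,
       from = from, to = to, root_vessel = which(art$kind == "root"),
       aa_node = aa_node, aa_id = aa$id, root_inlet = root_in)
}

# Conductance Laplacian of the artery network (rows/cols = pressure nodes)
# plus the root-inlet conductance vector b (flow in = b * P_root - ...).
hemodynamic_laplacian <- function(net) {
  g <- 1 / net$resistance
  n <- net$n
  L <- matrix(0, n, n)
  broot <- numeric(n)
  for (k in seq_along(g)) {
    i <- net$from[k]; j <- net$to[k]
    if (is.na(i)) {           # root vessel: inlet held at P_root
      L[j, j] <- L[j, j] + g[k]
      broot[j] <- broot[j] + g[k]
    } else {
      L[i, i] <- L[i, i] + g[k]
      L[j, j] <- L[j, j] + g[k]
      L[i, j] <- L[i, j] - g[k]
      L[j, i] <- L[j, i] - g[k]
    }
  }
  list(L = L, broot = broot)
}

#' Steady-state nodal pressures of a vascular tree
#'
#' Solves the linear resistor-network equations for the junction pressures
#' with the root inlet held at `p_root`. Nephron outflows at the arteriole
#' origin nodes are given either as fixed flows (`outflow`, one per
#' arteriole, recycled) or as linear sinks draining through the afferent
#' resistance `r_a` to the glomerular pressure `p_g`, in which case the sink
#' flow `(P_node - p_g)/r_a` is part of the linear solve.
#'
#' @param tree a `vascular_tree`.
#' @param p_root root perfusion pressure (kPa).
#' @param outflow fixed nephron outflow(s) (nL/s), one per arteriole, or NULL
#'   to use the linear sink model.
#' @param p_g,r_a glomerular pressure (kPa) and afferent resistance
#'   (kPa*s/nL) of the linear sink model (used when `outflow` is NULL).
#' @return A list of class `hemodynamic_state`: `node` (ids), `pressure`
#'   (kPa), `aa_node`, `aa_pressure` (pressure at each arteriole origin),
#'   `f_neph` (per-nephron inflow, nL/s), `root_inflow` (nL/s), `p_root`.
#' @export
steady_pressures <- function(tree, p_root, outflow = NULL, p_g = 6.5,
                             r_a = 2.4) {
  net <- hemodynamic_network(tree)
  lap <- hemodynamic_laplacian(net)
  L <- lap$L
  rhs <- lap$broot * p_root
  naa <- length(net$aa_node)
  if (!is.null(outflow)) {
    f <- rep_len(outflow, naa)
    for (k in seq_len(naa)) rhs[net$aa_node[k]] <- rhs[net$aa_node[k]] - f[k]
  } else {
    p_g <- rep_len(p_g, naa); r_a <- rep_len(r_a, naa)
    for (k in seq_len(naa)) {
      j <- net$aa_node[k]
      L[j, j] <- L[j, j] + 1 / r_a[k]
      rhs[j] <- rhs[j] + p_g[k] / r_a[k]
    }
  }
  P <- drop(solve(L, rhs))
  aa_p <- P[net$aa_node]
  f_neph <- if (!is.null(outflow)) rep_len(outflow, naa)
    else (aa_p - p_g) / r_a
  rv <- net$root_vessel
  structure(list(node = net$nodes, pressure = P, aa_node = net$nodes[net$aa_node],
                 aa_id = net$aa_id, aa_pressure = aa_p, f_neph = f_neph,
                 root_inflow = (p_root - P[net$to[rv]]) / net$resistance[rv],
                 p_root = p_root),
            class = "hemodynamic_state")
}

#' @export
print.hemodynamic_state <- function(x, ...) {
  cat("<hemodynamic_state>", length(x$node), "pressure nodes, P_root =",
      x$p_root, "kPa\n")
  cat(sprintf("  root inflow %.4g nL/s; arteriole-origin pressure %.4g +/- %.3g kPa\n",
              x$root_inflow, mean(x$aa_pressure),
              ifelse(length(x$aa_pressure) > 1, stats::sd(x$aa_pressure), 0)))
  invisible(x)
}

#' Time derivatives of the nodal pressures
#'
#' Conservation of flow at every junction with lumped nodal compliance:
#' `C_hdr dP_j/dt = sum(inflows) - sum(outflows) - sum(nephron outflows)`.
#' The root inlet pressure is a fixed boundary, not a state.
#'
#' @param pressures named or plain numeric vector of node pressures (kPa) in
#'   the order of `hemodynamic_network(tree)$nodes` (the artery child nodes
#'   in creation order).
#' @param tree a `vascular_tree`.
#' @param p_root root pressure boundary (kPa).
#' @param nephron_outflow per-arteriole outflow F_neph (nL/s), recycled.
#' @param c_hdr vessel compliance (nL/kPa); stable operating range is about
#'   0.3-5.
#' @return dP/dt (kPa/s) per pressure node.
#' @export
pressure_derivatives <- function(pressures, tree, p_root, nephron_outflow = 0,
                                 c_hdr = 3.0) {
  net <- hemodynamic_network(tree)
  if (length(pressures) != net$n)
    stop("expected ", net$n, " node pressures, got ", length(pressures))
  lap <- hemodynamic_laplacian(net)
  flow_in <- lap$broot * p_root - drop(lap$L %*% pressures)
  f <- rep_len(nephron_outflow, length(net$aa_node))
  for (k in seq_along(f))
    flow_in[net$aa_node[k]] <- flow_in[net$aa_node[k]] - f[k]
  flow_in / c_hdr
}
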