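# Electrotonic conduction along the vascular endothelium.
#
# Each vessel is a chain of units (one unit = a ring of endothelial cells of
# effective length L_c); a unit has leak conductance G_u = N*G_c to the
# resting potential and is gap-junction coupled to its chain neighbors with
# G_g = N*G_gj, where N is the number of cells in the cross-section. Branch
# points couple the three adjacent units with a triangle of conductances
# derived from how the cells of each vessel split toward the other two.
# Membrane dynamics are taken as instantaneous, so signal spread reduces to
# one sparse linear solve.

#' Endothelial cell-layer parameters
#'
#' @param w_c cell width (um); a vessel of diameter D has `N = pi*D/w_c`
#'   cells in its cross-section.
#' @param l_c effective cell length (um); a vessel of length L is a chain of
#'   `M = L/l_c` units.
#' @param g_gj gap junction conductance of one cell (1/MOhm).
#' @param g_c whole-cell (leak) conductance (1/MOhm).
#' @param c_c whole-cell capacitance (pF).
#' @param v_rest resting membrane potential (mV).
#' @return An object of class `endothelial_params`.
#' @export
endothelial_params <- function(w_c = 5, l_c = 50, g_gj = 1 / 3, g_c = 1 / 8,
                               c_c = 20, v_rest = -40) {
  stopifnot(w_c > 0, l_c > 0, g_gj > 0, g_c > 0, c_c > 0)
  structure(list(w_c = w_c, l_c = l_c, g_gj = g_gj, g_c = g_c, c_c = c_c,
                 v_rest = v_rest), class = "endothelial_params")
}

# round half away from zero, floored at 1
round_count <- function(x) pmax(1L, as.integer(floor(x + 0.5)))

#' Discretize a vessel into endothelial units
#'
#' `N = round(pi*D/w_c)` cells per cross-section and `M = round(L/l_c)` units
#' along the vessel (both floored at 1); per-unit leak conductance
#' `G_u = N*g_c`, capacitance `C_u = N*c_c` and chain gap conductance
#' `G_g = N*g_gj`.
#'
#' @param diam,length vessel diameter and length (um).
#' @param pars an [endothelial_params()].
#' @return List with `n_cells`, `n_units`, `g_u`, `c_u`, `g_g`.
#' @export
discretize_vessel <- function(diam, length, pars = endothelial_params()) {
  stopifnot(all(diam > 0), all(length > 0))
  n <- round_count(pi * diam / pars$w_c)
  m <- round_count(length / pars$l_c)
  list(n_cells = n, n_units = m, g_u = n * pars$g_c, c_u = n * pars$c_c,
       g_g = n * pars$g_gj)
}

# Split n cells into two groups proportional to d1:d2 (largest remainder, so
# the two parts sum to n exactly).
split_cells <- function(n, d1, d2) {
  s1 <- n * d1 / (d1 + d2)
  f1 <- as.integer(floor(s1)); f2 <- as.integer(floor(n - s1))
  left <- n - f1 - f2
  if (left > 0L) {
    if ((s1 - f1) >= (n - s1 - f2)) f1 <- f1 + left else f2 <- f2 + left
  }
  c(f1, f2)
}

#' Triangle conductances at a branch point
#'
#' The cells of each of the three vessels split toward the other two in
#' proportion to their diameters; the number of gap junctions between two
#' vessels is the arithmetic mean of the cell counts facing each other, and
#' the coupling conductance is that count times the single-cell gap junction
#' conductance. Symmetric by construction.
#'
#' @param d_i,d_j,d_k diameters (um) of the three vessels at the branch.
#' @param pars an [endothelial_params()].
#' @return List with conductances `g_ij`, `g_ik`, `g_jk` (1/MOhm) and the
#'   underlying junction cell counts `n_ij`, `n_ik`, `n_jk`.
#' @export
branch_conductances <- function(d_i, d_j, d_k, pars = endothelial_params()) {
  stopifnot(d_i > 0, d_j > 0, d_k > 0)
  n_i <- round_count(pi * d_i / pars$w_c)
  n_j <- round_count(pi * d_j / pars$w_c)
  n_k <- round_count(pi * d_k / pars$w_c)
  si <- split_cells(n_i, d_j, d_k)   # i's cells toward j, k
  sj <- split_cells(n_j, d_i, d_k)   # j's cells toward i, k
  sk <- split_cells(n_k, d_i, d_j)   # k's cells toward i, j
  n_ij <- (si[1] + sj[1]) / 2
  n_ik <- (si[2] + sk[1]) / 2
  n_jk <- (sj[2] + sk[2]) / 2
  list(g_ij = n_ij * pars$g_gj, g_ik = n_ik * pars$g_gj,
       g_jk = n_jk * pars$g_gj, n_ij = n_ij, n_ik = n_ik, n_jk = n_jk)
}

#' Root boundary conductance
#'
#' The tree is cut out of a larger arterial bed; each of the two upstream
#' vessels beyond the root is represented by a conductance `2 * N_root *
#' g_gj` to a terminal held at the resting potential.
#'
#' @param n_root number of cells in the root cross-section.
#' @param pars an [endothelial_params()].
#' @return Conductance (1/MOhm) per connected upstream vessel.
#' @export
root_conductance <- function(n_root, pars = endothelial_params()) {
  stopifnot(n_root >= 1)
  2 * n_root * pars$g_gj
}

#' Assemble the endothelial conductance network of a tree
#'
#' Builds the unit chains of every vessel (arteries and afferent arterioles),
#' the within-vessel gap couplings, the branch-point triangle couplings, the
#' two-vessel junction couplings, and (optionally) the root boundary leak to
#' the resting potential.
#'
#' @param tree a `vascular_tree`.
#' @param pars an [endothelial_params()].
#' @param eq6_literal logical; if `TRUE`, within-vessel couplings between
#'   units use the unit leak conductance `G_u` as the coupling coefficient
#'   (the literal form of the printed interior-unit equation) instead of the
#'   gap conductance `G_g`.
#' @param ground_root logical; include the root boundary conductances.
#' @return An object of class `electrical_network`: unit bookkeeping, the
#'   symmetric sparse coupling matrix, per-unit leak conductances, and the
#'   distal unit index of every afferent arteriole.
#' @export
electrical_network <- function(tree, pars = endothelial_params(),
                               eq6_literal = FALSE, ground_root = TRUE) {
  v <- tree$vessels
  nv <- nrow(v)
  disc <- discretize_vessel(v$diameter, v$length, pars)
  m <- disc$n_units
  offset <- c(0L, cumsum(m))[seq_len(nv)]   # first unit index - 1 per vessel
  n_units <- sum(m)
  g_u <- rep(disc$g_u, m)
  c_u <- rep(disc$c_u, m)

  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  add_link <- function(a, b, g) {
    ii <<- c(ii, a); jj <<- c(jj, b); gg <<- c(gg, g)
  }
  # within-vessel chains
  for (k in seq_len(nv)) {
    if (m[k] > 1) {
      u <- offset[k] + seq_len(m[k])
      g_link <- if (eq6_literal) disc$g_u[k] else disc$g_g[k]
      add_link(u[-m[k]], u[-1], rep(g_link, m[k] - 1L))
    }
  }
  first_unit <- offset + 1L
  last_unit <- offset + m
  # junctions
  children <- split(seq_len(nv), v$parent_node)
  parent_row <- match(v$parent_node, v$child_node)
  for (nd in names(children)) {
    ch <- children[[nd]]
    pr <- parent_row[ch[1]]
    if (is.na(pr)) next                    # root inlet: handled below
    if (length(ch) == 1L) {
      g <- pars$g_gj * (disc$n_cells[pr] + disc$n_cells[ch]) / 2
      add_link(last_unit[pr], first_unit[ch], g)
    } else if (length(ch) == 2L) {
      bc <- branch_conductances(v$diameter[pr], v$diameter[ch[1]],
                                v$diameter[ch[2]], pars)
      add_link(last_unit[pr], first_unit[ch[1]], bc$g_ij)
      add_link(last_unit[pr], first_unit[ch[2]], bc$g_ik)
      add_link(first_unit[ch[1]], first_unit[ch[2]], bc$g_jk)
    } else {
      stop("node with more than two daughter vessels is not supported")
    }
  }
  ground <- numeric(n_units)
  if (ground_root) {
    rt <- which(v$kind == "root")
    if (length(rt) == 1L)
      ground[first_unit[rt]] <- 2 * root_conductance(disc$n_cells[rt], pars)
  }
  aa_rows <- which(v$kind == "afferent_arteriole")
  structure(list(
    n_units = n_units, g_u = g_u, c_u = c_u, ground = ground,
    links = list(i = ii, j = jj, g = gg),
    vessel_first_unit = first_unit, vessel_last_unit = last_unit,
    vessel_id = v$id, aa_id = v$id[aa_rows],
    aa_distal_unit = last_unit[aa_rows],
    v_rest = pars$v_rest, pars = pars
  ), class = "electrical_network")
}

#' @export
print.electrical_network <- function(x, ...) {
  cat("<electrical_network>", x$n_units, "endothelial units,",
      length(x$links$g), "gap couplings,", length(x$aa_id),
      "afferent arterioles\n")
  invisible(x)
}

# system matrix: graph Laplacian of gap couplings + leak + boundary ground
electrical_system_matrix <- function(network) {
  n <- network$n_units
  l <- network$links
  A <- Matrix::sparseMatrix(
    i = c(l$i, l$j, l$i, l$j, seq_len(n)),
    j = c(l$j, l$i, l$i, l$j, seq_len(n)),
    x = c(-l$g, -l$g, l$g, l$g, network$g_u + network$ground),
    dims = c(n, n))
  Matrix::forceSymmetric(A)
}

#' Quasi-static endothelial voltages
#'
#' Solves the steady state of the cable network: at every unit the leak
#' current `G_u (V - V_rest)` (plus the root boundary current) balances the
#' gap-junction currents and any injected current. The system matrix is
#' symmetric positive definite, so the solution is unique.
#'
#' @param network an [electrical_network()].
#' @param injected per-unit injected current (pA per MOhm-normalized units,
#'   i.e. mV * 1/MOhm); either a full-length vector or a named assignment via
#'   `units`/`currents`.
#' @param units,currents alternative sparse specification: unit indices and
#'   the currents injected there.
#' @return Numeric vector of unit potentials (mV).
#' @export
steady_state_voltages <- function(network, injected = NULL, units = NULL,
                                  currents = NULL) {
  n <- network$n_units
  I <- numeric(n)
  if (!is.null(injected)) {
    stopifnot(length(injected) == n)
    I <- as.numeric(injected)
  }
  if (!is.null(units)) I[units] <- I[units] + currents
  if (any(!is.finite(I))) stop("injected currents must be finite")
  A <- electrical_system_matrix(network)
  w <- Matrix::solve(A, I)
  network$v_rest + as.numeric(w)
}

#' Electrotonic coupling strength between two afferent arterioles
#'
#' Injects a unit test current at the distal (macula-densa) end of the source
#' arteriole, solves the cable network, and returns the ratio of the voltage
#' deflections from rest at the distal ends of target and source.
#'
#' @param tree a `vascular_tree` (or an [electrical_network()] built from
#'   one).
#' @param source_aa,target_aa vessel ids of the two arterioles.
#' @param pars an [endothelial_params()].
#' @param ... passed to [electrical_network()] when `tree` is a tree.
#' @return Dimensionless transfer coefficient in `(0, 1]`.
#' @export
coupling_strength <- function(tree, source_aa, target_aa,
                              pars = endothelial_params(), ...) {
  net <- if (inherits(tree, "electrical_network")) tree
    else electrical_network(tree, pars, ...)
  su <- net$aa_distal_unit[match(source_aa, net$aa_id)]
  tu <- net$aa_distal_unit[match(target_aa, net$aa_id)]
  if (is.na(su) || is.na(tu)) stop("arteriole id not found in the tree")
  V <- steady_state_voltages(net, units = su, currents = 1)
  (V[tu] - net$v_rest) / (V[su] - net$v_rest)
}

#' Nephron-to-nephron electrotonic coupling matrix
#'
#' `K[m, n]` is the voltage-transfer coefficient from source arteriole `n` to
#' target arteriole `m` under a test current at the distal end of `n`
#' (diagonal 1). One sparse factorization serves all sources. The matrix
#' depends only on geometry and conductances and need not be symmetric
#' (asymmetric branchings conduct anisotropically), but all entries lie in
#' `(0, 1]`.
#'
#' @param tree a `vascular_tree` (or an `electrical_network`).
#' @param pars an [endothelial_params()].
#' @param ... passed to [electrical_network()].
#' @return Matrix with rownames/colnames the arteriole vessel ids.
#' @export
coupling_matrix <- function(tree, pars = endothelial_params(), ...) {
  net <- if (inherits(tree, "electrical_network")) tree
    else electrical_network(tree, pars, ...)
  naa <- length(net$aa_id)
  if (naa < 1) stop("tree has no afferent arterioles")
  A <- electrical_system_matrix(net)
  rhs <- Matrix::sparseMatrix(i = net$aa_distal_unit, j = seq_len(naa),
                              x = 1, dims = c(net$n_units, naa))
  W <- as.matrix(Matrix::solve(A, rhs))
  defl <- W[net$aa_distal_unit, , drop = FALSE]   # targets x sources
  K <- sweep(defl, 2, diag(defl), "/")
  dimnames(K) <- list(net$aa_id, net$aa_id)
  K
}
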