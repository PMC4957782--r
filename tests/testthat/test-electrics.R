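# Endothelial discretization, branch conductances and the quasi-static
# voltage solve.

test_that("vessel discretization follows the cell-count rules", {
  pars <- endothelial_params()
  d <- discretize_vessel(20, 50, pars)
  expect_equal(d$n_cells, 13L)          # round(4*pi) with half-up rounding
  expect_equal(d$n_units, 1L)           # L = L_c
  expect_equal(d$g_u, 13 / 8)
  expect_equal(d$c_u, 13 * 20)
  expect_equal(d$g_g, 13 / 3)
  # the ratio G_u / G_g is diameter independent
  d2 <- discretize_vessel(87, 430, pars)
  expect_equal(d$g_u / d$g_g, d2$g_u / d2$g_g)
  expect_equal(d2$n_units, round(430 / 50))
  # floors at one cell / one unit
  tiny <- discretize_vessel(1, 10, pars)
  expect_equal(tiny$n_cells, 1L)
  expect_equal(tiny$n_units, 1L)
})

test_that("branch cell splits are proportional with exact totals", {
  pars <- endothelial_params()
  # N_i = 12 cells split 3:1 -> 9 and 3 (largest-remainder apportionment)
  expect_equal(nephronet:::split_cells(12L, 3, 1), c(9L, 3L))
  # exhaustive check of the averaging rule on a small grid
  for (n in c(5L, 12L, 31L)) for (dj in c(10, 25)) for (dk in c(5, 40)) {
    sp <- nephronet:::split_cells(n, dj, dk)
    expect_equal(sum(sp), n)
    expect_lt(abs(sp[1] - n * dj / (dj + dk)), 1)
  }
  # equal daughters couple equally to the parent when the parent's cell
  # count is even (an odd count cannot split evenly into integers)
  bc <- branch_conductances(32, 20, 20, pars)   # N_i = round(32 pi/5) = 20
  expect_equal(bc$g_ij, bc$g_ik)
  # symmetric by construction: the j-k coupling is one number
  expect_equal(bc$n_jk * pars$g_gj, bc$g_jk)
  # hand trace: N_i = 20 splits 10/10; N_j = N_k = 13 split 8 toward the
  # parent and 5 toward the sibling; junction counts are arithmetic means
  expect_equal(bc$n_ij, (10 + 8) / 2)
  expect_equal(bc$n_jk, (5 + 5) / 2)
})

test_that("root boundary conductance is 2 N G_gj per connected vessel", {
  pars <- endothelial_params()
  expect_equal(root_conductance(10, pars), 20 * pars$g_gj)
  expect_equal(root_conductance(20, pars), 2 * root_conductance(10, pars))
})

test_that("quasi-static voltages: rest state, closed form, dense oracle", {
  pars <- endothelial_params()
  # zero injection: rest everywhere
  net <- electrical_network(fixture_y_tree(), pars)
  V <- steady_state_voltages(net)
  expect_equal(V, rep(pars$v_rest, net$n_units), tolerance = 1e-12)
  # isolated single unit: V = V_rest + I / G_u
  lone <- nephronet:::make_tree(data.frame(
    id = 1L, parent_node = 1L, child_node = 2L, diameter = 20, length = 10,
    kind = "root", stringsAsFactors = FALSE))
  net1 <- electrical_network(lone, pars, ground_root = FALSE)
  expect_equal(steady_state_voltages(net1, units = 1, currents = 1),
               pars$v_rest + 1 / (13 * pars$g_c), tolerance = 1e-12)
  # two 1-unit vessels in series; inject into the arteriole end
  one <- electrical_network(fixture_single_nephron(feed_length = 10,
                                                   feed_diam = 20,
                                                   aa_length = 10),
                            pars, ground_root = FALSE)
  V1 <- steady_state_voltages(one, units = one$aa_distal_unit, currents = 1)
  g <- pars$g_gj * (13 + 13) / 2
  gu <- 13 * pars$g_c
  A <- matrix(c(gu + g, -g, -g, gu + g), 2)
  w <- solve(A, c(0, 1))
  expect_equal(V1, pars$v_rest + w, tolerance = 1e-12)
  # larger random trees: sparse solve equals the dense direct solve
  for (s in 1:3) {
    tree <- build_ksabt(50, 22, default_morphometry(), seed = 40 + s)
    nete <- electrical_network(tree, pars)
    inj_at <- nete$aa_distal_unit[1]
    Vs <- steady_state_voltages(nete, units = inj_at, currents = 1)
    Vd <- dense_voltage_oracle(nete, inj_at, 1)
    expect_lt(max(abs(Vs - Vd)) / max(abs(Vd - pars$v_rest)), 1e-10)
  }
})

test_that("voltage solution is linear: superposition holds", {
  tree <- build_ksabt(50, 22, default_morphometry(), seed = 44)
  net <- electrical_network(tree)
  u <- net$aa_distal_unit[1:2]
  Va <- steady_state_voltages(net, units = u[1], currents = 1) - net$v_rest
  Vb <- steady_state_voltages(net, units = u[2], currents = 2) - net$v_rest
  Vab <- steady_state_voltages(net, units = u, currents = c(1, 2)) - net$v_rest
  expect_lt(max(abs(Vab - (Va + Vb))), 1e-10 * max(abs(Vab)))
})

test_that("coupling strength is 1 at the source and decays with distance", {
  y <- fixture_y_tree()
  aa <- afferent_arterioles(y)$id
  expect_equal(coupling_strength(y, aa[1], aa[1]), 1)
  k <- sapply(c(50, 150, 250), function(L2)
    coupling_strength(fixture_y_tree(aa2_length = L2), 3, 2))
  expect_true(all(diff(k) < 0))         # longer arteriole, weaker signal
  expect_true(all(k > 0 & k < 1))
})

test_that("the minimal Y geometry spans the published coupling regimes", {
  # sweeping the second arteriole over 50-250 um and 20-40 um reproduces
  # coupling strengths of about 0.05 and about 0.1 inside the swept range
  ks <- outer(c(50, 150, 200, 250), c(20, 30, 40),
              Vectorize(function(L2, D2)
                coupling_strength(fixture_y_tree(aa2_length = L2,
                                                 aa2_diam = D2), 3, 2)))
  expect_lt(min(ks), 0.06)
  expect_gt(max(ks), 0.09)
  expect_true(any(abs(ks - 0.05) < 0.025))
  expect_true(any(abs(ks - 0.10) < 0.05))
})

test_that("coupling matrices are bounded, unit-diagonal and factor-shared", {
  expect_equal(unname(coupling_matrix(fixture_single_nephron())),
               matrix(1, 1, 1))
  tree <- build_ksabt(50, 22, default_morphometry(), seed = 47)
  K <- coupling_matrix(tree)
  expect_equal(unname(diag(K)), rep(1, nrow(K)))
  off <- K[row(K) != col(K)]
  expect_true(all(off > 0 & off < 1))
  # agrees with one-at-a-time coupling_strength computations
  net <- electrical_network(tree)
  ids <- as.integer(rownames(K))
  expect_equal(K[2, 1], coupling_strength(net, ids[1], ids[2]),
               tolerance = 1e-10)
  expect_equal(K[1, 2], coupling_strength(net, ids[2], ids[1]),
               tolerance = 1e-10)
})

test_that("arterioles branching off large vessels couple more weakly than siblings", {
  tree <- build_ksabt(80, 22, default_morphometry(), seed = 55)
  v <- tree$vessels
  K <- coupling_matrix(tree)
  aa <- afferent_arterioles(tree)
  owner <- match(aa$parent_node, v$child_node)
  feed <- v$diameter[owner]
  # mean coupling received by arterioles fed from the widest vessels vs from
  # the narrowest
  ids <- as.character(aa$id)
  recv <- sapply(ids, function(i) mean(K[i, setdiff(ids, i)]))
  big <- feed > stats::median(feed)
  expect_lt(mean(recv[big]), mean(recv[!big]))
})

test_that("the printed interior-coupling variant is available as a switch", {
  y <- fixture_y_tree(aa2_length = 150)
  k_gap <- coupling_strength(y, 3, 2)
  net_lit <- electrical_network(y, eq6_literal = TRUE)
  k_lit <- coupling_strength(net_lit, 3, 2)
  expect_false(isTRUE(all.equal(k_gap, k_lit)))
})
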