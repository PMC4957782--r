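# Tree construction: Murray's law, ABT/KSABT algorithms, segmentation,
# Strahler orders, summaries and serialization.

test_that("Murray complement diameter has its closed form and limits", {
  expect_equal(murray_second_daughter(30, 25), (27000 - 15625)^(1 / 3))
  expect_equal(murray_second_daughter(30, 25), 22.4887, tolerance = 1e-4)
  expect_equal(murray_second_daughter(10, 1e-6), 10, tolerance = 1e-6)
  d <- murray_second_daughter(10, 10 * 2^(-1 / 3))   # symmetric split
  expect_equal(d, 10 * 2^(-1 / 3), tolerance = 1e-12)
  expect_error(murray_second_daughter(10, 10), "invalid bifurcation")
  expect_error(murray_second_daughter(10, 11), "invalid bifurcation")
})

test_that("degenerate symmetric ABT is the closed-form perfect binary tree", {
  # ratio 2^(-1/3) per level: 40 -> 31.7 -> 25.2 -> 20; stops at level 3
  tree <- build_abt(40, 22, degenerate_morphometry(), seed = 1)
  aa <- afferent_arterioles(tree)
  expect_equal(nrow(aa), 8L)
  expect_equal(unique(aa$depth), 3L)
  expect_equal(unique(round(aa$diameter, 10)), round(40 * 2^(-1), 10))
  expect_equal(nrow(tree$vessels), 15L)   # 1 + 2 + 4 + 8
})

test_that("every bifurcation and attachment satisfies Murray's law", {
  for (variant in c("abt", "ksabt")) {
    for (s in 1:3) {
      tree <- build_vascular_tree(60, 22, default_morphometry(),
                                  variant = variant, seed = s)
      v <- tree$vessels
      cube <- rowsum(v$diameter^3, v$parent_node)
      nd <- as.integer(rownames(cube))
      root_in <- v$parent_node[v$kind == "root"]
      keep <- nd != root_in
      parent <- v$diameter[match(nd[keep], v$child_node)]^3
      expect_lt(max(abs(cube[keep] / parent - 1)), 1e-9)
    }
  }
})

test_that("diameter decreases monotonically from root to every leaf", {
  tree <- build_ksabt(80, 22, default_morphometry(), seed = 2)
  v <- tree$vessels
  owner <- match(v$parent_node, v$child_node)
  ok <- !is.na(owner)
  expect_true(all(v$diameter[ok] < v$diameter[owner[ok]] + 1e-12))
})

test_that("arterioles sit only at terminal nodes in the ABT but side-branch in the KSABT", {
  ta <- build_abt(60, 22, default_morphometry(), seed = 3)
  va <- ta$vessels
  aa_parents <- va$parent_node[va$kind == "afferent_arteriole"]
  # in an ABT every arteriole's sibling set contains no mid-vessel artery
  # continuation, and no artery has an arteriole attached mid-vessel
  expect_true(all(!va$seg_continuation))
  expect_true(all(va$origin_offset == 0))

  tk <- build_ksabt(60, 22, default_morphometry(), seed = 3)
  vk <- tk$vessels
  expect_gt(sum(vk$seg_continuation), 0)
  expect_gt(sum(vk$origin_offset > 0), 0)
  # the root is never segmented: no arteriole may attach along the root
  root_node <- vk$child_node[vk$kind == "root"]
  expect_false(any(vk$kind == "root" & vk$seg_continuation))
})

test_that("same seed and config give a bitwise-identical tree", {
  t1 <- build_ksabt(60, 22, default_morphometry(), seed = 99)
  t2 <- build_ksabt(60, 22, default_morphometry(), seed = 99)
  expect_identical(t1$vessels, t2$vessels)
})

test_that("KSABT degenerates to the ABT as the spacing rate vanishes", {
  prof0 <- default_morphometry()
  prof_tiny <- morphometry_profile(
    prof0$ddp_mean_coeffs, prof0$ddp_sd_coeffs, prof0$vlvd_mean_coeffs,
    prof0$vlvd_sd_coeffs, aa_spacing_rate = 1e-12,
    aa_diam_mean = prof0$aa_diam_mean, aa_diam_sd = prof0$aa_diam_sd,
    valid_diameter_range = prof0$valid_diameter_range)
  na <- nk <- da <- dk <- numeric(20)
  for (s in 1:20) {
    sa <- summary(build_abt(60, 22, prof0, seed = s))
    sk <- summary(build_ksabt(60, 22, prof_tiny, seed = 100 + s))
    na[s] <- sa$n_aa; nk[s] <- sk$n_aa
    da[s] <- sa$max_depth; dk[s] <- sk$max_depth
  }
  expect_lt(abs(mean(na) - mean(nk)) / mean(na), 0.1)
  expect_lt(abs(mean(da) - mean(dk)), 1)
  # with zero events, a KSABT vessel is a single uncut segment
  tk <- build_ksabt(60, 22, prof_tiny, seed = 1)
  expect_true(all(!tk$vessels$seg_continuation))
})

test_that("segment_vessel walks deterministically with prescribed spacings", {
  prof <- degenerate_morphometry()   # AA diameter fixed at 19.25
  # spacing L/2 on a vessel of length L: exactly two attachment events
  w <- segment_vessel(40, 200, shift = NA_real_, profile = prof, d_stop = 5,
                      spacings = c(100, 100, 100))
  expect_equal(nrow(w$events), 2L)
  expect_equal(w$events$position, c(100, 200))
  expect_true(all(diff(c(40, w$events$diameter_after)) < 0))
  # Murray at every attachment
  expect_equal(w$events$diameter_before^3,
               w$events$diameter_after^3 + w$events$aa_diameter^3,
               tolerance = 1e-12)
  # no-event limit: vessel unchanged, shift decreases by the vessel length
  w0 <- segment_vessel(40, 200, shift = 350, profile = prof, d_stop = 5)
  expect_equal(nrow(w0$events), 0L)
  expect_equal(w0$out_shift, 150)
  expect_equal(w0$final_diameter, 40)
  # diameter exhaustion: stop with a terminal stub
  we <- segment_vessel(24, 500, shift = NA_real_, profile = prof, d_stop = 22,
                       spacings = c(50, 50, 50))
  expect_true(we$exhausted)
  expect_lte(we$stub_diameter, 22)
  expect_equal(we$stub_length, 450)
})

test_that("Strahler orders match the brute-force recursion", {
  expect_equal(strahler_orders(fixture_single_nephron()), c(1L, 1L))
  # perfect binary tree of depth 3: root order 4 under the equal-children rule
  tree <- build_abt(40, 22, degenerate_morphometry(), seed = 1)
  ord <- strahler_orders(tree)
  expect_equal(ord[tree$vessels$kind == "root"], 4L)
  expect_equal(ord[tree$vessels$kind == "afferent_arteriole"], rep(1L, 8))
  for (s in 4:6) {
    tr <- build_ksabt(50, 22, default_morphometry(), seed = s)
    expect_identical(strahler_orders(tr), strahler_brute(tr))
  }
})

test_that("tree summaries report the hand-traced arteriole walk distances", {
  # chain of three segments with one sampled arteriole at each junction
  d0 <- 30
  a1 <- 19; d1 <- murray_second_daughter(d0, a1)
  a2 <- 18; d2 <- murray_second_daughter(d1, a2)
  vessels <- data.frame(
    id = 1:6,
    parent_node = c(1L, 2L, 2L, 3L, 3L, 4L),
    child_node = c(2L, 3L, 7L, 4L, 8L, 9L),
    diameter = c(d0, d1, a1, d2, a2, d2),
    length = c(120, 75, 50, 40, 50, 60),
    kind = c("root", "artery", "afferent_arteriole", "artery",
             "afferent_arteriole", "afferent_arteriole"),
    origin_offset = c(0, 0, 120, 75, 195, 115),
    depth = 0L,
    carry_from = c(NA, 1L, NA, 2L, NA, 4L),
    seg_continuation = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    stub = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  tree <- structure(list(vessels = vessels,
                         meta = list(variant = "ksabt", d_initial = d0,
                                     d_stop = 22, seed = NA_integer_,
                                     profile = list(name = "manual"))),
                    class = "vascular_tree")
  validate_tree(tree)
  s <- summary(tree)
  expect_equal(s$n_aa, 3L)
  # walk: the chain runs root -> segment -> segment with sampled arterioles
  # at 120 um and at 120 + 75 = 195 um, so one spacing of 75 um; the stub
  # remainder is excluded as a truncation artifact
  expect_equal(s$aa_distances, 75)
  # one arteriole only: empty distance list
  expect_length(summary(fixture_single_nephron())$aa_distances, 0)
})

test_that("KSABT walk distances follow the configured exponential law", {
  tree <- build_ksabt(150, 22, default_morphometry(), seed = 8)
  d <- summary(tree)$aa_distances
  expect_gt(length(d), 80)
  ks <- suppressWarnings(stats::ks.test(d, "pexp",
                                        rate = default_morphometry()$aa_spacing_rate))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(d)))  # 1% critical value
})

test_that("daughter-parent diameter pairs exclude arterioles for the KSABT", {
  tk <- build_ksabt(60, 22, default_morphometry(), seed = 5)
  sk <- summary(tk)
  aa_d <- afferent_arterioles(tk)$diameter
  expect_false(any(sk$daughter_parent$daughter_diameter %in% aa_d))
  ta <- build_abt(60, 22, default_morphometry(), seed = 5)
  sa <- summary(ta)
  expect_true(any(sa$daughter_parent$daughter_diameter <= 22))
})

test_that("trees survive a JSON round trip and validation catches tampering", {
  tree <- build_ksabt(60, 22, default_morphometry(), seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_tree(tree, path)
  back <- load_tree(path)
  expect_equal(back$vessels, tree$vessels, tolerance = 1e-12)
  expect_equal(back$meta$seed, 6)
  # regeneration from recorded metadata (seed + profile) reproduces the tree
  prof <- do.call(morphometry_profile, back$meta$profile)
  again <- build_vascular_tree(back$meta$d_initial, back$meta$d_stop, prof,
                               variant = back$meta$variant,
                               seed = back$meta$seed)
  expect_equal(again$vessels, tree$vessels, tolerance = 1e-12)
  # corrupt one diameter: Murray's law violation must be caught on load
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$vessels$diameter_um[2] <- raw$vessels$diameter_um[2] * 1.05
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_tree(bad), "Murray")
  # missing fields are reported as malformed
  raw$vessels$diameter_um <- NULL
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad2, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_tree(bad2), "malformed")
})

test_that("builder rejects inconsistent stop diameters", {
  expect_error(build_abt(20, 22), "d_initial > d_stop")
  expect_error(build_abt(40, -1), "d_initial > d_stop")
})
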