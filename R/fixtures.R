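# Canned small geometries for experiments and tests.

# construct a vascular_tree from explicit vessel rows (validated)
make_tree <- function(vessels, variant = "abt", d_initial = NA_real_,
                      d_stop = NA_real_, seed = NA_integer_,
                      profile_name = "manual") {
  defaults <- data.frame(origin_offset = 0, depth = 0L,
                         carry_from = NA_integer_, seg_continuation = FALSE,
                         stub = FALSE)
  for (nm in names(defaults))
    if (is.null(vessels[[nm]])) vessels[[nm]] <- defaults[[nm]]
  if (is.null(vessels$id)) vessels$id <- seq_len(nrow(vessels))
  tree <- structure(list(
    vessels = vessels,
    meta = list(variant = variant, d_initial = d_initial, d_stop = d_stop,
                seed = seed, profile = list(name = profile_name))
  ), class = "vascular_tree")
  validate_tree(tree)
  tree
}

#' Minimal fixture geometries
#'
#' Small canned structures used throughout the examples and tests:
#'
#' * `fixture_single_nephron()`: one feed vessel continuing into a single
#'   afferent arteriole of the same diameter (a pure series connection).
#' * `fixture_y_tree()`: the minimal branching structure of one root vessel
#'   and two afferent arterioles. The first arteriole is fixed (50 um long,
#'   20 um wide); the length and diameter of the second are free, and the
#'   root diameter follows from Murray's law.
#' * `fixture_branch()`: a small generated ABT or KSABT branch
#'   (`D_initial = 40` um, `D_stop = 22` um) with a fixed seed.
#'
#' @param feed_length,feed_diam feed vessel geometry (um).
#' @param aa_length,aa_diam arteriole geometry (um).
#' @return A `vascular_tree`.
#' @export
fixture_single_nephron <- function(feed_length = 300, feed_diam = 20,
                                   aa_length = 50, aa_diam = feed_diam) {
  if (aa_diam != feed_diam)
    stop("a series connection conserves the diameter; set aa_diam = feed_diam")
  make_tree(data.frame(
    id = 1:2, parent_node = c(1L, 2L), child_node = c(2L, 3L),
    diameter = c(feed_diam, aa_diam), length = c(feed_length, aa_length),
    kind = c("root", "afferent_arteriole"), stringsAsFactors = FALSE
  ), variant = "fixture", d_initial = feed_diam, d_stop = aa_diam)
}

#' @rdname fixture_single_nephron
#' @param root_length root vessel length (um).
#' @param aa1_length,aa1_diam geometry of the first arteriole (um).
#' @param aa2_length,aa2_diam geometry of the second arteriole (um).
#' @export
fixture_y_tree <- function(root_length = 300, aa1_length = 50, aa1_diam = 20,
                           aa2_length = 50, aa2_diam = 20) {
  root_diam <- (aa1_diam^3 + aa2_diam^3)^(1 / 3)
  make_tree(data.frame(
    id = 1:3, parent_node = c(1L, 2L, 2L), child_node = c(2L, 3L, 4L),
    diameter = c(root_diam, aa1_diam, aa2_diam),
    length = c(root_length, aa1_length, aa2_length),
    kind = c("root", "afferent_arteriole", "afferent_arteriole"),
    stringsAsFactors = FALSE
  ), variant = "fixture", d_initial = root_diam, d_stop = max(aa1_diam, aa2_diam))
}

#' @rdname fixture_single_nephron
#' @param variant `"abt"` or `"ksabt"`.
#' @param seed integer seed for the generator.
#' @param profile a [morphometry_profile()].
#' @export
fixture_branch <- function(variant = c("ksabt", "abt"), seed = 42,
                           profile = default_morphometry()) {
  variant <- match.arg(variant)
  build_vascular_tree(40, 22, profile, variant = variant, seed = seed)
}
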