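# Vascular tree generation: recursive asymmetric bifurcation (ABT) and the
# kidney-specific variant with exponentially spaced afferent arterioles
# side-branching off every non-root vessel (KSABT).
#
# A tree is stored as a table of vessel segments. Each segment joins its
# parent_node to its child_node; afferent arterioles are childless segments.
# Murray's law (Dp^3 = Dd1^3 + Dd2^3) is enforced at every bifurcation and at
# every arteriole attachment, so the cube of the diameter is conserved down
# the tree.

#' Murray's law complement diameter
#'
#' Diameter of the second daughter vessel at a bifurcation, from Murray's law
#' `Dp^3 = Dd1^3 + Dd2^3`.
#'
#' @param parent_diam parent diameter (um).
#' @param first_daughter_diam diameter of the first (sampled) daughter (um);
#'   must lie strictly inside `(0, parent_diam)`.
#' @return `(parent_diam^3 - first_daughter_diam^3)^(1/3)` (um), vectorized.
#' @export
murray_second_daughter <- function(parent_diam, first_daughter_diam) {
  if (any(parent_diam <= 0)) stop("parent diameter must be positive")
  if (any(first_daughter_diam <= 0) ||
      any(first_daughter_diam >= parent_diam))
    stop("invalid bifurcation: first daughter diameter must be in (0, Dp)")
  (parent_diam^3 - first_daughter_diam^3)^(1 / 3)
}

# ---------------------------------------------------------------------------

#' Segment a vessel with exponentially spaced afferent arterioles
#'
#' Walks along a vessel of the given diameter and length, placing afferent
#' arteriole origins at exponentially distributed spacings (continuing a
#' spacing carried in from an upstream vessel), reducing the continuing
#' diameter by Murray's law at every attachment. The walk ends either when
#' the next position overshoots the vessel (the residual distance is the
#' outgoing shift) or when the reduced diameter falls to `d_stop` or below
#' (the remaining piece of the vessel becomes a terminal arteriole stub).
#'
#' @param diameter,length vessel diameter and length (um).
#' @param shift incoming shift: residual distance (um) to the next arteriole
#'   event, carried over from the upstream vessel; `NA` to start a fresh
#'   exponential draw.
#' @param profile a [morphometry_profile()].
#' @param d_stop stop diameter (um).
#' @param spacings optional vector of spacings overriding the exponential
#'   draws (for deterministic testing); consumed in order after the incoming
#'   shift is exhausted.
#' @return A list with `events` (data frame: position, aa_diameter,
#'   diameter_before, diameter_after), `final_diameter`, `out_shift`
#'   (residual distance past the vessel end, `NA` if the walk exhausted the
#'   diameter), `exhausted` (logical), `stub_diameter`, `stub_length`
#'   (only when exhausted), and `skipped` (count of attachment sites skipped
#'   because no admissible arteriole diameter could be drawn).
#' @export
segment_vessel <- function(diameter, length, shift = NA_real_, profile,
                           d_stop, spacings = NULL) {
  w <- segment_walk(diameter, length, shift, profile$aa_spacing_rate,
                    profile$aa_diam_mean, profile$aa_diam_sd, d_stop,
                    spacings)
  w$events <- data.frame(position = w$ev_pos, aa_diameter = w$ev_aa,
                         diameter_before = w$ev_before,
                         diameter_after = w$ev_after)
  w[c("events", "final_diameter", "out_shift", "exhausted", "stub_diameter",
      "stub_length", "skipped")]
}

# internal fast walk (plain vectors, no data frame allocation)
segment_walk <- function(diameter, length, shift, rate, aa_mean, aa_sd,
                         d_stop, spacings = NULL) {
  stopifnot(diameter > 0, length > 0)
  draw_i <- 0L
  pos <- 0; d_cur <- diameter
  nxt <- function() {
    if (!is.null(spacings)) {
      draw_i <<- draw_i + 1L
      if (draw_i > base::length(spacings)) Inf else spacings[[draw_i]]
    } else stats::rexp(1, rate = rate)
  }
  remaining <- if (is.na(shift)) nxt() else shift
  ev_pos <- numeric(16); ev_aa <- numeric(16)
  ev_before <- numeric(16); ev_after <- numeric(16)
  ne <- 0L
  skipped <- 0L
  done <- function(out_shift, exhausted, stub_d, stub_l) {
    idx <- seq_len(ne)
    list(ev_pos = ev_pos[idx], ev_aa = ev_aa[idx], ev_before = ev_before[idx],
         ev_after = ev_after[idx], n_events = ne,
         final_diameter = d_cur, out_shift = out_shift,
         exhausted = exhausted, stub_diameter = stub_d, stub_length = stub_l,
         skipped = skipped)
  }
  repeat {
    if (pos + remaining > length)
      return(done(pos + remaining - length, FALSE, NA_real_, NA_real_))
    pos <- pos + remaining
    # draw the arteriole diameter; redraw (capped) while it is not strictly
    # inside (0, d_cur), then skip the site
    d_aff <- NA_real_
    for (k in 1:100) {
      cand <- stats::rnorm(1, aa_mean, aa_sd)
      if (cand > 0 && cand < d_cur) { d_aff <- cand; break }
    }
    if (is.na(d_aff)) {
      skipped <- skipped + 1L
      warning("no admissible arteriole diameter below ", signif(d_cur, 4),
              " um after 100 draws; skipping the attachment site",
              call. = FALSE)
      remaining <- nxt()
      next
    }
    d_next <- (d_cur^3 - d_aff^3)^(1 / 3)
    ne <- ne + 1L
    if (ne > base::length(ev_pos)) {
      ev_pos <- c(ev_pos, numeric(ne)); ev_aa <- c(ev_aa, numeric(ne))
      ev_before <- c(ev_before, numeric(ne)); ev_after <- c(ev_after, numeric(ne))
    }
    ev_pos[ne] <- pos; ev_aa[ne] <- d_aff
    ev_before[ne] <- d_cur; ev_after[ne] <- d_next
    if (d_next <= d_stop) {
      d_cur <- d_next
      return(done(NA_real_, TRUE, d_next, max(length - pos, 1e-6)))
    }
    d_cur <- d_next
    remaining <- nxt()
  }
}

#' Build a renal arterial tree
#'
#' Generates an asymmetric bifurcating tree by recursive application of the
#' daughter-diameter law and Murray's law, starting from a root vessel of
#' diameter `d_initial` and stopping when daughters reach `d_stop` or below
#' (such daughters become afferent arterioles). With `variant = "ksabt"`,
#' every non-root vessel is additionally segmented: afferent arterioles
#' side-branch at exponentially distributed spacings along the vessel (with
#' the residual spacing carried from a vessel into its first daughter), each
#' attachment reducing the continuing diameter by Murray's law, and the
#' subsequent bifurcation uses the reduced diameter.
#'
#' Recursion is depth-first, first daughter first; the first daughter is the
#' sampled one and the second is its Murray complement.
#'
#' @param d_initial root vessel diameter (um).
#' @param d_stop stop diameter (um); daughters at or below it become
#'   afferent arterioles. Must satisfy `d_initial > d_stop > 0`.
#' @param profile a [morphometry_profile()].
#' @param variant `"abt"` (arterioles only at terminal branch points) or
#'   `"ksabt"` (exponentially spaced arterioles over the whole tree).
#' @param seed optional integer seed; stored in the tree metadata.
#' @param max_depth recursion depth cap guarding against pathological
#'   profiles; branches hitting it are terminated with a warning.
#' @return An object of class `vascular_tree`: a list with `vessels` (data
#'   frame: id, parent_node, child_node, diameter, length, kind,
#'   origin_offset, depth, carry_from, seg_continuation, stub) and `meta`.
#' @export
build_vascular_tree <- function(d_initial, d_stop,
                                profile = default_morphometry(),
                                variant = c("abt", "ksabt"), seed = NULL,
                                max_depth = 60L) {
  variant <- match.arg(variant)
  stopifnot(inherits(profile, "morphometry_profile"))
  if (!(d_initial > d_stop) || d_stop <= 0)
    stop("need d_initial > d_stop > 0")
  if (!is.null(seed)) set.seed(seed)

  depth_hits <- 0L
  n_extrapolated <- 0L
  lambda_on <- variant == "ksabt" && profile$aa_spacing_rate > 0

  vm <- profile$vlvd_mean_coeffs; vs <- profile$vlvd_sd_coeffs
  dm <- profile$ddp_mean_coeffs; ds <- profile$ddp_sd_coeffs
  rate <- profile$aa_spacing_rate
  aa_mean <- profile$aa_diam_mean; aa_sd <- profile$aa_diam_sd
  rng_lo <- profile$valid_diameter_range[1]
  rng_hi <- profile$valid_diameter_range[2]

  draw_length <- function(d) {
    if (d < rng_lo || d > rng_hi) n_extrapolated <<- n_extrapolated + 1L
    m <- vm[1] + d * vm[2]
    s <- max(vs[1] + d * vs[2], 0)
    x <- stats::rnorm(1, m, s)
    if (x <= 0) {
      for (k in 1:100) { x <- stats::rnorm(1, m, s); if (x > 0) break }
      if (x <= 0) x <- 0.01 * max(abs(m), 1)
    }
    x
  }
  draw_daughter <- function(d) {
    if (d < rng_lo || d > rng_hi) n_extrapolated <<- n_extrapolated + 1L
    m <- dm[1] + d * (dm[2] + d * (dm[3] + d * dm[4]))
    s <- max(ds[1] + d * ds[2], 0)
    x <- stats::rnorm(1, m, s)
    if (x <= 0 || x >= d) {
      for (k in 1:100) {
        x <- stats::rnorm(1, m, s)
        if (x > 0 && x < d) break
      }
      if (x <= 0) x <- 0.01 * d else if (x >= d) x <- 0.99 * d
    }
    min(x, d * (1 - 1e-12))
  }

  # vessel table columns (written in place; grown by doubling)
  cap <- 4096L
  v_parent <- integer(cap); v_child <- integer(cap)
  v_diam <- numeric(cap); v_len <- numeric(cap)
  v_kind <- character(cap); v_off <- numeric(cap)
  v_depth <- integer(cap); v_carry <- rep(NA_integer_, cap)
  v_cont <- logical(cap); v_stub <- logical(cap)
  n <- 0L      # rows written
  nn <- 1L     # last node id handed out (node 1 = root inlet)

  # work stack of pending arterial vessels: parent node, diameter, depth,
  # incoming shift (NA = fresh draw), id of the segment the shift carries
  # from, and whether the vessel is the (unsegmented) root
  scap <- 128L
  stk_node <- integer(scap); stk_diam <- numeric(scap)
  stk_depth <- integer(scap); stk_shift <- numeric(scap)
  stk_carry <- integer(scap); stk_root <- logical(scap)
  sp <- 1L
  stk_node[1] <- 1L; stk_diam[1] <- d_initial; stk_depth[1] <- 0L
  stk_shift[1] <- NA_real_; stk_carry[1] <- NA_integer_; stk_root[1] <- TRUE

  while (sp > 0L) {
    node <- stk_node[sp]; D <- stk_diam[sp]; depth <- stk_depth[sp]
    shift <- stk_shift[sp]; carry <- stk_carry[sp]; is_root <- stk_root[sp]
    sp <- sp - 1L
    L <- draw_length(D)

    walk <- if (lambda_on && !is_root)
      segment_walk(D, L, shift, rate, aa_mean, aa_sd, d_stop)
    else NULL
    nev <- if (is.null(walk)) 0L else walk$n_events

    # ensure capacity for this iteration (segments + arterioles + daughters)
    need <- n + 2L * nev + 4L
    while (need > cap) {
      grow <- cap
      v_parent <- c(v_parent, integer(grow)); v_child <- c(v_child, integer(grow))
      v_diam <- c(v_diam, numeric(grow)); v_len <- c(v_len, numeric(grow))
      v_kind <- c(v_kind, character(grow)); v_off <- c(v_off, numeric(grow))
      v_depth <- c(v_depth, integer(grow))
      v_carry <- c(v_carry, rep(NA_integer_, grow))
      v_cont <- c(v_cont, logical(grow)); v_stub <- c(v_stub, logical(grow))
      cap <- cap + grow
    }

    kind0 <- if (is_root) "root" else "artery"
    d_cur <- D; seg_start <- 0
    prev_carry <- carry; is_cont <- FALSE
    if (nev > 0L) {
      for (e in seq_len(nev)) {
        # segment ending at this arteriole origin
        n <- n + 1L; nn <- nn + 1L
        v_parent[n] <- node; v_child[n] <- nn; v_diam[n] <- d_cur
        v_len[n] <- walk$ev_pos[e] - seg_start; v_kind[n] <- kind0
        v_off[n] <- seg_start; v_depth[n] <- depth; v_carry[n] <- prev_carry
        v_cont[n] <- is_cont
        node <- nn; prev_carry <- n; is_cont <- TRUE
        # the arteriole at the segment end
        n <- n + 1L; nn <- nn + 1L
        v_parent[n] <- node; v_child[n] <- nn
        v_diam[n] <- walk$ev_aa[e]; v_len[n] <- draw_length(walk$ev_aa[e])
        v_kind[n] <- "afferent_arteriole"; v_off[n] <- walk$ev_pos[e]
        v_depth[n] <- depth; v_carry[n] <- NA_integer_; v_cont[n] <- FALSE
        d_cur <- walk$ev_after[e]; seg_start <- walk$ev_pos[e]
      }
    }
    if (!is.null(walk) && walk$exhausted) {
      # the remaining piece of the vessel is a terminal arteriole stub
      n <- n + 1L; nn <- nn + 1L
      v_parent[n] <- node; v_child[n] <- nn; v_diam[n] <- walk$stub_diameter
      v_len[n] <- walk$stub_length; v_kind[n] <- "afferent_arteriole"
      v_off[n] <- seg_start; v_depth[n] <- depth; v_carry[n] <- prev_carry
      v_cont[n] <- FALSE; v_stub[n] <- TRUE
      next
    }
    # final (or only) segment of the vessel, then bifurcation at its end
    n <- n + 1L; nn <- nn + 1L
    v_parent[n] <- node; v_child[n] <- nn; v_diam[n] <- d_cur
    v_len[n] <- L - seg_start; v_kind[n] <- kind0
    v_off[n] <- seg_start; v_depth[n] <- depth; v_carry[n] <- prev_carry
    v_cont[n] <- is_cont
    node <- nn
    out_shift <- if (is.null(walk)) NA_real_ else walk$out_shift
    out_carry <- if (is.null(walk) || is.na(out_shift)) NA_integer_ else n

    d1 <- draw_daughter(d_cur)
    d2 <- murray_second_daughter(d_cur, d1)
    dd <- c(d1, d2)
    capped <- dd > d_stop & depth + 1L > max_depth
    depth_hits <- depth_hits + sum(capped)
    is_art <- dd > d_stop & !capped
    gets_shift <- c(FALSE, FALSE)
    if (!is.na(out_shift) && any(is_art))
      gets_shift[which(is_art)[1]] <- TRUE
    for (k in 2:1) {   # push the second daughter first: LIFO pops d1 first
      if (!is_art[k]) {
        # terminal daughter below the stop diameter: an afferent arteriole
        n <- n + 1L; nn <- nn + 1L
        v_parent[n] <- node; v_child[n] <- nn; v_diam[n] <- dd[k]
        v_len[n] <- draw_length(dd[k]); v_kind[n] <- "afferent_arteriole"
        v_off[n] <- 0; v_depth[n] <- depth + 1L; v_carry[n] <- NA_integer_
        v_cont[n] <- FALSE
      } else {
        sp <- sp + 1L
        if (sp > scap) {
          stk_node <- c(stk_node, integer(scap)); stk_diam <- c(stk_diam, numeric(scap))
          stk_depth <- c(stk_depth, integer(scap)); stk_shift <- c(stk_shift, numeric(scap))
          stk_carry <- c(stk_carry, integer(scap)); stk_root <- c(stk_root, logical(scap))
          scap <- 2L * scap
        }
        stk_node[sp] <- node; stk_diam[sp] <- dd[k]; stk_depth[sp] <- depth + 1L
        stk_shift[sp] <- if (gets_shift[k]) out_shift else NA_real_
        stk_carry[sp] <- if (gets_shift[k]) out_carry else NA_integer_
        stk_root[sp] <- FALSE
      }
    }
  }

  if (depth_hits > 0)
    warning(depth_hits, " branch(es) hit the depth cap (max_depth = ",
            max_depth, ") and were terminated as arterioles", call. = FALSE)

  idx <- seq_len(n)
  vessels <- data.frame(
    id = idx,
    parent_node = v_parent[idx],
    child_node = v_child[idx],
    diameter = v_diam[idx],
    length = v_len[idx],
    kind = v_kind[idx],
    origin_offset = v_off[idx],
    depth = v_depth[idx],
    carry_from = v_carry[idx],
    seg_continuation = v_cont[idx],
    stub = v_stub[idx],
    stringsAsFactors = FALSE
  )
  tree <- structure(list(
    vessels = vessels,
    meta = list(variant = variant, d_initial = d_initial, d_stop = d_stop,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                profile = unclass(profile),
                n_extrapolated = n_extrapolated,
                package_version = as.character(utils::packageVersion("nephronet")))
  ), class = "vascular_tree")
  validate_tree(tree)
  tree
}

#' @rdname build_vascular_tree
#' @export
build_abt <- function(d_initial, d_stop, profile = default_morphometry(),
                      seed = NULL, max_depth = 60L) {
  build_vascular_tree(d_initial, d_stop, profile, variant = "abt",
                      seed = seed, max_depth = max_depth)
}

#' @rdname build_vascular_tree
#' @export
build_ksabt <- function(d_initial, d_stop, profile = default_morphometry(),
                        seed = NULL, max_depth = 60L) {
  build_vascular_tree(d_initial, d_stop, profile, variant = "ksabt",
                      seed = seed, max_depth = max_depth)
}

#' Validate the structural invariants of a vascular tree
#'
#' Checks: exactly one root; positive diameters and lengths; every vessel's
#' parent node exists; the graph is a connected tree; arterioles are
#' childless; and Murray's law holds at every internal node (the cube of the
#' incoming diameter equals the sum of cubes of the outgoing diameters,
#' relative tolerance `tol`).
#'
#' @param tree a `vascular_tree`.
#' @param tol relative tolerance for Murray's law.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_tree <- function(tree, tol = 1e-9) {
  v <- tree$vessels
  if (sum(v$kind == "root") != 1) stop("tree must have exactly one root vessel")
  if (any(v$diameter <= 0)) stop("all diameters must be positive")
  if (any(v$length <= 0)) stop("all lengths must be positive")
  if (anyDuplicated(v$child_node)) stop("child nodes must be unique")
  root_in <- v$parent_node[v$kind == "root"]
  if (!all(v$parent_node %in% c(root_in, v$child_node)))
    stop("dangling parent node(s)")
  aa_nodes <- v$child_node[v$kind == "afferent_arteriole"]
  if (any(aa_nodes %in% v$parent_node))
    stop("afferent arterioles must be childless")
  # Murray's law at every internal node (vectorized: sum of daughter cubes
  # grouped by parent node against the cube of the incoming vessel)
  cube_in <- rowsum(v$diameter^3, v$parent_node)
  nd <- as.integer(rownames(cube_in))
  keep <- nd != root_in
  pid <- match(nd[keep], v$child_node)
  rel_err <- abs(cube_in[keep] / v$diameter[pid]^3 - 1)
  if (any(rel_err > tol))
    stop(sprintf("Murray's law violated at node %d (rel. error %.3g)",
                 nd[keep][which.max(rel_err)], max(rel_err)))
  # connectivity: every vessel reachable from the root inlet node
  children <- split(seq_len(nrow(v)), v$parent_node)
  queue <- as.character(root_in)
  seen <- 0L
  while (length(queue)) {
    rows <- unlist(children[queue], use.names = FALSE)
    seen <- seen + length(rows)
    queue <- as.character(v$child_node[rows])
  }
  if (seen != nrow(v)) stop("tree is not connected (or contains a cycle)")
  invisible(TRUE)
}

#' Strahler stream orders of a vascular tree
#'
#' Leaves get order 1; a parent gets the maximum of its children's orders,
#' incremented by one when that maximum is attained by at least two children.
#'
#' @param tree a `vascular_tree`.
#' @return Integer vector of orders, one per vessel (in `tree$vessels` order).
#' @export
strahler_orders <- function(tree) {
  v <- tree$vessels
  n <- nrow(v)
  ord <- integer(n)
  children <- split(seq_len(n), v$parent_node)
  # children always have larger ids than their parent (creation order), so a
  # reverse pass is a valid bottom-up traversal
  for (i in rev(seq_len(n))) {
    ch <- children[[as.character(v$child_node[i])]]
    if (is.null(ch)) {
      ord[i] <- 1L
    } else {
      co <- ord[ch]
      m <- max(co)
      ord[i] <- m + as.integer(sum(co == m) >= 2L)
    }
  }
  ord
}

#' Summary statistics of a vascular tree
#'
#' Afferent-arteriole count and diameter statistics, per-vessel
#' length/diameter data, daughter-vs-parent diameter pairs at bifurcations
#' (arterioles excluded for KSABT trees, where they are side branches rather
#' than daughters), and the along-vessel distances between consecutive
#' sampled arteriole origins in segmentation-walk order (stub remainders and
#' terminal below-stop daughters are not sampled origins and are excluded).
#'
#' @param object a `vascular_tree`.
#' @param ... unused.
#' @return A list of class `vascular_tree_summary`.
#' @export
summary.vascular_tree <- function(object, ...) {
  v <- object$vessels
  aa <- v[v$kind == "afferent_arteriole", ]
  art <- v[v$kind != "afferent_arteriole", ]

  # daughter-vs-parent diameter pairs at bifurcations (not segmentation
  # continuations); arterioles count as daughters only in the ABT, where the
  # terminal daughters are the arterioles
  owner <- match(v$parent_node, v$child_node)   # parent vessel row index
  is_pair <- !v$seg_continuation & !is.na(owner)
  if (identical(object$meta$variant, "ksabt"))
    is_pair <- is_pair & v$kind != "afferent_arteriole"
  pairs <- data.frame(parent_diameter = v$diameter[owner[is_pair]],
                      daughter_diameter = v$diameter[is_pair])

  structure(list(
    variant = object$meta$variant,
    d_initial = object$meta$d_initial,
    d_stop = object$meta$d_stop,
    n_vessels = nrow(v),
    n_arteries = nrow(art),
    n_aa = nrow(aa),
    aa_diam_mean = mean(aa$diameter),
    aa_diam_sd = stats::sd(aa$diameter),
    max_depth = max(v$depth),
    total_artery_length = sum(art$length),
    length_diameter = data.frame(diameter = art$diameter, length = art$length),
    daughter_parent = pairs,
    aa_distances = aa_walk_distances(object)
  ), class = "vascular_tree_summary")
}

# Distances between consecutive sampled arteriole origins along each
# segmentation-walk chain. A chain follows the carry of the residual spacing:
# within-vessel segments and first-daughter continuations. Only origins
# placed by the spacing walk count (origin_offset > 0, not a stub): terminal
# daughters below the stop diameter and stub remainders are not sampled
# origins. Distances across a fresh start are undefined and not reported.
aa_walk_distances <- function(tree) {
  v <- tree$vessels
  art <- which(v$kind != "afferent_arteriole")
  succ <- rep(NA_integer_, nrow(v))
  for (i in art) {
    cf <- v$carry_from[i]
    if (!is.na(cf)) succ[cf] <- i
  }
  sampled <- v$kind == "afferent_arteriole" & !v$stub & v$origin_offset > 0
  aa_at <- split(v$id[sampled], v$parent_node[sampled])
  heads <- art[is.na(v$carry_from[art])]
  out <- numeric(0)
  for (h in heads) {
    cum <- 0; last <- NA_real_
    i <- h
    while (!is.na(i)) {
      cum <- cum + v$length[i]
      naa <- length(aa_at[[as.character(v$child_node[i])]])
      if (naa > 0) {
        pts <- rep(cum, naa)
        if (!is.na(last)) out <- c(out, diff(c(last, pts)))
        else if (naa > 1) out <- c(out, diff(pts))
        last <- cum
      }
      i <- succ[i]
    }
  }
  out
}

#' @export
print.vascular_tree_summary <- function(x, ...) {
  cat(sprintf("%s tree: D_initial = %g um, D_stop = %g um\n",
              toupper(x$variant), x$d_initial, x$d_stop))
  cat(sprintf("  %d vessels (%d arteries), max depth %d\n",
              x$n_vessels, x$n_arteries, x$max_depth))
  cat(sprintf("  afferent arterioles: %d, diameter %.2f +/- %.2f um\n",
              x$n_aa, x$aa_diam_mean, x$aa_diam_sd))
  if (length(x$aa_distances))
    cat(sprintf("  inter-arteriole walk distances: n = %d, mean %.1f um\n",
                length(x$aa_distances), mean(x$aa_distances)))
  invisible(x)
}

#' @export
print.vascular_tree <- function(x, ...) {
  v <- x$vessels
  cat(sprintf("<vascular_tree> %s, D_initial = %g, D_stop = %g um\n",
              toupper(x$meta$variant), x$meta$d_initial, x$meta$d_stop))
  cat(sprintf("  %d vessels, %d afferent arterioles, seed = %s\n",
              nrow(v), sum(v$kind == "afferent_arteriole"),
              ifelse(is.na(x$meta$seed), "none", x$meta$seed)))
  invisible(x)
}

#' Plot a vascular tree as a topological dendrogram
#'
#' Horizontal extent is cumulative vessel length from the root; vertical
#' placement spreads the leaves. Afferent arterioles are drawn in red. The
#' layout is cosmetic; trees carry no 3D embedding.
#'
#' @param x a `vascular_tree`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vascular_tree <- function(x, ...) {
  v <- x$vessels
  n <- nrow(v)
  children <- split(seq_len(n), v$parent_node)
  xend <- numeric(n); y <- numeric(n)
  # x from root downwards (ids are in creation order, parents first)
  xstart <- numeric(n)
  pid_all <- match(v$parent_node, v$child_node)
  for (i in seq_len(n)) {
    xstart[i] <- if (is.na(pid_all[i])) 0 else xend[pid_all[i]]
    xend[i] <- xstart[i] + v$length[i]
  }
  leaf <- !(v$child_node %in% v$parent_node)
  y[leaf] <- seq_len(sum(leaf))
  for (i in rev(seq_len(n))) {
    ch <- children[[as.character(v$child_node[i])]]
    if (!is.null(ch)) y[i] <- mean(y[ch])
  }
  graphics::plot(NA, xlim = c(0, max(xend)), ylim = c(0, sum(leaf) + 1),
                 xlab = "path length from root (um)", ylab = "",
                 yaxt = "n", ...)
  cols <- ifelse(v$kind == "afferent_arteriole", "red3", "grey25")
  graphics::segments(xstart, y, xend, y, col = cols,
                     lwd = pmax(0.5, v$diameter / 20))
  pid <- match(v$parent_node, v$child_node)
  ok <- !is.na(pid)
  graphics::segments(xstart[ok], y[pid[ok]], xstart[ok], y[ok],
                     col = "grey70")
  invisible(x)
}

#' Save / load a vascular tree (JSON)
#'
#' Lossless JSON round trip (full double precision) including metadata;
#' loading re-validates all structural invariants.
#'
#' @param tree a `vascular_tree`.
#' @param path file path.
#' @return `load_tree` returns the `vascular_tree`; `save_tree` invisibly
#'   returns `path`.
#' @export
save_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vascular_tree"))
  v <- tree$vessels
  out <- list(
    nodes = sort(unique(c(v$parent_node, v$child_node))),
    vessels = data.frame(
      id = v$id, parent_node = v$parent_node, child_node = v$child_node,
      diameter_um = v$diameter, length_um = v$length, kind = v$kind,
      origin_offset_um = v$origin_offset, depth = v$depth,
      carry_from = v$carry_from, seg_continuation = v$seg_continuation,
      stub = v$stub),
    meta = tree$meta
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("id", "parent_node", "child_node", "diameter_um", "length_um",
            "kind")
  if (is.null(raw$vessels) || !all(need %in% names(raw$vessels)))
    stop("malformed tree file: missing vessel fields")
  vr <- raw$vessels
  nv <- nrow(vr)
  vessels <- data.frame(
    id = as.integer(vr$id),
    parent_node = as.integer(vr$parent_node),
    child_node = as.integer(vr$child_node),
    diameter = as.numeric(vr$diameter_um),
    length = as.numeric(vr$length_um),
    kind = as.character(vr$kind),
    origin_offset = if (!is.null(vr$origin_offset_um))
      as.numeric(vr$origin_offset_um) else numeric(nv),
    depth = if (!is.null(vr$depth)) as.integer(vr$depth) else integer(nv),
    carry_from = if (!is.null(vr$carry_from)) as.integer(vr$carry_from)
      else rep(NA_integer_, nv),
    seg_continuation = if (!is.null(vr$seg_continuation))
      as.logical(vr$seg_continuation) else logical(nv),
    stub = if (!is.null(vr$stub)) as.logical(vr$stub) else logical(nv),
    stringsAsFactors = FALSE
  )
  meta <- raw$meta
  if (!is.null(meta$seed) && is.null(meta$seed)) meta$seed <- NA_integer_
  tree <- structure(list(vessels = vessels, meta = meta),
                    class = "vascular_tree")
  validate_tree(tree)
  tree
}

# convenience accessors ------------------------------------------------------

#' Afferent arterioles of a tree
#'
#' @param tree a `vascular_tree`.
#' @return The rows of `tree$vessels` that are afferent arterioles.
#' @export
afferent_arterioles <- function(tree) {
  tree$vessels[tree$vessels$kind == "afferent_arteriole", ]
}
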