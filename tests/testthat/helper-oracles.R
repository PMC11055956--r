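# Brute-force oracles and shared fixtures. Oracles are deliberately slow,
# direct translations of the definitions; they never call the kernels they
# check.

# -- brute-force box median with edge replication ---------------------------
brute_median_3d <- function(vol, r) {
  d <- dim(vol)
  out <- array(NA_real_, dim = d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    zz <- pmin(pmax((z - r[1]):(z + r[1]), 1), d[1])
    yy <- pmin(pmax((y - r[2]):(y + r[2]), 1), d[2])
    xx <- pmin(pmax((x - r[3]):(x + r[3]), 1), d[3])
    nb <- vol[zz, yy, xx]
    out[z, y, x] <- sort(nb)[ceiling(length(nb) / 2)]
  }
  out
}

# -- brute-force anisotropic EDT (distance to nearest TRUE voxel centre) ----
brute_edt <- function(src, spacing) {
  d <- dim(src)
  idx <- which(src)
  out <- array(Inf, dim = d)
  if (!length(idx)) return(out)
  sc <- arrayInd(idx, d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    dz <- (sc[, 1] - z) * spacing[1]
    dy <- (sc[, 2] - y) * spacing[2]
    dx <- (sc[, 3] - x) * spacing[3]
    out[z, y, x] <- sqrt(min(dz * dz + dy * dy + dx * dx))
  }
  out
}

# -- brute-force branch levels on a segment list ----------------------------
# segments: data.frame(id, node_a, node_b, length_um) of ONE connected
# acyclic network. Enumerates all endpoint-to-endpoint simple paths to find
# the main branch, then assigns levels by repeated sweeps of the
# "1 + level of an attached segment" rule.
brute_branch_levels <- function(segments) {
  nodes <- sort(unique(c(segments$node_a, segments$node_b)))
  deg <- table(factor(c(segments$node_a, segments$node_b), levels = nodes))
  endpoints <- nodes[deg == 1]
  adj <- lapply(nodes, function(nd)
    which(segments$node_a == nd | segments$node_b == nd))
  names(adj) <- as.character(nodes)
  other_end <- function(si, nd)
    if (segments$node_a[si] == nd) segments$node_b[si] else segments$node_a[si]

  # DFS all simple paths between two nodes, returning segment-index paths
  paths_between <- function(from, to) {
    found <- list()
    walk <- function(nd, used_segs) {
      if (nd == to) { found[[length(found) + 1L]] <<- used_segs; return() }
      for (si in adj[[as.character(nd)]]) {
        if (si %in% used_segs) next
        walk(other_end(si, nd), c(used_segs, si))
      }
    }
    walk(from, integer(0))
    found
  }

  best_len <- -Inf; best_path <- integer(0); best_pair <- c(Inf, Inf)
  if (length(endpoints) >= 2) {
    for (i in seq_along(endpoints)) for (j in seq_along(endpoints)) {
      if (i >= j) next
      for (pp in paths_between(endpoints[i], endpoints[j])) {
        len <- sum(segments$length_um[pp])
        pair <- sort(c(endpoints[i], endpoints[j]))
        better <- len > best_len + 1e-12 ||
          (abs(len - best_len) <= 1e-12 &&
             (pair[1] < best_pair[1] ||
                (pair[1] == best_pair[1] && pair[2] < best_pair[2])))
        if (better) { best_len <- len; best_path <- pp; best_pair <- pair }
      }
    }
  } else best_path <- 1L
  lev <- rep(NA_integer_, nrow(segments))
  lev[best_path] <- 0L
  repeat {
    changed <- FALSE
    for (si in seq_len(nrow(segments))) {
      if (!is.na(lev[si])) next
      nb <- setdiff(unique(unlist(adj[as.character(c(segments$node_a[si],
                                                     segments$node_b[si]))])), si)
      nl <- lev[nb]
      if (any(!is.na(nl))) {
        lev[si] <- min(nl, na.rm = TRUE) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lev
}

# random tree as a segment table (n_seg segments, random attachment)
random_segment_tree <- function(n_seg, seed) {
  set.seed(seed)
  segments <- data.frame(id = 1L, node_a = 1L, node_b = 2L,
                         length_um = runif(1, 5, 50))
  next_node <- 3L
  for (s in seq_len(n_seg - 1)) {
    at <- sample(c(segments$node_a, segments$node_b), 1)
    segments <- rbind(segments,
                      data.frame(id = s + 1L, node_a = at, node_b = next_node,
                                 length_um = runif(1, 5, 50)))
    next_node <- next_node + 1L
  }
  segments
}

# wrap a segment table into a minimal vessel_graph for branch_levels()
as_vessel_graph <- function(segments) {
  structure(list(
    segments = data.frame(id = segments$id, network = 1L,
                          node_a = segments$node_a, node_b = segments$node_b,
                          length_um = segments$length_um,
                          mean_diameter_um = NA_real_,
                          branch_level = NA_integer_),
    networks = data.frame(id = 1L, n_segments = nrow(segments),
                          length_um = sum(segments$length_um)),
    nodes = data.frame(id = sort(unique(c(segments$node_a, segments$node_b)))),
    paths = list(), spacing = c(1, 1, 1)), class = "vessel_graph")
}

# -- geometric fixtures -----------------------------------------------------

# axis-aligned tube (capsule) mask along x
make_tube_mask <- function(dims, spacing, radius, z0, y0, x_from, x_to) {
  vol <- array(0, dim = dims)
  pts <- cbind(z = z0, y = y0, x = seq(x_from, x_to, by = min(spacing) / 2))
  vtsquant:::cpp_stamp_balls(vol, pts, rep(radius, nrow(pts)),
                             spacing[1], spacing[2], spacing[3], 1)
  array(vol > 0.5, dim = dims)
}

ball_mask <- function(dims, spacing, center, radius) {
  zc <- ((seq_len(dims[1]) - 1) * spacing[1] - center[1])^2
  yc <- ((seq_len(dims[2]) - 1) * spacing[2] - center[2])^2
  xc <- ((seq_len(dims[3]) - 1) * spacing[3] - center[3])^2
  array(outer(outer(zc, yc, "+"), xc, "+") <= radius^2, dim = dims)
}

# -- shared phantom fixtures (computed once per test run) -------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# moderate phantom for segmentation/descriptor unit tests
small_phantom <- function() cached("small_phantom", {
  spec <- phantom_spec(
    spheroid_radius = 70, voxel_spacing = c(2, 1.5, 1.5), margin = 16,
    seed = 7,
    vessel_params = list(n_roots = 2, branch_prob = 0.15,
                         radius_range = c(4, 9), step_length = 8,
                         max_depth = 3),
    cell_params = list(
      tumor = list(render = "compartment"),
      fibroblast = list(render = "compartment"),
      cd11b = list(count = 25, orb_diameter = 10, placement = "uniform",
                   min_separation = 15),
      hif1a = list(count = 15, orb_diameter = 10, placement = "uniform",
                   min_separation = 15)))
  generate_phantom(spec)
})

small_phantom_prepped <- function() cached("small_phantom_prepped", {
  ph <- small_phantom()
  st <- median_filter_3d(ph$stack, 2)
  st <- combined_channel(st)
  cfg <- pipeline_config()
  vm <- vts_surface_mask(st, cfg)
  list(stack = st, config = cfg, vts = vm, truth = ph$truth)
})
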