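# Tracing of the CD31-positive pseudovascular network.
#
# The binary vessel mask is thinned to a one-voxel curve skeleton
# (topology-preserving sequential thinning), the skeleton is condensed
# into a graph of nodes (junction clusters, endpoints) and segments
# (maximal branch-free voxel chains), short spur segments are pruned, and
# segments are annotated with physical length, local-radius based mean
# diameter, and branch level relative to the main branch of their network.
#
# Skeletonization runs on the voxel grid; all lengths, radii and
# positions are reported in micrometres, which handles anisotropic voxels
# (an approximation for strongly anisotropic spacing, see the vignette).

# adjacency among a set of skeleton voxels (26-connectivity), as an edge
# list of indices into `coords` (1-based rows)
skeleton_edges <- function(coords, dims) {
  if (nrow(coords) < 2)
    return(matrix(integer(0), ncol = 2))
  key <- (coords[, 1] - 1) + dims[1] * ((coords[, 2] - 1) + dims[2] * (coords[, 3] - 1))
  ord <- order(key)
  key_s <- key[ord]
  edges <- list()
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  # only "positive" half of the offsets to avoid duplicate edges
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), ]
  for (k in seq_len(nrow(offs))) {
    zz <- coords[, 1] + offs$dz[k]
    yy <- coords[, 2] + offs$dy[k]
    xx <- coords[, 3] + offs$dx[k]
    valid <- zz >= 1 & zz <= dims[1] & yy >= 1 & yy <= dims[2] &
      xx >= 1 & xx <= dims[3]
    nkey <- (zz - 1) + dims[1] * ((yy - 1) + dims[2] * (xx - 1))
    pos <- findInterval(nkey, key_s)
    hit <- valid & pos >= 1 & key_s[pmax(pos, 1)] == nkey
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(which(hit), ord[pos[hit]])
  }
  if (!length(edges)) matrix(integer(0), ncol = 2) else do.call(rbind, edges)
}

# Build nodes/segments from a skeleton voxel set. Internal workhorse of
# skeletonize_and_graph(); returns NULL-diameter, NULL-level structures.
build_vessel_graph <- function(coords, dims, spacing) {
  n <- nrow(coords)
  empty <- structure(list(
    nodes = data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                       x = numeric(0), degree = integer(0)),
    segments = data.frame(id = integer(0), network = integer(0),
                          node_a = integer(0), node_b = integer(0),
                          length_um = numeric(0),
                          mean_diameter_um = numeric(0),
                          branch_level = integer(0)),
    paths = list(), networks = data.frame(id = integer(0),
                                          n_segments = integer(0),
                                          length_um = numeric(0)),
    spacing = spacing, dims = dims, skeleton_coords = coords),
    class = "vessel_graph")
  if (n == 0) return(empty)

  edges <- skeleton_edges(coords, dims)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }

  is_junction <- deg >= 3
  # junction clusters: components among 26-adjacent junction voxels
  cluster <- integer(n)
  ncl <- 0L
  for (v in which(is_junction)) {
    if (cluster[v]) next
    ncl <- ncl + 1L
    queue <- v; cluster[v] <- ncl
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[u]])
        if (is_junction[w] && !cluster[w]) { cluster[w] <- ncl; queue <- c(queue, w) }
    }
  }

  um <- coords_to_um(coords, spacing)

  # nodes: one per junction cluster, one per endpoint / isolated voxel
  node_of_voxel <- integer(n)          # 0 = chain voxel
  node_pos <- list(); node_deg <- integer(0)
  for (cl in seq_len(ncl)) {
    vs <- which(cluster == cl)
    node_pos[[cl]] <- colMeans(um[vs, , drop = FALSE])
    node_of_voxel[vs] <- cl
  }
  nn <- ncl
  for (v in which(deg <= 1)) {
    nn <- nn + 1L
    node_pos[[nn]] <- um[v, ]
    node_of_voxel[v] <- nn
  }

  # chains: components of non-node voxels (all have degree <= 2)
  seg_list <- list()
  visited <- node_of_voxel > 0L
  add_segment <- function(path_voxels, na, nb) {
    pts <- um[path_voxels, , drop = FALSE]
    if (na > 0) pts <- rbind(node_pos[[na]], pts)
    if (nb > 0) pts <- rbind(pts, node_pos[[nb]])
    len <- if (nrow(pts) >= 2) sum(sqrt(rowSums(diff(pts)^2))) else 0
    seg_list[[length(seg_list) + 1L]] <<-
      list(node_a = na, node_b = nb, path = pts, length = len,
           voxels = path_voxels)
  }

  for (v in seq_len(n)) {
    if (visited[v]) next
    # walk the chain containing v to one end
    chain <- v; visited[v] <- TRUE
    for (dir_try in 1:2) {
      cur <- if (dir_try == 1) v else chain[1]
      prev <- if (dir_try == 1) 0L else if (length(chain) > 1) chain[2] else 0L
      repeat {
        nxt <- adj[[cur]]
        nxt <- nxt[!node_of_voxel[nxt] & nxt != prev & !visited[nxt]]
        if (!length(nxt)) break
        w <- nxt[1]
        visited[w] <- TRUE
        if (dir_try == 1) chain <- c(chain, w) else chain <- c(w, chain)
        prev <- cur; cur <- w
      }
    }
    # attached nodes at each end (smallest node id wins for determinism)
    ends <- c(chain[1], chain[length(chain)])
    att <- lapply(ends, function(e) {
      cand <- node_of_voxel[adj[[e]]]
      sort(unique(cand[cand > 0]))
    })
    na <- if (length(att[[1]])) att[[1]][1] else 0L
    nb_cand <- att[[2]]
    if (length(chain) == 1 && length(att[[1]]) >= 2) {
      # single voxel bridging two nodes
      nb_cand <- att[[1]][-1]
    } else {
      nb_cand <- nb_cand[!(length(chain) == 1 & nb_cand == na)]
    }
    nb <- if (length(nb_cand)) nb_cand[1] else 0L
    add_segment(chain, na, nb)
  }

  # direct node-node adjacencies without an intermediate chain voxel
  seen_pairs <- character(0)
  for (r in seq_len(nrow(edges))) {
    a <- node_of_voxel[edges[r, 1]]; b <- node_of_voxel[edges[r, 2]]
    if (a > 0 && b > 0 && a != b) {
      key <- paste(min(a, b), max(a, b))
      if (!key %in% seen_pairs) {
        seen_pairs <- c(seen_pairs, key)
        pts <- rbind(node_pos[[min(a, b)]], node_pos[[max(a, b)]])
        seg_list[[length(seg_list) + 1L]] <-
          list(node_a = min(a, b), node_b = max(a, b), path = pts,
               length = sqrt(sum((pts[2, ] - pts[1, ])^2)),
               voxels = integer(0))
      }
    }
  }

  if (!length(seg_list)) return(empty)

  # networks: connected components over segments sharing nodes; segments
  # with virtual endpoints (0) get a private node id for the union-find
  ns <- length(seg_list)
  virt <- nn
  ends_mat <- t(vapply(seg_list, function(s) {
    a <- s$node_a; b <- s$node_b
    if (a == 0) { virt <<- virt + 1L; a <- virt }
    if (b == 0) { virt <<- virt + 1L; b <- virt }
    c(a, b)
  }, integer(2)))
  g <- igraph::graph_from_edgelist(ends_mat, directed = FALSE)
  memb <- igraph::components(g)$membership
  seg_net <- memb[ends_mat[, 1]]
  # renumber networks by first appearance
  seg_net <- match(seg_net, unique(seg_net))

  node_used <- sort(unique(c(ends_mat)))
  node_used <- node_used[node_used <= nn]
  node_degree <- tabulate(c(ends_mat[ends_mat <= nn]), nbins = nn)
  nodes <- data.frame(id = node_used,
                      z = vapply(node_used, function(i) node_pos[[i]][1], 0),
                      y = vapply(node_used, function(i) node_pos[[i]][2], 0),
                      x = vapply(node_used, function(i) node_pos[[i]][3], 0),
                      degree = node_degree[node_used])

  segments <- data.frame(id = seq_len(ns),
                         network = seg_net,
                         node_a = ends_mat[, 1], node_b = ends_mat[, 2],
                         length_um = vapply(seg_list, `[[`, 0, "length"),
                         mean_diameter_um = NA_real_,
                         branch_level = NA_integer_)
  paths <- lapply(seg_list, `[[`, "path")
  seg_voxels <- lapply(seg_list, `[[`, "voxels")

  net_ids <- sort(unique(seg_net))
  networks <- data.frame(id = net_ids,
                         n_segments = as.integer(table(factor(seg_net, net_ids))),
                         length_um = as.numeric(tapply(segments$length_um,
                                                       factor(seg_net, net_ids), sum)))

  structure(list(nodes = nodes, segments = segments, paths = paths,
                 networks = networks, spacing = spacing, dims = dims,
                 skeleton_coords = coords, seg_voxels = seg_voxels),
            class = "vessel_graph")
}

#' Skeletonize a vessel mask and build the segment graph
#'
#' @param cd31_mask logical 3-D array (vessel foreground).
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param prune_length spur segments (ending free) shorter than this (um)
#'   are removed and the graph rebuilt; 0 disables pruning.
#' @return object of class `vessel_graph` with `nodes`, `segments` (no
#'   diameters/levels yet), `paths` and `networks`. An empty mask gives an
#'   empty graph.
#' @export
skeletonize_and_graph <- function(cd31_mask, spacing, prune_length = 5) {
  stopifnot(length(dim(cd31_mask)) == 3)
  dims <- dim(cd31_mask)
  skel <- cpp_skeletonize(array(as.logical(cd31_mask), dim = dims))
  coords <- index_to_coords(which(skel), dims)
  graph <- build_vessel_graph(coords, dims, spacing)
  if (prune_length > 0) {
    repeat {
      deg_of <- setNames(graph$nodes$degree, graph$nodes$id)
      free_end <- function(nid) nid > max(graph$nodes$id, 0) ||
        is.na(deg_of[as.character(nid)]) || deg_of[as.character(nid)] <= 1
      spur <- vapply(seq_len(nrow(graph$segments)), function(i) {
        s <- graph$segments[i, ]
        (free_end(s$node_a) || free_end(s$node_b)) && s$length_um < prune_length
      }, logical(1))
      # never prune a network down to nothing
      if (!any(spur)) break
      keep_net <- table(graph$segments$network)
      for (i in which(spur))
        if (keep_net[as.character(graph$segments$network[i])] <= 1)
          spur[i] <- FALSE
      if (!any(spur)) break
      drop_voxels <- unlist(graph$seg_voxels[spur])
      if (!length(drop_voxels)) break
      keep <- setdiff(seq_len(nrow(coords)), drop_voxels)
      coords <- graph$skeleton_coords[keep, , drop = FALSE]
      graph <- build_vessel_graph(coords, dims, spacing)
    }
  }
  graph$prune_length <- prune_length
  graph
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d network(s), %d segment(s), total length %.1f um\n",
              nrow(x$networks), nrow(x$segments), sum(x$segments$length_um)))
  invisible(x)
}

#' Fill per-segment mean diameters from the vessel mask
#'
#' The local radius at every skeleton path point is the anisotropic
#' Euclidean distance to the nearest background voxel centre; the segment
#' mean diameter is twice the mean point radius. The voxel-centre
#' convention biases radii upward by at most about half a voxel diagonal.
#'
#' @param graph a `vessel_graph`.
#' @param cd31_mask the mask the skeleton was traced from.
#' @param spacing voxel spacing um.
#' @return graph with `segments$mean_diameter_um` filled.
#' @export
segment_diameters <- function(graph, cd31_mask, spacing = graph$spacing) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!nrow(graph$segments)) return(graph)
  dims <- dim(cd31_mask)
  d_bg <- cpp_edt(array(!cd31_mask, dim = dims), spacing[1], spacing[2], spacing[3])
  for (i in seq_len(nrow(graph$segments))) {
    pts <- graph$paths[[i]]
    vox <- pmin(pmax(round(sweep(pts, 2, spacing, "/")) + 1, 1),
                matrix(dims, nrow(pts), 3, byrow = TRUE))
    idx <- (vox[, 1] - 1) + dims[1] * ((vox[, 2] - 1) + dims[2] * (vox[, 3] - 1)) + 1
    r <- d_bg[idx]
    if (any(r == 0))
      stop("internal inconsistency: skeleton point outside the vessel mask")
    graph$segments$mean_diameter_um[i] <- 2 * mean(r)
  }
  graph
}

#' Assign branch levels relative to each network's main branch
#'
#' Per network, the main branch is the endpoint-to-endpoint path of
#' maximal total length (on a maximum-length spanning tree if the network
#' has cycles; ties broken by the lexicographically smallest endpoint-id
#' pair). Its segments get level 0; every other segment's level is one
#' more than the minimal level among the segments it attaches to.
#'
#' @param graph a `vessel_graph`.
#' @return graph with `segments$branch_level` filled.
#' @export
branch_levels <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  seg <- graph$segments
  if (!nrow(seg)) return(graph)
  seg$branch_level <- NA_integer_

  for (net in graph$networks$id) {
    rows <- which(seg$network == net)
    sub <- seg[rows, ]
    verts <- sort(unique(c(sub$node_a, sub$node_b)))
    g <- igraph::graph_from_edgelist(
      cbind(match(sub$node_a, verts), match(sub$node_b, verts)),
      directed = FALSE)
    igraph::E(g)$length <- sub$length_um
    igraph::E(g)$row <- seq_along(rows)

    # maximum-length spanning tree (chords get levels afterwards)
    tree <- igraph::mst(g, weights = -igraph::E(g)$length)
    in_tree <- igraph::E(g)$row %in% igraph::E(tree)$row

    # main branch: weighted-diameter path between two tree leaves
    dmat <- igraph::distances(tree, weights = igraph::E(tree)$length)
    # distances() is symmetric only up to rounding; normalize each
    # candidate pair instead of filtering on orientation
    best <- which(dmat >= max(dmat) * (1 - 1e-12), arr.ind = TRUE)
    best <- unique(t(apply(best, 1, sort)))
    pair_ids <- cbind(verts[best[, 1]], verts[best[, 2]])
    pick <- order(pair_ids[, 1], pair_ids[, 2])[1]
    from <- best[pick, 1]; to <- best[pick, 2]
    main_rows <- integer(0)
    if (from != to) {
      sp <- igraph::shortest_paths(tree, from = from, to = to,
                                   weights = igraph::E(tree)$length,
                                   output = "epath")
      main_rows <- igraph::E(tree)$row[as.integer(sp$epath[[1]])]
    } else {
      main_rows <- 1L   # single-segment loop network
    }

    lev <- rep(NA_integer_, length(rows))
    lev[main_rows] <- 0L
    # BFS over tree segments sharing a node
    shares_node <- function(i, j)
      sub$node_a[i] %in% c(sub$node_a[j], sub$node_b[j]) ||
      sub$node_b[i] %in% c(sub$node_a[j], sub$node_b[j])
    frontier <- main_rows
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in seq_along(rows)) {
        if (!is.na(lev[i]) || !in_tree[i]) next
        if (any(vapply(frontier, shares_node, logical(1), i = i))) {
          lev[i] <- min(lev[frontier[vapply(frontier, shares_node,
                                            logical(1), i = i)]]) + 1L
          nxt <- c(nxt, i)
        }
      }
      if (!length(nxt)) break
      frontier <- nxt
    }
    # chords: one more than the lower-levelled attachment
    for (i in seq_along(rows)) {
      if (!is.na(lev[i])) next
      nb <- which(!is.na(lev) & vapply(seq_along(rows), function(j)
        j != i && shares_node(i, j), logical(1)))
      lev[i] <- if (length(nb)) min(lev[nb]) + 1L else 0L
    }
    seg$branch_level[rows] <- lev
  }
  graph$segments <- seg
  graph
}

#' Per-network statistics and whole-VTS aggregates
#'
#' Every mask voxel is assigned to the network of its nearest skeleton
#' voxel (anisotropic distance; ties to the smaller network id), so the
#' per-network volumes partition the CD31 mask exactly.
#'
#' @param graph a `vessel_graph` with segments.
#' @param cd31_mask the vessel mask.
#' @param spacing voxel spacing um.
#' @return list with `networks` (data.frame id, n_segments, length_um,
#'   volume_um3) and `aggregates` (total_length_um, n_networks,
#'   n_segments, segments_per_network, total_cd31_volume_um3).
#' @export
network_stats <- function(graph, cd31_mask, spacing = graph$spacing) {
  stopifnot(inherits(graph, "vessel_graph"))
  dims <- dim(cd31_mask)
  vv <- prod(spacing)
  nets <- graph$networks
  nets$volume_um3 <- numeric(nrow(nets))
  if (nrow(nets) > 0 && any(cd31_mask)) {
    best_d <- array(Inf, dim = dims)
    assign_net <- array(0L, dim = dims)
    for (net in nets$id) {
      seg_rows <- which(graph$segments$network == net)
      vox <- unique(unlist(graph$seg_voxels[seg_rows]))
      src <- array(FALSE, dim = dims)
      if (length(vox)) {
        co <- graph$skeleton_coords[vox, , drop = FALSE]
      } else {
        # segment without own voxels (direct node-node link): use node pos
        a <- graph$segments$node_a[seg_rows]
        co <- round(sweep(as.matrix(
          graph$nodes[match(a, graph$nodes$id), c("z", "y", "x")]),
          2, spacing, "/")) + 1
      }
      src[(co[, 1] - 1) + dims[1] * ((co[, 2] - 1) + dims[2] * (co[, 3] - 1)) + 1] <- TRUE
      dnet <- cpp_edt(src, spacing[1], spacing[2], spacing[3])
      upd <- dnet < best_d
      best_d[upd] <- dnet[upd]
      assign_net[upd] <- net
    }
    inmask <- which(cd31_mask)
    counts <- table(factor(assign_net[inmask], levels = nets$id))
    nets$volume_um3 <- as.numeric(counts) * vv
  }
  multi <- nets$n_segments >= 1
  list(networks = nets,
       aggregates = list(
         total_length_um = sum(nets$length_um),
         n_networks = nrow(nets),
         n_segments = sum(nets$n_segments),
         segments_per_network = if (any(multi)) mean(nets$n_segments[multi]) else NA_real_,
         total_cd31_volume_um3 = sum(cd31_mask) * vv))
}

#' Trace a vessel mask end to end
#'
#' Convenience wrapper: skeletonize + graph, diameters, branch levels and
#' network statistics in one call.
#'
#' @param cd31_mask logical vessel mask.
#' @param spacing voxel spacing um.
#' @param prune_length spur prune length um.
#' @return list with `graph` (annotated `vessel_graph`) and `stats` (see
#'   [network_stats()]).
#' @export
trace_vessels <- function(cd31_mask, spacing, prune_length = 5) {
  graph <- skeletonize_and_graph(cd31_mask, spacing, prune_length)
  graph <- segment_diameters(graph, cd31_mask, spacing)
  graph <- branch_levels(graph)
  list(graph = graph, stats = network_stats(graph, cd31_mask, spacing))
}
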