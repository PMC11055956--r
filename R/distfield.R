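# Distance fields from the pseudovasculature, supply index, cell-to-
# structure distances and Col IV association.
#
# Distances are voxel-centre to voxel-centre, anisotropic, in um. The
# field's domain is "inside the VTS and outside the PV": voxels outside
# the VTS carry NA (out of domain), and with an empty vessel mask every
# in-domain voxel carries Inf ("no vessel" sentinel).

#' Distance field from the pseudovessel surface
#'
#' @param cd31_mask logical vessel mask.
#' @param vts_mask logical VTS body mask (congruent dims).
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @return object of class `distance_field`: `field` (numeric array, um;
#'   NA outside the domain), `spacing`, `n_domain`.
#' @export
pv_distance_field <- function(cd31_mask, vts_mask, spacing) {
  stopifnot(identical(dim(cd31_mask), dim(vts_mask)))
  dims <- dim(cd31_mask)
  if (!any(cd31_mask)) {
    warning("empty CD31 mask: distance field is the 'no vessel' sentinel (Inf)")
    field <- array(Inf, dim = dims)
  } else {
    field <- cpp_edt(array(as.logical(cd31_mask), dim = dims),
                     spacing[1], spacing[2], spacing[3])
  }
  out_of_domain <- !vts_mask | (cd31_mask & vts_mask)
  field[out_of_domain] <- NA_real_
  structure(list(field = field, spacing = as.numeric(spacing),
                 n_domain = sum(!out_of_domain)),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  v <- x$field[!is.na(x$field)]
  cat(sprintf("<distance_field> %d in-domain voxels, median %.2f um\n",
              length(v), median(v)))
  invisible(x)
}

#' Histogram and summary of the PV distance field
#'
#' @param field a [pv_distance_field()].
#' @param bin_width bin width, um.
#' @return list with `histogram` (data.frame bin_lo, bin_hi, count),
#'   `median_um`, `mean_um`, `n`. With no vessel anywhere the histogram is
#'   empty and the median is the Inf sentinel.
#' @export
distance_histogram <- function(field, bin_width = 5) {
  stopifnot(inherits(field, "distance_field"), bin_width > 0)
  v <- field$field[!is.na(field$field)]
  finite <- v[is.finite(v)]
  if (!length(finite)) {
    return(list(histogram = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                                       count = integer(0)),
                median_um = if (length(v)) Inf else NA_real_,
                mean_um = if (length(v)) Inf else NA_real_,
                n = length(v)))
  }
  nb <- ceiling((max(finite) + 1e-9) / bin_width)
  bin <- pmin(floor(finite / bin_width) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  list(histogram = data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
                              bin_hi = seq_len(nb) * bin_width,
                              count = counts),
       median_um = median(finite), mean_um = mean(finite), n = length(finite))
}

#' Pseudovessel supply index
#'
#' SI = relative CD31 volume (percent of the VTS volume) divided by the
#' median in-VTS distance to the nearest PV (um). Higher values indicate a
#' larger and more homogeneously distributed pseudovasculature.
#'
#' @param cd31_relative_volume_pct percent in (0, 100].
#' @param median_distance_um positive, finite median PV distance, um.
#' @return dimensionless scalar.
#' @export
supply_index <- function(cd31_relative_volume_pct, median_distance_um) {
  if (!is.finite(cd31_relative_volume_pct) ||
      cd31_relative_volume_pct <= 0 || cd31_relative_volume_pct > 100)
    stop("relative CD31 volume must be in (0, 100] percent")
  if (!is.finite(median_distance_um) || median_distance_um <= 0)
    stop("median PV distance must be finite and positive")
  cd31_relative_volume_pct / median_distance_um
}

# boundary voxels of a mask: foreground with a 6-neighbour background
mask_boundary <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    i <- seq_len(d[ax])
    j <- pmin(pmax(i + by, 1L), d[ax])
    switch(ax, m[j, , ], m[, j, ], m[, , j])
  }
  interior <- mask
  for (ax in 1:3)
    for (by in c(-1L, 1L))
      interior <- interior & array(shift(mask, ax, by), dim = d)
  # faces of the volume count as boundary
  edge <- array(FALSE, dim = d)
  edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE
  edge[, , c(1, d[3])] <- TRUE
  array(mask & (!interior | edge), dim = d)
}

#' Distances from cell centroids to a target structure
#'
#' Exact minimal Euclidean distance (um) from each centroid to the voxel
#' centres of a target mask (`mode = "mask"`) or of its surface voxels
#' (`mode = "surface"`).
#'
#' @param cells a `cell_set` from [detect_cells()] or a data.frame with
#'   z/y/x um columns.
#' @param target logical 3-D target mask.
#' @param spacing voxel spacing um.
#' @param mode `"mask"` or `"surface"`.
#' @return list with `distances` (data.frame z, y, x, distance_um) and
#'   `median_um`. An empty target yields the Inf sentinel.
#' @export
cell_distances <- function(cells, target, spacing, mode = c("mask", "surface")) {
  mode <- match.arg(mode)
  pts <- if (inherits(cells, "cell_set")) cells$cells else cells
  pts <- as.data.frame(pts)
  if (!nrow(pts))
    return(list(distances = data.frame(z = numeric(0), y = numeric(0),
                                       x = numeric(0), distance_um = numeric(0)),
                median_um = NA_real_))
  tgt <- if (mode == "surface") mask_boundary(target) else target
  dims <- dim(target)
  if (!any(tgt)) {
    d <- rep(Inf, nrow(pts))
  } else {
    # exact nearest-voxel search, bounded per cell: the EDT at the cell's
    # containing voxel plus the centre offset caps the search radius, so
    # only a small box of candidate voxels needs scanning
    edt <- cpp_edt(array(tgt, dim = dims), spacing[1], spacing[2], spacing[3])
    d <- vapply(seq_len(nrow(pts)), function(i) {
      p <- c(pts$z[i], pts$y[i], pts$x[i])
      v <- pmin(pmax(round(p / spacing) + 1, 1), dims)
      off <- sqrt(sum(((v - 1) * spacing - p)^2))
      r0 <- edt[v[1], v[2], v[3]] + off + 1e-9
      lo <- pmax(floor((p - r0) / spacing) + 1, 1)
      hi <- pmin(ceiling((p + r0) / spacing) + 1, dims)
      sub <- tgt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      idx <- which(sub)
      co <- index_to_coords(idx, dim(sub))
      co <- sweep(co, 2, lo - 1, "+")
      um <- coords_to_um(co, spacing)
      sqrt(min((um[, 1] - p[1])^2 + (um[, 2] - p[2])^2 + (um[, 3] - p[3])^2))
    }, numeric(1))
  }
  list(distances = data.frame(z = pts$z, y = pts$y, x = pts$x, distance_um = d),
       median_um = median(d))
}

#' Col IV partition relative to the pseudovasculature
#'
#' Partitions Col IV-positive voxels into PV-associated (within `d_assoc`
#' um of a CD31 voxel, inside the VTS), in-VTS non-associated, and
#' outside-VTS, and reports the associated volume relative to the CD31
#' volume.
#'
#' @param coliv_mask logical Col IV mask.
#' @param cd31_mask logical vessel mask.
#' @param vts_mask logical VTS body mask.
#' @param spacing voxel spacing um.
#' @param d_assoc association distance, um.
#' @return list of fractions and volumes (um^3); `associated_fraction` is
#'   the PV-associated share of all Col IV voxels, `associated_over_cd31`
#'   the associated Col IV volume over the CD31 volume.
#' @export
coliv_association <- function(coliv_mask, cd31_mask, vts_mask, spacing,
                              d_assoc = 3) {
  stopifnot(identical(dim(coliv_mask), dim(cd31_mask)),
            identical(dim(coliv_mask), dim(vts_mask)))
  vv <- prod(spacing)
  n_coliv <- sum(coliv_mask)
  if (n_coliv == 0)
    return(list(associated_fraction = NA_real_, associated_over_cd31 = NA_real_,
                frac_in_vts_nonassociated = NA_real_, frac_outside_vts = NA_real_,
                volumes_um3 = list(associated = 0, in_vts_nonassociated = 0,
                                   outside_vts = 0, coliv_total = 0,
                                   cd31_total = sum(cd31_mask) * vv)))
  if (!any(cd31_mask)) {
    warning("empty CD31 mask: Col IV association fraction is 0")
    d <- array(Inf, dim = dim(cd31_mask))
  } else {
    d <- cpp_edt(array(as.logical(cd31_mask), dim = dim(cd31_mask)),
                 spacing[1], spacing[2], spacing[3])
  }
  assoc <- coliv_mask & vts_mask & d <= d_assoc
  outside <- coliv_mask & !vts_mask
  nonassoc <- coliv_mask & vts_mask & !assoc
  n_cd31 <- sum(cd31_mask)
  list(associated_fraction = sum(assoc) / n_coliv,
       associated_over_cd31 = if (n_cd31 > 0) sum(assoc) / n_cd31 else NA_real_,
       frac_in_vts_nonassociated = sum(nonassoc) / n_coliv,
       frac_outside_vts = sum(outside) / n_coliv,
       volumes_um3 = list(associated = sum(assoc) * vv,
                          in_vts_nonassociated = sum(nonassoc) * vv,
                          outside_vts = sum(outside) * vv,
                          coliv_total = n_coliv * vv,
                          cd31_total = n_cd31 * vv))
}

#' Export a distance field as the 8-bit channel convention
#'
#' Quantizes the finite part of the field into 0..254 over `max_um` and
#' codes out-of-domain and beyond-range voxels as 255, the convention used
#' for visual inspection channels. The float field remains the
#' quantitative representation.
#'
#' @param field a [pv_distance_field()].
#' @param max_um distance mapped to 254; defaults to the field maximum.
#' @return integer array 0..255.
#' @export
distance_field_8bit <- function(field, max_um = NULL) {
  stopifnot(inherits(field, "distance_field"))
  v <- field$field
  if (is.null(max_um)) {
    finite <- v[is.finite(v) & !is.na(v)]
    max_um <- if (length(finite)) max(finite) else 1
  }
  q <- floor(pmin(pmax(v, 0), max_um) / max_um * 254)
  q[!is.finite(v) | is.na(v)] <- 255
  array(as.integer(q), dim = dim(v))
}
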