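# Per-channel compartment segmentation and point-cell detection.

# voxel linear index -> integer (z, y, x) 1-based coordinates
index_to_coords <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  r <- idx0 %/% dims[1]
  y <- r %% dims[2]
  x <- r %/% dims[2]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

coords_to_um <- function(coords, spacing) {
  sweep(coords - 1, 2, spacing, "*")
}

#' Segment one channel into a compartment mask and connected objects
#'
#' Smooths the channel at the per-channel surface-detail scale (Gaussian,
#' sigma = detail/2), thresholds it with the channel's configured rule,
#' restricts the mask to the VTS body, drops connected objects smaller
#' than `min_object_volume` and labels the rest with 26-connectivity.
#'
#' @param stack a [vts_stack()].
#' @param role channel role to segment.
#' @param config a [pipeline_config()].
#' @param vts_mask logical VTS body mask (from [vts_surface_mask()]), or
#'   `NULL` to segment the full grid.
#' @return object of class `compartment_seg`: `mask` (logical array),
#'   `labels` (integer array), `objects` (data.frame id, volume_um3,
#'   centroid z/y/x um), `role`, `threshold`, `settings`.
#' @export
segment_channel <- function(stack, role, config = pipeline_config(),
                            vts_mask = NULL) {
  stopifnot(inherits(stack, "vts_stack"))
  a <- get_channel(stack, role)
  sp <- stack$spacing
  sigma_um <- config$surface_detail_channel / 2
  sm <- if (sigma_um > 0)
    cpp_gauss_blur(a, sigma_um / sp[1], sigma_um / sp[2], sigma_um / sp[3])
  else a
  thr <- resolve_threshold(as.vector(sm), threshold_rule(config, role))
  mask <- array(sm > thr, dim = dim(a))
  if (!is.null(vts_mask)) mask <- mask & vts_mask
  lab <- cpp_label(mask, 26L)

  vv <- voxel_volume(stack)
  objects <- data.frame(id = integer(0), volume_um3 = numeric(0),
                        z = numeric(0), y = numeric(0), x = numeric(0))
  if (max(lab) > 0) {
    idx <- which(lab > 0L)
    lv <- lab[idx]
    counts <- tabulate(lv)
    keep <- which(counts * vv >= config$min_object_volume)
    if (length(keep)) {
      keep_voxel <- lv %in% keep
      idx <- idx[keep_voxel]; lv <- lv[keep_voxel]
      # relabel compactly, ordered by original label
      newid <- match(lv, sort(unique(lv)))
      co <- coords_to_um(index_to_coords(idx, dim(a)), sp)
      cz <- rowsum(co[, 1], newid); cy <- rowsum(co[, 2], newid)
      cx <- rowsum(co[, 3], newid)
      n_per <- tabulate(newid)
      objects <- data.frame(id = seq_along(n_per),
                            volume_um3 = n_per * vv,
                            z = cz[, 1] / n_per, y = cy[, 1] / n_per,
                            x = cx[, 1] / n_per)
      lab[] <- 0L
      lab[idx] <- newid
      mask <- array(lab > 0L, dim = dim(a))
    } else {
      lab[] <- 0L
      mask[] <- FALSE
    }
  }

  structure(list(role = role, mask = mask, labels = lab, objects = objects,
                 threshold = thr,
                 settings = list(surface_detail = config$surface_detail_channel,
                                 min_object_volume = config$min_object_volume),
                 spacing = sp),
            class = "compartment_seg")
}

#' @export
print.compartment_seg <- function(x, ...) {
  cat(sprintf("<compartment_seg> role '%s': %d object(s), %.0f um^3 total\n",
              x$role, nrow(x$objects), sum(x$objects$volume_um3)))
  invisible(x)
}

#' Per-object volume table
#'
#' @param seg a `compartment_seg` from [segment_channel()].
#' @return list with `table` (data.frame id, volume_um3, sorted descending)
#'   and `summary` (n, median, max um^3).
#' @export
object_volume_distribution <- function(seg) {
  stopifnot(inherits(seg, "compartment_seg"))
  tab <- seg$objects[order(-seg$objects$volume_um3), c("id", "volume_um3")]
  rownames(tab) <- NULL
  list(table = tab,
       summary = list(n = nrow(tab),
                      median_um3 = if (nrow(tab)) median(tab$volume_um3) else NA_real_,
                      max_um3 = if (nrow(tab)) max(tab$volume_um3) else NA_real_))
}

#' Detect point-like cells as scale-matched blobs
#'
#' Laplacian-of-Gaussian detection at the scale of the configured cell
#' diameter (sigma = diameter / (2 sqrt(3))): the channel is blurred, the
#' scale-normalised negative Laplacian is computed in physical units, and
#' its 26-neighbourhood local maxima above the quality threshold are kept.
#' Centroids are refined to sub-voxel precision by a response-weighted mean
#' over a one-sigma window.
#'
#' @param stack a [vts_stack()].
#' @param role channel role.
#' @param config a [pipeline_config()]; uses `cell_diameter` (um) and
#'   `cell_quality` (minimal LoG response, intensity units).
#' @param vts_mask optional logical mask; detections outside are dropped.
#' @return object of class `cell_set`: data.frame `cells` (z, y, x um,
#'   quality), `role`, `diameter`.
#' @export
detect_cells <- function(stack, role, config = pipeline_config(),
                         vts_mask = NULL) {
  stopifnot(inherits(stack, "vts_stack"))
  a <- get_channel(stack, role)
  sp <- stack$spacing
  dims <- dim(a)
  sigma <- config$cell_diameter / (2 * sqrt(3))

  sm <- cpp_gauss_blur(a, sigma / sp[1], sigma / sp[2], sigma / sp[3])
  # scale-normalised negative Laplacian, finite differences in um
  lap <- array(0, dim = dims)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  lap <- lap + (sm[c(2:nz, nz), , ] - 2 * sm + sm[c(1, 1:(nz - 1)), , ]) / sp[1]^2
  lap <- lap + (sm[, c(2:ny, ny), ] - 2 * sm + sm[, c(1, 1:(ny - 1)), ]) / sp[2]^2
  lap <- lap + (sm[, , c(2:nx, nx)] - 2 * sm + sm[, , c(1, 1:(nx - 1))]) / sp[3]^2
  resp <- array(-sigma^2 * lap, dim = dims)
  rm(lap, sm)

  maxima <- cpp_local_maxima(resp, config$cell_quality)
  if (!is.null(vts_mask)) maxima <- maxima & vts_mask
  idx <- which(maxima)

  cells <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      quality = numeric(0))
  if (length(idx)) {
    # collapse plateau maxima (equal-valued 26-adjacent voxels)
    lab <- cpp_label(array(maxima, dim = dims), 26L)
    lv <- lab[idx]
    co <- index_to_coords(idx, dims)
    reps <- !duplicated(lv)
    co <- co[reps, , drop = FALSE]
    q <- resp[idx][reps]
    # sub-voxel refinement: background-subtracted response-weighted
    # centroid over +-1.5 sigma
    w <- pmax(1L, round(1.5 * sigma / sp))
    refined <- matrix(NA_real_, nrow(co), 3)
    for (i in seq_len(nrow(co))) {
      zr <- max(1, co[i, 1] - w[1]):min(dims[1], co[i, 1] + w[1])
      yr <- max(1, co[i, 2] - w[2]):min(dims[2], co[i, 2] + w[2])
      xr <- max(1, co[i, 3] - w[3]):min(dims[3], co[i, 3] + w[3])
      block <- resp[zr, yr, xr, drop = FALSE]
      block <- pmax(block - min(block), 0)
      tot <- sum(block)
      if (tot <= 0) {
        refined[i, ] <- (co[i, ] - 1) * sp
      } else {
        bz <- apply(block, 1, sum); by <- apply(block, 2, sum)
        bx <- apply(block, 3, sum)
        refined[i, ] <- c(sum((zr - 1) * sp[1] * bz),
                          sum((yr - 1) * sp[2] * by),
                          sum((xr - 1) * sp[3] * bx)) / tot
      }
    }
    ord <- order(refined[, 1], refined[, 2], refined[, 3])
    cells <- data.frame(z = refined[ord, 1], y = refined[ord, 2],
                        x = refined[ord, 3], quality = q[ord])
  }

  structure(list(role = role, cells = cells,
                 diameter = config$cell_diameter, spacing = sp),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> role '%s': %d cell(s), nominal diameter %g um\n",
              x$role, nrow(x$cells), x$diameter))
  invisible(x)
}
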