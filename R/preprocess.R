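# Preprocessing: denoising, combined channel, VTS body delineation.

#' 3-D median filter
#'
#' Box median over a `(2r+1)^3`-style neighbourhood with per-axis
#' half-widths (in voxels) and replicated edges, applied to every channel.
#' A radius of 0 on all axes is the identity.
#'
#' @param stack a [vts_stack()].
#' @param radius scalar or length-3 `(rz, ry, rx)` half-width in voxels;
#'   defaults to the config value 2 (a 5x5x5 box).
#' @return filtered [vts_stack()].
#' @export
median_filter_3d <- function(stack, radius = 2) {
  stopifnot(inherits(stack, "vts_stack"))
  r <- as.integer(round(rep_len(radius, 3)))
  if (any(r < 0)) stop("median filter radius must be >= 0")
  stack$channels <- lapply(stack$channels, cpp_median_box,
                           rz = r[1], ry = r[2], rx = r[3])
  stack
}

#' Additively combined channel
#'
#' Voxelwise sum of all fluorescence channels, saturated at the dtype
#' maximum (255 for 8-bit-scaled data), appended to the stack under the
#' role `vts_combined`. An existing combined channel is replaced.
#'
#' @param stack a [vts_stack()].
#' @param saturation saturation ceiling; defaults to the dtype maximum
#'   (255 for `uint8`/`float32` 0-255 data, 65535 for `uint16`).
#' @return stack with the `vts_combined` channel appended.
#' @export
combined_channel <- function(stack, saturation = NULL) {
  stopifnot(inherits(stack, "vts_stack"))
  src <- stack$channels[setdiff(names(stack$channels), "vts_combined")]
  if (length(src) < 1) stop("no fluorescence channels to combine")
  if (is.null(saturation))
    saturation <- if (stack$dtype == "uint16") 65535 else 255
  acc <- src[[1]]
  for (a in src[-1]) acc <- acc + a
  stack$channels$vts_combined <- array(pmin(acc, saturation), dim = dim(acc))
  stack
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * 256) + 1L, 1L), 256L),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

# resolve a threshold rule against the data
resolve_threshold <- function(x, rule) {
  method <- rule$method %||% "otsu"
  switch(method,
         otsu = otsu_threshold(x),
         quantile = {
           if (is.null(rule$q) || rule$q <= 0 || rule$q >= 1)
             stop("quantile threshold needs q in (0,1)")
           as.numeric(quantile(x, rule$q))
         },
         absolute = {
           if (is.null(rule$value)) stop("absolute threshold needs `value`")
           rule$value
         },
         stop(sprintf("unknown threshold method '%s'", method)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fill interior holes: background is 6-connected; any background component
# not touching the volume border is interior and becomes foreground.
fill_holes_3d <- function(mask) {
  bg <- cpp_label(array(!mask, dim = dim(mask)), 6L)
  d <- dim(mask)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  holes <- bg > 0 & !(bg %in% border_labels)
  array(mask | holes, dim = d)
}

# keep only the largest 26-connected component
largest_component <- function(mask) {
  lab <- cpp_label(mask, 26L)
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(lab[lab > 0])
  array(lab == which.max(counts), dim = dim(mask))
}

#' Delineate the VTS body from the combined channel
#'
#' Smooths the combined channel at the VTS surface-detail scale (Gaussian,
#' sigma = detail/2), thresholds it, keeps the largest 26-connected
#' component and fills interior holes (6-connected background).
#'
#' @param stack a [vts_stack()] with a `vts_combined` channel (see
#'   [combined_channel()]).
#' @param config a [pipeline_config()]; uses `surface_detail_vts` and the
#'   threshold rule for role `vts_combined`.
#' @return list with `mask` (logical array) and `volume_um3`.
#' @export
vts_surface_mask <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "vts_stack"))
  a <- get_channel(stack, "vts_combined")
  sigma_um <- config$surface_detail_vts / 2
  sp <- stack$spacing
  sm <- cpp_gauss_blur(a, sigma_um / sp[1], sigma_um / sp[2], sigma_um / sp[3])
  thr <- resolve_threshold(as.vector(sm), threshold_rule(config, "vts_combined"))
  mask <- array(sm > thr, dim = dim(a))
  mask <- largest_component(mask)
  if (is.null(mask))
    stop("NoSpheroidFound: no foreground component above the VTS threshold")
  mask <- fill_holes_3d(mask)
  list(mask = mask, volume_um3 = sum(mask) * voxel_volume(stack),
       threshold = thr)
}
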