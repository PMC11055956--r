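# Multichannel stack container and TIFF/YAML I/O.
#
# Coordinate convention: voxel arrays have dim = (nz, ny, nx); the physical
# position of voxel (iz, iy, ix) (1-based) is ((iz-1)*dz, (iy-1)*dy,
# (ix-1)*dx) micrometres, i.e. voxel centres on a grid anchored at the
# origin. All distances everywhere in the package are micrometres.

CHANNEL_ROLES <- c("vts_combined", "tumor", "fibroblast", "cd31",
                   "cd11b", "colIV", "hif1a", "custom")

DTYPE_MAX <- c(uint8 = 255, uint16 = 65535, float32 = NA_real_)

#' Multichannel voxel stack
#'
#' Container for a 3-D multichannel fluorescence stack with anisotropic
#' physical voxel spacing and named channel roles. Channels are stored as a
#' named list of 3-D arrays with dim `(nz, ny, nx)`; names are the channel
#' roles (e.g. `"cd31"`, `"tumor"`).
#'
#' @param channels named list of 3-D numeric arrays, all the same dim. Names
#'   must be unique; known roles are `r paste(CHANNEL_ROLES, collapse = ", ")`
#'   but arbitrary names are accepted (treated as `custom`).
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in
#'   micrometres; strictly positive.
#' @param dtype storage type used on disk: `"uint8"`, `"uint16"` or
#'   `"float32"`.
#' @return object of class `vts_stack`.
#' @export
vts_stack <- function(channels, spacing, dtype = "float32") {
  if (!is.list(channels) || length(channels) < 1)
    stop("`channels` must be a non-empty named list of 3-D arrays")
  if (is.null(names(channels)) || anyDuplicated(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channel names must be unique and non-empty")
  dims <- lapply(channels, function(a) {
    if (length(dim(a)) != 3) stop("each channel must be a 3-D array")
    dim(a)
  })
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all channels must share the same dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (dz, dy, dx) in um")
  dtype <- match.arg(dtype, names(DTYPE_MAX))
  structure(list(channels = channels, spacing = spacing, dtype = dtype),
            class = "vts_stack")
}

#' @export
print.vts_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<vts_stack> %d x %d x %d voxels (z,y,x), %d channel(s), %s\n",
              d[1], d[2], d[3], length(x$channels), x$dtype))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g um (dz, dy, dx)\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  roles:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.vts_stack <- function(x) dim(x$channels[[1]])

stack_dim <- function(stack) dim(stack$channels[[1]])

#' Extract one channel by role
#'
#' @param stack a [vts_stack()].
#' @param role channel role name.
#' @return 3-D array.
#' @export
get_channel <- function(stack, role) {
  if (!role %in% names(stack$channels))
    stop(sprintf("channel role '%s' not present (have: %s)", role,
                 paste(names(stack$channels), collapse = ", ")))
  stack$channels[[role]]
}

has_channel <- function(stack, role) role %in% names(stack$channels)

#' Voxel volume in cubic micrometres
#' @param stack a [vts_stack()] (or a spacing vector).
#' @return scalar, um^3 per voxel.
#' @export
voxel_volume <- function(stack) {
  sp <- if (inherits(stack, "vts_stack")) stack$spacing else as.numeric(stack)
  prod(sp)
}

# ------------------------------------------------------------------- I/O ---

#' Write a multichannel stack to TIFF
#'
#' Pages are written channel-major (all z planes of channel 1, then channel
#' 2, ...). Physical spacing, channel roles, dtype and plane layout go into
#' a JSON sidecar `<path>.json`. 8/16-bit data is rescaled into the TIFF
#' unit range and restored exactly (as integer arrays) on read; float data
#' is stored as 32-bit float, which the TIFF library reproduces to within
#' 2^-32 of the written value.
#'
#' @param stack a [vts_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "vts_stack"))
  d <- stack_dim(stack)
  scale <- DTYPE_MAX[[stack$dtype]]
  bits <- switch(stack$dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    if (!is.na(scale)) a <- a / scale
    for (iz in seq_len(d[1]))
      pages[[length(pages) + 1L]] <- matrix(a[iz, , ], nrow = d[2], ncol = d[3])
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "LZW", reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write TIFF '%s': %s", path, attr(ok, "condition")$message))
  meta <- list(spacing_um = stack$spacing, channel_roles = names(stack$channels),
               dtype = stack$dtype, dim_zyx = d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel stack from TIFF
#'
#' Spacing and channel roles come from the JSON sidecar written by
#' [write_stack()] when present (sidecar metadata wins over the config, with
#' a message); otherwise both must be supplied through `config`
#' (`config$spacing`, `config$channel_roles`).
#'
#' @param path TIFF file path.
#' @param config optional [pipeline_config()] or plain list supplying
#'   `spacing` and `channel_roles` for plain TIFFs.
#' @return a [vts_stack()].
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- try(tiff::readTIFF(path, all = TRUE, info = FALSE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop(sprintf("cannot read TIFF '%s'", path))
  if (!is.list(pages)) pages <- list(pages)

  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  if (!is.null(meta)) {
    spacing <- as.numeric(meta$spacing_um)
    roles <- as.character(meta$channel_roles)
    dtype <- meta$dtype
    if (!is.null(config) && !is.null(config$spacing) &&
        any(abs(as.numeric(config$spacing) - spacing) > 1e-9))
      message("read_stack: file metadata spacing overrides config spacing")
  } else {
    if (is.null(config) || is.null(config$spacing) || is.null(config$channel_roles))
      stop("no metadata sidecar; config must supply `spacing` and `channel_roles`")
    spacing <- as.numeric(config$spacing)
    roles <- as.character(config$channel_roles)
    dtype <- "float32"
  }

  n_pages <- length(pages)
  n_ch <- length(roles)
  if (n_pages %% n_ch != 0)
    stop(sprintf("page count %d is not a multiple of the %d configured channels",
                 n_pages, n_ch))
  nz <- n_pages %/% n_ch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  scale <- DTYPE_MAX[[dtype]]
  channels <- vector("list", n_ch)
  names(channels) <- roles
  for (c_i in seq_len(n_ch)) {
    a <- array(0, dim = c(nz, ny, nx))
    for (iz in seq_len(nz)) a[iz, , ] <- pages[[(c_i - 1L) * nz + iz]]
    if (!is.na(scale)) {
      a <- round(a * scale)
      storage.mode(a) <- "integer"
    }
    channels[[c_i]] <- a
  }
  vts_stack(channels, spacing, dtype)
}

# ---------------------------------------------------------------- config ---

#' Pipeline configuration
#'
#' Collects the tunable settings of the whole analysis pipeline with the
#' defaults used throughout. Lengths are micrometres.
#'
#' @param median_radius 3-D median filter setting per axis (half-width in
#'   voxels; 2 gives a 5x5x5 box).
#' @param surface_detail_channel smoothing scale (um) for per-channel
#'   compartment segmentation.
#' @param surface_detail_vts smoothing scale (um) for the VTS body surface.
#' @param thresholds named list per channel role; each entry either
#'   `list(method = "otsu")`, `list(method = "quantile", q = 0.99)` or
#'   `list(method = "absolute", value = 40)`. Roles without an entry fall
#'   back to `default_threshold`.
#' @param default_threshold fallback threshold rule.
#' @param min_object_volume smallest connected object kept, um^3.
#' @param cell_diameter nominal cell orb diameter, um.
#' @param cell_quality minimal Laplacian-of-Gaussian blob response
#'   (intensity units) for cell detection.
#' @param coliv_association_distance association distance between Col IV and
#'   CD31 voxels, um.
#' @param prune_length skeleton spur prune length, um.
#' @param distance_bin_width distance histogram bin width, um.
#' @param spacing default voxel spacing (dz, dy, dx) um, used when a file
#'   carries no metadata.
#' @param channel_roles default channel role order for plain TIFFs.
#' @return a list of class `vts_config`.
#' @export
pipeline_config <- function(median_radius = 2,
                            surface_detail_channel = 2,
                            surface_detail_vts = 10,
                            thresholds = list(),
                            default_threshold = list(method = "otsu"),
                            min_object_volume = 50,
                            cell_diameter = 10,
                            cell_quality = 10,
                            coliv_association_distance = 3,
                            prune_length = 5,
                            distance_bin_width = 5,
                            spacing = c(1, 0.5, 0.5),
                            channel_roles = c("tumor", "fibroblast", "cd31")) {
  cfg <- list(median_radius = median_radius,
              surface_detail_channel = surface_detail_channel,
              surface_detail_vts = surface_detail_vts,
              thresholds = thresholds,
              default_threshold = default_threshold,
              min_object_volume = min_object_volume,
              cell_diameter = cell_diameter,
              cell_quality = cell_quality,
              coliv_association_distance = coliv_association_distance,
              prune_length = prune_length,
              distance_bin_width = distance_bin_width,
              spacing = spacing,
              channel_roles = channel_roles)
  for (nm in c("surface_detail_channel", "surface_detail_vts",
               "min_object_volume", "cell_diameter", "prune_length",
               "distance_bin_width", "coliv_association_distance"))
    if (cfg[[nm]] < 0) stop(sprintf("`%s` must be non-negative", nm))
  if (median_radius < 0) stop("`median_radius` must be non-negative")
  class(cfg) <- c("vts_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return a `vts_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

threshold_rule <- function(config, role) {
  if (!is.null(config$thresholds[[role]])) config$thresholds[[role]]
  else config$default_threshold
}
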