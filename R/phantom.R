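# Synthetic VTS phantom generator.
#
# Emulates the imaging situation the pipeline is built for: a dense
# spheroid body, an embedded branching pseudovessel network of varying
# radius rendered into a CD31 channel, dense complementary tumor/fibroblast
# compartments, point-like cells as ~10 um orbs in their own channels, a
# Col IV sheath around the vessels, PSF blur and Poisson + Gaussian noise.
# Every structure is also returned noiselessly as ground truth so each
# downstream stage can be validated against known geometry.

#' Phantom specification
#'
#' @param spheroid_radius spheroid body radius, um.
#' @param voxel_spacing voxel spacing `(dz, dy, dx)`, um.
#' @param channel_set channels to render; subset of
#'   `c("tumor", "fibroblast", "cd31", "cd11b", "colIV", "hif1a")`.
#' @param vessel_params list: `n_roots` (trees grown), `branch_prob`
#'   (branching probability per growth step), `radius_range` (um, c(min,
#'   max)), `step_length` (um per growth step), `max_depth` (maximal branch
#'   generation).
#' @param cell_params named list per population; each entry a list with
#'   `count`, `orb_diameter` (um), `placement` (`"uniform"`, `"shell"` or
#'   `"core"`) and optionally `min_separation` (um, default: touching hard
#'   spheres) for orb populations, or `list(render = "compartment")` for a
#'   dense volumetric compartment (tumor/fibroblast style; the first
#'   compartment population may set `fraction`, its share of the spheroid
#'   body, default 0.5).
#' @param noise_params list: `photon_scale` (photons per intensity unit for
#'   shot noise; 0 disables), `gaussian_sd` (additive read noise, intensity
#'   units), `background_level` (baseline intensity).
#' @param psf_sigma isotropic Gaussian PSF sigma, um (0 disables blur).
#' @param margin empty border around the spheroid, um.
#' @param seed integer seed; the whole phantom is a pure function of the
#'   spec including this seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(spheroid_radius = 150,
                         voxel_spacing = c(2, 1.3, 1.3),
                         channel_set = c("tumor", "fibroblast", "cd31",
                                         "cd11b", "colIV", "hif1a"),
                         vessel_params = list(n_roots = 3, branch_prob = 0.12,
                                              radius_range = c(4, 9),
                                              step_length = 8, max_depth = 4),
                         cell_params = list(
                           tumor = list(render = "compartment"),
                           fibroblast = list(render = "compartment"),
                           cd11b = list(count = 25, orb_diameter = 10,
                                        placement = "uniform"),
                           hif1a = list(count = 25, orb_diameter = 10,
                                        placement = "core")),
                         noise_params = list(photon_scale = 2, gaussian_sd = 3,
                                             background_level = 10),
                         psf_sigma = 1,
                         margin = 15,
                         seed = 1L) {
  if (spheroid_radius <= 0) stop("spheroid_radius must be positive")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be strictly positive")
  vp <- vessel_params
  if (vp$n_roots < 0 || vp$max_depth < 0) stop("vessel counts must be >= 0")
  if (vp$branch_prob < 0 || vp$branch_prob > 1) stop("branch_prob must be in [0,1]")
  if (any(vp$radius_range <= 0) || max(vp$radius_range) > spheroid_radius / 4)
    stop("radius_range must lie in (0, spheroid_radius/4)")
  if (vp$step_length <= 0) stop("step_length must be positive")
  for (nm in names(cell_params)) {
    cp <- cell_params[[nm]]
    if (identical(cp$render, "compartment")) next
    if (is.null(cp$count) || cp$count < 0) stop("cell counts must be >= 0")
    if (is.null(cp$orb_diameter) || cp$orb_diameter <= 0 ||
        cp$orb_diameter / 2 >= spheroid_radius)
      stop("orb radius must be positive and smaller than the spheroid")
  }
  spec <- list(spheroid_radius = spheroid_radius,
               voxel_spacing = as.numeric(voxel_spacing),
               channel_set = channel_set,
               vessel_params = vessel_params,
               cell_params = cell_params,
               noise_params = noise_params,
               psf_sigma = psf_sigma,
               margin = margin,
               seed = as.integer(seed))
  class(spec) <- c("phantom_spec", "list")
  spec
}

phantom_grid <- function(spec) {
  extent <- 2 * (spec$spheroid_radius + spec$margin)
  dims <- pmax(8L, as.integer(ceiling(extent / spec$voxel_spacing)) + 1L)
  center <- (dims - 1) / 2 * spec$voxel_spacing
  list(dims = dims, center = center)
}

# uniform point in a ball of radius r around the origin
runif_ball <- function(n, r) {
  p <- matrix(rnorm(3 * n), ncol = 3)
  p <- p / sqrt(rowSums(p^2))
  p * r * runif(n)^(1 / 3)
}

#' Grow a synthetic branching vessel network
#'
#' Random recursive trees: each of `n_roots` seeds starts inside the
#' spheroid and grows with a persistent, slowly wandering direction in
#' steps of `step_length` um; at each step a side branch is spawned with
#' probability `branch_prob` (up to `max_depth` generations). Growth stops
#' at the spheroid boundary. Per-point radii taper from the root radius
#' toward the tips and are non-increasing from root to tip along every
#' path. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`; `$centerlines` is a list of
#'   branches, each with `points` (n x 3 matrix, um, z/y/x stack frame),
#'   `radius` (um per point), `network` (root id) and `depth`.
#' @export
generate_vessel_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- phantom_grid(spec)
  vp <- spec$vessel_params
  R <- spec$spheroid_radius
  rmin <- min(vp$radius_range); rmax <- max(vp$radius_range)
  taper <- 0.85          # per-step radius decay factor toward the tip
  dir_wander <- 0.45     # sd of the per-step direction perturbation
  branch_r_factor <- 0.8 # child branches start thinner than the parent

  branches <- list()

  grow <- function(pos, dir, radius, depth, network) {
    pts <- matrix(pos, ncol = 3)
    radii <- radius
    max_steps <- ceiling(2.5 * R / vp$step_length)
    for (s in seq_len(max_steps)) {
      dir <- dir + dir_wander * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      new_pos <- pos + vp$step_length * dir
      if (sqrt(sum(new_pos^2)) > R - radius) break
      radius <- max(rmin, radius * taper^(1 / 4))
      pos <- new_pos
      pts <- rbind(pts, pos)
      radii <- c(radii, radius)
      if (depth < vp$max_depth && runif(1) < vp$branch_prob && radius > rmin) {
        perp <- rnorm(3)
        perp <- perp - sum(perp * dir) * dir
        perp <- perp / sqrt(sum(perp^2))
        child_dir <- 0.55 * dir + 0.84 * perp  # ~57 degree take-off
        child_dir <- child_dir / sqrt(sum(child_dir^2))
        grow(pos, child_dir, max(rmin, branch_r_factor * radius), depth + 1, network)
      }
    }
    if (nrow(pts) >= 2)
      branches[[length(branches) + 1L]] <<- list(points = pts, radius = radii,
                                                 network = network, depth = depth)
    invisible(NULL)
  }

  if (vp$n_roots > 0) {
    roots <- runif_ball(vp$n_roots, 0.55 * R)
    for (k in seq_len(vp$n_roots)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      grow(roots[k, ], dir, runif(1, 0.8 * rmax, rmax), 0L, k)
    }
  }

  # shift from spheroid-centred physical coordinates to the stack frame
  branches <- lapply(branches, function(b) {
    b$points <- sweep(b$points, 2, g$center, "+")
    colnames(b$points) <- c("z", "y", "x")
    b
  })

  truth <- list(centerlines = branches,
                spheroid_center = g$center,
                spheroid_radius = R,
                dims = g$dims,
                spacing = spec$voxel_spacing,
                cell_centroids = list(),
                masks = list())
  class(truth) <- c("phantom_truth", "list")
  truth
}

#' Total centreline length of a generated network, um
#' @param truth a `phantom_truth`.
#' @return scalar um.
#' @export
centerline_length <- function(truth) {
  sum(vapply(truth$centerlines, function(b) {
    if (nrow(b$points) < 2) return(0)
    sum(sqrt(rowSums(diff(b$points)^2)))
  }, numeric(1)))
}

# resample a polyline (with per-point radii) at ~`step` um spacing
resample_polyline <- function(points, radius, step) {
  seg <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(list(points = points[1, , drop = FALSE], radius = radius[1]))
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  out_p <- cbind(approx(cum, points[, 1], xout = s)$y,
                 approx(cum, points[, 2], xout = s)$y,
                 approx(cum, points[, 3], xout = s)$y)
  out_r <- approx(cum, radius, xout = s)$y
  list(points = out_p, radius = out_r)
}

new_volume <- function(dims) array(0, dim = dims)

place_orbs <- function(n, orb_r, placement, R, center, avoid = NULL,
                       min_separation = 2 * orb_r, max_attempts = 1e4) {
  if (n == 0) return(matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("z", "y", "x"))))
  placed <- matrix(NA_real_, nrow = n, ncol = 3)
  k <- 0; attempts <- 0
  while (k < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop(sprintf("could not place %d non-overlapping orbs in %d attempts",
                   n, max_attempts))
    p <- switch(placement,
      uniform = runif_ball(1, R - orb_r),
      core = runif_ball(1, max(orb_r, 0.4 * R - orb_r)),
      shell = {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        matrix(u * runif(1, 0.75 * R, R - orb_r), ncol = 3)
      },
      stop(sprintf("unknown placement rule '%s'", placement)))
    ok <- TRUE
    if (k > 0) {
      dd <- sqrt(rowSums(sweep(placed[seq_len(k), , drop = FALSE], 2, p)^2))
      if (any(dd < min_separation)) ok <- FALSE
    }
    if (ok && !is.null(avoid) && nrow(avoid) > 0) {
      dd <- sqrt(rowSums(sweep(avoid, 2, p)^2))
      if (any(dd < 2 * orb_r)) ok <- FALSE
    }
    if (ok) { k <- k + 1; placed[k, ] <- p }
  }
  placed <- sweep(placed, 2, center, "+")
  colnames(placed) <- c("z", "y", "x")
  placed
}

#' Rasterize a phantom into a multichannel stack with ground truth
#'
#' Renders vessels as tubes of local radius (CD31), the tumor/fibroblast
#' compartments as complementary dense regions of the spheroid body, orb
#' populations as hard spheres (non-overlapping within a population), a Col
#' IV sheath around the vessels plus extra-spheroidal Col IV patches, then
#' applies Gaussian PSF blur and Poisson/Gaussian noise. Intensities are on
#' a 0-255 scale. Noiseless binary masks and all centroids are filled into
#' the returned ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param truth a `phantom_truth` from [generate_vessel_network()].
#' @return list with `stack` (a [vts_stack()]) and `truth` (masks and
#'   centroids filled in).
#' @export
rasterize_phantom <- function(spec, truth) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  set.seed(spec$seed + 1L)
  g <- phantom_grid(spec)
  dims <- g$dims
  sp <- spec$voxel_spacing
  R <- spec$spheroid_radius
  np <- spec$noise_params

  # spheroid body mask from voxel-centre distances
  zc <- ((seq_len(dims[1]) - 1) * sp[1] - g$center[1])^2
  yc <- ((seq_len(dims[2]) - 1) * sp[2] - g$center[2])^2
  xc <- ((seq_len(dims[3]) - 1) * sp[3] - g$center[3])^2
  r2 <- outer(outer(zc, yc, "+"), xc, "+")
  spheroid <- array(r2 <= R^2, dim = dims)
  rm(r2)

  truth$masks$spheroid <- spheroid

  body_intensity <- 150
  orb_intensity <- 210
  tube_intensity <- 200
  clip_warnings <- 0L

  # vessel tube mask (shared by cd31 and colIV)
  tube_mask <- NULL
  if (length(truth$centerlines) > 0) {
    vol <- new_volume(dims)
    stamp_step <- min(sp) / 2
    for (b in truth$centerlines) {
      rs <- resample_polyline(b$points, b$radius, stamp_step)
      clip_warnings <- clip_warnings +
        cpp_stamp_balls(vol, rs$points, rs$radius, sp[1], sp[2], sp[3], 1)
    }
    tube_mask <- array(vol > 0.5, dim = dims)
    rm(vol)
  } else {
    tube_mask <- array(FALSE, dim = dims)
  }

  # tumor/fibroblast compartment split: smooth random field over the body
  compartments <- NULL
  wants_compartment <- vapply(spec$cell_params,
                              function(cp) identical(cp$render, "compartment"),
                              logical(1))
  if (any(wants_compartment)) {
    first_cp <- spec$cell_params[[which(wants_compartment)[1]]]
    frac <- first_cp$fraction %||% 0.5
    field <- array(rnorm(prod(dims)), dim = dims)
    field <- cpp_gauss_blur(field, 25 / sp[1], 25 / sp[2], 25 / sp[3])
    cut <- quantile(field[spheroid], 1 - frac, names = FALSE)
    compartments <- list(first = array(field > cut, dim = dims) & spheroid,
                         second = array(field <= cut, dim = dims) & spheroid)
    rm(field)
  }

  channels <- list()
  comp_used <- 0L
  orb_avoid <- NULL

  for (role in spec$channel_set) {
    vol <- new_volume(dims)
    cp <- spec$cell_params[[role]]
    if (role == "cd31") {
      vol[tube_mask] <- tube_intensity
      truth$masks$cd31 <- tube_mask
    } else if (role == "colIV") {
      d_cd31 <- cpp_edt(tube_mask, sp[1], sp[2], sp[3])
      sheath <- array(is.finite(d_cd31) & d_cd31 > 0 & d_cd31 <= 2.5, dim = dims)
      rm(d_cd31)
      # patches of matrix deposited outside but attached to the spheroid
      n_patch <- 3
      if (n_patch > 0) {
        u <- matrix(rnorm(3 * n_patch), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        pc <- sweep(u * (R + 6), 2, g$center, "+")
        pv <- new_volume(dims)
        clip_warnings <- clip_warnings +
          cpp_stamp_balls(pv, pc, rep(8, n_patch), sp[1], sp[2], sp[3], 1)
        sheath <- sheath | (array(pv > 0.5, dim = dims) & !spheroid)
        rm(pv)
      }
      vol[sheath] <- tube_intensity
      truth$masks$colIV <- sheath
    } else if (!is.null(cp) && identical(cp$render, "compartment")) {
      comp_used <- comp_used + 1L
      m <- if (comp_used == 1L) compartments$first else compartments$second
      vol[m] <- body_intensity
      # individual bright cells are not resolvable in these dense channels
      truth$masks[[role]] <- m
    } else {
      count <- if (is.null(cp)) 0L else cp$count
      orb_d <- if (is.null(cp)) 10 else cp$orb_diameter
      placement <- if (is.null(cp)) "uniform" else cp$placement
      min_sep <- cp$min_separation %||% orb_d
      cent <- place_orbs(count, orb_d / 2, placement, R, g$center,
                         avoid = orb_avoid, min_separation = max(min_sep, orb_d))
      orb_avoid <- rbind(orb_avoid, cent)
      if (nrow(cent) > 0) {
        clip_warnings <- clip_warnings +
          cpp_stamp_balls(vol, cent, rep(orb_d / 2, nrow(cent)),
                          sp[1], sp[2], sp[3], orb_intensity)
      }
      truth$cell_centroids[[role]] <- cent
      truth$masks[[role]] <- array(vol > 0.5, dim = dims)
    }
    channels[[role]] <- vol
  }

  # a faint body glow in the dense cellular channels makes the combined
  # channel cover the whole spheroid, as a dense cell mass does in practice
  for (role in intersect(names(channels), c("tumor", "fibroblast"))) {
    a <- channels[[role]]
    a[spheroid & a == 0] <- 25
    channels[[role]] <- a
  }

  if (clip_warnings > 0)
    warning(sprintf("%d rendered structure(s) were clipped at the stack bounds",
                    clip_warnings))

  # optics + noise
  for (role in names(channels)) {
    a <- channels[[role]]
    if (spec$psf_sigma > 0)
      a <- cpp_gauss_blur(a, spec$psf_sigma / sp[1], spec$psf_sigma / sp[2],
                          spec$psf_sigma / sp[3])
    a <- a + np$background_level
    if (np$photon_scale > 0)
      a <- array(rpois(length(a), pmax(a, 0) * np$photon_scale) / np$photon_scale,
                 dim = dims)
    if (np$gaussian_sd > 0)
      a <- a + array(rnorm(length(a), 0, np$gaussian_sd), dim = dims)
    # 8-bit camera quantization
    channels[[role]] <- array(round(pmin(pmax(a, 0), 255)), dim = dims)
  }

  stack <- vts_stack(channels, sp, dtype = "uint8")
  list(stack = stack, truth = truth)
}

#' Generate a complete phantom (network + rasterization)
#' @param spec a [phantom_spec()].
#' @return list with `stack` and `truth` as in [rasterize_phantom()].
#' @export
generate_phantom <- function(spec) {
  truth <- generate_vessel_network(spec)
  rasterize_phantom(spec, truth)
}

#' Reference full-channel phantom configuration
#'
#' The package's standard validation phantom: a 150 um-radius spheroid on a
#' ~330 um anisotropic grid (about 256 voxels across in-plane), three vessel
#' roots with radii 4-9 um, complementary tumor/fibroblast compartments, and
#' 25 CD11b and 25 Hif1a orbs placed uniformly with >= 15 um separation (the
#' condition under which single-cell detection is specified to be exact).
#'
#' @param seed integer seed.
#' @return a [phantom_spec()].
#' @export
reference_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    seed = seed,
    cell_params = list(
      tumor = list(render = "compartment"),
      fibroblast = list(render = "compartment"),
      cd11b = list(count = 25, orb_diameter = 10, placement = "uniform",
                   min_separation = 15),
      hif1a = list(count = 25, orb_diameter = 10, placement = "uniform",
                   min_separation = 15)))
}

# -------------------------------------------------------- ranking dataset ---

#' Synthetic treated/control ratio table with observer scores
#'
#' Draws per-group ratios of PV volume (`rV`), supply index (`rSI`) and
#' segments-per-network (`rSN`) log-uniformly from `ratio_range` and sets
#' the observer score to the model VEI plus Gaussian noise, clipped to
#' `[-1, 1]`. Stands in for observer-annotated treatment groups when
#' exercising the VEI calibration.
#'
#' @param n_groups number of treatment groups (>= 6, the number of free
#'   model parameters).
#' @param model a [vei_model()]; defaults to the published fit.
#' @param noise_sd observer-score noise sd (score units).
#' @param seed integer seed.
#' @param ratio_range range of the log-uniform ratio draw.
#' @return data.frame with columns `group`, `rV`, `rSI`, `rSN`, `os`.
#' @export
generate_ranking_dataset <- function(n_groups, model = vei_model(),
                                     noise_sd = 0.02, seed = 1L,
                                     ratio_range = c(0.25, 4)) {
  if (n_groups < 6)
    stop("n_groups must be >= 6: the VEI model has six free parameters")
  set.seed(as.integer(seed))
  draw <- function(n) exp(runif(n, log(ratio_range[1]), log(ratio_range[2])))
  tab <- data.frame(group = sprintf("G%03d", seq_len(n_groups)),
                    rV = draw(n_groups), rSI = draw(n_groups),
                    rSN = draw(n_groups))
  os <- compute_vei(tab, model)
  if (noise_sd > 0) os <- os + rnorm(n_groups, 0, noise_sd)
  tab$os <- pmin(pmax(os, -1), 1)
  tab
}
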