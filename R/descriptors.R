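# The multiparametric per-VTS descriptor table.
#
# Every analyzed VTS is summarized as one row of named parameters drawn
# from a versioned registry. With the full staining configuration (three
# cellular channels plus CD11b, Col IV and Hif1a) the registry defines
# exactly 71 parameters; with only the three cellular channels (tumor,
# fibroblast, CD31) the defined subset has exactly 46. Families whose
# required channels are absent are dropped as a whole - there are no
# silent missing values.

REGISTRY_VERSION <- "1.0.0"

#' Parameter registry
#'
#' The named parameters a descriptor row can contain, their family, units
#' and required channels. The registry is versioned; descriptor tables
#' embed the version so rows from different registry versions are never
#' silently pooled.
#'
#' @return data.frame with columns `name`, `family`, `units`, `requires`
#'   (comma-separated channel roles).
#' @export
parameter_registry <- function() {
  p <- function(name, family, units, requires = "") {
    data.frame(name = name, family = family, units = units,
               requires = requires)
  }
  core3 <- "tumor,fibroblast,cd31"
  reg <- rbind(
    p("vts_volume_um3", "size", "um3"),

    p("tumor_volume_um3", "composition", "um3", "tumor"),
    p("tumor_volume_rel", "composition", "fraction", "tumor"),
    p("fibroblast_volume_um3", "composition", "um3", "fibroblast"),
    p("fibroblast_volume_rel", "composition", "fraction", "fibroblast"),
    p("cd31_volume_um3", "composition", "um3", "cd31"),
    p("cd31_volume_rel", "composition", "fraction", "cd31"),
    p("comp_frac_tumor", "composition", "fraction", core3),
    p("comp_frac_fibroblast", "composition", "fraction", core3),
    p("comp_frac_cd31", "composition", "fraction", core3),

    p("tumor_n_cells", "cells", "count", "tumor"),
    p("tumor_cell_density_mm3", "cells", "1/mm3", "tumor"),
    p("tumor_median_dist_pv_um", "cells", "um", "tumor,cd31"),
    p("tumor_median_dist_surface_um", "cells", "um", "tumor"),
    p("tumor_median_dist_complement_um", "cells", "um", "tumor,fibroblast"),
    p("fibroblast_n_cells", "cells", "count", "fibroblast"),
    p("fibroblast_cell_density_mm3", "cells", "1/mm3", "fibroblast"),
    p("fibroblast_median_dist_pv_um", "cells", "um", "fibroblast,cd31"),
    p("fibroblast_median_dist_surface_um", "cells", "um", "fibroblast"),
    p("fibroblast_median_dist_complement_um", "cells", "um", "tumor,fibroblast"),
    p("tumor_fibroblast_cell_ratio", "cells", "ratio", "tumor,fibroblast"),

    p("pv_n_networks", "pv_network", "count", "cd31"),
    p("pv_n_segments", "pv_network", "count", "cd31"),
    p("pv_segments_per_network", "pv_network", "count", "cd31"),
    p("pv_total_length_um", "pv_network", "um", "cd31"),
    p("pv_mean_segment_length_um", "pv_network", "um", "cd31"),
    p("pv_diameter_mean_um", "pv_network", "um", "cd31"),
    p("pv_diameter_median_um", "pv_network", "um", "cd31"),
    p("pv_diameter_sd_um", "pv_network", "um", "cd31"),
    p("pv_diameter_p10_um", "pv_network", "um", "cd31"),
    p("pv_diameter_p90_um", "pv_network", "um", "cd31"),
    p("pv_branch_level_mean", "pv_network", "level", "cd31"),
    p("pv_branch_level_max", "pv_network", "level", "cd31"),
    p("pv_branch_frac_main", "pv_network", "fraction", "cd31"),
    p("pv_network_volume_mean_um3", "pv_network", "um3", "cd31"),
    p("pv_network_volume_median_um3", "pv_network", "um3", "cd31"),
    p("pv_network_volume_max_um3", "pv_network", "um3", "cd31"),
    p("pv_network_length_mean_um", "pv_network", "um", "cd31"),
    p("pv_network_length_max_um", "pv_network", "um", "cd31"),

    p("pvdist_mean_um", "distance_field", "um", "cd31"),
    p("pvdist_median_um", "distance_field", "um", "cd31"),
    p("pvdist_q25_um", "distance_field", "um", "cd31"),
    p("pvdist_q75_um", "distance_field", "um", "cd31"),
    p("pvdist_p90_um", "distance_field", "um", "cd31"),
    p("pvdist_max_um", "distance_field", "um", "cd31"),
    p("pv_supply_index", "distance_field", "", "cd31"),

    p("cd11b_volume_um3", "macrophage", "um3", "cd11b"),
    p("cd11b_volume_rel", "macrophage", "fraction", "cd11b"),
    p("cd11b_n_cells", "macrophage", "count", "cd11b"),
    p("cd11b_cell_density_mm3", "macrophage", "1/mm3", "cd11b"),
    p("cd11b_median_dist_pv_um", "macrophage", "um", "cd11b,cd31"),
    p("cd11b_median_dist_surface_um", "macrophage", "um", "cd11b"),
    p("cd11b_n_aggregates", "macrophage", "count", "cd11b"),
    p("cd11b_aggregate_volume_median_um3", "macrophage", "um3", "cd11b"),
    p("cd11b_aggregate_volume_max_um3", "macrophage", "um3", "cd11b"),
    p("cd11b_aggregate_volume_mean_um3", "macrophage", "um3", "cd11b"),

    p("coliv_volume_um3", "ecm", "um3", "colIV"),
    p("coliv_volume_rel", "ecm", "fraction", "colIV"),
    p("coliv_assoc_fraction", "ecm", "fraction", "colIV,cd31"),
    p("coliv_assoc_over_cd31", "ecm", "ratio", "colIV,cd31"),
    p("coliv_frac_nonassociated", "ecm", "fraction", "colIV,cd31"),
    p("coliv_frac_outside_vts", "ecm", "fraction", "colIV"),
    p("coliv_n_objects", "ecm", "count", "colIV"),

    p("hif1a_volume_um3", "hypoxia", "um3", "hif1a"),
    p("hif1a_volume_rel", "hypoxia", "fraction", "hif1a"),
    p("hif1a_n_cells", "hypoxia", "count", "hif1a"),
    p("hif1a_cell_density_mm3", "hypoxia", "1/mm3", "hif1a"),
    p("hif1a_median_dist_pv_um", "hypoxia", "um", "hif1a,cd31"),
    p("hif1a_median_dist_surface_um", "hypoxia", "um", "hif1a"),
    p("hif1a_n_objects", "hypoxia", "count", "hif1a"),
    p("hif1a_object_volume_median_um3", "hypoxia", "um3", "hif1a")
  )
  reg
}

registry_for_channels <- function(channels) {
  reg <- parameter_registry()
  ok <- vapply(reg$requires, function(req) {
    if (!nzchar(req)) return(TRUE)
    all(strsplit(req, ",")[[1]] %in% channels)
  }, logical(1))
  reg[ok, , drop = FALSE]
}

stat_or_na <- function(x, f) if (length(x)) f(x) else NA_real_

#' Compute the full descriptor row for one VTS stack
#'
#' Runs the whole pipeline (median filter, combined channel, VTS surface,
#' per-channel segmentation, cell detection, vessel tracing, distance
#' field, Col IV association) and assembles the registry parameters whose
#' required channels are present. Deterministic given stack and config.
#'
#' @param stack a [vts_stack()].
#' @param config a [pipeline_config()].
#' @param sample_id,group,experiment annotations carried into the row.
#' @param strict if TRUE, any registry channel missing from the stack is
#'   an error instead of a dropped family.
#' @return one-row data.frame (class `descriptor_row`); attribute
#'   `registry_version` records the registry.
#' @export
compute_descriptors <- function(stack, config = pipeline_config(),
                                sample_id = "vts1", group = "control",
                                experiment = "exp1", strict = FALSE) {
  stopifnot(inherits(stack, "vts_stack"))
  present <- setdiff(names(stack$channels), "vts_combined")
  if (strict) {
    needed <- unique(unlist(strsplit(parameter_registry()$requires, ",")))
    missing <- setdiff(needed[nzchar(needed)], present)
    if (length(missing))
      stop(sprintf("strict mode: missing channels %s",
                   paste(missing, collapse = ", ")))
  }
  reg <- registry_for_channels(present)
  sp <- stack$spacing
  vv <- voxel_volume(stack)

  stack <- median_filter_3d(stack, config$median_radius)
  stack <- combined_channel(stack)
  vts <- vts_surface_mask(stack, config)
  vals <- list(vts_volume_um3 = vts$volume_um3)
  vts_vol <- vts$volume_um3

  segs <- list(); cellsets <- list()
  for (role in intersect(c("tumor", "fibroblast", "cd31", "cd11b", "colIV",
                           "hif1a"), present)) {
    segs[[role]] <- segment_channel(stack, role, config, vts$mask)
    vals[[paste0(sub("colIV", "coliv", role), "_volume_um3")]] <-
      sum(segs[[role]]$objects$volume_um3)
    vals[[paste0(sub("colIV", "coliv", role), "_volume_rel")]] <-
      sum(segs[[role]]$objects$volume_um3) / vts_vol
  }
  for (role in intersect(c("tumor", "fibroblast", "cd11b", "hif1a"), present))
    cellsets[[role]] <- detect_cells(stack, role, config, vts$mask)

  if (all(c("tumor", "fibroblast", "cd31") %in% present)) {
    tot <- vals$tumor_volume_rel + vals$fibroblast_volume_rel + vals$cd31_volume_rel
    if (tot > 0) {
      vals$comp_frac_tumor <- vals$tumor_volume_rel / tot
      vals$comp_frac_fibroblast <- vals$fibroblast_volume_rel / tot
      vals$comp_frac_cd31 <- vals$cd31_volume_rel / tot
    } else {
      vals$comp_frac_tumor <- vals$comp_frac_fibroblast <- vals$comp_frac_cd31 <- NA_real_
    }
  }

  # vessel tracing + distance field
  if ("cd31" %in% present) {
    cd31_mask <- segs$cd31$mask
    tr <- trace_vessels(cd31_mask, sp, config$prune_length)
    agg <- tr$stats$aggregates
    segtab <- tr$graph$segments
    nettab <- tr$stats$networks
    vals$pv_n_networks <- agg$n_networks
    vals$pv_n_segments <- agg$n_segments
    vals$pv_segments_per_network <- agg$segments_per_network
    vals$pv_total_length_um <- agg$total_length_um
    vals$pv_mean_segment_length_um <- stat_or_na(segtab$length_um, mean)
    dd <- segtab$mean_diameter_um
    vals$pv_diameter_mean_um <- stat_or_na(dd, mean)
    vals$pv_diameter_median_um <- stat_or_na(dd, median)
    vals$pv_diameter_sd_um <- if (length(dd) > 1) sd(dd) else NA_real_
    vals$pv_diameter_p10_um <- stat_or_na(dd, function(x) quantile(x, 0.1, names = FALSE))
    vals$pv_diameter_p90_um <- stat_or_na(dd, function(x) quantile(x, 0.9, names = FALSE))
    bl <- segtab$branch_level
    vals$pv_branch_level_mean <- stat_or_na(bl, mean)
    vals$pv_branch_level_max <- stat_or_na(bl, function(x) max(x))
    vals$pv_branch_frac_main <- stat_or_na(bl, function(x) mean(x == 0))
    vals$pv_network_volume_mean_um3 <- stat_or_na(nettab$volume_um3, mean)
    vals$pv_network_volume_median_um3 <- stat_or_na(nettab$volume_um3, median)
    vals$pv_network_volume_max_um3 <- stat_or_na(nettab$volume_um3, function(x) max(x))
    vals$pv_network_length_mean_um <- stat_or_na(nettab$length_um, mean)
    vals$pv_network_length_max_um <- stat_or_na(nettab$length_um, function(x) max(x))

    df <- suppressWarnings(pv_distance_field(cd31_mask, vts$mask, sp))
    dh <- distance_histogram(df, config$distance_bin_width)
    v <- df$field[!is.na(df$field) & is.finite(df$field)]
    vals$pvdist_mean_um <- dh$mean_um
    vals$pvdist_median_um <- dh$median_um
    vals$pvdist_q25_um <- stat_or_na(v, function(x) quantile(x, 0.25, names = FALSE))
    vals$pvdist_q75_um <- stat_or_na(v, function(x) quantile(x, 0.75, names = FALSE))
    vals$pvdist_p90_um <- stat_or_na(v, function(x) quantile(x, 0.9, names = FALSE))
    vals$pvdist_max_um <- stat_or_na(v, function(x) max(x))
    rel_pct <- 100 * vals$cd31_volume_rel
    vals$pv_supply_index <-
      if (is.finite(dh$median_um) && dh$median_um > 0 && rel_pct > 0 && rel_pct <= 100)
        supply_index(rel_pct, dh$median_um) else NA_real_
  }

  dens <- function(n) n / (vts_vol / 1e9)  # per mm^3
  for (role in intersect(c("tumor", "fibroblast", "cd11b", "hif1a"), present)) {
    cs <- cellsets[[role]]
    n <- nrow(cs$cells)
    vals[[paste0(role, "_n_cells")]] <- n
    vals[[paste0(role, "_cell_density_mm3")]] <- dens(n)
    if ("cd31" %in% present)
      vals[[paste0(role, "_median_dist_pv_um")]] <-
        cell_distances(cs, segs$cd31$mask, sp, "mask")$median_um
    vals[[paste0(role, "_median_dist_surface_um")]] <-
      cell_distances(cs, vts$mask, sp, "surface")$median_um
  }
  if (all(c("tumor", "fibroblast") %in% present)) {
    vals$tumor_median_dist_complement_um <-
      cell_distances(cellsets$tumor, segs$fibroblast$mask, sp, "mask")$median_um
    vals$fibroblast_median_dist_complement_um <-
      cell_distances(cellsets$fibroblast, segs$tumor$mask, sp, "mask")$median_um
    nf <- nrow(cellsets$fibroblast$cells)
    vals$tumor_fibroblast_cell_ratio <-
      if (nf > 0) nrow(cellsets$tumor$cells) / nf else NA_real_
  }

  if ("cd11b" %in% present) {
    ov <- object_volume_distribution(segs$cd11b)
    vals$cd11b_n_aggregates <- ov$summary$n
    vals$cd11b_aggregate_volume_median_um3 <- ov$summary$median_um3
    vals$cd11b_aggregate_volume_max_um3 <- ov$summary$max_um3
    vals$cd11b_aggregate_volume_mean_um3 <-
      stat_or_na(ov$table$volume_um3, mean)
  }
  if ("colIV" %in% present) {
    # association is judged against the un-VTS-restricted Col IV signal so
    # matrix attached outside the spheroid is counted
    seg_out <- segment_channel(stack, "colIV", config, vts_mask = NULL)
    vals$coliv_n_objects <- nrow(seg_out$objects)
    if ("cd31" %in% present) {
      ca <- suppressWarnings(
        coliv_association(seg_out$mask, segs$cd31$mask, vts$mask, sp,
                          config$coliv_association_distance))
      vals$coliv_assoc_fraction <- ca$associated_fraction
      vals$coliv_assoc_over_cd31 <- ca$associated_over_cd31
      vals$coliv_frac_nonassociated <- ca$frac_in_vts_nonassociated
      vals$coliv_frac_outside_vts <- ca$frac_outside_vts
    } else {
      vals$coliv_frac_outside_vts <- NA_real_
    }
  }
  if ("hif1a" %in% present) {
    vals$hif1a_n_objects <- nrow(segs$hif1a$objects)
    vals$hif1a_object_volume_median_um3 <-
      stat_or_na(segs$hif1a$objects$volume_um3, median)
  }

  # assemble in registry order
  row <- as.data.frame(c(list(sample_id = sample_id, group = group,
                              experiment = experiment),
                         setNames(lapply(reg$name, function(nm) {
                           v <- vals[[nm]]
                           if (is.null(v)) NA_real_ else as.numeric(v)
                         }), reg$name)))
  attr(row, "registry_version") <- REGISTRY_VERSION
  class(row) <- c("descriptor_row", class(row))
  row
}

#' Pool descriptor rows into one table
#'
#' @param rows list of `descriptor_row` objects (or a single one).
#' @param strict if TRUE, rows must share the identical parameter set.
#' @return data.frame with one row per VTS; attribute `registry_version`.
#' @export
pool_descriptors <- function(rows, strict = TRUE) {
  if (inherits(rows, "descriptor_row")) rows <- list(rows)
  vers <- unique(vapply(rows, function(r) attr(r, "registry_version") %||% "?",
                        character(1)))
  if (length(vers) != 1)
    stop(sprintf("registry version mismatch: %s", paste(vers, collapse = " vs ")))
  colsets <- unique(vapply(rows, function(r) paste(names(r), collapse = "|"),
                           character(1)))
  if (strict && length(colsets) != 1)
    stop("rows carry different parameter sets; pool with strict = FALSE or recompute")
  out <- do.call(rbind, lapply(rows, function(r) { class(r) <- "data.frame"; r }))
  attr(out, "registry_version") <- vers
  out
}
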