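# Adipose-compartment segmentation of fat-fraction stacks.
#
# Pipeline per slice: (1) threshold the combined fat/water image to remove
# background and keep the body (largest connected component, small holes
# filled); (2) threshold the fat-fraction image inside that mask; (3) trace
# rays from outside the body toward its centroid to find, per ray, the outer
# edge of subcutaneous fat and the first fat-to-nonfat transition inside it
# (the inner boundary); (4) split fat into subcutaneous (on/outside the inner
# boundary) and visceral (strictly inside). Volumes are voxel counts times
# voxel volume; nonadipose tissue is the residual of total tissue after SAT
# and VAT.

#' Otsu threshold of an image
#'
#' Maximizes between-class variance over a 256-bin histogram; the standard
#' choice for bimodal body/background and fat/water histograms.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins histogram bins.
#' @return threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.vector(x[is.finite(x)])
  if (length(unique(x)) < 2L) return(max(x))
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 4-connected component labelling by iterative max-label propagation.
# Returns an integer matrix: 0 background, components numbered by size rank.
label_components <- function(mask) {
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  repeat {
    up <- rbind(lab[-1, , drop = FALSE], 0)
    down <- rbind(0, lab[-nr, , drop = FALSE])
    left <- cbind(lab[, -1, drop = FALSE], 0)
    right <- cbind(0, lab[, -nc, drop = FALSE])
    new <- pmax(lab, up, down, left, right)
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nr, nc))
  sizes <- tabulate(match(lab[lab > 0], ids))
  rank <- match(ids, ids[order(sizes, decreasing = TRUE)])
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- rank[match(lab[lab > 0], ids)]
  out
}

# Fill enclosed background holes smaller than max_area pixels.
fill_holes <- function(mask, max_area = Inf) {
  bg <- label_components(!mask)
  if (!any(bg > 0)) return(mask)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  for (id in setdiff(unique(bg[bg > 0]), border_ids)) {
    if (sum(bg == id) < max_area) mask[bg == id] <- TRUE
  }
  mask
}

#' Tissue mask from the combined fat/water image
#'
#' Thresholds the combined-signal image to remove background, keeps the
#' largest connected foreground component (rejecting disconnected lateral
#' components such as arms) and fills enclosed holes below `max_hole_area`.
#' An all-background result is returned flagged (attribute `flags`), not as
#' an error.
#'
#' @param combined_signal slice matrix.
#' @param threshold numeric threshold, or `"otsu"`.
#' @param max_hole_area holes (enclosed background) smaller than this many
#'   pixels are filled.
#' @param keep_largest keep only the largest connected component.
#' @return logical matrix with attribute `flags` (character vector, possibly
#'   empty).
#' @export
tissue_mask <- function(combined_signal, threshold = "otsu",
                        max_hole_area = 1000, keep_largest = TRUE) {
  if (any(!is.finite(combined_signal))) stop_validation("image must be finite-valued")
  flags <- character()
  thr <- if (identical(threshold, "otsu")) otsu_threshold(combined_signal) else threshold
  mask <- combined_signal > thr
  if (!any(mask)) {
    flags <- "empty_tissue_mask"
  } else {
    if (keep_largest) mask <- label_components(mask) == 1L
    mask <- fill_holes(mask, max_hole_area)
  }
  structure(mask, flags = flags)
}

#' Fat mask from the fat-fraction image
#'
#' @param fat_fraction slice matrix in \[0, 1\] (clamped).
#' @param tissue logical tissue mask from [tissue_mask()].
#' @param ff_threshold fat-fraction threshold in \[0, 1\].
#' @return logical matrix: `fat_fraction >= ff_threshold` within tissue.
#' @export
fat_mask <- function(fat_fraction, tissue, ff_threshold = 0.5) {
  if (ff_threshold < 0 || ff_threshold > 1) {
    stop_validation("ff_threshold must lie in [0, 1]")
  }
  if (!any(tissue)) stop_validation("tissue mask is empty")
  pmin(pmax(fat_fraction, 0), 1) >= ff_threshold & tissue
}

#' Trace the subcutaneous fat boundaries radially
#'
#' Casts `n_rays` equiangular rays from outside the body toward the tissue
#' centroid. Per ray, the first sustained run of fat pixels marks the outer
#' subcutaneous boundary; the first sustained fat-to-nonfat transition after
#' it marks the inner boundary (the visceral compartment lies inside it).
#' Rays that hit no fat are interpolated from angular neighbours. If fewer
#' than `min_hit_frac` of rays intersect fat the result is flagged
#' `"no_subcutaneous_ring"`.
#'
#' @param fat logical fat mask.
#' @param tissue logical tissue mask (defines the centroid).
#' @param n_rays number of equiangular rays.
#' @param step radial sampling step, pixels.
#' @param min_run consecutive samples required to accept a fat run or a
#'   fat-to-nonfat transition (noise guard).
#' @param min_hit_frac minimum fraction of rays that must intersect fat.
#' @return list of class `sat_boundaries`: `angles`, `r_outer`, `r_inner`
#'   (pixels from the centroid, interpolated where missing), `centroid`
#'   (row, col), `outer_xy`/`inner_xy` contour vertices (row, col), `flags`.
#' @export
trace_subcutaneous_boundaries <- function(fat, tissue = fat, n_rays = 360L,
                                          step = 0.5, min_run = 2L,
                                          min_hit_frac = 0.5) {
  if (!any(fat)) stop_validation("fat mask is empty")
  nr <- nrow(fat); nc <- ncol(fat)
  idx <- which(tissue | fat, arr.ind = TRUE)
  cen <- colMeans(idx)                       # (row, col)
  angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  r_max <- sqrt(max((c(1, nr) - cen[1])^2)) + sqrt(max((c(1, nc) - cen[2])^2))
  radii <- seq(r_max, 0, by = -step)         # outside -> centre
  # sample fat at nearest pixel along every ray at once
  rows <- round(cen[1] + outer(sin(angles), radii))
  cols <- round(cen[2] + outer(cos(angles), radii))
  inside <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  fat_hit <- matrix(FALSE, n_rays, length(radii))
  fat_hit[inside] <- fat[cbind(rows[inside], cols[inside])]

  r_outer <- r_inner <- rep(NA_real_, n_rays)
  for (i in seq_len(n_rays)) {
    rl <- rle(fat_hit[i, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fat_runs <- which(rl$values & rl$lengths >= min_run)
    if (!length(fat_runs)) next
    first <- fat_runs[1]
    r_outer[i] <- radii[starts[first]]
    # first sustained non-fat run after the subcutaneous run
    gap <- which(!rl$values & rl$lengths >= min_run & seq_along(rl$values) > first)
    r_inner[i] <- if (length(gap)) radii[ends[gap[1] - 1L]] else 0
  }

  flags <- character()
  hit_frac <- mean(!is.na(r_outer))
  if (hit_frac < min_hit_frac) flags <- c(flags, "no_subcutaneous_ring")
  miss <- is.na(r_outer)
  if (any(miss) && any(!miss)) {
    r_outer <- interp_circular(angles, r_outer)
    r_inner <- interp_circular(angles, r_inner)
  } else if (all(miss)) {
    stop_estimation("no ray intersected fat with a run of length >= ", min_run)
  }
  r_inner <- pmin(r_inner, r_outer)
  if (stats::median(r_inner) < 2) flags <- c(flags, "no_visceral_cavity")
  structure(class = "sat_boundaries", list(
    angles = angles, r_outer = r_outer, r_inner = r_inner, centroid = cen,
    outer_xy = cbind(row = cen[1] + r_outer * sin(angles),
                     col = cen[2] + r_outer * cos(angles)),
    inner_xy = cbind(row = cen[1] + r_inner * sin(angles),
                     col = cen[2] + r_inner * cos(angles)),
    n_missing = sum(miss), flags = flags))
}

# linear interpolation of per-angle radii across NA gaps, wrapping at 2*pi
interp_circular <- function(angles, r) {
  ok <- !is.na(r)
  if (all(ok)) return(r)
  xa <- c(angles[ok] - 2 * pi, angles[ok], angles[ok] + 2 * pi)
  ya <- rep(r[ok], 3L)
  r[!ok] <- stats::approx(xa, ya, xout = angles[!ok])$y
  r
}

#' Split fat into subcutaneous and visceral compartments
#'
#' Visceral fat is every fat pixel strictly inside the inner boundary;
#' subcutaneous fat is every fat pixel on or outside it (closed-outer /
#' open-inner convention, so a pixel exactly on the inner boundary is SAT).
#'
#' @param fat logical fat mask.
#' @param tissue logical tissue mask.
#' @param boundaries a `sat_boundaries` from [trace_subcutaneous_boundaries()].
#' @return list of class `slice_masks`: `tissue_mask`, `fat_mask`, `sat_mask`,
#'   `vat_mask`, `boundaries`, `flags`.
#' @export
split_compartments <- function(fat, tissue, boundaries) {
  if (!inherits(boundaries, "sat_boundaries")) {
    stop_validation("boundaries must come from trace_subcutaneous_boundaries()")
  }
  if (any(!is.finite(boundaries$r_inner)) || any(boundaries$r_inner < 0)) {
    stop_validation("invalid inner contour (non-finite or negative radii)")
  }
  nr <- nrow(fat); nc <- ncol(fat)
  cen <- boundaries$centroid
  rows <- matrix(seq_len(nr), nr, nc) - cen[1]
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cen[2]
  r <- sqrt(rows^2 + cols^2)
  th <- atan2(rows, cols) %% (2 * pi)
  ang <- boundaries$angles
  xa <- c(ang - 2 * pi, ang, ang + 2 * pi)
  r_in_at <- matrix(stats::approx(xa, rep(boundaries$r_inner, 3L), xout = as.vector(th))$y,
                    nr, nc)
  vat <- fat & (r < r_in_at)          # strictly inside: open inner boundary
  sat <- fat & !vat                   # on-boundary pixels go to SAT
  structure(class = "slice_masks", list(
    tissue_mask = tissue, fat_mask = fat, sat_mask = sat, vat_mask = vat,
    boundaries = boundaries, flags = boundaries$flags))
}

#' Sum per-slice masks into compartment volumes
#'
#' Volume = pixel count x voxel volume, summed over slices and reported in
#' liters; nonadipose tissue (NAT) is total tissue minus SAT minus VAT, so the
#' additivity identity holds exactly by construction.
#'
#' @param slice_masks list of `slice_masks` (one per slice).
#' @param voxel_dims voxel size in mm (length 3).
#' @return list of class `segmentation_result`: `per_slice`, `sat_volume_l`,
#'   `vat_volume_l`, `total_tissue_volume_l`, `nat_volume_l`, `flags`,
#'   `voxel_dims`.
#' @export
volumes <- function(slice_masks, voxel_dims) {
  if (!length(slice_masks)) stop_validation("need at least one slice")
  check_positive(voxel_dims, "voxel_dims")
  shapes <- vapply(slice_masks, function(m) paste(dim(m$tissue_mask), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop_validation("inconsistent slice shapes: ",
                                                    paste(unique(shapes), collapse = ", "))
  voxvol_l <- prod(voxel_dims) / 1e6
  count <- function(field) sum(vapply(slice_masks, function(m) sum(m[[field]]), 0))
  sat <- count("sat_mask") * voxvol_l
  vat <- count("vat_mask") * voxvol_l
  tot <- count("tissue_mask") * voxvol_l
  structure(class = "segmentation_result", list(
    per_slice = slice_masks,
    sat_volume_l = sat, vat_volume_l = vat,
    total_tissue_volume_l = tot, nat_volume_l = tot - sat - vat,
    flags = unique(unlist(lapply(slice_masks, `[[`, "flags"))),
    voxel_dims = voxel_dims))
}

#' Segment a fat-fraction stack end to end
#'
#' @param stack a `fat_fraction_stack` (e.g. from [generate_phantom()]`$stack`
#'   or [read_stack()]).
#' @param ff_threshold fat-fraction threshold.
#' @param signal_threshold combined-signal threshold or `"otsu"`.
#' @param n_rays rays for boundary tracing.
#' @param ... further arguments to [trace_subcutaneous_boundaries()].
#' @return a `segmentation_result`.
#' @export
segment_stack <- function(stack, ff_threshold = 0.5, signal_threshold = "otsu",
                          n_rays = 360L, ...) {
  stopifnot(inherits(stack, "fat_fraction_stack"))
  nsl <- dim(stack$fat_fraction)[3]
  masks <- vector("list", nsl)
  for (k in seq_len(nsl)) {
    cs <- stack$combined_signal[, , k]
    ff <- stack$fat_fraction[, , k]
    tis <- tissue_mask(cs, threshold = signal_threshold)
    if (length(attr(tis, "flags"))) {
      empty <- matrix(FALSE, nrow(cs), ncol(cs))
      masks[[k]] <- structure(class = "slice_masks", list(
        tissue_mask = empty, fat_mask = empty, sat_mask = empty,
        vat_mask = empty, boundaries = NULL, flags = attr(tis, "flags")))
      next
    }
    fat <- fat_mask(ff, tis, ff_threshold)
    if (!any(fat)) {
      empty <- matrix(FALSE, nrow(cs), ncol(cs))
      masks[[k]] <- structure(class = "slice_masks", list(
        tissue_mask = unclass(tis), fat_mask = empty, sat_mask = empty,
        vat_mask = empty, boundaries = NULL, flags = "empty_fat_mask"))
      next
    }
    bnd <- trace_subcutaneous_boundaries(fat, tis, n_rays = n_rays, ...)
    masks[[k]] <- split_compartments(fat, unclass(tis), bnd)
  }
  volumes(masks, stack$voxel_dims)
}

#' Write a segmentation as a NIfTI label map plus per-slice area CSV
#'
#' Labels: 0 background, 1 NAT, 2 SAT, 3 VAT.
#'
#' @param seg a `segmentation_result`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_segmentation <- function(seg, dir) {
  stopifnot(inherits(seg, "segmentation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nsl <- length(seg$per_slice)
  d <- dim(seg$per_slice[[1]]$tissue_mask)
  lab <- array(0L, dim = c(d, nsl))
  px_mm2 <- prod(seg$voxel_dims[1:2])
  areas <- data.frame(slice = seq_len(nsl), tissue_mm2 = 0, fat_mm2 = 0,
                      sat_mm2 = 0, vat_mm2 = 0, flags = "")
  for (k in seq_len(nsl)) {
    m <- seg$per_slice[[k]]
    sl <- matrix(0L, d[1], d[2])
    sl[m$tissue_mask] <- 1L
    sl[m$sat_mask] <- 2L
    sl[m$vat_mask] <- 3L
    lab[, , k] <- sl
    areas[k, 2:5] <- c(sum(m$tissue_mask), sum(m$fat_mask),
                       sum(m$sat_mask), sum(m$vat_mask)) * px_mm2
    areas$flags[k] <- paste(m$flags, collapse = ";")
  }
  paths <- c(labels = file.path(dir, "labels.nii"),
             areas = file.path(dir, "slice_areas.csv"))
  write_nifti(lab, paths["labels"], seg$voxel_dims, "uint8")
  utils::write.csv(areas, paths["areas"], row.names = FALSE)
  invisible(paths)
}
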