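# Synthetic fat-fraction phantoms with mask-derived ground truth.
#
# Bodies are ellipses (optionally asymmetric SAT thickness, optionally lobed
# non-convex inner boundary) with a high-fat subcutaneous ring, a low-fat
# interior, and circular high-fat visceral blobs. Ground-truth compartment
# volumes are counted from the drawn masks, not from area formulas, so a
# downstream segmentation error reflects the algorithm and not rasterization.

#' Specify a body phantom
#'
#' @param slice_count number of axial slices.
#' @param image_size pixels per side (square slices).
#' @param voxel_dims in-plane and through-plane voxel size, mm (length 3).
#' @param outer_semiaxes body-ellipse semiaxes in mm, `c(a, b)`; a circle if
#'   one value is given.
#' @param sat_thickness subcutaneous ring thickness, mm.
#' @param sat_asymmetry fractional modulation of ring thickness with angle
#'   (`thickness * (1 + sat_asymmetry * cos(theta))`); 0 = uniform ring.
#' @param inner_lobes `list(n = lobes, amp_mm = depth)`: sinusoidal lobing of
#'   the inner boundary making it non-convex; `n = 0` disables.
#' @param vat_blobs list of visceral fat blobs, each
#'   `list(center = c(x_mm, y_mm), radius = mm, fat_fraction = ff)`; centers
#'   relative to the body center. Blobs must lie strictly inside the inner
#'   boundary.
#' @param sat_ff,interior_ff fat fraction drawn in the ring / the interior.
#' @param body_signal combined-signal intensity inside the body (background 0).
#' @param background_noise_sd Gaussian noise sd added to the fat-fraction
#'   channel (clamped back to \[0, 1\]); the combined-signal channel receives
#'   noise with sd `background_noise_sd * body_signal`.
#' @param slice_scale optional per-slice scale factors for the semiaxes
#'   (defaults to all 1: a cylinder-of-ellipses slab).
#' @param rotation_deg in-plane rotation of the whole body, degrees.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(slice_count = 4L, image_size = 128L,
                         voxel_dims = c(3, 3, 10), outer_semiaxes = c(160, 120),
                         sat_thickness = 25, sat_asymmetry = 0,
                         inner_lobes = list(n = 0L, amp_mm = 0),
                         vat_blobs = list(), sat_ff = 0.85, interior_ff = 0.1,
                         body_signal = 100, background_noise_sd = 0,
                         slice_scale = NULL, rotation_deg = 0, seed = 1L) {
  check_positive(slice_count, "slice_count")
  check_positive(image_size, "image_size")
  check_positive(voxel_dims, "voxel_dims")
  if (length(voxel_dims) != 3L) stop_validation("voxel_dims must have length 3")
  if (length(outer_semiaxes) == 1L) outer_semiaxes <- rep(outer_semiaxes, 2L)
  check_positive(outer_semiaxes, "outer_semiaxes")
  check_positive(sat_thickness, "sat_thickness")
  ffs <- c(sat_ff, interior_ff, vapply(vat_blobs, `[[`, 0, "fat_fraction"))
  if (any(ffs < 0 | ffs > 1)) stop_validation("fat fractions must lie in [0, 1]")
  slice_scale <- slice_scale %||% rep(1, slice_count)
  if (length(slice_scale) != slice_count) {
    stop_validation("slice_scale must have one value per slice")
  }
  spec <- structure(class = "phantom_spec", list(
    slice_count = as.integer(slice_count), image_size = as.integer(image_size),
    voxel_dims = as.double(voxel_dims), outer_semiaxes = as.double(outer_semiaxes),
    sat_thickness = sat_thickness, sat_asymmetry = sat_asymmetry,
    inner_lobes = inner_lobes, vat_blobs = vat_blobs, sat_ff = sat_ff,
    interior_ff = interior_ff, body_signal = body_signal,
    background_noise_sd = background_noise_sd, slice_scale = slice_scale,
    rotation_deg = rotation_deg, seed = as.integer(seed)))
  validate_blobs(spec)
  spec
}

# radius of the outer ellipse boundary along angle theta
ellipse_radius <- function(theta, a, b) {
  1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
}

inner_radius_of <- function(spec, theta, scale = 1) {
  r_out <- ellipse_radius(theta, spec$outer_semiaxes[1] * scale,
                          spec$outer_semiaxes[2] * scale)
  thick <- spec$sat_thickness * (1 + spec$sat_asymmetry * cos(theta))
  lobes <- spec$inner_lobes
  lobe <- if (lobes$n > 0) lobes$amp_mm * (0.5 + 0.5 * cos(lobes$n * theta)) else 0
  pmax(r_out - thick - lobe, 0)
}

validate_blobs <- function(spec) {
  smin <- min(spec$slice_scale)
  for (blob in spec$vat_blobs) {
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    bx <- blob$center[1] + blob$radius * cos(th)
    by <- blob$center[2] + blob$radius * sin(th)
    r_pt <- sqrt(bx^2 + by^2)
    if (any(r_pt >= inner_radius_of(spec, atan2(by, bx), smin))) {
      stop_validation("vat blob at (", blob$center[1], ", ", blob$center[2],
                      ") does not lie strictly inside the inner boundary")
    }
  }
  invisible(spec)
}

#' Generate a fat-fraction phantom with mask ground truth
#'
#' Draws the phantom described by `spec` and returns both the two-channel
#' image stack and its ground truth: per-slice label maps
#' (0 background, 1 nonadipose interior, 2 subcutaneous ring, 3 visceral blob)
#' and compartment volumes counted from those label maps.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom` with elements `stack`
#'   (class `fat_fraction_stack`: `fat_fraction`, `combined_signal`,
#'   `voxel_dims`, `slab_convention`), `truth` (`labels` array plus
#'   `sat_volume_l`, `vat_volume_l`, `tissue_volume_l`, `nat_volume_l`) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  vx <- spec$voxel_dims[1]; vy <- spec$voxel_dims[2]
  c0 <- (n + 1) / 2
  x0 <- outer(rep(1, n), (seq_len(n) - c0) * vx)  # column -> x, mm
  y0 <- outer((seq_len(n) - c0) * vy, rep(1, n))  # row -> y, mm
  phi <- spec$rotation_deg * pi / 180             # work in the body frame
  x <- cos(phi) * x0 + sin(phi) * y0
  y <- -sin(phi) * x0 + cos(phi) * y0
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)

  ff <- array(0, dim = c(n, n, spec$slice_count))
  cs <- array(0, dim = c(n, n, spec$slice_count))
  labels <- array(0L, dim = c(n, n, spec$slice_count))

  for (k in seq_len(spec$slice_count)) {
    s <- spec$slice_scale[k]
    r_out <- ellipse_radius(theta, spec$outer_semiaxes[1] * s, spec$outer_semiaxes[2] * s)
    r_in <- inner_radius_of(spec, theta, s)
    body <- r <= r_out
    interior <- r <= r_in
    sat <- body & !interior
    vat <- matrix(FALSE, n, n)
    ff_k <- matrix(0, n, n)
    ff_k[interior] <- spec$interior_ff
    ff_k[sat] <- spec$sat_ff
    for (blob in spec$vat_blobs) {
      inblob <- interior & ((x - blob$center[1])^2 + (y - blob$center[2])^2 <= blob$radius^2)
      vat <- vat | inblob
      ff_k[inblob] <- blob$fat_fraction
    }
    lab <- matrix(0L, n, n)
    lab[interior] <- 1L
    lab[sat] <- 2L
    lab[vat] <- 3L
    labels[, , k] <- lab
    ff[, , k] <- ff_k
    cs[, , k] <- ifelse(body, spec$body_signal, 0)
  }

  if (spec$background_noise_sd > 0) {
    set.seed(spec$seed)
    ff <- ff + array(stats::rnorm(length(ff), 0, spec$background_noise_sd), dim = dim(ff))
    cs <- cs + array(stats::rnorm(length(cs), 0, spec$background_noise_sd * spec$body_signal),
                     dim = dim(cs))
    ff <- pmin(pmax(ff, 0), 1)
  }

  voxvol_l <- prod(spec$voxel_dims) / 1e6
  stack <- structure(class = "fat_fraction_stack", list(
    fat_fraction = ff, combined_signal = cs, voxel_dims = spec$voxel_dims,
    slab_convention = "neck-to-knees, arms excluded"))
  truth <- list(
    labels = labels,
    sat_volume_l = sum(labels == 2L) * voxvol_l,
    vat_volume_l = sum(labels == 3L) * voxvol_l,
    tissue_volume_l = sum(labels != 0L) * voxvol_l,
    nat_volume_l = sum(labels == 1L) * voxvol_l)
  structure(class = "phantom", list(stack = stack, truth = truth, spec = spec))
}

#' Write a phantom to disk (NIfTI per channel + JSON ground-truth sidecar)
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- phantom$stack
  paths <- c(
    fat_fraction = file.path(dir, "fat_fraction.nii"),
    combined_signal = file.path(dir, "combined_signal.nii"),
    truth_labels = file.path(dir, "truth_labels.nii"),
    truth = file.path(dir, "ground_truth.json"))
  write_nifti(st$fat_fraction, paths["fat_fraction"], st$voxel_dims, "float32")
  write_nifti(st$combined_signal, paths["combined_signal"], st$voxel_dims, "float32")
  write_nifti(phantom$truth$labels, paths["truth_labels"], st$voxel_dims, "uint8")
  truth <- phantom$truth[c("sat_volume_l", "vat_volume_l", "tissue_volume_l", "nat_volume_l")]
  truth$seed <- phantom$spec$seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a two-channel image stack written by [write_phantom()]
#'
#' @param dir directory holding `fat_fraction.nii` and `combined_signal.nii`.
#' @return a `fat_fraction_stack`.
#' @export
read_stack <- function(dir) {
  if (!file.exists(file.path(dir, "fat_fraction.nii"))) {
    stop_validation("no fat_fraction.nii in ", dir)
  }
  ffp <- read_nifti(file.path(dir, "fat_fraction.nii"))
  csp <- read_nifti(file.path(dir, "combined_signal.nii"))
  structure(class = "fat_fraction_stack", list(
    fat_fraction = pmin(pmax(ffp$img, 0), 1), combined_signal = csp$img,
    voxel_dims = ffp$voxel_dims, slab_convention = "neck-to-knees, arms excluded"))
}
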