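# Synthetic voxel-label brain phantom and label-volume IO.
#
# The phantom stands in for a resampled rat brain atlas: an ellipsoidal brain
# with a flattened dorsal cap, a CSF layer, a one-voxel dura surface shell, a
# rigid skull shell with a rectangular craniotomy window over the left parietal
# surface, paired ventricles, and an arched midline-spanning white-matter band
# (the corpus-callosum surrogate).  All geometry is analytic, so generation is
# deterministic and voxel counts can be checked against brute-force
# point-in-solid tests.

#' Tissue label codes
#'
#' Named integer codes used by every [label_volume()] produced by this package.
#'
#' @return Named integer vector with entries `background`, `grey`, `white`,
#'   `csf`, `ventricle`, `skull`, `dura_surface`.
#' @export
phantom_labels <- function() {
  c(background = 0L, grey = 1L, white = 2L, csf = 3L,
    ventricle = 4L, skull = 5L, dura_surface = 6L)
}

#' Construct a label volume
#'
#' A label volume is a 3-D integer grid of tissue labels with a voxel size and
#' a world origin (coordinates of the centre of voxel `(0,0,0)`; world
#' coordinate = origin + index * voxel_size, 0-based indices).
#'
#' @param data 3-D integer array of label codes.
#' @param voxel_size Numeric length-3, mm per axis (all > 0).
#' @param origin Numeric length-3, mm.
#' @param label_map Named integer vector mapping label names to codes.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size, origin = c(0, 0, 0),
                         label_map = phantom_labels()) {
  stopifnot(length(dim(data)) == 3L, length(voxel_size) == 3L,
            length(origin) == 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0 on all axes")
  storage.mode(data) <- "integer"
  unknown <- setdiff(unique(as.vector(data)), unname(label_map))
  if (length(unknown) > 0L) {
    stop("unregistered label value(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$data), collapse = " x "), "voxels at",
      paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  counts <- table(factor(as.vector(x$data), levels = unname(x$label_map),
                         labels = names(x$label_map)))
  print(counts)
  invisible(x)
}

#' Voxel-centre world coordinates along each axis
#' @param vol A `label_volume`.
#' @return List of three numeric vectors (x, y, z axis coordinates, mm).
#' @keywords internal
voxel_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$voxel_size[k])
}

#' Phantom geometry specification
#'
#' Defaults give a rat-scale brain (half-axes 7 x 9 x 4.5 mm with a
#' superellipsoidal coronal profile: flat dorsally, falling away laterally,
#' so a flat impactor engages it progressively; the crown above z = 4.4 mm
#' is clipped) at 0.5 mm resolution, a 0.5 mm CSF layer, 1 mm
#' skull, a 7 x 6 mm craniotomy window over the right parietal surface
#' (x in [0.5, 6.5] mm lateral of the midline, matching an impact centred
#' ~3.5 mm lateral), and an arched callosal band 0.8 mm thick with its apex
#' 1.5 mm below the dorsal surface.
#'
#' @param voxel_size Isotropic voxel edge, mm.
#' @param brain_half_axes Ellipsoid half-axes (x, y, z), mm.
#' @param z_cap Dorsal flattening height, mm (brain truncated above this;
#'   the default barely clips the ellipsoid crown).
#' @param csf_thickness CSF layer thickness, mm (0 gives no CSF voxels).
#' @param skull_thickness Skull shell thickness, mm.
#' @param cc_arc List: `thickness` (mm), `depth` (apex depth below z_cap, mm),
#'   `curvature` (1/mm; arch z = z_cap - depth - curvature * x^2),
#'   `half_length` (anteroposterior half-extent, mm), `lateral` (|x| cut, mm).
#' @param ventricles List: `centers` (2 x 3 matrix, mm), `half_axes` (mm).
#' @param craniotomy_window List: `x` and `y` ranges (mm) of the skull opening.
#' @param margin Grid padding beyond the skull, mm.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size = 0.5,
                         brain_half_axes = c(7, 9, 4.5),
                         z_cap = 4.4,
                         csf_thickness = 0.5,
                         skull_thickness = 1,
                         cc_arc = list(thickness = 0.8, depth = 1.5,
                                       curvature = 0.06, half_length = 2,
                                       lateral = 5),
                         ventricles = list(
                           centers = rbind(c(-1.5, 1, 0.5), c(1.5, 1, 0.5)),
                           half_axes = c(0.7, 2, 0.7)),
                         craniotomy_window = list(x = c(0.5, 6.5),
                                                  y = c(-3.5, 3.5)),
                         margin = 1) {
  spec <- list(voxel_size = voxel_size, brain_half_axes = brain_half_axes,
               z_cap = z_cap, csf_thickness = csf_thickness,
               skull_thickness = skull_thickness, cc_arc = cc_arc,
               ventricles = ventricles, craniotomy_window = craniotomy_window,
               margin = margin)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$voxel_size > 0, all(spec$brain_half_axes > 0),
            spec$csf_thickness >= 0, spec$skull_thickness > 0,
            spec$cc_arc$thickness > 0, spec$cc_arc$depth > 0)
  # window must lie on the dorsal skull surface, inside the skull's x extent
  outer_x <- spec$brain_half_axes[1] + spec$csf_thickness +
    spec$voxel_size + spec$skull_thickness
  if (max(abs(spec$craniotomy_window$x)) > outer_x) {
    stop("craniotomy window exceeds skull extent on the x axis")
  }
  apex <- spec$z_cap - spec$cc_arc$depth
  if (apex < -spec$brain_half_axes[3]) {
    stop("cc arc apex below the brain on the z axis")
  }
  invisible(spec)
}

# Membership test for the brain-shaped solid inflated by `offset` mm.
# Superellipsoidal coronal profile: quartic in x (flat dorsally, falling
# away laterally, as in a rat coronal section), quadratic in y and z.
.phantom_shape <- function(x, y, z, half, z_cap, offset = 0) {
  a <- half[1] + offset; b <- half[2] + offset; c3 <- half[3] + offset
  ((x / a)^4 + (y / b)^2 + (z / c3)^2 <= 1) & (z <= z_cap + offset)
}

# Membership test for the callosal arch band.
.phantom_cc <- function(x, y, z, z_cap, arc) {
  arch <- z_cap - arc$depth - arc$curvature * x^2
  (abs(y) <= arc$half_length) & (abs(x) <= arc$lateral) &
    (abs(z - arch) <= arc$thickness / 2)
}

#' Generate the synthetic brain phantom
#'
#' Deterministically rasterises the analytic phantom geometry onto a voxel
#' grid sized to contain the skull plus a margin.  Brain tissue labels are
#' mirror-symmetric about the midsagittal (x = 0) plane; the craniotomy
#' window affects only the skull label.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()] containing all seven tissue labels.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  lab <- phantom_labels()
  h <- spec$voxel_size
  off_total <- spec$csf_thickness + h + spec$skull_thickness
  ext_x <- spec$brain_half_axes[1] + off_total + spec$margin
  ext_y <- spec$brain_half_axes[2] + off_total + spec$margin
  ext_zlo <- spec$brain_half_axes[3] + off_total + spec$margin
  ext_zhi <- spec$z_cap + off_total + spec$margin
  nx <- 2L * ceiling(ext_x / h); ny <- 2L * ceiling(ext_y / h)
  nz <- ceiling((ext_zlo + ext_zhi) / h)
  # x and y centred on 0 so voxel centres mirror exactly; z spans the brain
  ox <- -(nx - 1) / 2 * h; oy <- -(ny - 1) / 2 * h
  oz <- -ext_zlo + h / 2
  xs <- ox + (seq_len(nx) - 1) * h
  ys <- oy + (seq_len(ny) - 1) * h
  zs <- oz + (seq_len(nz) - 1) * h
  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))

  half <- spec$brain_half_axes; zc <- spec$z_cap
  sk_out <- .phantom_shape(X, Y, Z, half, zc, off_total)
  if (any(sk_out[c(1, nx), , ]) || any(sk_out[, c(1, ny), ]) ||
      any(sk_out[, , c(1, nz)])) {
    ax <- c("x", "y", "z")[which(c(any(sk_out[c(1, nx), , ]),
                                   any(sk_out[, c(1, ny), ]),
                                   any(sk_out[, , c(1, nz)])))[1]]
    stop("phantom geometry exceeds grid bounds on the ", ax, " axis")
  }
  du_out <- .phantom_shape(X, Y, Z, half, zc, spec$csf_thickness + h)
  cs_out <- .phantom_shape(X, Y, Z, half, zc, spec$csf_thickness)
  brain  <- .phantom_shape(X, Y, Z, half, zc, 0)

  data <- array(lab[["background"]], dim = c(nx, ny, nz))
  data[sk_out] <- lab[["skull"]]
  data[du_out] <- lab[["dura_surface"]]
  data[cs_out] <- lab[["csf"]]
  data[brain]  <- lab[["grey"]]
  data[brain & .phantom_cc(X, Y, Z, zc, spec$cc_arc)] <- lab[["white"]]
  vc <- spec$ventricles
  for (i in seq_len(nrow(vc$centers))) {
    vent <- ((X - vc$centers[i, 1]) / vc$half_axes[1])^2 +
      ((Y - vc$centers[i, 2]) / vc$half_axes[2])^2 +
      ((Z - vc$centers[i, 3]) / vc$half_axes[3])^2 <= 1
    data[brain & vent] <- lab[["ventricle"]]
  }
  # craniotomy: remove skull (only skull) inside the dorsal window
  win <- spec$craniotomy_window
  cran <- (data == lab[["skull"]]) &
    X >= win$x[1] & X <= win$x[2] & Y >= win$y[1] & Y <= win$y[2] & Z > 0
  data[cran] <- lab[["background"]]

  label_volume(data, rep(h, 3), c(ox, oy, oz))
}

#' Extract a corpus-callosum mask from one coronal plane
#'
#' @param vol A [label_volume()].
#' @param coronal_plane 1-based y-axis index of the coronal plane.
#' @return A `cc_mask`: logical 3-D array (thin in y) plus plane metadata.
#' @export
make_cc_mask <- function(vol, coronal_plane) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$data)
  if (coronal_plane < 1 || coronal_plane > d[2]) {
    stop("coronal plane index out of range")
  }
  white <- vol$label_map[["white"]]
  mask <- array(FALSE, dim = d)
  mask[, coronal_plane, ] <- vol$data[, coronal_plane, ] == white
  if (!any(mask)) {
    stop("no white matter in coronal plane ", coronal_plane,
         ": empty corpus-callosum mask")
  }
  structure(list(mask = mask, plane = coronal_plane,
                 voxel_size = vol$voxel_size, origin = vol$origin),
            class = "cc_mask")
}

#' y-axis index closest to a world y coordinate
#' @param vol A `label_volume`.
#' @param y_world World y, mm.
#' @return 1-based plane index.
#' @export
coronal_index <- function(vol, y_world = 0) {
  which.min(abs(voxel_axes(vol)[[2]] - y_world))
}

#' Read / write label volumes as NIfTI with a JSON label-map sidecar
#'
#' `write_label_volume()` writes `<path>` (NIfTI, integer data, voxel size in
#' the pixdim fields) and `<path minus extension>.json` holding the label map
#' and world origin.  `read_label_volume()` reverses this; it refuses
#' non-integer data and label values absent from the sidecar map.
#'
#' @param vol A [label_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_label_volume()` returns a [label_volume()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  sidecar <- .sidecar_path(path)
  jsonlite::write_json(list(label_map = as.list(vol$label_map),
                            origin = vol$origin),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) stop("missing label-map sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  vals <- as.vector(img)
  if (any(vals != round(vals))) stop("non-integer data in label volume ", path)
  arr <- array(as.integer(round(vals)), dim = dim(img))
  label_map <- vapply(meta$label_map, as.integer, integer(1))
  unknown <- setdiff(unique(as.vector(arr)), unname(label_map))
  if (length(unknown) > 0L) {
    stop("label value(s) not in sidecar map: ", paste(unknown, collapse = ", "))
  }
  label_volume(arr, RNifti::pixdim(img)[1:3], as.numeric(meta$origin),
               label_map)
}

.sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Write a segment or mask label map as NIfTI
#' @param arr Integer 3-D array.
#' @param vol Reference `label_volume` supplying voxel size and origin.
#' @param path Output NIfTI path.
#' @keywords internal
write_mask_nifti <- function(arr, vol, path) {
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
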