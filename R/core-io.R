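# Domain types and NIfTI input/output.
#
# All grids share a fixed semantic axis order: x runs right-to-left,
# y ventral-to-dorsal (so gravity in the supine posture points along +y)
# and z caudal-to-cranial. In NIfTI orientation terms this is "LPS".
# Keeping one internal convention makes the vertical-ROI and phantom code
# unconditional; files whose header orientation differs are reoriented on
# read.

.LUNG_ORIENTATION <- "LPS"

.new_grid <- function(data, spacing, class) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite lengths (mm)")
  if (length(dim(data)) < 3L)
    stop("expected 3 spatial dimensions")
  structure(list(data = data, spacing = spacing),
            class = c(class, "lung_grid"))
}

#' CT volume in Hounsfield units
#'
#' Container for a 3-D CT grid with voxel spacing metadata. Axis semantics
#' are fixed: x right-to-left, y ventral-to-dorsal, z caudal-to-cranial.
#'
#' @param data 3-D numeric array of Hounsfield units.
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @return An object of class `ct_volume` (a `lung_grid`).
#' @export
ct_volume <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("expected 3 spatial dimensions")
  if (any(dim(data) < 2L)) stop("grid must have at least 2 voxels per axis")
  if (any(!is.finite(data))) stop("CT data must be finite")
  .new_grid(data, spacing, "ct_volume")
}

#' Binary lung parenchyma mask
#'
#' @param data 3-D array coercible to logical; TRUE marks parenchyma.
#' @param spacing Voxel spacing in mm (must match the companion volume).
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("expected 3 spatial dimensions")
  d <- dim(data)
  data <- array(as.logical(data), dim = d)
  if (any(is.na(data))) stop("mask values must be 0/1")
  if (!any(data)) stop("mask is empty")
  .new_grid(data, spacing, "lung_mask")
}

#' Voxel gas-fraction map
#'
#' Gas fraction F_gas in `[0, 1]` inside the lung mask; voxels outside the
#' mask are `NA`.
#'
#' @param data 3-D numeric array of gas fractions (NA outside the mask).
#' @param spacing Voxel spacing in mm.
#' @return An object of class `aeration_map`.
#' @export
aeration_map <- function(data, spacing) {
  v <- data[!is.na(data)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("in-mask gas fractions must lie within [0, 1]")
  .new_grid(data, spacing, "aeration_map")
}

#' Voxel volumetric-strain map
#'
#' Volumetric strain s = J - 1 on the end-expiratory grid, `NA` outside the
#' reporting mask. In-mask strain must exceed -1 (positive Jacobian).
#'
#' @param data 3-D numeric array (NA outside the mask).
#' @param spacing Voxel spacing in mm.
#' @return An object of class `strain_map`.
#' @export
strain_map <- function(data, spacing) {
  v <- data[!is.na(data)]
  if (length(v) && min(v) <= -1)
    stop("in-mask strain must be > -1 (Jacobian must be positive)")
  .new_grid(data, spacing, "strain_map")
}

#' Dense displacement field
#'
#' Vector field u on the end-expiratory grid, in mm, such that
#' T(x) = x + u(x) maps each end-expiratory location to its end-inspiratory
#' correspondent.
#'
#' @param data 4-D numeric array, last axis of size 3 (x, y, z components in
#'   mm).
#' @param spacing Voxel spacing in mm.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(data, spacing) {
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field must be 4-D with a size-3 last axis")
  if (any(!is.finite(data))) stop("displacement field must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths (mm)")
  structure(list(data = data, spacing = spacing),
            class = c("displacement_field", "lung_grid"))
}

.grid_dim <- function(x) {
  d <- dim(x$data)
  d[1:3]
}

#' Geometry compatibility predicate
#'
#' TRUE iff two grids share shape and voxel spacing (spacing tolerance
#' 1e-6 mm). Pure predicate; never errors on valid grids.
#'
#' @param a,b `lung_grid` objects (volumes, masks, maps or fields).
#' @return Logical scalar.
#' @export
check_geometry <- function(a, b) {
  if (is.null(a) || is.null(b)) stop("both arguments must be non-null")
  identical(.grid_dim(a), .grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) <= 1e-6
}

.stop_geometry <- function(a, b, what = "inputs") {
  if (!check_geometry(a, b))
    stop(sprintf("geometry mismatch between %s: shapes/spacings must agree",
                 what))
  invisible(TRUE)
}

.lps_xform <- function(spacing) {
  structure(diag(c(-spacing[1], -spacing[2], spacing[3], 1)), code = 2L)
}

#' Read a volume, mask, map or field from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file, normalizes its axis order to the package
#' convention (x right-to-left, y ventral-to-dorsal, z caudal-to-cranial;
#' reorienting when the header orientation differs) and populates spacing
#' from the header.
#'
#' @param path Path to an existing NIfTI file.
#' @param type One of `"ct"`, `"mask"`, `"aeration"`, `"strain"`, `"field"`;
#'   selects the returned class. Fields must be stored as 4-D with a size-3
#'   last axis.
#' @return A `lung_grid` object of the requested type.
#' @export
read_volume <- function(path, type = c("ct", "mask", "aeration", "strain",
                                       "field")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ori) && is.character(ori) && nchar(ori) == 3L &&
      ori != .LUNG_ORIENTATION) {
    img <- tryCatch({ RNifti::orientation(img) <- .LUNG_ORIENTATION; img },
                    warning = function(w) img)
  }
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (type == "field") {
    if (length(d) != 4L || d[4] != 3L)
      stop("expected a 4-D displacement field with size-3 last axis")
    return(displacement_field(array(as.numeric(img), dim = d), pd[1:3]))
  }
  if (length(d) != 3L) stop("expected 3 spatial dimensions")
  sp <- pd[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("invalid voxel spacing in header (zero or negative)")
  a <- array(as.numeric(img), dim = d)
  switch(type,
         ct = ct_volume(a, sp),
         mask = lung_mask(a, sp),
         aeration = aeration_map(a, sp),
         strain = strain_map(a, sp))
}

#' Write a volume, mask, map or field to NIfTI
#'
#' Masks are stored as 8-bit integers, scalar maps and CT volumes as 32-bit
#' float, displacement fields as 4-D 32-bit float with the vector component
#' on the last axis. The header records spacing and the package orientation.
#'
#' @param vol A `lung_grid` object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "lung_grid"))
  sp <- vol$spacing
  if (inherits(vol, "lung_mask")) {
    a <- array(as.integer(vol$data), dim = dim(vol$data))
    dtype <- "uint8"
  } else {
    a <- vol$data
    dtype <- "float"
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- if (length(dim(a)) == 4L) c(sp, 1) else sp
  RNifti::qform(img) <- .lps_xform(sp)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
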