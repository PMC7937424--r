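#' CT volume in Hounsfield units
#'
#' Container for a single 3D CT acquisition. Voxel values are attenuation in
#' Hounsfield units (HU, water = 0); `spacing` gives the physical voxel size
#' in mm along the (x, y, z) axes, with the third index `k` running over
#' slices. Voxel indices are 1-based and stored in R's native linear order
#' (the first index varies fastest).
#'
#' @param values 3D numeric array of HU values; all entries must be finite.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#' @param phase Contrast phase, one of `"unenhanced"`, `"arterial"`,
#'   `"venous"`, `"delayed"`.
#' @param subject_id Optional opaque subject identifier.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, phase = "unenhanced", subject_id = NA_character_) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort_geometry("`values` must be a 3D array of HU values")
  }
  if (any(dim(values) < 1L)) {
    abort_geometry("each dimension of the volume must contain at least one voxel")
  }
  if (!all(is.finite(values))) {
    abort_geometry("HU values must all be finite")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort_geometry("`spacing` must be three strictly positive voxel sizes in mm")
  }
  phase <- match.arg(phase, ct_phases())
  structure(
    list(values = values, spacing = spacing, phase = phase,
         subject_id = as.character(subject_id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %s phase, %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              x$phase, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' A lesion segmentation aligned voxel-for-voxel with its paired
#' [ct_volume()]: same grid shape and same spacing. The mask must select at
#' least one voxel.
#'
#' @param mask Logical (or 0/1 numeric) 3D array.
#' @param spacing Numeric length-3 voxel size in mm.
#'
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, spacing) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort_geometry("`mask` must be a 3D array")
  }
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) abort_geometry("mask entries must be TRUE/FALSE")
  if (!any(mask)) abort_empty_voi("mask selects no voxels (empty VOI)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_geometry("`spacing` must be three strictly positive voxel sizes in mm")
  }
  structure(list(mask = mask, spacing = spacing), class = "voi_mask")
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a 3D NIfTI image and returns it as a [ct_volume()]. Values are taken
#' as already being in HU (any scl_slope/scl_inter rescaling is applied by the
#' NIfTI reader); voxel spacing comes from the file header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @inheritParams ct_volume
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, phase = "unenhanced", subject_id = NA_character_) {
  if (!file.exists(path)) abort_io(paste0("cannot read volume: no such file '", path, "'"))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_io(paste0("failed to read NIfTI file '", path, "': ",
                                                      conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    abort_metadata(paste0("expected a 3D image, got ", length(dim(arr)), " dimensions"))
  }
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3L || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0)) {
    abort_metadata("NIfTI header field 'pixdim' is missing or non-positive")
  }
  ct_volume(arr, spacing = pix[1:3], phase = phase, subject_id = subject_id)
}

#' Write a CT volume (or mask) to NIfTI
#'
#' @param volume A [ct_volume()] or [voi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "voi_mask")) {
    arr <- volume$mask + 0L
    spacing <- volume$spacing
  } else if (inherits(volume, "ct_volume")) {
    arr <- volume$values
    spacing <- volume$spacing
  } else {
    abort_parameter("`volume` must be a ct_volume or voi_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a VOI mask from a NIfTI file
#'
#' Voxels with value > 0.5 are taken as inside the VOI.
#'
#' @inheritParams load_volume
#' @return A [voi_mask()].
#' @export
load_mask <- function(path) {
  vol <- load_volume(path)
  voi_mask(vol$values > 0.5, spacing = vol$spacing)
}

#' Extract the HU sample inside a VOI
#'
#' Pulls out the HU values at all mask voxels, in deterministic order (the
#' first voxel index varies fastest). The returned sample carries voxel
#' coordinates and grid geometry so that spatial (second-order) features can
#' be computed downstream.
#'
#' @param volume A [ct_volume()].
#' @param mask A [voi_mask()] on the same grid; spacings must agree within
#'   1e-3 mm.
#'
#' @return An object of class `voi_sample` with elements `values`, `coords`
#'   (n x 3 integer matrix of 1-based voxel indices), `voxel_count`,
#'   `grid_dim` and `spacing`.
#' @export
extract_voi <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$values), dim(mask$mask))) {
    abort_geometry("volume and mask grids have different shapes")
  }
  if (any(abs(volume$spacing - mask$spacing) > 1e-3)) {
    abort_geometry("volume and mask voxel spacings differ by more than 1e-3 mm")
  }
  if (!any(mask$mask)) abort_empty_voi("mask selects no voxels (empty VOI)")
  coords <- which(mask$mask, arr.ind = TRUE)
  dimnames(coords) <- NULL
  structure(
    list(values = as.numeric(volume$values[mask$mask]),
         coords = coords,
         voxel_count = nrow(coords),
         grid_dim = dim(volume$values),
         spacing = volume$spacing),
    class = "voi_sample"
  )
}

#' Mean VOI densitometry
#'
#' Arithmetic mean of the HU values inside a VOI — the conventional
#' "mean densitometry value" of adrenal CT reporting.
#'
#' @param sample A `voi_sample` from [extract_voi()], or a bare numeric
#'   vector of HU values.
#' @return A single HU value.
#' @export
mean_densitometry <- function(sample) {
  values <- if (inherits(sample, "voi_sample")) sample$values else as.numeric(sample)
  if (length(values) == 0L) abort_empty_voi("cannot compute densitometry of an empty VOI")
  mean(values)
}
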