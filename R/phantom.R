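# Synthetic lesion phantoms.
#
# Each phantom is an ellipsoidal lesion filled with a spatially correlated
# Gaussian texture (smoothed white noise, rescaled to the target mean/SD over
# the VOI), optionally carrying implanted necrosis blobs (low HU, near-fluid)
# and calcification specks (high HU). Contrast phases are the unenhanced
# volume plus a class-specific enhancement offset and a small correlated
# phase noise, so phase-wise mean densitometry reproduces the intended
# washout pattern of the lesion class.

# Class presets. Intensity statistics per class follow the cohort means/SDs
# of adrenal series: carcinoma 33.4(4.7) HU, adenoma 20.2(9.2) HU,
# incidentaloma 2.8(9.4) HU on unenhanced CT. Venous/delayed offsets are
# solved from the per-class absolute/relative washout means
# (carcinoma 30.0/16.5, adenoma 32.2/23.7, incidentaloma 63.3/46.5 per cent),
# so enhanced mean V and delayed mean D satisfy
#   100 (V - D) / V        = relative washout
#   100 (V - D) / (V - U)  = absolute washout.
# Carcinomas get a shorter texture correlation length and necrosis implants:
# malignant lesions are spatially more disorganized and frequently necrotic.
phantom_class_defaults <- function(class_label) {
  switch(class_label,
    carcinoma = list(
      base_mean = 33.4, base_sd = 4.7, texture_correlation_length = 1,
      necrosis_fraction = 0.15, necrosis_mean = 22, necrosis_sd = 2,
      calcification_fraction = 0, calcification_mean = 300, calcification_sd = 50,
      enhancement = c(arterial = 30.0, venous = 40.82, delayed = 28.57)),
    adenoma = list(
      base_mean = 20.2, base_sd = 9.2, texture_correlation_length = 2,
      necrosis_fraction = 0, necrosis_mean = 22, necrosis_sd = 2,
      calcification_fraction = 0, calcification_mean = 300, calcification_sd = 50,
      enhancement = c(arterial = 45.0, venous = 56.32, delayed = 38.19)),
    incidentaloma = list(
      base_mean = 2.8, base_sd = 9.4, texture_correlation_length = 2,
      necrosis_fraction = 0, necrosis_mean = 22, necrosis_sd = 2,
      calcification_fraction = 0, calcification_mean = 300, calcification_sd = 50,
      enhancement = c(arterial = 12.0, venous = 7.75, delayed = 2.84))
  )
}

#' Specification of a synthetic lesion phantom
#'
#' Builds a validated parameter set for [generate_phantom()]. Defaults for
#' the intensity statistics, texture correlation and contrast-phase
#' enhancement are filled in per lesion class; any field can be overridden.
#'
#' @param class_label `"carcinoma"`, `"adenoma"` or `"incidentaloma"`.
#' @param shape Grid dimensions (voxels) of the generated volumes.
#' @param spacing Voxel size in mm.
#' @param base_mean,base_sd Target mean and voxel-wise SD (HU) of the VOI on
#'   unenhanced CT. The generated lesion is rescaled so the realized VOI mean
#'   equals `base_mean` exactly; the SD equals `base_sd` exactly for lesions
#'   without implants.
#' @param texture_correlation_length Gaussian smoothing sigma, in voxels,
#'   applied to the white-noise texture field.
#' @param necrosis_fraction,necrosis_mean,necrosis_sd Fraction of VOI voxels
#'   replaced by necrotic (near-fluid) tissue, and its HU mean/SD.
#' @param calcification_fraction,calcification_mean,calcification_sd Same for
#'   calcification specks (high HU).
#' @param enhancement Named numeric vector of phase enhancement offsets (HU)
#'   with entries `arterial`, `venous`, `delayed`.
#' @param enhancement_noise_sd SD (HU) of the zero-mean correlated noise added
#'   to each contrast phase (phases are not voxel-wise copies of each other).
#' @param seed Integer seed; the seed fully determines the phantom.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("carcinoma", "adenoma", "incidentaloma"),
                         shape = c(28L, 28L, 10L),
                         spacing = c(0.744, 0.744, 5),
                         base_mean = NULL, base_sd = NULL,
                         texture_correlation_length = NULL,
                         necrosis_fraction = NULL, necrosis_mean = NULL, necrosis_sd = NULL,
                         calcification_fraction = NULL, calcification_mean = NULL,
                         calcification_sd = NULL,
                         enhancement = NULL,
                         enhancement_noise_sd = 2,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  d <- phantom_class_defaults(class_label)
  spec <- list(
    class_label = class_label,
    shape = as.integer(shape),
    spacing = as.numeric(spacing),
    base_mean = base_mean %||% d$base_mean,
    base_sd = base_sd %||% d$base_sd,
    texture_correlation_length = texture_correlation_length %||% d$texture_correlation_length,
    necrosis_fraction = necrosis_fraction %||% d$necrosis_fraction,
    necrosis_mean = necrosis_mean %||% d$necrosis_mean,
    necrosis_sd = necrosis_sd %||% d$necrosis_sd,
    calcification_fraction = calcification_fraction %||% d$calcification_fraction,
    calcification_mean = calcification_mean %||% d$calcification_mean,
    calcification_sd = calcification_sd %||% d$calcification_sd,
    enhancement = enhancement %||% d$enhancement,
    enhancement_noise_sd = enhancement_noise_sd,
    seed = as.integer(seed)
  )
  if (length(spec$shape) != 3L || any(spec$shape < 1L)) {
    abort_spec("`shape` must be three positive voxel counts")
  }
  if (spec$base_sd < 0) abort_spec("`base_sd` must be non-negative")
  fr <- c(spec$necrosis_fraction, spec$calcification_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort_spec("implant fractions must lie in [0, 1] and sum to at most 1")
  }
  if (!all(c("arterial", "venous", "delayed") %in% names(spec$enhancement))) {
    abort_spec("`enhancement` must name arterial, venous and delayed offsets")
  }
  structure(spec, class = "phantom_spec")
}

# separable Gaussian smoothing of a 3D array via banded kernel matrices,
# kernel truncated at 3 sigma and renormalized at the edges
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  offs <- seq(-half, half)
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (m in seq_along(offs)) {
    i <- seq_len(n)
    j <- i + offs[m]
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- w[m]
  }
  K / rowSums(K)
}

gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  a <- smoothing_matrix(d[1], sigma) %*% matrix(arr, d[1])
  arr <- array(a, d)
  a <- smoothing_matrix(d[2], sigma) %*% matrix(aperm(arr, c(2, 1, 3)), d[2])
  arr <- aperm(array(a, d[c(2, 1, 3)]), c(2, 1, 3))
  a <- smoothing_matrix(d[3], sigma) %*% matrix(aperm(arr, c(3, 1, 2)), d[3])
  aperm(array(a, d[c(3, 1, 2)]), c(2, 3, 1))
}

# correlated zero-mean unit-SD field over the masked voxels
correlated_field <- function(shape, sigma, mask) {
  f <- gaussian_smooth_3d(array(rnorm(prod(shape)), shape), sigma)
  v <- f[mask]
  s <- sd_pop(v)
  if (s == 0) f[] <- 0 else f <- (f - mean(v)) / s
  f
}

# contiguous blob of `size` voxels grown from a random in-mask centre
blob_indices <- function(coords, size) {
  centre <- coords[sample.int(nrow(coords), 1L), ]
  d2 <- (coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2 + (coords[, 3] - centre[3])^2
  order(d2)[seq_len(size)]
}

#' Generate a synthetic lesion phantom
#'
#' Produces one [ct_volume()] per contrast phase (unenhanced, arterial,
#' venous, delayed) plus the shared ellipsoidal [voi_mask()]. The same seed
#' always yields voxel-wise identical output.
#'
#' After any implants, the unenhanced VOI is recentred so its mean equals
#' `base_mean` exactly; contrast phases add the class enhancement offset and
#' a zero-mean correlated phase noise, so the phase-wise VOI means (and hence
#' the washout percentages) are fully determined by the phantom parameters.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volumes` (named list of four [ct_volume()]s),
#'   `mask` (a [voi_mask()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::local_seed(spec$seed)

  shape <- spec$shape
  centre <- (shape + 1) / 2
  semi <- pmax((shape - 1) / 2, 0.5) * 0.9
  ii <- slice.index(array(0, shape), 1)
  jj <- slice.index(array(0, shape), 2)
  kk <- slice.index(array(0, shape), 3)
  mask <- ((ii - centre[1]) / semi[1])^2 + ((jj - centre[2]) / semi[2])^2 +
    ((kk - centre[3]) / semi[3])^2 <= 1
  if (!any(mask)) abort_spec("degenerate shape: the ellipsoidal mask is empty")
  n_voi <- sum(mask)
  coords <- which(mask, arr.ind = TRUE)
  dimnames(coords) <- NULL

  base <- array(-50, shape)  # background: retroperitoneal fat, never inside the VOI
  field <- correlated_field(shape, spec$texture_correlation_length, mask)
  base[mask] <- field[mask] * spec$base_sd + spec$base_mean

  n_necro <- round(spec$necrosis_fraction * n_voi)
  if (n_necro > 0) {
    # several mid-sized blobs rather than one: necrotic change is multifocal
    n_blobs <- max(1L, round(n_necro / 150))
    per <- diff(round(seq(0, n_necro, length.out = n_blobs + 1)))
    hit <- unique(unlist(lapply(per[per > 0], function(sz) blob_indices(coords, sz))))
    base[coords[hit, , drop = FALSE]] <-
      rnorm(length(hit), spec$necrosis_mean, spec$necrosis_sd)
  }
  n_calc <- round(spec$calcification_fraction * n_voi)
  if (n_calc > 0) {
    n_specks <- max(1L, round(n_calc / 40))  # calcifications are small specks
    per <- diff(round(seq(0, n_calc, length.out = n_specks + 1)))
    hit <- unique(unlist(lapply(per[per > 0], function(sz) blob_indices(coords, sz))))
    base[coords[hit, , drop = FALSE]] <-
      rnorm(length(hit), spec$calcification_mean, spec$calcification_sd)
  }
  # recentre: the realized VOI mean is exactly the configured target
  base[mask] <- base[mask] - mean(base[mask]) + spec$base_mean

  make_phase <- function(phase, offset) {
    v <- base
    if (offset != 0 || spec$enhancement_noise_sd > 0) {
      noise <- correlated_field(shape, spec$texture_correlation_length, mask) *
        spec$enhancement_noise_sd
      v[mask] <- v[mask] + offset + noise[mask]
      v[!mask] <- v[!mask] + offset * 0.5  # background enhances less
    }
    ct_volume(v, spec$spacing, phase = phase)
  }

  volumes <- list(
    unenhanced = ct_volume(base, spec$spacing, phase = "unenhanced"),
    arterial = make_phase("arterial", spec$enhancement[["arterial"]]),
    venous = make_phase("venous", spec$enhancement[["venous"]]),
    delayed = make_phase("delayed", spec$enhancement[["delayed"]])
  )
  list(volumes = volumes, mask = voi_mask(mask, spec$spacing), spec = spec)
}
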