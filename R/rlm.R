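# Grey-level run-length matrix (RLM) and the Galloway feature set.

#' Compute the grey-level run-length matrix of a VOI
#'
#' For each direction, every maximal collinear chain of in-VOI voxels is
#' decomposed into maximal runs of equal grey level; a voxel outside the VOI
#' breaks the chain. Run counts `r(i, j)` (grey level i, run length j) are
#' pooled over all directions. Each direction traverses every VOI voxel
#' exactly once, so per direction `sum(j * r) = n_voxels`.
#'
#' @inheritParams compute_glcm
#' @return An object of class `rlm`: `r` (Ng x Lmax count matrix),
#'   `n_runs`, `n_voxels_traversed` (voxel count times number of
#'   directions), `n_grey`, `n_directions`, `mode`.
#' @export
compute_rlm <- function(q, mode = c("3d", "2d"), offsets = NULL) {
  stopifnot(inherits(q, "quantized_voi"))
  mode <- match.arg(mode)
  if (is.null(offsets)) offsets <- direction_offsets(mode)
  n_vox <- length(q$levels)
  if (n_vox == 0L) abort_empty_voi("cannot compute run lengths of an empty VOI")

  ng <- q$n_grey
  lmax <- max(q$grid_dim)
  counts <- matrix(0, ng, lmax)
  coords <- q$coords
  lv <- q$levels

  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    axis <- which(o != 0L)[1]  # o[axis] == +1 by construction of the offset set
    tt <- coords[, axis]
    key <- coords - tcrossprod(tt, o)
    ord <- order(key[, 1], key[, 2], key[, 3], tt)
    k1 <- key[ord, 1]; k2 <- key[ord, 2]; k3 <- key[ord, 3]
    tv <- tt[ord]
    lo <- lv[ord]
    new_run <- c(TRUE, diff(k1) != 0 | diff(k2) != 0 | diff(k3) != 0 |
                   diff(tv) != 1L | diff(lo) != 0L)
    id <- cumsum(new_run)
    lens <- tabulate(id)
    run_lv <- lo[new_run]
    counts <- counts + matrix(tabulate(run_lv + (lens - 1L) * ng, ng * lmax), ng, lmax)
  }

  structure(
    list(r = counts, n_runs = sum(counts),
         n_voxels_traversed = n_vox * nrow(offsets),
         n_grey = ng, n_directions = nrow(offsets), mode = mode),
    class = "rlm"
  )
}

#' Galloway features of a run-length matrix
#'
#' The 11 RLM features of the radiomic signature, all normalized by the
#' total number of runs except run percentage (`rlm_rp`), which is runs per
#' voxel traversed.
#'
#' @param m A [compute_rlm()] result.
#' @return Named numeric vector of 11 features, names prefixed `rlm_`.
#' @export
rlm_features <- function(m) {
  stopifnot(inherits(m, "rlm"))
  r <- m$r
  nr <- m$n_runs
  if (nr < 1) abort_degenerate("run-length matrix contains no runs")
  i2 <- matrix(seq_len(nrow(r))^2, nrow(r), ncol(r))
  j2 <- matrix(seq_len(ncol(r))^2, nrow(r), ncol(r), byrow = TRUE)

  c(
    rlm_sre = sum(r / j2) / nr,
    rlm_lre = sum(r * j2) / nr,
    rlm_gln = sum(rowSums(r)^2) / nr,
    rlm_rln = sum(colSums(r)^2) / nr,
    rlm_rp = nr / m$n_voxels_traversed,
    rlm_lgre = sum(r / i2) / nr,
    rlm_hgre = sum(r * i2) / nr,
    rlm_srlge = sum(r / (i2 * j2)) / nr,
    rlm_srhge = sum(r * i2 / j2) / nr,
    rlm_lrlge = sum(r * j2 / i2) / nr,
    rlm_lrhge = sum(r * i2 * j2) / nr
  )
}
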