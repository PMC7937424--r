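# Synthetic cohorts: feature tables drawn directly from group-specific
# normals (fast, used for statistical calibration), and image-based cohorts
# assembled from lesion phantoms (used for the end-to-end pipeline).

#' Specification of a synthetic cohort feature table
#'
#' Describes a three-group cohort (carcinoma ACC, adenoma, incidentaloma AI)
#' of per-subject 32-feature vectors per phase. Features are independent
#' normals on a standardized scale: both benign groups have mean 0 and unit
#' SD for every feature, and the ACC group mean is shifted by `separation`
#' SDs on every feature (or by the per-feature vector `acc_shift`).
#' Optionally the first `n_outliers` ACC subjects are displaced far from all
#' group centroids, emulating gross within-class anomalies such as massively
#' calcified carcinomas.
#'
#' @param n_acc,n_adenoma,n_ai Group sizes (all >= 2). Defaults 10/9/11,
#'   the sizes of the adrenal study cohort the generator emulates.
#' @param separation ACC mean shift in pooled-SD units, applied to every
#'   feature. 0 gives the null (labels independent of features).
#' @param acc_shift Optional length-32 vector of per-feature ACC shifts,
#'   overriding `separation`.
#' @param feature_sd Common feature SD (> 0).
#' @param n_outliers Number of ACC subjects displaced as outliers.
#' @param outlier_shift Per-feature displacement (in SD units, random sign)
#'   of each outlier from the ACC centroid.
#' @param phases Phases to simulate.
#' @param seed Integer seed; one seed drives the whole cohort.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_acc = 10L, n_adenoma = 9L, n_ai = 11L,
                        separation = 5, acc_shift = NULL, feature_sd = 1,
                        n_outliers = 0L, outlier_shift = 15,
                        phases = c("unenhanced", "arterial", "venous"),
                        seed = 1L) {
  n <- c(n_acc, n_adenoma, n_ai)
  if (any(n < 2L)) abort_spec("every group must have n >= 2")
  if (feature_sd <= 0) abort_spec("`feature_sd` must be > 0")
  n_feat <- length(radiomic_feature_names())
  acc_shift <- acc_shift %||% rep(separation, n_feat)
  if (length(acc_shift) != n_feat) {
    abort_spec(paste0("`acc_shift` must have one entry per feature (", n_feat, ")"))
  }
  if (n_outliers > n_acc) abort_spec("cannot inject more outliers than ACC subjects")
  phases <- match.arg(phases, ct_phases(), several.ok = TRUE)
  structure(
    list(n_acc = as.integer(n_acc), n_adenoma = as.integer(n_adenoma),
         n_ai = as.integer(n_ai), separation = separation,
         acc_shift = as.numeric(acc_shift), feature_sd = feature_sd,
         n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
         phases = phases, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort feature table
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per (subject, phase): `subject_id`, `group`
#'   (factor ACC/adenoma/AI), `phase`, `injected_outlier` (ground-truth flag
#'   for the displaced subjects) and the 32 feature columns.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)

  feat <- radiomic_feature_names()
  groups <- rep(c("ACC", "adenoma", "AI"), c(spec$n_acc, spec$n_adenoma, spec$n_ai))
  n_sub <- length(groups)
  ids <- sprintf("S%02d", seq_len(n_sub))
  outlier_ids <- if (spec$n_outliers > 0) ids[seq_len(spec$n_outliers)] else character()
  # each outlier keeps one displacement direction across phases
  out_dir <- lapply(seq_len(spec$n_outliers), function(i) {
    sample(c(-1, 1), length(feat), replace = TRUE) * spec$outlier_shift
  })

  centre <- function(group) if (group == "ACC") spec$acc_shift else rep(0, length(feat))

  rows <- purrr::map(spec$phases, function(ph) {
    x <- matrix(rnorm(n_sub * length(feat), sd = spec$feature_sd), n_sub)
    for (s in seq_len(n_sub)) x[s, ] <- x[s, ] + centre(groups[s])
    for (i in seq_along(outlier_ids)) {
      s <- match(outlier_ids[i], ids)
      x[s, ] <- x[s, ] + out_dir[[i]]
    }
    colnames(x) <- feat
    dplyr::bind_cols(
      tibble(subject_id = ids,
             group = factor(groups, levels = c("ACC", "adenoma", "AI")),
             phase = ph,
             injected_outlier = ids %in% outlier_ids),
      as_tibble(x)
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate an image-based phantom cohort
#'
#' Builds a full synthetic study: for each subject a lesion phantom is
#' generated (subject-level mean densitometry drawn from the class
#' distribution, respecting the 10 HU lipid-rich/lipid-poor selection split
#' between surveillance incidentalomas and operated lesions), the 32
#' radiomic features are extracted per requested phase, and washout
#' densitometry is computed from the phase-wise VOI means (venous as the
#' enhanced measurement). Each subject's contrast-phase offsets are solved
#' from a per-subject draw of the class's absolute/relative washout
#' distribution, so the washout percentages of the lesion classes are
#' reproduced exactly. A configurable number of
#' carcinomas carry massive calcifications, emulating gross outliers.
#'
#' @param n_acc,n_adenoma,n_ai Group sizes; defaults 10/9/11.
#' @param shape,spacing Phantom grid geometry passed to [phantom_spec()].
#' @param n_grey,mode,distance Texture extraction settings, see
#'   [extract_features()].
#' @param n_calcified_acc Number of carcinomas generated with massive
#'   calcification (default 2).
#' @param phases Phases for feature extraction.
#' @param seed Integer seed driving the whole cohort.
#'
#' @return A list with `features` (tibble, one row per subject x phase:
#'   `subject_id`, `group`, `calcified`, phase, features, provenance) and
#'   `washout` (tibble, one row per subject from [washout_table()]).
#' @export
generate_phantom_cohort <- function(n_acc = 10L, n_adenoma = 9L, n_ai = 11L,
                                    shape = c(28L, 28L, 10L),
                                    spacing = c(0.744, 0.744, 5),
                                    n_grey = 32L, mode = "3d", distance = 1L,
                                    n_calcified_acc = 2L,
                                    phases = c("unenhanced", "arterial", "venous"),
                                    seed = 1L) {
  if (any(c(n_acc, n_adenoma, n_ai) < 2L)) abort_spec("every group must have n >= 2")
  if (n_calcified_acc > n_acc) abort_spec("more calcified carcinomas than carcinomas")
  phases <- match.arg(phases, ct_phases(), several.ok = TRUE)
  withr::local_seed(seed)

  classes <- rep(c("carcinoma", "adenoma", "incidentaloma"), c(n_acc, n_adenoma, n_ai))
  group_of <- c(carcinoma = "ACC", adenoma = "adenoma", incidentaloma = "AI")
  n_sub <- length(classes)
  ids <- sprintf("S%02d", seq_len(n_sub))
  calcified <- seq_len(n_sub) <= n_calcified_acc  # first carcinomas
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)

  feature_rows <- vector("list", n_sub)
  washout_rows <- vector("list", n_sub)
  # subject-level mean densitometry honours the study's inclusion criteria:
  # operated lesions (carcinoma/adenoma) are lipid-poor (> 10 HU), the
  # surveillance incidentalomas lipid-rich (< 10 HU)
  draw_subject_mean <- function(cls, defs) {
    repeat {
      m <- rnorm(1, defs$base_mean, defs$base_sd)
      if (cls == "incidentaloma" && m < 10) return(m)
      if (cls != "incidentaloma" && m > 10) return(m)
    }
  }

  # per-class washout distributions, absolute/relative mean (SD) in per cent;
  # each subject's venous and delayed offsets are solved from its own washout
  # draw, so the washout percentages are exact per subject:
  #   V = U * aw / (aw - rw),  D = V * (1 - rw)
  washout_pars <- list(
    carcinoma = c(aw = 30.0, aw_sd = 0.2, rw = 16.5, rw_sd = 0.2),
    adenoma = c(aw = 32.2, aw_sd = 0.1, rw = 23.7, rw_sd = 0.4),
    incidentaloma = c(aw = 63.3, aw_sd = 0.3, rw = 46.5, rw_sd = 0.5)
  )

  for (s in seq_len(n_sub)) {
    cls <- classes[s]
    defs <- phantom_class_defaults(cls)
    subject_mean <- draw_subject_mean(cls, defs)
    wp <- washout_pars[[cls]]
    aw <- rnorm(1, wp[["aw"]], wp[["aw_sd"]]) / 100
    rw <- rnorm(1, wp[["rw"]], wp[["rw_sd"]]) / 100
    v_hu <- subject_mean * aw / (aw - rw)
    d_hu <- v_hu * (1 - rw)
    enh <- c(arterial = defs$enhancement[["arterial"]] + rnorm(1, 0, 1),
             venous = v_hu - subject_mean, delayed = d_hu - subject_mean)
    spec <- phantom_spec(
      cls, shape = shape, spacing = spacing,
      base_mean = subject_mean,
      calcification_fraction = if (calcified[s]) 0.12 else defs$calcification_fraction,
      enhancement = enh, seed = sub_seeds[s]
    )
    ph <- generate_phantom(spec)
    feature_rows[[s]] <- purrr::map(phases, function(p) {
      vol <- ph$volumes[[p]]
      vol$subject_id <- ids[s]
      extract_features(vol, ph$mask, n_grey = n_grey, mode = mode, distance = distance)
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(group = factor(group_of[[cls]], levels = c("ACC", "adenoma", "AI")),
                    calcified = calcified[s], .after = "subject_id")
    voi_mean <- function(p) mean_densitometry(extract_voi(ph$volumes[[p]], ph$mask))
    washout_rows[[s]] <- tibble(
      subject_id = ids[s],
      group = factor(group_of[[cls]], levels = c("ACC", "adenoma", "AI")),
      hu_unenhanced = voi_mean("unenhanced"),
      hu_enhanced = voi_mean("venous"),
      hu_delayed = voi_mean("delayed")
    )
  }

  list(
    features = dplyr::bind_rows(feature_rows),
    washout = washout_table(dplyr::bind_rows(washout_rows))
  )
}
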