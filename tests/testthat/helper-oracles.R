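# Independent brute-force oracles for the second-order texture features.
# These deliberately share no code with the package: co-occurrences are
# counted by looping over all ordered voxel pairs, runs by walking each
# voxel chain step by step, and features by direct transcription of the
# defining sums.

# random small VOI on a grid: returns a list mimicking a quantized VOI
random_small_voi <- function(seed, max_dim = 6L, ng_max = 8L, density = 0.6) {
  set.seed(seed)
  dims <- sample(2:max_dim, 3, replace = TRUE)
  ng <- sample(2:ng_max, 1)
  n_cells <- prod(dims)
  inside <- runif(n_cells) < density
  if (sum(inside) < 4) inside[sample(n_cells, 4)] <- TRUE
  mask <- array(inside, dims)
  coords <- which(mask, arr.ind = TRUE)
  dimnames(coords) <- NULL
  levels <- sample.int(ng, nrow(coords), replace = TRUE)
  list(dims = dims, ng = ng, mask = mask, coords = coords, levels = levels)
}

# wrap a raw VOI into package objects (volume holds the levels as "HU")
voi_as_quantized <- function(v) {
  structure(list(levels = as.integer(v$levels), n_grey = v$ng,
                 bin_edges = seq(1, v$ng, length.out = v$ng + 1),
                 coords = v$coords, grid_dim = v$dims),
            class = "quantized_voi")
}

bf_glcm <- function(v, offsets) {
  offs <- rbind(offsets, -offsets)
  keyset <- apply(offs, 1, paste, collapse = ",")
  ng <- v$ng
  P <- matrix(0, ng, ng)
  n <- nrow(v$coords)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      d <- v$coords[b, ] - v$coords[a, ]
      if (paste(d, collapse = ",") %in% keyset) {
        P[v$levels[a], v$levels[b]] <- P[v$levels[a], v$levels[b]] + 1
      }
    }
  }
  list(p = P / sum(P), n_pairs = sum(P))
}

bf_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:ng) { sx <- sx + (i - mux)^2 * px[i]; sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng)  # psum[k] = p_{x+y}(k), pdiff[k+1] = p_{x-y}(k)
  ac <- 0; ent <- 0; idm <- 0; ctr <- 0; dis <- 0; en <- 0
  shade <- 0; prom <- 0; vr <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    psum[i + j] <- psum[i + j] + pij
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + pij
    ac <- ac + i * j * pij
    if (pij > 0) ent <- ent - pij * log2(pij)
    idm <- idm + pij / (1 + (i - j)^2)
    ctr <- ctr + (i - j)^2 * pij
    dis <- dis + abs(i - j) * pij
    en <- en + pij^2
    shade <- shade + (i + j - mux - muy)^3 * pij
    prom <- prom + (i + j - mux - muy)^4 * pij
    vr <- vr + (i - (mux + muy) / 2)^2 * pij
  }
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  }
  sv <- 0
  for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  de <- 0; mud <- 0
  for (k in 0:(ng - 1)) {
    mud <- mud + k * pdiff[k + 1]
    if (pdiff[k + 1] > 0) de <- de - pdiff[k + 1] * log2(pdiff[k + 1])
  }
  dv <- 0
  for (k in 0:(ng - 1)) dv <- dv + (k - mud)^2 * pdiff[k + 1]
  c(glcm_autocorrelation = ac,
    glcm_cluster_prominence = prom,
    glcm_cluster_shade = shade,
    glcm_contrast = ctr,
    glcm_correlation = if (sx * sy > 0) (ac - mux * muy) / (sx * sy) else 0,
    glcm_difference_entropy = de,
    glcm_difference_variance = dv,
    glcm_dissimilarity = dis,
    glcm_energy = en,
    glcm_entropy = ent,
    glcm_homogeneity_idm = idm,
    glcm_maximum_probability = max(p),
    glcm_sum_average = sa,
    glcm_sum_entropy = se,
    glcm_sum_variance = sv,
    glcm_variance = vr)
}

bf_rlm <- function(v, offsets, lmax) {
  ng <- v$ng
  key <- apply(v$coords, 1, paste, collapse = ",")
  level_at <- setNames(v$levels, key)
  R <- matrix(0, ng, lmax)
  np <- 0
  for (r in seq_len(nrow(offsets))) {
    d <- offsets[r, ]
    np <- np + nrow(v$coords)
    for (a in seq_len(nrow(v$coords))) {
      prev <- paste(v$coords[a, ] - d, collapse = ",")
      if (!is.na(level_at[prev]) && level_at[prev] == v$levels[a]) next  # not a run start
      len <- 1
      cur <- v$coords[a, ]
      repeat {
        nxt <- paste(cur + d, collapse = ",")
        if (is.na(level_at[nxt]) || level_at[nxt] != v$levels[a]) break
        len <- len + 1
        cur <- cur + d
      }
      R[v$levels[a], len] <- R[v$levels[a], len] + 1
    }
  }
  list(r = R, n_runs = sum(R), np = np)
}

bf_rlm_features <- function(R, nr, np) {
  ng <- nrow(R); lmax <- ncol(R)
  sre <- 0; lre <- 0; lgre <- 0; hgre <- 0; srlge <- 0; srhge <- 0
  lrlge <- 0; lrhge <- 0
  for (i in 1:ng) for (j in 1:lmax) {
    rij <- R[i, j]
    sre <- sre + rij / j^2;  lre <- lre + rij * j^2
    lgre <- lgre + rij / i^2; hgre <- hgre + rij * i^2
    srlge <- srlge + rij / (i^2 * j^2); srhge <- srhge + rij * i^2 / j^2
    lrlge <- lrlge + rij * j^2 / i^2;   lrhge <- lrhge + rij * i^2 * j^2
  }
  gln <- 0
  for (i in 1:ng) gln <- gln + sum(R[i, ])^2
  rln <- 0
  for (j in 1:lmax) rln <- rln + sum(R[, j])^2
  c(rlm_sre = sre / nr, rlm_lre = lre / nr, rlm_gln = gln / nr, rlm_rln = rln / nr,
    rlm_rp = nr / np, rlm_lgre = lgre / nr, rlm_hgre = hgre / nr,
    rlm_srlge = srlge / nr, rlm_srhge = srhge / nr,
    rlm_lrlge = lrlge / nr, rlm_lrhge = lrhge / nr)
}

# Mann-Whitney pairwise AUC oracle (ties count one half)
bf_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small helpers used across test files
make_volume <- function(values, spacing = c(1, 1, 1), phase = "unenhanced") {
  ct_volume(array(values, dim = dim(values) %||% c(length(values), 1, 1)),
            spacing = spacing, phase = phase)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
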