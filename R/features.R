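#' Discretize ROI intensities to grey levels
#'
#' Maps raw in-ROI intensities to integer grey levels by relative (min-max
#' within ROI) resampling:
#' `level(x) = min(Ngrey, floor(Ngrey * (x - min) / (max - min)) + 1)`.
#' A uniform ROI (max = min) maps every voxel to level 1. Voxels outside the
#' mask carry the background sentinel 0. Because the rescaling is relative,
#' any strictly increasing affine transform of the intensities yields the
#' same levels, which makes all downstream texture features invariant to
#' scanner scale and offset.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param n_levels number of grey levels (default 64).
#' @return A `discretized_roi`: integer level array (0 outside the ROI),
#'   `n_levels`, and the source min/max used.
#' @export
discretize_roi <- function(volume, mask, n_levels = 64L) {
  check_geometry(volume, mask)
  check_nonempty(mask)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be >= 2")
  x <- volume$intensities[mask$voxels]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(mask$voxels))
  if (hi > lo) {
    lev[mask$voxels] <- pmin(n_levels,
                             as.integer(floor(n_levels * (x - lo) / (hi - lo))) + 1L)
  } else {
    lev[mask$voxels] <- 1L
  }
  structure(list(levels = lev, n_levels = n_levels, min = lo, max = hi),
            class = "discretized_roi")
}

# The 13 unique 3-D lattice directions at Chebyshev distance 1 (one of each
# antipodal pair).
all_directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  m <- d[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

feature_families <- function() {
  list(
    firstorder = c("min", "max", "mean", "std", "skewness", "kurtosis",
                   "entropy", "uniformity", "volume_voxels", "volume_ml",
                   "sphericity", "compacity"),
    glcm = c("homogeneity", "energy", "contrast", "correlation", "entropy",
             "dissimilarity"),
    glrlm = c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE",
              "LRHGE", "GLNU", "RLNU", "RP"),
    ngldm = c("coarseness", "contrast", "busyness"),
    glzlm = c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE",
              "LZHGE", "GLNU", "ZLNU", "ZP")
  )
}

#' First-order histogram and shape features
#'
#' Eight histogram statistics on the raw in-ROI intensities (`min`, `max`,
#' `mean`, population `std`, moment `skewness` m3/s^3 and `kurtosis` m4/s^4,
#' plus Shannon `entropy` in bits and `uniformity` computed on the
#' discretized 64-level histogram with 0*log(0) = 0), and four shape
#' descriptors: `volume_voxels`, `volume_ml` (voxel count times voxel volume
#' / 1000), `sphericity` = pi^(1/3) (6V)^(2/3) / A and `compacity` =
#' A^(3/2) / V, with the surface area A obtained by counting exposed voxel
#' faces weighted by their physical face area. Skewness and kurtosis are
#' undefined (missing) when the intensity spread is zero, including the
#' single-voxel ROI.
#'
#' @inheritParams discretize_roi
#' @return Named numeric vector of 12 values.
#' @export
first_order_features <- function(volume, mask, n_levels = 64L) {
  check_geometry(volume, mask)
  check_nonempty(mask)
  x <- volume$intensities[mask$voxels]
  n <- length(x)
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else NA_real_
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 else NA_real_
  dro <- discretize_roi(volume, mask, n_levels)
  p <- tabulate(dro$levels[mask$voxels], nbins = n_levels) / n
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  unif <- sum(p^2)
  sp <- volume$spacing_mm
  vol_mm3 <- n * prod(sp)
  area <- surface_area_mm2(mask$voxels, sp)
  c(min = min(x), max = max(x), mean = mu, std = s, skewness = skew,
    kurtosis = kurt, entropy = ent, uniformity = unif,
    volume_voxels = n, volume_ml = vol_mm3 / 1000,
    sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area,
    compacity = area^(3 / 2) / vol_mm3)
}

# Surface area by exposed-face counting: a face between an in-mask voxel and
# an out-of-mask (or out-of-bounds) neighbour contributes the physical area
# of that face.
surface_area_mm2 <- function(vox, spacing) {
  d <- dim(vox)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox
  faces <- 0
  areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
             spacing[1] * spacing[2])
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (a in 1:3) {
    s <- shifts[[a]]
    nb_pos <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
                  (2:(d[3] + 1)) + s[3], drop = FALSE]
    nb_neg <- pad[(2:(d[1] + 1)) - s[1], (2:(d[2] + 1)) - s[2],
                  (2:(d[3] + 1)) - s[3], drop = FALSE]
    faces <- faces + (sum(vox & !nb_pos) + sum(vox & !nb_neg)) * areas[a]
  }
  faces
}

#' Grey-level co-occurrence matrix features
#'
#' Co-occurrences of grey-level pairs at lattice distance 1 are accumulated
#' over all 13 unique 3-D directions (each pair counted in both
#' orientations, so the matrix is symmetric), pooled into a single matrix
#' and normalized to probabilities p(i, j). Returns homogeneity
#' sum p/(1+|i-j|), energy sum p^2, contrast sum (i-j)^2 p, correlation
#' sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j), entropy -sum p log2 p and
#' dissimilarity sum |i-j| p. With no neighbouring in-ROI pair all six are
#' missing; correlation is missing when the marginal variance is zero
#' (uniform ROI).
#'
#' @param droi a [discretize_roi()] result.
#' @param directions integer matrix of lattice offsets (rows); defaults to
#'   the 13 unique 3-D directions.
#' @return Named numeric vector of 6 values.
#' @export
glcm_features <- function(droi, directions = all_directions_3d()) {
  counts <- cpp_glcm_counts(droi$levels, droi$n_levels, directions)
  tot <- sum(counts)
  nm <- feature_families()$glcm
  if (tot == 0) return(setNames(rep(NA_real_, 6), nm))
  p <- counts / tot
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu_i <- sum(seq_len(nrow(p)) * pi_)
  sd_i <- sqrt(sum((seq_len(nrow(p)) - mu_i)^2 * pi_))
  corr <- if (sd_i > 0)
    sum((i - mu_i) * (j - mu_i) * p) / sd_i^2 else NA_real_
  pz <- p[p > 0]
  c(homogeneity = sum(p / (1 + abs(i - j))),
    energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    entropy = -sum(pz * log2(pz)),
    dissimilarity = sum(abs(i - j) * p))
}

#' Grey-level run-length matrix features
#'
#' Maximal collinear runs of equal grey level are counted along each of the
#' 13 unique 3-D directions and pooled into one matrix r(i, l) (level i,
#' length l). With N_r total runs and N_p in-ROI voxels, the classical
#' Galloway/Chu indices are returned; run percentage is
#' `RP = N_r / (n_directions * N_p)`, the pooled-direction analogue of
#' runs-per-voxel, so RP is 1 for a fully fragmented ROI and 1/L for a
#' single run of length L under one direction.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 values.
#' @export
glrlm_features <- function(droi, directions = all_directions_3d()) {
  r <- cpp_glrlm_counts(droi$levels, droi$n_levels, directions)
  n_run <- sum(r)
  n_vox <- sum(droi$levels > 0)
  p <- r / n_run
  i <- row(p); l <- col(p)
  c(SRE = sum(p / l^2), LRE = sum(p * l^2),
    LGRE = sum(p / i^2), HGRE = sum(p * i^2),
    SRLGE = sum(p / (i^2 * l^2)), SRHGE = sum(p * i^2 / l^2),
    LRLGE = sum(p * l^2 / i^2), LRHGE = sum(p * i^2 * l^2),
    GLNU = sum(rowSums(r)^2) / n_run,
    RLNU = sum(colSums(r)^2) / n_run,
    RP = n_run / (nrow(directions) * n_vox))
}

#' Neighbourhood grey-level difference matrix features
#'
#' For each in-ROI voxel the absolute difference between its level and the
#' mean level of its 26-neighbourhood (restricted to in-ROI voxels) is
#' accumulated per level into s(i); voxels with no in-ROI neighbour
#' contribute zero. With p_i the level probabilities, returns the
#' Amadasun-King coarseness `1 / (eps + sum p_i s_i)` (the small guard
#' `eps` keeps the uniform-ROI limit finite at 1/eps), contrast
#' `[sum_{i!=j} p_i p_j (i-j)^2 / (Ng (Ng-1))] * [sum s_i / N]` with Ng the
#' number of levels present (missing for a uniform ROI, where the first
#' factor is 0/0; note contrast scales with the cube of the label distance
#' in a two-level ROI, quadratically through (i-j)^2 and linearly through
#' s), and busyness `sum p_i s_i / sum_{i,j present} |i p_i - j p_j|`
#' (missing for a uniform ROI, whose denominator is zero).
#'
#' @inheritParams glcm_features
#' @param eps guard added to the coarseness denominator.
#' @return Named numeric vector of 3 values.
#' @export
ngldm_features <- function(droi, eps = 1e-6) {
  res <- cpp_ngldm_sums(droi$levels, droi$n_levels)
  s <- res$s
  cnt <- res$count
  n <- sum(cnt)
  p <- cnt / n
  present <- which(p > 0)
  coars <- 1 / (eps + sum(p * s))
  ng <- length(present)
  if (ng > 1) {
    ii <- outer(present, present, function(a, b) (a - b)^2)
    pp <- outer(p[present], p[present])
    contr <- (sum(pp * ii) / (ng * (ng - 1))) * (sum(s) / n)
    ip <- present * p[present]
    busy_den <- sum(abs(outer(ip, ip, `-`)))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else NA_real_
  } else {
    contr <- NA_real_
    busy <- NA_real_
  }
  c(coarseness = coars, contrast = contr, busyness = busy)
}

#' Grey-level zone length matrix features
#'
#' Zones are maximal 26-connected components of equal grey level; the matrix
#' z(i, s) counts zones of level i and size s. Indices mirror the run-length
#' family with zone size in place of run length; zone percentage is
#' `ZP = n_zones / N_p`, so a uniform ROI of V voxels has ZP = 1/V and a
#' checkerboard has ZP = 1.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 values.
#' @export
glzlm_features <- function(droi) {
  zones <- cpp_glzlm_zones(droi$levels, droi$n_levels)
  n_zone <- nrow(zones)
  n_vox <- sum(droi$levels > 0)
  lev <- zones[, 1]
  sz <- zones[, 2]
  c(SZE = mean(1 / sz^2), LZE = mean(sz^2),
    LGZE = mean(1 / lev^2), HGZE = mean(lev^2),
    SZLGE = mean(1 / (lev^2 * sz^2)), SZHGE = mean(lev^2 / sz^2),
    LZLGE = mean(sz^2 / lev^2), LZHGE = mean(lev^2 * sz^2),
    GLNU = sum(table(lev)^2) / n_zone,
    ZLNU = sum(table(sz)^2) / n_zone,
    ZP = n_zone / n_vox)
}

#' Extract the full per-ROI feature vector
#'
#' `extract_features()` computes the 43 features of one ROI on one sequence
#' (12 first-order/shape, 6 GLCM, 11 GLRLM, 3 NGLDM, 11 GLZLM), with names
#' `<family>_<feature>`. `extract_patient()` concatenates the vectors over
#' both sequences for both structures (86 per structure, 172 per patient),
#' prefixing names as `<structure>_<sequence>_<family>_<feature>`.
#' `extract_cohort()` stacks patients into a feature table. Undefined
#' feature values (degenerate ROIs) propagate as `NA`, never as silent
#' zeros.
#'
#' @inheritParams discretize_roi
#' @return `extract_features()`: named numeric vector of 43 values.
#' @export
extract_features <- function(volume, mask, n_levels = 64L) {
  fo <- first_order_features(volume, mask, n_levels)
  dro <- discretize_roi(volume, mask, n_levels)
  v <- c(fo, glcm_features(dro), glrlm_features(dro), ngldm_features(dro),
         glzlm_features(dro))
  fam <- feature_families()
  names(v) <- unlist(lapply(names(fam), function(f) paste(f, fam[[f]], sep = "_")),
                     use.names = FALSE)
  v
}

#' @rdname extract_features
#' @param patient a `synthetic_patient` or any list with `volumes` (named by
#'   sequence) and `masks` (named by structure).
#' @export
extract_patient <- function(patient, n_levels = 64L) {
  out <- numeric(0)
  for (st in names(patient$masks)) {
    for (sq in names(patient$volumes)) {
      v <- extract_features(patient$volumes[[sq]], patient$masks[[st]], n_levels)
      names(v) <- paste(st, sq, names(v), sep = "_")
      out <- c(out, v)
    }
  }
  out
}

#' @rdname extract_features
#' @param patients list of patients.
#' @return `extract_cohort()`: a feature table (data frame, `patient_id`
#'   plus 172 feature columns).
#' @export
extract_cohort <- function(patients, n_levels = 64L) {
  rows <- lapply(patients, extract_patient, n_levels = n_levels)
  mat <- do.call(rbind, rows)
  data.frame(patient_id = vapply(patients, `[[`, "", "patient_id"), mat,
             check.names = FALSE, row.names = NULL)
}

#' @rdname extract_features
#' @param table a feature table.
#' @param structure structure whose columns to keep.
#' @param sequence optionally restrict to one sequence.
#' @export
structure_columns <- function(table, structure, sequence = NULL) {
  prefix <- if (is.null(sequence)) paste0(structure, "_")
  else paste0(structure, "_", sequence, "_")
  feat <- setdiff(names(table), "patient_id")
  keep <- feat[startsWith(feat, prefix)]
  table[, c("patient_id", keep), drop = FALSE]
}
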