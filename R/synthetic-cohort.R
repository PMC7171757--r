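#' Specify a synthetic dual-sequence imaging cohort
#'
#' The generator emulates the kind of cohort the pipeline targets: for each
#' patient, two co-registered 3-D MR-like volumes (contrast-enhanced T1 and
#' T2), an ellipsoidal primary-tumour ROI and one involved-node ROI, and
#' right-censored outcomes for four endpoints (LC, RC, DMFS, OS). Texture
#' inside each ROI is a Gaussian random field: white noise smoothed by a
#' Gaussian kernel whose correlation length (voxels) and amplitude
#' ("contrast") vary per patient and per structure. Those four latent
#' parameters drive the hazards: the linear predictor of each endpoint is the
#' inner product of `effect_sizes[[endpoint]]` with the standardized latents,
#' on an exponential (or Weibull) baseline. By default LC hazards depend on
#' the tumour latents and RC/DMFS/OS on the node latents, so that the
#' qualitative contrast between tumour-based and node-based models is
#' recoverable by construction. Censoring is administrative: one uniform
#' censoring time per patient, with its upper bound calibrated numerically to
#' the requested overall censoring fraction.
#'
#' Latents are standardized using the known mean and standard deviation of
#' their uniform sampling ranges, so an effect size `b` yields a hazard ratio
#' of `exp(b * sqrt(12)/2)` across the latent's interquartile range.
#'
#' @param n_patients number of patients (>= 2).
#' @param volume_shape integer triple, voxels per array axis.
#' @param voxel_spacing_mm positive triple, mm per voxel per axis.
#' @param roi_radius_range_mm named list with elements `tumor` and `node`,
#'   each a (min, max) semi-axis range in mm.
#' @param texture_corr_length_range (min, max) Gaussian-field correlation
#'   length, in voxels.
#' @param texture_contrast_range (min, max) texture amplitude, in intensity
#'   units relative to the structure mean.
#' @param n_sequences number of MR sequences (2: T1CE and T2).
#' @param baseline_hazard_scale baseline time scale in months (exponential
#'   mean when all effects are zero).
#' @param hazard_model `"exponential"` or `"weibull"`.
#' @param weibull_shape shape parameter when `hazard_model = "weibull"`.
#' @param effect_sizes named list, one element per endpoint (`LC`, `RC`,
#'   `DMFS`, `OS`), each a named numeric vector of log-hazard coefficients on
#'   the standardized latents `tumor_contrast`, `tumor_corr_length`,
#'   `node_contrast`, `node_corr_length`.
#' @param censoring_rate target fraction censored, in [0, 1).
#' @param seed master integer seed; every random draw in the cohort flows
#'   from it through named child streams (one per patient, one for event
#'   times, one for censoring).
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 93L,
                        volume_shape = c(96L, 96L, 20L),
                        voxel_spacing_mm = c(1, 1, 5),
                        roi_radius_range_mm = list(tumor = c(8, 22),
                                                   node = c(4, 9)),
                        texture_corr_length_range = c(0.5, 2.5),
                        texture_contrast_range = c(0.2, 1.0),
                        n_sequences = 2L,
                        baseline_hazard_scale = 60,
                        hazard_model = c("exponential", "weibull"),
                        weibull_shape = 1,
                        effect_sizes = default_effect_sizes(),
                        censoring_rate = 0.3,
                        seed = 1L) {
  hazard_model <- match.arg(hazard_model)
  spec <- list(n_patients = as.integer(n_patients),
               volume_shape = as.integer(volume_shape),
               voxel_spacing_mm = as.numeric(voxel_spacing_mm),
               roi_radius_range_mm = roi_radius_range_mm,
               texture_corr_length_range = as.numeric(texture_corr_length_range),
               texture_contrast_range = as.numeric(texture_contrast_range),
               n_sequences = as.integer(n_sequences),
               baseline_hazard_scale = as.numeric(baseline_hazard_scale),
               hazard_model = hazard_model,
               weibull_shape = as.numeric(weibull_shape),
               effect_sizes = effect_sizes,
               censoring_rate = as.numeric(censoring_rate),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_effect_sizes <- function() {
  list(LC   = c(tumor_contrast = 0.9, tumor_corr_length = 0.6),
       RC   = c(node_contrast = 0.9, node_corr_length = 0.6),
       DMFS = c(node_contrast = 0.8, node_corr_length = 0.5),
       OS   = c(node_contrast = 0.8, node_corr_length = 0.5))
}

endpoint_names <- function() c("LC", "RC", "DMFS", "OS")
latent_names <- function() {
  c("tumor_contrast", "tumor_corr_length", "node_contrast", "node_corr_length")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 2L)
    stop("configuration error in 'n_patients': need at least 2 patients")
  if (length(spec$volume_shape) != 3L || any(spec$volume_shape < 4L))
    stop("configuration error in 'volume_shape': need a 3-D grid, >= 4 voxels per axis")
  if (any(spec$voxel_spacing_mm <= 0))
    stop("configuration error in 'voxel_spacing_mm': spacing must be positive")
  for (s in c("tumor", "node")) {
    r <- spec$roi_radius_range_mm[[s]]
    if (is.null(r) || length(r) != 2L || any(r <= 0) || r[2] < r[1])
      stop("configuration error in 'roi_radius_range_mm$", s,
           "': need a positive (min, max) range")
  }
  extent <- spec$volume_shape * spec$voxel_spacing_mm
  rt <- spec$roi_radius_range_mm$tumor[2]
  rn <- spec$roi_radius_range_mm$node[2]
  # tumour sits at the volume centre, node beside it along axis 1 (4 mm gap)
  if (any(2 * rt + 2 > extent) ||
      2 * rt + 4 * rn + 8 > extent[1] || any(2 * rn + 2 > extent[-1]))
    stop("configuration error in 'roi_radius_range_mm': ",
         "ROIs at maximum radius do not fit inside the volume")
  if (any(spec$texture_corr_length_range <= 0) ||
      diff(spec$texture_corr_length_range) < 0)
    stop("configuration error in 'texture_corr_length_range'")
  if (any(spec$texture_contrast_range <= 0) ||
      diff(spec$texture_contrast_range) < 0)
    stop("configuration error in 'texture_contrast_range'")
  if (spec$censoring_rate < 0 || spec$censoring_rate >= 1)
    stop("configuration error in 'censoring_rate': need a value in [0, 1)")
  if (spec$baseline_hazard_scale <= 0 || spec$weibull_shape <= 0)
    stop("configuration error in 'baseline_hazard_scale'/'weibull_shape'")
  es <- spec$effect_sizes
  if (!all(endpoint_names() %in% names(es)))
    stop("configuration error in 'effect_sizes': need entries for ",
         paste(endpoint_names(), collapse = ", "))
  for (ep in endpoint_names()) {
    v <- es[[ep]]
    if (length(v) && (!all(is.finite(v)) ||
                      !all(names(v) %in% latent_names())))
      stop("configuration error in 'effect_sizes$", ep,
           "': finite values named after latents required")
  }
  invisible(spec)
}

# Periodic Gaussian smoothing of white noise by FFT; sigma in voxels.
gaussian_random_field <- function(dim, sigma) {
  noise <- array(rnorm(prod(dim)), dim = dim)
  ax <- lapply(dim, function(n) {
    d <- 0:(n - 1)
    pmin(d, n - d)
  })
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  kern <- exp(-d2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    prod(dim)
  (f - mean(f)) / stats::sd(f)
}

# Ellipsoid in physical coordinates (voxel centres at (index - 0.5) * spacing).
ellipsoid_mask <- function(dim, spacing, center_mm, radii_mm) {
  ax <- lapply(1:3, function(a) ((seq_len(dim[a]) - 0.5) * spacing[a] -
                                   center_mm[a]) / radii_mm[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  array(d2 <= 1, dim = dim)
}

# mean/sd of U(a, b), used to standardize latents analytically
unif_standardize <- function(x, range) {
  (x - mean(range)) / (diff(range) / sqrt(12))
}

sequence_labels <- function(n) c("T1CE", "T2")[seq_len(n)]

# structure-specific mean intensity and texture multiplier per sequence
intensity_profile <- function() {
  list(T1CE = list(background = 40, tumor = 120, node = 110, mult = 1.0,
                   noise_sd = 4),
       T2   = list(background = 30, tumor = 80, node = 90, mult = 0.7,
                   noise_sd = 4))
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n_patients` patients from the generative model described in
#' [cohort_spec()]. Identical specs (including the seed) reproduce the cohort
#' bit-identically.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `synthetic_patient` objects, each with `volumes` (one
#'   [image_volume()] per sequence), `masks` (tumor and node [roi_mask()]),
#'   `latent_params` (the true texture parameters) and `outcomes` (one row
#'   per endpoint: `endpoint`, `time_months`, `event`). The spec is attached
#'   as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n_patients
  seeds <- child_seeds(spec$seed,
                       c(paste0("patient_", seq_len(n)), "survival", "censoring"))
  dims <- spec$volume_shape
  sp <- spec$voxel_spacing_mm
  extent <- dims * sp
  prof <- intensity_profile()
  seqs <- sequence_labels(spec$n_sequences)

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[[paste0("patient_", i)]])
    lat <- c(tumor_contrast = runif(1, spec$texture_contrast_range[1],
                                    spec$texture_contrast_range[2]),
             tumor_corr_length = runif(1, spec$texture_corr_length_range[1],
                                       spec$texture_corr_length_range[2]),
             node_contrast = runif(1, spec$texture_contrast_range[1],
                                   spec$texture_contrast_range[2]),
             node_corr_length = runif(1, spec$texture_corr_length_range[1],
                                      spec$texture_corr_length_range[2]))
    rad_t <- runif(3, spec$roi_radius_range_mm$tumor[1],
                   spec$roi_radius_range_mm$tumor[2])
    rad_n <- runif(3, spec$roi_radius_range_mm$node[1],
                   spec$roi_radius_range_mm$node[2])
    ctr_t <- extent / 2
    ctr_n <- ctr_t
    ctr_n[1] <- ctr_t[1] + rad_t[1] + rad_n[1] + 4   # 4 mm gap along axis 1
    mask_t <- ellipsoid_mask(dims, sp, ctr_t, rad_t)
    mask_n <- ellipsoid_mask(dims, sp, ctr_n, rad_n)
    mask_n <- mask_n & !mask_t
    field_t <- gaussian_random_field(dims, lat[["tumor_corr_length"]])
    field_n <- gaussian_random_field(dims, lat[["node_corr_length"]])

    volumes <- lapply(seqs, function(sq) {
      p <- prof[[sq]]
      # background mean scaled by texture amplitude relative to a 100-unit mean
      img <- array(p$background + rnorm(prod(dims), sd = p$noise_sd),
                   dim = dims)
      img[mask_t] <- p$tumor +
        p$mult * 100 * lat[["tumor_contrast"]] * field_t[mask_t]
      img[mask_n] <- p$node +
        p$mult * 100 * lat[["node_contrast"]] * field_n[mask_n]
      image_volume(img, sp, sq)
    })
    names(volumes) <- seqs

    patients[[i]] <- structure(
      list(patient_id = sprintf("P%03d", i),
           volumes = volumes,
           masks = list(tumor = roi_mask(mask_t, "tumor"),
                        node = roi_mask(mask_n, "node")),
           latent_params = lat,
           outcomes = NULL),
      class = "synthetic_patient")
  }

  # linear predictors per endpoint from standardized latents
  z <- vapply(patients, function(p) {
    c(unif_standardize(p$latent_params[["tumor_contrast"]],
                       spec$texture_contrast_range),
      unif_standardize(p$latent_params[["tumor_corr_length"]],
                       spec$texture_corr_length_range),
      unif_standardize(p$latent_params[["node_contrast"]],
                       spec$texture_contrast_range),
      unif_standardize(p$latent_params[["node_corr_length"]],
                       spec$texture_corr_length_range))
  }, numeric(4))
  rownames(z) <- latent_names()

  lp <- vapply(endpoint_names(), function(ep) {
    b <- spec$effect_sizes[[ep]]
    if (!length(b)) return(rep(0, n))
    colSums(z[names(b), , drop = FALSE] * b)
  }, numeric(n))
  if (n == 1L) lp <- matrix(lp, nrow = 1, dimnames = list(NULL, endpoint_names()))

  set.seed(seeds[["survival"]])
  times <- apply(lp, 2, function(l)
    draw_ph_times(l, spec$baseline_hazard_scale, spec$hazard_model,
                  spec$weibull_shape))
  set.seed(seeds[["censoring"]])
  cens <- draw_censoring(as.numeric(exp(lp)) / spec$baseline_hazard_scale,
                         spec$censoring_rate, n)

  for (i in seq_len(n)) {
    obs <- pmin(times[i, ], cens[i])
    patients[[i]]$outcomes <- data.frame(
      patient_id = patients[[i]]$patient_id,
      endpoint = endpoint_names(),
      time_months = as.numeric(obs),
      event = as.integer(times[i, ] <= cens[i]),
      row.names = NULL)
  }
  attr(patients, "spec") <- spec
  patients
}

# Inverse-transform sampling from a proportional-hazards Weibull:
# S(t) = exp(-(t/b)^k * exp(lp)); k = 1 is the exponential baseline.
draw_ph_times <- function(lp, scale, model, shape) {
  k <- if (model == "exponential") 1 else shape
  u <- runif(length(lp))
  scale * (-log(u) * exp(-lp))^(1 / k)
}

# One uniform administrative censoring time per patient on (0, tau); tau is
# calibrated so the expected censored fraction over the cohort's exponential
# rates equals `rate`. With rate = 0 no censoring is applied.
draw_censoring <- function(lambda, rate, n) {
  if (rate <= 0) return(rep(Inf, n))
  tau <- calibrate_censoring_tau(lambda, rate)
  runif(n, 0, tau)
}

calibrate_censoring_tau <- function(lambda, rate) {
  pc <- function(tau) mean((1 - exp(-lambda * tau)) / (lambda * tau)) - rate
  # pc is decreasing in tau from 1 - rate ... find bracketing interval
  lo <- 1e-6; hi <- 1e6
  uniroot(pc, c(lo, hi), tol = 1e-8)$root
}

#' @rdname generate_cohort
#' @param patients a list of `synthetic_patient`s.
#' @return `cohort_outcomes()`: long data frame with one row per patient per
#'   endpoint.
#' @export
cohort_outcomes <- function(patients) {
  do.call(rbind, lapply(patients, `[[`, "outcomes"))
}

#' @rdname generate_cohort
#' @param dir output directory; one NIfTI per sequence and per mask per
#'   patient plus `outcomes.csv`.
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in patients) {
    for (sq in names(p$volumes))
      write_volume(p$volumes[[sq]],
                   file.path(dir, sprintf("%s_%s.nii.gz", p$patient_id, sq)))
    for (st in names(p$masks))
      write_mask(p$masks[[st]],
                 file.path(dir, sprintf("%s_mask_%s.nii.gz", p$patient_id, st)),
                 spacing_mm = p$volumes[[1]]$spacing_mm)
  }
  write_outcomes(cohort_outcomes(patients), file.path(dir, "outcomes.csv"))
  invisible(dir)
}

#' Fast tabular cohort: features plus survival outcomes, no images
#'
#' Bypasses image synthesis for testing the selection, modelling and
#' evaluation stages. Features are multivariate normal with an AR(1)
#' correlation structure (`cor(f_i, f_j) = rho^|i-j|`); the log hazard is
#' linear in the first `length(effect_sizes)` features on an exponential
#' baseline; censoring is uniform administrative, calibrated as in
#' [generate_cohort()].
#'
#' @param n_patients,n_features table dimensions; `n_features` must be at
#'   least `length(effect_sizes)`.
#' @param effect_sizes numeric vector of log-hazard coefficients for the
#'   informative features (may be empty for a pure-noise cohort).
#' @param censoring_rate target censored fraction in [0, 1).
#' @param seed integer seed.
#' @param rho AR(1) feature correlation.
#' @param baseline_hazard_scale exponential baseline scale, months.
#' @param endpoint endpoint label attached to the outcomes.
#' @return list with `features` (data frame, `patient_id` + `f001`...) and
#'   `outcomes` (long outcome table).
#' @export
generate_feature_cohort <- function(n_patients, n_features,
                                    effect_sizes = numeric(),
                                    censoring_rate = 0.2, seed = 1L,
                                    rho = 0.3, baseline_hazard_scale = 36,
                                    endpoint = "OS") {
  if (n_patients < 2L) stop("validation error: 'n_patients' must be >= 2")
  if (n_features < length(effect_sizes) || n_features < 1L)
    stop("validation error: 'n_features' must cover all effect sizes")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("validation error: 'censoring_rate' must be in [0, 1)")
  seeds <- child_seeds(seed, c("features", "survival", "censoring"))
  set.seed(seeds[["features"]])
  sigma <- rho^abs(outer(seq_len(n_features), seq_len(n_features), `-`))
  x <- matrix(rnorm(n_patients * n_features), n_patients) %*% chol(sigma)
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  lp <- if (length(effect_sizes))
    as.numeric(x[, seq_along(effect_sizes), drop = FALSE] %*% effect_sizes)
  else rep(0, n_patients)
  set.seed(seeds[["survival"]])
  times <- draw_ph_times(lp, baseline_hazard_scale, "exponential", 1)
  set.seed(seeds[["censoring"]])
  cens <- draw_censoring(exp(lp) / baseline_hazard_scale, censoring_rate,
                         n_patients)
  ids <- sprintf("P%03d", seq_len(n_patients))
  list(features = data.frame(patient_id = ids, x, check.names = FALSE),
       outcomes = data.frame(patient_id = ids, endpoint = endpoint,
                             time_months = pmin(times, cens),
                             event = as.integer(times <= cens)))
}

#' Randomly split a cohort into training and validation sets
#'
#' Simple (unstratified) random split; the training size is
#' `round(train_fraction * n)`, so 93 patients at a 2/3 fraction give the
#' 62/31 partition used throughout.
#'
#' @param x a list of patients or a data frame with one row per patient.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train`, `validation` (same type as `x`) and
#'   the index vectors `train_idx`, `validation_idx`.
#' @export
split_cohort <- function(x, train_fraction = 2 / 3, seed = 1L) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("validation error: 'train_fraction' must be in (0, 1)")
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop("validation error: split would leave an empty group")
  set.seed(seed)
  idx <- sample.int(n, n_train)
  take <- function(obj, i) if (is.data.frame(obj)) obj[i, , drop = FALSE] else obj[i]
  list(train = take(x, sort(idx)),
       validation = take(x, setdiff(seq_len(n), idx)),
       train_idx = sort(idx),
       validation_idx = setdiff(seq_len(n), idx))
}
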