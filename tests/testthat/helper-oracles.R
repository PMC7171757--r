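# Pure-R brute-force oracles for the texture matrices, written as naive
# enumerations independent of the package's compiled kernels.

make_droi <- function(levels, n_levels = max(levels)) {
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 min = NA_real_, max = NA_real_),
            class = "discretized_roi")
}

in_bounds <- function(i, d) all(i >= 1L) && all(i <= d)

oracle_glcm_counts <- function(levels, ng, dirs) {
  d <- dim(levels)
  out <- matrix(0, ng, ng)
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      a <- levels[x, y, z]
      if (a == 0) next
      q <- c(x, y, z) + dd
      if (!in_bounds(q, d)) next
      b <- levels[q[1], q[2], q[3]]
      if (b == 0) next
      out[a, b] <- out[a, b] + 1
      out[b, a] <- out[b, a] + 1
    }
  }
  out
}

oracle_glrlm_counts <- function(levels, ng, dirs) {
  d <- dim(levels)
  maxlen <- max(d)
  out <- matrix(0, ng, maxlen)
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      a <- levels[x, y, z]
      if (a == 0) next
      p <- c(x, y, z) - dd
      if (in_bounds(p, d) && levels[p[1], p[2], p[3]] == a) next  # not a start
      len <- 1
      q <- c(x, y, z) + dd
      while (in_bounds(q, d) && levels[q[1], q[2], q[3]] == a) {
        len <- len + 1
        q <- q + dd
      }
      out[a, len] <- out[a, len] + 1
    }
  }
  out
}

oracle_ngldm_sums <- function(levels, ng) {
  d <- dim(levels)
  s <- numeric(ng)
  cnt <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- levels[x, y, z]
    if (a == 0) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(q, d)) next
      b <- levels[q[1], q[2], q[3]]
      if (b > 0) nb <- c(nb, b)
    }
    cnt[a] <- cnt[a] + 1
    if (length(nb)) s[a] <- s[a] + abs(a - mean(nb))
  }
  list(s = s, count = cnt)
}

# zone sizes via iterative min-label propagation over the 26-neighbourhood
oracle_glzlm_zones <- function(levels) {
  d <- dim(levels)
  lab <- array(seq_along(levels), dim = d)
  lab[levels == 0] <- NA
  repeat {
    changed <- FALSE
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      if (is.na(lab[x, y, z])) next
      a <- levels[x, y, z]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        q <- c(x + dx, y + dy, z + dz)
        if (!in_bounds(q, d)) next
        if (is.na(lab[q[1], q[2], q[3]])) next
        if (levels[q[1], q[2], q[3]] != a) next
        if (lab[q[1], q[2], q[3]] < lab[x, y, z]) {
          lab[x, y, z] <- lab[q[1], q[2], q[3]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  zones <- table(lab[!is.na(lab)])
  data.frame(level = levels[as.integer(names(zones))],
             size = as.integer(zones))
}

# a small cohort spec used across tests: tiny volumes, fast to generate
small_cohort_spec <- function(n_patients, seed, ...) {
  cohort_spec(n_patients = n_patients,
              volume_shape = c(40L, 40L, 20L),
              voxel_spacing_mm = c(1.5, 1.5, 3),
              roi_radius_range_mm = list(tumor = c(7, 11), node = c(4, 7)),
              seed = seed, ...)
}

# wrap a plain array as a unit-spacing volume/mask pair
toy_volume <- function(arr, spacing = c(1, 1, 1), sequence = "T1CE") {
  image_volume(arr, spacing, sequence)
}
toy_mask <- function(arr, structure = "tumor") roi_mask(arr, structure)
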