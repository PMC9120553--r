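# Shared fixtures: tiny grids, parcels and timecourses built in code.

tiny_grid <- function(dim = c(6L, 6L, 6L), voxel_mm = 2) {
  default_grid(dim, voxel_mm)
}

cube_parcel <- function(dim = c(6L, 6L, 6L), from = 2, to = 4,
                        label = "cube") {
  m <- array(FALSE, dim = dim)
  m[from:to, from:to, from:to] <- TRUE
  parcel(m, label = label)
}

# single-region synthetic voxel matrix: planted voxels carry `signal`,
# the rest pure noise
planted_matrix <- function(nvox, planted_rows, signal, noise_sd = 0,
                           seed = 1) {
  T_ <- length(signal)
  withr::with_seed(seed, {
    Y <- matrix(rnorm(nvox * T_, sd = noise_sd), nvox, T_)
    Y[planted_rows, ] <- Y[planted_rows, , drop = FALSE] +
      rep(signal, each = length(planted_rows))
    Y
  })
}

# small two-group cohort on disk, cached per test session
small_cohort_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache) || !dir.exists(cache)) {
      dir <- file.path(tempdir(), "movieroi_small_cohort")
      if (!dir.exists(dir)) {
        cc <- cohort_config(
          groups = list(adult = list(n = 4, ages = rep(25, 4)),
                        threeyo = list(n = 3, ages = c(3.1, 3.4, 3.8))),
          seed = 42)
        generate_cohort(cc, dir)
      }
      cache <<- dir
    }
    cache
  }
})
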