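# Small configurations and hand-built objects shared across tests.

eye_affine <- function(vox = 3) diag(c(vox, vox, vox, 1))

# Tiny three-region study: 10x10x8 grid, radius-2 spheres.
tiny_config <- function(seed = 1, n_patients = 6, n_controls = 6,
                        n_volumes = 80, ...) {
  synthetic_config(
    n_patients = n_patients, n_controls = n_controls,
    grid_shape = c(10L, 10L, 8L), n_volumes = n_volumes,
    region_specs = list(
      list(name = "r_ofc", center = c(3, 3, 4), radius = 2),
      list(name = "l_ofc", center = c(8, 3, 4), radius = 2),
      list(name = "r_putamen", center = c(5, 8, 4), radius = 2)),
    seed = seed, ...)
}

# A deterministic bold series from plain rnorm data.
toy_bold <- function(nx = 4, ny = 4, nz = 3, nt = 40, tr = 2, seed = 42,
                     vox = 3) {
  set.seed(seed)
  bold_series(array(rnorm(nx * ny * nz * nt), dim = c(nx, ny, nz, nt)),
              affine = eye_affine(vox), tr_seconds = tr,
              subject_id = "toy")
}

# A block mask covering an interior box of the toy grid.
toy_mask <- function(nx = 4, ny = 4, nz = 3, vox = 3) {
  lab <- array(0L, dim = c(nx, ny, nz))
  lab[1:nx, 1:ny, 1:nz] <- 1L
  network_mask(lab, eye_affine(vox), c("1" = "box"))
}

toy_motion <- function(nt, scale = 0.05, seed = 7) {
  set.seed(seed)
  motion_params(apply(matrix(rnorm(nt * 3), nt, 3) * scale, 2, cumsum),
                apply(matrix(rnorm(nt * 3), nt, 3) * scale / 100, 2,
                      cumsum))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
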