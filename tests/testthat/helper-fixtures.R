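# Shared fixtures, memoized so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_phantom <- function(seed = 1, grid = 48, voxel_size = 1.0,
                            noise_sd = 4, bias = 0.05) {
  key <- paste("ph", seed, grid, voxel_size, noise_sd, bias, sep = "_")
  memo(key, generate_phantom(phantom_spec(
    grid_shape = rep(grid, 3), voxel_size = voxel_size,
    noise_sd = noise_sd, bias_amplitude = bias, seed = seed)))
}

# a small untrained denoiser: inference-path tests (conservation, shapes,
# determinism) do not depend on training quality
fixture_tiny_model <- function() {
  memo("tiny_model", build_denoiser(
    vinn_config(slab_thickness = 7, base_channels = 4, depth = 2,
                time_embedding_dim = 8), seed = 11))
}

fixture_schedule <- function(T_steps = 20) {
  memo(paste0("sched_", T_steps), build_schedule(T_steps))
}

# fan mesh: center vertex 1 connected to a ring of n outer vertices
fan_mesh <- function(n = 6) {
  ang <- 2 * pi * seq_len(n) / n
  vertices <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0))
  faces <- cbind(1L, 1L + seq_len(n), 1L + c(seq_len(n)[-1], 1L))
  structure(list(vertices = vertices, faces = faces, affine = diag(4)),
            class = "surface_mesh")
}

random_small_mask <- function(d = c(12, 12, 12), n = 60) {
  m <- array(0, d)
  m[sample(prod(d), n)] <- 1
  m
}
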