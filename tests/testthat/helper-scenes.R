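# Shared small simulation scenes, built once per test run.

scene_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = scene_cache)) assign(key, builder(), envir = scene_cache)
  get(key, envir = scene_cache)
}

# 48^2 disc acquisition, 4 coils, fully sampled, noiseless
scene_2d <- function() cached("scene_2d", function() {
  traj <- make_uniform_spokes_2d(152, 48, oversampling = 2)
  image <- make_disc_phantom(48, 15, 7)
  make_scene(image, traj, n_coils = 4, seed = 1, nufft_width = 6)
})

# single-coil real symmetric 2D scene with a uniform receive profile (the
# real-part objective of Stoch-Olejniczak presumes an essentially real object)
scene_2d_1coil <- function() cached("scene_2d_1coil", function() {
  traj <- make_uniform_spokes_2d(152, 48, oversampling = 2)
  image <- make_disc_phantom(48, 15, 7)
  maps <- sensitivity_maps(array(1 + 0i, c(48, 48, 1)))
  plan <- nufft_plan(traj_coords(traj), c(48, 48))
  list(image = image, maps = maps, traj = traj,
       clean_kspace = simulate_kspace(image, maps, traj, plan = plan),
       nufft_width = 6)
})

gap_error <- function(filled, clean, gidx) {
  sqrt(sum(Mod(filled$data[, gidx, ] - clean$data[, gidx, ])^2)) /
    sqrt(sum(Mod(clean$data[, gidx, ])^2))
}

# exact centered DFT helpers mirroring the package's k-space convention,
# rebuilt here independently for oracle use
oracle_dft_1d <- function(n) {
  nc <- n %/% 2
  outer(0:(n - 1), 0:(n - 1),
        function(j, m) exp(-2i * pi * (j - nc) * (m - nc) / n))
}
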