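# shared fixtures, generated in code; cached so several files can reuse the
# same phantom without regenerating it
.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, force(expr), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

# 32^3 study-in-miniature used by unit tests (full-size 64^3 phantoms are
# exercised in the acceptance suite)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(32, 32, 32),
         lesion_centre_mm = c(20, 18, 16),
         lesion_radius_mm = 6, core_radius_mm = 3,
         perturb_rotation_deg = c(1, -0.8, 0.5),
         perturb_translation_mm = c(1.5, -1, 0.8)),
    list(...))
  do.call(phantom_spec, args)
}

small_case <- function() cached("small", generate_phantom(small_spec()))

light_reg <- function() registration_params(levels = 2, max_iters = 80,
                                            sampling = 0.5)
light_ga <- function(seed = 42L) ga_params(population = 20, generations = 30,
                                           seed = seed)

# a qe_map whose membership values equal `arr` (theta_low = 0, theta_high = 1
# makes the fuzzifier the identity on [0, 1])
qem_of <- function(arr, spacing = c(1, 1, 1)) {
  pre <- image_volume(array(0, dim(arr)), spacing)
  post <- image_volume(arr, spacing)
  compute_qem(pre, post, fuzz_params(0, 1))
}

# a run_config wired for the 32^3 miniature study
small_config <- function(case, seed = 7L, agents = c("agent1", "agent2"),
                         patient = 1L) {
  run_config(case$pre1, case$post1, case$pre2, case$post2, case$lesion,
             agents = agents, patient = patient,
             bias = bias_params(grid_mm = 16), reg = light_reg(),
             ga = light_ga(), seed = seed)
}
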