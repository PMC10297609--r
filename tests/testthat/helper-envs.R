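# Hand-built environment realisations for geometric oracles.

make_env <- function(spheroids, spec = arena_spec(), alpha = NA_real_,
                     vf = NA_real_) {
  structure(list(spec = spec, spheroids = spheroids,
                 alpha_measured = alpha, vf_astro_measured = vf,
                 n_points = NA_real_, seed_used = 0),
            class = "glu_env")
}

empty_env <- function(edge_um = 4) {
  make_env(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          r = numeric(),
                          role = factor(character(),
                                        levels = c("neuronal", "astroglial"))),
           spec = arena_spec(edge_um = edge_um, alpha = 1, vf_astro = 0),
           alpha = 1, vf = 0)
}

sphere_env <- function(x, y, z, r, role = "neuronal", edge_um = 4,
                       alpha_target = 0.99) {
  make_env(tibble::tibble(x = x, y = y, z = z, r = r,
                          role = factor(role,
                                        levels = c("neuronal", "astroglial"))),
           spec = arena_spec(edge_um = edge_um, alpha = alpha_target,
                             vf_astro = 1 - alpha_target))
}

# distance from a point to the cleft capsule axis segment |z| <= hz
capsule_axis_dist <- function(x, y, z, hz) {
  dz <- pmax(abs(z) - hz, 0)
  sqrt(x^2 + y^2 + dz^2)
}
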