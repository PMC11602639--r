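# Shared fixtures, generated in code. Small phantoms keep the suite fast
# while preserving the geometry that matters: a bright asymmetric shell on a
# dark background at 2 mm isotropic resolution.

tiny_phantom <- function(shape = c(32, 32, 32), noise_sd = 0, seed = 1L) {
  generate_phantom(phantom_spec(shape = shape, spacing = 2,
                                noise_sd = noise_sd, seed = seed))
}

# an asymmetric test block useful for exact-rotation checks
asym_block <- function(n = 16) {
  a <- array(0, dim = c(n, n, n))
  a[2:5, 2:3, 2:8] <- 1
  a[9:12, 3:10, 4:6] <- 2
  a[4, 12, 10] <- 5
  volume3d(a, 1)
}

random_transform_list <- function(n, range = 15, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    sample_random_transform(range, 2)))
}
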