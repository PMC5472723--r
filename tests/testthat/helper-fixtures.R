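## Shared fixtures, built in code at test time.

## tiny deterministic movie
tiny_movie <- function(T = 12, H = 6, W = 6, seed = 1) {
  with_seed_test(seed, stimulus_movie(array(rnorm(T * H * W), c(T, H, W))))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## random small symmetric matrix
rand_sym <- function(P, sd = 1, seed = 1) {
  with_seed_test(seed, {
    m <- matrix(rnorm(P * P, sd = sd), P, P)
    (m + t(m)) / 2
  })
}

## random small qc_params consistent with a design
rand_params <- function(P, K, seed = 1, quadratic = TRUE) {
  with_seed_test(seed, {
    J <- if (quadratic) rand_sym(P, sd = 0.05, seed = seed + 1)
         else matrix(0, P, P)
    qc_params(a1 = rnorm(1, sd = 0.3), v1 = rnorm(P, sd = 0.1), J = J,
              v2 = rnorm(K, sd = 0.5), a2 = rnorm(1, sd = 0.3),
              d = runif(1, 0.5, 2))
  })
}

## brute-force grid size: enumerate valid top-left offsets
brute_grid <- function(H, patch, stride) {
  sum(vapply(0:max(0, H - patch), function(o)
    (o %% stride == 0) && (o + patch <= H), logical(1)))
}
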