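# Shared fixtures: small cached pipeline-stage runs reused across test files
# (computed lazily, once per test session).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

small_stage1 <- function() {
  cached("stage1", run_stage1(source_spec(), slab_geometry(), 8000, seed = 7))
}

small_stage2_pt <- function() {
  cached("stage2_pt",
         run_stage2(small_stage1(), np_spec("Pt"), beam_mode("equilibrium"),
                    resamples = 1, seed = 11))
}

small_stage2_water <- function() {
  cached("stage2_water",
         run_stage2(small_stage1(), np_spec("water"), beam_mode("equilibrium"),
                    resamples = 1, seed = 11))
}

random_records <- function(n, seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  data.frame(kind = sample(c("photon", "electron"), n, replace = TRUE),
             energy_eV = stats::runif(n, 200, 662e3),
             x_nm = stats::rnorm(n, 0, 1e5),
             y_nm = stats::rnorm(n, 0, 1e5),
             z_nm = stats::rnorm(n, 0, 1e5),
             ux = u[, 1], uy = u[, 2], uz = u[, 3],
             weight = stats::runif(n, 0.1, 2),
             history = sample.int(n, n))
}
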