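# Phantom fixtures are built in code and cached per test run; the small
# configuration (128 matrix, 2 slices) keeps unit tests fast while the
# full-size study configuration is reserved for the acceptance checks.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.phantom_cache[[key]])) .phantom_cache[[key]] <- builder()
  .phantom_cache[[key]]
}

small_spec <- function(group = "reperfused", ...) {
  phantom_spec(group, matrix_size = c(128L, 128L), n_slices = 2L,
               seed = 4242L, ...)
}

small_truth <- function(group = "reperfused") {
  cached(paste0("small-", group),
         function() build_phantom(small_spec(group)))
}

full_truth <- function(group = "reperfused") {
  cached(paste0("full-", group),
         function() build_phantom(phantom_spec(group, seed = 777L)))
}

# independent re-implementation of the sample mean/sd for oracle use
direct_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)), n = n)
}
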