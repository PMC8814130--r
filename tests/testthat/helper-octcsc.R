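# Shared fixtures: desk-scale synthetic volumes (64 x 128 raw images with
# the proportional "tiny" preprocessing preset) and a compact SIP
# configuration, so unit tests stay fast while exercising real code paths.

tiny_sp <- function(...)
  synth_params(image_height = 64, image_width = 128, ...)

tiny_pp <- function() preprocess_params(preset = "tiny")

quick_sip <- function(...)
  sip_spec(head_widths = c(32L, 16L, 8L, 3L), channels = c(4L, 8L, 8L, 8L),
           dropout_rate = 0.2, ...)

# memoised tiny dataset shared across test files
.fixture_env <- new.env(parent = emptyenv())

tiny_cases <- function(n_per_class = 4, seed = 1234) {
  key <- paste0("cases_", n_per_class, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_dataset(n_per_class, n_per_class,
                                            n_per_class, tiny_sp(),
                                            seed = seed)
  .fixture_env[[key]]
}

# independent first-principles kappa from raw label vectors (not via the
# package's confusion-matrix route)
kappa_brute <- function(actual, predicted) {
  labs <- c("acute", "chronic", "normal")
  po <- mean(actual == predicted)
  pe <- 0
  for (l1 in labs) pe <- pe + mean(actual == l1) * mean(predicted == l1)
  (po - pe) / (1 - pe)
}
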