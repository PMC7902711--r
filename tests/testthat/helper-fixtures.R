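# Shared fixtures, all built in code.

# A trimmed trial: one species, two tissues, a handful of classes. Keeps the
# heavier model tests fast while exercising the same code paths.
small_design <- function(classes = c("control_D10", "control_D22",
                                     "-N", "-K", "-Fe", "-Zn", "-Na"),
                         n_replicates = 5) {
  build_design(
    classes = classes,
    species = "rapeseed",
    tissues = list(rapeseed = c("roots", "YLB")),
    n_replicates = n_replicates
  )
}

small_table <- function(seed = 1, noise_sigma = 0.15, design = small_design(),
                        ...) {
  generate_ionome(
    design,
    default_effects(design, "rapeseed", noise_sigma = noise_sigma, ...),
    seed = seed
  )
}

# Three well-separated Gaussian blobs in 5 dimensions: linearly separable,
# so a 2-component PLS-DA must classify them perfectly.
separable_blobs <- function(n_per = 10, seed = 42) {
  withr::with_seed(seed, {
    centers <- rbind(
      c(10, 0, 0, 0, 0),
      c(0, 10, 0, 0, 0),
      c(0, 0, 10, 0, 0)
    )
    X <- do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(rnorm(n_per * 5, sd = 0.3), n_per, 5), 2, centers[k, ], "+")
    }))
    colnames(X) <- paste0("V", 1:5)
    list(X = X, classes = rep(c("a", "b", "c"), each = n_per))
  })
}
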