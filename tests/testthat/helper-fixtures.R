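# Shared fixtures: small working size keeps the suite fast; ROI geometry
# scales with the image automatically.

test_params <- function(...) {
  gen_params(image_size = c(200, 300), ...)
}

# planted-feature table: 38 features named like the layer-2 vector, two of
# which (5 and 20) carry a class shift of the given effect size
planted_table <- function(seed, n = 200, effect = 1.5, informative = c(5, 20)) {
  set.seed(seed)
  p <- 38
  y <- rep(c("P", "F"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, informative[1]] <- X[, informative[1]] + ifelse(y == "P", effect, 0)
  X[, informative[2]] <- X[, informative[2]] - ifelse(y == "P", effect, 0)
  colnames(X) <- daqu_feature_names("L2")
  feature_table(X, y)
}

planted_feature_names <- function(informative = c(5, 20)) {
  daqu_feature_names("L2")[informative]
}

# tiny linearly separable two-feature table
separable_table <- function(seed = 1, n = 40) {
  set.seed(seed)
  y <- rep(c("P", "F"), each = n / 2)
  X <- cbind(f1 = rnorm(n, ifelse(y == "P", 3, -3), 0.5),
             f2 = rnorm(n, 0, 1))
  feature_table(X, y)
}

# memoized corpora so expensive generation is shared across tests in a file
local({
  cache <- new.env(parent = emptyenv())
  corpus_cache <<- function(key, builder) {
    if (!exists(key, envir = cache)) assign(key, builder(), envir = cache)
    get(key, envir = cache)
  }
})

test_corpus <- function(n_per_grade = 10, seed = 7, params = test_params()) {
  corpus_cache(sprintf("corpus_%d_%d_%s", n_per_grade, seed,
                       paste(params$image_size, collapse = "x")),
               function() generate_dataset(n_per_grade, params, seed))
}
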