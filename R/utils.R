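# internal helpers shared across modules

# derive a reproducible child seed (< 2^31) from a base seed and a stream index
deriveSeed <- function(seed, k) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + 101 * as.numeric(k)
  as.integer(x %% 2147483629)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# balanced (inverse-frequency) class weights: n / (k * n_c)
balancedClassWeights <- function(y) {
  tab <- table(y)
  w <- as.numeric(length(y) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

zStats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1  # constant columns pass through untouched
  list(center = ctr, scale = scl)
}

zApply <- function(X, stats) {
  sweep(sweep(X, 2, stats$center, "-"), 2, stats$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopInput <- function(...) stop(sprintf(...), call. = FALSE)
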