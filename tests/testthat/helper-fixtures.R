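# Shared fixtures, generated in code.

toy_dataset <- function() {
  expression_dataset(
    matrix(c(1, 2, 3, 4, 5, 7), nrow = 3,
           dimnames = list(c("g1", "g2", "g3"), c("sA", "sB"))),
    labels = c(1L, -1L)
  )
}

# A well-separated balanced 2-D design for exact-prediction checks.
separable_2d <- function() {
  x <- cbind(c(2, 2), c(3, 3), c(-2, -2), c(-3, -3))
  list(x = x, y = c(1, 1, -1, -1))
}

# Standardized random matrix: p features x m samples.
random_standardized <- function(p, m, seed = 1) {
  set.seed(seed)
  standardize_samples(matrix(rnorm(p * m), p, m))
}

skew_fixture <- function(seed = 1) {
  generate_dataset(preset_spec("skew_1to4", seed = seed))
}

expect_tbl_near <- function(tbl, col, value, tol = 1e-10) {
  expect_equal(tbl[[col]], value, tolerance = tol)
}
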