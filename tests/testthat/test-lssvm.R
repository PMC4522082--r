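# Independent oracle: block elimination of the bordered system.
# With S = K + I/C, b = (1' S^-1 y) / (1' S^-1 1) and alpha = S^-1 (y - b 1).
lssvm_oracle <- function(Kmat, y, C = 1) {
  S <- Kmat + diag(length(y)) / C
  Sy <- solve(S, y)
  S1 <- solve(S, rep(1, length(y)))
  b <- sum(Sy) / sum(S1)
  list(b = b, alpha = drop(solve(S, y - b)))
}

test_that("identity-kernel training has the closed-form solution", {
  # K = I, labels (+1,+1,+1,-1), C = 1: b = mean(y), alpha_i = (y_i - b)/2
  y <- c(1, 1, 1, -1)
  sol <- lssvm_solve(diag(4), y, C = 1)
  expect_equal(sol$b, 0.5)
  expect_equal(sol$alpha, (y - 0.5) / 2)
  expect_equal(sum(sol$alpha), 0, tolerance = 1e-12)
})

test_that("a symmetric pair under the linear kernel gives zero intercept", {
  x <- cbind(c(1, 2, -1), c(-1, -2, 1))
  model <- lssvm_train(x, c(1, -1))
  expect_equal(model$bias, 0, tolerance = 1e-12)
  expect_equal(model$alphas, -rev(model$alphas), tolerance = 1e-12)
})

test_that("the dual solve matches the block-elimination oracle", {
  set.seed(11)
  for (trial in 1:8) {
    m <- sample(3:30, 1)
    G <- matrix(rnorm(m * m), m)
    Kmat <- crossprod(G) / m  # PSD kernel matrix
    y <- sample(c(-1, 1), m, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- runif(1, 0.2, 5)
    sol <- lssvm_solve(Kmat, y, C)
    ref <- lssvm_oracle(Kmat, y, C)
    expect_equal(sol$b, ref$b, tolerance = 1e-8)
    expect_equal(sol$alpha, ref$alpha, tolerance = 1e-8)
    expect_equal(sum(sol$alpha), 0, tolerance = 1e-8)
  }
})

test_that("multipliers always sum to zero across kernels", {
  x <- random_standardized(25, 12, seed = 7)
  y <- rep(c(1, -1), 6)
  for (fam in c("linear", "rbf", "quad", "mlp")) {
    model <- lssvm_train(x, y, spec = kernel_spec(fam))
    expect_equal(sum(model$alphas), 0, tolerance = 1e-8)
  }
})

test_that("identity Gram makes off-support predictions the majority vote", {
  # the overfitting-bias mechanism: an orthogonal-sample model predicts any
  # distant sample at the intercept b = mean(y)
  m <- 20
  y <- c(rep(1, 15), rep(-1, 5))
  xs <- standardize_samples(diag(m))  # near-orthogonal standardized columns
  model <- lssvm_train(xs, y, spec = kernel_spec("rbf"))
  expect_equal(model$gram_structure, "identity_like")
  expect_equal(model$bias, mean(y), tolerance = 1e-6)
  # a new sample far from all training samples decides at b
  set.seed(1)
  far <- standardize_samples(matrix(rnorm(m), m, 1))
  expect_equal(decision_values(model, far), mean(y), tolerance = 1e-3)
  expect_equal(predict(model, far), 1L)
  # training points: decision = b + alpha_i
  d_tr <- decision_values(model, xs)
  expect_equal(d_tr, model$bias + model$alphas, tolerance = 1e-6)
})

test_that("monotone skew: with K = I the intercept is the label mean", {
  for (n_pos in c(3, 6, 9)) {
    y <- c(rep(1, n_pos), rep(-1, 2))
    sol <- lssvm_solve(diag(length(y)), y)
    expect_equal(sol$b, mean(y), tolerance = 1e-10)
  }
  b_vals <- sapply(c(3, 6, 9), function(n_pos) {
    lssvm_solve(diag(n_pos + 2), c(rep(1, n_pos), rep(-1, 2)))$b
  })
  expect_true(all(diff(b_vals) > 0))
})

test_that("prediction recovers a separable toy exactly with zero tie to +1", {
  sep <- separable_2d()
  model <- lssvm_train(sep$x, sep$y)
  expect_equal(predict(model, sep$x), c(1L, 1L, -1L, -1L))
  expect_equal(decision_values(model, matrix(0, 2, 0)), numeric(0))
  expect_error(decision_values(model, matrix(0, 3, 1)), "mismatch")
  # a zero decision value maps to +1
  zero_model <- model
  zero_model$alphas <- rep(0, 4)
  zero_model$bias <- 0
  expect_equal(predict(zero_model, sep$x), rep(1L, 4))
})

test_that("signed multiplier report reflects class structure", {
  sep <- separable_2d()
  model <- lssvm_train(sep$x, sep$y)
  rep_ <- signed_alpha_report(model)
  expect_equal(rep_$n_positive_sign, rep_$n_negative_sign)
  expect_equal(sign(rep_$signed_alphas), sep$y)
  # 3-vs-1 identity-kernel case has a positive intercept
  y <- c(1, 1, 1, -1)
  m2 <- list(alphas = (y - 0.5) / 2, bias = 0.5, train_y = y)
  class(m2) <- "lssvm"
  r2 <- signed_alpha_report(m2)
  expect_equal(r2$bias_sign, 1)
  expect_equal(r2$n_positive_sign, 3L)
})

test_that("model text serialization round-trips", {
  sep <- separable_2d()
  model <- lssvm_train(sep$x, sep$y)
  path <- withr::local_tempfile(fileext = ".txt")
  write_lssvm(model, path)
  back <- read_lssvm(path)
  expect_equal(back$alphas, model$alphas)
  expect_equal(back$bias, model$bias)
  expect_equal(predict(back, sep$x), predict(model, sep$x))
})

test_that("tidy and glance expose multipliers and the model summary", {
  sep <- separable_2d()
  model <- lssvm_train(sep$x, sep$y)
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  expect_equal(td$alpha, model$alphas)
  gl <- glance(model)
  expect_equal(gl$kernel, "linear")
  expect_equal(gl$bias, model$bias)
})
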