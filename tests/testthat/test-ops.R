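test_that("gelu matches the exact Gaussian-CDF definition", {
  # independent oracle: Phi(x) by numerical integration of the density
  phi_int <- function(x) {
    stats::integrate(stats::dnorm, -Inf, x, rel.tol = 1e-12)$value
  }
  for (x in c(-3, -1, -0.25, 0.5, 1, 2.5)) {
    expect_equal(gelu(x), x * phi_int(x), tolerance = 1e-9)
  }
  expect_identical(gelu(0), 0)
  # limits: identity for large x, zero for very negative x
  expect_equal(gelu(30), 30, tolerance = 1e-12)
  expect_lt(abs(gelu(-10)), 1e-20)
  # elementwise over matrices
  m <- matrix(c(-1, 0, 1, 2), 2)
  expect_equal(gelu(m), m * pnorm(m))
})

test_that("glu gates the linear branch through a sigmoid", {
  X <- matrix(c(1, 3, 2, 4), 2)
  # open/closed/half-open gates
  expect_equal(glu(X, diag(2), c(0, 0), matrix(0, 2, 2), c(0, 0)), 0.5 * X)
  expect_equal(glu(X, diag(2), c(0, 0), matrix(0, 2, 2), c(100, 100)), X,
               tolerance = 1e-12)
  # integer toy against direct elementwise arithmetic
  W1 <- matrix(c(1, 0, 1, 1), 2); b1 <- c(1, -1)
  W2 <- matrix(c(0, 1, 1, 0), 2); b2 <- c(0, 1)
  a <- X %*% W1 + rep(b1, each = 2)
  s <- 1 / (1 + exp(-(X %*% W2 + rep(b2, each = 2))))
  expect_equal(glu(X, W1, b1, W2, b2), a * s, tolerance = 1e-12)
})

test_that("attention matches a brute-force softmax oracle", {
  rng <- phosppi:::rng_local(11)
  Q <- matrix(rng$rnorm(6), 2, 3)
  K <- matrix(rng$rnorm(9), 3, 3)
  V <- matrix(rng$rnorm(12), 3, 4)
  expect_equal(attention(Q, K, V), attention_oracle(Q, K, V),
               tolerance = 1e-9)
  # saturation: a query aligned with one key, others orthogonal
  Ks <- diag(3)
  Vs <- matrix(1:9, 3, byrow = TRUE)
  out <- attention(matrix(c(100, 0, 0), 1), Ks, Vs)
  expect_equal(as.numeric(out), Vs[1, ], tolerance = 1e-6)
  # uniform scores average the value rows
  out <- attention(matrix(0, 1, 3), Ks, Vs)
  expect_equal(as.numeric(out), colMeans(Vs), tolerance = 1e-12)
  # masked keys receive no weight; all-masked errors
  out <- attention(matrix(0, 1, 3), Ks, Vs, key_mask = c(TRUE, TRUE, FALSE))
  expect_equal(as.numeric(out), colMeans(Vs[1:2, ]), tolerance = 1e-12)
  expect_error(attention(Q, Ks, Vs, key_mask = rep(FALSE, 3)), "masked")
})

test_that("attention_fusion reproduces the gated combination exactly", {
  rng <- phosppi:::rng_local(7)
  for (i in 1:20) {
    hl <- rng$rnorm(8); ha <- rng$rnorm(8); hb <- rng$rnorm(8)
    W <- rng$rnorm(24); b <- rng$rnorm(1)
    f <- attention_fusion(hl, ha, hb, W, b)
    expect_gt(f$alpha, 0); expect_lt(f$alpha, 1)
    # algebraic identity to machine precision
    expect_equal(f$h, f$alpha * hl + f$alpha * ha + (1 - f$alpha) * hb,
                 tolerance = 1e-15)
  }
  # limits of the gate
  one <- rep(1, 4)
  f <- attention_fusion(one, one, 5 * one, rep(100, 12), 0)
  expect_equal(f$h, one + one, tolerance = 1e-6)          # alpha -> 1
  f <- attention_fusion(one, one, 5 * one, rep(-100, 12), 0)
  expect_equal(f$h, 5 * one, tolerance = 1e-6)            # alpha -> 0
  # zero weights give alpha = 1/2 and the half-sum of all three
  f <- attention_fusion(one, 2 * one, 4 * one, rep(0, 12), 0)
  expect_equal(f$alpha, 0.5)
  expect_equal(f$h, 0.5 * one + 1 * one + 2 * one)
  # convex variant divides by 1 + alpha
  fn <- attention_fusion(one, 2 * one, 4 * one, rep(0, 12), 0, normalize = TRUE)
  expect_equal(fn$h, f$h / 1.5)
  expect_error(attention_fusion(one, one, c(1, 2), rep(0, 10)), "equal length")
})

test_that("soft voting averages probability pairs", {
  v <- soft_vote(c(0.6, 0.4), c(0.8, 0.2))
  expect_equal(c(v$p0, v$p1), c(0.7, 0.3))
  expect_equal(v$label, 0L)
  # idempotence and normalization
  v <- soft_vote(c(0.35, 0.65), c(0.35, 0.65))
  expect_equal(c(v$p0, v$p1), c(0.35, 0.65))
  rng <- phosppi:::rng_local(3)
  p1 <- rng$runif(10); p2 <- rng$runif(10)
  v <- soft_vote(cbind(1 - p1, p1), cbind(1 - p2, p2))
  expect_equal(v$p0 + v$p1, rep(1, 10))
  expect_equal(v$p1, (p1 + p2) / 2, tolerance = 1e-15)
  # exact tie at threshold predicts class 0
  expect_equal(soft_vote(c(0.6, 0.4), c(0.4, 0.6))$label, 0L)
})

test_that("hard voting follows agreement and breaks ties softly", {
  expect_equal(hard_vote(c(0.2, 0.8), c(0.4, 0.6)), 1L)
  expect_equal(hard_vote(c(0.8, 0.2), c(0.7, 0.3)), 0L)
  # 1-1 tie -> soft mean (0.5, 0.5) -> tie rule -> 0
  expect_equal(hard_vote(c(0.6, 0.4), c(0.4, 0.6)), 0L)
  # a voter at exactly 0.5 predicts class 0
  expect_equal(hard_vote(c(0.5, 0.5), c(0.6, 0.4)), 0L)
})

test_that("max-confidence voting picks the more confident submodel", {
  v <- max_confidence_vote(c(0.9, 0.1), c(0.6, 0.4))
  expect_equal(c(v$p0, v$p1), c(0.9, 0.1))
  v <- max_confidence_vote(c(0.3, 0.7), c(0.8, 0.2))
  expect_equal(c(v$p0, v$p1), c(0.8, 0.2))
  # equal confidence falls back to the soft mean
  v <- max_confidence_vote(c(0.7, 0.3), c(0.3, 0.7))
  expect_equal(c(v$p0, v$p1), c(0.5, 0.5))
  expect_equal(v$label, 0L)
})

test_that("all voters agree when the submodels emit identical pairs", {
  rng <- phosppi:::rng_local(19)
  for (i in 1:25) {
    p <- rng$runif(1)
    pair <- c(1 - p, p)
    lab <- soft_vote(pair, pair)$label
    expect_equal(hard_vote(pair, pair), lab)
    expect_equal(max_confidence_vote(pair, pair)$label, lab)
  }
})
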