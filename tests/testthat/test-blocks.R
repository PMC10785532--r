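# Building blocks: shape contracts, value ranges, analytic special cases and
# gradient correctness.

test_that("conv_block halves spatial dims and enforces its preconditions", {
  set.seed(1)
  b <- conv_block(1, 32)
  y <- forward(b, array(rnorm(64 * 64), c(64, 64, 1)))
  expect_equal(dim(tensor_value(y)), c(32L, 32L, 32L, 1L))

  b2 <- conv_block(32, 64)
  y2 <- forward(b2, array(rnorm(2 * 2 * 32), c(2, 2, 32)))
  expect_equal(dim(tensor_value(y2)), c(1L, 1L, 64L, 1L))

  b3 <- conv_block(3, 8)
  expect_error(forward(b3, array(0, c(64, 63, 3))), "odd|width")
  expect_error(forward(b, array(0, c(64, 64, 2))), "channel")
})

test_that("convolution kernel agrees with a direct-loop oracle", {
  set.seed(2)
  x <- array(rnorm(8 * 6 * 2 * 2), c(8, 6, 2, 2))
  for (cfg in list(list(k = 4, s = 2, p = 1), list(k = 3, s = 1, p = 1),
                   list(k = 1, s = 1, p = 0))) {
    w <- array(rnorm(cfg$k^2 * 2 * 3), c(cfg$k, cfg$k, 2, 3))
    got <- seanet:::cpp_conv2d_forward(x, w, cfg$s, cfg$p)
    want <- conv2d_loop_oracle(x, w, cfg$s, cfg$p)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("deconv_upsample doubles spatial dims and round-trips with conv_block", {
  set.seed(3)
  d <- deconv_upsample(64, 32)
  y <- forward(d, array(rnorm(16 * 16 * 64), c(16, 16, 64)))
  expect_equal(dim(tensor_value(y)), c(32L, 32L, 32L, 1L))

  d1 <- deconv_upsample(8, 8)
  y1 <- forward(d1, array(rnorm(8), c(1, 1, 8)))
  expect_equal(dim(tensor_value(y1))[1:2], c(2L, 2L))

  # shape round trip: upsample then strided conv restores the original dims
  x <- array(rnorm(6 * 10 * 8 * 2), c(6, 10, 8, 2))
  up <- forward(deconv_upsample(8, 4), x)
  down <- forward(conv_block(4, 8), up)
  expect_equal(dim(tensor_value(down)), dim(x))
})

test_that("attention gate preserves x's shape, bounds coefficients in (0,1), and
           reduces to pure scaling with hand-set parameters", {
  set.seed(4)
  g <- attention_gate(32, 64)
  x <- array(rnorm(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  G <- array(rnorm(16 * 16 * 64 * 2), c(16, 16, 64, 2))
  y <- forward(g, x, gating = G)
  expect_equal(dim(tensor_value(y)), dim(x))
  a <- tensor_value(g$last_attention)
  expect_true(all(a > 0 & a < 1))

  # zero the coefficient-branch conv and its BN scale: sigmoid(0) = 0.5 exactly
  g$psi$value <- g$psi$value * 0
  g$gp$value <- g$gp$value * 0     # BN gamma
  g$bp$value <- g$bp$value * 0     # BN beta
  y05 <- forward(g, x, gating = G)
  expect_equal(tensor_value(y05), 0.5 * x, tolerance = 1e-12)

  expect_error(forward(g, x, gating = array(0, c(8, 8, 64, 2))), "upsample")
})

test_that("SE module is exact per-channel scaling with an oracle-checked squeeze", {
  set.seed(5)
  se <- se_module(16, reduction = 8)
  x <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  y <- tensor_value(forward(se, x))
  s <- tensor_value(se$last_weights)
  expect_true(all(s > 0 & s < 1))
  expect_equal(dim(s), c(16L, 2L))

  # rank-1 per channel: output / input is constant over spatial positions
  for (n in 1:2) for (ch in 1:16) {
    ratio <- y[, , ch, n] / x[, , ch, n]
    expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
    expect_equal(ratio[1, 1], s[ch, n], tolerance = 1e-12)
  }

  # squeeze equals a naive per-channel mean
  z <- tensor_value(seanet:::op_global_mean_pool(as_tensor(x)))
  for (n in 1:2) for (ch in 1:16) {
    acc <- 0
    for (i in 1:8) for (j in 1:8) acc <- acc + x[i, j, ch, n]
    expect_equal(z[ch, n], acc / 64, tolerance = 1e-12)
  }

  # reduced width uses integer division with a floor of 1
  expect_equal(se_module(16, 8)$reduced, 2L)
  expect_equal(se_module(4, 8)$reduced, 1L)
})

test_that("SE-Res block preserves shape, is non-negative, and collapses to
           relu(x) when the residual branch is silenced", {
  set.seed(6)
  blk <- se_res_block(32)
  x <- array(rnorm(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  y <- tensor_value(forward(blk, x))
  expect_equal(dim(y), dim(x))
  expect_true(all(y >= 0))

  # zero the last conv + its BN affine: branch output is 0 after SE scaling
  blk$c3$w$value <- blk$c3$w$value * 0
  blk$c3$gamma$value <- blk$c3$gamma$value * 0
  blk$c3$beta$value <- blk$c3$beta$value * 0
  y0 <- tensor_value(forward(blk, x))
  expect_equal(y0, pmax(x, 0), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(forward(blk, array(0, c(16, 16, 8, 2))), "channel")
})

test_that("every block parameter receives a finite nonzero gradient", {
  set.seed(7)
  blk <- se_res_block(8)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  out <- forward(blk, x, training = TRUE)
  loss <- new_tensor(sum(tensor_value(out)^2), list(out),
                     function(g) list(2 * g * tensor_value(out)))
  zero_grad(blk$params)
  backward(loss)
  norms <- vapply(blk$params, function(p) {
    expect_false(is.null(p$grad))
    sqrt(sum(p$grad^2))
  }, numeric(1))
  expect_true(all(is.finite(norms)))
  expect_true(all(norms > 0))
})

test_that("block gradients match finite differences through BN, SE and
           activations", {
  set.seed(8)
  blk <- se_res_block(4)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  lossf <- function() {
    out <- forward(blk, x, training = TRUE)
    v <- tensor_value(out)
    new_tensor(sum(v^2) / 2, list(out), function(g) list(g * v))
  }
  l <- lossf()
  zero_grad(blk$params)
  backward(l)
  for (nm in c("se_res.conv2.w", "se_res.conv1.bn.gamma", "se_res.se.fc1.w",
               "se_res.conv3.bn.beta")) {
    p <- blk$params[[nm]]
    idx <- seq_len(min(4, length(p$value)))
    fd <- vapply(idx, function(i) {
      old <- p$value[i]
      p$value[i] <- old + 1e-5
      lp <- tensor_value(lossf())
      p$value[i] <- old - 1e-5
      lm <- tensor_value(lossf())
      p$value[i] <- old
      (lp - lm) / 2e-5
    }, numeric(1))
    expect_equal(as.vector(p$grad)[idx], fd, tolerance = 1e-4)
  }
})
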