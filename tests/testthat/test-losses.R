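# Loss closed forms, the Dice/Jaccard special cases of the Tversky index, the
# hybrid recomposition identity, and differentiability.

test_that("cross-entropy matches its closed forms", {
  t <- array(c(1, 0, 1, 0), c(2, 2, 1, 1))
  # perfect prediction (after clamping) -> ~0
  expect_lt(cross_entropy_loss(t, t), 1e-5)
  # maximal uncertainty -> ln 2 for any target
  p5 <- array(0.5, dim(t))
  expect_equal(cross_entropy_loss(p5, t), log(2), tolerance = 1e-12)
  # hand arithmetic
  p <- array(c(0.9, 0.2), c(2, 1, 1, 1))
  tt <- array(c(1, 0), c(2, 1, 1, 1))
  expect_equal(cross_entropy_loss(p, tt), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(array(0.5, c(2, 2)), array(0, c(2, 3))),
               "shape")
})

test_that("Tversky index reproduces Dice and Jaccard on the worked example", {
  p <- array(c(1, 1, 0, 0), c(4, 1, 1, 1))
  t <- array(c(1, 0, 1, 0), c(4, 1, 1, 1))
  # TP=1, FP=1, FN=1
  expect_equal(tversky_index(p, t, tversky_params(0.5, 0.5)), 0.5,
               tolerance = 1e-6)
  expect_equal(tversky_index(p, t, tversky_params(1, 1)), 1 / 3,
               tolerance = 1e-6)
  # identical nonempty masks score 1 under any weights
  expect_equal(tversky_index(t, t, tversky_params(0.2, 1.5)), 1,
               tolerance = 1e-6)
})

test_that("Tversky equals independent Dice/Jaccard on 100 random mask pairs", {
  set.seed(101)
  for (rep in 1:100) {
    mp <- random_mask_pair()
    cc <- confusion_loop_oracle(mp$pred, mp$target)
    p <- array(mp$pred, c(8, 8, 1, 1))
    t <- array(mp$target, c(8, 8, 1, 1))
    sm <- 1e-6
    dice_ref <- (2 * cc$tp + 2 * sm) / (2 * cc$tp + cc$fp + cc$fn + 2 * sm)
    jac_ref <- (cc$tp + sm) / (cc$tp + cc$fp + cc$fn + sm)
    expect_equal(tversky_index(p, t, tversky_params(0.5, 0.5)), dice_ref,
                 tolerance = 1e-10)
    expect_equal(tversky_index(p, t, tversky_params(1, 1)), jac_ref,
                 tolerance = 1e-10)
  }
})

test_that("hybrid loss recomposes exactly and honours degenerate weights", {
  set.seed(102)
  p <- array(runif(16 * 16), c(16, 16, 1, 1))
  t <- array(rbinom(256, 1, 0.2), c(16, 16, 1, 1))
  par <- tversky_params(lambda_weight = 10)
  l <- hybrid_loss(p, t, par)
  ce <- cross_entropy_loss(p, t)
  idx <- tversky_index(p, t, par)
  expect_equal(l$total, ce + 10 * (1 - idx), tolerance = 1e-10)
  expect_equal(l$ce_component, ce, tolerance = 1e-12)
  expect_equal(l$tversky_component, 1 - idx, tolerance = 1e-12)

  # lambda = 0 reduces to pure cross-entropy
  l0 <- hybrid_loss(p, t, tversky_params(lambda_weight = 0))
  expect_identical(l0$total, l0$ce_component)

  # perfect binary prediction -> ~0 total
  lp <- hybrid_loss(t, t, par)
  expect_lt(lp$total, 1e-4)
})

test_that("Tversky index stays in [0,1] and decreases with added false-positive
           mass", {
  set.seed(103)
  for (rep in 1:20) {
    p <- array(runif(64), c(8, 8, 1, 1))
    t <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
    par <- tversky_params()
    i0 <- tversky_index(p, t, par)
    expect_gte(i0, 0)
    expect_lte(i0, 1)
    # raising predicted probability on background pixels adds FP mass only
    p2 <- p
    p2[t == 0] <- pmin(1, p2[t == 0] + 0.2)
    expect_lte(tversky_index(p2, t, par), i0 + 1e-12)
  }
})

test_that("hybrid loss is differentiable with gradients matching finite
           differences", {
  set.seed(104)
  pv <- array(runif(6 * 6, 0.05, 0.95), c(6, 6, 1, 1))
  tv <- array(rbinom(36, 1, 0.4), c(6, 6, 1, 1))
  par <- tversky_params()
  p <- param_tensor(pv, "p")
  l <- hybrid_loss(p, tv, par)
  zero_grad(list(p))
  backward(l$total)
  fd <- numeric_gradient(function(x) {
    hybrid_loss(array(x, dim(pv)), tv, par)$total
  }, pv)
  expect_equal(as.vector(p$grad), as.vector(fd), tolerance = 1e-5)
})

test_that("empty-foreground targets give index 1 via smoothing, not 0/0", {
  z <- array(0, c(4, 4, 1, 1))
  expect_equal(tversky_index(z, z, tversky_params()), 1, tolerance = 1e-9)
  expect_equal(hybrid_loss(z, z, tversky_params())$tversky_component, 0,
               tolerance = 1e-9)
  # both weights zero is the explicit degenerate case: index is identically 1
  expect_equal(tversky_index(array(runif(16), c(4, 4, 1, 1)), z,
                             tversky_params(0, 0)),
               1, tolerance = 1e-9)
})
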