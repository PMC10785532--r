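# Network assembly: shape preservation, determinism, spiral wiring, the
# hand-composed forward oracle, padding arithmetic, and checkpoint round trips.

test_that("forward output matches input spatial dims for depths 2-4", {
  for (depth in 2:4) {
    set.seed(depth)
    m <- build_model(network_config(depth = depth, in_channels = 1,
                                    base_channels = 4), seed = depth)
    n <- 2^depth * 2
    x <- array(runif(n * n * 2), c(n, n, 1, 2))
    p <- model_forward(m, x)
    expect_equal(dim(p), c(n, n, 1L, 2L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("builds are deterministic under a seed", {
  cfg <- tiny_net_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(names(m1$params), names(m2$params))
  np <- function(m) sum(vapply(m$params, function(p) length(p$value), numeric(1)))
  expect_identical(np(m1), np(m2))
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(model_forward(m1, x), model_forward(m2, x))
})

test_that("eval-mode forward is idempotent", {
  m <- build_model(tiny_net_config(), seed = 1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  expect_identical(model_forward(m, x), model_forward(m, x))
})

test_that("depth-2 forward equals a hand-composed operator chain bit-exactly", {
  m <- build_model(tiny_net_config(depth = 2, base = 4), seed = 21)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  got <- model_forward(m, x)

  # compose the same blocks step by step, mirroring the spiral wiring
  x0 <- as_tensor(x)
  x1 <- forward(m$encoders[[1]], x0)
  x2 <- forward(m$encoders[[2]], x1)
  st1 <- m$decoders[[1]]            # level 1 (deepest stage)
  G1 <- forward(st1$deconv, x2)
  cat1 <- seanet:::op_concat_ch(forward(st1$gate, x1, gating = G1),
                                forward(st1$se_res, x1))
  st0 <- m$decoders[[2]]            # level 0 (input image as shallow feature)
  G0 <- forward(st0$deconv, cat1)
  cat0 <- seanet:::op_concat_ch(forward(st0$gate, x0, gating = G0),
                                forward(st0$se_res, x0))
  logits <- seanet:::op_add_channel_bias(
    seanet:::op_conv2d(cat0, m$head_w, 1L, 0L), m$head_b)
  want <- tensor_value(seanet:::op_sigmoid(logits))
  expect_identical(got, want)
})

test_that("the wiring graph has no direct shallow-to-concat shortcut", {
  m <- build_model(network_config(depth = 3, in_channels = 1, base_channels = 4),
                   seed = 1)
  w <- model_wiring(m)
  # encoder features (and the input) feed only attention gates and SE-Res blocks
  shallow <- grepl("^x", w$from)
  expect_true(all(w$op[shallow] %in% c("attention_gate", "se_res_block",
                                       "deconv_upsample")))
  expect_false(any(shallow & w$op == "concat"))
  # the only deconv fed by an encoder feature is the bottleneck's
  expect_identical(w$from[w$op == "deconv_upsample" & shallow], "x3")
  # spiral closure: every stage's G comes from the previous stage's concat
  deconv_src <- w$from[w$op == "deconv_upsample"]
  expect_identical(deconv_src, c("x3", "concat2", "concat1"))
})

test_that("indivisible inputs are rejected with advice to pad", {
  m <- build_model(tiny_net_config(depth = 3), seed = 1)
  expect_error(model_forward(m, array(0, c(20, 24, 1, 1))), "pad_to_valid")
})

test_that("pad_to_valid reaches the next multiple of 2^depth and round-trips", {
  img <- array(runif(640 * 800 * 3), c(640, 800, 3))
  p <- pad_to_valid(img, 8)
  expect_equal(dim(p$image)[1:2], c(768L, 1024L))
  back <- crop_to_original(p$image, p$crop)
  expect_equal(back[, , , 1], img, ignore_attr = TRUE)

  # already-valid dims pass through unchanged
  ok <- array(runif(64 * 64), c(64, 64, 1))
  p2 <- pad_to_valid(ok, 4)
  expect_equal(p2$image[, , 1, 1], ok[, , 1], ignore_attr = TRUE)
  expect_equal(p2$crop, list(height = 64L, width = 64L),
               ignore_attr = TRUE, tolerance = 0)
})

test_that("checkpoint save/load reproduces eval-mode outputs bit-exactly", {
  m <- build_model(tiny_net_config(), seed = 31)
  # perturb BN running stats away from their init so they are truly exercised
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  invisible(forward(m, x, training = TRUE))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_forward(m, x), model_forward(m2, x))
})

test_that("every parameter of a depth-3 model gets a finite nonzero gradient
           from the hybrid loss (no dead branch in the spiral)", {
  set.seed(42)
  m <- build_model(network_config(depth = 3, in_channels = 1, base_channels = 8),
                   seed = 42)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  t <- array(0, c(32, 32, 1, 2))
  t[8:20, 10:22, , ] <- 1
  out <- forward(m, x, training = TRUE)
  loss <- hybrid_loss(out, t)
  zero_grad(m$params)
  backward(loss$total)
  norms <- vapply(m$params, function(p) {
    expect_false(is.null(p$grad), info = p$name)
    sqrt(sum(p$grad^2))
  }, numeric(1))
  expect_true(all(is.finite(norms)))
  expect_true(all(norms > 0), info = paste(names(norms)[norms == 0], collapse = ", "))
})
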