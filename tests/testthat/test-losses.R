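# Independent index-loop oracles, kept deliberately naive.
loop_l1 <- function(pred, target) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(target[i] - pred[i])
  s / length(pred)
}
loop_sq <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s
}

test_that("content loss equals the mean absolute difference oracle", {
  set.seed(1)
  pred <- array(runif(3 * 4 * 4), c(4, 4, 3, 1))
  expect_equal(content_loss(pred, pred), 0)
  expect_equal(content_loss(pred, pred + 0.1), 0.1, tolerance = 1e-12)
  # single entry differing by 1 in a 3x4x4 image
  target <- pred
  target[2, 3, 1, 1] <- pred[2, 3, 1, 1] + 1
  expect_equal(content_loss(pred, target), 1 / 48, tolerance = 1e-12)
  target2 <- array(runif(48), dim(pred))
  expect_equal(content_loss(pred, target2), loop_l1(pred, target2),
               tolerance = 1e-9)
  expect_error(content_loss(pred, array(0, c(4, 4, 1, 1))), "shape")
})

test_that("attention loss sums unnormalized squared errors across 5 levels", {
  set.seed(2)
  mk <- function() lapply(0:4, function(e)
    array(runif(64 / 4^e * 1), c(8 / 2^e, 8 / 2^e, 1, 1)))
  a <- mk()
  expect_equal(attention_loss(a, a), 0)
  # one level differing by 0.5 at exactly 4 cells
  b <- a
  b[[2]][1:4] <- a[[2]][1:4] + 0.5
  expect_equal(attention_loss(b, a), 4 * 0.25, tolerance = 1e-12)
  # random stacks against the flat-vector oracle
  m <- mk()
  want <- sum(vapply(1:5, function(l) loop_sq(a[[l]], m[[l]]), numeric(1)))
  expect_equal(attention_loss(a, m), want, tolerance = 1e-9)
  expect_error(attention_loss(a[1:4], m[1:4]), "5 levels")
  # normalized variant divides each level by its cell count
  wantn <- sum(vapply(1:5, function(l)
    loop_sq(a[[l]], m[[l]]) / length(a[[l]]), numeric(1)))
  expect_equal(attention_loss(a, m, normalize = TRUE), wantn,
               tolerance = 1e-9)
})

test_that("adversarial and discriminator losses follow the log forms", {
  expect_equal(adversarial_loss_g(0.5), log(0.5), tolerance = 1e-12)
  # loss approaches 0 from below as scores vanish
  expect_lt(adversarial_loss_g(1e-9), 0)
  expect_gt(adversarial_loss_g(1e-9), -1e-8)
  # monotone: higher scores, lower loss
  s <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  l <- vapply(s, adversarial_loss_g, numeric(1))
  expect_true(all(diff(l) < 0))
  expect_error(adversarial_loss_g(1.2), "scores")
  expect_error(adversarial_loss_g(0), "scores")

  expect_equal(discriminator_loss(0.5, 0.5), -(log(0.5) + log(0.5)),
               tolerance = 1e-12)
  # optimum: real -> 1, fake -> 0
  expect_lt(discriminator_loss(1 - 1e-9, 1e-9), 1e-6)
  # strictly decreasing in real scores with fake fixed
  lr <- vapply(s, function(r) discriminator_loss(r, 0.3), numeric(1))
  expect_true(all(diff(lr) < 0))
  # batch expectation is the arithmetic mean
  expect_equal(adversarial_loss_g(c(0.2, 0.8)),
               mean(log(1 - c(0.2, 0.8))), tolerance = 1e-12)
})

test_that("the weighted total combines the four parts linearly", {
  expect_equal(total_generator_loss(list(adv = 0, con = 0, per = 0, att = 0)),
               0)
  parts <- list(adv = -0.69, con = 0.1, per = 0.002, att = 1.0)
  expect_equal(total_generator_loss(parts), -0.69 + 10 + 2 + 1,
               tolerance = 1e-12)
  w2 <- loss_weights(2, 200, 2000, 2)
  expect_equal(total_generator_loss(parts, w2),
               2 * total_generator_loss(parts), tolerance = 1e-12)
  expect_error(loss_weights(-1, 100, 1000, 1), "non-negative")
})

test_that("perceptual loss matches a scalar-loop recomputation on a tiny extractor", {
  # two-conv extractor with hand-set weights on 4x4 inputs
  fx <- feature_extractor("random_seeded", seed = 1, width_mult = 1 / 32,
                          tap = c(block = 1, conv = 2))
  w1 <- fx$weights[["b1.c1"]]
  w2 <- fx$weights[["b1.c2"]]
  set.seed(3)
  pred <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))
  target <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))

  expect_equal(perceptual_loss(pred, pred, fx), 0)

  # independent double-precision loop oracle for conv -> relu -> conv -> relu
  f_oracle <- function(x) {
    h1 <- pmax(brute_conv(x, w1, pad = 1), 0)
    pmax(brute_conv(h1, w2, pad = 1), 0)
  }
  fp <- f_oracle(pred)
  ft <- f_oracle(target)
  want <- loop_sq(fp, ft) / (4 * 4)
  got <- perceptual_loss(pred, target, fx)
  expect_equal(got, want, tolerance = 1e-6)

  # homogeneity: doubling the feature difference quadruples the loss
  d <- dim(fx_forward(fx, pred)$feat)
  diff1 <- sum((fx_forward(fx, pred)$feat - fx_forward(fx, target)$feat)^2)
  expect_equal(got * 4, 4 * diff1 / (d[1] * d[2]), tolerance = 1e-9)

  # pretrained mode has no weights available and says what to do instead
  expect_error(feature_extractor("pretrained"), "random_seeded")
})

test_that("gradients flow to the generator but never into the frozen extractor", {
  fx <- feature_extractor("random_seeded", seed = 2, width_mult = 1 / 32,
                          tap = c(block = 2, conv = 1))
  w_before <- fx$weights
  set.seed(4)
  pred <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  target <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  pg <- hazegan:::perceptual_loss_with_grad(pred, target, fx)
  # a gradient reaches the input
  expect_gt(sum(abs(pg$grad)), 0)
  expect_identical(dim(pg$grad), dim(pred))
  # the extractor's weights are untouched by the pass
  expect_identical(fx$weights, w_before)
  # finite-difference agreement on a few coordinates (double-precision path
  # up to float32 convolution rounding)
  idx <- c(5, 50, 150)
  for (i in idx) {
    eps <- 1e-3
    pp <- pred; pp[i] <- pp[i] + eps
    pm <- pred; pm[i] <- pm[i] - eps
    num <- (perceptual_loss(pp, target, fx) -
              perceptual_loss(pm, target, fx)) / (2 * eps)
    expect_equal(pg$grad[i], num, tolerance = 0.05)
  }
})
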