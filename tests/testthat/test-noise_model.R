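test_that("normalized distance is zero at the center and clamps at the rim", {
  d <- normalized_distance(c(21, 21), c(11, 11), 5)
  expect_equal(d[11, 11], 0)
  expect_equal(d[11, 16], 1)        # exactly one radius away
  expect_equal(d[11, 21], 1)        # two radii away, clamped
  expect_error(normalized_distance(c(8, 8), c(4, 4), 0), "radius")
})

test_that("uniform fields hold their constants inside the disc, identity outside", {
  spec <- noise_spec("uniform", c(16, 16), 6, list(t = 0.1, A = 0.6))
  f <- uniform_field(spec, c(32, 32))
  dist <- sqrt(outer((1:32 - 16)^2, (1:32 - 16)^2, "+"))
  expect_true(all(f$t_map[dist <= 6] == 0.1))
  expect_true(all(f$a_map[dist <= 6] == 0.6))
  expect_true(all(f$t_map[dist > 6] == 1))
  expect_error(noise_spec("uniform", c(1, 1), 5, list(t = 0.5)), "invalid")
  expect_error(noise_spec("uniform", c(1, 1), 5, list(A = 0.5)), "invalid")
})

test_that("linear fields follow the radial interpolation with a plateau", {
  # closed forms at d = 0, 0.5, 1 with plateau threshold 0.8
  spec <- noise_spec("linear", c(17, 17), 8, list(plateau_threshold = 0.8))
  d <- normalized_distance(c(33, 33), c(17, 17), 8)
  dist <- sqrt(outer((1:33 - 17)^2, (1:33 - 17)^2, "+"))
  # pre-blur maps rebuilt by hand to isolate the formula (rim included)
  t_expect <- ifelse(dist <= 8, d * 0.4 + (1 - d) * 0.1, 1)
  a_lin <- d * 0.6 + (1 - d) * 1
  a_expect <- ifelse(a_lin > 0.8, 1, a_lin)
  expect_equal(t_expect[17, 17], 0.1)             # d = 0
  expect_equal(a_expect[17, 17], 1)
  expect_equal(t_expect[17, 25], 0.4, tolerance = 1e-12)  # d = 1
  expect_equal(a_expect[17, 25], 0.6, tolerance = 1e-12)
  expect_equal(t_expect[17, 21], 0.25, tolerance = 1e-12) # d = 0.5
  expect_equal(a_expect[17, 21], 0.8, tolerance = 1e-12)  # not > 0.8: no clamp

  f <- linear_field(spec, c(33, 33))
  expect_equal(f$t_map, t_expect, tolerance = 1e-12)
  # the shipped field blurs A with a normalized 5x5 Gaussian kernel
  expect_equal(f$a_map, hazegan:::gaussian_blur5(a_expect), tolerance = 1e-12)
  # t monotone non-decreasing in d across the disc interior
  inside_cols <- which(dist[17, ] <= 8)
  ord <- inside_cols[order(d[17, inside_cols])]
  expect_true(all(diff(f$t_map[17, ord]) >= -1e-12))
})

test_that("exponential fields match their closed forms", {
  spec <- noise_spec("exponential", c(17, 17), 8, list(theta = 0.5))
  f <- exponential_field(spec, c(33, 33))
  d <- normalized_distance(c(33, 33), c(17, 17), 8)
  expect_true(all(f$t_map[d >= 0.5] == 1))
  expect_equal(f$t_map[17, 17], exp(-2))          # d = 0
  expect_equal(f$a_map[17, 17], 1)                # e^0
  expect_equal(f$a_map[17, 25], exp(-0.5))        # d = 1, theta = 0.5
  # A monotone non-increasing in d
  ord <- order(d[17, ])
  expect_true(all(diff(f$a_map[17, ord]) <= 1e-12))
  expect_error(noise_spec("exponential", c(1, 1), 5, list(theta = 0.8)),
               "theta")
})

test_that("the scattering model composites as a convex combination", {
  clean <- matrix(0.5, 8, 8)
  # t = 1 everywhere: identity
  f1 <- list(t_map = matrix(1, 8, 8), a_map = matrix(0.8, 8, 8))
  expect_identical(apply_scattering(clean, f1), clean)
  # t = 0: full occlusion at A
  f0 <- list(t_map = matrix(0, 8, 8), a_map = matrix(0.8, 8, 8))
  expect_equal(apply_scattering(clean, f0), matrix(0.8, 8, 8))
  # hand value: 0.5*0.2 + 0.8*0.8 = 0.74
  fm <- list(t_map = matrix(0.2, 8, 8), a_map = matrix(0.8, 8, 8))
  expect_equal(apply_scattering(clean, fm), matrix(0.74, 8, 8))
  expect_error(apply_scattering(matrix(0.5, 4, 4), f1), "shape")
  # convexity: output bounded by [min(J, A), max(J, A)]
  set.seed(2)
  J <- matrix(runif(64), 8, 8)
  f <- list(t_map = matrix(runif(64, 0.01, 1), 8, 8),
            a_map = matrix(runif(64), 8, 8))
  out <- apply_scattering(J, f)
  expect_true(all(out >= pmin(J, f$a_map) - 1e-12))
  expect_true(all(out <= pmax(J, f$a_map) + 1e-12))
})

test_that("spot sampling respects counts, mixture weights and ranges", {
  shape <- c(64, 64)
  counts <- integer(0)
  forms <- character(0)
  for (i in 1:2000) {
    specs <- sample_specs(shape, seed = i)
    counts <- c(counts, length(specs))
    forms <- c(forms, vapply(specs, function(s) s$form, character(1)))
    for (s in specs) {
      expect_gt(s$radius, 0)
      if (s$form == "uniform") {
        expect_true(s$params$t >= 0.1 && s$params$t <= 0.4)
        expect_true(s$params$A >= 0.6 && s$params$A <= 1)
      } else if (s$form == "linear") {
        expect_true(s$params$plateau_threshold > 0.75 &&
                      s$params$plateau_threshold < 0.85)
      } else {
        expect_true(s$params$theta > 0.3 && s$params$theta < 0.7)
      }
    }
  }
  expect_true(all(counts >= 3 & counts <= 8))
  freq <- table(factor(forms, c("uniform", "linear", "exponential"))) /
    length(forms)
  expect_lt(abs(freq[["uniform"]] - 0.2), 0.02)
  expect_lt(abs(freq[["linear"]] - 0.4), 0.02)
  expect_lt(abs(freq[["exponential"]] - 0.4), 0.02)
  # determinism
  expect_identical(sample_specs(shape, seed = 42), sample_specs(shape, seed = 42))
})

test_that("corruption is local, order-invariant and identity without spots", {
  sc <- tiny_scene(seed = 1)
  expect_identical(corrupt(sc$image, list())$noisy, sc$image)

  spec1 <- noise_spec("uniform", c(16, 16), 6, list(t = 0.2, A = 0.9))
  spec2 <- noise_spec("exponential", c(48, 48), 8, list(theta = 0.4))
  one <- corrupt(sc$image, list(spec1))
  dist1 <- sqrt(outer((1:64 - 16)^2, (1:64 - 16)^2, "+"))
  expect_true(all(one$noisy[dist1 > 6] == sc$image[dist1 > 6]))
  expect_false(all(one$noisy[dist1 <= 6] == sc$image[dist1 <= 6]))

  # disjoint spots: each region equals its single-spot result
  both <- corrupt(sc$image, list(spec1, spec2))
  two <- corrupt(sc$image, list(spec2))
  dist2 <- sqrt(outer((1:64 - 48)^2, (1:64 - 48)^2, "+"))
  expect_equal(both$noisy[dist1 <= 6], one$noisy[dist1 <= 6])
  expect_equal(both$noisy[dist2 <= 8], two$noisy[dist2 <= 8])

  # order invariance over random overlapping pairs
  for (i in 1:10) {
    specs <- sample_specs(c(64, 64), seed = 500 + i)[1:2]
    ab <- corrupt(sc$image, specs)
    ba <- corrupt(sc$image, rev(specs))
    expect_identical(ab$noisy, ba$noisy)
  }
})

test_that("target attention stacks mirror the corruption support level by level", {
  sc <- tiny_scene(seed = 2)
  # identical images: all-zero stack
  z <- target_attention_stack(sc$image, sc$image)
  expect_length(z, 5)
  for (l in 1:5) expect_true(all(z[[l]] == 0))
  for (l in 1:4) expect_equal(dim(z[[l + 1]]), dim(z[[l]]) %/% 2L)

  # a single changed pixel pools to 0.25 at level 2 under average pooling
  noisy <- sc$image
  noisy[9, 9] <- sc$image[9, 9] + 1e9 # placeholder replaced below
  noisy[9, 9] <- 1
  delta <- abs(1 - sc$image[9, 9])
  st <- target_attention_stack(noisy, sc$image)
  expect_equal(st[[2]][5, 5], delta * 0.25)
  expect_equal(sum(st[[1]] > 0), 1)

  # support of level 1 equals the set of changed pixels after corruption
  pair <- tiny_pair(seed = 3)
  changed <- pair$noisy != pair$clean
  expect_identical(pair$attention_targets[[1]] > 0, changed)
  expect_error(target_attention_stack(matrix(0, 8, 8), matrix(0, 8, 8)),
               "divisible")
})
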