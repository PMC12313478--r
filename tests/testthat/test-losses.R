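# Training objectives against hand-computed and closed-form oracles.

toy_probs_2x2 <- function() {
  # class-1 probability [1,1,0,0] over a 2x2 grid, class 0 the complement
  p1 <- matrix(c(1, 1, 0, 0), 2, 2)
  p <- array(0, c(2, 2, 2, 1))
  p[1, , , 1] <- 1 - p1
  p[2, , , 1] <- p1
  p
}
toy_truth_2x2 <- function() array(c(0L, 1L, 1L, 0L), c(2, 2, 1))

test_that("dice loss reproduces the hand-counted overlap toy", {
  # |p|=2, |y|=2, overlap 1 for both classes: Dice = 2*1/(2+2) = 0.5
  l <- dice_loss(toy_probs_2x2(), toy_truth_2x2())
  expect_equal(ad_val(l), 0.5, tolerance = 1e-5)
  # perfect prediction: loss ~ 0
  y <- random_mask(4, 4, 2, seed = 9)
  expect_lt(ad_val(dice_loss(one_hot(y, 3L), y)), 1e-5)
  # predicting only a class absent from the truth: both classes disjoint
  # from their targets, so the mean soft Dice collapses to ~0
  pred <- array(0, c(2, 4, 4, 1)); pred[2, , , ] <- 1
  yy <- array(0L, c(4, 4, 1))
  expect_lt(1 - ad_val(dice_loss(pred, yy)), 1e-4)
  expect_error(dice_loss(array(0.5, c(2, 2, 2, 0)), yy), "empty")
})

test_that("cross entropy matches closed forms", {
  K <- 3L
  y <- random_mask(3, 3, 2, K, seed = 2)
  unif <- array(1 / K, c(K, 3, 3, 2))
  expect_equal(ad_val(cross_entropy_loss(unif, y)), log(3), tolerance = 1e-8)
  half <- one_hot(y, K) * 0.5 + (1 - one_hot(y, K)) * 0.25
  expect_equal(ad_val(cross_entropy_loss(half, y)), log(2), tolerance = 1e-8)
  expect_lt(ad_val(cross_entropy_loss(one_hot(y, K), y)), 1e-5)
})

test_that("supervised loss is the mean of its two parts", {
  p <- random_probs(3, 4, 4, 2, seed = 5)
  y <- random_mask(4, 4, 2, seed = 6)
  s <- ad_val(supervised_loss(p, y))
  expect_equal(s, (ad_val(cross_entropy_loss(p, y)) + ad_val(dice_loss(p, y))) / 2,
               tolerance = 1e-10)
  expect_lt(ad_val(supervised_loss(one_hot(y, 3L), y)), 1e-5)
  # uniform prediction on the 2x2 toy, against independently composed parts
  unif <- array(1 / 2, c(2, 2, 2, 1))
  yy <- toy_truth_2x2()
  oh <- one_hot(yy, 2L)
  dice_by_hand <- mean(vapply(1:2, function(k) {
    2 * sum(unif[k, , , ] * oh[k, , , ]) / (sum(unif[k, , , ]) + sum(oh[k, , , ]))
  }, 0))
  expect_equal(ad_val(supervised_loss(unif, yy)),
               (log(2) + (1 - dice_by_hand)) / 2, tolerance = 1e-5)
})

test_that("consistency error and loss follow the squared-distance contract", {
  p <- random_probs(3, 2, 2, 1, seed = 1)
  expect_equal(max(abs(ad_val(consistency_error(p, p)))), 0)
  q <- p
  q[1, 1, 1, 1] <- q[1, 1, 1, 1] + 0.1
  e <- ad_val(consistency_error(p, q))
  expect_equal(e[1, 1, 1, 1], 0.01, tolerance = 1e-10)
  expect_equal(sum(e), 0.01, tolerance = 1e-10)
  # symmetry and the 4-pixel arithmetic example
  expect_equal(ad_val(consistency_error(q, p)), e)
  m <- array(c(0.04, 0, 0, 0), c(1, 2, 2, 1))
  expect_equal(ad_val(consistency_loss(m)), 0.01)
  expect_equal(ad_val(consistency_loss(m * 3)), 0.03)
  expect_error(consistency_error(p, random_probs(3, 4, 4, 1)), "mismatch")
})

test_that("stabilization loss gates per the flag table", {
  mse <- array(runif(16), c(1, 4, 4, 1))
  zeros <- array(0, c(1, 4, 4, 1))
  lo <- array(0.1, c(1, 4, 4, 1)); hi <- array(0.2, c(1, 4, 4, 1))
  # identical student outputs: zero regardless of flags
  expect_equal(ad_val(stabilization_loss(
    list(eps_a = lo, eps_b = hi, r_a = 1L, r_b = 1L), zeros)), 0)
  # both stable, eps_a < eps_b everywhere: full mean
  expect_equal(ad_val(stabilization_loss(
    list(eps_a = lo, eps_b = hi, r_a = 1L, r_b = 1L), mse)), mean(mse))
  # indicator blocks when this student is less stable
  expect_equal(ad_val(stabilization_loss(
    list(eps_a = hi, eps_b = lo, r_a = 1L, r_b = 1L), mse)), 0)
  expect_equal(ad_val(stabilization_loss(
    list(eps_a = hi, eps_b = lo, r_a = 1L, r_b = 1L), mse, flip = TRUE)),
    mean(mse))
  # fall-through branch multiplies by r_a
  expect_equal(ad_val(stabilization_loss(
    list(eps_a = lo, eps_b = hi, r_a = 0L, r_b = 0L), mse)), 0)
  expect_equal(ad_val(stabilization_loss(
    list(eps_a = lo, eps_b = hi, r_a = 1L, r_b = 0L), mse)), mean(mse))
})

test_that("adversarial losses match the binary cross-entropy closed forms", {
  expect_lt(ad_val(adversarial_generator_loss(c(1, 1))), 1e-6)
  expect_equal(ad_val(adversarial_generator_loss(0.5)), log(2), tolerance = 1e-9)
  v <- ad_val(adversarial_generator_loss(seq(0.1, 0.9, by = 0.1)))
  singles <- vapply(seq(0.1, 0.9, by = 0.1),
                    function(d) ad_val(adversarial_generator_loss(d)), 0)
  expect_true(all(diff(singles) < 0))   # monotone decreasing in d_out
  expect_lt(ad_val(discriminator_loss(1, 0)), 1e-6)
  expect_equal(ad_val(discriminator_loss(0.5, 0.5)), 2 * log(2), tolerance = 1e-9)
  for (s in 1:5) {
    r <- ws(s, runif(4, 0.01, 0.99)); f <- ws(s + 10, runif(4, 0.01, 0.99))
    expect_gte(ad_val(discriminator_loss(r, f)), 0)
  }
})

test_that("total loss reproduces the weighted-sum identity", {
  br <- total_student_loss(1, 1, 1, 1, weights = c(0.5, 0.2, 0.05))
  expect_equal(br$total, 1.75, tolerance = 1e-12)
  expect_equal(total_student_loss(0, 0, 0, 0)$total, 0)
  expect_equal(total_student_loss(0.37, 5, 5, 5, weights = c(0, 0, 0))$total, 0.37)
  # invariant: total = seg + sum(lambda * parts) on random draws
  for (s in 1:20) {
    parts <- ws(s, runif(4, 0, 3))
    w <- ws(s + 50, runif(3, 0, 1))
    br <- total_student_loss(parts[1], parts[2], parts[3], parts[4], w)
    expect_equal(br$total, parts[1] + sum(w * parts[2:4]), tolerance = 1e-6)
  }
  expect_error(total_student_loss(NaN, 0, 0, 0), "seg")
})

test_that("losses are finite and non-negative on random valid inputs", {
  for (s in 1:100) {
    p <- random_probs(3, 4, 4, 1, seed = s)
    q <- random_probs(3, 4, 4, 1, seed = s + 1000)
    y <- random_mask(4, 4, 1, seed = s)
    vals <- c(ad_val(dice_loss(p, y)), ad_val(cross_entropy_loss(p, y)),
              ad_val(supervised_loss(p, y)),
              ad_val(consistency_loss(consistency_error(p, q))))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})

test_that("dice loss and dice similarity sum to one", {
  p <- random_probs(3, 6, 6, 2, seed = 3)
  y <- random_mask(6, 6, 2, seed = 4)
  expect_equal(ad_val(dice_loss(p, y)) + ad_val(dice_similarity(p, y)), 1,
               tolerance = 1e-10)
})

test_that("autograd of every loss matches finite differences on a 2x2 instance", {
  y <- array(c(0L, 1L, 2L, 1L), c(2, 2, 1))
  p0 <- random_probs(3, 2, 2, 1, seed = 7)
  q0 <- random_probs(3, 2, 2, 1, seed = 8)
  for (make in list(
    function(p) dice_loss(p, y),
    function(p) cross_entropy_loss(p, y),
    function(p) supervised_loss(p, y),
    function(p) consistency_loss(consistency_error(p, nd(q0))))) {
    pn <- ad_param(p0)
    loss <- make(pn)
    zero_grads(list(pn))
    ad_backward(loss)
    ng <- numgrad(function(v) ad_val(make(ad_param(v))), p0)
    expect_lt(max(abs(pn$grad - ng)) / max(abs(ng)), 1e-3)
  }
})
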