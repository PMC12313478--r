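# EMA, ramp, stability flags, and the dual-student loop.

test_that("EMA update follows the closed-form recursion", {
  expect_equal(ema_update(0, 1, alpha = 0.999), 0.001, tolerance = 1e-12)
  expect_equal(ema_update(0.37, 0.37, alpha = 0.999), 0.37)
  # constant student for n steps: theta'_n = a^n theta'_0 + (1 - a^n) theta
  th0 <- 2; th <- -1; a <- 0.9
  cur <- th0
  for (n in 1:7) {
    cur <- ema_update(cur, th, alpha = a)
    expect_equal(cur, a^n * th0 + (1 - a^n) * th, tolerance = 1e-12)
  }
  expect_error(ema_update(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("EMA teacher parameters stay within the student history envelope", {
  hist <- ws(1, rnorm(50))
  th0 <- 0.5
  teacher <- th0
  for (i in seq_along(hist)) {
    teacher <- ema_update(teacher, hist[i], alpha = 0.9)
    expect_gte(teacher, min(th0, hist[1:i]))
    expect_lte(teacher, max(th0, hist[1:i]))
  }
  # model-level: teacher equals student at init, then tracks it
  m <- tiny_model(seed = 1)
  t <- smfnet:::clone_smf(m)
  p_m <- collect_params(unclass(m))
  p_t <- collect_params(unclass(t))
  old <- p_m[[1]]$value
  p_m[[1]]$value <- p_m[[1]]$value + 1
  ema_update(t, m, alpha = 0.5)
  expect_equal(p_t[[1]]$value, old + 0.5, tolerance = 1e-12)
})

test_that("the ramp is the stated Gaussian curve", {
  d <- 1.3
  expect_equal(ramp_weight(d, 0, 10), d * exp(-5), tolerance = 1e-12)
  expect_equal(ramp_weight(d, 10, 10), d)
  expect_equal(ramp_weight(d, 25, 10), d)      # saturates past the ramp
  expect_equal(ramp_weight(d, 0, 0), d)        # zero-length ramp starts full
  w <- vapply(0:10, function(e) ramp_weight(d, e, 10), 0)
  expect_true(all(diff(w) > 0))
  expect_lt(ramp_weight(d, 0, 10), ramp_weight(d, 5, 10))
  expect_lt(ramp_weight(d, 5, 10), ramp_weight(d, 10, 10))
})

test_that("stability flags combine agreement and confidence", {
  conf <- array(0.005, c(3, 4, 4, 1)); conf[1, , , ] <- 0.99
  expect_equal(stability_flag(conf, conf, tau = 0.6), 1L)
  unif <- array(1 / 3, c(3, 4, 4, 1))
  expect_equal(stability_flag(unif, unif, tau = 0.6), 0L)
  # agreement fraction equals a brute-force pixel count on a 4x4 toy
  p1 <- array(0.01, c(2, 4, 4, 1)); p2 <- p1
  top <- ws(2, matrix(sample(1:2, 16, TRUE), 4, 4))
  top2 <- top; top2[1, 1] <- 3L - top2[1, 1]   # flip exactly one pixel
  for (i in 1:4) for (j in 1:4) {
    p1[top[i, j], i, j, 1] <- 0.95
    p1[3L - top[i, j], i, j, 1] <- 0.05
    p2[top2[i, j], i, j, 1] <- 0.95
    p2[3L - top2[i, j], i, j, 1] <- 0.05
  }
  frac <- mean(top == top2)                     # 15/16
  expect_equal(stability_flag(p1, p2, tau = 0.6,
                              agree_frac = frac), 1L)
  expect_equal(stability_flag(p1, p2, tau = 0.6,
                              agree_frac = frac + 1e-6), 0L)
})

test_that("dual-student steps stay finite and honor the total identity", {
  dtr <- make_corpus(4, 4, grid = 16L, seed = 21L)
  ds <- load_corpus(dtr)
  vocab <- corpus_vocab(ds)
  cfg <- das_config(epochs = 1L, seed = 5L, ramp_epochs = 2L)
  tr <- das_trainer(tiny_cfg(), cfg, vocab, 16L)
  lb <- stack_samples(ds$labeled)
  ub <- stack_samples(ds$unlabeled)
  for (i in 1:10) {
    res <- train_step_dual(tr, lb, ub, epoch = 1L, step = i)
    for (who in c("A", "B")) {
      br <- res[[who]]
      expect_true(all(is.finite(c(br$seg, br$cons, br$sta, br$adv, br$total))))
      expect_gte(br$seg, 0); expect_gte(br$cons, 0)
      expect_gte(br$sta, 0); expect_gte(br$adv, 0)
      expect_equal(br$total,
                   br$seg + sum(br$weights * c(br$cons, br$sta, br$adv)),
                   tolerance = 1e-6)
    }
  }
  expect_error(train_step_dual(tr, NULL, ub, 0L), "labeled")
})

test_that("training is reproducible given the seed", {
  dtr <- make_corpus(4, 2, grid = 16L, seed = 31L)
  dva <- make_corpus(2, 0, grid = 16L, seed = 32L)
  train <- load_corpus(dtr); vald <- load_corpus(dva)
  vocab <- corpus_vocab(train, vald)
  run <- function() {
    cfg <- das_config(epochs = 2L, seed = 9L)
    tr <- das_trainer(tiny_cfg(), cfg, vocab, 16L)
    das_fit(tr, train, vald)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(module_state(smfnet:::trainer_parts(f1$trainer)),
                   module_state(smfnet:::trainer_parts(f2$trainer)))
})

test_that("zero unsupervised weights reduce to independent supervised runs", {
  dtr <- make_corpus(4, 4, grid = 16L, seed = 41L)
  train <- load_corpus(dtr)
  vocab <- corpus_vocab(train)
  fit_with <- function(framework, lambda, init_id = 1L) {
    cfg <- das_config(framework = framework, lambda = lambda, epochs = 5L,
                      seed = 13L, use_teacher = FALSE)
    tr <- das_trainer(tiny_cfg(), cfg, vocab, 16L, init_id = init_id)
    das_fit(tr, train)
    tr
  }
  dual <- fit_with("dual_student", c(0, 0, 0))
  supA <- fit_with("supervised", c(0, 0, 0), init_id = 1L)
  supB <- fit_with("supervised", c(0, 0, 0), init_id = 2L)
  expect_identical(module_state(unclass(dual$students$A$model)),
                   module_state(unclass(supA$students$A$model)))
  expect_identical(module_state(unclass(dual$students$B$model)),
                   module_state(unclass(supB$students$A$model)))
})

test_that("the mean-teacher objective trains and logs finite losses", {
  dtr <- make_corpus(4, 4, grid = 16L, seed = 51L)
  train <- load_corpus(dtr)
  vocab <- corpus_vocab(train)
  cfg <- das_config(framework = "mean_teacher", epochs = 2L, seed = 3L,
                    delta = 0.5, ramp_epochs = 4L)
  tr <- das_trainer(tiny_cfg(), cfg, vocab, 16L)
  fit <- das_fit(tr, train)
  expect_length(fit$history, 2L)
  expect_true(is.finite(fit$history[[2]]$loss$A$total))
  expect_false(is.null(tr$teacher))
})

test_that("supervised descent reduces the training loss on the overfit preset", {
  dtr <- make_corpus(4, 0, grid = 16L, seed = 61L, count_probs = c(0, 1))
  train <- load_corpus(dtr)
  vocab <- corpus_vocab(train)
  cfg <- das_config(framework = "supervised", epochs = 8L, seed = 7L,
                    lr = 1e-3)
  tr <- das_trainer(tiny_cfg(), cfg, vocab, 16L)
  fit <- das_fit(tr, train)
  first <- fit$history[[1]]$loss$A$seg
  last <- fit$history[[8]]$loss$A$seg
  expect_lt(last, first)
})
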