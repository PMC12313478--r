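# Architecture contracts: shapes, gating bounds, ablation switches,
# determinism.

test_that("an encoder stage doubles channels and halves spatial dims", {
  m <- tiny_model()
  x <- ws(2, array(rnorm(4 * 16 * 16 * 2), c(4, 16, 16, 2)))
  out <- down_cnn(m$enc[[2]], x, train = FALSE)   # stage 2: 4 -> 8 channels
  expect_equal(dim(ad_val(out)), c(8, 8, 8, 2))
  expect_true(all(is.finite(ad_val(out))))
  zero <- array(0, c(4, 16, 16, 1))
  expect_true(all(is.finite(ad_val(down_cnn(m$enc[[2]], zero)))))
  expect_error(down_cnn(m$enc[[2]], array(0, c(4, 15, 15, 1))), "even")
})

test_that("pooled output sizes follow the floor-halving oracle", {
  for (sz in c(16L, 24L, 32L, 48L, 64L)) {
    x <- array(0, c(1, sz, sz, 1))
    out <- smfnet:::ad_maxpool(nd(x), 2L)
    expect_equal(dim(ad_val(out))[2:3], c(sz %/% 2L, sz %/% 2L))
  }
})

test_that("ctbn broadcasts text to a non-negative, spatially constant map", {
  m <- tiny_model()
  pooled <- ws(3, matrix(rnorm(2 * 16), 2, 16))
  out <- ad_val(ctbn(m$ctbn[[1]], pooled, 8L, 8L))
  expect_equal(dim(out), c(4, 8, 8, 2))
  expect_gte(min(out), 0)
  # spatially constant per channel and sample
  expect_lt(max(abs(sweep(out, c(1, 4), out[, 1, 1, ]))), 1e-12)
  # zero text embedding: pure bias pathway, still spatially constant
  z <- ad_val(ctbn(m$ctbn[[1]], matrix(0, 2, 16), 8L, 8L))
  expect_lt(max(abs(sweep(z, c(1, 4), z[, 1, 1, ]))), 1e-12)
  # two different texts yield different maps
  p2 <- pooled + 1
  expect_false(identical(out, ad_val(ctbn(m$ctbn[[1]], p2, 8L, 8L))))
})

test_that("mtt fusion preserves shape and respects the text switch", {
  m <- tiny_model()
  v <- tiny_vocab()
  anns1 <- lapply(rep("1 lesion in the upper left of the organ", 2),
                  tokenize, vocab = v, max_len = 12L)
  anns2 <- lapply(rep("no lesion in the organ", 2),
                  tokenize, vocab = v, max_len = 12L)
  txt1 <- encode_text(m$text, anns1)
  x <- ws(4, array(rnorm(4 * 16 * 16 * 2), c(4, 16, 16, 2)))
  out <- mtt_fuse(m, 1L, x, txt1)
  expect_equal(dim(ad_val(out)), dim(x))
  # zero image features: finite and spatially constant (token content only)
  z <- ad_val(mtt_fuse(m, 1L, array(0, c(4, 16, 16, 2)), txt1))
  expect_true(all(is.finite(z)))
  expect_lt(max(abs(sweep(z, c(1, 4), z[, 1, 1, ]))), 1e-10)
  expect_error(mtt_fuse(m, 2L, x, txt1), "geometry")
  # constant-text model is bit-insensitive to the text string
  mc <- tiny_model(cfg = tiny_cfg(use_text = FALSE))
  px <- ws(5, array(runif(16 * 16 * 2), c(16, 16, 2)))
  o1 <- predict_smf(mc, px, vapply(anns1, `[[`, "", "text"))
  o2 <- predict_smf(mc, px, vapply(anns2, `[[`, "", "text"))
  expect_identical(o1$probs, o2$probs)
})

test_that("the fusion chain emits one map per level with halving dims", {
  cfg <- smf_config("tiny")
  m <- ws(6, smf_model(cfg, tiny_vocab(), 32L))
  anns <- lapply(rep("no lesion in the organ", 1), tokenize,
                 vocab = tiny_vocab(), max_len = 20L)
  txt <- encode_text(m$text, anns)
  pyr <- list()
  h <- nd(array(0.1, c(1, 32, 32, 1)))
  for (i in 1:4) {
    if (i > 1) h <- smfnet:::ad_maxpool(pyr[[i - 1]], 2L)
    h <- smfnet:::fwd_cbr(m$enc[[i]]$cbr2,
                          smfnet:::fwd_cbr(m$enc[[i]]$cbr1, h, FALSE), FALSE)
    pyr[[i]] <- h
  }
  M <- down_mtt_chain(m, pyr, txt)
  expect_length(M, 4L)
  for (i in 1:4) {
    expect_equal(dim(ad_val(M[[i]])),
                 c(16L * 2L^(i - 1L), 32L / 2^(i - 1), 32L / 2^(i - 1), 1L))
    expect_true(all(is.finite(ad_val(M[[i]]))))
  }
  # dropping the +x_img residual changes the output (ablation hook)
  M2 <- down_mtt_chain(m, pyr, txt, skip_residual = TRUE)
  expect_false(identical(ad_val(M[[2]]), ad_val(M2[[2]])))
  expect_error(down_mtt_chain(m, pyr[1:3], txt), "levels")
})

test_that("meam gates multiplicatively within the sigmoid bound", {
  m <- tiny_model()
  x <- ws(7, array(rnorm(4 * 16 * 16 * 2), c(4, 16, 16, 2)))
  out <- ad_val(meam(m$meam[[1]], x))
  expect_equal(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  expect_equal(ad_val(meam(m$meam[[1]], array(0, dim(x)))), array(0, dim(x)))
  # constant map: average- and max-pooled streams coincide and the third
  # stream equals their sum pointwise
  cst <- nd(array(0.7, c(4, 8, 8, 1)))
  ap <- smfnet:::ad_scale(smfnet:::ad_sum_ch(cst), 1 / 4)
  mp <- smfnet:::ad_max_ch(cst)
  expect_equal(ad_val(ap), ad_val(mp), tolerance = 1e-12)
  s1 <- ad_val(smfnet:::ad_maxpool(ap, 3L, 1L, 1L))
  s2 <- ad_val(smfnet:::ad_maxpool(mp, 3L, 1L, 1L))
  s3 <- ad_val(smfnet:::ad_maxpool(smfnet:::ad_add(ap, mp), 3L, 1L, 1L))
  expect_equal(s3, s1 + s2, tolerance = 1e-12)
  # spatial-pooling variant holds the same gating bound
  ms <- tiny_model(cfg = tiny_cfg(meam_pool = "spatial"))
  outs <- ad_val(meam(ms$meam[[1]], x))
  expect_true(all(abs(outs) <= abs(x) + 1e-12))
})

test_that("full forward conserves shape and normalizes probabilities", {
  m <- tiny_model()
  px <- ws(8, array(runif(16 * 16 * 2), c(16, 16, 2)))
  txt <- rep("no lesion in the organ", 2)
  out <- smf_forward(m, px, txt)
  expect_equal(dim(ad_val(out$logits)), c(3, 16, 16, 2))
  sums <- apply(ad_val(out$probs), c(2, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # evaluation-mode forward is deterministic
  o2 <- smf_forward(m, px, txt)
  expect_identical(ad_val(out$logits), ad_val(o2$logits))
  expect_error(smf_forward(m, array(0.5, c(15, 15, 1)), "x"), "divisible")
  expect_error(smf_forward(m, array(NaN, c(16, 16, 1)), "x"), "finite")
})

test_that("ablation switches change only their own pathway", {
  px <- ws(9, array(runif(16 * 16 * 1), c(16, 16, 1)))
  txt <- "1 lesion in the upper left of the organ"
  base <- predict_smf(tiny_model(seed = 5), px, txt)
  no_meam <- predict_smf(tiny_model(seed = 5, cfg = tiny_cfg(use_meam = FALSE)),
                         px, txt)
  expect_equal(dim(no_meam$probs), dim(base$probs))
  expect_false(identical(base$probs, no_meam$probs))
  no_mtt <- tiny_model(seed = 5, cfg = tiny_cfg(use_mtt = FALSE))
  p1 <- predict_smf(no_mtt, px, txt)
  p2 <- predict_smf(no_mtt, px, "no lesion in the organ")
  # without the fusion branch the text cannot reach the output
  expect_identical(p1$probs, p2$probs)
})

test_that("checkpoints round-trip the model bit-exactly", {
  m <- tiny_model(seed = 11)
  px <- ws(10, array(runif(16 * 16 * 1), c(16, 16, 1)))
  before <- predict_smf(m, px, "no lesion in the organ")
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  after <- predict_smf(m2, px, "no lesion in the organ")
  expect_identical(before$probs, after$probs)
  expect_error(load_checkpoint(tempfile()), "not found")
})
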