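# Dataset loading, transforms and file round-trips.

write_tiny_corpus <- function(n_img, n_mask, skip_text_for = NULL) {
  dir <- tempfile("io")
  dir.create(file.path(dir, "images"), recursive = TRUE)
  dir.create(file.path(dir, "masks"), recursive = TRUE)
  ids <- sprintf("im%02d", seq_len(n_img))
  for (i in seq_len(n_img)) {
    img <- ws(i, matrix(runif(16 * 16), 16, 16))
    smfnet:::write_gray_png(img, file.path(dir, "images", paste0(ids[i], ".png")))
    if (i <= n_mask) {
      m <- matrix(0L, 16, 16); m[5:9, 5:9] <- 1L; m[7, 7] <- 2L
      smfnet:::write_mask_png(m, file.path(dir, "masks", paste0(ids[i], ".png")))
    }
  }
  keep <- setdiff(ids, skip_text_for)
  write.csv(data.frame(id = keep, text = paste("text for", keep)),
            file.path(dir, "texts.csv"), row.names = FALSE)
  dir
}

test_that("mask presence drives the labeled/unlabeled split", {
  d <- write_tiny_corpus(10, 5)
  ds <- load_dataset(file.path(d, "images"), file.path(d, "masks"),
                     file.path(d, "texts.csv"))
  expect_length(ds$labeled, 5L)
  expect_length(ds$unlabeled, 5L)
  expect_false(is.null(ds$labeled[[1]]$mask))
  expect_null(ds$unlabeled[[1]]$mask)
  expect_match(ds$unlabeled[[1]]$text, "text for")
  d0 <- write_tiny_corpus(10, 0)
  ds0 <- load_dataset(file.path(d0, "images"), file.path(d0, "masks"),
                      file.path(d0, "texts.csv"))
  expect_length(ds0$labeled, 0L)
  expect_length(ds0$unlabeled, 10L)
})

test_that("a missing text row fails naming the offending id", {
  d <- write_tiny_corpus(3, 1, skip_text_for = "im02")
  expect_error(load_dataset(file.path(d, "images"), file.path(d, "masks"),
                            file.path(d, "texts.csv")),
               "im02")
})

test_that("the no-text switch substitutes the constant string", {
  d <- write_tiny_corpus(2, 1)
  ds <- load_dataset(file.path(d, "images"), file.path(d, "masks"),
                     file.path(d, "texts.csv"), no_text = TRUE)
  expect_equal(ds$labeled[[1]]$text, "no finding")
})

test_that("identity transform is a bit-exact no-op", {
  img <- image_batch(ws(1, array(runif(16 * 16 * 2), c(16, 16, 2))))
  msk <- mask_batch(random_mask(16, 16, 2, seed = 2))
  out <- apply_transform(augment_transform("identity"), img, msk)
  expect_identical(out$image$pixels, img$pixels)
  expect_identical(out$mask$labels, msk$labels)
})

test_that("four quarter-turns restore the original batch", {
  img <- image_batch(ws(3, array(runif(16 * 16 * 2), c(16, 16, 2))))
  t1 <- augment_transform("rotation90", list(k = 1L))
  cur <- img
  for (i in 1:4) cur <- apply_transform(t1, cur)$image
  expect_identical(cur$pixels, img$pixels)
  t4 <- augment_transform("rotation90", list(k = 4L))
  expect_identical(apply_transform(t4, img)$image$pixels, img$pixels)
})

test_that("gaussian noise is reproducible given the seed", {
  img <- image_batch(array(0.5, c(16, 16, 1)))
  t <- augment_transform("gaussian-noise", list(sd = 0.1), seed = 99L)
  a <- apply_transform(t, img)$image$pixels
  b <- apply_transform(t, img)$image$pixels
  expect_identical(a, b)
  t2 <- augment_transform("gaussian-noise", list(sd = 0.1), seed = 100L)
  expect_false(identical(a, apply_transform(t2, img)$image$pixels))
})

test_that("spatial transforms keep image and mask aligned", {
  # delta image and delta mask at the same pixel must move together
  for (tr in list(augment_transform("rotation90", list(k = 1L)),
                  augment_transform("rotation90", list(k = 3L)),
                  augment_transform("horizontal-flip"))) {
    px <- array(0, c(16, 16, 1)); px[4, 11, 1] <- 1
    mk <- array(0L, c(16, 16, 1)); mk[4, 11, 1] <- 2L
    out <- apply_transform(tr, image_batch(px), mask_batch(mk))
    expect_equal(which(out$image$pixels == 1), which(out$mask$labels == 2L))
    expect_equal(sum(out$mask$labels == 2L), 1L)
  }
})

test_that("rotation90 rejects non-square grids", {
  px <- array(0, c(16, 8, 1))
  expect_error(apply_transform(augment_transform("rotation90"),
                               image_batch(px)), "square")
})

test_that("predictions round-trip losslessly through PNG and NIfTI", {
  lab <- random_mask(16, 16, 1, seed = 8)
  probs <- one_hot(lab, 3L) * 0.98 + 0.01
  seg <- seg_output(log(probs))
  expect_identical(seg$labels, lab)   # argmax recovers the construction
  p1 <- tempfile(fileext = ".png")
  write_prediction(seg, p1, "png")
  expect_identical(read_prediction(p1), matrix(lab[, , 1], 16, 16))
  p2 <- tempfile(fileext = ".nii.gz")
  write_prediction(seg, p2, "nifti")
  expect_identical(read_prediction(p2), matrix(lab[, , 1], 16, 16))
  # header affine is preserved on a plain write
  v <- RNifti::readNifti(p2)
  expect_equal(dim(v), c(16, 16))
  expect_error(write_prediction(seg, tempfile(), "bmp"))
  # all-background prediction writes a file of zeros
  z <- seg_output(log(one_hot(array(0L, c(8, 8, 1)), 2L) * 0.9 + 0.05))
  p3 <- tempfile(fileext = ".png")
  write_prediction(z, p3, "png")
  expect_true(all(read_prediction(p3) == 0L))
})

test_that("a 64x64 NIfTI map survives write/read bit-exactly", {
  lab <- random_mask(64, 64, 1, seed = 12)
  seg <- seg_output(log(one_hot(lab, 3L) * 0.9 + 0.05))
  p <- tempfile(fileext = ".nii.gz")
  write_prediction(seg, p, "nifti")
  expect_identical(read_prediction(p), matrix(lab[, , 1], 64, 64))
})
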