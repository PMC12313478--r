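# Reading/writing images, masks and text tables, plus the paired
# perturbations used by the consistency machinery. Masks and images are
# row-major with origin top-left; NIfTI affines pass through untouched.

#' Construct an image batch
#' @param pixels array (H,W,N) with intensities in \[0,1\] (a single matrix
#'   is promoted to N = 1).
#' @param ids sample identifiers.
#' @return an `image_batch`.
#' @export
image_batch <- function(pixels, ids = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(length(dim(pixels)) == 3L)
  if (any(!is.finite(pixels))) stop("non-finite pixel values")
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(dim(pixels)[3]))
  structure(list(pixels = pixels, ids = ids), class = "image_batch")
}

#' Construct a mask batch
#' @param labels integer array (H,W,N) with values in 0..K-1.
#' @param num_classes K.
#' @return a `mask_batch`.
#' @export
mask_batch <- function(labels, num_classes = 3L) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  stopifnot(length(dim(labels)) == 3L)
  if (any(labels < 0L | labels >= num_classes))
    stop("labels outside 0..", num_classes - 1L)
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 num_classes = as.integer(num_classes)),
            class = "mask_batch")
}

write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

read_image_any <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(read_gray_png(path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- RNifti::readNifti(path)
    a <- as.array(v)
    if (length(dim(a)) > 2L) a <- a[, , 1]
    return(a)
  }
  stop("unsupported image format: ", path)
}

read_text_table <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    tb <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    stop("unsupported text table format: ", path)
  }
  stopifnot(all(c("id", "text") %in% names(tb)))
  setNames(as.character(tb$text), tb$id)
}

#' Load a multimodal dataset from disk
#'
#' Samples with a mask file are labeled; the rest form the unlabeled pool
#' (unlabeled samples keep their text). Every image id must appear in the
#' text table.
#'
#' @param image_dir directory of PNG/NIfTI images.
#' @param mask_dir directory of mask files (may be missing/empty).
#' @param text_table CSV or JSON-Lines file with columns `id`, `text`.
#' @param no_text replace all text with the constant no-finding string
#'   (text-disabled ablation).
#' @return list with `labeled` and `unlabeled` sample lists; each sample has
#'   `id`, `image`, `text` and (labeled only) `mask`.
#' @export
load_dataset <- function(image_dir, mask_dir = NULL, text_table,
                         no_text = FALSE) {
  files <- sort(list.files(image_dir, pattern = "\\.(png|nii|nii\\.gz)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no images found in ", image_dir)
  texts <- read_text_table(text_table)
  labeled <- list()
  unlabeled <- list()
  for (f in files) {
    id <- sub("\\.(png|nii|nii\\.gz)$", "", f, ignore.case = TRUE)
    if (!id %in% names(texts))
      stop("text table has no row for image id '", id, "'")
    img <- read_image_any(file.path(image_dir, f))
    txt <- if (no_text) "no finding" else unname(texts[[id]])
    mpath <- if (!is.null(mask_dir)) file.path(mask_dir, f) else ""
    if (nzchar(mpath) && file.exists(mpath)) {
      mask <- read_mask_png(mpath)
      if (!all(dim(mask) == dim(img)))
        stop("mask/image shape mismatch for id '", id, "'")
      labeled[[length(labeled) + 1L]] <-
        list(id = id, image = img, mask = mask, text = txt)
    } else {
      unlabeled[[length(unlabeled) + 1L]] <-
        list(id = id, image = img, text = txt)
    }
  }
  list(labeled = labeled, unlabeled = unlabeled)
}

#' Load a generated corpus directory
#' @param dir directory written by [generate_corpus()].
#' @param no_text text-disabled ablation flag.
#' @return see [load_dataset()].
#' @export
load_corpus <- function(dir, no_text = FALSE) {
  load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
               file.path(dir, "texts.csv"), no_text = no_text)
}

# Stack a list of samples into batches.
stack_samples <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  px <- array(0, dim = c(H, W, length(samples)))
  for (i in seq_along(samples)) px[, , i] <- samples[[i]]$image
  img <- image_batch(px, vapply(samples, `[[`, "", "id"))
  has_mask <- !is.null(samples[[1]]$mask)
  msk <- NULL
  if (has_mask) {
    lb <- array(0L, dim = c(H, W, length(samples)))
    for (i in seq_along(samples)) lb[, , i] <- samples[[i]]$mask
    msk <- mask_batch(lb)
  }
  list(image = img, mask = msk,
       texts = vapply(samples, `[[`, "", "text"))
}

# ---- augmentation transforms ------------------------------------------------

#' Construct an augmentation transform
#'
#' Spatial kinds (`rotation90`, `horizontal-flip`) are label-preserving grid
#' bijections applied identically to image and mask; intensity kinds
#' (`gaussian-noise`, `brightness`) act on the image only. Deterministic
#' given (`params`, `seed`).
#'
#' @param kind one of `"identity"`, `"rotation90"`, `"horizontal-flip"`,
#'   `"gaussian-noise"`, `"brightness"`.
#' @param params kind-specific list: `k` quarter-turns, `sd` noise level, or
#'   `delta` brightness shift.
#' @param seed integer used by `gaussian-noise`.
#' @return an `augment_transform`.
#' @export
augment_transform <- function(kind = c("identity", "rotation90",
                                       "horizontal-flip", "gaussian-noise",
                                       "brightness"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    identity = list(),
    rotation90 = list(k = 1L),
    `horizontal-flip` = list(),
    `gaussian-noise` = list(sd = 0.05),
    brightness = list(delta = 0.1))
  params <- utils::modifyList(defaults, params)
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "augment_transform")
}

is_spatial <- function(t) t$kind %in% c("identity", "rotation90", "horizontal-flip")

# Pixel permutation over the flattened H*W grid (column-major flattening,
# matching R matrices): out_flat = in_flat[perm].
transform_perm <- function(t, H, W) {
  idx <- matrix(seq_len(H * W), H, W)
  out <- switch(t$kind,
    identity = idx,
    `horizontal-flip` = idx[, W:1, drop = FALSE],
    rotation90 = {
      k <- t$params$k %% 4L
      m <- idx
      for (i in seq_len(k)) {
        if (nrow(m) != ncol(m)) stop("rotation90 requires a square grid")
        m <- t(m)[nrow(m):1, , drop = FALSE]   # one quarter turn CCW... (CW in row/col terms)
      }
      m
    },
    stop("transform kind '", t$kind, "' is not spatial"))
  as.integer(out)
}

#' Apply a transform to image (and optionally mask) batches
#'
#' @param t an [augment_transform()].
#' @param img an `image_batch` (or (H,W,N) array).
#' @param mask optional `mask_batch`; only spatial kinds touch it.
#' @return list with `image` and (when given) `mask`, transformed in
#'   lockstep.
#' @export
apply_transform <- function(t, img, mask = NULL) {
  if (!inherits(t, "augment_transform")) stop("unknown transform object")
  px <- if (inherits(img, "image_batch")) img$pixels else img
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  d <- dim(px)
  H <- d[1]; W <- d[2]; N <- d[3]
  if (is_spatial(t)) {
    perm <- transform_perm(t, H, W)
    pm <- array(px, dim = c(H * W, N))[perm, , drop = FALSE]
    out_px <- array(pm, dim = d)
    out_mask <- NULL
    if (!is.null(mask)) {
      lb <- if (inherits(mask, "mask_batch")) mask$labels else mask
      lm <- array(lb, dim = c(H * W, N))[perm, , drop = FALSE]
      out_mask <- mask_batch(array(lm, dim = d),
                             if (inherits(mask, "mask_batch")) mask$num_classes else 3L)
    }
  } else {
    out_px <- switch(t$kind,
      `gaussian-noise` = {
        noise <- with_seed(t$seed, array(rnorm(prod(d), sd = t$params$sd), d))
        pmin(pmax(px + noise, 0), 1)
      },
      brightness = pmin(pmax(px + t$params$delta, 0), 1))
    out_mask <- if (!is.null(mask)) {
      if (inherits(mask, "mask_batch")) mask else mask_batch(mask)
    }
  }
  ids <- if (inherits(img, "image_batch")) img$ids else NULL
  list(image = image_batch(out_px, ids), mask = out_mask)
}

# Apply a spatial transform to a probability node (K,H,W,N); identity for
# intensity-only kinds (they do not move labels).
transform_probs_node <- function(t, probs, H, W) {
  if (!is_spatial(t) || t$kind == "identity") return(nd(probs))
  ad_pixperm(nd(probs), transform_perm(t, H, W), H, W)
}

#' Write a segmentation prediction to disk
#'
#' The argmax label map round-trips exactly: reading the file back yields
#' the identical integer map.
#'
#' @param seg a `seg_output` (single sample or batch of 1).
#' @param path output file.
#' @param format `"png"` or `"nifti"`.
#' @return the path, invisibly.
#' @export
write_prediction <- function(seg, path, format = c("png", "nifti")) {
  format <- match.arg(format)
  lab <- seg$labels
  if (length(dim(lab)) == 3L) {
    stopifnot(dim(lab)[3] == 1L)
    lab <- lab[, , 1]
  }
  if (format == "png") {
    write_mask_png(lab, path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(lab), dim = dim(lab))),
                       path)
  }
  invisible(path)
}

#' Read a prediction written by [write_prediction()]
#' @param path file path.
#' @return integer label matrix.
#' @export
read_prediction <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(read_mask_png(path))
  a <- as.array(RNifti::readNifti(path))
  matrix(as.integer(round(a)), dim(a)[1], dim(a)[2])
}
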