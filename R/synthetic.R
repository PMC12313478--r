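# Synthetic multimodal phantoms: a low-contrast elliptical "organ"
# containing small circular "lesions", plus a templated text string tied to
# the mask (lesion count and location), in the exact on-disk layout the
# loader reads. The text/mask link is causal by construction, so ablations
# that disable text have a measurable effect.

#' Phantom specification
#'
#' @param grid c(H, W); each divisible by 16 for the default 4-level model.
#' @param organ list with `center` c(row, col), `axes` c(a, b) in pixels,
#'   `angle` radians.
#' @param lesions list of lesions: each a list with `center` c(row, col),
#'   `radius` (> 0) and optional `intensity` offset (defaults to
#'   `contrast`).
#' @param noise_sd gaussian pixel noise standard deviation.
#' @param contrast intensity gap between lesion and organ tissue, in (0,1].
#' @param seed integer; fixes the noise realization.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(64L, 64L),
                         organ = list(center = grid / 2, axes = c(20, 12),
                                      angle = 0),
                         lesions = list(),
                         noise_sd = 0.05,
                         contrast = 0.15,
                         seed = 1L) {
  stopifnot(length(grid) == 2L, contrast > 0, contrast <= 1, noise_sd >= 0)
  for (l in lesions) stopifnot(l$radius > 0)
  structure(list(grid = as.integer(grid), organ = organ, lesions = lesions,
                 noise_sd = noise_sd, contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

inside_ellipse <- function(rows, cols, organ) {
  ca <- cos(organ$angle); sa <- sin(organ$angle)
  dr <- rows - organ$center[1]
  dc <- cols - organ$center[2]
  u <- ca * dr + sa * dc
  v <- -sa * dr + ca * dc
  (u / organ$axes[1])^2 + (v / organ$axes[2])^2 <= 1
}

# Location word from the centroid of the label-2 pixels relative to the
# organ bounding box, split into thirds per axis (origin top-left).
location_words <- function(mask) {
  org <- which(mask >= 1L, arr.ind = TRUE)
  les <- which(mask == 2L, arr.ind = TRUE)
  if (nrow(les) == 0L) return(NULL)
  cen <- colMeans(les)
  fr <- (cen[1] - min(org[, 1])) / max(1L, diff(range(org[, 1])))
  fc <- (cen[2] - min(org[, 2])) / max(1L, diff(range(org[, 2])))
  vert <- c("upper", "middle", "lower")[pmin(3L, 1L + floor(fr * 3))]
  horiz <- c("left", "center", "right")[pmin(3L, 1L + floor(fc * 3))]
  c(vert, horiz)
}

phantom_text <- function(mask, n_lesions) {
  if (n_lesions == 0L) return("no lesion in the organ")
  loc <- location_words(mask)
  sprintf("%d lesion%s in the %s %s of the organ",
          n_lesions, if (n_lesions > 1L) "s" else "", loc[1], loc[2])
}

#' Generate one phantom sample
#'
#' The mask carries label 1 on organ-minus-lesion pixels and label 2 on
#' lesion pixels; the image is a piecewise-constant base (background 0.30,
#' organ 0.45, lesion offset by `contrast`) plus seeded gaussian noise,
#' clipped to \[0,1\]; the text states the lesion count and, when lesions
#' exist, one of nine location phrases derived from the lesion centroid.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (H,W matrix), `mask` (H,W integer matrix) and
#'   `text` (string).
#' @export
generate_sample <- function(spec) {
  H <- spec$grid[1]; W <- spec$grid[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  organ <- inside_ellipse(rows, cols, spec$organ)
  mask <- matrix(0L, H, W)
  mask[organ] <- 1L
  img <- matrix(0.30, H, W)
  img[organ] <- 0.45
  for (l in spec$lesions) {
    if (!inside_ellipse(l$center[1], l$center[2], spec$organ))
      stop("lesion center at (", l$center[1], ",", l$center[2],
           ") lies outside the organ")
    disk <- ((rows - l$center[1])^2 + (cols - l$center[2])^2 <= l$radius^2) &
      organ
    mask[disk] <- 2L
    img[disk] <- 0.45 + (l$intensity %||% spec$contrast)
  }
  img <- with_seed(spec$seed,
                   img + matrix(rnorm(H * W, sd = spec$noise_sd), H, W))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, text = phantom_text(mask, length(spec$lesions)))
}

# Draw a randomized phantom spec around a base spec. Lesion count follows
# `count_probs` over 0..(length-1); lesion centers are sampled inside a
# shrunken organ ellipse so the whole disk stays inside tissue.
random_spec <- function(base, seed, count_probs = c(0.25, 0.5, 0.25),
                        radius_range = NULL) {
  H <- base$grid[1]
  if (is.null(radius_range)) radius_range <- c(3, 6) * H / 64
  with_seed(seed, {
    organ <- base$organ
    organ$center <- organ$center + runif(2, -0.05, 0.05) * H
    organ$axes <- organ$axes * runif(2, 0.85, 1.15)
    organ$angle <- runif(1, -pi / 6, pi / 6)
    n_les <- sample.int(length(count_probs), 1L, prob = count_probs) - 1L
    lesions <- list()
    for (i in seq_len(n_les)) {
      repeat {
        r <- runif(1, radius_range[1], radius_range[2])
        # uniform in the unit disk, mapped into the shrunken ellipse
        th <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
        shrink <- pmax(organ$axes - r - 1, 0.3 * organ$axes)
        u <- rad * cos(th) * shrink[1]
        v <- rad * sin(th) * shrink[2]
        ca <- cos(organ$angle); sa <- sin(organ$angle)
        cen <- organ$center + c(ca * u - sa * v, sa * u + ca * v)
        if (inside_ellipse(cen[1], cen[2], organ)) break
      }
      lesions[[i]] <- list(center = cen, radius = r)
    }
    phantom_spec(base$grid, organ, lesions, base$noise_sd, base$contrast,
                 seed = sample.int(.Machine$integer.max, 1L))
  })
}

#' Generate a phantom corpus on disk
#'
#' Writes `n_labeled + n_unlabeled` samples in the loader's layout:
#' `images/<id>.png`, `masks/<id>.png` (labeled ids only), `texts.csv` and a
#' JSON manifest recording every sample's specification. Per-sample seeds
#' derive deterministically from `seed`.
#'
#' @param dir output directory (created).
#' @param n_labeled,n_unlabeled sample counts (>= 0).
#' @param base_spec template [phantom_spec()]; geometry randomizes around it.
#' @param seed corpus seed.
#' @param count_probs probabilities of 0, 1, ... lesions per sample.
#' @param radius_range lesion radius bounds in pixels (default scales the
#'   3-6 px range of a 64-px grid).
#' @return the manifest, invisibly.
#' @export
generate_corpus <- function(dir, n_labeled, n_unlabeled,
                            base_spec = phantom_spec(), seed = 1L,
                            count_probs = c(0.25, 0.5, 0.25),
                            radius_range = NULL) {
  stopifnot(n_labeled >= 0L, n_unlabeled >= 0L)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- n_labeled + n_unlabeled
  seeds <- with_seed(seed, sample.int(1e9, max(n, 1L)))
  ids <- sprintf("ph%04d", seq_len(n))
  texts <- character(n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- random_spec(base_spec, seeds[i], count_probs, radius_range)
    s <- generate_sample(sp)
    write_gray_png(s$image, file.path(dir, "images", paste0(ids[i], ".png")))
    if (i <= n_labeled)
      write_mask_png(s$mask, file.path(dir, "masks", paste0(ids[i], ".png")))
    texts[i] <- s$text
    manifest[[i]] <- list(id = ids[i], labeled = i <= n_labeled,
                          n_lesions = length(sp$lesions),
                          seed = seeds[i], text = s$text)
  }
  utils::write.csv(data.frame(id = ids, text = texts),
                   file.path(dir, "texts.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_labeled = n_labeled,
                            n_unlabeled = n_unlabeled,
                            grid = base_spec$grid,
                            contrast = base_spec$contrast,
                            noise_sd = base_spec$noise_sd,
                            samples = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
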