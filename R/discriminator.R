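#' Construct an adversarial discriminator
#'
#' Scores (image, predicted-mask) pairs with a per-sample realness value in
#' (0,1). The image and the class-probability map are concatenated along
#' channels and passed through four stride-2 Conv-LeakyReLU blocks, one
#' pooling-based attention gate (the same MEAM construction used at the
#' segmentation skip connections), global average pooling and a linear head.
#' Both discriminators of the dual-student framework are built by this one
#' constructor, which guarantees their structural identity.
#'
#' @param num_classes number of probability channels in the mask input.
#' @param base width of the first convolution block.
#' @param meam_pool pooling axis for the attention gate.
#' @return a `smf_disc` module list.
#' @export
disc_model <- function(num_classes = 3L, base = 16L,
                       meam_pool = c("channel", "spatial")) {
  meam_pool <- match.arg(meam_pool)
  cin <- 1L + num_classes
  widths <- base * c(1L, 2L, 4L, 8L)
  blocks <- list()
  for (i in seq_along(widths)) {
    blocks[[i]] <- init_conv(if (i == 1L) cin else widths[i - 1L], widths[i], 4L)
  }
  fake_cfg <- list(meam_pool = meam_pool)
  structure(list(num_classes = as.integer(num_classes),
                 blocks = blocks,
                 att = init_meam(widths[length(widths)], fake_cfg),
                 headw = init_linear(widths[length(widths)], 1L)),
            class = c("smf_disc", "list"))
}

# Forward to the pre-sigmoid logit node; n-vector output.
disc_logits <- function(disc, images, probs) {
  px <- if (inherits(images, "image_batch")) images$pixels else images
  if (is.array(px) && length(dim(px)) == 3L) {
    d <- dim(px)
    px <- array(px, dim = c(1L, d[1], d[2], d[3]))
  }
  px <- nd(px)
  probs <- nd(probs)
  dp <- dim(probs$value)
  di <- dim(px$value)
  if (!all(di[2:4] == dp[2:4]))
    stop("image and probability map shapes disagree: ",
         paste(di, collapse = "x"), " vs ", paste(dp, collapse = "x"))
  h <- ad_concat_ch(px, probs)
  for (b in disc$blocks) {
    h <- ad_leaky_relu(ad_conv2d(h, b$w, b$b, 4L, pad = 1L, stride = 2L), 0.2)
  }
  h <- meam(disc$att, h)
  g <- ad_gap(h)
  z <- ad_linear(g, disc$headw$w, disc$headw$b)
  ad_node(as.numeric(z$value), list(z), function(gr) list(matrix(gr, ncol = 1L)))
}

#' Score (image, segmentation) pairs
#'
#' @param disc a `smf_disc`.
#' @param images array (H,W,N) or `image_batch`.
#' @param seg_probs array or node (K,H,W,N) of class probabilities.
#' @return numeric vector of per-sample realness scores in (0,1).
#' @export
discriminate <- function(disc, images, seg_probs) {
  if (inherits(seg_probs, "seg_output")) seg_probs <- seg_probs$probs
  with_no_grad(val(ad_sigmoid(disc_logits(disc, images, seg_probs))))
}
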