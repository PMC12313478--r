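#' Model configuration
#'
#' Builds the configuration list for the dual U-shaped segmentation network.
#' The encoder is a conventional U-Net channel ladder (`base_channels`
#' doubling per level); the text-guided branch fuses broadcast text features
#' into each encoder level through a gated transformer block; a
#' pooling-based attention gate (MEAM) sits at every skip connection.
#'
#' @param preset `"tiny"` (16-channel ladder, 64x64 inputs) or `"full"`
#'   (64-channel ladder, 256x256 inputs).
#' @param depth number of resolution levels.
#' @param base_channels channels at the first level.
#' @param num_classes number of segmentation classes (background included).
#' @param d_text text embedding dimensionality.
#' @param vit_dim,vit_heads,vit_mlp_ratio transformer block geometry used by
#'   the fusion blocks.
#' @param vit_max_tokens spatial maps are average-pooled into square patches
#'   until at most this many tokens enter a transformer block.
#' @param use_text,use_meam,use_mtt ablation switches: constant text,
#'   identity skip attention, and removal of the text-fusion branch.
#' @param meam_pool `"channel"` (pool across channels, spatial gate) or
#'   `"spatial"` (pool across pixels, channel gate).
#' @param max_len,coarse_window,text_layers text encoder geometry.
#' @param no_text_string replacement text used when `use_text = FALSE`.
#' @return a config list of class `smf_config`.
#' @export
smf_config <- function(preset = c("tiny", "full"),
                       depth = 4L,
                       base_channels = NULL,
                       num_classes = 3L,
                       d_text = 64L,
                       vit_dim = 64L,
                       vit_heads = 4L,
                       vit_mlp_ratio = 2,
                       vit_max_tokens = 64L,
                       use_text = TRUE,
                       use_meam = TRUE,
                       use_mtt = TRUE,
                       meam_pool = c("channel", "spatial"),
                       max_len = 20L,
                       coarse_window = 2L,
                       text_layers = 2L,
                       no_text_string = "no finding") {
  preset <- match.arg(preset)
  meam_pool <- match.arg(meam_pool)
  if (is.null(base_channels)) base_channels <- if (preset == "tiny") 16L else 64L
  stopifnot(depth >= 2L, base_channels >= 1L, num_classes >= 2L,
            vit_dim %% vit_heads == 0L)
  structure(list(
    preset = preset, depth = as.integer(depth),
    base_channels = as.integer(base_channels),
    num_classes = as.integer(num_classes),
    d_text = as.integer(d_text), vit_dim = as.integer(vit_dim),
    vit_heads = as.integer(vit_heads), vit_mlp_ratio = vit_mlp_ratio,
    vit_max_tokens = as.integer(vit_max_tokens),
    use_text = use_text, use_meam = use_meam, use_mtt = use_mtt,
    meam_pool = meam_pool, max_len = as.integer(max_len),
    coarse_window = as.integer(coarse_window),
    text_layers = as.integer(text_layers),
    no_text_string = no_text_string
  ), class = "smf_config")
}

level_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

# Patch edge for a transformer block at map size h x w: smallest power of two
# with (h/p)*(w/p) <= max_tokens.
patch_edge <- function(h, w, max_tokens) {
  p <- 1L
  while ((h %/% p) * (w %/% p) > max_tokens) p <- p * 2L
  p
}

init_vit_unit <- function(C, h, w, cfg) {
  p <- patch_edge(h, w, cfg$vit_max_tokens)
  L <- (h %/% p) * (w %/% p)
  list(
    p = p, L = L, h = h, w = w, C = C,
    win = init_linear(C, cfg$vit_dim),
    block = init_tblock(cfg$vit_dim, cfg$vit_heads, cfg$vit_mlp_ratio),
    wout = init_linear(cfg$vit_dim, C)
  )
}

# No positional embedding here: token identity comes entirely from content,
# so a spatially constant input yields a spatially constant output.
fwd_vit_unit <- function(m, x) {
  tok <- ad_patchify(x, m$p)
  tok <- ad_linear(tok, m$win$w, m$win$b)
  tok <- fwd_tblock(m$block, tok, m$L)
  tok <- ad_linear(tok, m$wout$w, m$wout$b)
  ad_unpatchify(tok, m$C, m$h, m$w, m$p)
}

init_ctbn <- function(C, d_text) {
  list(lin = init_linear(d_text, C), conv = init_conv(C, C, 1L), bn = init_bn(C))
}

init_meam <- function(C, cfg) {
  if (cfg$meam_pool == "channel") {
    list(pool = "channel", cbr = init_conv(C, C, 3L), clab = init_conv(1L, 1L, 1L))
  } else {
    list(pool = "spatial", cbr = init_conv(C, C, 3L), clab = init_linear(C, C))
  }
}

#' Construct the segmentation model
#'
#' All parameters are drawn from the current RNG stream in a fixed order, so
#' `set.seed()` before the call fixes the initialization.
#'
#' @param cfg an [smf_config()].
#' @param vocab an `smf_vocab` built from the training texts.
#' @param img_size input edge length (square grids); must be divisible by
#'   `2^depth`.
#' @return a model object (nested list of parameter nodes) of class
#'   `smf_model`.
#' @export
smf_model <- function(cfg, vocab, img_size = 64L) {
  stopifnot(inherits(cfg, "smf_config"), img_size %% 2L^cfg$depth == 0L)
  ch <- level_channels(cfg)
  sizes <- img_size %/% 2L^(seq_len(cfg$depth) - 1L)
  enc <- list()
  for (i in seq_len(cfg$depth)) {
    cin <- if (i == 1L) 1L else ch[i - 1L]
    enc[[i]] <- list(cbr1 = init_cbr(cin, ch[i]), cbr2 = init_cbr(ch[i], ch[i]))
  }
  text <- text_encoder(vocab, cfg$d_text, cfg$max_len, cfg$text_layers,
                       cfg$vit_heads, cfg$coarse_window)
  ctbn <- lapply(seq_len(cfg$depth), function(i) init_ctbn(ch[i], cfg$d_text))
  vit_down <- lapply(seq_len(cfg$depth), function(i)
    init_vit_unit(ch[i], sizes[i], sizes[i], cfg))
  mtt_ds <- vector("list", cfg$depth)
  for (i in seq(2L, cfg$depth)) mtt_ds[[i]] <- init_conv(ch[i - 1L], ch[i], 1L)
  vit_up <- vector("list", cfg$depth)
  up_mtt <- vector("list", cfg$depth)
  for (i in seq(cfg$depth - 1L, 1L)) {
    up_mtt[[i]] <- init_conv(ch[i + 1L], ch[i], 3L)
    vit_up[[i]] <- init_vit_unit(ch[i], sizes[i], sizes[i], cfg)
  }
  meam <- lapply(seq_len(cfg$depth), function(i) init_meam(ch[i], cfg))
  up_cnn <- vector("list", cfg$depth)
  for (i in seq(cfg$depth - 1L, 1L)) {
    up_cnn[[i]] <- list(up = init_conv(ch[i + 1L], ch[i], 3L),
                        cbr1 = init_cbr(ch[i], ch[i]),
                        cbr2 = init_cbr(ch[i], ch[i]))
  }
  head <- init_conv(ch[1L], cfg$num_classes, 1L)
  structure(list(cfg = cfg, img_size = as.integer(img_size), text = text,
                 enc = enc, ctbn = ctbn, vit_down = vit_down, mtt_ds = mtt_ds,
                 vit_up = vit_up, up_mtt = up_mtt, meam = meam,
                 up_cnn = up_cnn, head = head),
            class = c("smf_model", "list"))
}

# ---- forward pieces ---------------------------------------------------------

#' One encoder down-sampling stage
#'
#' Two Conv3x3-BatchNorm-ReLU blocks followed by 2x2 max pooling: channels
#' change from the stage's input width to its output width and spatial
#' dimensions halve.
#'
#' @param stage a stage module (`model$enc[[i]]`).
#' @param x feature node or array (C,H,W,N).
#' @param train batch-norm mode.
#' @return pooled feature node at the next level.
#' @export
down_cnn <- function(stage, x, train = FALSE) {
  x <- nd(x)
  d <- dim(x$value)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L)
    stop("spatial dims must be even for 2x2 pooling, got ", d[2], "x", d[3])
  ad_maxpool(fwd_cbr(stage$cbr2, fwd_cbr(stage$cbr1, x, train), train), 2L)
}

#' Text-conditioning block (CTBN)
#'
#' Projects the pooled text embedding to the level's channel width,
#' broadcasts it over the spatial grid, and applies Conv1x1-BatchNorm-ReLU.
#' The output is non-negative and spatially constant per channel.
#'
#' @param mod a ctbn module (`model$ctbn[[i]]`).
#' @param pooled pooled text node or matrix (N, d_text).
#' @param h,w target spatial size.
#' @param train batch-norm mode.
#' @return feature node (C, h, w, N).
#' @export
ctbn <- function(mod, pooled, h, w, train = FALSE) {
  v <- ad_linear(nd(pooled), mod$lin$w, mod$lin$b)
  x <- ad_broadcast_hw(v, h, w)
  x <- ad_conv2d(x, mod$conv$w, mod$conv$b, mod$conv$k)
  x <- ad_batchnorm(x, mod$bn$gamma, mod$bn$beta, mod$bn$st, train)
  ad_relu(x)
}

#' Multimodal token-transformer fusion
#'
#' Gates the image features by the broadcast text features (Hadamard
#' product) and passes the result through a transformer encoder block over
#' spatial patch tokens.
#'
#' @param model an `smf_model`.
#' @param level pyramid level (1-based).
#' @param img_feat feature node (C,h,w,N) at that level.
#' @param txt output of [encode_text()].
#' @param train batch-norm mode.
#' @param path `"down"` or `"up"` transformer stack.
#' @return fused feature node, same shape as `img_feat`.
#' @export
mtt_fuse <- function(model, level, img_feat, txt, train = FALSE, path = "down") {
  img_feat <- nd(img_feat)
  vm <- if (path == "down") model$vit_down[[level]] else model$vit_up[[level]]
  d <- dim(img_feat$value)
  if (d[2] != vm$h || d[3] != vm$w)
    stop("feature map ", d[2], "x", d[3], " does not match level ", level,
         " transformer geometry ", vm$h, "x", vm$w)
  ct <- ctbn(model$ctbn[[level]], txt$pooled, vm$h, vm$w, train)
  fwd_vit_unit(vm, ad_mul(img_feat, ct))
}

#' Hierarchical text-fusion encoder chain
#'
#' Level 1 fuses the first encoder stage's features with the text; each
#' deeper level fuses the down-sampled previous fusion output added to the
#' corresponding encoder features.
#'
#' @param model an `smf_model`.
#' @param img_pyramid list of per-level encoder feature nodes.
#' @param txt output of [encode_text()].
#' @param train batch-norm mode.
#' @param skip_residual drop the `+ x_img` term (ablation hook).
#' @return list of fused feature nodes, one per level.
#' @export
down_mtt_chain <- function(model, img_pyramid, txt, train = FALSE,
                           skip_residual = FALSE) {
  depth <- model$cfg$depth
  if (length(img_pyramid) != depth)
    stop("image pyramid has ", length(img_pyramid), " levels, expected ", depth)
  M <- vector("list", depth)
  M[[1L]] <- mtt_fuse(model, 1L, img_pyramid[[1L]], txt, train)
  for (i in seq(2L, depth)) {
    ds <- ad_conv2d(ad_maxpool(M[[i - 1L]], 2L),
                    model$mtt_ds[[i]]$w, model$mtt_ds[[i]]$b, 1L)
    x <- if (skip_residual) ds else ad_add(ds, nd(img_pyramid[[i]]))
    M[[i]] <- mtt_fuse(model, i, x, txt, train)
  }
  M
}

#' Multimodal enhanced attention module
#'
#' A pooling-based gate in the style of CBAM's mean/max fusion: after a
#' Conv3x3+ReLU, average- and max-pooled maps are each sharpened by a
#' stride-1 3x3 spatial max pool, a third stream pools their sum, the three
#' streams are summed and squashed through a Conv1x1+sigmoid alignment layer,
#' and the resulting gate in (0,1) multiplies the input.
#'
#' @param mod a meam module (`model$meam[[i]]`).
#' @param x feature node (C,h,w,N).
#' @return gated feature node, same shape; elementwise no larger in
#'   magnitude than `x`.
#' @export
meam <- function(mod, x) {
  x <- nd(x)
  f <- ad_relu(ad_conv2d(x, mod$cbr$w, mod$cbr$b, mod$cbr$k))
  if (mod$pool == "channel") {
    C <- dim(f$value)[1L]
    ap <- ad_scale(ad_sum_ch(f), 1 / C)
    mp <- ad_max_ch(f)
    s1 <- ad_maxpool(ap, 3L, 1L, 1L)
    s2 <- ad_maxpool(mp, 3L, 1L, 1L)
    s3 <- ad_maxpool(ad_add(ap, mp), 3L, 1L, 1L)
    s <- ad_add(ad_add(s1, s2), s3)
    gate <- ad_sigmoid(ad_conv2d(s, mod$clab$w, mod$clab$b, 1L))
    ad_mul_gate(x, gate)
  } else {
    ap <- ad_gap(f)
    mp <- ad_max_sp(f)
    s <- ad_add(ad_add(ap, mp), ad_add(ap, mp))
    gate <- ad_sigmoid(ad_linear(s, mod$clab$w, mod$clab$b))
    ad_mul_chvec(x, gate)
  }
}

#' Full forward pass
#'
#' Runs the CNN encoder, the parallel text-fusion chain, the transformer
#' decoder path, the gated skip connections and the CNN decoder, ending in a
#' 1x1 convolution to per-class logits at input resolution.
#'
#' @param model an `smf_model`.
#' @param images array (H,W,N) or `image_batch`.
#' @param texts list of `text_annotation`s, or character vector (tokenized
#'   with the model's vocabulary). Ignored (replaced by the constant
#'   no-finding string) when `cfg$use_text` is FALSE.
#' @param train batch-norm mode; evaluation mode is deterministic.
#' @return list with `logits` and `probs` nodes (K,H,W,N).
#' @export
smf_forward <- function(model, images, texts = NULL, train = FALSE) {
  cfg <- model$cfg
  px <- if (inherits(images, "image_batch")) images$pixels else images
  stopifnot(is.array(px), length(dim(px)) == 3L)
  d <- dim(px)
  if (any(d[1:2] %% 2L^cfg$depth != 0L))
    stop("image dims must be divisible by 2^depth = ", 2L^cfg$depth)
  if (any(!is.finite(px))) stop("non-finite pixel values")
  N <- d[3]
  anns <- prepare_texts(model, texts, N)
  txt <- encode_text(model$text, anns)
  x0 <- array(px, dim = c(1L, d[1], d[2], N))
  xs <- vector("list", cfg$depth)
  h <- nd(x0)
  for (i in seq_len(cfg$depth)) {
    if (i > 1L) h <- ad_maxpool(xs[[i - 1L]], 2L)
    h <- fwd_cbr(model$enc[[i]]$cbr2,
                 fwd_cbr(model$enc[[i]]$cbr1, h, train), train)
    xs[[i]] <- h
  }
  if (cfg$use_mtt) {
    M <- down_mtt_chain(model, xs, txt, train)
    U <- vector("list", cfg$depth)
    U[[cfg$depth]] <- M[[cfg$depth]]
    for (i in seq(cfg$depth - 1L, 1L)) {
      up <- ad_conv2d(ad_upsample2(U[[i + 1L]]),
                      model$up_mtt[[i]]$w, model$up_mtt[[i]]$b, 3L)
      U[[i]] <- fwd_vit_unit(model$vit_up[[i]], ad_add(up, M[[i]]))
    }
  }
  Fs <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    pre <- if (cfg$use_mtt) ad_add(xs[[i]], U[[i]]) else xs[[i]]
    Fs[[i]] <- if (cfg$use_meam) meam(model$meam[[i]], pre) else pre
  }
  D <- Fs[[cfg$depth]]
  for (i in seq(cfg$depth - 1L, 1L)) {
    up <- ad_conv2d(ad_upsample2(D), model$up_cnn[[i]]$up$w,
                    model$up_cnn[[i]]$up$b, 3L)
    D <- fwd_cbr(model$up_cnn[[i]]$cbr2,
                 fwd_cbr(model$up_cnn[[i]]$cbr1, ad_add(up, Fs[[i]]), train),
                 train)
  }
  logits <- ad_conv2d(D, model$head$w, model$head$b, 1L)
  list(logits = logits, probs = ad_softmax_ch(logits))
}

prepare_texts <- function(model, texts, N) {
  cfg <- model$cfg
  if (!cfg$use_text) {
    a <- tokenize(cfg$no_text_string, model$text$vocab, cfg$max_len)
    return(rep(list(a), N))
  }
  if (is.null(texts)) texts <- rep("", N)
  if (is.character(texts))
    texts <- lapply(texts, tokenize, vocab = model$text$vocab,
                    max_len = cfg$max_len)
  stopifnot(length(texts) == N)
  texts
}

#' Predict segmentation maps
#'
#' Deterministic evaluation-mode forward pass returning plain arrays.
#'
#' @param model an `smf_model`.
#' @param images array (H,W,N) or `image_batch`.
#' @param texts per-sample texts (see [smf_forward()]).
#' @return a `seg_output`: list with `logits`, `probs` (K,H,W,N) and
#'   `labels` (H,W,N; 0-based argmax classes).
#' @export
predict_smf <- function(model, images, texts = NULL) {
  out <- with_no_grad(smf_forward(model, images, texts, train = FALSE))
  seg_output(val(out$logits), val(out$probs))
}

#' Bundle logits and probabilities
#' @param logits,probs arrays (K,H,W,N).
#' @return `seg_output` list with argmax `labels` (H,W,N).
#' @export
seg_output <- function(logits, probs = NULL) {
  if (is.null(probs)) {
    d <- dim(logits)
    m <- array(logits, dim = c(d[1], prod(d[-1])))
    m <- exp(sweep(m, 2L, apply(m, 2L, max)))
    probs <- array(sweep(m, 2L, colSums(m), "/"), dim = d)
  }
  d <- dim(probs)
  lab <- apply(array(probs, dim = c(d[1], prod(d[-1]))), 2L, which.max) - 1L
  structure(list(logits = logits, probs = probs,
                 labels = array(as.integer(lab), dim = d[-1])),
            class = "seg_output")
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration (as YAML text), the
#' vocabulary, the image size and every parameter value and running moment.
#'
#' @param model an `smf_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  parts <- unclass(model)
  parts <- parts[setdiff(names(parts), c("cfg", "img_size"))]
  saveRDS(list(cfg_yaml = yaml::as.yaml(unclass(model$cfg)),
               vocab = model$text$vocab,
               img_size = model$img_size,
               state = module_state(parts)), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file path written by [save_checkpoint()].
#' @return an `smf_model` with restored parameters.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  cfg <- do.call(smf_config, yaml::yaml.load(ck$cfg_yaml))
  model <- with_seed(0L, smf_model(cfg, ck$vocab, ck$img_size))
  parts <- unclass(model)
  parts <- parts[setdiff(names(parts), c("cfg", "img_size"))]
  module_set_state(parts, ck$state)
  model
}
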