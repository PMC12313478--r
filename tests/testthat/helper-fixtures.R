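# Shared fixtures and internal aliases for the test suite.

ws <- smfnet:::with_seed
nd <- smfnet:::nd
ad_val <- smfnet:::val
ad_backward <- smfnet:::ad_backward
ad_param <- smfnet:::ad_param
collect_params <- smfnet:::collect_params
zero_grads <- smfnet:::zero_grads
grad_norm <- smfnet:::grad_norm
adam <- smfnet:::adam
module_state <- smfnet:::module_state
module_arch <- smfnet:::module_arch
stack_samples <- smfnet:::stack_samples

template_texts <- c(
  "no lesion in the organ",
  "1 lesion in the upper left of the organ",
  "1 lesion in the lower right of the organ",
  "2 lesions in the middle center of the organ",
  "no finding")

tiny_vocab <- function() build_vocab(template_texts)

# Small geometry for unit tests: depth 2, 4-channel ladder, 16x16 grids.
tiny_cfg <- function(...) {
  smf_config(depth = 2L, base_channels = 4L, num_classes = 3L, d_text = 16L,
             vit_dim = 16L, vit_heads = 2L, vit_max_tokens = 16L,
             max_len = 12L, text_layers = 1L, ...)
}

tiny_model <- function(seed = 1L, img = 16L, cfg = tiny_cfg()) {
  ws(seed, smf_model(cfg, tiny_vocab(), img))
}

# Phantom base spec scaled to a grid edge.
base_spec <- function(grid = 32L, ...) {
  phantom_spec(grid = c(grid, grid),
               organ = list(center = c(grid, grid) / 2,
                            axes = c(20, 12) * grid / 64, angle = 0),
               ...)
}

make_corpus <- function(nl, nu, grid = 32L, seed = 1L,
                        count_probs = c(0.25, 0.5, 0.25), ...) {
  dir <- tempfile("corpus")
  generate_corpus(dir, nl, nu, base_spec(grid, ...), seed = seed,
                  count_probs = count_probs)
  dir
}

corpus_vocab <- function(...) {
  ds <- list(...)
  texts <- unlist(lapply(ds, function(d)
    vapply(c(d$labeled, d$unlabeled), `[[`, "", "text")))
  build_vocab(c(texts, "no finding"))
}

# Central-difference gradient of f (numeric scalar function) at x.
numgrad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

random_probs <- function(K, H, W, N, seed = 1L) {
  ws(seed, {
    z <- array(abs(rnorm(K * H * W * N)) + 0.05, c(K, H, W, N))
    m <- array(z, c(K, H * W * N))
    array(sweep(m, 2L, colSums(m), "/"), c(K, H, W, N))
  })
}

random_mask <- function(H, W, N, K = 3L, seed = 1L) {
  ws(seed, array(sample(0:(K - 1L), H * W * N, TRUE), c(H, W, N)))
}
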