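#' Build a vocabulary from a text corpus
#'
#' Lower-cases, strips punctuation and splits on whitespace. The special
#' tokens `<pad>` (id 1) and `<unk>` (id 2) are always present.
#'
#' @param texts character vector of training texts.
#' @return an object of class `smf_vocab`: list with `tokens` (character) and
#'   `index` (named integer lookup).
#' @export
#' @examples
#' v <- build_vocab(c("one lesion in the upper left of the organ"))
#' tokenize("one lesion", v)
build_vocab <- function(texts) {
  words <- sort(unique(unlist(lapply(texts, split_words))))
  tokens <- c("<pad>", "<unk>", words)
  structure(list(tokens = tokens,
                 index = setNames(seq_along(tokens), tokens)),
            class = "smf_vocab")
}

split_words <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9 ]+", " ", text)
  w <- strsplit(trimws(text), "\\s+")[[1]]
  w[nzchar(w)]
}

#' Tokenize a text string
#'
#' Deterministic lookup of each word in the vocabulary; unknown words map to
#' the `<unk>` id. The id sequence is padded with `<pad>` ids to
#' `max_len`.
#'
#' @param text a single string.
#' @param vocab an `smf_vocab`.
#' @param max_len padded sequence length.
#' @return a `text_annotation`: list with `text`, `token_ids` (length
#'   `max_len`) and `length` (number of real tokens).
#' @export
tokenize <- function(text, vocab, max_len = 20L) {
  if (!inherits(vocab, "smf_vocab") || length(vocab$tokens) == 0L)
    stop("empty or invalid vocabulary")
  w <- split_words(text)
  if (length(w) > max_len)
    stop("text has ", length(w), " tokens, exceeding max length ", max_len)
  ids <- unname(vocab$index[w])
  ids[is.na(ids)] <- 2L
  structure(list(text = text,
                 token_ids = as.integer(c(ids, rep(1L, max_len - length(ids)))),
                 length = length(w)),
            class = "text_annotation")
}

#' Group tokens into coarse-grained phrases
#'
#' Contiguous, non-overlapping sliding windows of `w` tokens covering all
#' non-pad positions; a shorter trailing group absorbs the remainder.
#'
#' @param tokens a `text_annotation`.
#' @param w window width.
#' @return list of integer vectors of token positions (empty list for an
#'   empty annotation).
#' @export
coarse_segment <- function(tokens, w = 2L) {
  n <- tokens$length
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = w)
  lapply(starts, function(s) seq(s, min(s + w - 1L, n)))
}

# ---- multi-granularity text encoder ----------------------------------------

#' Construct the multi-granularity text encoder
#'
#' A compact trainable stand-in for a pretrained multi-granularity language
#' model: a token embedding table feeds two streams - fine-grained (token
#' level) and coarse-grained (window-mean phrase level) - through a shared
#' stack of transformer encoder layers with pad masking. `pooled` is the mean
#' of the two streams' masked means. The `adapter` hook accepts externally
#' computed embeddings in place of the internal table.
#'
#' @param vocab an `smf_vocab`.
#' @param d_text embedding dimensionality.
#' @param max_len maximum (padded) token sequence length.
#' @param n_layers number of shared transformer layers.
#' @param heads attention heads.
#' @param window coarse-grain window width.
#' @return a module list; pass to [encode_text()].
#' @export
text_encoder <- function(vocab, d_text = 64L, max_len = 20L, n_layers = 2L,
                         heads = 4L, window = 2L) {
  V <- length(vocab$tokens)
  Lc <- as.integer(ceiling(max_len / window))
  list(
    vocab = vocab,
    d_text = as.integer(d_text),
    max_len = as.integer(max_len),
    window = as.integer(window),
    Lc = Lc,
    table = ad_param(matrix(rnorm(V * d_text, sd = 0.02), V, d_text)),
    pos_f = ad_param(matrix(rnorm(max_len * d_text, sd = 0.02), max_len, d_text)),
    pos_c = ad_param(matrix(rnorm(Lc * d_text, sd = 0.02), Lc, d_text)),
    blocks = lapply(seq_len(n_layers), function(i) init_tblock(d_text, heads, 2)),
    adapter = NULL
  )
}

# Stack annotations into (Lmax, N) id and mask matrices.
stack_annotations <- function(anns, max_len) {
  ids <- vapply(anns, function(a) a$token_ids, integer(max_len))
  dim(ids) <- c(max_len, length(anns))
  mask <- vapply(anns, function(a) {
    c(rep(1, a$length), rep(0, max_len - a$length))
  }, numeric(max_len))
  dim(mask) <- c(max_len, length(anns))
  list(ids = ids, mask = mask)
}

# Coarse mixing matrix: block-diagonal row-normalized window means over
# non-pad positions; (N*Lc, N*Lmax).
coarse_mixing <- function(mask, window, Lc) {
  Lf <- nrow(mask)
  N <- ncol(mask)
  M <- matrix(0, N * Lc, N * Lf)
  cmask <- matrix(0, Lc, N)
  for (n in seq_len(N)) {
    len <- sum(mask[, n])
    if (len == 0) next
    starts <- seq(1L, len, by = window)
    for (gi in seq_along(starts)) {
      pos <- seq(starts[gi], min(starts[gi] + window - 1L, len))
      M[(n - 1L) * Lc + gi, (n - 1L) * Lf + pos] <- 1 / length(pos)
      cmask[gi, n] <- 1
    }
  }
  list(M = M, mask = cmask)
}

# Masked-mean mixing matrix (N, N*L): average of unmasked rows per sample.
masked_mean_mixing <- function(mask) {
  L <- nrow(mask)
  N <- ncol(mask)
  M <- matrix(0, N, N * L)
  for (n in seq_len(N)) {
    len <- sum(mask[, n])
    if (len > 0) M[n, (n - 1L) * L + which(mask[, n] > 0)] <- 1 / len
  }
  M
}

#' Encode tokenized text into fine and coarse embedding streams
#'
#' @param enc module from [text_encoder()].
#' @param anns list of `text_annotation` objects (one per sample).
#' @param embeddings optional externally computed embedding matrix
#'   (`N*max_len` x `d_text`), routed through the adapter hook instead of the
#'   internal table.
#' @return list with `ad_node` streams `fine` (N*Lf x d), `coarse`
#'   (N*Lc x d), `pooled` (N x d), plus masks and lengths.
#' @export
encode_text <- function(enc, anns, embeddings = NULL) {
  st <- stack_annotations(anns, enc$max_len)
  bad <- st$ids > nrow(enc$table$value) | st$ids < 1L
  if (any(bad)) stop("token id out of vocabulary range")
  N <- length(anns)
  Lf <- enc$max_len
  emb <- if (is.null(embeddings)) ad_embedding(st$ids, enc$table) else nd(embeddings)
  fmask <- as.numeric(st$mask)
  fine <- ad_add_pos(emb, enc$pos_f)
  cm <- coarse_mixing(st$mask, enc$window, enc$Lc)
  coarse <- ad_add_pos(ad_const_matmul(cm$M, emb), enc$pos_c)
  cmask <- as.numeric(cm$mask)
  for (b in enc$blocks) {
    fine <- fwd_tblock(b, fine, Lf, fmask)
    coarse <- fwd_tblock(b, coarse, enc$Lc, cmask)
  }
  pooled_f <- ad_const_matmul(masked_mean_mixing(st$mask), fine)
  pooled_c <- ad_const_matmul(masked_mean_mixing(cm$mask), coarse)
  pooled <- ad_scale(ad_add(pooled_f, pooled_c), 0.5)
  list(fine = fine, coarse = coarse, pooled = pooled,
       fine_mask = st$mask, coarse_mask = cm$mask, n = N)
}
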