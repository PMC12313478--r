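# Layer constructors: each returns a list of parameter nodes (plus any
# running-statistics environment) consumed by the forward helpers below.
# Construction order is deterministic, so a fixed RNG seed fixes the
# initialization.

init_conv <- function(cin, cout, k) {
  fan_in <- cin * k * k
  list(
    w = ad_param(matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)),
    b = ad_param(rep(0, cout)),
    k = as.integer(k)
  )
}

init_linear <- function(din, dout) {
  r <- sqrt(6 / (din + dout))
  list(
    w = ad_param(matrix(runif(din * dout, -r, r), din, dout)),
    b = ad_param(rep(0, dout))
  )
}

init_bn <- function(c) {
  st <- new.env(parent = emptyenv())
  st$rm <- rep(0, c)
  st$rv <- rep(1, c)
  list(gamma = ad_param(rep(1, c)), beta = ad_param(rep(0, c)), st = st)
}

init_ln <- function(d) {
  list(gamma = ad_param(rep(1, d)), beta = ad_param(rep(0, d)))
}

# Conv3x3 -> BN -> ReLU
init_cbr <- function(cin, cout, k = 3L) {
  list(conv = init_conv(cin, cout, k), bn = init_bn(cout))
}

fwd_cbr <- function(m, x, train) {
  h <- ad_conv2d(x, m$conv$w, m$conv$b, m$conv$k)
  h <- ad_batchnorm(h, m$bn$gamma, m$bn$beta, m$bn$st, train)
  ad_relu(h)
}

# A transformer encoder block (pre-norm): LN -> MHSA -> residual,
# LN -> MLP -> residual.  Operates on token matrices (N*L, d).
init_tblock <- function(d, heads, mlp_ratio) {
  dm <- as.integer(round(d * mlp_ratio))
  list(
    ln1 = init_ln(d),
    wq = init_linear(d, d), wk = init_linear(d, d), wv = init_linear(d, d),
    wo = init_linear(d, d),
    ln2 = init_ln(d),
    mlp1 = init_linear(d, dm), mlp2 = init_linear(dm, d),
    heads = as.integer(heads)
  )
}

fwd_tblock <- function(m, tok, L, mask = NULL) {
  h <- ad_layernorm(tok, m$ln1$gamma, m$ln1$beta)
  a <- ad_attention(ad_linear(h, m$wq$w, m$wq$b),
                    ad_linear(h, m$wk$w, m$wk$b),
                    ad_linear(h, m$wv$w, m$wv$b),
                    L, m$heads, mask)
  tok <- ad_add(tok, ad_linear(a, m$wo$w, m$wo$b))
  h <- ad_layernorm(tok, m$ln2$gamma, m$ln2$beta)
  h <- ad_linear(ad_relu(ad_linear(h, m$mlp1$w, m$mlp1$b)), m$mlp2$w, m$mlp2$b)
  ad_add(tok, h)
}

# ---- state extraction / cloning --------------------------------------------

# Flatten every parameter value and BN running moment into a named list.
module_state <- function(x, path = "") {
  out <- list()
  if (inherits(x, "ad_node")) {
    if (x$is_param) out[[path]] <- x$value
    return(out)
  }
  if (is.environment(x)) {
    out[[paste0(path, ".rm")]] <- x$rm
    out[[paste0(path, ".rv")]] <- x$rv
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      out <- c(out, module_state(x[[i]], paste0(path, "/", nms[i])))
    }
  }
  out
}

module_set_state <- function(x, state, path = "") {
  if (inherits(x, "ad_node")) {
    if (x$is_param) x$value <- state[[path]]
    return(invisible(x))
  }
  if (is.environment(x)) {
    x$rm <- state[[paste0(path, ".rm")]]
    x$rv <- state[[paste0(path, ".rv")]]
    return(invisible(x))
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) module_set_state(x[[i]], state, paste0(path, "/", nms[i]))
  }
  invisible(x)
}

# Deep copy: fresh parameter nodes and fresh BN state environments.
clone_module <- function(x) {
  if (inherits(x, "ad_node")) {
    if (x$is_param) return(ad_param(x$value))
    return(ad_node(x$value))
  }
  if (is.environment(x)) {
    st <- new.env(parent = emptyenv())
    st$rm <- x$rm
    st$rv <- x$rv
    return(st)
  }
  if (is.list(x)) {
    out <- lapply(x, clone_module)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

# Architecture summary: parameter shapes by path, values ignored.
module_arch <- function(x) {
  st <- module_state(x)
  paste(vapply(names(st), function(nm) {
    d <- dim(st[[nm]]) %||% length(st[[nm]])
    paste0(nm, ":", paste(d, collapse = "x"))
  }, ""), collapse = ";")
}
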