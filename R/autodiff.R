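#' @useDynLib smfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Internal engine state: node id counter and the grad-recording switch.
.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L
.ad$enabled <- TRUE

#' Create an autodiff node
#'
#' Nodes form a dynamically built computation graph. Each node stores its
#' value, its parent nodes and a vector-Jacobian-product closure used during
#' the reverse sweep. Values are plain numeric arrays/matrices.
#'
#' @param value numeric array, matrix or scalar.
#' @param parents list of parent nodes the value was computed from.
#' @param vjp function(grad) returning a list of gradients, one per parent
#'   (NULL entries for parents that need no gradient).
#' @param is_param TRUE for trainable parameters.
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), vjp = NULL, is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  rg <- is_param
  if (!rg && length(parents)) {
    for (p in parents) if (inherits(p, "ad_node") && p$rg) { rg <- TRUE; break }
  }
  if (!.ad$enabled && !is_param) rg <- FALSE
  e$parents <- if (rg && .ad$enabled) parents else list()
  e$vjp <- if (rg && .ad$enabled) vjp else NULL
  e$rg <- rg
  e$is_param <- is_param
  e$grad <- NULL
  .ad$counter <- .ad$counter + 1L
  e$nid <- .ad$counter
  class(e) <- "ad_node"
  e
}

#' @export
print.ad_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<ad_node", if (x$is_param) "param" else "",
      if (is.null(d)) paste0("len ", length(x$value)) else paste(d, collapse = "x"),
      ">\n")
  invisible(x)
}

ad_param <- function(value) ad_node(value, is_param = TRUE)

# Wrap raw numerics as constant leaves; pass nodes through.
nd <- function(x) if (inherits(x, "ad_node")) x else ad_node(x)

val <- function(x) if (inherits(x, "ad_node")) x$value else x

#' Detach a node from the graph
#' @param x an `ad_node`.
#' @return a constant leaf with the same value.
#' @keywords internal
ad_detach <- function(x) ad_node(val(x))

#' Evaluate without recording gradients
#' @param expr expression to evaluate.
#' @keywords internal
with_no_grad <- function(expr) {
  old <- .ad$enabled
  .ad$enabled <- FALSE
  on.exit(.ad$enabled <- old)
  expr
}

#' Reverse sweep from a scalar loss node
#'
#' Accumulates gradients into `$grad` of every reachable node that requires
#' one (parameters keep theirs until zeroed).
#'
#' @param loss scalar `ad_node`.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_node"), length(loss$value) == 1L)
  # Iterative topological sort (post-order DFS).
  order <- vector("list", 256L); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L)); nstack <- 1L
  while (nstack > 0L) {
    fr <- stack[[nstack]]; stack[[nstack]] <- NULL; nstack <- nstack - 1L
    node <- fr$node
    key <- as.character(node$nid)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      nstack <- nstack + 1L; stack[[nstack]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (inherits(p, "ad_node") && p$rg && is.null(seen[[as.character(p$nid)]])) {
          nstack <- nstack + 1L; stack[[nstack]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  # Seed and sweep in reverse topological order (children before parents).
  tmp <- new.env(parent = emptyenv())   # nid -> accumulated grad for non-params
  getg <- function(n) if (n$is_param) n$grad else tmp[[as.character(n$nid)]]
  addg <- function(n, g) {
    if (is.null(g)) return(invisible())
    if (n$is_param) {
      n$grad <- if (is.null(n$grad)) g else n$grad + g
    } else {
      k <- as.character(n$nid)
      tmp[[k]] <- if (is.null(tmp[[k]])) g else tmp[[k]] + g
    }
    invisible()
  }
  tmp[[as.character(loss$nid)]] <- 1
  for (i in seq_len(norder)) {
    node <- order[[norder - i + 1L]]
    g <- getg(node)
    if (is.null(g) || is.null(node$vjp)) next
    pg <- node$vjp(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (inherits(p, "ad_node") && p$rg) addg(p, pg[[j]])
    }
  }
  invisible(loss)
}

# ---- parameter utilities ----------------------------------------------------

# Collect every ad_node parameter inside an arbitrarily nested list.
collect_params <- function(x, out = list()) {
  if (inherits(x, "ad_node")) {
    if (x$is_param) out[[length(out) + 1L]] <- x
    return(out)
  }
  if (is.list(x)) for (el in x) out <- collect_params(el, out)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible()
}

grad_norm <- function(params) {
  s <- 0
  for (p in params) if (!is.null(p$grad)) s <- s + sum(p$grad^2)
  sqrt(s)
}

#' Adam optimizer
#'
#' @param params list of parameter nodes (from `collect_params()`).
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates; `beta2 = 0.99` follows the
#'   training recipe's momentum setting.
#' @param eps numerical stabilizer.
#' @return optimizer object with `$step()` and `$zero_grad()`.
#' @keywords internal
adam <- function(params, lr = 3e-4, beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr
  step <- function() {
    st$t <- st$t + 1L
    bc1 <- 1 - beta1^st$t
    bc2 <- 1 - beta2^st$t
    for (i in seq_along(st$params)) {
      p <- st$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
      st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
      p$value <- p$value - st$lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
    }
    invisible()
  }
  list(step = step, zero_grad = function() zero_grads(params), state = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded sub-computations do not
#' disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
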