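# Training objectives. Every function accepts either plain arrays or
# autodiff nodes for the probability inputs and returns an `ad_node` scalar
# (use val() for the numeric value), so the same code serves analysis and
# training.

as_probs <- function(x) {
  if (inherits(x, "seg_output")) x <- x$probs
  nd(x)
}

as_labels <- function(x) {
  if (inherits(x, "mask_batch")) x <- x$labels
  x
}

#' One-hot encode an integer label map
#' @param labels array (H,W,N) with values in 0..K-1.
#' @param K number of classes.
#' @return array (K,H,W,N).
#' @export
one_hot <- function(labels, K) {
  labels <- as_labels(labels)
  d <- dim(labels)
  oh <- array(0, dim = c(K, d))
  idx <- cbind(as.integer(labels) + 1L,
               arrayInd(seq_along(labels), d))
  oh[idx] <- 1
  oh
}

#' Soft Dice loss
#'
#' One minus the mean (over batch and classes) soft Dice coefficient
#' `2|p*y| / (|p|+|y|)`, computed on probabilities with a smoothing constant
#' in numerator and denominator.
#'
#' @param probs class probabilities (K,H,W,N): array, node or `seg_output`.
#' @param target integer labels (H,W,N) or `mask_batch`.
#' @param smooth smoothing constant.
#' @return scalar `ad_node` in \[0,1\].
#' @export
dice_loss <- function(probs, target, smooth = 1e-6) {
  probs <- as_probs(probs)
  d <- dim(probs$value)
  K <- d[1]; N <- d[4]
  if (N == 0L) stop("empty batch")
  oh <- one_hot(target, K)
  stopifnot(all(dim(oh) == d))
  M <- d[2] * d[3]
  pv <- array(probs$value, dim = c(K, M, N))
  yv <- array(oh, dim = c(K, M, N))
  inter <- apply(pv * yv, c(1, 3), sum)
  psum <- apply(pv, c(1, 3), sum)
  ysum <- apply(yv, c(1, 3), sum)
  num <- 2 * inter + smooth
  den <- psum + ysum + smooth
  loss <- 1 - mean(num / den)
  ad_node(loss, list(probs), function(g) {
    # d/dp of -(2*inter+s)/den: -(2*y*den - num)/den^2, averaged over K*N
    gy <- array(0, dim = d)
    for (n in seq_len(N)) {
      for (k in seq_len(K)) {
        gy[k, , , n] <- -(2 * oh[k, , , n] * den[k, n] - num[k, n]) / den[k, n]^2
      }
    }
    list(g * gy / (K * N))
  })
}

#' Soft Dice similarity
#' @inheritParams dice_loss
#' @return scalar `ad_node`; equals one minus [dice_loss()].
#' @export
dice_similarity <- function(probs, target, smooth = 1e-6) {
  ad_sub(nd(1), dice_loss(probs, target, smooth))
}

#' Pixelwise cross-entropy on probabilities
#'
#' Mean over pixels of the negative log-probability of the true class;
#' probabilities are clipped below at 1e-7.
#'
#' @inheritParams dice_loss
#' @return scalar `ad_node` >= 0.
#' @export
cross_entropy_loss <- function(probs, target) {
  probs <- as_probs(probs)
  d <- dim(probs$value)
  K <- d[1]
  oh <- one_hot(target, K)
  n_pix <- prod(d[-1])
  pc <- pmax(probs$value, 1e-7)
  loss <- -sum(oh * log(pc)) / n_pix
  ad_node(loss, list(probs), function(g) {
    list(-g * oh / pc / n_pix)
  })
}

#' Supervised segmentation loss
#'
#' The mean of the cross-entropy and Dice terms. The combination of a
#' cross-entropy *loss* with a Dice *similarity* would reward wrong
#' predictions, so the Dice loss (one minus the coefficient) is used by
#' default; `dice_as_similarity = TRUE` switches to the literal similarity
#' reading.
#'
#' @inheritParams dice_loss
#' @param dice_as_similarity use the Dice similarity instead of the Dice
#'   loss in the sum.
#' @return scalar `ad_node`.
#' @export
supervised_loss <- function(probs, target, dice_as_similarity = FALSE) {
  probs <- as_probs(probs)
  dterm <- if (dice_as_similarity) dice_similarity(probs, target)
           else dice_loss(probs, target)
  ad_scale(ad_add(cross_entropy_loss(probs, target), dterm), 0.5)
}

#' Pixelwise consistency error map
#'
#' Squared Euclidean distance between two probability maps, summed over
#' classes: the agreement measure between a prediction on a transformed
#' input and the transformed prediction.
#'
#' @param p1,p2 probability maps (K,H,W,N): arrays, nodes or `seg_output`s.
#' @return `ad_node` map (1,H,W,N), elementwise >= 0.
#' @export
consistency_error <- function(p1, p2) {
  p1 <- as_probs(p1); p2 <- as_probs(p2)
  if (!all(dim(p1$value) == dim(p2$value)))
    stop("shape mismatch between probability maps")
  dd <- ad_sub(p1, p2)
  ad_sum_ch(ad_mul(dd, dd))
}

#' Consistency loss
#' @param epsilon error map from [consistency_error()].
#' @return scalar `ad_node`: the spatial mean of the map.
#' @export
consistency_loss <- function(epsilon) {
  ad_mean(nd(epsilon))
}

#' Cross-student stabilization loss
#'
#' Pixel MSE between the two students' predictions, gated per sample: when
#' both stability flags are set, only pixels where this student's
#' consistency error is below the peer's contribute; otherwise the sample
#' contributes `r_a * mse`. The gate itself carries no gradient.
#'
#' @param flags list with `eps_a`, `eps_b` ((1,H,W,N) arrays or nodes) and
#'   per-sample binary vectors `r_a`, `r_b`.
#' @param mse_map `ad_node`/array (1,H,W,N) of squared differences.
#' @param flip reverse the indicator direction (gate where this student is
#'   the *less* stable one).
#' @return scalar `ad_node` >= 0.
#' @export
stabilization_loss <- function(flags, mse_map, flip = FALSE) {
  mse_map <- nd(mse_map)
  ea <- val(flags$eps_a); eb <- val(flags$eps_b)
  d <- dim(mse_map$value)
  N <- d[4]
  wmap <- array(0, dim = d)
  for (n in seq_len(N)) {
    if (flags$r_a[n] == 1 && flags$r_b[n] == 1) {
      ind <- if (flip) ea[, , , n] > eb[, , , n] else ea[, , , n] < eb[, , , n]
      wmap[, , , n] <- as.numeric(ind)
    } else {
      wmap[, , , n] <- flags$r_a[n]
    }
  }
  ad_mean(ad_mul_const(mse_map, wmap))
}

#' Generator-side adversarial loss
#'
#' Cross-entropy of the discriminator's realness score against the "real"
#' target: `-mean(log d_out)`. Zero when the discriminator is fully fooled,
#' monotone decreasing in the score.
#'
#' @param d_out realness scores in (0,1): numeric vector or node.
#' @return scalar `ad_node` >= 0.
#' @export
adversarial_generator_loss <- function(d_out) {
  ad_neg(ad_mean(ad_log(nd(d_out), eps = 1e-7)))
}

#' Discriminator loss
#'
#' `CE(real, 1) + CE(fake, 0)` on realness scores.
#'
#' @param real_out,fake_out realness scores in (0,1).
#' @return scalar `ad_node` >= 0.
#' @export
discriminator_loss <- function(real_out, fake_out) {
  real_out <- nd(real_out); fake_out <- nd(fake_out)
  ad_add(ad_neg(ad_mean(ad_log(real_out, eps = 1e-7))),
         ad_neg(ad_mean(ad_log(ad_sub(nd(1), fake_out), eps = 1e-7))))
}

#' Weighted total training loss
#'
#' `total = seg + lambda1*cons + lambda2*sta + lambda3*adv`; the default
#' weights (0.5, 0.2, 0.05) are the configuration found best in the ablation
#' over weight settings.
#'
#' @param seg,cons,sta,adv scalar components (numerics or nodes).
#' @param weights numeric length-3 vector (lambda1, lambda2, lambda3).
#' @return a `loss_breakdown`: list with numeric `seg`, `cons`, `sta`,
#'   `adv`, `total`, `weights`, and the composed `node` when any input was a
#'   node.
#' @export
total_student_loss <- function(seg, cons = 0, sta = 0, adv = 0,
                               weights = c(0.5, 0.2, 0.05)) {
  stopifnot(length(weights) == 3L)
  anynode <- any(vapply(list(seg, cons, sta, adv), inherits, TRUE,
                        what = "ad_node"))
  node <- NULL
  if (anynode) {
    node <- ad_add(nd(seg),
                   ad_add(ad_scale(nd(cons), weights[1]),
                          ad_add(ad_scale(nd(sta), weights[2]),
                                 ad_scale(nd(adv), weights[3]))))
  }
  parts <- c(seg = val(nd(seg)), cons = val(nd(cons)),
             sta = val(nd(sta)), adv = val(nd(adv)))
  if (any(!is.finite(parts)))
    stop("non-finite loss component: ",
         paste(names(parts)[!is.finite(parts)], collapse = ", "))
  structure(list(seg = parts[["seg"]], cons = parts[["cons"]],
                 sta = parts[["sta"]], adv = parts[["adv"]],
                 total = parts[["seg"]] + sum(weights * parts[c("cons", "sta", "adv")]),
                 weights = weights, node = node),
            class = "loss_breakdown")
}
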