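# Dual-student adversarial training: two independently initialized students exchanging
# stability-gated constraints, per-student adversarial discriminators, an
# optional EMA teacher, and a Gaussian ramp on the unsupervised weight.
# Every stochastic draw runs under an explicitly derived seed, so identical
# configurations reproduce bit-identically and the supervised reduction
# (all unsupervised weights zero) matches plain supervised training exactly.

#' Training configuration
#'
#' @param framework `"dual_student"` (default), `"mean_teacher"`, or
#'   `"supervised"`.
#' @param lambda numeric length 3: weights of the consistency,
#'   stabilization and adversarial terms; the (0.5, 0.2, 0.05) default is
#'   the weighting found best in the ablation over weight settings.
#' @param delta final unsupervised weight of the Gaussian ramp
#'   (mean-teacher objective); the dual-student ramp is normalized to 1.
#' @param ramp_epochs ramp length in epochs.
#' @param alpha EMA smoothing coefficient for the teacher.
#' @param tau confidence threshold of the stability flag.
#' @param lr Adam learning rate.
#' @param epochs,patience training length and early-stopping patience (in
#'   epochs without validation improvement).
#' @param val_every validate every this many epochs.
#' @param batch_labeled,batch_unlabeled batch sizes.
#' @param use_teacher maintain an EMA teacher (feeds the second
#'   discriminator in dual-student mode).
#' @param flip_stability reverse the stability indicator direction.
#' @param dice_as_similarity literal similarity reading of the supervised
#'   objective.
#' @param noise_sd gaussian noise given to the teacher's input.
#' @param seed master seed; all other seeds derive from it.
#' @return a `das_config` list.
#' @export
das_config <- function(framework = c("dual_student", "mean_teacher",
                                     "supervised"),
                       lambda = c(0.5, 0.2, 0.05),
                       delta = 1.0,
                       ramp_epochs = 10L,
                       alpha = 0.999,
                       tau = 0.6,
                       lr = 3e-4,
                       epochs = 10L,
                       patience = 20L,
                       val_every = 1L,
                       batch_labeled = 4L,
                       batch_unlabeled = 4L,
                       use_teacher = TRUE,
                       flip_stability = FALSE,
                       dice_as_similarity = FALSE,
                       noise_sd = 0.05,
                       seed = 1L) {
  framework <- match.arg(framework)
  stopifnot(length(lambda) == 3L, alpha > 0, alpha < 1, tau > 0, tau < 1)
  structure(as.list(environment()), class = "das_config")
}

#' Exponential-moving-average teacher update
#'
#' `theta' <- alpha * theta' + (1 - alpha) * theta`, elementwise over all
#' parameters (and batch-norm running moments). Mutates and returns the
#' teacher when given models; pure when given numeric arrays.
#'
#' @param teacher,student matching numeric arrays or `smf_model`s.
#' @param alpha smoothing coefficient in (0,1).
#' @return the updated teacher.
#' @export
ema_update <- function(teacher, student, alpha = 0.999) {
  if (is.numeric(teacher)) {
    if (!identical(dim(teacher), dim(student)) ||
        length(teacher) != length(student))
      stop("parameter shape mismatch")
    return(alpha * teacher + (1 - alpha) * student)
  }
  tp <- unclass(teacher); sp <- unclass(student)
  keep <- setdiff(names(tp), c("cfg", "img_size"))
  st_t <- module_state(tp[keep])
  st_s <- module_state(sp[keep])
  if (!identical(names(st_t), names(st_s))) stop("parameter shape mismatch")
  upd <- Map(function(a, b) alpha * a + (1 - alpha) * b, st_t, st_s)
  module_set_state(tp[keep], upd)
  teacher
}

#' Gaussian ramp-up weight
#'
#' `delta * exp(-5 * (1 - I)^2)` with progress `I = min(epoch/ramp, 1)`;
#' rises from `delta * exp(-5)` at epoch 0 to `delta` at the end of the
#' ramp.
#'
#' @param delta final weight.
#' @param epoch current epoch (>= 0).
#' @param ramp_epochs ramp length; 0 means fully ramped from the start.
#' @return scalar weight.
#' @export
ramp_weight <- function(delta, epoch, ramp_epochs) {
  I <- if (ramp_epochs <= 0) 1 else min(epoch / ramp_epochs, 1)
  delta * exp(-5 * (1 - I)^2)
}

#' Per-sample stability flag
#'
#' A sample is stable (r = 1) when the argmax classes of the two predictions
#' agree on at least 90% of pixels and the mean max-class probability of the
#' first prediction reaches `tau`.
#'
#' @param probs,probs_perturbed probability arrays (K,H,W,N) (or nodes /
#'   `seg_output`s).
#' @param tau confidence threshold in (0,1).
#' @param agree_frac required agreement fraction.
#' @return integer vector of 0/1 flags, one per sample.
#' @export
stability_flag <- function(probs, probs_perturbed, tau = 0.6,
                           agree_frac = 0.9) {
  stopifnot(tau > 0, tau < 1)
  p1 <- val(as_probs(probs)); p2 <- val(as_probs(probs_perturbed))
  d <- dim(p1)
  K <- d[1]; M <- d[2] * d[3]; N <- d[4]
  r <- integer(N)
  for (n in seq_len(N)) {
    m1 <- matrix(p1[, , , n], K, M)
    m2 <- matrix(p2[, , , n], K, M)
    a1 <- max.col(t(m1), ties.method = "first")
    a2 <- max.col(t(m2), ties.method = "first")
    conf <- mean(m1[cbind(a1, seq_len(M))])
    r[n] <- as.integer(mean(a1 == a2) >= agree_frac && conf >= tau)
  }
  r
}

# Derived seeds; kept well below 2^31.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 1000003L)
  for (k in ks) s <- (s * 131 + as.double(k)) %% 1000003
  as.integer(s) + 7L
}

# ---- trainer construction ---------------------------------------------------

#' Assemble a dual-student adversarial trainer
#'
#' Students (and discriminators) are independently initialized from seeds
#' derived from `cfg$seed`; the optional teacher starts as a copy of
#' student A.
#'
#' @param model_cfg an [smf_config()].
#' @param cfg a [das_config()].
#' @param vocab an `smf_vocab`.
#' @param img_size input edge length.
#' @param init_id initialization stream of the (first) student; student A
#'   uses stream 1 and student B stream 2, so a supervised run with
#'   `init_id = 2` starts from student B's exact initialization.
#' @return a trainer object (list of students, discriminators, optimizers).
#' @export
das_trainer <- function(model_cfg, cfg, vocab, img_size = 64L, init_id = 1L) {
  sA <- with_seed(derive_seed(cfg$seed, init_id), smf_model(model_cfg, vocab, img_size))
  students <- list(A = list(model = sA, opt = adam(collect_params(unclass(sA)), lr = cfg$lr)))
  discs <- NULL
  if (cfg$framework != "supervised") {
    if (cfg$framework == "dual_student") {
      sB <- with_seed(derive_seed(cfg$seed, 2), smf_model(model_cfg, vocab, img_size))
      students$B <- list(model = sB, opt = adam(collect_params(unclass(sB)), lr = cfg$lr))
    }
    d1 <- with_seed(derive_seed(cfg$seed, 3),
                    disc_model(model_cfg$num_classes, meam_pool = model_cfg$meam_pool))
    d2 <- with_seed(derive_seed(cfg$seed, 4),
                    disc_model(model_cfg$num_classes, meam_pool = model_cfg$meam_pool))
    discs <- list(D1 = list(model = d1, opt = adam(collect_params(unclass(d1)), lr = cfg$lr)),
                  D2 = list(model = d2, opt = adam(collect_params(unclass(d2)), lr = cfg$lr)))
  }
  teacher <- NULL
  tpairs <- NULL
  if (cfg$use_teacher && cfg$framework != "supervised") {
    teacher <- clone_smf(students$A$model)
    tpairs <- ema_pairs(teacher, students$A$model)
  }
  structure(list(cfg = cfg, model_cfg = model_cfg, students = students,
                 discs = discs, teacher = teacher, tpairs = tpairs,
                 img_size = img_size),
            class = "das_trainer")
}

clone_smf <- function(model) {
  out <- clone_module(unclass(model))
  class(out) <- class(model)
  out
}

# ---- single training step ---------------------------------------------------

student_unlab_graph <- function(tr, who, ub, tstep, cache) {
  cfg <- tr$cfg
  st <- tr$students[[who]]
  H <- dim(ub$image$pixels)[1]; W <- dim(ub$image$pixels)[2]
  p_tx <- smf_forward(st$model, tstep$timg$image, ub$texts, train = TRUE)$probs
  p_x <- smf_forward(st$model, ub$image, ub$texts, train = TRUE)$probs
  tp_x <- transform_probs_node(tstep$t, p_x, H, W)
  eps <- consistency_error(p_tx, tp_x)
  cache[[who]] <- utils::modifyList(cache[[who]], list(
    p_tx = p_tx, p_x = p_x, eps_node = eps, eps = val(eps),
    r = stability_flag(val(p_tx), val(tp_x), cfg$tau),
    probs_u = val(p_x)))
  invisible()
}

student_loss_graph <- function(tr, who, lb, ub, epoch, cache) {
  cfg <- tr$cfg
  st <- tr$students[[who]]
  out_l <- smf_forward(st$model, lb$image, lb$texts, train = TRUE)
  seg <- supervised_loss(out_l$probs, lb$mask,
                         dice_as_similarity = cfg$dice_as_similarity)
  cache[[who]]$probs_l <- val(out_l$probs)
  ramp <- ramp_weight(1, epoch, cfg$ramp_epochs)
  lam <- cfg$lambda * ramp
  cons <- nd(0); sta <- nd(0); adv <- nd(0)
  if (!is.null(ub) && any(lam > 0)) {
    own <- cache[[who]]
    if (lam[1] > 0) cons <- consistency_loss(own$eps_node)
    other <- setdiff(names(tr$students), who)
    if (lam[2] > 0 && length(other) == 1L) {
      peer <- cache[[other]]
      # peer predictions enter as constants: no cross-gradients
      dd <- ad_sub(own$p_tx, nd(val(peer$p_tx)))
      mse <- ad_sum_ch(ad_mul(dd, dd))
      flags <- list(eps_a = own$eps, eps_b = peer$eps,
                    r_a = own$r, r_b = peer$r)
      sta <- stabilization_loss(flags, mse, flip = cfg$flip_stability)
    }
    if (lam[3] > 0) {
      dn <- if (who == "A") tr$discs$D1$model else tr$discs$D2$model
      z <- disc_logits(dn, ub$image, own$p_x)
      adv <- adversarial_generator_loss(ad_sigmoid(z))
    }
  }
  total_student_loss(seg, cons, sta, adv, weights = lam)
}

#' One dual-student training step
#'
#' Runs, for each student: supervised loss on the labeled batch;
#' transform-consistency and stability-gated cross-student losses on the
#' unlabeled batch; a generator-side adversarial loss against its
#' discriminator; one Adam step. Then one discriminator step each, and an
#' EMA teacher update. The peer's predictions enter each student's loss as
#' constants (no cross-gradients).
#'
#' @param tr a [das_trainer()].
#' @param lb labeled batch: list(image, mask, texts) from `stack_samples()`.
#' @param ub unlabeled batch or NULL.
#' @param epoch current epoch (ramp progress).
#' @param step step index within the epoch (seeds the perturbation draw).
#' @return list of `loss_breakdown`s, one per student.
#' @export
train_step_dual <- function(tr, lb, ub, epoch, step = 0L) {
  cfg <- tr$cfg
  if (is.null(lb)) stop("at least one labeled sample per step is required")
  tstep <- NULL
  if (!is.null(ub)) {
    tstep <- draw_step_transform(tr, ub, epoch, step)
  }
  cache <- new.env(parent = emptyenv())
  for (who in names(tr$students)) cache[[who]] <- list()
  lam_on <- any(cfg$lambda * ramp_weight(1, epoch, cfg$ramp_epochs) > 0)
  if (!is.null(ub) && lam_on) {
    for (who in names(tr$students)) {
      student_unlab_graph(tr, who, ub, tstep, cache)
    }
  }
  res <- list()
  for (who in names(tr$students)) {
    st <- tr$students[[who]]
    dparams <- if (!is.null(tr$discs)) {
      collect_params(unclass(tr$discs[[if (who == "A") "D1" else "D2"]]$model))
    } else list()
    st$opt$zero_grad()
    zero_grads(dparams)
    br <- student_loss_graph(tr, who, lb, ub, epoch, cache)
    ad_backward(br$node)
    st$opt$step()
    zero_grads(dparams)
    res[[who]] <- br
  }
  # Discriminator updates (Eqs. of the adversarial objective): real pairs
  # are predictions on labeled data (D1) / teacher predictions on noised
  # input (D2); fakes are student predictions on unlabeled data.
  if (!is.null(tr$discs) && !is.null(ub) &&
      cfg$lambda[3] * ramp_weight(1, epoch, cfg$ramp_epochs) > 0) {
    update_discriminators(tr, lb, ub, cache)
  }
  if (!is.null(tr$teacher)) ema_step(tr$tpairs, cfg$alpha)
  res
}

draw_step_transform <- function(tr, ub, epoch, step) {
  s <- derive_seed(tr$cfg$seed, 100, epoch, step)
  kind <- with_seed(s, sample(c("rotation90", "horizontal-flip"), 1L))
  t <- if (kind == "rotation90") {
    augment_transform("rotation90", list(k = with_seed(s + 1L, sample(1:3, 1L))),
                      seed = s)
  } else {
    augment_transform("horizontal-flip", seed = s)
  }
  list(t = t, timg = apply_transform(t, ub$image))
}

# Fast EMA path: aligned (teacher, student) parameter nodes and batch-norm
# state environments, collected once at trainer construction.
ema_pairs <- function(teacher, student) {
  walk <- function(t, s, acc) {
    if (inherits(t, "ad_node")) {
      if (t$is_param) acc$params[[length(acc$params) + 1L]] <- list(t, s)
      return(acc)
    }
    if (is.environment(t)) {
      acc$bn[[length(acc$bn) + 1L]] <- list(t, s)
      return(acc)
    }
    if (is.list(t)) for (i in seq_along(t)) acc <- walk(t[[i]], s[[i]], acc)
    acc
  }
  keep <- setdiff(names(unclass(teacher)), c("cfg", "img_size"))
  walk(unclass(teacher)[keep], unclass(student)[keep],
       list(params = list(), bn = list()))
}

ema_step <- function(pairs, alpha) {
  for (p in pairs$params) {
    p[[1]]$value <- alpha * p[[1]]$value + (1 - alpha) * p[[2]]$value
  }
  for (b in pairs$bn) {
    b[[1]]$rm <- alpha * b[[1]]$rm + (1 - alpha) * b[[2]]$rm
    b[[1]]$rv <- alpha * b[[1]]$rv + (1 - alpha) * b[[2]]$rv
  }
  invisible()
}

update_discriminators <- function(tr, lb, ub, cache) {
  cfg <- tr$cfg
  for (dn in names(tr$discs)) {
    d <- tr$discs[[dn]]
    who <- if (dn == "D1") "A" else if (!is.null(tr$students$B)) "B" else "A"
    fake_probs <- cache[[who]]$probs_u
    if (is.null(fake_probs)) next
    if (dn == "D1" || is.null(tr$teacher)) {
      real_img <- lb$image
      real_probs <- cache[[who]]$probs_l
    } else {
      noise_t <- augment_transform("gaussian-noise",
                                   list(sd = cfg$noise_sd),
                                   seed = derive_seed(cfg$seed, 200,
                                                      d$opt$state$t))
      x_ema <- apply_transform(noise_t, ub$image)$image
      real_img <- x_ema
      real_probs <- val(with_no_grad(
        smf_forward(tr$teacher, x_ema, ub$texts, train = FALSE)$probs))
    }
    d$opt$zero_grad()
    zr <- disc_logits(d$model, real_img, real_probs)
    zf <- disc_logits(d$model, ub$image, fake_probs)
    loss <- discriminator_loss(ad_sigmoid(zr), ad_sigmoid(zf))
    ad_backward(loss)
    d$opt$step()
  }
  invisible()
}

# Mean-teacher objective: supervised Dice + ramped (MSE-to-teacher +
# adversarial terms); discriminators per the adversarial formulation.
train_step_mt <- function(tr, lb, ub, epoch, step = 0L) {
  cfg <- tr$cfg
  st <- tr$students$A
  out_l <- smf_forward(st$model, lb$image, lb$texts, train = TRUE)
  seg <- dice_loss(out_l$probs, lb$mask)
  lam <- ramp_weight(cfg$delta, epoch, cfg$ramp_epochs)
  semi <- nd(0); adv <- nd(0)
  cache <- list(probs_l = val(out_l$probs))
  if (!is.null(ub)) {
    noise_t <- augment_transform("gaussian-noise", list(sd = cfg$noise_sd),
                                 seed = derive_seed(cfg$seed, 300, epoch, step))
    x_ema <- apply_transform(noise_t, ub$image)$image
    p_u <- smf_forward(st$model, ub$image, ub$texts, train = TRUE)$probs
    p_ema <- val(with_no_grad(
      smf_forward(tr$teacher, x_ema, ub$texts, train = FALSE)$probs))
    dd <- ad_sub(p_u, nd(p_ema))
    semi <- ad_mean(ad_mul(dd, dd))
    z1 <- disc_logits(tr$discs$D1$model, ub$image, p_u)
    z2 <- disc_logits(tr$discs$D2$model, ub$image, p_u)
    adv <- ad_add(adversarial_generator_loss(ad_sigmoid(z1)),
                  adversarial_generator_loss(ad_sigmoid(z2)))
    cache$probs_u <- val(p_u)
    cache$x_ema <- x_ema
    cache$p_ema <- p_ema
  }
  total <- ad_add(seg, ad_scale(ad_add(semi, adv), lam))
  dparams <- c(collect_params(unclass(tr$discs$D1$model)),
               collect_params(unclass(tr$discs$D2$model)))
  st$opt$zero_grad(); zero_grads(dparams)
  ad_backward(total)
  st$opt$step(); zero_grads(dparams)
  if (!is.null(ub)) {
    for (dn in c("D1", "D2")) {
      d <- tr$discs[[dn]]
      d$opt$zero_grad()
      if (dn == "D1") {
        zr <- disc_logits(d$model, lb$image, cache$probs_l)
      } else {
        zr <- disc_logits(d$model, cache$x_ema, cache$p_ema)
      }
      zf <- disc_logits(d$model, ub$image, cache$probs_u)
      ad_backward(discriminator_loss(ad_sigmoid(zr), ad_sigmoid(zf)))
      d$opt$step()
    }
  }
  ema_step(tr$tpairs, cfg$alpha)
  list(A = total_student_loss(val(seg), val(semi), 0, val(adv),
                              weights = c(lam, 0, lam)))
}

# ---- fit loop ---------------------------------------------------------------

#' Train on a corpus with early stopping
#'
#' @param tr a [das_trainer()].
#' @param train dataset list (`labeled`, `unlabeled`) from [load_corpus()],
#'   or a corpus directory.
#' @param val optional validation dataset (labeled samples used).
#' @param verbose print per-epoch summaries.
#' @return list with the trainer (best-validation parameters restored),
#'   `history` (per-epoch losses and validation metrics) and `best_epoch`.
#' @export
das_fit <- function(tr, train, val = NULL, verbose = FALSE) {
  cfg <- tr$cfg
  if (is.character(train)) train <- load_corpus(train)
  if (is.character(val)) val <- load_corpus(val)
  if (length(train$labeled) == 0L) stop("empty labeled training set")
  nl <- length(train$labeled)
  nu <- length(train$unlabeled)
  use_unlab <- cfg$framework != "supervised" && nu > 0L
  steps <- max(1L, ceiling(nl / cfg$batch_labeled))
  history <- list()
  best <- list(dice = -Inf, epoch = NA_integer_, state = NULL)
  wait <- 0L
  vb <- if (!is.null(val) && length(val$labeled) > 0L)
    stack_samples(val$labeled) else NULL
  for (epoch in seq_len(cfg$epochs) - 1L) {
    ord_l <- with_seed(derive_seed(cfg$seed, 10, epoch), sample.int(nl))
    ord_u <- if (use_unlab)
      with_seed(derive_seed(cfg$seed, 11, epoch), sample.int(nu)) else integer()
    acc <- NULL
    for (s in seq_len(steps) - 1L) {
      li <- ord_l[(s * cfg$batch_labeled + 1L):min((s + 1L) * cfg$batch_labeled, nl)]
      lb <- stack_samples(train$labeled[li])
      ub <- NULL
      if (use_unlab) {
        start <- (s * cfg$batch_unlabeled) %% nu
        pos <- ((start + seq_len(min(cfg$batch_unlabeled, nu)) - 1L) %% nu) + 1L
        ub <- stack_samples(train$unlabeled[ord_u[pos]])
      }
      br <- if (cfg$framework == "mean_teacher") {
        train_step_mt(tr, lb, ub, epoch, s)
      } else {
        train_step_dual(tr, lb, ub, epoch, s)
      }
      acc <- if (is.null(acc)) br else
        Map(function(a, b) {
          for (f in c("seg", "cons", "sta", "adv", "total")) a[[f]] <- a[[f]] + b[[f]]
          a
        }, acc, br)
    }
    ep <- list(epoch = epoch,
               loss = lapply(acc, function(a)
                 list(seg = a$seg / steps, cons = a$cons / steps,
                      sta = a$sta / steps, adv = a$adv / steps,
                      total = a$total / steps, weights = a$weights)))
    do_val <- !is.null(vb) &&
      (epoch %% cfg$val_every == cfg$val_every - 1L || epoch == cfg$epochs - 1L)
    if (do_val) {
      pr <- predict_smf(tr$students$A$model, vb$image, vb$texts)
      rep <- metric_report(pr, vb$mask)
      ep$val <- list(mean_dice = rep$mean_dice, miou = rep$miou,
                     mae = rep$mae)
      md <- if (is.na(rep$mean_dice)) -Inf else rep$mean_dice
      if (md > best$dice) {
        best <- list(dice = md, epoch = epoch,
                     state = module_state(trainer_parts(tr)))
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (verbose)
        message(sprintf("epoch %d: train total %.4f, val dice %.4f",
                        epoch, ep$loss$A$total, rep$mean_dice))
      if (wait >= cfg$patience) {
        history[[length(history) + 1L]] <- ep
        break
      }
    } else if (verbose) {
      message(sprintf("epoch %d: train total %.4f", epoch, ep$loss$A$total))
    }
    history[[length(history) + 1L]] <- ep
  }
  if (!is.null(best$state)) module_set_state(trainer_parts(tr), best$state)
  list(trainer = tr, history = history, best_epoch = best$epoch)
}

trainer_parts <- function(tr) {
  parts <- list(students = lapply(tr$students, function(s) unclass(s$model)))
  if (!is.null(tr$discs))
    parts$discs <- lapply(tr$discs, function(d) unclass(d$model))
  if (!is.null(tr$teacher)) parts$teacher <- unclass(tr$teacher)
  parts
}
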