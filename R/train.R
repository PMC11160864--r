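## Training: teacher pretraining, student distillation with the hierarchical
## layer-selective feedback objective, and the supervised baseline. Adam with
## cosine-annealed learning rate throughout.

#' Training configuration
#'
#' Defaults follow the reference protocol at toy scale: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, learning rate starting at `0.001` with
#' per-epoch cosine annealing down to `1e-6`, batch size 8, random
#' rotation/flip augmentation (additive-noise augmentation is deliberately
#' not offered; it is unsuitable for CT).
#'
#' @param epochs Number of epochs (>= 1).
#' @param lr,lr_min Initial and final learning rate of the cosine schedule.
#' @param betas Adam moment decay rates.
#' @param batch_size Mini-batch size.
#' @param seed Seed controlling initialisation, shuffling and augmentation.
#' @param weights A [loss_weights()] list (multi-task objective).
#' @param control An [hlfd_control()] list (distillation operators).
#' @param augment Apply random 90-degree rotation / flip each epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 1e-3, lr_min = 1e-6,
                         betas = c(0.9, 0.999), batch_size = 8L, seed = 0L,
                         weights = loss_weights(), control = hlfd_control(),
                         augment = TRUE) {
  if (epochs < 1L) stop_hlfd("epochs must be >= 1")
  if (lr <= 0) stop_hlfd("lr must be positive")
  structure(list(epochs = as.integer(epochs), lr = lr, lr_min = lr_min,
                 betas = betas, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), weights = weights, control = control,
                 augment = isTRUE(augment)),
            class = "train_config")
}

cosine_lr <- function(epoch, epochs, lr, lr_min) {
  if (epochs == 1L) return(lr)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

adam_new <- function(params)
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(state, params, grads, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / c1) /
      (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

#' Seed-stable train/validation split
#'
#' @param data A `phantom_set` or list of samples.
#' @param val_fraction Fraction held out (default 0.2).
#' @param seed Shuffle seed.
#' @return List with `train` and `val` subsets.
#' @export
split_phantoms <- function(data, val_fraction = 0.2, seed = 0L) {
  n <- length(data)
  idx <- with_seed(seed, sample.int(n))
  n_val <- max(1L, round(val_fraction * n))
  keep_attrs <- function(x, idx) {
    out <- structure(x[idx], class = class(x))
    for (a in c("organ", "difficulty", "seed", "size")) attr(out, a) <- attr(x, a)
    out
  }
  list(train = keep_attrs(data, idx[seq_len(n - n_val)]),
       val = keep_attrs(data, idx[seq(n - n_val + 1L, n)]))
}

# Window + stack a list of samples into (H, W, 1, B) images and (H, W, B) masks.
make_batch <- function(samples) {
  h <- nrow(samples[[1]]$image); w <- ncol(samples[[1]]$image)
  B <- length(samples)
  xb <- array(0, c(h, w, 1L, B)); mb <- array(0, c(h, w, B))
  for (b in seq_len(B)) {
    s <- samples[[b]]
    xb[, , 1L, b] <- hu_window(s$image, organ_window(s$meta$organ))
    mb[, , b] <- s$mask
  }
  list(x = xb, mask = mb)
}

# Nearest-neighbour mask downsampling (stays exactly binary).
mask_at_scale <- function(mb, h, w) {
  d <- dim(mb)
  if (d[1] == h && d[2] == w) return(mb)
  ih <- pmin(pmax(round((seq_len(h) - 0.5) * d[1] / h + 0.5), 1L), d[1])
  iw <- pmin(pmax(round((seq_len(w) - 0.5) * d[2] / w + 0.5), 1L), d[2])
  mb[ih, iw, , drop = FALSE]
}

maybe_augment <- function(s, cfg) {
  if (!cfg$augment) return(s)
  augment_sample(s, rot = sample(0:3, 1), flip = sample(c(TRUE, FALSE), 1))
}

# Numeric attention map sum_c |x|^p of an (H, W, C, B) tensor.
att4d <- function(x, exponent = 1) {
  d <- dim(x)
  a <- abs(x)
  if (exponent != 1) a <- a^exponent
  out <- array(0, c(d[1], d[2], 1, d[4]))
  for (c in seq_len(d[3])) out[, , 1, ] <- out[, , 1, ] + a[, , c, ]
  out
}

# Frozen-teacher batch outputs (no tape): middle/late encoder features and
# decoder probability maps.
teacher_batch_outputs <- function(teacher, xb) {
  ctx <- ctx_make(teacher)
  enc <- encode_ctx(ctx, xb)
  s <- length(enc)
  hd <- teacher_decode_ctx(ctx, enc)
  list(mids = enc[seq(2L, s - 1L)], late = enc[[s]],
       p_mids = lapply(hd$mids, softmax4d), p_late = softmax4d(hd$late))
}

unify_mids_4d <- function(mids) {
  hs <- vapply(mids, function(m) dim(m)[1], integer(1))
  ws <- vapply(mids, function(m) dim(m)[2], integer(1))
  h <- min(hs); w <- min(ws)
  res <- lapply(mids, resize4d, h_out = h, w_out = w)
  d1 <- dim(res[[1]])
  chans <- vapply(res, function(m) dim(m)[3], integer(1))
  out <- array(0, c(h, w, sum(chans), d1[4]))
  at <- 0L
  for (m in res) { out[, , at + seq_len(dim(m)[3]), ] <- m; at <- at + dim(m)[3] }
  out
}

unify_mid_probs_4d <- function(p_mids) {
  hs <- vapply(p_mids, function(m) dim(m)[1], integer(1))
  ws <- vapply(p_mids, function(m) dim(m)[2], integer(1))
  h <- min(hs); w <- min(ws)
  acc <- Reduce(`+`, lapply(p_mids, resize4d, h_out = h, w_out = w)) / length(p_mids)
  d <- dim(acc)
  n <- d[1] * d[2]
  for (b in seq_len(d[4])) {
    sl <- matrix(acc[, , , b], n, d[3])
    acc[, , , b] <- array(sl / rowSums(sl), c(d[1], d[2], d[3]))
  }
  acc
}

# Build the full multi-task loss graph for one student batch. Returns the
# tape, the per-component node ids, and the parameter-node map.
student_loss_graph <- function(teacher, student, xb, mb, weights, control) {
  tp <- tape_new()
  ctx <- ctx_make(student, tp)
  x <- tp_const(tp, xb)
  enc <- encode_ctx(ctx, x)
  s <- length(enc)
  logits <- student_head_ctx(ctx, enc[[s]], dim(xb)[1], dim(xb)[2])
  seg <- tp_focal_dice(tp, logits, mb, gamma = weights$focal_gamma,
                       dice_eps = weights$dice_eps)
  distill <- !is.null(teacher) && (weights$beta > 0 || weights$lambda > 0)
  if (distill) {
    tb <- teacher_batch_outputs(teacher, xb)
    ex <- control$attention_exponent
    # feature level: unified mids -> early, late -> each mid
    zmid_t <- unify_mids_4d(tb$mids)
    at_mid <- tp_const(tp, att4d(zmid_t, ex))
    a_early <- tp_resize(tp, tp_attention(tp, enc[[1]], ex),
                         dim(zmid_t)[1], dim(zmid_t)[2])
    ufd <- tp_att_distance(tp, a_early, at_mid, control$eps, control$norm)
    at_late <- tp_const(tp, att4d(tb$late, ex))
    dl <- dim(tb$late)
    ifd_terms <- lapply(seq(2L, s - 1L), function(i) {
      a <- tp_resize(tp, tp_attention(tp, enc[[i]], ex), dl[1], dl[2])
      tp_att_distance(tp, a, at_late, control$eps, control$norm)
    })
    ifd <- tp_lincomb(tp, ifd_terms, rep(1, length(ifd_terms)))
    # pixel level: unified mid probs -> early aux, late probs -> each mid aux
    aux <- student_aux_ctx(ctx, enc)
    pt_mid <- unify_mid_probs_4d(tb$p_mids)
    ps_early <- tp_softmax(tp, tp_resize(tp, aux$early, dim(pt_mid)[1], dim(pt_mid)[2]))
    pt_mid_id <- tp_const(tp, pt_mid)
    upd <- if (control$kl_direction == "student_first")
      tp_kl(tp, ps_early, pt_mid_id, control$kl_eps)
    else tp_kl(tp, pt_mid_id, ps_early, control$kl_eps)
    pl <- dim(tb$p_late)
    pt_late_id <- tp_const(tp, tb$p_late)
    ipd_terms <- lapply(aux$mids, function(l) {
      ps <- tp_softmax(tp, tp_resize(tp, l, pl[1], pl[2]))
      if (control$kl_direction == "student_first") tp_kl(tp, ps, pt_late_id, control$kl_eps)
      else tp_kl(tp, pt_late_id, ps, control$kl_eps)
    })
    ipd <- tp_lincomb(tp, ipd_terms, rep(1 / length(ipd_terms), length(ipd_terms)))
  } else {
    ufd <- ifd <- upd <- ipd <- tp_const(tp, 0)
  }
  total <- tp_lincomb(tp, list(seg, ufd, ifd, upd, ipd),
                      c(1, weights$beta, weights$beta, weights$lambda, weights$lambda))
  breakdown <- hlfd_loss(tp_value(tp, seg), tp_value(tp, ufd), tp_value(tp, ifd),
                         tp_value(tp, upd), tp_value(tp, ipd), weights)
  list(tape = tp, total = total, breakdown = breakdown, param_ids = ctx$pids,
       components = list(seg = seg, ufd = ufd, ifd = ifd, upd = upd, ipd = ipd))
}

# One optimisation step's gradients for each student parameter (used by the
# trainer and by diagnostic tests of gradient routing).
student_step_grads <- function(teacher, student, xb, mb, weights, control) {
  g <- student_loss_graph(teacher, student, xb, mb, weights, control)
  if (!is.finite(g$breakdown$total))
    stop_hlfd("training diverged: non-finite loss (seg=%g ufd=%g ifd=%g upd=%g ipd=%g)",
              g$breakdown$seg, g$breakdown$ufd, g$breakdown$ifd,
              g$breakdown$upd, g$breakdown$ipd)
  grads_all <- tp_backward(g$tape, g$total)
  grads <- lapply(g$param_ids, function(id) grads_all[[id]])
  list(grads = grads, breakdown = g$breakdown)
}

epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Pretrain the reference teacher
#'
#' Supervised training with the focal-dice loss applied to the final
#' full-resolution head and every deep-supervision head (mask downsampled to
#' each head's scale by nearest neighbour; head losses averaged). Adam with
#' cosine annealing; random rotation/flip augmentation.
#'
#' @param data Training `phantom_set` (non-empty).
#' @param spec Teacher [network_spec()].
#' @param config A [train_config()].
#' @param val Optional validation `phantom_set`; final Dice/RVD are reported.
#' @param out Optional directory: writes `train_log.csv` and
#'   `teacher.rds` (+ JSON sidecar).
#' @param eval_every If positive and `val` is given, record the validation
#'   Dice in the log every `eval_every` epochs (column `val_dsc`).
#' @return An object of class `hlfd_teacher_fit` with `network`, `log`
#'   (one row per epoch), `val` metrics and `config`.
#' @export
train_teacher <- function(data, spec = network_spec("teacher"),
                          config = train_config(), val = NULL, out = NULL,
                          eval_every = 0L) {
  if (!length(data)) stop_hlfd("train_teacher: empty dataset")
  net <- build_teacher(spec, config$seed)
  opt <- adam_new(net$params)
  log <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch, config$epochs, config$lr, config$lr_min)
      losses <- c()
      for (bidx in epoch_batches(length(data), config$batch_size)) {
        batch <- make_batch(lapply(data[bidx], maybe_augment, cfg = config))
        tp <- tape_new()
        ctx <- ctx_make(net, tp)
        x <- tp_const(tp, batch$x)
        enc <- encode_ctx(ctx, x)
        hd <- teacher_decode_ctx(ctx, enc)
        heads <- c(list(hd$early), hd$mids, list(hd$late))
        terms <- lapply(heads, function(h) {
          dm <- dim(tp_value(tp, h))
          tp_focal_dice(tp, h, mask_at_scale(batch$mask, dm[1], dm[2]),
                        gamma = config$weights$focal_gamma,
                        dice_eps = config$weights$dice_eps)
        })
        # final full-resolution head carries most of the weight; the
        # deep-supervision heads share the rest
        n_ds <- length(terms) - 1L
        loss <- tp_lincomb(tp, terms, c(0.6, rep(0.4 / n_ds, n_ds)))
        if (!is.finite(tp_value(tp, loss)))
          stop_hlfd("teacher training diverged: non-finite loss at epoch %d", epoch)
        grads_all <- tp_backward(tp, loss)
        grads <- lapply(ctx$pids, function(id) grads_all[[id]])
        upd <- adam_step(opt, net$params, grads, lr, config$betas)
        opt <- upd$state; net$params <- upd$params
        losses <- c(losses, tp_value(tp, loss))
      }
      vd <- if (!is.null(val) && eval_every > 0L && epoch %% eval_every == 0L)
        evaluate(net, val)$summary$dsc_mean else NA_real_
      log[[epoch]] <- data.frame(epoch = epoch, seg = mean(losses), ufd = 0,
                                 ifd = 0, upd = 0, ipd = 0, total = mean(losses),
                                 lr = lr, val_dsc = vd)
    }
  })
  log <- do.call(rbind, log)
  fit <- structure(list(network = net, log = log,
                        val = if (!is.null(val)) evaluate(net, val) else NULL,
                        config = config),
                   class = c("hlfd_teacher_fit", "hlfd_fit"))
  if (!is.null(out)) write_fit(fit, out, "teacher")
  fit
}

student_training_core <- function(teacher, data, spec, config, val, out, label,
                                  eval_every = 0L) {
  if (!length(data)) stop_hlfd("empty dataset")
  if (!is.null(teacher)) {
    if (!inherits(teacher, "hlfd_teacher")) stop_hlfd("teacher must be an hlfd_teacher")
    teacher <- freeze(teacher)
    check_tap_compat(teacher, spec)
  } else if (config$weights$beta > 0 || config$weights$lambda > 0) {
    stop_hlfd("distillation weights are nonzero but no teacher was given")
  }
  net <- build_student(spec, config$seed)
  opt <- adam_new(net$params)
  steps <- list()
  log <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch, config$epochs, config$lr, config$lr_min)
      ep <- list()
      for (bidx in epoch_batches(length(data), config$batch_size)) {
        batch <- make_batch(lapply(data[bidx], maybe_augment, cfg = config))
        sg <- student_step_grads(teacher, net, batch$x, batch$mask,
                                 config$weights, config$control)
        upd <- adam_step(opt, net$params, sg$grads, lr, config$betas)
        opt <- upd$state; net$params <- upd$params
        ep[[length(ep) + 1L]] <- as.data.frame(sg$breakdown)
      }
      ep <- do.call(rbind, ep)
      steps[[epoch]] <- cbind(epoch = epoch, ep)
      vd <- if (!is.null(val) && eval_every > 0L && epoch %% eval_every == 0L)
        evaluate(net, val)$summary$dsc_mean else NA_real_
      log[[epoch]] <- data.frame(epoch = epoch, seg = mean(ep$seg),
                                 ufd = mean(ep$ufd), ifd = mean(ep$ifd),
                                 upd = mean(ep$upd), ipd = mean(ep$ipd),
                                 total = mean(ep$total), lr = lr, val_dsc = vd)
    }
  })
  fit <- structure(list(network = net, teacher_frozen = !is.null(teacher),
                        log = do.call(rbind, log), steps = do.call(rbind, steps),
                        val = if (!is.null(val)) evaluate(net, val) else NULL,
                        config = config),
                   class = c("hlfd_student_fit", "hlfd_fit"))
  if (!is.null(out)) write_fit(fit, out, label)
  fit
}

# Spatial compatibility of teacher and student taps: same number of middle
# taps (the losses pair them positionally).
check_tap_compat <- function(teacher, student_spec) {
  nt <- teacher$spec$n_mid; ns <- student_spec$n_mid
  if (nt != ns)
    stop_hlfd("configuration error: teacher has %d middle taps but student has %d (tap '%s')",
              nt, ns, student_spec$tap_plan$mids[min(nt, ns) + 1L])
  invisible(TRUE)
}

#' Distill a student from a frozen teacher
#'
#' Trains the student on the multi-task objective
#' `seg + beta * (ufd + ifd) + lambda * (upd + ipd)`: supervised focal-dice
#' on the final head, attention-transfer feature losses (teacher unified
#' middle layers -> student early layer; teacher terminal layer -> each
#' student middle layer) and pixel-level KL losses (teacher unified middle
#' predictive maps -> student early auxiliary map; teacher terminal
#' predictive map -> each student middle auxiliary map). The teacher is
#' frozen throughout: its parameters enter the graph as constants and are
#' bit-identical before and after training. With `beta = lambda = 0` the
#' run reduces exactly to supervised student training.
#'
#' @param teacher A trained `hlfd_teacher` (or `hlfd_teacher_fit`).
#' @param data Training `phantom_set`.
#' @param spec Student [network_spec()].
#' @param config A [train_config()]; `config$weights` carries beta/lambda.
#' @param val Optional validation `phantom_set`.
#' @param out Optional output directory (`train_log.csv`, checkpoint).
#' @param eval_every If positive and `val` is given, record the validation
#'   Dice in the log every `eval_every` epochs (column `val_dsc`).
#' @return An object of class `hlfd_student_fit` with the trained `network`,
#'   per-epoch `log`, per-step `steps` breakdown table, `val` metrics and
#'   `config`.
#' @export
distill_student <- function(teacher, data,
                            spec = network_spec("student", c(6, 12, 24, 48)),
                            config = train_config(), val = NULL, out = NULL,
                            eval_every = 0L) {
  if (inherits(teacher, "hlfd_teacher_fit")) teacher <- teacher$network
  student_training_core(teacher, data, spec, config, val, out, "student_hlfd",
                        eval_every)
}

#' Train a student without distillation (supervised baseline)
#'
#' Identical training loop to [distill_student()] but with no teacher and
#' only the supervised focal-dice loss; the comparison baseline for the
#' distillation benefit.
#'
#' @inheritParams distill_student
#' @return An `hlfd_student_fit`.
#' @export
train_student <- function(data, spec = network_spec("student", c(6, 12, 24, 48)),
                          config = train_config(), val = NULL, out = NULL,
                          eval_every = 0L) {
  config$weights <- loss_weights(beta = 0, lambda = 0,
                                 focal_gamma = config$weights$focal_gamma,
                                 dice_eps = config$weights$dice_eps)
  student_training_core(NULL, data, spec, config, val, out, "student_nokd",
                        eval_every)
}

write_fit <- function(fit, out, label) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$log, file.path(out, "train_log.csv"), row.names = FALSE)
  if (!is.null(fit$steps))
    utils::write.csv(fit$steps, file.path(out, "step_log.csv"), row.names = FALSE)
  save_network(fit$network, file.path(out, paste0(label, ".rds")))
  invisible(out)
}

#' @export
print.hlfd_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<%s: %d epochs, final loss %.4f", class(x)[1], n, x$log$total[n]))
  if (!is.null(x$val)) cat(sprintf(", val DSC %.4f", x$val$summary$dsc_mean))
  cat(">\n")
  invisible(x)
}

#' @export
summary.hlfd_fit <- function(object, ...) {
  cat(sprintf("%s\n", class(object)[1]))
  print(object$network)
  cat(sprintf("epochs: %d  batch size: %d  lr: %g -> %g\n",
              object$config$epochs, object$config$batch_size,
              object$config$lr, object$config$lr_min))
  w <- object$config$weights
  cat(sprintf("objective: seg + %.2f*(ufd+ifd) + %.2f*(upd+ipd)\n", w$beta, w$lambda))
  cat("loss trajectory (first/last epochs):\n")
  print(utils::head(object$log, 2))
  print(utils::tail(object$log, 2))
  if (!is.null(object$val)) { cat("validation: "); print(object$val) }
  invisible(object)
}

#' Plot training loss curves
#'
#' @param x An `hlfd_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hlfd_fit <- function(x, ...) {
  comp <- x$log[, c("seg", "ufd", "ifd", "upd", "ipd", "total")]
  keep <- vapply(comp, function(v) any(v != 0), logical(1))
  graphics::matplot(x$log$epoch, comp[, keep, drop = FALSE], type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = names(comp)[keep], lty = 1,
                   col = seq_len(sum(keep)), bty = "n")
  invisible(x)
}

#' @export
predict.hlfd_fit <- function(object, image, ...) predict(object$network, image, ...)
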