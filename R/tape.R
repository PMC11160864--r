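## A minimal reverse-mode automatic-differentiation tape.
##
## The tape records a directed acyclic graph of array-valued nodes; each op
## stores its value, parent ids and a backward closure mapping the incoming
## gradient to gradients for the parents. Gradients of every op are verified
## against central finite differences in the test suite. Tensors on the tape
## use the engine layout H x W x C x B.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- vector("list", 256L)
  tp
}

tp_push <- function(tp, value, parents = integer(), backward = NULL) {
  parents <- as.integer(parents)  # force promises before touching the tape
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- list(value = value, parents = parents, backward = backward)
  tp$n
}

tp_const <- function(tp, value) tp_push(tp, value)
tp_param <- function(tp, value) tp_push(tp, value)
tp_value <- function(tp, id) {
  id <- as.integer(id)  # force the promise before reading the node list
  tp$nodes[[id]]$value
}

# Reverse sweep from scalar node `id`; returns the list of gradients
# (indexed by node id; NULL where no gradient flows).
tp_backward <- function(tp, id) {
  grads <- vector("list", tp$n)
  grads[[id]] <- 1
  for (i in seq(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      if (is.null(pg[[k]])) next
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

## ---- primitive ops ---------------------------------------------------------

tp_conv2d <- function(tp, x, w, b, stride = 1L, pad = 1L) {
  xv <- tp_value(tp, x); wv <- tp_value(tp, w); bv <- tp_value(tp, b)
  y <- nn_conv2d_fwd(xv, wv, bv, as.integer(stride), as.integer(pad))
  tp_push(tp, y, c(x, w, b), function(g) {
    gr <- nn_conv2d_bwd(xv, wv, g, as.integer(stride), as.integer(pad))
    list(gr$dx, gr$dw, as.numeric(gr$db))
  })
}

tp_relu <- function(tp, x) {
  xv <- tp_value(tp, x)
  y <- pmax(xv, 0)
  tp_push(tp, y, x, function(g) list(g * (xv > 0)))
}

tp_add <- function(tp, a, b) {
  tp_push(tp, tp_value(tp, a) + tp_value(tp, b), c(a, b), function(g) list(g, g))
}

# Channel concatenation of (H, W, C, B) tensors.
tp_concat <- function(tp, ids) {
  vals <- lapply(ids, tp_value, tp = tp)
  chans <- vapply(vals, function(v) dim(v)[3], integer(1))
  d1 <- dim(vals[[1]])
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ends <- cumsum(chans)
  tp_push(tp, out, ids, function(g) {
    lapply(seq_along(ids), function(k) {
      idx <- (ends[k] - chans[k] + 1L):ends[k]
      g[, , idx, , drop = FALSE]
    })
  })
}

tp_resize <- function(tp, x, h_out, w_out) {
  xv <- tp_value(tp, x)
  d <- dim(xv)
  if (d[1] == h_out && d[2] == w_out) return(x)
  tp_push(tp, resize4d(xv, h_out, w_out), x,
          function(g) list(resize4d_adjoint(g, d[1], d[2])))
}

tp_softmax <- function(tp, x) {
  p <- softmax4d(tp_value(tp, x))
  tp_push(tp, p, x, function(g) {
    d <- dim(p)
    n <- d[1] * d[2]
    dx <- array(0, d)
    for (b in seq_len(d[4])) {
      pm <- matrix(p[, , , b], n, d[3])
      gm <- matrix(g[, , , b], n, d[3])
      s <- rowSums(gm * pm)
      dx[, , , b] <- array(pm * (gm - s), c(d[1], d[2], d[3]))
    }
    list(dx)
  })
}

# Scalar linear combination sum(coefs * nodes).
tp_lincomb <- function(tp, ids, coefs) {
  v <- sum(vapply(seq_along(ids), function(k) coefs[k] * tp_value(tp, ids[[k]]), numeric(1)))
  tp_push(tp, v, unlist(ids), function(g) as.list(g * coefs))
}

## ---- composite ops (hand-derived backward, finite-difference tested) -------

# Channel-aggregated attention map: a[h,w,b] = sum_c |x[h,w,c,b]|^p.
tp_attention <- function(tp, x, exponent = 1) {
  xv <- tp_value(tp, x)
  d <- dim(xv)
  ax <- abs(xv)
  axp <- if (exponent == 1) ax else ax^exponent
  a <- array(0, c(d[1], d[2], 1, d[4]))
  for (c in seq_len(d[3])) a[, , 1, ] <- a[, , 1, ] + axp[, , c, ]
  tp_push(tp, a, x, function(g) {
    dx <- xv
    der <- if (exponent == 1) sign(xv) else exponent * ax^(exponent - 1) * sign(xv)
    for (c in seq_len(d[3])) dx[, , c, ] <- g[, , 1, ] * der[, , c, ]
    list(dx)
  })
}

# Distance between L2-normalised flattened maps, averaged over the batch:
# mean_b || a_b/max(||a_b||,eps) - b_b/max(||b_b||,eps) ||  (L2 or L1).
tp_att_distance <- function(tp, a, b, eps = 1e-8, norm = "L2") {
  av <- tp_value(tp, a); bv <- tp_value(tp, b)
  d <- dim(av)
  B <- d[4]; n <- d[1] * d[2] * d[3]
  am <- matrix(av, n, B); bm <- matrix(bv, n, B)
  sa <- pmax(sqrt(colSums(am^2)), eps)
  sb <- pmax(sqrt(colSums(bm^2)), eps)
  va <- sweep(am, 2, sa, "/"); vb <- sweep(bm, 2, sb, "/")
  diff <- va - vb
  per <- if (norm == "L2") sqrt(colSums(diff^2)) else colSums(abs(diff))
  val <- mean(per)
  tp_push(tp, val, c(a, b), function(g) {
    gd <- if (norm == "L2") sweep(diff, 2, pmax(per, 1e-12), "/") else sign(diff)
    gd <- gd * (g / B)
    # through v = a / max(||a||, eps): projection when the guard is inactive
    ga <- gd; gb <- -gd
    for (k in seq_len(B)) {
      if (sa[k] > eps) ga[, k] <- (ga[, k] - va[, k] * sum(va[, k] * ga[, k])) / sa[k]
      else ga[, k] <- ga[, k] / eps
      if (sb[k] > eps) gb[, k] <- (gb[, k] - vb[, k] * sum(vb[, k] * gb[, k])) / sb[k]
      else gb[, k] <- gb[, k] / eps
    }
    list(array(ga, d), array(gb, d))
  })
}

# Pixel-averaged KL divergence sum_k p[k] log((p[k]+eps)/(q[k]+eps)),
# mean over pixels and batch; p and q are probability tensors.
tp_kl <- function(tp, p, q, eps = 1e-8) {
  pv <- tp_value(tp, p); qv <- tp_value(tp, q)
  d <- dim(pv)
  npx <- d[1] * d[2] * d[4]
  lr <- log((pv + eps) / (qv + eps))
  val <- sum(pv * lr) / npx
  tp_push(tp, val, c(p, q), function(g) {
    list((lr + pv / (pv + eps)) * (g / npx),
         -(pv / (qv + eps)) * (g / npx))
  })
}

# Supervised focal + soft-dice loss on 2-class logits (H, W, 2, B) against a
# binary mask (H, W, B). Focal term is pixel-averaged; dice is per-sample,
# averaged over the batch.
tp_focal_dice <- function(tp, logits, mask, gamma = 2, dice_eps = 1, eps = 1e-8) {
  lv <- tp_value(tp, logits)
  d <- dim(lv)
  if (d[3] != 2L) stop_hlfd("focal-dice loss expects 2-class logits, got %d channels", d[3])
  if (!all(mask %in% c(0, 1))) stop_hlfd("mask must be binary {0,1}")
  B <- d[4]; npx <- d[1] * d[2] * B
  p <- softmax4d(lv)
  pfg <- array(p[, , 2, ], c(d[1], d[2], B))
  m <- array(mask, c(d[1], d[2], B))
  ptrue <- pfg * m + (1 - pfg) * (1 - m)
  omp <- pmax(1 - ptrue, 1e-12)
  focal <- -mean(omp^gamma * log(ptrue + eps))
  num <- s <- numeric(B)
  for (b in seq_len(B)) {
    num[b] <- 2 * sum(pfg[, , b] * m[, , b]) + dice_eps
    s[b]   <- sum(pfg[, , b]) + sum(m[, , b]) + dice_eps
  }
  dice <- mean(1 - num / s)
  tp_push(tp, focal + dice, logits, function(g) {
    # d focal / d ptrue, per pixel
    dfp <- (gamma * omp^(gamma - 1) * log(ptrue + eps) - omp^gamma / (ptrue + eps)) / npx
    # back to d/d pfg: ptrue = pfg for fg pixels, 1 - pfg otherwise
    dpfg <- dfp * (2 * m - 1)
    for (b in seq_len(B))
      dpfg[, , b] <- dpfg[, , b] - (2 * m[, , b] * s[b] - num[b]) / (s[b]^2 * B)
    # softmax backward with dp = (0, dpfg)
    dl <- lv
    sdot <- dpfg * pfg
    dl[, , 1, ] <- array(p[, , 1, ], c(d[1], d[2], B)) * (-sdot)
    dl[, , 2, ] <- pfg * (dpfg - sdot)
    list(dl * g)
  })
}
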