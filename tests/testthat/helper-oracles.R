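# Literal-equation brute-force oracles, written independently of the package
# internals (plain loops, no shared helpers). Used to pin the distillation
# losses and the interpolation to their defining formulas.

# attention vector: flatten sum_c |f|^p over channels, L2-normalise with guard
oracle_att_vec <- function(f, p = 1, eps = 1e-8) {
  d <- dim(f)  # C x H x W
  a <- matrix(0, d[2], d[3])
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
    s <- 0
    for (c in seq_len(d[1])) s <- s + abs(f[c, h, w])^p
    a[h, w] <- s
  }
  v <- as.numeric(a)
  v / max(sqrt(sum(v^2)), eps)
}

# UFD-style distance between two same-shape feature maps (no resampling)
oracle_att_distance <- function(fs, ft, p = 1, eps = 1e-8) {
  vs <- oracle_att_vec(fs, p, eps)
  vt <- oracle_att_vec(ft, p, eps)
  sqrt(sum((vs - vt)^2))
}

# IFD: sum over student mids of the distance to the teacher late map
oracle_ifd <- function(mids, late, p = 1, eps = 1e-8)
  sum(vapply(mids, oracle_att_distance, numeric(1), ft = late, p = p, eps = eps))

# per-pixel softmax of a K x H x W logit array, by loops
oracle_softmax <- function(l) {
  d <- dim(l)
  out <- array(0, d)
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
    z <- l[, h, w]
    e <- exp(z - max(z))
    out[, h, w] <- e / sum(e)
  }
  out
}

# pixel-averaged KL divergence, literal sum
oracle_kl <- function(ps, pt, eps = 1e-8) {
  d <- dim(ps)
  acc <- 0
  for (h in seq_len(d[2])) for (w in seq_len(d[3]))
    for (k in seq_len(d[1]))
      acc <- acc + ps[k, h, w] * log((ps[k, h, w] + eps) / (pt[k, h, w] + eps))
  acc / (d[2] * d[3])
}

oracle_upd <- function(student_logits, pt, eps = 1e-8)
  oracle_kl(oracle_softmax(student_logits), pt, eps)

oracle_ipd <- function(mid_logits, pt, eps = 1e-8)
  mean(vapply(mid_logits, function(l) oracle_kl(oracle_softmax(l), pt, eps), numeric(1)))

# direct per-output-pixel bilinear interpolation (half-pixel centres),
# independent of the package's matrix-based implementation
oracle_bilinear <- function(x, ho, wo) {
  hi <- nrow(x); wi <- ncol(x)
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    sy <- min(max((i - 0.5) * hi / ho - 0.5, 0), hi - 1)
    sx <- min(max((j - 0.5) * wi / wo - 0.5, 0), wi - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, hi - 1); x1 <- min(x0 + 1, wi - 1)
    fy <- sy - y0; fx <- sx - x0
    out[i, j] <- (1 - fy) * (1 - fx) * x[y0 + 1, x0 + 1] +
      (1 - fy) * fx * x[y0 + 1, x1 + 1] +
      fy * (1 - fx) * x[y1 + 1, x0 + 1] +
      fy * fx * x[y1 + 1, x1 + 1]
  }
  out
}

# random simplex-valued probability map
rand_prob_map <- function(k, h, w) {
  x <- array(stats::rexp(k * h * w), c(k, h, w))
  s <- apply(x, c(2, 3), sum)
  for (i in seq_len(k)) x[i, , ] <- x[i, , ] / s
  x
}

rand_fm <- function(c, h, w) array(stats::rnorm(c * h * w), c(c, h, w))

tiny_phantoms <- function(n, seed = 11, size = 32) {
  generate_phantoms(n, size, "kidney", "easy", seed = seed)
}
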