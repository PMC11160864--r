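## Internal numerical utilities shared by the loss operators and the
## network engine. Tensor layout in the training engine is H x W x C x B;
## user-facing feature maps are C x H x W (see feature_map()).

#' @useDynLib hlfd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG state so builders and generators are
# reproducible without clobbering the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_hlfd <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop_hlfd("%s contains non-finite values", what)
  invisible(x)
}

# Row-interpolation matrix for 1-D bilinear resampling, half-pixel-centre
# convention (not corner-aligned); rows sum to 1, so constants are preserved.
bilinear_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) { M[, 1L] <- 1; return(M) }
  src <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    M[i, lo[i] + 1] <- M[i, lo[i] + 1] + (1 - frac[i])
    M[i, hi[i] + 1] <- M[i, hi[i] + 1] + frac[i]
  }
  M
}

# 2-D bilinear resize of a matrix.
resize2d <- function(x, h_out, w_out) {
  Rh <- bilinear_matrix(h_out, nrow(x))
  Rw <- bilinear_matrix(w_out, ncol(x))
  Rh %*% x %*% t(Rw)
}

# Bilinear resize of an (H, W, C, B) tensor along the two leading dims.
# Implemented as two tensor contractions with the interpolation matrices.
resize4d <- function(x, h_out, w_out) {
  d <- dim(x)
  if (d[1] == h_out && d[2] == w_out) return(x)
  Rh <- bilinear_matrix(h_out, d[1])
  Rw <- bilinear_matrix(w_out, d[2])
  y <- Rh %*% matrix(x, d[1], prod(d[-1]))        # (Ho, W*C*B)
  dim(y) <- c(h_out, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  z <- Rw %*% matrix(y, d[2], h_out * d[3] * d[4])
  dim(z) <- c(w_out, h_out, d[3], d[4])
  aperm(z, c(2, 1, 3, 4))
}

# Adjoint of resize4d (exact transpose of the linear map), used in backprop.
resize4d_adjoint <- function(g, h_in, w_in) {
  d <- dim(g)  # (Ho, Wo, C, B)
  Rh <- bilinear_matrix(d[1], h_in)
  Rw <- bilinear_matrix(d[2], w_in)
  y <- t(Rh) %*% matrix(g, d[1], prod(d[-1]))
  dim(y) <- c(h_in, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  z <- t(Rw) %*% matrix(y, d[2], h_in * d[3] * d[4])
  dim(z) <- c(w_in, h_in, d[3], d[4])
  aperm(z, c(2, 1, 3, 4))
}

# Per-pixel softmax over the channel dimension of an (H, W, C, B) tensor.
# Works on a (pixels x channels) view per sample, immune to dim dropping.
softmax4d <- function(x) {
  d <- dim(x)
  n <- d[1] * d[2]
  out <- array(0, d)
  for (b in seq_len(d[4])) {
    sl <- matrix(x[, , , b], n, d[3])
    mx <- sl[, 1]
    for (c in seq_len(d[3])[-1]) mx <- pmax(mx, sl[, c])
    ex <- exp(sl - mx)
    out[, , , b] <- array(ex / rowSums(ex), c(d[1], d[2], d[3]))
  }
  out
}

# Channel-first (C, H, W) <-> engine (H, W, C, B=1) conversions.
chw_to_hwcb <- function(x) {
  d <- dim(x)
  array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
}

hwcb_to_chw <- function(x, b = 1L) {
  d <- dim(x)
  aperm(array(x[, , , b], d[1:3]), c(3, 1, 2))
}
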