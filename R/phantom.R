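## Synthetic CT-like phantom slices with tumor masks, plus Hounsfield-unit
## windowing and the rotation/flip augmentation used during training.

#' Hounsfield windowing specification
#'
#' @param lo,hi Window bounds in Hounsfield units, `lo < hi`. Presets:
#'   [kidney_window()] is (-200, 300), [liver_window()] is (-40, 160),
#'   the radiological standards for the two organs.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop_hlfd("window requires lo < hi (got %s, %s)", lo, hi)
  structure(list(lo = lo, hi = hi), class = "window_spec")
}

#' @rdname window_spec
#' @export
kidney_window <- function() window_spec(-200, 300)

#' @rdname window_spec
#' @export
liver_window <- function() window_spec(-40, 160)

organ_window <- function(organ) switch(organ, kidney = kidney_window(), liver = liver_window())

#' Window a Hounsfield-unit image to [0, 1]
#'
#' Clamps intensities to `[lo, hi]` and maps the window affinely onto
#' `[0, 1]`, the standard CT preprocessing that concentrates display range
#' on the organ of interest.
#'
#' @param image Numeric array of HU values.
#' @param w A [window_spec()].
#' @return Array of the same shape with values in `[0, 1]`.
#' @examples
#' hu_window(c(-200, 50, 500), kidney_window())  # 0, 0.5, 1
#' @export
hu_window <- function(image, w) {
  if (!inherits(w, "window_spec")) stop_hlfd("w must be a window_spec")
  (pmin(pmax(image, w$lo), w$hi) - w$lo) / (w$hi - w$lo)
}

# Smooth random field: coarse normal grid bilinearly upsampled.
smooth_field <- function(size, coarse, sd) {
  resize2d(matrix(stats::rnorm(coarse * coarse, sd = sd), coarse, coarse), size, size)
}

difficulty_params <- function(difficulty) {
  switch(difficulty,
         easy = list(contrast = 60, noise_sd = 5),
         hard = list(contrast = 25, noise_sd = 10),
         stop_hlfd("difficulty must be 'easy' or 'hard'"))
}

organ_hu_base <- function(organ) switch(organ, kidney = c(25, 40), liver = c(45, 60))

gen_one_phantom <- function(size, organ, dp, index, seed) {
  xg <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  yg <- matrix(rep(seq_len(size), times = size), size, size)  # row index

  img <- -80 + smooth_field(size, max(4L, size %/% 8L), 30)

  # organ ellipse
  cx <- stats::runif(1, 0.4, 0.6) * size
  cy <- stats::runif(1, 0.4, 0.6) * size
  a <- stats::runif(1, 0.22, 0.36) * size
  b <- stats::runif(1, 0.22, 0.36) * size
  th <- stats::runif(1, 0, pi)
  dx <- xg - cx; dy <- yg - cy
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  inside <- u^2 + v^2 <= 1
  base_rng <- organ_hu_base(organ)
  organ_hu <- stats::runif(1, base_rng[1], base_rng[2])
  tex <- smooth_field(size, max(4L, size %/% 8L), 4)
  img[inside] <- organ_hu + tex[inside]

  # tumors: irregular blobs (radial Fourier noise), hypodense by `contrast`
  mask <- matrix(0, size, size)
  n_tum <- sample(0:3, 1, prob = c(0.15, 0.4, 0.3, 0.15))
  for (t in seq_len(n_tum)) {
    rr <- sqrt(stats::runif(1)) * 0.55
    ang <- stats::runif(1, 0, 2 * pi)
    tu <- rr * cos(ang); tv <- rr * sin(ang)  # ellipse-normalised coords
    tcx <- cx + (tu * a) * cos(th) - (tv * b) * sin(th)
    tcy <- cy + (tu * a) * sin(th) + (tv * b) * cos(th)
    r0 <- stats::runif(1, 0.25, 0.5) * min(a, b)
    amp <- stats::rnorm(3, sd = 0.12)
    phs <- stats::runif(3, 0, 2 * pi)
    px <- xg - tcx; py <- yg - tcy
    rho <- sqrt(px^2 + py^2)
    phi <- atan2(py, px)
    redge <- r0 * (1 + 0.35 * (amp[1] * cos(2 * phi + phs[1]) +
                                 amp[2] * cos(3 * phi + phs[2]) +
                                 amp[3] * cos(4 * phi + phs[3])))
    blob <- rho <= redge & inside  # tumors stay inside the organ
    delta <- dp$contrast * stats::runif(1, 0.8, 1.2)
    img[blob] <- organ_hu - delta + tex[blob]
    mask[blob] <- 1
  }

  img <- img + matrix(stats::rnorm(size * size, sd = dp$noise_sd), size, size)
  structure(list(image = img, mask = mask,
                 meta = list(organ = organ, seed = seed, index = index,
                             n_tumors = n_tum)),
            class = "phantom_sample")
}

#' Generate synthetic CT phantom slices with tumor masks
#'
#' Each sample is a pseudo-Hounsfield-unit slice containing one elliptical
#' organ (organ-typical HU band: kidney 25-40, liver 45-60), zero to three
#' hypodense tumor blobs with irregular radially-perturbed boundaries, a
#' smooth background tissue texture around -80 HU, and additive Gaussian
#' noise. Tumor pixels always lie inside the organ ellipse. `difficulty`
#' controls the tumor/organ HU contrast and the noise level (easy: contrast
#' 60 HU, noise sd 5; hard: contrast 25 HU, noise sd 10). Deterministic
#' given `seed`.
#'
#' @param n Number of samples (>= 1).
#' @param size Image side in pixels (>= 16; default 64).
#' @param organ `"kidney"` or `"liver"`.
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed Integer seed.
#' @return A list of `phantom_sample` objects (class `phantom_set`), each
#'   with fields `image` (HU matrix), `mask` (binary matrix), `meta`.
#' @export
generate_phantoms <- function(n, size = 64L, organ = c("kidney", "liver"),
                              difficulty = c("easy", "hard"), seed = 0L) {
  organ <- match.arg(organ)
  difficulty <- match.arg(difficulty)
  if (n < 1L) stop_hlfd("n must be >= 1")
  if (size < 16L) stop_hlfd("size must be >= 16 pixels")
  dp <- difficulty_params(difficulty)
  samples <- with_seed(seed, lapply(seq_len(n), function(i)
    gen_one_phantom(as.integer(size), organ, dp, i, seed)))
  structure(samples, class = c("phantom_set", "list"),
            organ = organ, difficulty = difficulty, seed = seed, size = size)
}

#' @export
print.phantom_set <- function(x, ...) {
  nonempty <- mean(vapply(x, function(s) sum(s$mask) > 0, logical(1)))
  cat(sprintf("<phantom_set: %d %s %s slices %dx%d, %.0f%% with tumors>\n",
              length(x), attr(x, "difficulty"), attr(x, "organ"),
              attr(x, "size"), attr(x, "size"), 100 * nonempty))
  invisible(x)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample %s #%d: %dx%d, %d tumors, %d tumor px>\n",
              x$meta$organ, x$meta$index, nrow(x$image), ncol(x$image),
              x$meta$n_tumors, sum(x$mask)))
  invisible(x)
}

rot90_mat <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  m
}

#' Rotate/flip augmentation of a phantom sample
#'
#' Applies a rotation by a multiple of 90 degrees and optionally a
#' horizontal flip, identically to image and mask. Restricting rotations to
#' 90-degree multiples keeps the mask exactly binary (no resampling). Either
#' pass `rot`/`flip` explicitly or a `seed` from which they are drawn
#' uniformly over the 8 dihedral transforms.
#'
#' @param sample A `phantom_sample`.
#' @param seed Integer seed for a random transform (ignored when `rot` is given).
#' @param rot Quarter-turns, 0-3.
#' @param flip Logical, horizontal flip after rotation.
#' @return The transformed `phantom_sample`.
#' @export
augment_sample <- function(sample, seed = NULL, rot = NULL, flip = NULL) {
  if (is.null(rot)) {
    if (is.null(seed)) stop_hlfd("augment_sample needs either a seed or explicit rot/flip")
    ch <- with_seed(seed, c(sample(0:3, 1), sample(c(TRUE, FALSE), 1)))
    rot <- ch[1]; flip <- as.logical(ch[2])
  }
  if (is.null(flip)) flip <- FALSE
  tr <- function(m) {
    m <- rot90_mat(m, rot)
    if (flip) m <- m[, ncol(m):1, drop = FALSE]
    m
  }
  sample$image <- tr(sample$image)
  sample$mask <- tr(sample$mask)
  sample
}

## ---- dataset IO ------------------------------------------------------------

# CRC32 (PNG chunk checksums), table-driven.
png_crc_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) else
            bitwShiftR(bitwAnd(c, -2L), 1)
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- png_crc_table()
  c <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(bitwShiftR(bitwAnd(c, -256L), 8) %% 16777216L, tab[idx + 1])
  }
  bitwXor(c, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(as.numeric(crc32(body)) %% 4294967296))
}

# Minimal 16-bit greyscale PNG writer (zlib stream with stored-deflate
# blocks; no installed R package writes 16-bit PNG). png::readPNG reads the
# result back as values in [0, 1].
write_png16 <- function(x, path) {
  x <- pmin(pmax(x, 0), 1)
  h <- nrow(x); w <- ncol(x)
  vals <- round(t(x) * 65535)  # row-major scanlines
  hi <- as.raw(vals %/% 256); lo <- as.raw(vals %% 256)
  scan <- raw(h * (1 + 2 * w))
  for (r in seq_len(h)) {
    off <- (r - 1) * (1 + 2 * w) + 1
    idx <- ((r - 1) * w + 1):(r * w)
    scan[seq(off + 1, off + 2 * w, by = 2)] <- hi[idx]
    scan[seq(off + 2, off + 2 * w, by = 2)] <- lo[idx]
  }
  # zlib: header, stored-deflate blocks, adler32
  adler <- {
    s1 <- 1; s2 <- 0
    v <- as.integer(scan)
    for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
      for (b in chunk) { s1 <- (s1 + b) %% 65521; s2 <- (s2 + s1) %% 65521 }
    }
    s2 * 65536 + s1
  }
  blocks <- raw(0)
  n <- length(scan); at <- 1
  while (at <= n) {
    len <- min(65535L, n - at + 1L)
    last <- as.integer(at + len - 1L == n)
    blocks <- c(blocks, as.raw(last),
                as.raw(c(len %% 256, len %/% 256)),
                as.raw(c(bitwAnd(bitwXor(len, 65535L), 255L), bitwXor(len, 65535L) %/% 256)),
                scan[at:(at + len - 1L)])
    at <- at + len
  }
  idat <- c(as.raw(c(0x78, 0x01)), blocks, u32be(adler))
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# HU values are stored in 16-bit PNGs via a fixed affine map; the manifest
# records the bounds so reading is lossless up to 16-bit quantisation.
HU_STORE_LO <- -1024
HU_STORE_HI <- 3072

#' Write a phantom dataset to disk
#'
#' Images are stored as 16-bit greyscale PNGs (HU mapped affinely onto the
#' recorded storage window), masks as 8-bit PNGs, plus a JSON manifest with
#' generation metadata and the HU storage bounds.
#'
#' @param samples A `phantom_set` or list of `phantom_sample`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    imgf <- sprintf("image_%04d.png", i)
    maskf <- sprintf("mask_%04d.png", i)
    write_png16((s$image - HU_STORE_LO) / (HU_STORE_HI - HU_STORE_LO),
                file.path(dir, imgf))
    png::writePNG(s$mask, file.path(dir, maskf))
    list(image = imgf, mask = maskf, organ = s$meta$organ,
         n_tumors = s$meta$n_tumors)
  })
  manifest <- list(n = length(samples),
                   size = nrow(samples[[1]]$image),
                   organ = attr(samples, "organ"),
                   difficulty = attr(samples, "difficulty"),
                   seed = attr(samples, "seed"),
                   hu_store = c(HU_STORE_LO, HU_STORE_HI),
                   samples = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `phantom_set`.
#' @export
read_phantom_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  lohi <- mf$hu_store
  samples <- lapply(seq_len(mf$n), function(i) {
    img <- png::readPNG(file.path(dir, mf$samples$image[i]))
    mask <- png::readPNG(file.path(dir, mf$samples$mask[i]))
    structure(list(image = img * (lohi[2] - lohi[1]) + lohi[1],
                   mask = round(mask),
                   meta = list(organ = mf$samples$organ[i], seed = mf$seed,
                               index = i, n_tumors = mf$samples$n_tumors[i])),
              class = "phantom_sample")
  })
  structure(samples, class = c("phantom_set", "list"), organ = mf$organ,
            difficulty = mf$difficulty, seed = mf$seed, size = mf$size)
}

#' Export a phantom stack as a NIfTI volume
#'
#' Stacks the slices into a height x width x n volume of HU values and
#' writes it with RNifti (suggested dependency).
#'
#' @param samples A `phantom_set`.
#' @param path Output `.nii`/`.nii.gz` path; the mask volume is written next
#'   to it with suffix `_mask`.
#' @return `path`, invisibly.
#' @export
export_nifti <- function(samples, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_hlfd("export_nifti requires the RNifti package")
  size <- nrow(samples[[1]]$image)
  vol <- array(0, c(size, size, length(samples)))
  msk <- vol
  for (i in seq_along(samples)) {
    vol[, , i] <- samples[[i]]$image
    msk[, , i] <- samples[[i]]$mask
  }
  RNifti::writeNifti(vol, path)
  RNifti::writeNifti(msk, sub("(\\.nii(\\.gz)?)$", "_mask\\1", path))
  invisible(path)
}
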