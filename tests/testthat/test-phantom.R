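# Phantom generator, HU windowing, augmentation, dataset IO.

test_that("hu_window clamps and rescales to [0, 1]", {
  kw <- kidney_window()
  expect_equal(hu_window(500, kw), 1)
  expect_equal(hu_window(-200, kw), 0)
  expect_equal(hu_window(50, kw), 0.5)
  lw <- liver_window()
  expect_equal(hu_window(c(-40, 60, 160, 1000, -500), lw), c(0, 0.5, 1, 1, 0))
  expect_error(window_spec(100, 100), "lo < hi")
  expect_error(hu_window(1, list(lo = 0, hi = 1)), "window_spec")
})

test_that("generation is deterministic and respects size/count contracts", {
  a <- generate_phantoms(5, 32, "kidney", "hard", seed = 42)
  b <- generate_phantoms(5, 32, "kidney", "hard", seed = 42)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  expect_identical(lapply(a, `[[`, "mask"), lapply(b, `[[`, "mask"))
  d <- generate_phantoms(5, 32, "kidney", "hard", seed = 43)
  expect_false(identical(a[[1]]$image, d[[1]]$image))
  for (s in a) {
    expect_equal(dim(s$image), dim(s$mask))
    expect_true(all(s$mask %in% c(0, 1)))
  }
  expect_error(generate_phantoms(0, 32), "n must")
  expect_error(generate_phantoms(3, 8), "size")
})

test_that("easy phantoms have higher tumor/organ contrast than hard ones", {
  # empirical contrast: tumor interior HU vs a 2-pixel ring around the tumor
  ring_contrast <- function(s) {
    m <- s$mask
    if (sum(m) < 4) return(NA_real_)
    dil <- m
    for (i in 1:2) {
      d <- dil
      d[-1, ] <- pmax(d[-1, ], dil[-nrow(dil), ])
      d[-nrow(d), ] <- pmax(d[-nrow(d), ], dil[-1, ])
      d[, -1] <- pmax(d[, -1], dil[, -ncol(dil)])
      d[, -ncol(d)] <- pmax(d[, -ncol(d)], dil[, -1])
      dil <- d
    }
    ring <- dil == 1 & m == 0
    if (sum(ring) < 4) return(NA_real_)
    mean(s$image[ring]) - mean(s$image[m == 1])
  }
  easy <- generate_phantoms(100, 48, "kidney", "easy", seed = 5)
  hard <- generate_phantoms(100, 48, "kidney", "hard", seed = 5)
  ce <- mean(vapply(easy, ring_contrast, numeric(1)), na.rm = TRUE)
  ch <- mean(vapply(hard, ring_contrast, numeric(1)), na.rm = TRUE)
  expect_gt(ce, ch)
  expect_gt(ce, 0)  # tumors are hypodense relative to surrounding tissue
})

test_that("most samples contain tumors and HU bands sit inside the organ window", {
  ds <- generate_phantoms(500, 32, "kidney", "easy", seed = 123)
  frac <- mean(vapply(ds, function(s) sum(s$mask) > 0, logical(1)))
  expect_gte(frac, 0.7)
  # windowed images keep usable contrast: organ interior is not saturated
  w <- kidney_window()
  mid_vals <- vapply(ds[1:50], function(s) {
    wi <- hu_window(s$image, w)
    stats::median(wi)
  }, numeric(1))
  expect_true(all(mid_vals > 0.05 & mid_vals < 0.95))
})

test_that("augmentation acts identically on image and mask and composes", {
  s <- generate_phantoms(1, 32, "kidney", "easy", seed = 9)[[1]]
  # four quarter-turns compose to the identity
  r <- s
  for (i in 1:4) r <- augment_sample(r, rot = 1, flip = FALSE)
  expect_equal(r$image, s$image)
  expect_equal(r$mask, s$mask)
  # mask pixel count is invariant under any dihedral transform
  for (rot in 0:3) for (flip in c(TRUE, FALSE)) {
    t <- augment_sample(s, rot = rot, flip = flip)
    expect_equal(sum(t$mask), sum(s$mask))
    # transform-then-invert round trip: tumor boundary IoU of 1
    inv <- augment_sample(t, rot = if (flip) 0L else (4L - rot) %% 4L, flip = flip)
    if (flip) inv <- augment_sample(inv, rot = (4L - rot) %% 4L, flip = FALSE)
    expect_equal(inv$mask, s$mask)
  }
  # seeded draws are reproducible
  a1 <- augment_sample(s, seed = 31)
  a2 <- augment_sample(s, seed = 31)
  expect_identical(a1$image, a2$image)
})

test_that("datasets round-trip through 16-bit PNG plus manifest", {
  ds <- generate_phantoms(4, 32, "liver", "easy", seed = 77)
  dir <- file.path(tempdir(), "phantom_ds")
  write_phantom_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_phantom_dataset(dir)
  expect_equal(length(back), 4L)
  for (i in 1:4) {
    # 16-bit quantisation of the 4096-HU storage window: ~0.03 HU resolution
    expect_lt(max(abs(back[[i]]$image - ds[[i]]$image)), 0.05)
    expect_equal(back[[i]]$mask, ds[[i]]$mask)
    expect_equal(back[[i]]$meta$organ, "liver")
  }
  # the image files really are 16-bit PNGs (IHDR bit-depth byte)
  hdr <- readBin(file.path(dir, "image_0001.png"), "raw", 32)
  expect_equal(as.integer(hdr[25]), 16L)
  img <- png::readPNG(file.path(dir, "image_0001.png"))
  expect_equal(dim(img), c(32L, 32L))
})

test_that("phantom stacks export to NIfTI volumes", {
  ds <- generate_phantoms(3, 32, "kidney", "easy", seed = 8)
  path <- file.path(tempdir(), "phantoms.nii.gz")
  export_nifti(ds, path)
  vol <- RNifti::readNifti(path)
  expect_equal(dim(vol), c(32L, 32L, 3L))
  expect_equal(max(abs(vol[, , 2] - ds[[2]]$image)), 0, tolerance = 1e-5)
  msk <- RNifti::readNifti(file.path(tempdir(), "phantoms_mask.nii.gz"))
  expect_true(all(msk %in% c(0, 1)))
})
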