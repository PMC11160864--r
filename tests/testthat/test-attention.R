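# Feature-level distillation: attention operator, unified middle
# representation, UFD/IFD losses.

test_that("attention_map aggregates absolute activations across channels", {
  f <- array(0, c(2, 2, 2))
  f[1, , ] <- matrix(c(1, -1, 0, 2), 2, 2, byrow = TRUE)
  f[2, , ] <- matrix(c(-1, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(attention_map(f), matrix(c(2, 2, 0, 2), 2, 2, byrow = TRUE))
  expect_equal(attention_map(array(0, c(3, 4, 4))), matrix(0, 4, 4))
  set.seed(1)
  for (i in 1:10) expect_true(all(attention_map(rand_fm(3, 5, 4)) >= 0))
  # exponent 2 squares before summing
  expect_equal(attention_map(f, exponent = 2),
               matrix(c(2, 2, 0, 4), 2, 2, byrow = TRUE))
  expect_error(attention_map(array(c(1, NA), c(1, 1, 2))), "finite")
})

test_that("unify_mids resamples to the smallest grid and concatenates channels", {
  mids <- list(rand_fm(8, 32, 32), rand_fm(16, 16, 16))
  u <- unify_mids(mids)
  expect_equal(dim(u$values), c(24L, 16L, 16L))
  # deeper mid is already at the target size: passed through untouched
  expect_equal(u$values[9:24, , ], mids[[2]])
  m1 <- rand_fm(4, 8, 8)
  expect_equal(unify_mids(list(m1))$values, m1)  # single mid returned unchanged
  const <- unify_mids(list(array(7, c(2, 4, 4)), array(1, c(1, 8, 8))))
  expect_equal(dim(const$values), c(3L, 4L, 4L))
  expect_true(all(abs(const$values[3, , ] - 1) < 1e-12))  # interpolation preserves constants
  expect_error(unify_mids(list()), "non-empty")
})

test_that("normalized_attention yields unit-L2 vectors with a zero-map guard", {
  f <- array(c(3, 4), c(1, 1, 2))
  v <- normalized_attention(f)
  expect_equal(v$values, c(0.6, 0.8))
  # constant 1x1 map upscaled to 2x2 stays constant, then unit-normalised
  v2 <- normalized_attention(array(5, c(1, 1, 1)), target_shape = c(2, 2))
  expect_equal(v2$values, rep(0.5, 4))
  # scale invariance under positive scaling
  set.seed(2)
  g <- rand_fm(3, 6, 6)
  for (s in c(0.01, 3, 1e4))
    expect_equal(normalized_attention(g * s)$values, normalized_attention(g)$values,
                 tolerance = 1e-9)
  # zero map passes the eps guard as a zero vector
  expect_equal(normalized_attention(array(0, c(2, 3, 3)))$values, rep(0, 9))
  # unit norm for arbitrary nonzero maps
  for (i in 1:20) {
    vv <- normalized_attention(rand_fm(2, 4, 5), target_shape = c(3, 3))
    expect_equal(sqrt(sum(vv$values^2)), 1, tolerance = 1e-6)
  }
})

test_that("ufd_loss matches closed forms and the literal-equation oracle", {
  # identical features -> 0
  f <- rand_fm(4, 8, 8)
  expect_equal(ufd_loss(f, f), 0)
  # orthogonal unit attention vectors -> sqrt(2)
  zs <- array(c(1, 0), c(1, 1, 2))
  zt <- array(c(0, 1), c(1, 1, 2))
  expect_equal(ufd_loss(zs, zt), sqrt(2), tolerance = 1e-12)
  # oracle equivalence on random same-shape instances (no resampling involved)
  set.seed(3)
  for (i in 1:120) {
    a <- rand_fm(sample(1:4, 1), 4, 4)
    b <- rand_fm(sample(1:4, 1), 4, 4)
    expect_equal(ufd_loss(a, b), oracle_att_distance(a, b), tolerance = 1e-6)
  }
  # cross-shape: package resampling agrees with an independent bilinear oracle
  for (i in 1:10) {
    a <- rand_fm(2, 8, 8); b <- rand_fm(3, 4, 4)
    am <- attention_map(a)
    ar <- oracle_bilinear(am, 4, 4)
    va <- as.numeric(ar) / max(sqrt(sum(ar^2)), 1e-8)
    vb <- oracle_att_vec(b)
    expect_equal(ufd_loss(a, b), sqrt(sum((va - vb)^2)), tolerance = 1e-6)
  }
})

test_that("ifd_loss sums per-layer terms (and matches the oracle)", {
  late <- rand_fm(4, 4, 4)
  expect_equal(ifd_loss(list(late, late), late), 0)
  # two orthogonal-attention mids -> each term sqrt(2), summed
  zs <- array(c(1, 0), c(1, 1, 2)); zt <- array(c(0, 1), c(1, 1, 2))
  expect_equal(ifd_loss(list(zs, zs), zt), 2 * sqrt(2), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:60) {
    mids <- lapply(1:2, function(j) rand_fm(2, 4, 4))
    lt <- rand_fm(3, 4, 4)
    expect_equal(ifd_loss(mids, lt), oracle_ifd(mids, lt), tolerance = 1e-6)
  }
  expect_error(ifd_loss(list(), late), "non-empty")
})

test_that("feature-level losses are nonnegative, bounded, symmetric and scale-invariant", {
  set.seed(5)
  for (i in 1:50) {
    a <- rand_fm(3, 5, 5); b <- rand_fm(2, 5, 5)
    l <- ufd_loss(a, b)
    expect_gte(l, 0)
    expect_lte(l, 2 + 1e-9)  # distance between unit vectors
    # symmetric in its two normalised arguments
    expect_equal(l, ufd_loss(b, a), tolerance = 1e-9)
    # invariant to positive scaling of either argument
    expect_equal(ufd_loss(a * 37, b), l, tolerance = 1e-7)
    expect_equal(ufd_loss(a, b * 0.001), l, tolerance = 1e-7)
  }
})

test_that("flfd_loss adds the unified and individual terms", {
  set.seed(6)
  mk_bundle <- function() {
    rep_bundle(feature_map(rand_fm(4, 16, 16), "early"),
               list(feature_map(rand_fm(8, 8, 8), "mid1"),
                    feature_map(rand_fm(16, 4, 4), "mid2")),
               feature_map(rand_fm(32, 2, 2), "late"))
  }
  rs <- mk_bundle(); rt <- mk_bundle()
  zmid <- unify_mids(lapply(rt$mids, function(m) m$values))
  expected <- ufd_loss(rs$early$values, zmid$values) +
    ifd_loss(lapply(rs$mids, function(m) m$values), rt$late$values)
  expect_equal(flfd_loss(rs, rt), expected, tolerance = 1e-12)
  expect_gte(flfd_loss(rs, rt), 0)
  # zero at identity of the compared attention patterns: constant-valued
  # maps all normalise to the uniform vector, so every term vanishes
  const_bundle <- rep_bundle(feature_map(array(2, c(4, 16, 16)), "early"),
                             list(feature_map(array(1, c(8, 8, 8)), "mid1"),
                                  feature_map(array(3, c(16, 4, 4)), "mid2")),
                             feature_map(array(5, c(32, 2, 2)), "late"))
  expect_equal(flfd_loss(const_bundle, const_bundle), 0, tolerance = 1e-9)
})
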