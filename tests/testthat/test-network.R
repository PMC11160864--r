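# Reference networks: tap shapes, reproducibility, freeze and export
# contracts, teacher predictive maps.

teacher_spec <- network_spec("teacher", c(8, 16, 32, 64))
student_spec <- network_spec("student", c(6, 12, 24, 48))

test_that("encoder taps follow the stride-2 downsampling plan", {
  te <- build_teacher(teacher_spec, seed = 1)
  fw <- forward_pass(te, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(fw$reps$early$values)[2:3], c(64L, 64L))
  expect_equal(lapply(fw$reps$mids, function(m) dim(m$values)[2:3]),
               list(c(32L, 32L), c(16L, 16L)))
  expect_equal(dim(fw$reps$late$values)[2:3], c(8L, 8L))
  # spatial monotonicity holds across input sizes divisible by the factor
  st <- build_student(student_spec, seed = 1)
  for (sz in c(32L, 48L, 64L)) {
    r <- forward_pass(st, matrix(runif(sz * sz), sz, sz))$reps
    sizes <- c(dim(r$early$values)[2],
               vapply(r$mids, function(m) dim(m$values)[2], integer(1)),
               dim(r$late$values)[2])
    expect_true(all(diff(sizes) < 0))
  }
})

test_that("builds are reproducible from seed and differ across seeds", {
  a <- build_teacher(teacher_spec, seed = 7)
  b <- build_teacher(teacher_spec, seed = 7)
  expect_identical(a$params, b$params)
  c <- build_teacher(teacher_spec, seed = 8)
  expect_true(any(mapply(function(x, y) any(x != y), a$params, c$params)))
  s1 <- build_student(student_spec, seed = 3)
  s2 <- build_student(student_spec, seed = 3)
  expect_identical(s1$params, s2$params)
})

test_that("invalid specs raise configuration errors", {
  expect_error(network_spec("teacher", c(8, 16)), "middle tap")
  expect_error(network_spec("teacher", c(8, 16, 32), deep_supervision = FALSE),
               "deep_supervision")
  expect_error(build_teacher(network_spec("student", c(4, 8, 16))), "teacher")
  expect_error(build_student(network_spec("teacher", c(4, 8, 16))), "student")
})

test_that("student auxiliary heads emit class-logit maps and are discardable", {
  st <- build_student(student_spec, seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- forward_pass(st, img)
  expect_equal(dim(fw$aux$early)[1], 2L)
  for (m in fw$aux$mids) expect_equal(dim(m)[1], 2L)
  expect_equal(length(fw$aux$mids), student_spec$n_mid)
  # export for inference: auxiliary heads gone, final output unchanged
  ex <- export_for_inference(st)
  expect_false(any(grepl("^aux_", names(ex$params))))
  fw2 <- forward_pass(ex, img)
  expect_null(fw2$aux)
  expect_identical(fw2$logits, fw$logits)
  # student is smaller than the teacher at default widths
  expect_lt(n_params(st), n_params(build_teacher(teacher_spec, 2)))
})

test_that("frozen teacher is deterministic and untouched by distillation", {
  te <- freeze(build_teacher(teacher_spec, seed = 5))
  img <- matrix(runif(32 * 32), 32, 32)
  f1 <- forward_pass(te, img); f2 <- forward_pass(te, img)
  expect_identical(f1$preds$late$values, f2$preds$late$values)
  before <- te$params
  data <- tiny_phantoms(8)
  fit <- distill_student(te, data, network_spec("student", c(4, 8, 16, 32)),
                         train_config(epochs = 1, batch_size = 4, seed = 1,
                                      augment = FALSE))
  expect_identical(te$params, before)
  # ... while the student's parameters did change
  init <- build_student(network_spec("student", c(4, 8, 16, 32)), 1)
  expect_true(any(mapply(function(x, y) any(x != y), fit$network$params, init$params)))
})

test_that("teacher predictive maps are simplex-valued at every tap", {
  te <- freeze(build_teacher(teacher_spec, seed = 9))
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- forward_pass(te, img)
  pb <- teacher_pred_maps(te, fw$reps)
  expect_equal(length(pb$mids), teacher_spec$n_mid)
  for (p in c(list(pb$early), pb$mids, list(pb$late))) {
    sums <- apply(p$values, c(2, 3), sum)
    expect_true(max(abs(sums - 1)) < 1e-6)
    expect_equal(dim(p$values)[1], 2L)
  }
  # repeated calls on the same frozen teacher agree exactly
  pb2 <- teacher_pred_maps(te, fw$reps)
  expect_identical(pb$late$values, pb2$late$values)
  # configuration error when deep supervision is absent
  te_bad <- te
  te_bad$spec$deep_supervision <- FALSE
  expect_error(teacher_pred_maps(te_bad, fw$reps), "deep-supervision")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  st <- build_student(student_spec, seed = 4)
  path <- file.path(tempdir(), "ckpt", "student.rds")
  save_network(st, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$role, "student")
  expect_equal(side$seed, 4L)
  back <- load_network(path)
  expect_identical(back$params, st$params)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict(back, img), predict(st, img))
})
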