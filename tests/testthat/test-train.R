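# Training pipeline: logging contracts, the supervised reduction, gradient
# routing, and consistency of the training graph with the public operators.

test_that("teacher training logs one row per epoch and the loss decreases", {
  ds <- tiny_phantoms(16)
  fit <- train_teacher(ds, network_spec("teacher", c(6, 12, 24, 48)),
                       train_config(epochs = 3, batch_size = 8, seed = 2))
  expect_s3_class(fit, "hlfd_teacher_fit")
  expect_equal(nrow(fit$log), 3L)
  expect_true(all(c("epoch", "seg", "ufd", "ifd", "upd", "ipd", "total", "lr")
                  %in% names(fit$log)))
  expect_lt(fit$log$total[3], fit$log$total[1])
  # cosine schedule spans lr .. lr_min
  expect_equal(fit$log$lr[1], 1e-3)
  expect_equal(fit$log$lr[3], 1e-6)
  expect_error(train_teacher(list(), config = train_config(epochs = 1)), "empty")
})

test_that("with beta = lambda = 0 distillation reduces to supervised training", {
  ds <- tiny_phantoms(16)
  spec <- network_spec("student", c(4, 8, 16, 32))
  te <- build_teacher(network_spec("teacher", c(6, 12, 24, 48)), seed = 1)
  cfg0 <- train_config(epochs = 2, batch_size = 8, seed = 7,
                       weights = loss_weights(beta = 0, lambda = 0))
  a <- distill_student(te, ds, spec, cfg0)
  b <- train_student(ds, spec, train_config(epochs = 2, batch_size = 8, seed = 7))
  expect_equal(a$log$total, b$log$total, tolerance = 1e-12)
  expect_equal(a$network$params, b$network$params, tolerance = 1e-12)
  # and the trajectory differs once distillation is on
  cfg1 <- train_config(epochs = 2, batch_size = 8, seed = 7)
  c <- distill_student(te, ds, spec, cfg1)
  expect_false(isTRUE(all.equal(c$network$params, b$network$params)))
  expect_true(all(c$log$ufd > 0) && all(c$log$upd > 0))
})

test_that("each loss component alone routes gradients to the student only", {
  ds <- tiny_phantoms(4)
  te <- freeze(build_teacher(network_spec("teacher", c(6, 12, 24, 48)), seed = 3))
  st <- build_student(network_spec("student", c(4, 8, 16, 32)), seed = 4)
  batch <- hlfd:::make_batch(ds[1:2])
  g <- hlfd:::student_loss_graph(te, st, batch$x, batch$mask,
                                 loss_weights(), hlfd_control())
  # frozen teacher parameters never enter the graph as trainable nodes
  expect_true(all(vapply(g$param_ids, is.numeric, logical(1))))
  for (comp in names(g$components)) {
    grads <- hlfd:::tp_backward(g$tape, g$components[[comp]])
    pg <- lapply(g$param_ids, function(id) grads[[id]])
    gnorm <- sum(vapply(pg, function(x) if (is.null(x)) 0 else sum(abs(x)), numeric(1)))
    expect_gt(gnorm, 0)
  }
  # seg reaches the main head but must not touch auxiliary heads
  grads <- hlfd:::tp_backward(g$tape, g$components$seg)
  aux_ids <- g$param_ids[grepl("^aux_", names(g$param_ids))]
  expect_true(all(vapply(aux_ids, function(id) is.null(grads[[id]]), logical(1))))
  # pixel-level losses are the only route into the auxiliary heads
  grads_upd <- hlfd:::tp_backward(g$tape, g$components$upd)
  expect_gt(sum(abs(grads_upd[[g$param_ids[["aux_early.w"]]]])), 0)
})

test_that("the training graph reproduces the public loss operators", {
  ds <- tiny_phantoms(2, size = 64)
  te <- freeze(build_teacher(network_spec("teacher", c(8, 16, 32, 64)), seed = 5))
  st <- build_student(network_spec("student", c(6, 12, 24, 48)), seed = 6)
  s <- ds[[1]]
  img <- hu_window(s$image, kidney_window())
  batch <- hlfd:::make_batch(ds[1])
  g <- hlfd:::student_loss_graph(te, st, batch$x, batch$mask,
                                 loss_weights(), hlfd_control())
  ft <- forward_pass(te, img)
  fs <- forward_pass(st, img)
  expect_equal(g$breakdown$seg, focal_dice_loss(fs$logits, s$mask), tolerance = 1e-8)
  zmid <- unify_mids(lapply(ft$reps$mids, function(m) m$values))
  expect_equal(g$breakdown$ufd, ufd_loss(fs$reps$early$values, zmid), tolerance = 1e-8)
  expect_equal(g$breakdown$ifd,
               ifd_loss(lapply(fs$reps$mids, function(m) m$values), ft$reps$late$values),
               tolerance = 1e-8)
  pmid <- unify_teacher_mid_probs(ft$preds$mids)
  expect_equal(g$breakdown$upd, upd_loss(fs$aux$early, pmid), tolerance = 1e-8)
  expect_equal(g$breakdown$ipd, ipd_loss(fs$aux$mids, ft$preds$late), tolerance = 1e-8)
  # stored total equals the independent recombination
  expect_equal(g$breakdown$total,
               g$breakdown$seg + 0.9 * (g$breakdown$ufd + g$breakdown$ifd) +
                 0.1 * (g$breakdown$upd + g$breakdown$ipd), tolerance = 1e-9)
})

test_that("distillation logs per-step breakdowns and writes artifacts", {
  ds <- tiny_phantoms(8)
  te <- build_teacher(network_spec("teacher", c(6, 12, 24, 48)), seed = 1)
  out <- file.path(tempdir(), "distill_out")
  fit <- distill_student(te, ds, network_spec("student", c(4, 8, 16, 32)),
                         train_config(epochs = 2, batch_size = 4, seed = 1),
                         val = ds[1:2], out = out)
  expect_equal(nrow(fit$steps), 2L * 2L)  # 2 epochs x 2 batches
  expect_true(all(c("seg", "ufd", "ifd", "upd", "ipd", "total") %in% names(fit$steps)))
  with(fit$steps, expect_equal(total, seg + 0.9 * (ufd + ifd) + 0.1 * (upd + ipd),
                               tolerance = 1e-9))
  expect_true(file.exists(file.path(out, "train_log.csv")))
  expect_true(file.exists(file.path(out, "student_hlfd.rds.json")))
  expect_false(is.null(fit$val))
  # mismatched tap counts are rejected with the offending tap named
  bad_spec <- network_spec("student", c(4, 8, 16, 32, 64))  # 3 mids vs teacher's 2
  expect_error(distill_student(te, ds, bad_spec, train_config(epochs = 1)),
               "middle taps")
})
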