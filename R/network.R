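## Miniature reference segmentation networks with named representation taps.
##
## The teacher is a compact encoder-decoder with long skip connections and
## deep-supervision heads (one class-logit head per decoder scale plus a 1x1
## head on the bottleneck); the student is a residual-block encoder with a
## light upsampling head and detachable 1x1 auxiliary class heads on its
## early and middle taps. Both are sized for CPU training; stage channels
## are configurable.

#' Describe a teacher or student network
#'
#' A network spec fixes the role, the per-stage channel widths and the tap
#' plan. The first stage is the "early" tap, the last the "late" tap, and
#' every stage in between a "mid" tap, so at least three stages are needed.
#' Each stage after the first halves the spatial resolution.
#'
#' @param role `"teacher"` or `"student"`.
#' @param stage_channels Positive integer vector of per-stage channel
#'   widths, length >= 3.
#' @param num_classes Number of output classes (default 2: background /
#'   foreground).
#' @param in_channels Image channels (default 1, grayscale).
#' @param deep_supervision Whether the decoder emits intermediate predictive
#'   maps. Must be `TRUE` for teachers (their middle predictive maps feed
#'   the pixel-level losses); ignored for students.
#' @return An object of class `network_spec` with the derived `tap_plan`
#'   (`early`, `mids`, `late` stage names) and `n_mid`.
#' @examples
#' network_spec("teacher", c(8, 16, 32, 64))
#' @export
network_spec <- function(role = c("teacher", "student"),
                         stage_channels = c(8, 16, 32, 64),
                         num_classes = 2L, in_channels = 1L,
                         deep_supervision = NULL) {
  role <- match.arg(role)
  stage_channels <- as.integer(stage_channels)
  if (any(stage_channels < 1L)) stop_hlfd("stage_channels must be positive")
  n_mid <- length(stage_channels) - 2L
  if (n_mid < 1L)
    stop_hlfd("configuration error: %d stages leave no middle tap (need >= 3 stages)",
              length(stage_channels))
  if (num_classes < 1L) stop_hlfd("num_classes must be positive")
  if (is.null(deep_supervision)) deep_supervision <- role == "teacher"
  if (role == "teacher" && !deep_supervision)
    stop_hlfd("configuration error: a teacher spec requires deep_supervision = TRUE")
  s <- length(stage_channels)
  tap_plan <- list(early = "stage1",
                   mids = paste0("stage", seq(2L, s - 1L)),
                   late = paste0("stage", s))
  structure(list(role = role, stage_channels = stage_channels,
                 num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 deep_supervision = deep_supervision,
                 n_mid = n_mid, tap_plan = tap_plan),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec %s: channels [%s], %d classes, %d mid taps%s>\n",
              x$role, paste(x$stage_channels, collapse = ", "), x$num_classes,
              x$n_mid, if (x$deep_supervision) ", deep supervision" else ""))
  invisible(x)
}

conv_layer <- function(name, k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                       head = FALSE)
  list(name = name, k = k, cin = cin, cout = cout, stride = stride, pad = pad,
       head = head)

# Decoder convs run at half the encoder width (but no narrower than the
# first stage): segmentation quality is boundary-dominated, so the shallow,
# full-resolution decoder stages keep their width while deep ones shrink.
dec_channels <- function(sc) pmax(sc[1], sc %/% 2L)

teacher_layers <- function(spec) {
  sc <- spec$stage_channels; s <- length(sc); k <- spec$num_classes
  dc <- dec_channels(sc)
  ly <- list(conv_layer("s1c1", 3L, spec$in_channels, sc[1]),
             conv_layer("s1c2", 3L, sc[1], sc[1]))
  for (i in 2:s)
    ly <- c(ly, list(conv_layer(sprintf("s%dc1", i), 3L, sc[i - 1], sc[i], stride = 2L),
                     conv_layer(sprintf("s%dc2", i), 3L, sc[i], sc[i])))
  for (i in (s - 1):1) {
    cin <- (if (i == s - 1L) sc[s] else dc[i + 1]) + sc[i]
    ly <- c(ly, list(conv_layer(sprintf("d%d", i), 3L, cin, dc[i])))
  }
  ly <- c(ly, list(conv_layer("head_late", 1L, sc[s], k, head = TRUE)))
  for (i in (s - 1):1)
    ly <- c(ly, list(conv_layer(sprintf("head_d%d", i), 1L, dc[i], k, head = TRUE)))
  ly
}

student_layers <- function(spec) {
  sc <- spec$stage_channels; s <- length(sc); k <- spec$num_classes
  ly <- list(conv_layer("stem", 3L, spec$in_channels, sc[1]))
  for (i in 2:s)
    ly <- c(ly, list(conv_layer(sprintf("s%dc1", i), 3L, sc[i - 1], sc[i], stride = 2L),
                     conv_layer(sprintf("s%dc2", i), 3L, sc[i], sc[i]),
                     conv_layer(sprintf("s%dskip", i), 1L, sc[i - 1], sc[i], stride = 2L)))
  ly <- c(ly, list(conv_layer("h1", 1L, sc[s], 16L),
                   conv_layer("h2", 3L, 16L, 8L),
                   conv_layer("h3", 1L, 8L, k, head = TRUE),
                   conv_layer("aux_early", 1L, sc[1], k, head = TRUE)))
  for (j in seq_len(s - 2L))
    ly <- c(ly, list(conv_layer(sprintf("aux_mid%d", j), 1L, sc[j + 1], k, head = TRUE)))
  ly
}

init_params <- function(layers, seed) {
  with_seed(seed, {
    params <- list()
    for (ly in layers) {
      sd <- sqrt(2 / (ly$k * ly$k * ly$cin))
      params[[paste0(ly$name, ".w")]] <-
        array(stats::rnorm(ly$k * ly$k * ly$cin * ly$cout, sd = sd),
              c(ly$k, ly$k, ly$cin, ly$cout))
      b <- numeric(ly$cout)
      # class heads start at the foreground prior (log-odds about -2.5) so
      # early training is not spent escaping the all-background regime
      if (isTRUE(ly$head) && ly$cout >= 2L) b[-1] <- -2.5
      params[[paste0(ly$name, ".b")]] <- b
    }
    params
  })
}

new_network <- function(spec, layers, seed, class) {
  ltab <- stats::setNames(layers, vapply(layers, `[[`, "", "name"))
  structure(list(spec = spec, layers = ltab, params = init_params(layers, seed),
                 seed = as.integer(seed), frozen = FALSE, aux_stripped = FALSE),
            class = c(class, "hlfd_net"))
}

#' Build the reference teacher network
#'
#' A compact encoder-decoder: each encoder stage is two 3x3 convolutions
#' (the first at stride 2 beyond stage 1); the decoder upsamples, concatenates
#' the same-scale encoder feature and convolves back down. Deep-supervision
#' 1x1 heads emit a class-logit map at every decoder scale plus the
#' bottleneck, furnishing the early/middle/late predictive maps.
#'
#' @param spec A teacher [network_spec()].
#' @param seed Integer seed; parameter initialisation (He-scaled normal) is
#'   bit-reproducible given the seed.
#' @return An object of class `hlfd_teacher` / `hlfd_net`.
#' @export
build_teacher <- function(spec, seed = 0L) {
  if (!inherits(spec, "network_spec") || spec$role != "teacher")
    stop_hlfd("configuration error: build_teacher needs a spec with role = 'teacher'")
  new_network(spec, teacher_layers(spec), seed, "hlfd_teacher")
}

#' Build the reference student network
#'
#' A residual-block encoder (each stage: stride-2 3x3 conv, 3x3 conv, and a
#' 1x1 stride-2 projection shortcut) with a light upsampling head producing
#' full-resolution class logits, plus detachable 1x1 auxiliary class heads on
#' the early and middle taps. The auxiliary heads exist only to receive the
#' pixel-level distillation losses and are discarded at inference
#' (see [export_for_inference()]).
#'
#' @param spec A student [network_spec()].
#' @param seed Integer seed for reproducible initialisation.
#' @return An object of class `hlfd_student` / `hlfd_net`.
#' @export
build_student <- function(spec, seed = 0L) {
  if (!inherits(spec, "network_spec") || spec$role != "student")
    stop_hlfd("configuration error: build_student needs a spec with role = 'student'")
  new_network(spec, student_layers(spec), seed, "hlfd_student")
}

#' Number of trainable parameters of a network
#' @param net An `hlfd_net`.
#' @return Integer count.
#' @export
n_params <- function(net) sum(vapply(net$params, length, integer(1)))

#' @export
print.hlfd_net <- function(x, ...) {
  cat(sprintf("<%s: channels [%s], %s parameters%s%s>\n",
              class(x)[1], paste(x$spec$stage_channels, collapse = ", "),
              format(n_params(x), big.mark = ","),
              if (x$frozen) ", frozen" else "",
              if (x$aux_stripped) ", inference-only" else ""))
  invisible(x)
}

#' Freeze a network
#'
#' A frozen network contributes no trainable parameters: during distillation
#' its parameters enter the computation graph as constants, so no gradient
#' reaches them and they are bit-identical before and after any number of
#' optimisation steps. Outputs are unchanged.
#'
#' @param net An `hlfd_net`.
#' @return The network, marked frozen.
#' @export
freeze <- function(net) {
  net$frozen <- TRUE
  net
}

#' Strip auxiliary heads for deployment
#'
#' Removes the student's auxiliary distillation heads. The final
#' segmentation output is unchanged: the auxiliary heads never feed the main
#' prediction path.
#'
#' @param net An `hlfd_student`.
#' @return The student without auxiliary-head parameters.
#' @export
export_for_inference <- function(net) {
  if (!inherits(net, "hlfd_student")) stop_hlfd("export_for_inference applies to students")
  aux <- grep("^aux_", names(net$params), value = TRUE)
  net$params[aux] <- NULL
  net$layers[grep("^aux_", names(net$layers), value = TRUE)] <- NULL
  net$aux_stripped <- TRUE
  net
}

## ---- forward passes (numeric or taped via ctx) -----------------------------

ctx_make <- function(net, tape = NULL) {
  pids <- NULL
  if (!is.null(tape)) {
    mk <- if (net$frozen) tp_const else tp_param
    pids <- lapply(net$params, function(p) mk(tape, p))
  }
  list(tape = tape, net = net, pids = pids)
}

c_dim <- function(ctx, x) if (is.null(ctx$tape)) dim(x) else dim(tp_value(ctx$tape, x))

c_conv <- function(ctx, x, name) {
  ly <- ctx$net$layers[[name]]
  if (is.null(ly)) stop_hlfd("configuration error: no layer '%s' in this network", name)
  wn <- paste0(name, ".w"); bn <- paste0(name, ".b")
  if (is.null(ctx$tape))
    nn_conv2d_fwd(x, ctx$net$params[[wn]], ctx$net$params[[bn]], ly$stride, ly$pad)
  else tp_conv2d(ctx$tape, x, ctx$pids[[wn]], ctx$pids[[bn]], ly$stride, ly$pad)
}

c_relu <- function(ctx, x) if (is.null(ctx$tape)) pmax(x, 0) else tp_relu(ctx$tape, x)
c_add  <- function(ctx, a, b) if (is.null(ctx$tape)) a + b else tp_add(ctx$tape, a, b)
c_resize <- function(ctx, x, h, w)
  if (is.null(ctx$tape)) resize4d(x, h, w) else tp_resize(ctx$tape, x, h, w)

c_concat <- function(ctx, ids) {
  if (!is.null(ctx$tape)) return(tp_concat(ctx$tape, ids))
  chans <- vapply(ids, function(v) dim(v)[3], integer(1))
  d1 <- dim(ids[[1]])
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in ids) { out[, , at + seq_len(dim(v)[3]), ] <- v; at <- at + dim(v)[3] }
  out
}

# Shared encoder walk; returns the list of per-stage outputs.
encode_ctx <- function(ctx, x) {
  spec <- ctx$net$spec
  s <- length(spec$stage_channels)
  enc <- vector("list", s)
  if (spec$role == "teacher") {
    h <- c_relu(ctx, c_conv(ctx, x, "s1c1"))
    enc[[1]] <- c_relu(ctx, c_conv(ctx, h, "s1c2"))
    for (i in 2:s) {
      h <- c_relu(ctx, c_conv(ctx, enc[[i - 1]], sprintf("s%dc1", i)))
      enc[[i]] <- c_relu(ctx, c_conv(ctx, h, sprintf("s%dc2", i)))
    }
  } else {
    enc[[1]] <- c_relu(ctx, c_conv(ctx, x, "stem"))
    for (i in 2:s) {
      main <- c_relu(ctx, c_conv(ctx, enc[[i - 1]], sprintf("s%dc1", i)))
      main <- c_conv(ctx, main, sprintf("s%dc2", i))
      skip <- c_conv(ctx, enc[[i - 1]], sprintf("s%dskip", i))
      enc[[i]] <- c_relu(ctx, c_add(ctx, main, skip))
    }
  }
  enc
}

# Teacher decoder over encoder taps; returns per-scale class-logit heads:
# list(early = full-res head, mids = intermediate heads (shallow to deep),
# late = bottleneck head).
teacher_decode_ctx <- function(ctx, enc) {
  s <- length(enc)
  heads <- vector("list", s - 1L)
  d <- enc[[s]]
  late_head <- c_conv(ctx, d, "head_late")
  for (i in (s - 1):1) {
    dm <- c_dim(ctx, enc[[i]])
    up <- c_resize(ctx, d, dm[1], dm[2])
    d <- c_relu(ctx, c_conv(ctx, c_concat(ctx, list(up, enc[[i]])), sprintf("d%d", i)))
    heads[[i]] <- c_conv(ctx, d, sprintf("head_d%d", i))
  }
  list(early = heads[[1]], mids = heads[seq(2L, s - 1L)], late = late_head)
}

student_head_ctx <- function(ctx, late, h_full, w_full) {
  dm <- c_dim(ctx, late)
  h <- c_relu(ctx, c_conv(ctx, late, "h1"))
  h <- c_resize(ctx, h, min(2L * dm[1], h_full), min(2L * dm[2], w_full))
  h <- c_relu(ctx, c_conv(ctx, h, "h2"))
  h <- c_resize(ctx, h, h_full, w_full)
  c_conv(ctx, h, "h3")
}

student_aux_ctx <- function(ctx, enc) {
  s <- length(enc)
  list(early = c_conv(ctx, enc[[1]], "aux_early"),
       mids = lapply(seq_len(s - 2L), function(j)
         c_conv(ctx, enc[[j + 1]], sprintf("aux_mid%d", j))))
}

as_input_hwcb <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L, 1L))
  else if (length(dim(image)) == 3L) image <- chw_to_hwcb(image)
  check_finite(image, "input image")
  image
}

hwcb_to_fm <- function(x, tag) feature_map(hwcb_to_chw(x), tag)
hwcb_to_probmap <- function(logits) prob_map(softmax_chw(hwcb_to_chw(logits)))

#' Run a network forward pass
#'
#' For a teacher, returns the encoder representation bundle and the decoder
#' predictive-map bundle (per-pixel softmax applied). For a student, returns
#' the representation bundle, the full-resolution class-logit map, and (if
#' present) the auxiliary class-logit maps for the early and middle taps.
#'
#' @param net An `hlfd_net`.
#' @param image An H x W matrix (values typically in `[0, 1]` after
#'   Hounsfield windowing) or a C x H x W array.
#' @return For teachers, `list(reps, preds)`; for students,
#'   `list(reps, logits, aux)` where `aux` is `NULL` after
#'   [export_for_inference()].
#' @export
forward_pass <- function(net, image) {
  x <- as_input_hwcb(image)
  ctx <- ctx_make(net)
  enc <- encode_ctx(ctx, x)
  plan <- net$spec$tap_plan
  s <- length(enc)
  reps <- rep_bundle(hwcb_to_fm(enc[[1]], plan$early),
                     lapply(seq(2L, s - 1L), function(i) hwcb_to_fm(enc[[i]], plan$mids[i - 1L])),
                     hwcb_to_fm(enc[[s]], plan$late))
  if (net$spec$role == "teacher") {
    hd <- teacher_decode_ctx(ctx, enc)
    preds <- pred_bundle(hwcb_to_probmap(hd$early),
                         lapply(hd$mids, hwcb_to_probmap),
                         hwcb_to_probmap(hd$late))
    list(reps = reps, preds = preds)
  } else {
    logits <- student_head_ctx(ctx, enc[[s]], dim(x)[1], dim(x)[2])
    aux <- NULL
    if (!net$aux_stripped) {
      a <- student_aux_ctx(ctx, enc)
      aux <- list(early = hwcb_to_chw(a$early), mids = lapply(a$mids, hwcb_to_chw))
    }
    list(reps = reps, logits = hwcb_to_chw(logits), aux = aux)
  }
}

#' Teacher predictive maps from encoder representations
#'
#' Passes the teacher's encoder output through the (deep-supervised) decoder
#' and converts every class-logit head to a probability map by per-pixel
#' softmax. The terminal representation is the decoder's principal input;
#' the skip connections additionally consume the early and middle taps, so
#' the full representation bundle is required.
#'
#' @param teacher An `hlfd_teacher` (typically [freeze()]d).
#' @param reps The teacher `rep_bundle` from [forward_pass()].
#' @return A `pred_bundle` of `prob_map`s.
#' @export
teacher_pred_maps <- function(teacher, reps) {
  if (!inherits(teacher, "hlfd_teacher")) stop_hlfd("teacher_pred_maps needs an hlfd_teacher")
  if (!isTRUE(teacher$spec$deep_supervision))
    stop_hlfd("configuration error: teacher lacks deep-supervision heads")
  if (!inherits(reps, "rep_bundle")) stop_hlfd("reps must be a rep_bundle")
  ctx <- ctx_make(teacher)
  enc <- c(list(chw_to_hwcb(reps$early$values)),
           lapply(reps$mids, function(m) chw_to_hwcb(m$values)),
           list(chw_to_hwcb(reps$late$values)))
  hd <- teacher_decode_ctx(ctx, enc)
  pred_bundle(hwcb_to_probmap(hd$early), lapply(hd$mids, hwcb_to_probmap),
              hwcb_to_probmap(hd$late))
}

#' Predict a segmentation for one image
#'
#' @param object An `hlfd_net` (teacher or student).
#' @param image H x W matrix in `[0, 1]` (windowed intensity).
#' @param type `"prob"` for the foreground-probability map, `"mask"` for the
#'   thresholded binary mask, `"logits"` for raw class logits.
#' @param threshold Foreground threshold for `type = "mask"` (default 0.5).
#' @param ... Unused.
#' @return A matrix (prob/mask) or class x H x W array (logits).
#' @export
predict.hlfd_net <- function(object, image, type = c("prob", "mask", "logits"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  fw <- forward_pass(object, image)
  logits <- if (object$spec$role == "teacher") {
    p <- fw$preds$early$values  # full-resolution head
    log(pmax(p, 1e-12))
  } else fw$logits
  if (type == "logits") return(logits)
  p <- softmax_chw(logits)[2, , ]
  if (type == "prob") p else (p >= threshold) * 1
}

## ---- checkpoints -----------------------------------------------------------

#' Save a network checkpoint
#'
#' Writes the serialized network plus a JSON sidecar carrying the spec and
#' seed for provenance.
#'
#' @param net An `hlfd_net`.
#' @param path Destination file (an `.json` sidecar is written next to it).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(net, path)
  side <- list(class = class(net)[1], role = net$spec$role,
               stage_channels = net$spec$stage_channels,
               num_classes = net$spec$num_classes,
               deep_supervision = net$spec$deep_supervision,
               seed = net$seed, n_params = n_params(net))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a network checkpoint written by [save_network()]
#' @param path Checkpoint file.
#' @return The `hlfd_net`.
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "hlfd_net")) stop_hlfd("'%s' is not a network checkpoint", path)
  net
}
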