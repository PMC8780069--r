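# Network assembly: backbone -> dual-path suppression block -> stretch ->
# factorized bilinear fusion -> L2 norm -> linear classifier.
#
# The backbone emits a (h, w, c) map per image (7 x 7 for the default input
# sizes). The local path flattens it to m x c spatial descriptors and applies
# stochastic peak suppression in training; the global path residual-encodes
# the same descriptors against n codewords and suppresses per-channel maxima.
# A learned position-axis affine map stretches the n x c encoding to m x c so
# both paths align position-wise for fusion.

CKPT_FORMAT <- "dsenet-checkpoint-1"

#' Model configuration
#'
#' @param backbone_name `"resnet50"` (50-layer residual backbone, for
#'   224-pixel inputs) or `"tiny"` (lightweight 3-stage test backbone, for
#'   56-pixel inputs by default).
#' @param n_classes number of output classes.
#' @param n_codewords number of residual-encoding codewords (default 8).
#' @param alpha global (orderless-path) suppressing factor in `[0, 1]`;
#'   the default 0 together with `beta = 0.1` is the setting that performed
#'   best in the ablation this architecture was tuned on.
#' @param beta local (spatial-path) suppressing factor in `[0, 1]`.
#' @param p Bernoulli channel-selection probability of the local suppression.
#' @param ct_max upper bound of the local-suppression pass count.
#' @param ls_recompute recompute the local peak mask each pass (see
#'   [local_suppression_config()]).
#' @param rank_k factorization rank of the fusion layer.
#' @param output_dim_o fusion output dimension; defaults to the backbone
#'   channel count (2048 for the 50-layer backbone).
#' @param lambda sparsity weight of the fusion soft-threshold step.
#' @param input_size square input resolution in pixels.
#' @param pretrained reserved flag for externally supplied backbone weights;
#'   the package never requires them.
#' @return an object of class `model_config`.
#' @export
model_config <- function(backbone_name = "resnet50", n_classes = 4L,
                         n_codewords = 8L, alpha = 0, beta = 0.1, p = 0.5,
                         ct_max = 3L, ls_recompute = TRUE, rank_k = 2L,
                         output_dim_o = NULL, lambda = 0.01,
                         input_size = if (backbone_name == "tiny") 56L else 224L,
                         pretrained = FALSE) {
  if (!backbone_name %in% c("resnet50", "tiny"))
    stop("unknown backbone: ", backbone_name, call. = FALSE)
  stopifnot(n_classes >= 2, n_codewords >= 1, input_size >= 8)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  # validates beta/p/ct_max
  local_suppression_config(beta, p, ct_max, ls_recompute)
  structure(list(backbone_name = backbone_name, n_classes = as.integer(n_classes),
                 n_codewords = as.integer(n_codewords), alpha = alpha,
                 beta = beta, p = p, ct_max = as.integer(ct_max),
                 ls_recompute = isTRUE(ls_recompute), rank_k = as.integer(rank_k),
                 output_dim_o = if (is.null(output_dim_o)) NULL else as.integer(output_dim_o),
                 lambda = lambda, input_size = as.integer(input_size),
                 pretrained = isTRUE(pretrained)),
            class = "model_config")
}

#' Build the classification network
#'
#' Instantiates the backbone and the dual-path head (codebook, stretch map,
#' fusion factorization, classifier) with all trainable parameters registered
#' in one flat named list, partitioned by the `backbone.` / `head.` name
#' prefixes.
#'
#' @param cfg a [model_config].
#' @param seed optional seed for reproducible initialization.
#' @return an object of class `dsenet_model`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  build <- function() {
    bb <- switch(cfg$backbone_name,
                 resnet50 = backbone_spec_resnet50(),
                 tiny = backbone_spec_tiny())
    if (cfg$input_size %% bb$downsample_factor != 0)
      stop("input_size must be a multiple of ", bb$downsample_factor, call. = FALSE)
    side <- cfg$input_size %/% bb$downsample_factor
    m <- side * side
    c_ <- bb$out_channels
    n <- cfg$n_codewords
    o <- cfg$output_dim_o %||% c_
    ini <- backbone_init(bb$spec)
    params <- ini$params
    cb <- codebook_init(n, c_)
    params[["head.codebook.D"]] <- cb$D
    params[["head.codebook.S"]] <- cb$S
    lim <- sqrt(6 / (n + m))
    params[["head.stretch.w"]] <- matrix(stats::runif(m * n, -lim, lim), m, n)
    params[["head.stretch.b"]] <- numeric(m)
    fp <- fbe_params(c_, c_, k = cfg$rank_k, o = o, lambda = cfg$lambda)
    params[["head.fbe.U"]] <- fp$U
    params[["head.fbe.V"]] <- fp$V
    params[["head.fbe.Q"]] <- fp$Q
    params[["head.fbe.B"]] <- fp$B
    lim_fc <- sqrt(6 / (o + cfg$n_classes))
    params[["head.fc.w"]] <- matrix(stats::runif(o * cfg$n_classes, -lim_fc, lim_fc),
                                    o, cfg$n_classes)
    params[["head.fc.b"]] <- numeric(cfg$n_classes)
    structure(list(cfg = cfg, spec = bb$spec, params = params,
                   buffers = ini$buffers, m = m, c = c_, o = o,
                   norm = list(mean = 0.5, sd = 0.25)),
              class = "dsenet_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Stretch the encoding matrix along the codeword axis
#'
#' Applies the learned affine map `W %*% E + b` (shared across channels) that
#' turns the `n x c` orderless encoding into an `m x c` position-aligned
#' feature for fusion.
#'
#' @param E `n x c` encoding matrix.
#' @param w `m x n` stretch weights.
#' @param b length-`m` bias.
#' @return `m x c` matrix.
#' @export
stretch_global <- function(E, w, b) {
  E <- as.matrix(E)
  if (ncol(w) != nrow(E)) stop("stretch map expects ", ncol(w),
                               " codeword rows, got ", nrow(E), call. = FALSE)
  w %*% E + b
}

# Head forward for one feature map (h x w x c array), with caches.
head_forward_one <- function(model, fm, training) {
  p <- model$params; cfg <- model$cfg
  Xm <- flatten_positions(fm)                   # m x c
  ls_cfg <- local_suppression_config(cfg$beta, cfg$p, cfg$ct_max, cfg$ls_recompute)
  ls <- local_suppress(t(Xm), ls_cfg, training = training)
  Xt <- t(ls$out)                               # m x c local path
  enc <- encode_block_forward(Xm, p[["head.codebook.D"]], p[["head.codebook.S"]],
                              cfg$alpha)
  E <- enc$out                                  # n x c global path
  Et <- stretch_global(E, p[["head.stretch.w"]], p[["head.stretch.b"]])
  fp <- structure(list(U = p[["head.fbe.U"]], V = p[["head.fbe.V"]],
                       Q = p[["head.fbe.Q"]], B = p[["head.fbe.B"]],
                       lambda = cfg$lambda), class = "fbe_params")
  fb <- fbe_block_forward(Xt, Et, fp)
  list(z = fb$out,
       cache = list(enc = enc$cache, ls_factor = ls$factor, fbe = fb$cache,
                    E = E, fm_dim = dim(fm)))
}

head_backward_one <- function(model, cache, dz) {
  p <- model$params
  fp <- structure(list(U = p[["head.fbe.U"]], V = p[["head.fbe.V"]],
                       Q = p[["head.fbe.Q"]], B = p[["head.fbe.B"]],
                       lambda = model$cfg$lambda), class = "fbe_params")
  fb <- fbe_block_backward(dz, fp, cache$fbe)
  # stretch backward
  dEt <- fb$dEt
  dWst <- dEt %*% t(cache$E)
  dbst <- rowSums(dEt)
  dE <- crossprod(p[["head.stretch.w"]], dEt)
  eb <- encode_block_backward(dE, cache$enc)
  dXm <- eb$dX + fb$dXt * t(cache$ls_factor)
  grads <- list("head.codebook.D" = eb$dD, "head.codebook.S" = eb$dS,
                "head.stretch.w" = dWst, "head.stretch.b" = dbst,
                "head.fbe.U" = fb$dU, "head.fbe.V" = fb$dV,
                "head.fbe.Q" = fb$dQ, "head.fbe.B" = fb$dB)
  list(dfm = array(dXm, cache$fm_dim), grads = grads)
}

#' Forward pass of the assembled network
#'
#' @param model a [build_model()] result.
#' @param x input array `(H, W, 3, N)` of preprocessed images (see
#'   [preprocess_images()]).
#' @param training logical; enables batch statistics and the stochastic local
#'   suppression. Evaluation mode is deterministic for fixed weights.
#' @param keep_cache retain intermediate caches for a backward pass.
#' @return a list with `logits` (`N x n_classes`), `fused` (`N x o` fused
#'   representations), and, when `keep_cache`, internal caches plus updated
#'   batch-norm `buffers`.
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[1] != model$cfg$input_size ||
      d[2] != model$cfg$input_size || d[3] != 3)
    stop("expected input of shape (", model$cfg$input_size, ", ",
         model$cfg$input_size, ", 3, N)", call. = FALSE)
  bb <- spec_forward(model$spec, x, model$params, model$buffers, training,
                     keep_cache = keep_cache)
  f <- bb$out
  N <- d[4]
  Zs <- matrix(0, N, model$o)
  head_caches <- if (keep_cache) vector("list", N) else NULL
  for (i in seq_len(N)) {
    hf <- head_forward_one(model, f[, , , i, drop = TRUE], training)
    Zs[i, ] <- hf$z
    if (keep_cache) head_caches[[i]] <- hf$cache
  }
  logits <- Zs %*% model$params[["head.fc.w"]] +
    rep(model$params[["head.fc.b"]], each = N)
  out <- list(logits = logits, fused = Zs, featmap = f)
  if (keep_cache) {
    out$bb_caches <- bb$caches
    out$head_caches <- head_caches
    out$buffers <- bb$buffers
  }
  out
}

#' Backward pass of the assembled network
#'
#' @param model the model used in the forward pass.
#' @param fwd the `keep_cache = TRUE` result of [model_forward()].
#' @param dlogits gradient of the scalar loss w.r.t. the logits
#'   (`N x n_classes`).
#' @param through_backbone propagate into the backbone (needed for training it;
#'   can be disabled when only head gradients are required).
#' @return a list with `grads` (named list over registered parameters) and
#'   `dfeat` (gradient at the backbone output).
#' @export
model_backward <- function(model, fwd, dlogits, through_backbone = TRUE) {
  N <- nrow(dlogits)
  Zs <- fwd$fused
  grads <- list("head.fc.w" = crossprod(Zs, dlogits),
                "head.fc.b" = colSums(dlogits))
  dZs <- dlogits %*% t(model$params[["head.fc.w"]])
  dfeat <- array(0, dim(fwd$featmap))
  for (i in seq_len(N)) {
    hb <- head_backward_one(model, fwd$head_caches[[i]], dZs[i, ])
    dfeat[, , , i] <- hb$dfm
    grads <- accumulate_grads(grads, hb$grads)
  }
  if (through_backbone) {
    bbk <- spec_backward(model$spec, dfeat, model$params, fwd$bb_caches)
    grads <- accumulate_grads(grads, bbk$grads)
  }
  list(grads = grads, dfeat = dfeat)
}

#' Report the end-to-end shape contract
#'
#' Runs one forward pass on a dummy input and returns the sizes of every
#' printed stage: backbone map, dual-path branches, fused vector, logits.
#'
#' @param model a [build_model()] result.
#' @return named list of integer shape vectors.
#' @export
inspect_shapes <- function(model) {
  s <- model$cfg$input_size
  x <- array(0, c(s, s, 3, 1))
  fw <- model_forward(model, x, training = FALSE)
  fd <- dim(fw$featmap)
  list(input = c(s, s, 3),
       backbone = c(fd[1], fd[2], fd[3]),
       global_branch = c(model$cfg$n_codewords, fd[3]),
       local_branch = c(model$m, fd[3]),
       stretched_global = c(model$m, fd[3]),
       fused = model$o,
       logits = model$cfg$n_classes)
}

#' Preprocess images into a network input batch
#'
#' Resizes each intensity matrix bilinearly to the model input size, rescales
#' `[0, 255]` to `[0, 1]`, replicates grayscale to three channels, and
#' standardizes with the model's normalization statistics.
#'
#' @param model a [build_model()] result (provides input size and statistics).
#' @param images list of numeric matrices in `[0, 255]`.
#' @return array of shape `(input_size, input_size, 3, N)`.
#' @export
preprocess_images <- function(model, images) {
  s <- model$cfg$input_size
  N <- length(images)
  x <- array(0, c(s, s, 3, N))
  for (i in seq_len(N)) {
    img <- resize_bilinear(as.matrix(images[[i]]), s, s) / 255
    img <- (img - model$norm$mean) / model$norm$sd
    x[, , 1, i] <- img; x[, , 2, i] <- img; x[, , 3, i] <- img
  }
  x
}

#' Save / load model checkpoints
#'
#' The checkpoint embeds the configuration, all parameters, batch-norm buffers
#' and normalization statistics; a round trip preserves weights bitwise.
#'
#' @param model a [build_model()] result.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `dsenet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = CKPT_FORMAT, cfg = model$cfg, params = model$params,
               buffers = model$buffers, norm = model$norm), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param n_classes if supplied, the checkpoint's class count must match.
#' @export
load_checkpoint <- function(path, n_classes = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, CKPT_FORMAT))
    stop("unsupported checkpoint format: ", ck$format %||% "<missing>",
         call. = FALSE)
  if (!is.null(n_classes) && ck$cfg$n_classes != n_classes)
    stop("checkpoint was trained with ", ck$cfg$n_classes,
         " classes, requested ", n_classes, call. = FALSE)
  model <- build_model(ck$cfg, seed = 0L)
  model$params <- ck$params
  model$buffers <- ck$buffers
  model$norm <- ck$norm
  model
}

#' Load only backbone weights from a checkpoint (transfer-learning path)
#'
#' Copies every `backbone.`-prefixed parameter and buffer whose name and shape
#' match; newly added head layers keep their initialization.
#'
#' @param model target model.
#' @param path checkpoint path.
#' @return the model with backbone weights replaced.
#' @export
load_backbone_weights <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$format, CKPT_FORMAT))
    stop("unsupported checkpoint format", call. = FALSE)
  for (nm in names(ck$params)) {
    if (startsWith(nm, "backbone.") && !is.null(model$params[[nm]]) &&
        identical(dim(model$params[[nm]]) %||% length(model$params[[nm]]),
                  dim(ck$params[[nm]]) %||% length(ck$params[[nm]]))) {
      model$params[[nm]] <- ck$params[[nm]]
    }
  }
  for (nm in names(ck$buffers)) {
    if (startsWith(nm, "backbone.") && !is.null(model$buffers[[nm]]))
      model$buffers[[nm]] <- ck$buffers[[nm]]
  }
  model
}
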