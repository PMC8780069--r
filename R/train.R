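# Training protocol: stratified ratio / k-fold splits, Adam with a 10x
# learning rate on the newly added head, and plateau halving of the learning
# rate after two consecutive non-improving epochs. No data augmentation is
# applied anywhere.

#' Specify a dataset split
#'
#' @param mode `"ratio"` (train/validation/test fractions) or `"kfold"`.
#' @param train_frac,val_frac,test_frac fractions summing to 1 (ratio mode);
#'   the default is the 70/15/15 protocol.
#' @param k number of folds (kfold mode).
#' @param stratified preserve per-class proportions (default `TRUE`).
#' @param seed integer seed; splits are deterministic given the seed.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(mode = c("ratio", "kfold"), train_frac = 0.7,
                       val_frac = 0.15, test_frac = 0.15, k = 5L,
                       stratified = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ratio") {
    fr <- c(train_frac, val_frac, test_frac)
    if (any(fr < 0) || any(fr >= 1) || abs(sum(fr) - 1) > 1e-8)
      stop("fractions must lie in [0, 1) and sum to 1", call. = FALSE)
    if (train_frac <= 0) stop("train fraction must be positive", call. = FALSE)
  } else {
    k <- as.integer(k)
    if (k < 2) stop("k must be >= 2", call. = FALSE)
  }
  structure(list(mode = mode, train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, k = as.integer(k),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n items over fractions, guaranteeing the
# counts sum to n. Exact remainder ties are broken by a preference order
# rotated with `rot`, so that strata with identical tied remainders spread
# their surplus across subsets instead of all favoring the same one.
apportion <- function(n, fr, rot = 0L) {
  raw <- n * fr
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    pref <- ((seq_along(fr) - 1L + rot) %% length(fr)) * 1e-9
    extra <- order(raw - base + pref, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build deterministic, stratified index sets
#'
#' In ratio mode returns disjoint, exhaustive `train` / `val` / `test` index
#' vectors; in kfold mode returns a list of `k` folds. Stratification
#' preserves class proportions within rounding.
#'
#' @param labels integer class ids (0-based or factor-like).
#' @param spec a [split_spec].
#' @return list of index vectors (1-based into `labels`).
#' @export
make_split <- function(labels, spec) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(labels)
  if (n < 1) stop("empty label vector", call. = FALSE)
  groups <- if (spec$stratified) split(seq_len(n), labels) else list(all = seq_len(n))
  with_seed(spec$seed, {
    if (spec$mode == "ratio") {
      fr <- c(spec$train_frac, spec$val_frac, spec$test_frac)
      parts <- list(train = integer(0), val = integer(0), test = integer(0))
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        sizes <- apportion(length(g), fr, rot = gi - 1L)
        if (sizes[1] < 1 || (fr[2] > 0 && sizes[2] < 1) || (fr[3] > 0 && sizes[3] < 1))
          stop("a class has too few samples for the requested fractions",
               call. = FALSE)
        g <- sample(g)
        parts$train <- c(parts$train, g[seq_len(sizes[1])])
        parts$val <- c(parts$val, g[sizes[1] + seq_len(sizes[2])])
        parts$test <- c(parts$test, g[sizes[1] + sizes[2] + seq_len(sizes[3])])
      }
      lapply(parts, sort)
    } else {
      folds <- vector("list", spec$k)
      for (g in groups) {
        if (length(g) < spec$k)
          stop("a class has fewer samples than folds", call. = FALSE)
        g <- sample(g)
        fid <- rep_len(seq_len(spec$k), length(g))
        for (f in seq_len(spec$k)) folds[[f]] <- c(folds[[f]], g[fid == f])
      }
      lapply(folds, sort)
    }
  })
}

#' Training configuration
#'
#' @param base_lr initial learning rate of pre-existing (backbone) layers.
#' @param new_layer_lr_mult learning-rate multiplier of newly added layers
#'   (default 10).
#' @param plateau_patience consecutive non-improving epochs before a decay.
#' @param lr_decay multiplicative decay factor (default 0.5, i.e. halving).
#' @param epochs,batch_size loop sizes.
#' @param seed seed controlling shuffling, suppression draws and
#'   initialization downstream.
#' @param monitor `"train"` (default) or `"val"`: which loss feeds the
#'   plateau schedule.
#' @param improve_tol minimum decrease counting as an improvement.
#' @param freeze_backbone exclude backbone parameters from optimization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(base_lr = 1e-4, new_layer_lr_mult = 10,
                         plateau_patience = 2L, lr_decay = 0.5, epochs = 50L,
                         batch_size = 32L, seed = 1L,
                         monitor = c("train", "val"), improve_tol = 1e-6,
                         freeze_backbone = FALSE) {
  monitor <- match.arg(monitor)
  stopifnot(base_lr > 0, new_layer_lr_mult > 0, plateau_patience >= 1,
            lr_decay > 0, lr_decay < 1, epochs >= 1, batch_size >= 1)
  structure(list(base_lr = base_lr, new_layer_lr_mult = new_layer_lr_mult,
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 monitor = monitor, improve_tol = improve_tol,
                 freeze_backbone = isTRUE(freeze_backbone)),
            class = "train_config")
}

#' Initial state of the plateau-halving schedule
#'
#' @param cfg a [train_config].
#' @return an `lr_state` list: `current_lr`, `epochs_without_improvement`,
#'   `best_loss`.
#' @export
lr_state_init <- function(cfg) {
  list(current_lr = cfg$base_lr, epochs_without_improvement = 0L,
       best_loss = Inf)
}

#' One step of the plateau-halving schedule
#'
#' An epoch loss improving on the best seen (by more than `improve_tol`)
#' resets the counter; after `plateau_patience` consecutive non-improving
#' epochs the learning rate is multiplied by `lr_decay` and the counter
#' resets.
#'
#' @param state an `lr_state` list.
#' @param epoch_loss the monitored loss of the finished epoch.
#' @param cfg a [train_config].
#' @return the updated state.
#' @export
lr_step <- function(state, epoch_loss, cfg) {
  if (!is.finite(epoch_loss)) stop("epoch loss must be finite", call. = FALSE)
  if (epoch_loss < state$best_loss - cfg$improve_tol) {
    state$best_loss <- epoch_loss
    state$epochs_without_improvement <- 0L
  } else {
    state$epochs_without_improvement <- state$epochs_without_improvement + 1L
    if (state$epochs_without_improvement >= cfg$plateau_patience) {
      state$current_lr <- state$current_lr * cfg$lr_decay
      state$epochs_without_improvement <- 0L
    }
  }
  state
}

#' Partition model parameters into optimizer groups
#'
#' Backbone parameters train at the base learning rate; all added layers
#' (codebook, scaling factors, stretch map, fusion factorization, classifier)
#' train at `new_layer_lr_mult` times that. The two groups cover every
#' registered parameter exactly once.
#'
#' @param model a [build_model()] result.
#' @param cfg a [train_config].
#' @return list with character vectors `backbone` and `head` of parameter
#'   names, plus `lr` per group.
#' @export
param_groups <- function(model, cfg = train_config()) {
  nms <- names(model$params)
  backbone <- nms[startsWith(nms, "backbone.")]
  head <- nms[startsWith(nms, "head.")]
  if (length(backbone) + length(head) != length(nms))
    stop("unpartitioned parameter(s): ",
         paste(setdiff(nms, c(backbone, head)), collapse = ", "), call. = FALSE)
  if (cfg$freeze_backbone) backbone <- character(0)
  list(backbone = backbone, head = head,
       lr = c(backbone = cfg$base_lr,
              head = cfg$base_lr * cfg$new_layer_lr_mult))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr_of, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr_of(nm) * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

softmax_ce <- function(logits, labels0) {
  n <- nrow(logits)
  a <- logits - apply(logits, 1, max)
  e <- exp(a)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels0 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

#' Train the network
#'
#' Minimizes multi-class cross-entropy with Adam, using the discriminative
#' learning rates and plateau-halving schedule of the training protocol.
#' Suppression of local spatial peaks is active only in training mode. The
#' best-validation-accuracy parameters are retained. All randomness (shuffling,
#' suppression draws) derives from `cfg$seed`, so a run is reproducible.
#'
#' @param model a [build_model()] result.
#' @param dataset a `dataset_index` (see [generate_phantoms()],
#'   [load_folder_dataset()]).
#' @param split list with `train` and `val` index vectors, e.g. from
#'   [make_split()].
#' @param cfg a [train_config].
#' @param verbose print one line per epoch to `stderr`.
#' @return list with `model` (best-validation weights), `history` (data frame
#'   of epoch, train_loss, val_acc, lr) and `best_val_acc`.
#' @export
train_model <- function(model, dataset, split, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  groups <- param_groups(model, cfg)
  lr_env <- new.env()
  lr_env$lrs <- lr_state_init(cfg)
  lr_of <- function(nm) {
    if (startsWith(nm, "head.")) lr_env$lrs$current_lr * cfg$new_layer_lr_mult
    else lr_env$lrs$current_lr
  }
  trainable <- c(groups$backbone, groups$head)
  opt <- adam_init(model$params[trainable])
  # dataset normalization statistics from the training portion
  tr_imgs <- dataset_images(dataset, split$train)
  pix <- unlist(lapply(tr_imgs[seq_len(min(64, length(tr_imgs)))],
                       function(m) as.numeric(m) / 255))
  model$norm <- list(mean = mean(pix), sd = max(stats::sd(pix), 1e-3))
  labels <- dataset_labels(dataset)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc = numeric(0), lr = numeric(0))
  best <- list(acc = -Inf, params = model$params, buffers = model$buffers)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample(split$train)
      nb <- ceiling(length(idx) / cfg$batch_size)
      epoch_loss <- 0
      for (b in seq_len(nb)) {
        bi <- idx[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, length(idx))]
        x <- preprocess_images(model, dataset_images(dataset, bi))
        fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
        model$buffers <- fw$buffers
        ce <- softmax_ce(fw$logits, labels[bi])
        if (!is.finite(ce$loss))
          stop("non-finite training loss at epoch ", epoch, ", batch ", b,
               call. = FALSE)
        bw <- model_backward(model, fw, ce$dlogits,
                             through_backbone = !cfg$freeze_backbone)
        step <- adam_step(model$params[trainable], bw$grads[trainable], opt, lr_of)
        model$params[trainable] <- step$params
        opt <- step$state
        epoch_loss <- epoch_loss + ce$loss * length(bi)
      }
      epoch_loss <- epoch_loss / length(idx)
      val_acc <- NA_real_
      if (length(split$val) > 0) {
        ev <- evaluate_model(model, dataset, split$val, batch_size = cfg$batch_size)
        val_acc <- ev$accuracy
        if (val_acc >= best$acc) {
          best <- list(acc = val_acc, params = model$params,
                       buffers = model$buffers)
        }
      } else {
        best <- list(acc = NA_real_, params = model$params,
                     buffers = model$buffers)
      }
      history <- rbind(history, data.frame(epoch = epoch, train_loss = epoch_loss,
                                           val_acc = val_acc,
                                           lr = lr_env$lrs$current_lr))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val acc %.4f  lr %.2e",
                        epoch, epoch_loss, val_acc, lr_env$lrs$current_lr))
      monitored <- if (cfg$monitor == "train" || is.na(val_acc)) epoch_loss
                   else -val_acc
      lr_env$lrs <- lr_step(lr_env$lrs, monitored, cfg)
    }
  })
  model$params <- best$params
  model$buffers <- best$buffers
  list(model = model, history = history, best_val_acc = best$acc)
}

#' Predict class probabilities and labels for dataset indices
#'
#' @param model a trained model.
#' @param dataset a `dataset_index`.
#' @param ids indices to evaluate (default: all records).
#' @param batch_size evaluation batch size.
#' @return list with `probs` (`n x n_classes`), `pred` (0-based labels),
#'   `actual`, `accuracy`.
#' @export
evaluate_model <- function(model, dataset, ids = NULL,
                           batch_size = 32L) {
  ids <- ids %||% seq_along(dataset$records)
  labels <- dataset_labels(dataset)[ids]
  probs <- matrix(0, length(ids), model$cfg$n_classes)
  nb <- ceiling(length(ids) / batch_size)
  for (b in seq_len(nb)) {
    sel <- ((b - 1) * batch_size + 1):min(b * batch_size, length(ids))
    x <- preprocess_images(model, dataset_images(dataset, ids[sel]))
    fw <- model_forward(model, x, training = FALSE)
    a <- fw$logits - apply(fw$logits, 1, max)
    e <- exp(a)
    probs[sel, ] <- e / rowSums(e)
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  list(probs = probs, pred = pred, actual = labels,
       accuracy = mean(pred == labels))
}
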