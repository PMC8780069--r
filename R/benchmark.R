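# Canonical offline benchmark: the four-class phantom task with the
# lightweight backbone, trained under the package's standard protocol
# (Adam, initial learning rate 1e-4, 10x on new layers, halving after two
# consecutive non-improving epochs, no augmentation).

#' Run the four-class phantom benchmark
#'
#' Generates 200 phantoms per class at 56-pixel resolution, splits them
#' 600 train / 200 test (stratified), trains the lightweight-backbone network
#' for up to `epochs` epochs (batch size 8, so the small training set still
#' yields enough optimizer steps) and reports test metrics. The 56-pixel
#' resolution keeps the benchmark CPU-friendly; phantom geometry is defined
#' in relative units, so the class structure matches the full-resolution
#' generator.
#'
#' @param seed integer seed controlling phantom generation, the split, weight
#'   initialization and training randomness.
#' @param epochs training epochs (default 10).
#' @param n_per_class phantoms generated per class (default 200).
#' @param verbose print per-epoch progress.
#' @return list with `test_accuracy`, `report` (a [metrics_report()]),
#'   `history`, `model`, `dataset`, `split`.
#' @export
run_phantom_benchmark <- function(seed = 1L, epochs = 10L, n_per_class = 200L,
                                  verbose = FALSE) {
  seed <- as.integer(seed)
  ds <- generate_phantoms(phantom_config(n_per_class = n_per_class,
                                         n_classes = 4L, image_size = 56L,
                                         seed = seed))
  sp <- make_split(dataset_labels(ds),
                   split_spec("ratio", train_frac = 0.75, val_frac = 0,
                              test_frac = 0.25, seed = seed + 1L))
  model <- build_model(model_config("tiny", n_classes = 4L), seed = seed + 2L)
  tcfg <- train_config(base_lr = 1e-4, new_layer_lr_mult = 10,
                       plateau_patience = 2L, lr_decay = 0.5,
                       epochs = as.integer(epochs), batch_size = 8L,
                       seed = seed + 3L, monitor = "train")
  tr <- train_model(model, ds, sp, tcfg, verbose = verbose)
  ev <- evaluate_model(tr$model, ds, sp$test)
  rep <- metrics_report(ev$actual, ev$pred, 4L, scores = ev$probs)
  list(test_accuracy = ev$accuracy, report = rep, history = tr$history,
       model = tr$model, dataset = ds, split = sp)
}
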