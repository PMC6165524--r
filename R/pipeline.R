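#' Simulate paired training and test feature sets
#'
#' Convenience wrapper for desk-scale experiments: simulates independent
#' balanced training and test stream collections with the default activity
#' parameterisation, then extracts spectral feature vectors from both.
#'
#' @param seed Master seed; train and test derive distinct sub-seeds.
#' @param train_streams_per_class,test_streams_per_class Streams per class
#'   (each 10-s stream yields 5 analysis windows at the default windowing).
#' @param duration_s,fs Stream length and sampling rate.
#' @param S,L Feature selection counts (default 25/25 -> 100 features).
#' @param specs Activity specs (default [default_activity_specs()]).
#' @return List with `train` and `test` [feature_set()]s (provenance "OR").
#' @export
synthetic_feature_sets <- function(seed = 1L, train_streams_per_class = 10,
                                   test_streams_per_class = 4,
                                   duration_s = 10, fs = 50, S = 25, L = 25,
                                   specs = default_activity_specs()) {
  tr_streams <- make_dataset(specs, train_streams_per_class, duration_s, fs,
                             seed = derive_seed(seed, 1L))
  te_streams <- make_dataset(specs, test_streams_per_class, duration_s, fs,
                             seed = derive_seed(seed, 2L))
  list(train = build_feature_set(tr_streams, S = S, L = L),
       test = build_feature_set(te_streams, S = S, L = L))
}

#' Run one end-to-end synthetic experiment
#'
#' Simulate -> extract -> (optionally augment) -> train -> evaluate on a
#' held-out synthetic test set. Augmentation is applied to training rows
#' only.
#'
#' @param seed Master seed (simulation, shuffle and training init).
#' @param variant Training-set variant: `"OR"`, `"OR+LA1"` or
#'   `"OR+LA1+SH+LA2"`.
#' @param learning_rate Adam learning rate (default 0.003).
#' @param cfg Base [lstm_config()]; seed and learning rate are overridden.
#' @param aug An [augmentation_spec()].
#' @param ... Passed to [synthetic_feature_sets()].
#' @return List: `model`, `cm` (held-out confusion matrix), `metrics`
#'   ([precision_recall_f1()] report), `accuracy` (percent).
#' @export
run_har_experiment <- function(seed = 1L, variant = "OR",
                               learning_rate = 0.003, cfg = lstm_config(),
                               aug = augmentation_spec(), ...) {
  sets <- synthetic_feature_sets(seed = seed, ...)
  train <- switch(variant,
                  "OR" = sets$train,
                  "OR+LA1" = augment_or_la1(sets$train, aug),
                  "OR+LA1+SH+LA2" = augment_full(sets$train, aug),
                  stop_bad_arg("unknown variant: ", variant))
  run_cfg <- cfg
  run_cfg$seed <- as.integer(seed)
  run_cfg$learning_rate <- learning_rate
  model <- train_lstm(train, run_cfg)
  pred <- predict(model, sets$test)
  cm <- confusion_matrix(as.character(sets$test$labels), as.character(pred),
                         classes = model$classes)
  list(model = model, cm = cm, metrics = precision_recall_f1(cm),
       accuracy = accuracy_from_cm(cm))
}
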