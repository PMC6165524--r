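#' Bundled reference confusion matrices
#'
#' The package ships the confusion matrices published for a three-activity
#' (standing/sitting/walking) wrist-IMU benchmark: its own 100- and
#' 200-feature spectral datasets (unaugmented `OR`, `OR+LA1`, and the full
#' `OR+LA1+SH+LA2` ensemble for the 100-feature set) and a three-activity
#' extract of the public UCI HAR archive (`OR` and `OR+LA1`), each at five
#' learning rates (0.0002, 0.003, 0.006, 0.01, 0.015). They serve as fixed
#' inputs for validating the metric arithmetic: accuracy, precision, recall,
#' F1 and accuracy deltas between variants.
#'
#' @param dataset Optional dataset key (e.g. `"own200_OR"`, `"uci_OR+LA1"`);
#'   `NULL` returns all.
#' @return A nested list `ref[[dataset]][[learning_rate]]` of `har_cm`
#'   matrices (learning rates as character keys, e.g. `"0.003"`), or the one
#'   sub-list for `dataset`.
#' @export
reference_cms <- function(dataset = NULL) {
  path <- system.file("extdata", "reference_confusion_matrices.csv",
                      package = "harspect")
  df <- utils::read.csv(path, check.names = FALSE)
  out <- list()
  for (ds in unique(df$dataset)) {
    sub <- df[df$dataset == ds, ]
    out[[ds]] <- list()
    for (lr in unique(sub$learning_rate)) {
      rows <- sub[sub$learning_rate == lr, ]
      m <- as.matrix(rows[match(HAR_CLASSES, rows$true), HAR_CLASSES])
      out[[ds]][[format(lr, scientific = FALSE)]] <-
        as_confusion_matrix(m, classes = HAR_CLASSES)
    }
  }
  if (is.null(dataset)) out else {
    if (!dataset %in% names(out)) {
      stop_bad_arg("unknown reference dataset: ", dataset)
    }
    out[[dataset]]
  }
}
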