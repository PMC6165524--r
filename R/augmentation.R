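#' Augmentation parameters
#'
#' Group sizes for the two local-averaging passes and the seed for the
#' per-class shuffle between them.
#'
#' @param G1 Group size for the first local averaging (default 4).
#' @param G2 Group size for the second local averaging (default 2).
#' @param shuffle_seed Integer seed for the per-class row shuffle.
#' @return Object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(G1 = 4, G2 = 2, shuffle_seed = 1L) {
  if (G1 < 2 || G2 < 2) stop_bad_arg("group sizes G1 and G2 must be >= 2")
  structure(list(G1 = as.integer(G1), G2 = as.integer(G2),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "augmentation_spec")
}

#' Grouped local averaging within classes
#'
#' Within each class partition (rows taken in their current order),
#' consecutive non-overlapping groups of `G` rows are element-wise averaged
#' into one synthetic row carrying that class label; leftover rows (fewer
#' than `G`) contribute nothing. Only the averaged rows are returned.
#'
#' @param fs A [feature_set()].
#' @param G Group size (>= 2).
#' @return A `feature_set` of `sum(floor(n_class / G))` averaged rows, same
#'   provenance tag as the input.
#' @export
local_average <- function(fs, G) {
  stopifnot(inherits(fs, "feature_set"))
  if (G < 2) stop_bad_arg("G must be >= 2")
  out_rows <- list()
  out_labels <- character(0)
  for (cl in levels(fs$labels)) {
    idx <- which(fs$labels == cl)
    n_groups <- length(idx) %/% G
    if (n_groups == 0) next
    for (g in seq_len(n_groups)) {
      rows <- idx[((g - 1) * G + 1):(g * G)]
      out_rows[[length(out_rows) + 1L]] <- colMeans(fs$features[rows, , drop = FALSE])
      out_labels <- c(out_labels, cl)
    }
  }
  mat <- if (length(out_rows)) do.call(rbind, out_rows) else
    matrix(numeric(0), ncol = ncol(fs$features),
           dimnames = list(NULL, colnames(fs$features)))
  feature_set(mat, out_labels, provenance = fs$provenance, S = fs$S, L = fs$L)
}

#' Seeded per-class row shuffle
#'
#' Rows are permuted independently within each class: the positions occupied
#' by a class keep holding that class, but which row sits where is
#' randomised. The row multiset and all per-class counts are unchanged, and
#' the permutation is deterministic given `seed`.
#'
#' @param fs A [feature_set()].
#' @param seed Integer seed.
#' @return A `feature_set` with permuted rows, provenance suffixed `"+SH"`
#'   when the input is an `"OR+LA1"` set.
#' @export
shuffle_rows <- function(fs, seed = 1L) {
  stopifnot(inherits(fs, "feature_set"))
  perm <- seq_len(nrow(fs$features))
  with_local_seed(seed, {
    for (cl in levels(fs$labels)) {
      idx <- which(fs$labels == cl)
      if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
    }
  })
  prov <- if (identical(fs$provenance, "OR+LA1")) "OR+LA1+SH" else fs$provenance
  feature_set(fs$features[perm, , drop = FALSE], as.character(fs$labels)[perm],
              provenance = prov, S = fs$S, L = fs$L)
}

#' First-stage augmentation: original rows plus their local averages
#'
#' Appends the `G1`-group local averages of the original feature set at the
#' tail end of the original rows.
#'
#' @param fs A `feature_set` with provenance `"OR"`.
#' @param spec An [augmentation_spec()].
#' @return A `feature_set` with provenance `"OR+LA1"`.
#' @export
augment_or_la1 <- function(fs, spec = augmentation_spec()) {
  stopifnot(inherits(fs, "feature_set"), inherits(spec, "augmentation_spec"))
  if (!identical(fs$provenance, "OR")) {
    stop_bad_arg("augment_or_la1 expects an OR feature set, got ",
                 fs$provenance)
  }
  la <- local_average(fs, spec$G1)
  feature_set(rbind(fs$features, la$features),
              c(as.character(fs$labels), as.character(la$labels)),
              provenance = "OR+LA1", S = fs$S, L = fs$L)
}

#' Full augmentation ensemble: OR + LA1 + SH + LA2
#'
#' Computes the first-stage set, shuffles it per class with
#' `spec$shuffle_seed`, then appends the `G2`-group local averages of the
#' shuffled set.
#'
#' @param fs A `feature_set` with provenance `"OR"`.
#' @param spec An [augmentation_spec()].
#' @return A `feature_set` with provenance `"OR+LA1+SH+LA2"`.
#' @export
augment_full <- function(fs, spec = augmentation_spec()) {
  stopifnot(inherits(fs, "feature_set"), inherits(spec, "augmentation_spec"))
  la1 <- augment_or_la1(fs, spec)
  sh <- shuffle_rows(la1, spec$shuffle_seed)
  la2 <- local_average(sh, spec$G2)
  feature_set(rbind(sh$features, la2$features),
              c(as.character(sh$labels), as.character(la2$labels)),
              provenance = "OR+LA1+SH+LA2", S = fs$S, L = fs$L)
}

#' Closed-form augmented sizes from per-class counts
#'
#' Size bookkeeping for the ensemble, computable before running it:
#' `|OR+LA1| = n + sum(floor(n_c / G1))` and
#' `|OR+LA1+SH+LA2| = |OR+LA1| + sum(floor(n'_c / G2))`, where `n'_c` are
#' the per-class counts after LA1.
#'
#' @param counts Integer vector of per-class row counts.
#' @param G1,G2 Group sizes.
#' @return Named list with `or`, `or_la1`, `full` total sizes and the
#'   per-class count vectors `counts_la1`, `counts_full`.
#' @export
augmented_sizes <- function(counts, G1 = 4, G2 = 2) {
  counts <- as.integer(counts)
  c1 <- counts + counts %/% G1
  c2 <- c1 + c1 %/% G2
  list(or = sum(counts), or_la1 = sum(c1), full = sum(c2),
       counts_la1 = c1, counts_full = c2)
}
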