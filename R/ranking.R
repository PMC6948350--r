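#' Rank features by coefficient magnitude
#'
#' Extracts biomarker importances from a fitted coefficient tensor. The
#' global importance of feature `i` is the l2 norm of row `i` of the
#' unfolded coefficient matrix (all tasks, all timepoints); per-timepoint
#' importances use the row norm of each timepoint's coefficient slice.
#' These are the quantities the row-sparsity penalty acts on, so features
#' it zeroes out rank at the bottom. Ties break toward the smaller feature
#' index.
#'
#' @param model a fitted `jrc_model`.
#' @param use which coefficient columns enter the norms: all, only the
#'   regression block, or only the classification block.
#' @return object of class `jrc_ranking`: `global` data frame
#'   (rank, feature, modality, score), `per_timepoint` score matrix
#'   (`d x T`), `per_modality` list of data frames, and the modality map.
#' @export
rank_features <- function(model,
                          use = c("all", "regression", "classification")) {
  use <- match.arg(use)
  stopifnot(inherits(model, "jrc_model"))
  cc <- model$c_r + model$c_c
  keep <- switch(use,
    all = seq_len(cc),
    regression = seq_len(model$c_r),
    classification = model$c_r + seq_len(model$c_c))
  if (length(keep) == 0L) stop(sprintf("model has no %s columns", use))
  V <- model$V[, keep, , drop = FALSE]
  d <- dim(V)[1]; TT <- dim(V)[3]
  per_tp <- sapply(seq_len(TT), function(t)
    sqrt(rowSums(matrix(V[, , t], d)^2)))
  per_tp <- matrix(per_tp, d, TT,
                   dimnames = list(model$feature_names,
                                   model$timepoint_names))
  global <- sqrt(rowSums(unfold(V)^2))
  modality <- character(d)
  for (i in seq_len(nrow(model$modality_map)))
    modality[model$modality_map$first[i]:model$modality_map$last[i]] <-
      model$modality_map$name[i]
  ord <- order(-global, seq_len(d))
  tab <- data.frame(rank = seq_len(d), feature = model$feature_names[ord],
                    feature_index = ord, modality = modality[ord],
                    score = global[ord], row.names = NULL)
  per_mod <- lapply(split(seq_len(d), factor(modality, unique(modality))),
                    function(idx) {
                      o <- idx[order(-global[idx], idx)]
                      data.frame(rank = seq_along(o),
                                 feature = model$feature_names[o],
                                 feature_index = o, score = global[o],
                                 row.names = NULL)
                    })
  structure(list(global = tab, per_timepoint = per_tp,
                 per_modality = per_mod, modality = modality,
                 modality_map = model$modality_map,
                 feature_names = model$feature_names), class = "jrc_ranking")
}

#' @export
print.jrc_ranking <- function(x, ...) {
  cat("Feature ranking (l2 row norms of the unfolded coefficients)\n")
  print(utils::head(x$global, 10), row.names = FALSE)
  invisible(x)
}

#' Top-k features from a ranking
#'
#' Returns the `k` highest-scoring features, optionally restricted to one
#' modality and/or re-scored within one timepoint. Requesting more features
#' than available returns all of them with a warning.
#'
#' @param ranked a [rank_features()] result.
#' @param k number of features requested.
#' @param modality optional modality name.
#' @param timepoint optional timepoint index or name; scores then come from
#'   that timepoint's coefficient slice.
#' @return data frame (rank, feature, feature_index, modality, score).
#' @export
top_k <- function(ranked, k, modality = NULL, timepoint = NULL) {
  stopifnot(inherits(ranked, "jrc_ranking"), k >= 1)
  d <- length(ranked$feature_names)
  idx <- seq_len(d)
  if (!is.null(modality)) {
    if (!modality %in% ranked$modality_map$name)
      stop(sprintf("unknown modality '%s'", modality))
    idx <- idx[ranked$modality == modality]
  }
  score <- if (is.null(timepoint)) {
    g <- numeric(d); g[ranked$global$feature_index] <- ranked$global$score
    g
  } else {
    if (is.character(timepoint))
      timepoint <- match(timepoint, colnames(ranked$per_timepoint))
    ranked$per_timepoint[, timepoint]
  }
  if (k > length(idx)) {
    warning(sprintf("k=%d exceeds the %d available features; returning all",
                    k, length(idx)))
    k <- length(idx)
  }
  o <- idx[order(-score[idx], idx)][seq_len(k)]
  data.frame(rank = seq_len(k), feature = ranked$feature_names[o],
             feature_index = o, modality = ranked$modality[o],
             score = score[o], row.names = NULL)
}

#' Longitudinal consistency of the top-k features
#'
#' Quantifies how stable the leading biomarkers are across visits: for every
#' pair of timepoints the Jaccard-style overlap
#' `|top-k(t1) intersect top-k(t2)| / k`, plus the count of features ranked
#' in the top-k at every timepoint. Row-sparse fits (large `gamma1`) share
#' their support across timepoints by construction and score high here.
#'
#' @param model a fitted `jrc_model` (needs `T >= 2`).
#' @param k top-list size.
#' @param use passed to [rank_features()].
#' @return list: `pairwise` (`T x T` overlap matrix), `mean_overlap`
#'   (off-diagonal mean), `always_top` (count), `top_sets` (list of index
#'   vectors).
#' @export
longitudinal_consistency <- function(model, k, use = "all") {
  ranked <- rank_features(model, use = use)
  TT <- ncol(ranked$per_timepoint)
  if (TT < 2) stop("need at least two timepoints")
  d <- nrow(ranked$per_timepoint)
  k <- min(k, d)
  tops <- lapply(seq_len(TT), function(t) {
    sc <- ranked$per_timepoint[, t]
    order(-sc, seq_len(d))[seq_len(k)]
  })
  P <- diag(1, TT)
  for (a in seq_len(TT - 1)) for (b in (a + 1):TT)
    P[a, b] <- P[b, a] <- length(intersect(tops[[a]], tops[[b]])) / k
  dimnames(P) <- list(colnames(ranked$per_timepoint),
                      colnames(ranked$per_timepoint))
  list(pairwise = P,
       mean_overlap = mean(P[upper.tri(P)]),
       always_top = length(Reduce(intersect, tops)),
       top_sets = tops, k = k)
}
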