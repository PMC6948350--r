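#' Predict cognitive scores and diagnoses from a fitted model
#'
#' Applies the stored standardization to new features and returns, per
#' timepoint, either the multivariate-regression predictions
#' `Xt %*% W_t` (`type = "scores"`) or the one-vs-all SVM decision
#' `argmax_k (x p_kt + b_kt)` (`type = "diagnosis"`). The per-class SVM
#' scores are not calibrated against one another, so the argmax rule is a
#' heuristic decision; exact ties resolve to the smallest class index.
#'
#' @param object a fitted `jrc_model`.
#' @param X numeric array `n x d x T` with the training feature layout.
#' @param type `"scores"`, `"diagnosis"`, or `"decision"` (the raw
#'   `n x c_c x T` SVM scores).
#' @param ... unused.
#' @return `"scores"`: `n x c_r x T` array; `"diagnosis"`: `n x T` integer
#'   matrix; `"decision"`: `n x c_c x T` array.
#' @export
predict.jrc_model <- function(object, X,
                              type = c("scores", "diagnosis", "decision"),
                              ...) {
  type <- match.arg(type)
  if (!is.array(X) || length(dim(X)) != 3L)
    stop("X must be an n x d x T array")
  d <- dim(object$V)[1]; TT <- dim(object$V)[3]
  if (dim(X)[2] != d || dim(X)[3] != TT)
    stop(sprintf("X must be n x %d x %d to match the model", d, TT))
  n <- dim(X)[1]
  Xs <- scaled_design(X, object$scaler)
  cc <- object$c_r + object$c_c
  if (type == "scores") {
    out <- array(0, c(n, object$c_r, TT))
    for (t in seq_len(TT)) {
      pred_t <- Xs[[t]] %*% object$V[, seq_len(object$c_r), t]
      if (!is.null(object$scaler$y_center))
        pred_t <- sweep(pred_t, 2, object$scaler$y_center[, t], "+")
      out[, , t] <- pred_t
    }
    return(out)
  }
  if (object$c_c == 0) stop("model has no classification task")
  S <- array(0, c(n, object$c_c, TT))
  for (t in seq_len(TT))
    S[, , t] <- Xs[[t]] %*%
      object$V[, object$c_r + seq_len(object$c_c), t] +
      rep(object$b[, t], each = n)
  if (type == "decision") return(S)
  lab <- matrix(0L, n, TT)
  for (t in seq_len(TT))
    lab[, t] <- max.col(matrix(S[, , t], n, object$c_c),
                        ties.method = "first")
  lab
}

#' Root mean-squared error
#'
#' @param truth,pred numeric vectors of equal, positive length.
#' @return `sqrt(mean((truth - pred)^2))`.
#' @export
rmse <- function(truth, pred) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (length(truth) == 0L || length(truth) != length(pred))
    stop("truth and pred must be nonempty and equal-length")
  sqrt(mean((truth - pred)^2))
}

#' Multi-class F1 scores
#'
#' Per-class one-vs-rest F1 (`2PR/(P+R)`, 0 when `P + R = 0`) and an overall
#' summary. The overall score defaults to the support-weighted mean of the
#' per-class values; macro (unweighted mean) and micro (pooled confusion
#' counts, equal to accuracy for single-label problems) variants are
#' available.
#'
#' @param truth,pred integer labels in `1..c_c` (any shape; flattened).
#' @param c_c number of classes.
#' @param average `"weighted"`, `"macro"` or `"micro"` for the overall score.
#' @return list with `per_class` (length `c_c`) and `overall` (scalar).
#' @export
multiclass_f1 <- function(truth, pred, c_c,
                          average = c("weighted", "macro", "micro")) {
  average <- match.arg(average)
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("length mismatch")
  if (any(truth < 1 | truth > c_c) || any(pred < 1 | pred > c_c))
    stop(sprintf("labels must lie in 1..%d", c_c))
  per <- numeric(c_c); support <- numeric(c_c)
  tp_all <- 0
  for (k in seq_len(c_c)) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    per[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    support[k] <- sum(truth == k)
    tp_all <- tp_all + tp
  }
  overall <- switch(average,
    weighted = if (sum(support) > 0) sum(per * support) / sum(support) else 0,
    macro = mean(per),
    micro = tp_all / length(truth))
  list(per_class = per, overall = overall)
}

# Patient-level fold assignment: a seeded shuffle cut into `folds` nearly
# equal parts; every timepoint of a patient shares its fold.
make_folds <- function(n, folds, seed) {
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of <- integer(n)
  start <- cumsum(c(0L, sizes))
  for (f in seq_len(folds)) fold_of[perm[(start[f] + 1L):start[f + 1L]]] <- f
  fold_of
}

subset_patients <- function(data, idx) {
  jrc_dataset(data$X[idx, , , drop = FALSE],
              data$Y_r[idx, , , drop = FALSE],
              if (data$c_c > 0) data$labels[idx, , drop = FALSE] else NULL,
              data$modality_map, c_c = data$c_c,
              feature_names = data$feature_names,
              timepoint_names = data$timepoint_names)
}

#' Repeated cross-validated evaluation
#'
#' Runs `repeats` independent shuffles of the patients; each shuffle is cut
#' into `folds` patient-level folds (all visits of a patient stay on one
#' side of every split). The model is fitted on each training part and
#' evaluated on the held-out part: RMSE per regression target per timepoint
#' (on the original target scale) and one-vs-rest F1 per class, averaged
#' over timepoints. Means and standard deviations are reported both across
#' all `repeats * folds` cells and across per-repeat means.
#'
#' @param data a [jrc_dataset()].
#' @param control a [jrc_control()] used for every fit.
#' @param repeats number of independent shuffles.
#' @param folds folds per shuffle (`>= 2`).
#' @param seed integer; drives all shuffles (fold tables are returned so a
#'   run can be reproduced exactly).
#' @param fitter fitting function `(data, control, seed) -> jrc_model`;
#'   replaceable by a stub for protocol tests or by a baseline adapter.
#' @return list of class `jrc_cv`: `n_fits`, `rmse` / `f1` summary tables,
#'   `null_rmse` (training-mean predictor, pooled), `fold_assignments`
#'   (`n x repeats` matrix) and the control used.
#' @export
cross_validate <- function(data, control = jrc_control(), repeats = 10L,
                           folds = 5L, seed = 1L, fitter = jrc_fit) {
  stopifnot(inherits(data, "jrc_data"))
  n <- dim(data$X)[1]
  if (folds < 2) stop("folds must be at least 2")
  if (n < folds) stop("more folds than patients")
  c_r <- dim(data$Y_r)[2]; c_c <- data$c_c; TT <- dim(data$X)[3]
  cell_rmse <- NULL; cell_null <- NULL; cell_f1 <- NULL
  fold_assign <- matrix(0L, n, repeats)
  n_fits <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- make_folds(n, folds, seed = seed + 1000L * (rep_i - 1L))
    fold_assign[, rep_i] <- fold_of
    for (f in seq_len(folds)) {
      test <- which(fold_of == f); train <- which(fold_of != f)
      dtrain <- subset_patients(data, train)
      dtest <- subset_patients(data, test)
      if (c_c > 0) {
        missing_cls <- setdiff(seq_len(c_c), unique(as.vector(dtrain$labels)))
        if (length(missing_cls))
          warning(sprintf(
            "repeat %d fold %d: class(es) %s absent from training data",
            rep_i, f, paste(missing_cls, collapse = ",")))
      }
      model <- fitter(dtrain, control, seed = seed + 7L * n_fits)
      n_fits <- n_fits + 1L
      if (c_r > 0) {
        pred <- predict(model, dtest$X, type = "scores")
        rm_tt <- matrix(0, c_r, TT)
        null_tt <- matrix(0, c_r, TT)
        for (t in seq_len(TT)) for (j in seq_len(c_r)) {
          rm_tt[j, t] <- rmse(dtest$Y_r[, j, t], pred[, j, t])
          null_tt[j, t] <- rmse(dtest$Y_r[, j, t],
                                rep(mean(dtrain$Y_r[, j, t]),
                                    length(test)))
        }
        cell_rmse <- rbind(cell_rmse, c(rep = rep_i, fold = f,
                                        pooled = mean(rm_tt),
                                        as.vector(rm_tt)))
        cell_null <- c(cell_null, mean(null_tt))
      }
      if (c_c > 0) {
        lab <- predict(model, dtest$X, type = "diagnosis")
        f1_tt <- matrix(0, c_c + 1L, TT)
        for (t in seq_len(TT)) {
          sc <- multiclass_f1(dtest$labels[, t], lab[, t], c_c)
          f1_tt[, t] <- c(sc$per_class, sc$overall)
        }
        cell_f1 <- rbind(cell_f1, c(rep = rep_i, fold = f,
                                    rowMeans(f1_tt)))
      }
    }
  }
  summarize <- function(cells, names_out) {
    if (is.null(cells)) return(NULL)
    vals <- cells[, -(1:2), drop = FALSE]
    colnames(vals) <- names_out
    by_rep <- rowsum(vals, cells[, "rep"]) / folds
    data.frame(metric = names_out,
               mean = colMeans(vals),
               sd_cells = apply(vals, 2, stats::sd),
               sd_repeats = apply(by_rep, 2, stats::sd),
               row.names = NULL)
  }
  target_names <- dimnames(data$Y_r)[[2]]
  if (is.null(target_names) && c_r > 0)
    target_names <- sprintf("score%d", seq_len(c_r))
  rmse_names <- if (c_r > 0)
    c("pooled", as.vector(outer(target_names, data$timepoint_names,
                                paste, sep = "@")))
  f1_names <- if (c_c > 0) c(sprintf("F1_class%d", seq_len(c_c)), "F1_all")
  structure(list(
    n_fits = n_fits,
    rmse = summarize(cell_rmse, rmse_names),
    f1 = summarize(cell_f1, f1_names),
    null_rmse = if (c_r > 0) mean(cell_null),
    fold_assignments = fold_assign,
    repeats = repeats, folds = folds, seed = seed, control = control
  ), class = "jrc_cv")
}

#' @export
print.jrc_cv <- function(x, ...) {
  cat(sprintf("Cross-validation: %d repeats x %d folds = %d fits\n",
              x$repeats, x$folds, x$n_fits))
  if (!is.null(x$rmse)) {
    cat("RMSE (original scale):\n")
    print(utils::head(x$rmse, 4), row.names = FALSE)
  }
  if (!is.null(x$f1)) {
    cat("F1 (averaged over timepoints):\n")
    print(x$f1, row.names = FALSE)
  }
  invisible(x)
}

#' Default penalty-weight grid
#'
#' Powers of ten from `1e-5` to `1e5` (11 values) for each of the three
#' penalty weights.
#' @return named list of three numeric vectors.
#' @export
default_gamma_grid <- function() {
  g <- 10^seq(-5, 5)
  list(gamma1 = g, gamma2 = g, gamma3 = g)
}

#' Hyperparameter grid search by repeated cross-validation
#'
#' Evaluates every combination of the supplied penalty weights with
#' [cross_validate()] and returns the combination with the best average
#' multitask score, operationalized as the mean of the overall F1 and
#' `1 - RMSE_pooled / RMSE_null` (the null model predicts the training
#' mean); absent tasks contribute nothing. Ties keep the earlier grid row.
#'
#' @param data a [jrc_dataset()].
#' @param grid named list with `gamma1`, `gamma2`, `gamma3` vectors
#'   (default [default_gamma_grid()]).
#' @param control base [jrc_control()]; its gammas are overridden per cell.
#' @param repeats,folds,seed,fitter passed to [cross_validate()].
#' @return list: `best` (a `jrc_control`), `table` (one row per combination
#'   with the score and summary metrics).
#' @export
grid_search <- function(data, grid = default_gamma_grid(),
                        control = jrc_control(), repeats = 1L, folds = 5L,
                        seed = 1L, fitter = jrc_fit) {
  cells <- expand.grid(gamma1 = grid$gamma1, gamma2 = grid$gamma2,
                       gamma3 = grid$gamma3, KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) == 0L) stop("empty grid")
  score <- numeric(nrow(cells)); f1v <- rep(NA_real_, nrow(cells))
  rmsev <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ctl <- control
    ctl$gamma1 <- cells$gamma1[i]; ctl$gamma2 <- cells$gamma2[i]
    ctl$gamma3 <- cells$gamma3[i]
    cv <- cross_validate(data, ctl, repeats = repeats, folds = folds,
                         seed = seed, fitter = fitter)
    parts <- numeric(0)
    if (!is.null(cv$f1)) {
      f1v[i] <- cv$f1$mean[cv$f1$metric == "F1_all"]
      parts <- c(parts, f1v[i])
    }
    if (!is.null(cv$rmse)) {
      rmsev[i] <- cv$rmse$mean[cv$rmse$metric == "pooled"]
      parts <- c(parts, 1 - rmsev[i] / cv$null_rmse)
    }
    score[i] <- mean(parts)
  }
  best_i <- which.max(score)  # first max wins ties
  best <- control
  best$gamma1 <- cells$gamma1[best_i]; best$gamma2 <- cells$gamma2[best_i]
  best$gamma3 <- cells$gamma3[best_i]
  list(best = best,
       table = cbind(cells, score = score, F1_all = f1v,
                     rmse_pooled = rmsev))
}
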