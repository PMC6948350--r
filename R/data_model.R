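#' Longitudinal multimodal dataset
#'
#' Bundles the feature tensor, regression targets and diagnostic labels of a
#' longitudinal study into a validated container. Features are organised as
#' an `n x d x T` array (patients x features x timepoints) whose feature axis
#' is partitioned into `K` contiguous, named modality blocks (e.g. MRI-derived
#' regional measures followed by SNP genotypes). Regression targets (e.g.
#' cognitive test scores) form an `n x c_r x T` array and diagnoses an
#' `n x T` integer matrix with values in `1..c_c`.
#'
#' Completeness is a precondition: rows with missing values are rejected, not
#' imputed, mirroring a complete-case cohort. All timepoint slices must share
#' the same patients and features.
#'
#' @param X numeric array, `n x d x T`.
#' @param Y_r numeric array, `n x c_r x T` (use `c_r = 0` for a pure
#'   classification problem).
#' @param labels integer matrix `n x T` with values in `1..c_c`, or `NULL`
#'   for a pure regression problem.
#' @param modality_map data frame with columns `name`, `first`, `last`
#'   giving 1-based inclusive feature ranges; blocks must be contiguous,
#'   disjoint and tile `1..d` in order.
#' @param c_c number of diagnostic classes; defaults to `max(labels)`
#'   (0 when `labels` is `NULL`).
#' @param feature_names,timepoint_names optional character vectors
#'   (length `d` / `T`).
#' @return an object of class `jrc_data`.
#' @seealso [load_dataset()], [make_synthetic()]
#' @export
jrc_dataset <- function(X, Y_r, labels = NULL, modality_map,
                        c_c = if (is.null(labels)) 0L else max(labels),
                        feature_names = NULL, timepoint_names = NULL) {
  if (!is.array(X) || length(dim(X)) != 3L)
    stop("X must be an n x d x T array")
  n <- dim(X)[1]; d <- dim(X)[2]; TT <- dim(X)[3]
  if (is.null(Y_r)) Y_r <- array(0, c(n, 0L, TT))
  if (length(dim(Y_r)) != 3L || dim(Y_r)[1] != n || dim(Y_r)[3] != TT)
    stop("Y_r must be an n x c_r x T array matching X")
  if (anyNA(X) || any(!is.finite(X)))
    stop("missing values in features (complete cases required)")
  if (length(Y_r) && (anyNA(Y_r) || any(!is.finite(Y_r))))
    stop("missing values in regression targets")
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    if (nrow(labels) != n || ncol(labels) != TT)
      stop("labels must be an n x T matrix")
    if (anyNA(labels)) stop("missing values in labels")
    if (any(labels != round(labels)) || any(labels < 1) || any(labels > c_c))
      stop(sprintf("labels must be integers in 1..%d", c_c))
    storage.mode(labels) <- "integer"
  } else if (c_c > 0) {
    stop("c_c > 0 requires labels")
  }
  modality_map <- validate_modality_map(modality_map, d)
  if (is.null(feature_names)) {
    feature_names <- dimnames(X)[[2]]
    if (is.null(feature_names)) feature_names <- sprintf("feat%d", seq_len(d))
  }
  if (length(feature_names) != d) stop("feature_names must have length d")
  if (is.null(timepoint_names)) {
    timepoint_names <- dimnames(X)[[3]]
    if (is.null(timepoint_names)) timepoint_names <- sprintf("t%d", seq_len(TT))
  }
  if (length(timepoint_names) != TT) stop("timepoint_names must have length T")
  structure(list(
    X = X, Y_r = Y_r, labels = labels, modality_map = modality_map,
    c_c = as.integer(c_c), feature_names = as.character(feature_names),
    timepoint_names = as.character(timepoint_names)
  ), class = "jrc_data")
}

# Checks that modality blocks are contiguous, disjoint and tile 1..d.
validate_modality_map <- function(map, d) {
  map <- as.data.frame(map)
  if (!all(c("name", "first", "last") %in% names(map)))
    stop("modality_map needs columns name, first, last")
  map$first <- as.integer(map$first); map$last <- as.integer(map$last)
  map <- map[order(map$first), , drop = FALSE]
  expected_first <- c(1L, utils::head(map$last, -1) + 1L)
  if (nrow(map) == 0L || any(map$first != expected_first) ||
      map$last[nrow(map)] != d || any(map$last < map$first))
    stop("modality blocks must tile features 1..d contiguously")
  if (anyDuplicated(map$name)) stop("duplicate modality names")
  rownames(map) <- NULL
  map[, c("name", "first", "last")]
}

#' @export
print.jrc_data <- function(x, ...) {
  dm <- dim(x$X)
  cat(sprintf("Longitudinal dataset: %d patients x %d features x %d timepoints\n",
              dm[1], dm[2], dm[3]))
  cat(sprintf("  regression targets: %d; classes: %d\n", dim(x$Y_r)[2], x$c_c))
  cat(sprintf("  modalities: %s\n",
              paste(sprintf("%s[%d:%d]", x$modality_map$name,
                            x$modality_map$first, x$modality_map$last),
                    collapse = ", ")))
  invisible(x)
}

#' Load a longitudinal dataset from delimited tables
#'
#' Reads one feature table and one target table per timepoint plus a modality
#' configuration. Every table has a header row and a first column of patient
#' IDs; the tables must agree on patient order and the feature tables on
#' column order. Target tables hold the regression score columns followed by
#' an integer diagnosis column (`label_col`); set `label_col = NULL` when the
#' study has no classification task.
#'
#' @param feature_files character vector of paths, one per timepoint, in
#'   chronological order.
#' @param target_files character vector of paths, same length and order.
#' @param modality_file path to a JSON or YAML file with a top-level `blocks`
#'   list of `{name, first_feature, last_feature}` entries (1-based,
#'   inclusive).
#' @param label_col name of the diagnosis column in the target tables.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return a [jrc_dataset()] object.
#' @export
load_dataset <- function(feature_files, target_files, modality_file,
                         label_col = "diagnosis", sep = ",") {
  if (length(feature_files) != length(target_files))
    stop("need one target table per feature table")
  TT <- length(feature_files)
  read1 <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop(sprintf("no data columns in %s", path))
    ids <- as.character(tab[[1]])
    vals <- tab[, -1, drop = FALSE]
    list(ids = ids, vals = vals, path = path)
  }
  feats <- lapply(feature_files, read1)
  targs <- lapply(target_files, read1)
  ids <- feats[[1]]$ids
  fnames <- colnames(feats[[1]]$vals)
  for (t in seq_len(TT)) {
    if (!identical(feats[[t]]$ids, ids) || !identical(targs[[t]]$ids, ids))
      stop(sprintf("patient IDs differ across tables (timepoint %d)", t))
    if (!identical(colnames(feats[[t]]$vals), fnames))
      stop(sprintf("feature columns differ across timepoints (timepoint %d)", t))
  }
  n <- length(ids); d <- length(fnames)
  X <- array(NA_real_, c(n, d, TT))
  for (t in seq_len(TT)) {
    m <- as.matrix(feats[[t]]$vals)
    if (!is.numeric(m) || anyNA(m))
      stop(sprintf("missing values or non-numeric entries in %s",
                   feats[[t]]$path))
    X[, , t] <- m
  }
  tnames <- colnames(targs[[1]]$vals)
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% tnames)
      stop(sprintf("label column '%s' not found in target tables", label_col))
    labels <- matrix(NA_integer_, n, TT)
  }
  score_cols <- setdiff(tnames, label_col)
  Y_r <- array(NA_real_, c(n, length(score_cols), TT))
  for (t in seq_len(TT)) {
    if (!identical(colnames(targs[[t]]$vals), tnames))
      stop(sprintf("target columns differ across timepoints (timepoint %d)", t))
    if (length(score_cols)) {
      m <- as.matrix(targs[[t]]$vals[, score_cols, drop = FALSE])
      if (!is.numeric(m) || anyNA(m))
        stop(sprintf("missing values in %s", targs[[t]]$path))
      Y_r[, , t] <- m
    }
    if (!is.null(labels)) labels[, t] <- as.integer(targs[[t]]$vals[[label_col]])
  }
  map <- read_modality_map(modality_file)
  data <- jrc_dataset(X, Y_r, labels, map, feature_names = fnames,
                      timepoint_names = sprintf("t%d", seq_len(TT)))
  dimnames(data$Y_r) <- list(NULL, score_cols, data$timepoint_names)
  data
}

read_modality_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  blocks <- cfg$blocks
  if (is.null(blocks)) stop("modality config needs a 'blocks' list")
  if (is.data.frame(blocks)) blocks <- split(blocks, seq_len(nrow(blocks)))
  data.frame(
    name = vapply(blocks, function(b) as.character(b$name), ""),
    first = vapply(blocks, function(b) as.integer(b$first_feature), 1L),
    last = vapply(blocks, function(b) as.integer(b$last_feature), 1L),
    stringsAsFactors = FALSE
  )
}

#' Write a dataset to delimited tables
#'
#' Inverse of [load_dataset()]: writes per-timepoint `features_t<k>.csv` and
#' `targets_t<k>.csv` tables plus `modalities.json` into `dir`. Numeric
#' values are written with 17 significant digits so a load/write round trip
#' is exact to full double precision.
#'
#' @param data a `jrc_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of files written.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "jrc_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(data$X)[1]; TT <- dim(data$X)[3]
  ids <- sprintf("P%04d", seq_len(n))
  score_names <- dimnames(data$Y_r)[[2]]
  if (is.null(score_names) && dim(data$Y_r)[2] > 0)
    score_names <- sprintf("score%d", seq_len(dim(data$Y_r)[2]))
  files <- list(features = character(TT), targets = character(TT))
  for (t in seq_len(TT)) {
    fp <- file.path(dir, sprintf("features_t%d.csv", t))
    tab <- data.frame(patient_id = ids,
                      apply(data$X[, , t, drop = FALSE], 2, format_g17),
                      check.names = FALSE)
    colnames(tab) <- c("patient_id", data$feature_names)
    utils::write.table(tab, fp, sep = ",", row.names = FALSE, quote = FALSE)
    files$features[t] <- fp
    tp <- file.path(dir, sprintf("targets_t%d.csv", t))
    tt <- data.frame(patient_id = ids, check.names = FALSE)
    for (j in seq_along(score_names))
      tt[[score_names[j]]] <- format_g17(data$Y_r[, j, t])
    if (data$c_c > 0) tt$diagnosis <- data$labels[, t]
    utils::write.table(tt, tp, sep = ",", row.names = FALSE, quote = FALSE)
    files$targets[t] <- tp
  }
  mp <- file.path(dir, "modalities.json")
  blocks <- lapply(seq_len(nrow(data$modality_map)), function(i) list(
    name = data$modality_map$name[i],
    first_feature = data$modality_map$first[i],
    last_feature = data$modality_map$last[i]
  ))
  jsonlite::write_json(list(blocks = blocks), mp, auto_unbox = TRUE)
  files$modalities <- mp
  invisible(files)
}

format_g17 <- function(x) sprintf("%.17g", as.numeric(x))

#' One-vs-all label encoding
#'
#' Expands integer class labels into the `{-1, +1}` coding used by the
#' per-class hinge losses: entry `(i, k, t)` is `+1` iff patient `i` carries
#' class `k` at timepoint `t`, else `-1`.
#'
#' @param labels integer matrix `n x T` (a vector is treated as `T = 1`).
#' @param c_c number of classes.
#' @return numeric array `n x c_c x T` with entries in `{-1, +1}`.
#' @export
encode_one_vs_all <- function(labels, c_c) {
  labels <- as.matrix(labels)
  n <- nrow(labels); TT <- ncol(labels)
  if (c_c == 0L) return(array(0, c(n, 0L, TT)))
  if (anyNA(labels) || any(labels != round(labels)) ||
      any(labels < 1) || any(labels > c_c))
    stop(sprintf("labels must be integers in 1..%d", c_c))
  Yc <- array(-1, c(n, c_c, TT))
  for (t in seq_len(TT))
    Yc[cbind(seq_len(n), labels[, t], t)] <- 1
  Yc
}

#' Unfold and refold the coefficient tensor
#'
#' `unfold()` rearranges a `d x c x T` tensor into the `d x (c*T)` matrix on
#' which the row-sparsity, modality-group and trace-norm penalties act:
#' timepoint slices are concatenated column-wise in chronological order, so
#' row `i` collects feature `i`'s coefficients across every task and visit.
#' `refold()` inverts the operation given the per-timepoint column count.
#'
#' @param V numeric array `d x c x T`.
#' @param M numeric matrix `d x (c*T)`.
#' @param c number of columns per timepoint slice.
#' @return `unfold()`: a `d x (c*T)` matrix; `refold()`: a `d x c x T` array.
#' @export
unfold <- function(V) {
  if (!is.array(V) || length(dim(V)) != 3L)
    stop("V must be a d x c x T array")
  d <- dim(V)[1]
  matrix(V, d, dim(V)[2] * dim(V)[3])
}

#' @rdname unfold
#' @export
refold <- function(M, c) {
  M <- as.matrix(M)
  if (ncol(M) %% c != 0) stop("column count is not a multiple of c")
  array(M, c(nrow(M), c, ncol(M) %/% c))
}

#' Serialize / restore a fitted model
#'
#' Writes the coefficient tensor, SVM biases and standardization parameters
#' as delimited text with 17 significant digits (exact double round trip)
#' next to a JSON metadata sidecar (dimensions, column partition, modality
#' map, hyperparameters). `read_model()` restores the `jrc_model`.
#'
#' @param model a fitted `jrc_model`.
#' @param dir directory to write into (created if needed).
#' @param drop_history logical; the per-iteration history is not serialized.
#' @return `write_model()` invisibly returns `dir`; `read_model()` returns
#'   the restored model.
#' @export
write_model <- function(model, dir, drop_history = TRUE) {
  stopifnot(inherits(model, "jrc_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) utils::write.table(
    matrix(format_g17(m), nrow(m), ncol(m)), file.path(dir, f),
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  wr(unfold(model$V), "V.csv")
  if (length(model$b)) wr(model$b, "b.csv")
  if (!is.null(model$scaler)) {
    wr(model$scaler$center, "center.csv")
    wr(model$scaler$scale, "scale.csv")
    if (!is.null(model$scaler$y_center))
      wr(model$scaler$y_center, "y_center.csv")
  }
  meta <- list(
    package = "longjrc", format = 1L,
    d = dim(model$V)[1], c_r = model$c_r, c_c = model$c_c,
    T = dim(model$V)[3],
    feature_names = model$feature_names,
    timepoint_names = model$timepoint_names,
    modality_map = model$modality_map,
    control = model$control[c("gamma1", "gamma2", "gamma3", "mu0", "rho",
                              "max_iter", "gap_tol", "mu_max", "standardize",
                              "init")],
    standardized = !is.null(model$scaler)
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  d <- meta$d; cc <- meta$c_c; cr <- meta$c_r; TT <- meta$T
  Vu <- rd("V.csv"); dimnames(Vu) <- NULL
  b <- if (cc > 0) {
    bm <- rd("b.csv"); dimnames(bm) <- NULL; matrix(bm, cc, TT)
  } else matrix(0, 0, TT)
  scaler <- NULL
  if (isTRUE(meta$standardized)) {
    ce <- rd("center.csv"); sc <- rd("scale.csv")
    dimnames(ce) <- dimnames(sc) <- NULL
    scaler <- list(center = matrix(ce, d, TT), scale = matrix(sc, d, TT))
    if (file.exists(file.path(dir, "y_center.csv"))) {
      yc <- rd("y_center.csv"); dimnames(yc) <- NULL
      scaler$y_center <- matrix(yc, cr, TT)
    }
  }
  ctl <- do.call(jrc_control, meta$control)
  new_jrc_model(refold(Vu, cr + cc), b, cr, cc,
                as.data.frame(meta$modality_map), meta$feature_names,
                meta$timepoint_names, scaler, ctl)
}

new_jrc_model <- function(V, b, c_r, c_c, modality_map, feature_names,
                          timepoint_names, scaler, control,
                          history = NULL) {
  structure(list(
    V = V, b = b, c_r = as.integer(c_r), c_c = as.integer(c_c),
    modality_map = modality_map, feature_names = feature_names,
    timepoint_names = timepoint_names, scaler = scaler,
    control = control, history = history
  ), class = "jrc_model")
}

#' @export
print.jrc_model <- function(x, ...) {
  dm <- dim(x$V)
  cat(sprintf("Joint regression-classification model: d=%d, c_r=%d, c_c=%d, T=%d\n",
              dm[1], x$c_r, x$c_c, dm[3]))
  nz <- sum(sqrt(rowSums(unfold(x$V)^2)) > 1e-8)
  cat(sprintf("  nonzero coefficient rows: %d / %d\n", nz, dm[1]))
  if (!is.null(x$history))
    cat(sprintf("  fitted in %d iterations (final max gap %.3g)\n",
                nrow(x$history), x$history$gap_max[nrow(x$history)]))
  invisible(x)
}

# Column indices of timepoint t's slice within the unfolded d x (c*T) matrix.
slice_cols <- function(t, c) ((t - 1L) * c + 1L):(t * c)
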