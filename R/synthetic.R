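#' Configuration of the synthetic-data generator
#'
#' Describes a synthetic longitudinal multimodal study with known ground
#' truth. The defaults emulate the structure of the motivating cohort at a
#' desk scale: four visits, three modality blocks, three continuous
#' cognitive scores, a three-class diagnosis, and a coefficient tensor that
#' carries all three structural assumptions of the model exactly — `s`
#' active feature rows shared across tasks and visits (row sparsity),
#' concentrated in `n_active_modalities` blocks (group sparsity), with the
#' active block of the unfolded tensor of rank at most `r` (low rank).
#'
#' @param n,d,T patients, features, timepoints.
#' @param K number of modality blocks.
#' @param block_sizes length-`K` integer vector summing to `d`.
#' @param block_names optional modality names.
#' @param c_r,c_c number of regression targets / diagnostic classes
#'   (`c_c = 0` or `c_c >= 2`).
#' @param s number of active features (`r <= s <= d`).
#' @param r rank of the active coefficient block (`>= c_c` so the class
#'   directions fit inside the low-rank factor).
#' @param noise_sd Gaussian noise sd added to the regression targets.
#' @param label_flip_rate probability that a label is replaced by a
#'   uniformly random other class, in `[0, 1)`.
#' @param n_active_modalities how many blocks carry the active features.
#' @param proto_strength separation of the class prototypes in units of the
#'   feature noise sd; larger values give wider SVM margins.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a validated list of class `jrc_synth_config`.
#' @export
synthetic_config <- function(n = 200L, d = 100L, T = 4L, K = 3L,
                             block_sizes = NULL, block_names = NULL,
                             c_r = 3L, c_c = 3L, s = 10L, r = 3L,
                             noise_sd = 0.1, label_flip_rate = 0,
                             n_active_modalities = 2L, proto_strength = 3,
                             seed = 1L) {
  if (is.null(block_sizes)) {
    block_sizes <- rep(d %/% K, K)
    block_sizes[K] <- d - sum(block_sizes[-K])
  }
  if (length(block_sizes) != K || sum(block_sizes) != d)
    stop("block_sizes must have length K and sum to d")
  if (is.null(block_names))
    block_names <- c("MRI", "SNP", "PET", sprintf("mod%d", seq_len(K)))[
      seq_len(K)]
  if (s > d) stop("s must not exceed d")
  if (c_c == 1L) stop("use c_c = 0 (no classification) or c_c >= 2")
  if (c_c > 0 && r < c_c) stop("r must be at least c_c")
  if (r > s) stop("r must not exceed s")
  if (r > min(d, (c_r + c_c) * T)) stop("r exceeds the attainable rank")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (label_flip_rate < 0 || label_flip_rate >= 1)
    stop("label_flip_rate must lie in [0, 1)")
  n_active_modalities <- min(as.integer(n_active_modalities), K)
  if (n_active_modalities < 1) stop("need at least one active modality")
  if (sum(sort(block_sizes, decreasing = TRUE)[seq_len(n_active_modalities)]) < s)
    stop("active modalities too small to host s active features")
  structure(as.list(environment()), class = "jrc_synth_config")
}

#' Generate a synthetic longitudinal dataset with known truth
#'
#' Builds a dataset matching the structural assumptions of the joint model.
#' The ground-truth coefficients are `V* = A [D_t, C_t]` on the `s` active
#' rows, with `A` an orthonormal `s x r` factor shared across visits, so the
#' unfolded truth is row-sparse, modality-concentrated and of rank at most
#' `r`. Features are standard normal except that on the active rows each
#' patient receives a class-prototype mean shift, making the `c_c`
#' one-vs-all problems linearly separable; the classification block is then
#' rescaled so the smallest functional margin is exactly 1 (zero hinge loss
#' at the truth). Regression targets are `X_t W*_t` plus Gaussian noise;
#' labels are the argmax of the true SVM scores, then flipped with
#' probability `label_flip_rate`. The rare patients whose noise draw breaks
#' the prototype's sign pattern are re-drawn (seeded), keeping separability
#' exact.
#'
#' @param config a [synthetic_config()].
#' @return list with `data` (a [jrc_dataset()]) and `truth`: `V` (true
#'   `d x c x T` tensor), `b`, `active_features`, `active_modalities`,
#'   `latent_labels` (pre-flip) and the config.
#' @export
make_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "jrc_synth_config"))
  cf <- config
  cc <- cf$c_r + cf$c_c
  first <- cumsum(c(1L, cf$block_sizes[-cf$K]))
  last <- cumsum(cf$block_sizes)
  map <- data.frame(name = cf$block_names, first = first, last = last,
                    stringsAsFactors = FALSE)

  # sub-stream 1: support structure
  set.seed(cf$seed)
  resample <- function(x, k) x[sample.int(length(x), k)]
  act_mods <- sort(resample(seq_len(cf$K), cf$n_active_modalities))
  pool <- unlist(lapply(act_mods, function(j) first[j]:last[j]))
  guaranteed <- vapply(act_mods, function(j) resample(first[j]:last[j], 1L), 1L)
  rest <- setdiff(pool, guaranteed)
  active <- sort(c(guaranteed,
                   if (cf$s > length(guaranteed))
                     resample(rest, cf$s - length(guaranteed))))

  # sub-stream 2: coefficient truth
  set.seed(cf$seed + 1000003L)
  A <- qr.Q(qr(matrix(stats::rnorm(cf$s * cf$r), cf$s, cf$r)))
  V <- array(0, c(cf$d, cc, cf$T))
  Cs <- vector("list", cf$T)
  for (t in seq_len(cf$T)) {
    Dt <- matrix(stats::rnorm(cf$r * cf$c_r), cf$r, cf$c_r)
    Ct <- if (cf$c_c > 0)
      qr.Q(qr(matrix(stats::rnorm(cf$r * cf$c_c), cf$r, cf$c_c)))
    else matrix(0, cf$r, 0L)
    Cs[[t]] <- Ct
    V[active, , t] <- A %*% cbind(Dt, Ct)
  }
  b <- matrix(0, cf$c_c, cf$T)

  # sub-stream 3: features, latent classes, separability repair
  set.seed(cf$seed + 2000003L)
  X <- array(stats::rnorm(cf$n * cf$d * cf$T), c(cf$n, cf$d, cf$T))
  z <- NULL
  if (cf$c_c > 0) {
    z <- matrix(sample.int(cf$c_c, cf$n * cf$T, replace = TRUE), cf$n, cf$T)
    min_margin <- Inf
    for (t in seq_len(cf$T)) {
      U <- A %*% Cs[[t]]                      # s x c_c unit class directions
      proto <- cf$proto_strength *
        (2 * U - matrix(rowSums(U), cf$s, cf$c_c))  # +beta on own, -beta on others
      X[, active, t] <- X[, active, t] + t(proto[, z[, t]])
      S <- X[, active, t] %*% U               # true SVM scores (b* = 0)
      sign_ok <- function(S) {
        want <- matrix(-1, cf$n, cf$c_c)
        want[cbind(seq_len(cf$n), z[, t])] <- 1
        rowSums(S * want > 0) == cf$c_c
      }
      bad <- which(!sign_ok(S))
      tries <- 0L
      while (length(bad) && tries < 10000L) {
        X[bad, active, t] <- matrix(stats::rnorm(length(bad) * cf$s),
                                    length(bad)) + t(proto[, z[bad, t]])
        S[bad, ] <- X[bad, active, t, drop = FALSE][, , 1] %*% U
        bad <- which(!sign_ok(S))
        tries <- tries + 1L
      }
      if (length(bad)) stop("could not achieve separable class structure")
      yk <- matrix(-1, cf$n, cf$c_c)
      yk[cbind(seq_len(cf$n), z[, t])] <- 1
      min_margin <- min(min_margin, min(S * yk))
    }
    # exact margin scaling: min functional margin of the truth becomes 1
    alpha <- 1 / min_margin
    V[, cf$c_r + seq_len(cf$c_c), ] <- alpha * V[, cf$c_r + seq_len(cf$c_c), ,
                                                 drop = FALSE]
  }

  # sub-stream 4: targets and label noise
  set.seed(cf$seed + 3000003L)
  Y_r <- array(0, c(cf$n, cf$c_r, cf$T))
  labels <- NULL
  for (t in seq_len(cf$T)) {
    if (cf$c_r > 0)
      Y_r[, , t] <- X[, , t] %*% V[, seq_len(cf$c_r), t] +
        cf$noise_sd * matrix(stats::rnorm(cf$n * cf$c_r), cf$n)
  }
  if (cf$c_c > 0) {
    labels <- matrix(0L, cf$n, cf$T)
    for (t in seq_len(cf$T)) {
      S <- X[, , t] %*% V[, cf$c_r + seq_len(cf$c_c), t]
      labels[, t] <- max.col(S, ties.method = "first")
    }
    stopifnot(identical(labels, matrix(as.integer(z), cf$n, cf$T)))
    if (cf$label_flip_rate > 0) {
      flip <- matrix(stats::runif(cf$n * cf$T) < cf$label_flip_rate,
                     cf$n, cf$T)
      shift <- matrix(sample.int(cf$c_c - 1L, cf$n * cf$T, replace = TRUE),
                      cf$n, cf$T)
      labels[flip] <- 1L + (labels[flip] - 1L + shift[flip]) %% cf$c_c
    }
  }
  dimnames(Y_r) <- list(NULL, if (cf$c_r > 0) sprintf("score%d",
                                                      seq_len(cf$c_r)), NULL)

  data <- jrc_dataset(X, Y_r, labels, map, c_c = cf$c_c)
  truth <- list(V = V, b = b, active_features = active,
                active_modalities = cf$block_names[act_mods],
                latent_labels = if (!is.null(z))
                  matrix(as.integer(z), cf$n, cf$T),
                config = cf)
  # structural invariants of the truth hold exactly
  Vu <- unfold(V)
  stopifnot(all(Vu[-active, ] == 0),
            qr(Vu)$rank <= cf$r)
  list(data = data, truth = truth)
}

#' Score recovery of the planted coefficient structure
#'
#' Compares a fitted model to the generator's ground truth: the top-`k`
#' features of the fitted ranking against the true active set (precision,
#' recall, F1), plus sign agreement and Pearson correlation between true
#' and fitted coefficients on the true support. An unfit (all-zero) model
#' scores 0 on all support metrics.
#'
#' @param truth the `truth` element returned by [make_synthetic()].
#' @param model a fitted `jrc_model`.
#' @param k size of the selected set; defaults to the number of planted
#'   active features.
#' @return list: `precision`, `recall`, `f1`, `sign_agreement`,
#'   `correlation`, `selected` (indices).
#' @export
recovery_metrics <- function(truth, model, k = length(truth$active_features)) {
  stopifnot(inherits(model, "jrc_model"))
  ranked <- rank_features(model)
  if (max(ranked$global$score) == 0)
    return(list(precision = 0, recall = 0, f1 = 0, sign_agreement = 0,
                correlation = 0, selected = integer(0)))
  sel <- ranked$global$feature_index[seq_len(min(k, nrow(ranked$global)))]
  act <- truth$active_features
  tp <- length(intersect(sel, act))
  precision <- tp / length(sel)
  recall <- tp / length(act)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  Vt <- unfold(truth$V)[act, , drop = FALSE]
  Vh <- unfold(model$V)[act, , drop = FALSE]
  nz <- Vt != 0
  sign_agreement <- if (any(nz)) mean(sign(Vt[nz]) == sign(Vh[nz])) else 0
  correlation <- if (stats::sd(Vh) > 0 && stats::sd(Vt) > 0)
    stats::cor(as.vector(Vt), as.vector(Vh)) else 0
  list(precision = precision, recall = recall, f1 = f1,
       sign_agreement = sign_agreement, correlation = correlation,
       selected = sort(sel))
}
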