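#' Proximal operators of the structured penalties
#'
#' Closed-form minimizers of `tau * penalty(X) + 0.5 * ||X - M||_F^2` for the
#' three penalties acting on the unfolded coefficient matrix:
#'
#' * `prox_row_l21()` — row-wise l2,1 shrinkage: each row `v` becomes
#'   `max(0, 1 - tau/||v||_2) * v` (a zero row stays zero).
#' * `prox_group_l1()` — block shrinkage over modality row-blocks: each block
#'   is scaled by `max(0, 1 - tau/||block||_F)`.
#' * `prox_trace()` — singular value thresholding: every singular value is
#'   replaced by `max(0, sigma - tau)`, singular vectors kept. Thresholded
#'   values below `1e-12 * sigma_max` are treated as exact zeros.
#'
#' @param M numeric matrix.
#' @param tau nonnegative threshold.
#' @param blocks list of integer row-index vectors that tile `1..nrow(M)`,
#'   or a modality map data frame with `first`/`last` columns.
#' @return matrix of the same shape as `M`.
#' @export
prox_row_l21 <- function(M, tau) {
  M <- as.matrix(M)
  if (tau < 0) stop("tau must be nonnegative")
  if (tau == 0) return(M)
  nrm <- sqrt(rowSums(M^2))
  scl <- ifelse(nrm > tau, 1 - tau / nrm, 0)
  scl[nrm == 0] <- 0
  M * scl
}

#' @rdname prox_row_l21
#' @export
prox_group_l1 <- function(M, blocks, tau) {
  M <- as.matrix(M)
  if (tau < 0) stop("tau must be nonnegative")
  blocks <- as_row_blocks(blocks, nrow(M))
  if (tau == 0) return(M)
  out <- M
  for (idx in blocks) {
    nrm <- sqrt(sum(M[idx, , drop = FALSE]^2))
    out[idx, ] <- if (nrm > tau) (1 - tau / nrm) * M[idx, , drop = FALSE] else 0
  }
  out
}

as_row_blocks <- function(blocks, d) {
  if (is.data.frame(blocks))
    blocks <- mapply(seq.int, blocks$first, blocks$last, SIMPLIFY = FALSE)
  if (!is.list(blocks)) stop("blocks must be a list or modality map")
  flat <- unlist(blocks)
  if (!identical(sort(as.integer(flat)), seq_len(d)))
    stop("blocks must tile rows 1..d")
  lapply(blocks, as.integer)
}

#' @rdname prox_row_l21
#' @export
prox_trace <- function(M, tau) {
  M <- as.matrix(M)
  if (tau < 0) stop("tau must be nonnegative")
  if (tau == 0) return(M)
  sv <- svd(M)
  dth <- pmax(sv$d - tau, 0)
  if (length(dth)) dth[dth < 1e-12 * max(sv$d, 0)] <- 0
  keep <- dth > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*%
    (dth[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Proximal operator of the one-sided hinge error
#'
#' Minimizes `(y*e)_+ + (mu/2) * (e - a)^2` over the scalar hinge error `e`,
#' where `a` is the full quadratic centre (label minus SVM score minus scaled
#' dual). For `y = +1` the solution is `a - 1/mu` when `a > 1/mu`, `0` on
#' `[0, 1/mu]`, and `a` when `a < 0`; `y = -1` is the sign-flipped case.
#' Vectorized over `a` and `y` elementwise.
#'
#' @param a numeric; the quadratic centre(s).
#' @param y labels in `{-1, +1}`, recycled against `a`.
#' @param mu positive quadratic weight.
#' @return numeric of the same shape as `a`.
#' @export
prox_hinge_error <- function(a, y, mu) {
  if (mu <= 0) stop("mu must be positive")
  if (any(abs(y) != 1)) stop("y must be -1 or +1")
  m <- y * a
  r <- ifelse(m > 1 / mu, m - 1 / mu, ifelse(m < 0, m, 0))
  out <- y * r
  if (is.array(a)) dim(out) <- dim(a)
  out
}

norm_l21 <- function(M) sum(sqrt(rowSums(M^2)))

norm_g1 <- function(M, blocks) {
  blocks <- as_row_blocks(blocks, nrow(M))
  sum(vapply(blocks, function(idx) sqrt(sum(M[idx, , drop = FALSE]^2)), 0))
}

norm_trace <- function(M) sum(svd(M, nu = 0, nv = 0)$d)

#' Composite objective of the joint model
#'
#' Evaluates the full training objective at a coefficient model: the sum over
#' timepoints of the squared-Frobenius regression residual, the hinge losses
#' of all per-class one-vs-all SVMs, and the three structured penalties
#' (`gamma1 * l2,1 + gamma2 * group-l1 + gamma3 * trace`) on the unfolded
#' coefficient matrix.
#'
#' When the model carries a standardization scaler the design is standardized
#' before the losses are computed, so the value refers to the optimization
#' problem actually solved by [jrc_fit()].
#'
#' @param model a `jrc_model` (fitted or hand-constructed).
#' @param data a `jrc_data` with matching dimensions.
#' @param control a [jrc_control()] supplying `gamma1..gamma3`; defaults to
#'   the model's own control.
#' @return a single nonnegative number.
#' @export
jrc_objective <- function(model, data, control = model$control) {
  stopifnot(inherits(model, "jrc_model"), inherits(data, "jrc_data"))
  Xs <- scaled_design(data$X, model$scaler)
  Yc <- if (model$c_c > 0) encode_one_vs_all(data$labels, model$c_c)
        else array(0, c(dim(data$X)[1], 0L, dim(data$X)[3]))
  Y_r <- data$Y_r
  if (!is.null(model$scaler$y_center) && model$c_r > 0) {
    n <- dim(data$X)[1]
    for (t in seq_len(dim(data$X)[3]))
      Y_r[, , t] <- sweep(matrix(Y_r[, , t], n, model$c_r), 2,
                          model$scaler$y_center[, t])
  }
  objective_core(unfold(model$V), model$b, Xs, Y_r, Yc,
                 model$c_r, model$c_c, data$modality_map, control)
}

# Eq-level objective on prepared (already standardized) per-timepoint designs.
objective_core <- function(Vu, b, Xs, Y_r, Yc, c_r, c_c, modality_map,
                           control) {
  TT <- length(Xs); cc <- c_r + c_c
  reg <- 0; hinge <- 0
  for (t in seq_len(TT)) {
    cols <- slice_cols(t, cc)
    Vt <- Vu[, cols, drop = FALSE]
    if (c_r > 0) {
      Rt <- Xs[[t]] %*% Vt[, seq_len(c_r), drop = FALSE] - Y_r[, , t]
      reg <- reg + sum(Rt^2)
    }
    if (c_c > 0) {
      S <- Xs[[t]] %*% Vt[, c_r + seq_len(c_c), drop = FALSE] +
        rep(b[, t], each = nrow(Xs[[t]]))
      hinge <- hinge + sum(pmax(1 - S * Yc[, , t], 0))
    }
  }
  reg + hinge +
    control$gamma1 * norm_l21(Vu) +
    control$gamma2 * norm_g1(Vu, modality_map) +
    control$gamma3 * norm_trace(Vu)
}

# Augmented Lagrangian of the split problem: objective with the hinge written
# through the error variables e, plus duals and quadratic couplings for the
# four constraints e = y - score, F = V, G = V, H = V.
augmented_lagrangian <- function(state) {
  p <- state$prep; ct <- state$control
  Vu <- state$Vu; mu <- state$mu
  reg <- 0; hinge <- 0; hq <- 0
  for (t in seq_len(p$TT)) {
    cols <- slice_cols(t, p$c)
    if (p$c_r > 0) {
      Rt <- p$Xs[[t]] %*% Vu[, cols[seq_len(p$c_r)], drop = FALSE] -
        p$Y_r[, , t]
      reg <- reg + sum(Rt^2)
    }
    if (p$c_c > 0) {
      S <- svm_scores(state, t)
      et <- state$e[, , t]; yt <- p$Yc[, , t]; lt <- state$lambda[, , t]
      hinge <- hinge + sum(pmax(yt * et, 0))
      hq <- hq + sum((et - (yt - S) + lt / mu)^2)
    }
  }
  reg + hinge + (mu / 2) * hq +
    ct$gamma1 * norm_l21(state$F) +
    ct$gamma2 * norm_g1(state$G, p$modality_map) +
    ct$gamma3 * norm_trace(state$H) +
    (mu / 2) * sum((state$F - Vu + state$Sigma / mu)^2) +
    (mu / 2) * sum((state$G - Vu + state$Theta / mu)^2) +
    (mu / 2) * sum((state$H - Vu + state$Omega / mu)^2)
}
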