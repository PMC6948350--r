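#' Solver and model hyperparameters
#'
#' Collects the penalty weights and multi-block ADMM controls. The defaults
#' are the tuned values of the reference analysis on longitudinal
#' imaging-genetics data (`gamma1 = 1e-5`, `gamma2 = 1e-2`, `gamma3 = 100`,
#' `mu0 = 1e-3`, `rho = 1.2`) with a 100-iteration budget and a `1e-3`
#' coupling-gap stopping tolerance.
#'
#' @param gamma1 weight of the row-wise l2,1 penalty (longitudinally
#'   consistent feature selection).
#' @param gamma2 weight of the group l1 penalty over modality blocks.
#' @param gamma3 weight of the trace-norm (low-rank) penalty.
#' @param mu0 initial augmented-Lagrangian penalty, `> 0`.
#' @param rho geometric growth factor of the penalty, `> 1`.
#' @param max_iter iteration cap.
#' @param gap_tol stopping tolerance on the largest coupling gap between each
#'   auxiliary variable and the expression it replaces.
#' @param mu_max cap on the penalty parameter (guards against floating-point
#'   overflow under unbounded geometric growth).
#' @param standardize z-score each feature column per timepoint before
#'   fitting; the scaler is stored in the model and re-applied at prediction.
#' @param init `"zero"` starts all primal/dual variables at zero;
#'   `"random"` draws the coefficients from `0.01 * N(0,1)`.
#' @param track_descent record the augmented Lagrangian after every primal
#'   block update (diagnostic columns `al_after_*` in the history).
#' @return a list of class `jrc_control`.
#' @export
jrc_control <- function(gamma1 = 1e-5, gamma2 = 1e-2, gamma3 = 100,
                        mu0 = 1e-3, rho = 1.2, max_iter = 100L,
                        gap_tol = 1e-3, mu_max = 1e8,
                        standardize = TRUE, init = c("zero", "random"),
                        track_descent = FALSE) {
  init <- match.arg(init)
  if (gamma1 < 0 || gamma2 < 0 || gamma3 < 0)
    stop("penalty weights must be nonnegative")
  if (mu0 <= 0) stop("mu0 must be positive")
  if (rho <= 1) stop("rho must exceed 1")
  if (mu_max < mu0) stop("mu_max must be at least mu0")
  if (max_iter < 1) stop("max_iter must be positive")
  if (gap_tol <= 0) stop("gap_tol must be positive")
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 mu0 = mu0, rho = rho, max_iter = as.integer(max_iter),
                 gap_tol = gap_tol, mu_max = mu_max,
                 standardize = isTRUE(standardize), init = init,
                 track_descent = isTRUE(track_descent)),
            class = "jrc_control")
}

# Per-timepoint column standardization. Returns list(Xs, scaler|NULL).
standardize_design <- function(X, standardize) {
  n <- dim(X)[1]; d <- dim(X)[2]; TT <- dim(X)[3]
  if (!standardize)
    return(list(Xs = lapply(seq_len(TT), function(t) matrix(X[, , t], n, d)),
                scaler = NULL))
  center <- matrix(0, d, TT); scl <- matrix(1, d, TT)
  Xs <- vector("list", TT)
  for (t in seq_len(TT)) {
    Xt <- matrix(X[, , t], n, d)
    mu <- colMeans(Xt)
    sd <- apply(Xt, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1  # constant columns pass through
    center[, t] <- mu; scl[, t] <- sd
    Xs[[t]] <- sweep(sweep(Xt, 2, mu), 2, sd, "/")
  }
  list(Xs = Xs, scaler = list(center = center, scale = scl))
}

scaled_design <- function(X, scaler) {
  n <- dim(X)[1]; d <- dim(X)[2]; TT <- dim(X)[3]
  lapply(seq_len(TT), function(t) {
    Xt <- matrix(X[, , t], n, d)
    if (is.null(scaler)) Xt
    else sweep(sweep(Xt, 2, scaler$center[, t]), 2, scaler$scale[, t], "/")
  })
}

# Precomputations shared by all iterations: the eigendecomposition of X'X per
# timepoint (W solve for any mu in O(d^2 c)), and the Cholesky factor of the
# mu-independent SPD system matrix of the joint (p, b) update.
admm_prepare <- function(data, control) {
  dm <- dim(data$X)
  n <- dm[1]; d <- dm[2]; TT <- dm[3]
  c_r <- dim(data$Y_r)[2]; c_c <- data$c_c
  std <- standardize_design(data$X, control$standardize)
  Xs <- std$Xs
  # a centered design cannot carry target means and the regression block has
  # no intercept, so the targets are centered too (restored at prediction)
  Y_r <- data$Y_r
  if (control$standardize && c_r > 0) {
    y_center <- apply(Y_r, c(2, 3), mean)
    for (t in seq_len(TT))
      Y_r[, , t] <- sweep(matrix(Y_r[, , t], n, c_r), 2,
                          y_center[, t])
    std$scaler$y_center <- matrix(y_center, c_r, TT)
  }
  prep <- list(n = n, d = d, TT = TT, c_r = c_r, c_c = c_c, c = c_r + c_c,
               Xs = Xs, Y_r = Y_r,
               Yc = if (c_c > 0) encode_one_vs_all(data$labels, c_c)
                    else array(0, c(n, 0L, TT)),
               modality_map = data$modality_map, scaler = std$scaler,
               eig = vector("list", TT), XtY = vector("list", TT),
               cholM = vector("list", TT))
  for (t in seq_len(TT)) {
    XtX <- crossprod(Xs[[t]])
    prep$eig[[t]] <- eigen(XtX, symmetric = TRUE)
    if (c_r > 0) prep$XtY[[t]] <- crossprod(Xs[[t]],
                                            matrix(Y_r[, , t], n, c_r))
    if (c_c > 0) {
      Xt1 <- colSums(Xs[[t]])
      M <- rbind(cbind(XtX + 3 * diag(d), Xt1), c(Xt1, n))
      prep$cholM[[t]] <- chol(M)
    }
  }
  prep
}

# Fresh solver state at iteration 0.
admm_init <- function(prep, control, seed) {
  d <- prep$d; cT <- prep$c * prep$TT
  set.seed(seed)
  Vu <- matrix(0, d, cT)
  b <- matrix(0, prep$c_c, prep$TT)
  if (control$init == "random") {
    Vu[] <- 0.01 * stats::rnorm(length(Vu))
    if (length(b)) b[] <- 0.01 * stats::rnorm(length(b))
  }
  state <- list(prep = prep, control = control, Vu = Vu, b = b,
                F = Vu, G = Vu, H = Vu,
                Sigma = matrix(0, d, cT), Theta = matrix(0, d, cT),
                Omega = matrix(0, d, cT),
                e = array(0, dim(prep$Yc)),
                lambda = array(0, dim(prep$Yc)),
                mu = control$mu0, iter = 0L)
  # e starts at its feasible value y - score (equals y when V = 0)
  if (prep$c_c > 0)
    for (t in seq_len(prep$TT))
      state$e[, , t] <- prep$Yc[, , t] - svm_scores(state, t)
  state
}

svm_scores <- function(state, t) {
  p <- state$prep
  cols <- slice_cols(t, p$c)[p$c_r + seq_len(p$c_c)]
  p$Xs[[t]] %*% state$Vu[, cols, drop = FALSE] +
    rep(state$b[, t], each = p$n)
}

# Joint exact minimization of the augmented Lagrangian over (V, b): the
# regression columns W_t and each SVM column pair (p_kt, b_kt) decouple.
update_V <- function(state) {
  p <- state$prep; mu <- state$mu
  FGH <- state$F + state$G + state$H
  D <- state$Sigma + state$Theta + state$Omega
  for (t in seq_len(p$TT)) {
    cols <- slice_cols(t, p$c)
    if (p$c_r > 0) {
      wc <- cols[seq_len(p$c_r)]
      rhs <- 2 * p$XtY[[t]] + mu * FGH[, wc, drop = FALSE] +
        D[, wc, drop = FALSE]
      ev <- p$eig[[t]]
      state$Vu[, wc] <- ev$vectors %*%
        ((crossprod(ev$vectors, rhs)) / (2 * ev$values + 3 * mu))
    }
    if (p$c_c > 0) {
      pc <- cols[p$c_r + seq_len(p$c_c)]
      # r_ik = e - y + lambda/mu for the hinge-coupling quadratic
      R <- matrix(state$e[, , t] - p$Yc[, , t] + state$lambda[, , t] / mu,
                  p$n, p$c_c)
      rhs <- rbind(-crossprod(p$Xs[[t]], R) + FGH[, pc, drop = FALSE] +
                     D[, pc, drop = FALSE] / mu,
                   -colSums(R))
      sol <- backsolve(p$cholM[[t]],
                       backsolve(p$cholM[[t]], rhs, transpose = TRUE))
      state$Vu[, pc] <- sol[seq_len(p$d), , drop = FALSE]
      state$b[, t] <- sol[p$d + 1L, ]
    }
  }
  state
}

# Elementwise hinge-error prox at centre a = (y - score) - lambda/mu.
update_e <- function(state) {
  p <- state$prep
  if (p$c_c == 0) return(state)
  for (t in seq_len(p$TT)) {
    A <- (p$Yc[, , t] - svm_scores(state, t)) - state$lambda[, , t] / state$mu
    state$e[, , t] <- prox_hinge_error(A, p$Yc[, , t], state$mu)
  }
  state
}

update_F <- function(state) {
  state$F <- prox_row_l21(state$Vu - state$Sigma / state$mu,
                          state$control$gamma1 / state$mu)
  state
}

update_G <- function(state) {
  state$G <- prox_group_l1(state$Vu - state$Theta / state$mu,
                           state$prep$modality_map,
                           state$control$gamma2 / state$mu)
  state
}

update_H <- function(state) {
  state$H <- prox_trace(state$Vu - state$Omega / state$mu,
                        state$control$gamma3 / state$mu)
  state
}

# Dual ascent at the current (pre-growth) penalty.
update_duals <- function(state) {
  p <- state$prep; mu <- state$mu
  if (p$c_c > 0)
    for (t in seq_len(p$TT)) {
      resid <- state$e[, , t] - (p$Yc[, , t] - svm_scores(state, t))
      state$lambda[, , t] <- state$lambda[, , t] + mu * resid
    }
  state$Sigma <- state$Sigma + mu * (state$F - state$Vu)
  state$Theta <- state$Theta + mu * (state$G - state$Vu)
  state$Omega <- state$Omega + mu * (state$H - state$Vu)
  state
}

update_mu <- function(mu, control) min(control$rho * mu, control$mu_max)

coupling_gaps <- function(state) {
  p <- state$prep
  ge <- 0
  if (p$c_c > 0)
    for (t in seq_len(p$TT))
      ge <- max(ge, max(abs(state$e[, , t] -
                              (p$Yc[, , t] - svm_scores(state, t)))))
  c(gap_F = max(abs(state$F - state$Vu)),
    gap_G = max(abs(state$G - state$Vu)),
    gap_H = max(abs(state$H - state$Vu)),
    gap_e = ge)
}

#' Fit the joint longitudinal model by multi-block ADMM
#'
#' Minimizes the composite objective of [jrc_objective()] — multivariate
#' regression loss plus one-vs-all SVM hinge losses plus
#' l2,1 / group-l1 / trace penalties on the unfolded coefficient tensor — by
#' variable splitting: auxiliary copies `F`, `G`, `H` of the unfolded
#' coefficients absorb one penalty each and per-element hinge errors `e`
#' absorb the SVM loss, all tied back by equality constraints. Each
#' iteration cycles exact primal updates (a linear solve for the
#' coefficients and biases, then one proximal step per auxiliary), dual
#' ascent, and geometric growth of the penalty parameter, stopping when
#' every coupling gap falls below `gap_tol` or after `max_iter` iterations.
#'
#' @param data a [jrc_dataset()].
#' @param control a [jrc_control()].
#' @param seed integer seed; fixes the (optional) random initialization so
#'   identical calls give bit-identical histories.
#' @return a `jrc_model` whose `history` element is a data frame with one
#'   row per iteration: objective, augmented Lagrangian, the four coupling
#'   gaps and their maximum, and the penalty parameter in force.
#' @examples
#' syn <- make_synthetic(synthetic_config(n = 40, d = 12, T = 2, K = 2,
#'                                        block_sizes = c(6, 6), c_r = 1,
#'                                        c_c = 2, s = 4, r = 2, seed = 1))
#' fit <- jrc_fit(syn$data, jrc_control(max_iter = 25), seed = 1)
#' utils::tail(fit$history[, c("iter", "objective", "gap_max")], 3)
#' @export
jrc_fit <- function(data, control = jrc_control(), seed = 1L) {
  stopifnot(inherits(data, "jrc_data"))
  prep <- admm_prepare(data, control)
  state <- admm_init(prep, control, seed)
  hist <- vector("list", control$max_iter)
  for (it in seq_len(control$max_iter)) {
    al <- numeric(0)
    if (control$track_descent) al["al_start"] <- augmented_lagrangian(state)
    state <- update_V(state)
    if (control$track_descent) al["al_after_V"] <- augmented_lagrangian(state)
    state <- update_e(state)
    if (control$track_descent) al["al_after_e"] <- augmented_lagrangian(state)
    state <- update_F(state)
    if (control$track_descent) al["al_after_F"] <- augmented_lagrangian(state)
    state <- update_G(state)
    if (control$track_descent) al["al_after_G"] <- augmented_lagrangian(state)
    state <- update_H(state)
    if (control$track_descent) al["al_after_H"] <- augmented_lagrangian(state)
    state <- update_duals(state)
    gaps <- coupling_gaps(state)
    obj <- objective_core(state$Vu, state$b, prep$Xs, prep$Y_r, prep$Yc,
                          prep$c_r, prep$c_c, prep$modality_map, control)
    if (!is.finite(obj) || any(!is.finite(state$Vu)))
      stop(sprintf("solver diverged (non-finite values at iteration %d)", it))
    rec <- c(iter = it, objective = obj,
             aug_lagrangian = augmented_lagrangian(state),
             gaps, gap_max = max(gaps), mu = state$mu, al)
    hist[[it]] <- rec
    state$mu <- update_mu(state$mu, control)
    state$iter <- it
    if (max(gaps) <= control$gap_tol) break
  }
  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  V <- refold(state$Vu, prep$c)
  dimnames(V) <- list(data$feature_names, NULL, data$timepoint_names)
  model <- new_jrc_model(V, state$b, prep$c_r, prep$c_c, data$modality_map,
                         data$feature_names, data$timepoint_names,
                         prep$scaler, control, history)
  model$seed <- as.integer(seed)
  model
}
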