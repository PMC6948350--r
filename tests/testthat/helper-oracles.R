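# Independent numerical oracles used across the suite. They minimize each
# defining objective directly (quasi-Newton with subgradients, or 1-D Brent
# search) and never call the closed-form operators they check.

frob2 <- function(A) sum(A^2)

# 1-D brute force: fine grid then Brent refinement of
# g(a) = tau*a + 0.5*(a - nrm)^2 over a >= 0 (the radial profile of every
# norm prox: for a fixed norm the quadratic is minimized along the input
# direction, so the matrix problem reduces to this scalar one).
radial_min <- function(nrm, tau) {
  g <- function(a) tau * a + 0.5 * (a - nrm)^2
  grid <- seq(0, nrm + 1, length.out = 2001)
  i <- which.min(g(grid))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  cand <- stats::optimize(g, c(lo, hi), tol = 1e-12)
  if (g(0) <= cand$objective) 0 else cand$minimum
}

prox_l21_oracle <- function(M, tau) {
  out <- M
  for (i in seq_len(nrow(M))) {
    nrm <- sqrt(sum(M[i, ]^2))
    out[i, ] <- if (nrm == 0) 0 else radial_min(nrm, tau) * M[i, ] / nrm
  }
  out
}

prox_group_oracle <- function(M, blocks, tau) {
  out <- M
  for (idx in blocks) {
    nrm <- sqrt(sum(M[idx, , drop = FALSE]^2))
    out[idx, ] <- if (nrm == 0) 0
      else radial_min(nrm, tau) * M[idx, , drop = FALSE] / nrm
  }
  out
}

# Explicit SVD, then numeric 1-D minimization per singular value (the
# quadratic decouples in the singular basis of M).
prox_trace_oracle <- function(M, tau) {
  sv <- svd(M)
  dnew <- vapply(sv$d, radial_min, 0, tau = tau)
  sv$u %*% (dnew * t(sv$v))
}

pen_l21 <- function(X) sum(sqrt(rowSums(X^2)))
pen_group <- function(blocks) function(X)
  sum(vapply(blocks, function(i) sqrt(sum(X[i, , drop = FALSE]^2)), 0))
pen_trace <- function(X) sum(svd(X, nu = 0, nv = 0)$d)

# 1-D oracle for the hinge-error prox: Brent search bracketing the centre.
hinge_prox_oracle <- function(a, y, mu) {
  fn <- function(e) max(y * e, 0) + mu / 2 * (e - a)^2
  lo <- min(a, 0) - 2 / mu - 1
  hi <- max(a, 0) + 2 / mu + 1
  stats::optimize(fn, c(lo, hi), tol = 1e-12)$minimum
}

# Term-by-term re-implementation of the augmented Lagrangian, written
# directly from its definition (independent of augmented_lagrangian()).
al_oracle <- function(state) {
  p <- state$prep; ct <- state$control; mu <- state$mu
  total <- 0
  for (t in seq_len(p$TT)) {
    cols <- longjrc:::slice_cols(t, p$c)
    Vt <- state$Vu[, cols, drop = FALSE]
    if (p$c_r > 0)
      total <- total + frob2(p$Xs[[t]] %*% Vt[, seq_len(p$c_r)] - p$Y_r[, , t])
    if (p$c_c > 0) {
      S <- p$Xs[[t]] %*% Vt[, p$c_r + seq_len(p$c_c)] +
        rep(state$b[, t], each = p$n)
      for (i in seq_len(p$n)) for (k in seq_len(p$c_c)) {
        yikt <- p$Yc[i, k, t]; eikt <- state$e[i, k, t]
        total <- total + max(yikt * eikt, 0) +
          mu / 2 * (eikt - (yikt - S[i, k]) + state$lambda[i, k, t] / mu)^2
      }
    }
  }
  blocks <- lapply(seq_len(nrow(p$modality_map)),
                   function(i) p$modality_map$first[i]:p$modality_map$last[i])
  total +
    ct$gamma1 * pen_l21(state$F) +
    ct$gamma2 * pen_group(blocks)(state$G) +
    ct$gamma3 * pen_trace(state$H) +
    mu / 2 * frob2(state$F - state$Vu + state$Sigma / mu) +
    mu / 2 * frob2(state$G - state$Vu + state$Theta / mu) +
    mu / 2 * frob2(state$H - state$Vu + state$Omega / mu)
}

# Brute-force confusion-matrix F1, looped and unvectorized on purpose.
f1_bruteforce <- function(truth, pred, c_c) {
  per <- numeric(c_c)
  for (k in seq_len(c_c)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (pred[i] == k && truth[i] == k) tp <- tp + 1
      if (pred[i] == k && truth[i] != k) fp <- fp + 1
      if (pred[i] != k && truth[i] == k) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    per[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  per
}

# Small random dataset for solver tests.
tiny_dataset <- function(n = 20, d = 8, TT = 2, c_r = 2, c_c = 3, seed = 1) {
  set.seed(seed)
  X <- array(rnorm(n * d * TT), c(n, d, TT))
  Y_r <- array(rnorm(n * c_r * TT), c(n, c_r, TT))
  labels <- if (c_c > 0)
    matrix(sample.int(c_c, n * TT, replace = TRUE), n, TT)
  map <- data.frame(name = c("MRI", "SNP"),
                    first = c(1L, d %/% 2 + 1L),
                    last = c(d %/% 2, d))
  jrc_dataset(X, Y_r, labels, map, c_c = c_c)
}

# Hand-built model around given coefficient slices (no scaler).
manual_model <- function(V, b, c_r, c_c, map = NULL, control = NULL) {
  d <- dim(V)[1]
  if (is.null(map)) map <- data.frame(name = "all", first = 1L, last = d)
  if (is.null(control))
    control <- jrc_control(gamma1 = 0, gamma2 = 0, gamma3 = 0,
                           standardize = FALSE)
  longjrc:::new_jrc_model(V, b, c_r, c_c, map,
                          sprintf("feat%d", seq_len(d)),
                          sprintf("t%d", seq_len(dim(V)[3])), NULL, control)
}
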