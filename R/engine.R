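# Reference-free factorization by alternating exact constrained least squares.
#
# The mixing model is Y = W H + eps with W (features x K) the cell-type
# profile matrix and H (K x samples) the proportion matrix; H columns live on
# the probability simplex, W entries are non-negative (expression) or in
# [0, 1] (methylation beta-values). Both update steps are row/column-separable
# exact constrained least-squares solves, so the reconstruction RMSE is
# non-increasing over alternating sweeps — the model-selection loop in the
# driver relies on that monotonicity.

.check_mode <- function(mode) {
  if (!mode %in% .MODES) stop("mode must be one of: ",
                              paste(.MODES, collapse = ", "))
  mode
}

.mode_of <- function(Y, mode = NULL) {
  if (!is.null(mode)) return(.check_mode(mode))
  m <- attr(Y, "mode")
  if (is.null(m)) stop("matrix carries no mode attribute; pass `mode`")
  .check_mode(m)
}

.as_proportions <- function(H, labels = NULL) {
  if (is.null(rownames(H))) {
    rownames(H) <- if (is.null(labels)) paste0("C", seq_len(nrow(H))) else labels
  }
  if (is.null(colnames(H))) colnames(H) <- paste0("s", seq_len(ncol(H)))
  stopifnot(min(H) >= 0, max(abs(colSums(H) - 1)) <= 1e-8)
  structure(H, class = c("proportion_matrix", "matrix", "array"))
}

#' Random initialization of the alternating fit
#'
#' Proportion columns are drawn uniformly on the simplex (normalized
#' independent exponentials); the initial profile matrix is the exact
#' constrained least-squares response to that draw.
#'
#' @param Ym mixture matrix restricted to the current feature list.
#' @param K number of cell types.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (the driver runs everything under one seeded stream).
#' @param mode data mode; defaults to the `mode` attribute of `Ym`.
#' @return list with elements `W` (m' x K) and `H` (K x n).
#' @export
rf_initialize <- function(Ym, K, seed = NULL, mode = NULL) {
  mode <- .mode_of(Ym, mode)
  n <- ncol(Ym)
  if (K > n) stop("K must not exceed the number of samples")
  draw <- function() {
    E <- matrix(stats::rexp(K * n), K, n)
    sweep(E, 2, colSums(E), "/")
  }
  H0 <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dimnames(H0) <- list(paste0("C", seq_len(K)), colnames(Ym))
  W0 <- update_profiles(Ym, H0, mode)
  list(W = W0, H = .as_proportions(H0))
}

#' Profile update: constrained least squares per feature
#'
#' Solves, for every feature row `y_p` of `Ym`,
#' `min || y_p - t(H) w_p ||^2` subject to `w_p >= 0` (expression) or
#' `0 <= w_p <= 1` (methylation). The constraints are enforced exactly by
#' active-face enumeration, not by clipping an unconstrained solution.
#'
#' @param Ym mixture matrix (m' x n).
#' @param H proportion matrix (K x n), full rank.
#' @param mode data mode; defaults to the `mode` attribute of `Ym`.
#' @return m' x K profile matrix with the mode's box constraints satisfied.
#' @export
update_profiles <- function(Ym, H, mode = NULL) {
  mode <- .mode_of(Ym, mode)
  K <- nrow(H)
  if (ncol(H) != ncol(Ym)) stop("H and Ym disagree on the number of samples")
  if (qr(t(H))$rank < K) {
    stop("proportion matrix is rank-deficient; consider fewer cell types")
  }
  AtA <- tcrossprod(H)                 # t(X) X with X = t(H)
  AtB <- H %*% t(Ym)                   # K x m'
  upper <- if (mode == "methylation") 1 else Inf
  Wt <- cls_solve_multi(AtA, AtB, lower = 0, upper = upper)
  W <- t(Wt)
  dimnames(W) <- list(rownames(Ym), rownames(H))
  structure(W, mode = mode, class = c("profile_matrix", "matrix", "array"))
}

#' Proportion update: simplex-constrained least squares per sample
#'
#' Solves, for every sample column `y_s`,
#' `min || y_s - W h ||^2` over the probability simplex
#' `{h >= 0, sum(h) = 1}`. With duplicate profile columns the minimizer is
#' non-unique; the minimum-norm solution is returned.
#'
#' @param Ym mixture matrix (m' x n).
#' @param W profile matrix (m' x K), full rank.
#' @return K x n proportion matrix; every column sums to one.
#' @export
update_proportions <- function(Ym, W) {
  K <- ncol(W)
  if (nrow(W) != nrow(Ym)) stop("W and Ym disagree on the number of features")
  if (qr(W)$rank < K) {
    stop("profile matrix is rank-deficient; consider fewer cell types")
  }
  AtA <- crossprod(W)
  AtB <- crossprod(W, Ym)              # K x n
  H <- cls_solve_multi(AtA, AtB, lower = 0, upper = Inf, sum_to = 1)
  dimnames(H) <- list(colnames(W), colnames(Ym))
  .as_proportions(H)
}

#' Reconstruction root-mean-square error
#'
#' `sqrt(mean((Y - W %*% H)^2))` over all entries.
#'
#' @param Y observed matrix (m x n).
#' @param W profile matrix (m x K).
#' @param H proportion matrix (K x n).
#' @return non-negative scalar.
#' @export
reconstruction_rmse <- function(Y, W, H) {
  if (nrow(W) != nrow(Y) || ncol(H) != ncol(Y) || ncol(W) != nrow(H)) {
    stop("non-conformable Y, W, H")
  }
  sqrt(mean((Y - W %*% H)^2))
}

#' Project profiles onto the complete feature set
#'
#' Applies the profile update to the full matrix, so that a full-matrix RMSE
#' (comparable across iterations that select different feature lists) can be
#' computed, and so that variance/CV rankings of estimated profiles cover all
#' features. The problem is row-separable: restricted to the selected rows it
#' reproduces [update_profiles()] exactly.
#'
#' @param Y_full complete mixture matrix (m x n).
#' @param H current proportion matrix.
#' @param mode data mode; defaults to the `mode` attribute of `Y_full`.
#' @return m x K profile matrix.
#' @export
project_full_profiles <- function(Y_full, H, mode = NULL) {
  update_profiles(Y_full, H, mode)
}

#' Alternating constrained factorization with restarts
#'
#' Alternates [update_proportions()] and [update_profiles()] from a random
#' simplex initialization until the relative RMSE change per sweep falls
#' below `tol` (relative, so the criterion is invariant to the measurement
#' scale — expression intensities and methylation beta-values converge
#' comparably) or `max_iter` sweeps are reached; repeats for `restarts`
#' random starts and returns the fit with the smallest reconstruction RMSE.
#' Deterministic given the RNG state (or `seed`).
#'
#' @param Ym mixture matrix restricted to the current feature list.
#' @param K number of cell types (K = 1 is allowed and analytic: H is a row
#'   of ones).
#' @param mode data mode; defaults to the `mode` attribute of `Ym`.
#' @param tol convergence tolerance on the per-sweep RMSE change.
#' @param max_iter maximum alternating sweeps per restart.
#' @param restarts number of random restarts.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list of class `deconv_fit` with elements `W`, `H`, `rmse`,
#'   `inner_iterations`, `converged`, `restart_index`.
#' @examples
#' truth <- sim_preset("expr4", m = 200, n = 30, seed = 2, noise_sd = 0)
#' fit <- rf_fit(truth$Y, K = 4, seed = 1)
#' fit
#' colSums(fit$H)[1:5]                  # simplex columns
#' @export
rf_fit <- function(Ym, K, mode = NULL, tol = 1e-4, max_iter = 200L,
                   restarts = 3L, seed = NULL) {
  mode <- .mode_of(Ym, mode)
  run <- function() .rf_fit_stream(Ym, K, mode, tol, max_iter, restarts)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.rf_fit_stream <- function(Ym, K, mode, tol, max_iter, restarts) {
  n <- ncol(Ym)
  if (K > n) stop("K must not exceed the number of samples")
  if (K == 1L) {
    H <- matrix(1, 1L, n, dimnames = list("C1", colnames(Ym)))
    W <- update_profiles(Ym, H, mode)
    fit <- list(W = W, H = .as_proportions(H),
                rmse = reconstruction_rmse(Ym, W, H),
                inner_iterations = 0L, converged = TRUE, restart_index = 1L)
    class(fit) <- "deconv_fit"
    return(fit)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    E <- matrix(stats::rexp(K * n), K, n)
    H0 <- sweep(E, 2, colSums(E), "/")
    alt <- .rf_alternate_cpp(unclass(Ym), H0, mode == "methylation", tol,
                             max_iter)
    if (is.null(best) || alt$rmse < best$rmse) {
      best <- alt
      best$restart_index <- r
    }
  }
  dimnames(best$W) <- list(rownames(Ym), paste0("C", seq_len(K)))
  best$W <- structure(best$W, mode = mode,
                      class = c("profile_matrix", "matrix", "array"))
  dimnames(best$H) <- list(paste0("C", seq_len(K)), colnames(Ym))
  best$H <- .as_proportions(best$H)
  best <- best[c("W", "H", "rmse", "inner_iterations", "converged",
                 "restart_index")]
  class(best) <- "deconv_fit"
  best
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf(
    "Reference-free fit: %d features x %d cell types x %d samples\n",
    nrow(x$W), ncol(x$W), ncol(x$H)))
  cat(sprintf("  RMSE %.6g after %d sweeps (restart %d, %s)\n", x$rmse,
              x$inner_iterations, x$restart_index,
              if (x$converged) "converged" else "max sweeps reached"))
  invisible(x)
}
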