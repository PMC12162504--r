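# Cross-cell-type differential analysis through the proportion-design model.
#
# With known (or currently estimated) proportions theta_s, the expected bulk
# signal of feature p is E[Y_p] = X beta_p, where X (n x K) stacks the sample
# proportion vectors as rows and beta_p = (mu_p1, ..., mu_pK) holds the
# cell-type means of the feature. The design has no intercept: rows of X sum
# to one, so the constant vector already lies in its column span. Ordinary
# least squares then yields t-tests for any linear contrast c' beta:
#   SvC  one cell type vs the average of the rest,
#   DvC  a pair's sum vs the sum of the rest (the literal sum contrast,
#        not a mean-of-means comparison),
#   PwD  one cell type vs another, directly.

#' Build the proportion design matrix
#'
#' Transposes a proportion matrix so that sample `s`'s proportion vector
#' becomes row `s` of the design.
#'
#' @param H K x n proportion matrix.
#' @return n x K design matrix whose rows sum to one.
#' @export
design_from_proportions <- function(H) {
  X <- t(H)
  if (max(abs(rowSums(X) - 1)) > 1e-8) {
    stop("design rows must sum to 1; is H a proportion matrix?")
  }
  X
}

.check_design <- function(X, n_needed = TRUE) {
  n <- nrow(X)
  K <- ncol(X)
  if (n_needed && n <= K) stop("need more samples than cell types (n > K)")
  XtX <- crossprod(X)
  if (kappa(XtX, exact = TRUE) > 1e10) {
    stop("proportion design is (near-)collinear; contrast tests would be ",
         "unreliable. Reduce K or check the proportion estimates.")
  }
  XtX
}

#' Ordinary least squares fit of one feature
#'
#' @param y length-n observation vector for one feature.
#' @param X n x K proportion design (see [design_from_proportions()]).
#' @return list with `beta` (cell-type means), `sigma2` (residual variance),
#'   `df` (`n - K`), and `XtX_inv` for contrast variance computation.
#' @export
ols_fit <- function(y, X) {
  n <- nrow(X)
  K <- ncol(X)
  y <- as.vector(y)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  XtX <- .check_design(X)
  XtX_inv <- solve(XtX)
  beta <- drop(XtX_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (n - K)
  list(beta = beta, sigma2 = sigma2, df = n - K, XtX_inv = XtX_inv)
}

#' t-test of a linear contrast of cell-type means
#'
#' `t = c'beta / sqrt(sigma2 * c' (X'X)^-1 c)` with `n - K` degrees of
#' freedom, two-sided. A zero residual variance (noiseless data) yields
#' `t = 0, p = 1` when the contrast estimate is zero and `p = 0` (perfect
#' separation) otherwise.
#'
#' @param fit output of [ols_fit()].
#' @param contrast a contrast spec from [svc_contrasts()], [dvc_contrasts()]
#'   or [pwd_contrasts()], or a bare numeric weight vector.
#' @return list with `t`, `p`, and the contrast `estimate`.
#' @export
contrast_test <- function(fit, contrast) {
  w <- if (is.list(contrast)) contrast$weights else contrast
  if (all(w == 0)) stop("contrast weights must not all be zero")
  est <- sum(w * fit$beta)
  if (fit$sigma2 <= 0) {
    if (abs(est) < 1e-12) return(list(t = 0, p = 1, estimate = est))
    return(list(t = sign(est) * Inf, p = 0, estimate = est))
  }
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtX_inv %*% w))
  tval <- est / se
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = fit$df), estimate = est)
}

.contrast <- function(weights, label, family) {
  list(weights = weights, label = label, family = family)
}

#' Single-vs-composite contrasts
#'
#' One contrast per cell type `k`: weight 1 on `k` and `-1/(K-1)` on every
#' other type, testing `mu_k` against the average of the remaining types.
#' At `K = 2` this collapses to the pairwise contrast.
#'
#' @param K number of cell types (>= 2).
#' @return list of contrast specs.
#' @export
svc_contrasts <- function(K) {
  if (K < 2L) stop("SvC needs K >= 2")
  lapply(seq_len(K), function(k) {
    w <- rep(-1 / (K - 1), K)
    w[k] <- 1
    .contrast(w, sprintf("SvC:k=%d", k), "SvC")
  })
}

#' Dual-vs-composite contrasts
#'
#' One contrast per unordered pair `{k, l}`: weight +1 on both pair members
#' and -1 on every other type, testing the pair's summed mean against the
#' summed mean of the rest. Contrasts equal to the negation of an earlier one
#' are dropped — at `K = 4` each pair mirrors its complementary pair, leaving
#' 3 distinct comparisons; for `K >= 5` all `choose(K, 2)` survive.
#'
#' @param K number of cell types (>= 3).
#' @return list of contrast specs.
#' @export
dvc_contrasts <- function(K) {
  if (K < 3L) stop("DvC needs K >= 3 (pair vs rest is undefined below that)")
  out <- list()
  seen <- list()
  for (k in seq_len(K - 1L)) {
    for (l in seq.int(k + 1L, K)) {
      w <- rep(-1, K)
      w[c(k, l)] <- 1
      dup <- any(vapply(seen, function(v) all(v == w) || all(v == -w),
                        logical(1L)))
      if (dup) next
      seen[[length(seen) + 1L]] <- w
      out[[length(out) + 1L]] <- .contrast(w, sprintf("DvC:{%d,%d}", k, l),
                                           "DvC")
    }
  }
  out
}

#' Pairwise-direct contrasts
#'
#' One contrast per unordered pair: +1 on `k`, -1 on `l`, zero elsewhere.
#'
#' @param K number of cell types (>= 2).
#' @return list of `choose(K, 2)` contrast specs.
#' @export
pwd_contrasts <- function(K) {
  if (K < 2L) stop("PwD needs K >= 2")
  out <- list()
  for (k in seq_len(K - 1L)) {
    for (l in seq.int(k + 1L, K)) {
      w <- rep(0, K)
      w[k] <- 1
      w[l] <- -1
      out[[length(out) + 1L]] <- .contrast(w, sprintf("PwD:%dv%d", k, l),
                                           "PwD")
    }
  }
  out
}

#' Genome-wide contrast testing
#'
#' Fits the proportion-design model to every feature at once (the design is
#' shared, so `X'X` is factorized a single time) and evaluates each contrast.
#'
#' @param Y mixture matrix (m x n) or plain numeric matrix.
#' @param H K x n proportion matrix.
#' @param contrasts list of contrast specs.
#' @return object of class `ct_tests`: list with matrices `t`, `p`,
#'   `estimate` (m x n_contrasts, feature IDs as row names, contrast labels
#'   as column names), `beta` (m x K), `sigma2`, `df`.
#' @export
test_all_features <- function(Y, H, contrasts) {
  X <- design_from_proportions(H)
  n <- nrow(X)
  K <- ncol(X)
  if (ncol(Y) != n) stop("Y and H disagree on the number of samples")
  XtX <- .check_design(X)
  XtX_inv <- solve(XtX)
  B <- XtX_inv %*% crossprod(X, t(Y))          # K x m
  res <- t(Y) - X %*% B                        # n x m
  sigma2 <- colSums(res^2) / (n - K)
  df <- n - K
  labels <- vapply(contrasts, `[[`, character(1L), "label")
  m <- nrow(Y)
  tmat <- pmat <- emat <- matrix(
    NA_real_, m, length(contrasts), dimnames = list(rownames(Y), labels))
  for (j in seq_along(contrasts)) {
    w <- contrasts[[j]]$weights
    if (length(w) != K) stop("contrast length does not match K")
    est <- drop(crossprod(B, w))               # length m
    v <- drop(t(w) %*% XtX_inv %*% w)
    se <- sqrt(sigma2 * v)
    tval <- ifelse(se > 0, est / se, ifelse(abs(est) < 1e-12, 0, Inf * sign(est)))
    pval <- ifelse(se > 0, 2 * stats::pt(-abs(tval), df),
                   ifelse(abs(est) < 1e-12, 1, 0))
    tmat[, j] <- tval
    pmat[, j] <- pval
    emat[, j] <- est
  }
  structure(list(t = tmat, p = pmat, estimate = emat, beta = t(B),
                 sigma2 = sigma2, df = df),
            class = "ct_tests")
}

#' @export
as.data.frame.ct_tests <- function(x, ...) {
  m <- nrow(x$t)
  C <- ncol(x$t)
  data.frame(
    feature_id = rep(rownames(x$t), times = C),
    contrast = rep(colnames(x$t), each = m),
    estimate = as.vector(x$estimate),
    t = as.vector(x$t),
    p = as.vector(x$p),
    stringsAsFactors = FALSE
  )
}

#' Deterministic feature ranking from test results
#'
#' Orders features by ascending p-value, breaking ties by descending |t|,
#' then (optionally) by descending |estimate|, then by original position, so
#' the ranking is fully reproducible. The estimate tie-break matters on
#' noiseless data, where perfectly separated features share `p = 0` and an
#' infinite t statistic but still differ in effect size.
#'
#' @param p numeric vector of p-values.
#' @param t numeric vector of t statistics, same length.
#' @param ids feature IDs; defaults to names of `p` or positions.
#' @param estimate optional vector of contrast estimates for tie-breaking.
#' @return character vector of feature IDs in rank order.
#' @export
rank_features <- function(p, t, ids = NULL, estimate = NULL) {
  if (length(p) != length(t)) stop("p and t must have equal length")
  if (is.null(ids)) ids <- if (!is.null(names(p))) names(p) else as.character(seq_along(p))
  if (is.null(estimate)) {
    ids[order(p, -abs(t), seq_along(p))]
  } else {
    ids[order(p, -abs(t), -abs(estimate), seq_along(p))]
  }
}
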