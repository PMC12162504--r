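# Evaluation of proportion estimates against truth.
#
# Reference-free components are anonymous, so estimated rows must first be
# matched to true cell types. Matching maximizes the summed per-type Pearson
# correlation (the headline metric) via optimal assignment on the cost
# 1 - PCC; MAE is then computed under the same alignment.

# Pearson correlation per (estimated row, true row) pair; a constant row has
# undefined correlation and contributes 0 by convention (penalized but finite).
.pcc_matrix <- function(H_est, H_true) {
  K <- nrow(H_true)
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (stats::sd(H_est[i, ]) == 0 || stats::sd(H_true[j, ]) == 0) next
      P[i, j] <- stats::cor(H_est[i, ], H_true[j, ])
    }
  }
  P
}

# Minimum-cost perfect assignment on a square cost matrix by shortest
# augmenting paths (Jonker-Volgenant style), O(K^3). Returns, for each
# column j, the assigned row.
.assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                  # columns are 1..n, slot n+1 is the virtual root
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) ans[j - 1L] <- p[j]
  ans
}

#' Match anonymous estimated components to true cell types
#'
#' Finds the bijection maximizing the summed Pearson correlation between
#' matched rows (optimal assignment on cost `1 - PCC`).
#'
#' @param H_est K x n estimated proportion matrix.
#' @param H_true K x n true proportion matrix.
#' @return integer vector `perm` with `perm[k]` the estimated row matched to
#'   true cell type `k`.
#' @export
match_components <- function(H_est, H_true) {
  if (!all(dim(H_est) == dim(H_true))) {
    stop("H_est and H_true must have identical dimensions")
  }
  P <- .pcc_matrix(H_est, H_true)
  .assignment(1 - P)
}

#' Mean Pearson correlation of matched proportions
#'
#' Average over cell types of the Pearson correlation across samples between
#' matched estimated and true rows. Constant rows contribute 0.
#'
#' @inheritParams match_components
#' @param perm optional precomputed matching from [match_components()].
#' @return scalar in \[-1, 1\].
#' @export
mean_pcc <- function(H_est, H_true, perm = NULL) {
  if (ncol(H_true) < 3L) stop("need at least 3 samples for a stable correlation")
  if (is.null(perm)) perm <- match_components(H_est, H_true)
  P <- .pcc_matrix(H_est, H_true)
  mean(P[cbind(perm, seq_len(nrow(H_true)))])
}

#' Mean absolute error of matched proportions
#'
#' Mean over all K x n entries of `|H_est[matched] - H_true|`.
#'
#' @inheritParams mean_pcc
#' @return scalar in \[0, 1\].
#' @export
proportion_mae <- function(H_est, H_true, perm = NULL) {
  if (!all(dim(H_est) == dim(H_true))) {
    stop("H_est and H_true must have identical dimensions")
  }
  if (is.null(perm)) perm <- match_components(H_est, H_true)
  mean(abs(H_est[perm, , drop = FALSE] - H_true))
}

#' Full evaluation report
#'
#' Bundles the component matching, per-type and mean Pearson correlations,
#' and the MAE under the same alignment.
#'
#' @inheritParams match_components
#' @return object of class `eval_report`: list with `permutation`,
#'   `per_type_pcc`, `mean_pcc`, `mae`, `n`, `K`.
#' @examples
#' H_true <- draw_proportions(50, c(1, 3, 0.5), seed = 1)
#' H_est <- unclass(H_true)[c(2, 3, 1), ]   # anonymous, permuted components
#' evaluate_proportions(H_est, H_true)      # matching recovers the labels
#' @export
evaluate_proportions <- function(H_est, H_true) {
  perm <- match_components(H_est, H_true)
  P <- .pcc_matrix(H_est, H_true)
  per_type <- P[cbind(perm, seq_len(nrow(H_true)))]
  names(per_type) <- rownames(H_true)
  structure(list(permutation = perm, per_type_pcc = per_type,
                 mean_pcc = mean(per_type),
                 mae = proportion_mae(H_est, H_true, perm),
                 n = ncol(H_true), K = nrow(H_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Proportion evaluation (K = %d, n = %d)\n", x$K, x$n))
  cat(sprintf("  mean PCC %.4f, MAE %.4f\n", x$mean_pcc, x$mae))
  cat("  per-type PCC:", paste(sprintf("%.3f", x$per_type_pcc), collapse = " "),
      "\n")
  invisible(x)
}
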