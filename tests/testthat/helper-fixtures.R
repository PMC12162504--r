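# In-code fixtures shared across test files.

# small expression-mode mixture with known truth
toy_truth <- function(m = 60, K = 3, n = 20, noise_sd = 0, seed = 1,
                      mode = "expression") {
  withr::with_seed(seed, {
    W <- if (mode == "expression") {
      matrix(rlnorm(m * K, meanlog = 3, sdlog = 1), m, K)
    } else {
      matrix(rbeta(m * K, 2, 2), m, K)
    }
    dimnames(W) <- list(paste0("f", seq_len(m)), paste0("C", seq_len(K)))
    W <- structure(W, mode = mode, class = c("profile_matrix", "matrix", "array"))
    H <- draw_proportions(n, rep(1, K))
    Y <- mix_mixture(W, H, noise_sd = noise_sd)
    list(W = W, H = H, Y = Y)
  })
}

# random proportion design with a fixed seed
toy_design <- function(n = 12, K = 3, seed = 1) {
  withr::with_seed(seed, t(draw_proportions(n, rep(1, K))))
}

# independent brute-force OLS via explicit normal equations
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX) %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  list(beta = drop(beta), sigma2 = sum(res^2) / df, df = df,
       XtX_inv = solve(XtX))
}

oracle_contrast <- function(fit, w) {
  est <- sum(w * fit$beta)
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtX_inv %*% w))
  tval <- est / se
  list(t = tval, p = 2 * stats::pt(-abs(tval), fit$df))
}

# exhaustive-permutation component matching oracle
oracle_match <- function(H_est, H_true) {
  K <- nrow(H_true)
  perms <- .all_perms(K)
  best <- NULL
  best_tot <- -Inf
  for (p in perms) {
    tot <- sum(vapply(seq_len(K), function(k) {
      if (sd(H_est[p[k], ]) == 0 || sd(H_true[k, ]) == 0) return(0)
      cor(H_est[p[k], ], H_true[k, ])
    }, numeric(1)))
    if (tot > best_tot) {
      best_tot <- tot
      best <- p
    }
  }
  list(perm = best, total = best_tot)
}

# all permutations of 1..K by inserting K into every slot
.all_perms <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (sub in .all_perms(K - 1L)) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1L]] <- append(sub, K, after = pos - 1L)
    }
  }
  out
}
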