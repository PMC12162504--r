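test_that("design construction transposes proportions without an intercept", {
  H <- matrix(c(0.3, 0.7, 0.6, 0.4), 2)
  X <- design_from_proportions(H)
  expect_equal(X[1, ], c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(X[2, ], c(0.6, 0.4), ignore_attr = TRUE)
  expect_equal(rowSums(X), c(1, 1), ignore_attr = TRUE)
  expect_equal(design_from_proportions(t(X)), X)
  expect_error(design_from_proportions(matrix(1:4, 2)), "sum to 1")
})

test_that("OLS fit matches brute-force normal equations", {
  X <- toy_design(n = 6, K = 2, seed = 2)
  y <- drop(X %*% c(2, 5))
  fit <- ols_fit(y, X)
  expect_equal(fit$beta, c(2, 5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$sigma2, 0, tolerance = 1e-18)
  expect_equal(fit$df, 4)

  withr::with_seed(4, {
    for (i in 1:20) {
      K <- sample(2:5, 1)
      n <- sample((K + 2):20, 1)
      X <- toy_design(n = n, K = K, seed = i + 100)
      y <- rnorm(n)
      fit <- ols_fit(y, X)
      o <- oracle_ols(y, X)
      expect_equal(fit$beta, o$beta, tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(fit$sigma2, o$sigma2, tolerance = 1e-10)
    }
  })

  # constant response: the constant lies in the span since rows sum to 1
  X <- toy_design(n = 9, K = 3, seed = 6)
  fit <- ols_fit(rep(4.2, 9), X)
  expect_equal(fit$beta, rep(4.2, 3), tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(ols_fit(rnorm(2), toy_design(n = 2, K = 3, seed = 1)), "n > K")
  Xc <- cbind(rep(0.5, 10), rep(0.5, 10))   # collinear proportions
  expect_error(ols_fit(rnorm(10), Xc), "collinear")
})

test_that("contrast t-tests match the closed-form Student-t oracle", {
  X <- toy_design(n = 12, K = 3, seed = 3)
  withr::with_seed(5, y <- drop(X %*% c(1, 2, 3)) + rnorm(12, sd = 0.3))
  fit <- ols_fit(y, X)
  w <- c(1, -0.5, -0.5)
  res <- contrast_test(fit, w)
  o <- oracle_contrast(fit, w)
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  # p from numerically integrated t density agrees with pt()
  dens <- function(x) dt(x, df = fit$df)
  p_num <- 2 * integrate(dens, abs(res$t), Inf, rel.tol = 1e-10)$value
  expect_equal(res$p, p_num, tolerance = 1e-8)

  # negating the contrast flips t, keeps p
  neg <- contrast_test(fit, -w)
  expect_equal(neg$t, -res$t)
  expect_equal(neg$p, res$p)

  # zero contrast estimate with noise: t = 0, p = 1
  fit0 <- list(beta = c(1, 1, 1), sigma2 = 0.5, df = 9,
               XtX_inv = fit$XtX_inv)
  r0 <- contrast_test(fit0, w)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # noiseless separation: p = 0
  fitsep <- list(beta = c(2, 1, 1), sigma2 = 0, df = 9, XtX_inv = fit$XtX_inv)
  expect_equal(contrast_test(fitsep, w)$p, 0)
  expect_equal(contrast_test(list(beta = c(1, 1, 1), sigma2 = 0, df = 9,
                                  XtX_inv = fit$XtX_inv), w)$p, 1)

  expect_error(contrast_test(fit, c(0, 0, 0)), "not all be zero")
})

test_that("contrast families have the published structure", {
  svc <- svc_contrasts(4)
  expect_length(svc, 4)
  expect_equal(svc[[1]]$weights, c(1, -1/3, -1/3, -1/3))
  for (ct in svc) expect_equal(sum(ct$weights), 0, tolerance = 1e-12)

  # K = 2 SvC collapses to the pairwise contrast
  expect_equal(svc_contrasts(2)[[1]]$weights, c(1, -1))

  expect_length(dvc_contrasts(4), 3)    # complementary pairs deduplicated
  expect_length(dvc_contrasts(6), 15)
  d3 <- dvc_contrasts(3)
  expect_length(d3, 3)
  for (ct in d3) expect_equal(sort(ct$weights), c(-1, 1, 1))
  expect_error(dvc_contrasts(2), "K >= 3")

  expect_length(pwd_contrasts(4), 6)
  expect_length(pwd_contrasts(2), 1)
  for (ct in pwd_contrasts(5)) expect_equal(sum(ct$weights), 0)
})

test_that("SvC with K = 2 produces p-values identical to PwD", {
  tt <- toy_truth(m = 30, K = 2, n = 15, noise_sd = 0.3, seed = 19)
  ps <- test_all_features(tt$Y, tt$H, svc_contrasts(2))$p
  pp <- test_all_features(tt$Y, tt$H, pwd_contrasts(2))$p
  expect_equal(unname(ps[, 1]), unname(pp[, 1]), tolerance = 1e-12)
})

test_that("vectorized genome-wide testing equals the per-feature loop", {
  tt <- toy_truth(m = 25, K = 3, n = 14, noise_sd = 0.4, seed = 23)
  contrasts <- c(svc_contrasts(3), dvc_contrasts(3), pwd_contrasts(3))
  res <- test_all_features(tt$Y, tt$H, contrasts)
  X <- design_from_proportions(tt$H)
  for (p in c(1, 7, 25)) {
    fit <- ols_fit(tt$Y[p, ], X)
    for (j in seq_along(contrasts)) {
      o <- contrast_test(fit, contrasts[[j]])
      expect_equal(res$t[p, j], o$t, tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(res$p[p, j], o$p, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }

  # permuting feature rows permutes results identically
  perm <- sample(25)
  res_p <- test_all_features(tt$Y[perm, ], tt$H, contrasts)
  expect_equal(res_p$t, res$t[perm, ], tolerance = 1e-12)

  # single-feature matrix reduces to one fit
  res1 <- test_all_features(tt$Y[1, , drop = FALSE], tt$H, contrasts[1])
  expect_equal(dim(res1$p), c(1L, 1L))

  df <- as.data.frame(res)
  expect_equal(nrow(df), 25 * length(contrasts))
})

test_that("feature ranking is deterministic with the documented tie rules", {
  expect_equal(rank_features(c(0.5, 0.01, 0.2), c(1, 1, 1)),
               c("2", "3", "1"))
  expect_equal(rank_features(c(0.1, 0.1, 0.1), c(1, 3, 2)),
               c("2", "3", "1"))
  expect_error(rank_features(c(0.1), c(1, 2)), "equal length")
  withr::with_seed(9, {
    p <- runif(50)
    t <- rnorm(50)
    ids <- paste0("f", 1:50)
    got <- rank_features(p, t, ids)
    expect_equal(got, ids[order(p, -abs(t), 1:50)])   # independent stable sort
  })
})
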