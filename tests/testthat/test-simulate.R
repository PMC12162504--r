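test_that("Dirichlet draws live on the simplex with the right moments", {
  H <- draw_proportions(10000, rep(1, 4), seed = 3)
  expect_equal(colSums(H), rep(1, 10000), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowMeans(H), rep(0.25, 4), tolerance = 0.01,
               ignore_attr = TRUE)

  alpha <- c(0.968, 4.706, 0.496, 0.347)
  H2 <- draw_proportions(10000, alpha, seed = 4)
  mu <- alpha / sum(alpha)
  v <- mu * (1 - mu) / (sum(alpha) + 1)       # closed-form Dirichlet variance
  expect_true(all(abs(rowMeans(H2) - mu) < 4 * sqrt(v / 10000)))

  expect_error(draw_proportions(5, c(1, -1)), "positive")
})

test_that("expression priors plant the requested marker structure", {
  pr0 <- make_expression_priors(200, 4, cts_fraction = 0, seed = 1)
  expect_equal(pr0$meanlog[, 1], pr0$meanlog[, 3])
  expect_length(pr0$markers$index, 0)

  pr <- make_expression_priors(200, 4, cts_fraction = 0.15, seed = 2)
  expect_length(pr$markers$index, 30)
  shifted <- abs(pr$meanlog[cbind(pr$markers$index, pr$markers$cell_type)] -
                   rowMeans(pr$meanlog[pr$markers$index, , drop = FALSE]))
  expect_true(all(shifted > 0))
  # noisy features are flagged with the inflated scale
  expect_equal(sum(pr$noise_scale > 1), round(0.3 * 200))

  # planted markers dominate the profile-variance ranking on average
  W <- draw_profiles(pr, seed = 3)
  v <- apply(log(W), 1, var)
  expect_gt(mean(rank(v)[pr$markers$index]), mean(rank(v)))
})

test_that("methylation priors stay in [0,1] and round-trip by moments", {
  pr <- make_methylation_priors(300, 4, seed = 5)
  expect_true(all(pr$mean >= 0.02 & pr$mean <= 0.98))
  W <- draw_profiles(pr, seed = 6)
  expect_gte(min(W), 0)
  expect_lte(max(W), 1)

  # method-of-moments identity: shapes -> (mean, precision) -> shapes
  sh <- decondiff:::.beta_shapes(pr$mean, pr$precision)
  mu_back <- sh$shape1 / (sh$shape1 + sh$shape2)
  nu_back <- sh$shape1 + sh$shape2
  expect_equal(mu_back, pr$mean, tolerance = 1e-10)
  expect_equal(unique(round(as.vector(nu_back), 10)), pr$precision)

  pr0 <- make_methylation_priors(100, 3, cts_fraction = 0, seed = 7)
  expect_equal(pr0$mean[, 1], pr0$mean[, 3])
})

test_that("profile draws match their closed-form moments", {
  pr <- make_expression_priors(1, 1, cts_fraction = 0, seed = 8)
  draws <- vapply(1:5000, function(i) draw_profiles(pr, seed = i)[1, 1],
                  numeric(1))
  mu <- exp(pr$meanlog[1, 1] + pr$sdlog^2 / 2)       # log-normal mean
  expect_equal(mean(draws), mu, tolerance = 0.05 * mu)
  expect_gt(min(draws), 0)
  expect_identical(draw_profiles(pr, seed = 42), draw_profiles(pr, seed = 42))
})

test_that("mixing is exact without noise and clamps to the mode domain", {
  tt <- toy_truth(m = 30, K = 3, n = 10, noise_sd = 0)
  expect_equal(unclass(tt$Y), unclass(tt$W %*% tt$H), tolerance = 1e-12,
               ignore_attr = TRUE)

  tm <- toy_truth(m = 200, K = 3, n = 40, noise_sd = 0.3, seed = 10,
                  mode = "methylation")
  expect_gte(min(tm$Y), 0)
  expect_lte(max(tm$Y), 1)

  # observed reconstruction error approaches the injected noise sd
  tt <- toy_truth(m = 400, K = 3, n = 50, noise_sd = 0, seed = 12)
  Yn <- mix_mixture(tt$W, tt$H, noise_sd = 2, seed = 13)
  expect_equal(reconstruction_rmse(Yn, tt$W, tt$H), 2, tolerance = 0.05)

  expect_error(mix_mixture(tt$W, tt$H, noise_sd = -1), "non-negative")
  expect_error(mix_mixture(tt$W, tt$H, noise_scale = c(1, 2)), "per feature")
})

test_that("reference-based prior estimation pools replicates correctly", {
  vals <- exp(c(1, 2, 3))
  ref <- rbind(g1 = c(vals, 10, 11, 12), g2 = rep(2, 6))
  colnames(ref) <- paste0("r", 1:6)
  pr <- estimate_priors_from_reference(ref, list(A = paste0("r", 1:3),
                                                 B = paste0("r", 4:6)),
                                       mode = "expression")
  expect_equal(pr$meanlog["g1", "A"], 2)
  expect_equal(pr$sdlog["g1", "A"], 1)
  # identical replicates: variance floored at a positive epsilon
  expect_gt(pr$sdlog["g2", "A"], 0)

  # pooling two groups equals estimating from the concatenated replicates
  pooled <- estimate_priors_from_reference(ref, list(AB = paste0("r", 1:6)),
                                           mode = "expression")
  expect_equal(pooled$meanlog["g1", "AB"], mean(log(ref["g1", ])))
  expect_equal(pooled$sdlog["g1", "AB"]^2, var(log(ref["g1", ])))

  expect_error(estimate_priors_from_reference(ref, list(A = "r1")),
               "fewer than 2")
})

test_that("presets reproduce the published study conditions", {
  s4 <- sim_preset("expr4", m = 200, n = 20, seed = 1)
  expect_equal(s4$alpha, c(0.968, 4.706, 0.496, 0.347))
  expect_equal(nrow(s4$H_true), 4L)
  expect_equal(attr(s4$Y, "mode"), "expression")

  s6 <- sim_preset("meth6", m = 200, n = 20, seed = 1)
  expect_equal(s6$alpha, c(0.89, 4.12, 0.47, 0.33, 0.61, 1.02))
  expect_equal(nrow(s6$H_true), 6L)
  expect_gte(min(s6$Y), 0)
  expect_lte(max(s6$Y), 1)

  r1 <- sim_preset("meth4", m = 150, n = 15, seed = 9)
  r2 <- sim_preset("meth4", m = 150, n = 15, seed = 9)
  expect_identical(unclass(r1$Y), unclass(r2$Y))
  expect_error(sim_preset("bogus"), "arg")
})
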