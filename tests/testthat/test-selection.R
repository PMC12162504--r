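test_that("per-comparison quota reproduces the published worked examples", {
  expect_equal(per_comparison_quota(1000, 4), 300L)
  expect_equal(per_comparison_quota(1000, 6), 200L)
  expect_equal(per_comparison_quota(1000, 3), 400L)
  expect_equal(per_comparison_quota(500, 4), 150L)
  # genuinely fractional case still ceils upward
  expect_equal(per_comparison_quota(1000, 7), as.integer(ceiling(1200 / 7)))
})

test_that("raw-CV selection ranks by sd/mean with the zero-mean convention", {
  Y <- mixture_matrix(rbind(f1 = c(1, 1, 1), f2 = c(1, 2, 3),
                            f3 = c(0, 0, 0)), "expression")
  fs <- select_cv_raw(Y, 2)
  expect_equal(as.character(fs)[1], "f2")
  expect_false("f3" %in% as.character(fs)[1])   # zero row never outranks varying

  withr::with_seed(31, {
    Y <- mixture_matrix(matrix(rlnorm(500), 50, 10), "expression")
    fs <- select_cv_raw(Y, 20)
    cv <- apply(Y, 1, sd) / rowMeans(Y)
    expect_equal(as.character(fs), rownames(Y)[order(-cv, 1:50)][1:20])
  })
  expect_error(select_cv_raw(Y, 100), "exceeds")
})

test_that("profile-dispersion selection matches brute-force ranking", {
  W <- rbind(a = c(5, 5, 5, 5), b = c(0, 0, 0, 8), c = c(2, 2, 2, 2.5))
  expect_equal(as.character(select_var_profiles(W, 1)), "b")
  expect_equal(as.character(select_cv_profiles(W, 1)), "b")
  expect_equal(as.character(select_var_profiles(W, 3))[3], "a")  # VAR 0 last

  withr::with_seed(37, {
    W <- matrix(rlnorm(200), 40, 5, dimnames = list(paste0("f", 1:40), NULL))
    v <- apply(W, 1, var)
    expect_equal(as.character(select_var_profiles(W, 15)),
                 rownames(W)[order(-v, 1:40)][1:15])
  })
})

test_that("round-robin merge deduplicates and respects rank order", {
  got <- merge_ranked_lists(list(c("a", "b", "c"), c("b", "d", "e")), 4)
  expect_equal(as.character(got), c("a", "b", "c", "d"))
  got2 <- merge_ranked_lists(list(c("a", "b"), c("c", "d")), 4)
  expect_equal(as.character(got2), c("a", "c", "b", "d"))
  expect_warning(merge_ranked_lists(list(c("a", "b"), c("b")), 5),
                 "pool exhausted")
  got3 <- merge_ranked_lists(list(c("a", "b"), c("c")), 2,
                             exclude = c("a"))
  expect_equal(as.character(got3), c("b", "c"))

  withr::with_seed(41, {
    for (i in 1:10) {
      lists <- lapply(1:4, function(j) sample(paste0("f", 1:60), 25))
      names(lists) <- paste0("L", 1:4)
      got <- suppressWarnings(merge_ranked_lists(lists, 40))
      expect_equal(anyDuplicated(got), 0L)
      # the features each list contributed were claimed in that list's order
      prov <- attr(got, "provenance")
      for (nm in names(lists)) {
        mine <- prov$feature_id[prov$contrast == nm]
        expect_false(is.unsorted(match(mine, lists[[nm]])))
      }
    }
  })
})

# noiseless instance with planted markers: only the first q features differ
# across cell types, all others are exactly constant
planted_instance <- function(q = 12, m = 40, K = 4, n = 24, seed = 55) {
  withr::with_seed(seed, {
    W <- matrix(5, m, K, dimnames = list(paste0("f", 1:m), NULL))
    marker_type <- rep_len(seq_len(K), q)
    for (i in seq_len(q)) W[i, marker_type[i]] <- 8
    W <- structure(W, mode = "expression",
                   class = c("profile_matrix", "matrix", "array"))
    H <- draw_proportions(n, rep(1, K))
    Y <- mix_mixture(W, H, noise_sd = 0)
    list(Y = Y, H = H, markers = paste0("f", 1:q))
  })
}

test_that("contrast-based selection finds exactly the planted markers", {
  inst <- planted_instance()
  fs <- select_svc(inst$Y, inst$H, m_target = 12)
  expect_setequal(as.character(fs), inst$markers)

  # comparison counts recorded in provenance: 4 SvC comparisons at K = 4
  expect_equal(length(unique(attr(fs, "provenance")$contrast)), 4L)
  fd <- suppressWarnings(select_dvc(inst$Y, inst$H, m_target = 12))
  expect_equal(length(unique(attr(fd, "provenance")$contrast)), 3L)
  expect_true(all(as.character(fd) %in% inst$markers))
})

test_that("hybrid allocation reproduces the canonical 400/300/300 recipe", {
  tt <- toy_truth(m = 2500, K = 4, n = 40, noise_sd = 0.3, seed = 61)
  fs <- select_rfdecd(tt$Y, tt$H, m_target = 1000)
  prov <- attr(fs, "provenance")
  expect_length(fs, 1000)
  expect_equal(anyDuplicated(fs), 0L)
  counts <- table(prov$block)
  expect_equal(unname(counts[c("A:svc", "B:dvc", "C:pooled")]),
               c(400L, 300L, 300L), ignore_attr = TRUE)
  # per-cell-type block-A sublists are pairwise disjoint by construction
  a <- prov[prov$block == "A:svc", ]
  expect_equal(anyDuplicated(a$feature_id), 0L)
  expect_equal(unname(table(a$contrast)), rep(100L, 4), ignore_attr = TRUE)
  b <- prov[prov$block == "B:dvc", ]
  expect_equal(unname(table(b$contrast)), rep(100L, 3), ignore_attr = TRUE)
  expect_length(intersect(a$feature_id, b$feature_id), 0)

  expect_error(select_rfdecd(tt$Y, tt$H[1:2, ], 100), "K >= 3")
})

test_that("hybrid allocation generalizes to K = 6 with cap trimming", {
  tt <- toy_truth(m = 2500, K = 6, n = 60, noise_sd = 0.3, seed = 67)
  fs <- select_rfdecd(tt$Y, tt$H, m_target = 1000)
  prov <- attr(fs, "provenance")
  expect_length(fs, 1000)
  counts <- table(prov$block)
  # 6 * round(400/6) = 402 trimmed to the 400 cap; D = 15, 15 * 20 = 300
  expect_equal(unname(counts[c("A:svc", "B:dvc", "C:pooled")]),
               c(400L, 300L, 300L), ignore_attr = TRUE)
  expect_equal(anyDuplicated(fs), 0L)
})

test_that("selection is deterministic and blocks stay disjoint under fuzz", {
  withr::with_seed(71, {
    for (i in 1:5) {
      K <- sample(3:5, 1)
      tt <- toy_truth(m = 400, K = K, n = 30, noise_sd = 0.5, seed = 70 + i)
      fs1 <- suppressWarnings(select_rfdecd(tt$Y, tt$H, m_target = 120))
      fs2 <- suppressWarnings(select_rfdecd(tt$Y, tt$H, m_target = 120))
      expect_identical(as.character(fs1), as.character(fs2))
      prov <- attr(fs1, "provenance")
      expect_equal(anyDuplicated(prov$feature_id), 0L)
    }
  })
})

test_that("marker enrichment: contrast selection beats variance selection", {
  # markers plus high-noise features that contaminate dispersion rankings;
  # enrichment = fraction of the selected set that is a planted marker
  truth <- sim_preset("expr4", m = 1200, n = 60, seed = 77)
  m_target <- 240
  marker_ids <- paste0("f", truth$markers$index)
  purity <- function(fs) mean(as.character(fs) %in% marker_ids)
  W_full <- project_full_profiles(truth$Y, truth$H_true)
  p_var <- purity(select_var_profiles(W_full, m_target))
  p_cv0 <- purity(select_cv_raw(truth$Y, m_target))
  p_svc <- purity(suppressWarnings(select_svc(truth$Y, truth$H_true, m_target)))
  p_dvc <- purity(suppressWarnings(select_dvc(truth$Y, truth$H_true, m_target)))
  p_rfd <- purity(suppressWarnings(select_rfdecd(truth$Y, truth$H_true, m_target)))
  expect_gt(p_svc, p_var)
  expect_gt(p_dvc, p_var)
  # the hybrid trades some purity for forced per-cell-type balance, but is
  # far more enriched than the raw-CV list it replaces
  expect_gt(p_rfd, p_cv0)
})
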