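# Feature-list construction for each of the six selection strategies.
#
# Variance/CV strategies rank features by dispersion (of the raw data at
# initialization, of the estimated cell-type profiles during iteration).
# The contrast-based strategies (SvC, DvC, PwD) rank features per comparison
# by differential p-value, take an oversampled per-comparison quota, and
# merge the lists round-robin with deduplication. The hybrid strategy
# combines SvC and DvC in three mutually exclusive blocks.

.feature_set <- function(ids, strategy, provenance = NULL) {
  if (anyDuplicated(ids)) stop("internal: duplicate features in a feature set")
  if (is.null(provenance)) {
    provenance <- data.frame(feature_id = ids, block = strategy,
                             contrast = NA_character_,
                             stringsAsFactors = FALSE)
  }
  structure(ids, strategy = strategy, provenance = provenance,
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d features (strategy %s)\n", length(x),
              attr(x, "strategy")))
  utils::str(unclass(x)[seq_len(min(6L, length(x)))])
  invisible(x)
}

#' Per-comparison candidate quota
#'
#' Each contrast contributes `ceiling((m_target / K) * 1.2)` ranked
#' candidates before merging: 1.2-fold oversampling leaves head-room for
#' features shared between comparisons that the deduplicating merge removes.
#' For the canonical `m_target = 1000`: 300 per comparison at `K = 4`, 400 at
#' `K = 3`, 200 at `K = 6`.
#'
#' @param m_target desired merged feature-list size.
#' @param K number of cell types.
#' @return integer quota.
#' @export
per_comparison_quota <- function(m_target, K) {
  if (m_target < K || K < 2L) stop("need m_target >= K >= 2")
  # tiny slack so exact multiples (e.g. 1000 * 1.2 / 6) do not ceil upward
  # from floating-point round-off
  as.integer(ceiling(m_target * 1.2 / K - 1e-9))
}

.rank_desc <- function(score) order(-score, seq_along(score))

.cv_scores <- function(M) {
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, stats::sd)
  ifelse(mu == 0, 0, sdv / mu)
}

#' Initial selection: top-CV features of the raw matrix
#'
#' Coefficient of variation per feature across samples (sample standard
#' deviation over mean; features with mean zero score 0), top `m_target`
#' in descending order.
#'
#' @param Y mixture matrix.
#' @param m_target number of features to select.
#' @return a `feature_set`.
#' @export
select_cv_raw <- function(Y, m_target) {
  if (m_target > nrow(Y)) stop("m_target exceeds the number of features")
  ids <- rownames(Y)[.rank_desc(.cv_scores(Y))[seq_len(m_target)]]
  .feature_set(ids, "cv0")
}

#' Profile-dispersion selection (VAR and CV strategies)
#'
#' Ranks every feature by the variance (or CV) of its estimated profile row
#' across the K cell types and keeps the top `m_target`. `W_hat` must cover
#' all features (see [project_full_profiles()]).
#'
#' @param W_hat m x K estimated profile matrix.
#' @param m_target number of features to select.
#' @return a `feature_set`.
#' @export
select_var_profiles <- function(W_hat, m_target) {
  if (m_target > nrow(W_hat)) stop("m_target exceeds the number of features")
  score <- apply(W_hat, 1L, stats::var)
  .feature_set(rownames(W_hat)[.rank_desc(score)[seq_len(m_target)]], "var")
}

#' @rdname select_var_profiles
#' @export
select_cv_profiles <- function(W_hat, m_target) {
  if (m_target > nrow(W_hat)) stop("m_target exceeds the number of features")
  .feature_set(rownames(W_hat)[.rank_desc(.cv_scores(W_hat))[seq_len(m_target)]],
               "cv")
}

#' Round-robin merge of ranked candidate lists
#'
#' Takes rank-1 candidates of every list first, then rank-2, and so on,
#' skipping features already claimed or listed in `exclude`, until `m_target`
#' features are collected. If the pooled candidates run out earlier, the
#' shorter set is returned with a warning.
#'
#' @param lists named list of character vectors, each internally
#'   duplicate-free and ordered by rank.
#' @param m_target number of features wanted.
#' @param exclude features that must not be selected.
#' @param strategy tag stored on the result.
#' @return a `feature_set` with per-feature provenance (source list).
#' @export
merge_ranked_lists <- function(lists, m_target, exclude = character(),
                               strategy = "merged") {
  for (l in lists) if (anyDuplicated(l)) stop("candidate lists must be duplicate-free")
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  # each turn a list contributes its highest-ranked not-yet-claimed candidate
  ptr <- rep(1L, length(lists))
  taken <- character(0)
  src <- character(0)
  repeat {
    progressed <- FALSE
    for (j in seq_along(lists)) {
      if (length(taken) >= m_target) break
      lj <- lists[[j]]
      while (ptr[j] <= length(lj) &&
             (lj[ptr[j]] %in% taken || lj[ptr[j]] %in% exclude)) {
        ptr[j] <- ptr[j] + 1L
      }
      if (ptr[j] > length(lj)) next
      taken <- c(taken, lj[ptr[j]])
      src <- c(src, names(lists)[j])
      ptr[j] <- ptr[j] + 1L
      progressed <- TRUE
    }
    if (length(taken) >= m_target || !progressed) break
  }
  if (length(taken) < m_target) {
    warning(sprintf("candidate pool exhausted: %d of %d features selected",
                    length(taken), m_target))
  }
  .feature_set(taken, strategy,
               data.frame(feature_id = taken, block = strategy, contrast = src,
                          stringsAsFactors = FALSE))
}

.ranked_lists <- function(tests, quota = NULL) {
  out <- list()
  for (j in seq_len(ncol(tests$p))) {
    ranked <- rank_features(tests$p[, j], tests$t[, j], rownames(tests$p),
                            estimate = tests$estimate[, j])
    out[[colnames(tests$p)[j]]] <-
      if (is.null(quota)) ranked else ranked[seq_len(min(quota, length(ranked)))]
  }
  out
}

.select_family <- function(Y, H, m_target, family) {
  K <- nrow(H)
  contrasts <- switch(family,
                      svc = svc_contrasts(K),
                      dvc = dvc_contrasts(K),
                      pwd = pwd_contrasts(K))
  tests <- test_all_features(Y, H, contrasts)
  q <- per_comparison_quota(m_target, K)
  merge_ranked_lists(.ranked_lists(tests, q), m_target, strategy = family)
}

#' Contrast-based selection strategies
#'
#' Runs the family's cross-cell-type contrasts over all features, ranks each
#' comparison by p-value, keeps [per_comparison_quota()] candidates per
#' comparison, and merges round-robin to `m_target` features.
#'
#' @param Y mixture matrix (all m features).
#' @param H current K x n proportion estimate.
#' @param m_target number of features to select.
#' @return a `feature_set`.
#' @export
select_svc <- function(Y, H, m_target) .select_family(Y, H, m_target, "svc")

#' @rdname select_svc
#' @export
select_dvc <- function(Y, H, m_target) .select_family(Y, H, m_target, "dvc")

#' @rdname select_svc
#' @export
select_pwd <- function(Y, H, m_target) .select_family(Y, H, m_target, "pwd")

# Claim features for each list in round-robin rank order so that no feature
# serves two lists; each list stops at `quota` claims. Returns claim records
# in claim order (used for cap trimming).
.round_robin_claim <- function(lists, quota, exclude = character()) {
  ptr <- rep(1L, length(lists))
  got <- rep(0L, length(lists))
  claimed <- character(0)
  rec_f <- character(0)
  rec_l <- character(0)
  repeat {
    progressed <- FALSE
    for (j in seq_along(lists)) {
      if (got[j] >= quota) next
      lj <- lists[[j]]
      while (ptr[j] <= length(lj) &&
             (lj[ptr[j]] %in% claimed || lj[ptr[j]] %in% exclude)) {
        ptr[j] <- ptr[j] + 1L
      }
      if (ptr[j] > length(lj)) next
      f <- lj[ptr[j]]
      ptr[j] <- ptr[j] + 1L
      claimed <- c(claimed, f)
      rec_f <- c(rec_f, f)
      rec_l <- c(rec_l, names(lists)[j])
      got[j] <- got[j] + 1L
      progressed <- TRUE
    }
    if (!progressed || all(got >= quota)) break
  }
  data.frame(feature_id = rec_f, contrast = rec_l, stringsAsFactors = FALSE)
}

#' Hybrid selection combining SvC and DvC
#'
#' Builds the feature list in three mutually exclusive blocks, generalizing
#' the canonical `K = 4`, `m_target = 1000` recipe (400 + 300 + 300) by a
#' 40/30/30 split:
#' \describe{
#'   \item{Block A (SvC)}{`round(0.4 * m_target / K)` features per cell type,
#'     claimed greedily in round-robin rank order so no feature serves two
#'     cell types; capped at `round(0.4 * m_target)` by trimming the
#'     last-claimed features when K does not divide the block size.}
#'   \item{Block B (DvC)}{`round(0.3 * m_target / D)` features per distinct
#'     dual-vs-composite comparison (`D = length(dvc_contrasts(K))`),
#'     excluding Block A, pairwise disjoint, capped analogously.}
#'   \item{Block C (pooled)}{the remaining features from the joint SvC + DvC
#'     p-value ranking (a feature's score is its smallest p across all
#'     contrasts), excluding blocks A and B.}
#' }
#'
#' @inheritParams select_svc
#' @return a `feature_set` whose provenance records block and contrast.
#' @export
select_rfdecd <- function(Y, H, m_target) {
  K <- nrow(H)
  if (K < 3L) stop("the hybrid strategy needs K >= 3 (it uses DvC)")
  svc_tests <- test_all_features(Y, H, svc_contrasts(K))
  dvc_tests <- test_all_features(Y, H, dvc_contrasts(K))

  cap_a <- round(0.4 * m_target)
  q_a <- round(cap_a / K)
  a <- .round_robin_claim(.ranked_lists(svc_tests), q_a)
  if (nrow(a) > cap_a) a <- a[seq_len(cap_a), , drop = FALSE]   # trim last-claimed

  D <- ncol(dvc_tests$p)
  cap_b <- round(0.3 * m_target)
  q_b <- round(cap_b / D)
  b <- .round_robin_claim(.ranked_lists(dvc_tests), q_b,
                          exclude = a$feature_id)
  if (nrow(b) > cap_b) b <- b[seq_len(cap_b), , drop = FALSE]

  # pooled ranking: per feature, the smallest p (ties: largest |t|) over all
  # SvC and DvC contrasts
  pool_p <- pmin(apply(svc_tests$p, 1L, min), apply(dvc_tests$p, 1L, min))
  pool_t <- pmax(apply(abs(svc_tests$t), 1L, max), apply(abs(dvc_tests$t), 1L, max))
  pooled <- rank_features(pool_p, pool_t, rownames(svc_tests$p))
  used <- c(a$feature_id, b$feature_id)
  c_ids <- setdiff(pooled, used)
  n_c <- m_target - length(used)
  if (length(c_ids) < n_c) {
    warning(sprintf("candidate pool exhausted: %d of %d features selected",
                    length(used) + length(c_ids), m_target))
    n_c <- length(c_ids)
  }
  c_ids <- c_ids[seq_len(n_c)]

  prov <- rbind(
    data.frame(feature_id = a$feature_id, block = "A:svc",
               contrast = a$contrast, stringsAsFactors = FALSE),
    data.frame(feature_id = b$feature_id, block = "B:dvc",
               contrast = b$contrast, stringsAsFactors = FALSE),
    data.frame(feature_id = c_ids, block = "C:pooled",
               contrast = NA_character_, stringsAsFactors = FALSE)
  )
  .feature_set(prov$feature_id, "rfdecd", prov)
}
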