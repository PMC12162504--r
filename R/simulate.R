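# Synthetic mixtures: Dirichlet proportions, log-normal / beta profiles,
# linear mixing with small Gaussian noise.
#
# Proportions come from Dirichlet distributions whose parameters reproduce
# realistic blood-like compositions: alpha = (0.968, 4.706, 0.496, 0.347) for
# four cell types and (0.89, 4.12, 0.47, 0.33, 0.61, 1.02) for six. Profiles
# are drawn per feature and cell type from a log-normal (expression
# intensities) or a beta distribution (methylation beta-values). A tunable
# fraction of features is planted as cell-type-specific markers: their
# location parameter is shifted in one randomly chosen cell type, which is
# what the contrast-based selection strategies are designed to find. Mixing
# is linear on the measurement scale, Y = W H + noise.
#
# A second tunable fraction of features is "noisy": their measurement noise
# is inflated by `noisy_scale`. This emulates the within-cell-type /
# technical variability of real arrays that makes raw-variance feature
# ranking misleading — high-CV features need not be cell-type informative —
# and is what separates the contrast-based selection strategies from
# variance-based ones (good deconvolution features have low within-type and
# high cross-type variation).

.DIRICHLET_4 <- c(0.968, 4.706, 0.496, 0.347)
.DIRICHLET_6 <- c(0.89, 4.12, 0.47, 0.33, 0.61, 1.02)

.maybe_seed <- function(seed, expr) {
  f <- function() expr
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

#' Draw proportion columns from a Dirichlet distribution
#'
#' Uses the standard gamma construction: each column is a vector of
#' independent `Gamma(alpha_k, 1)` draws normalized to sum to one, giving
#' `Dirichlet(alpha)` with mean `alpha / sum(alpha)`.
#'
#' @param n number of samples (columns).
#' @param alpha positive Dirichlet parameter vector (length K).
#' @param seed optional integer seed.
#' @return K x n `proportion_matrix`.
#' @export
draw_proportions <- function(n, alpha, seed = NULL) {
  if (any(alpha <= 0)) stop("Dirichlet parameters must be positive")
  K <- length(alpha)
  H <- .maybe_seed(seed, {
    G <- matrix(stats::rgamma(K * n, shape = alpha, rate = 1), K, n)
    sweep(G, 2, colSums(G), "/")
  })
  dimnames(H) <- list(paste0("C", seq_len(K)), paste0("s", seq_len(n)))
  .as_proportions(H)
}

.plant_markers <- function(m, K, cts_fraction) {
  n_mark <- round(cts_fraction * m)
  if (n_mark == 0L) {
    return(list(index = integer(0), cell_type = integer(0), sign = numeric(0)))
  }
  idx <- sample.int(m, n_mark)
  ct <- sample.int(K, n_mark, replace = TRUE)
  sg <- sample(c(-1, 1), n_mark, replace = TRUE)
  ord <- order(idx)
  list(index = idx[ord], cell_type = ct[ord], sign = sg[ord])
}

#' Profile priors for simulated expression data
#'
#' Baseline log-mean per feature is `Normal(6, 1.5^2)` (shared across cell
#' types) with log-sd 0.3, mimicking microarray-scale intensities. A
#' `cts_fraction` subset of features becomes cell-type-specific markers: one
#' randomly chosen cell type's log-mean is shifted by `+/- effect_size`.
#'
#' @param m number of features.
#' @param K number of cell types.
#' @param cts_fraction fraction of features planted as markers.
#' @param effect_size marker shift on the log scale.
#' @param noisy_fraction fraction of features with inflated measurement
#'   noise (see [mix_mixture()]).
#' @param noisy_scale noise-sd multiplier for the noisy features.
#' @param seed optional integer seed.
#' @return object of class `profile_priors` (mode `"expression"`).
#' @export
make_expression_priors <- function(m, K, cts_fraction = 0.2, effect_size = 2,
                                   noisy_fraction = 0.3, noisy_scale = 20,
                                   seed = NULL) {
  if (cts_fraction < 0 || cts_fraction > 1) stop("cts_fraction must be in [0,1]")
  if (noisy_fraction < 0 || noisy_fraction > 1) stop("noisy_fraction must be in [0,1]")
  pri <- .maybe_seed(seed, {
    base <- stats::rnorm(m, mean = 6, sd = 1.5)
    mu <- matrix(base, m, K)
    mk <- .plant_markers(m, K, cts_fraction)
    if (length(mk$index) > 0L) {
      mu[cbind(mk$index, mk$cell_type)] <-
        mu[cbind(mk$index, mk$cell_type)] + mk$sign * effect_size
    }
    ns <- rep(1, m)
    if (noisy_fraction > 0) {
      ns[sample.int(m, round(noisy_fraction * m))] <- noisy_scale
    }
    list(mu = mu, mk = mk, ns = ns)
  })
  structure(list(mode = "expression", meanlog = pri$mu, sdlog = 0.3,
                 markers = pri$mk, noise_scale = pri$ns,
                 cts_fraction = cts_fraction, effect_size = effect_size,
                 noisy_fraction = noisy_fraction, noisy_scale = noisy_scale,
                 m = m, K = K),
            class = "profile_priors")
}

# beta shapes from mean and common precision: a = mu * nu, b = (1 - mu) * nu
.beta_shapes <- function(mu, precision) {
  list(shape1 = mu * precision, shape2 = (1 - mu) * precision)
}

#' Profile priors for simulated methylation data
#'
#' Baseline mean beta-value per feature is drawn from an equal mixture of
#' `Beta(2, 8)` (hypomethylated), `Beta(8, 2)` (hypermethylated) and
#' `Beta(5, 5)` (intermediate) CpG classes. Markers shift the mean by
#' `+/- effect_size` in one random cell type, clamped to \[0.02, 0.98\].
#' Per-entry beta shapes are recovered by method of moments with a common
#' precision (`shape1 + shape2`, default 50).
#'
#' @inheritParams make_expression_priors
#' @param precision common beta precision `shape1 + shape2`.
#' @return object of class `profile_priors` (mode `"methylation"`).
#' @export
make_methylation_priors <- function(m, K, cts_fraction = 0.2,
                                    effect_size = 0.4, precision = 50,
                                    noisy_fraction = 0.3, noisy_scale = 10,
                                    seed = NULL) {
  if (cts_fraction < 0 || cts_fraction > 1) stop("cts_fraction must be in [0,1]")
  if (noisy_fraction < 0 || noisy_fraction > 1) stop("noisy_fraction must be in [0,1]")
  pri <- .maybe_seed(seed, {
    comp <- sample.int(3L, m, replace = TRUE)
    base <- c(stats::rbeta(m, 2, 8), stats::rbeta(m, 8, 2),
              stats::rbeta(m, 5, 5))[(comp - 1L) * m + seq_len(m)]
    mu <- matrix(base, m, K)
    mk <- .plant_markers(m, K, cts_fraction)
    if (length(mk$index) > 0L) {
      shifted <- mu[cbind(mk$index, mk$cell_type)] + mk$sign * effect_size
      mu[cbind(mk$index, mk$cell_type)] <- pmin(pmax(shifted, 0.02), 0.98)
    }
    ns <- rep(1, m)
    if (noisy_fraction > 0) {
      ns[sample.int(m, round(noisy_fraction * m))] <- noisy_scale
    }
    list(mu = pmin(pmax(mu, 0.02), 0.98), mk = mk, ns = ns)
  })
  sh <- .beta_shapes(pri$mu, precision)
  structure(list(mode = "methylation", shape1 = sh$shape1, shape2 = sh$shape2,
                 mean = pri$mu, precision = precision, markers = pri$mk,
                 noise_scale = pri$ns, cts_fraction = cts_fraction,
                 effect_size = effect_size, noisy_fraction = noisy_fraction,
                 noisy_scale = noisy_scale, m = m, K = K),
            class = "profile_priors")
}

#' Draw a cell-type profile matrix from priors
#'
#' Independent draw per (feature, cell type): log-normal for expression,
#' beta for methylation.
#'
#' @param priors a `profile_priors` object.
#' @param seed optional integer seed.
#' @return m x K `profile_matrix` respecting the mode's domain.
#' @export
draw_profiles <- function(priors, seed = NULL) {
  m <- priors$m
  K <- priors$K
  W <- .maybe_seed(seed, {
    if (priors$mode == "expression") {
      matrix(stats::rlnorm(m * K, meanlog = priors$meanlog,
                           sdlog = priors$sdlog), m, K)
    } else {
      matrix(stats::rbeta(m * K, priors$shape1, priors$shape2), m, K)
    }
  })
  dimnames(W) <- list(paste0("f", seq_len(m)), paste0("C", seq_len(K)))
  structure(W, mode = priors$mode,
            class = c("profile_matrix", "matrix", "array"))
}

#' Mix profiles and proportions into a bulk matrix
#'
#' `Y = W H + eps` with independent Gaussian noise, `eps_ps ~
#' Normal(0, (noise_sd * noise_scale_p)^2)`. Defaults: sd 0.01 on the
#' methylation beta scale, `0.05 * median(|W H|)` for expression ("small"
#' relative noise); `noise_scale` defaults to 1 for every feature
#' (homoscedastic). The noisy matrix is clamped to the mode's domain
#' (\[0, 1\] or non-negative); the noiseless truth is never clamped.
#'
#' @param W_true m x K profile matrix (with a `mode` attribute).
#' @param H_true K x n proportion matrix.
#' @param noise_sd Gaussian noise standard deviation; `NULL` for the
#'   mode-specific default.
#' @param noise_scale length-m per-feature noise-sd multiplier (scalar 1 for
#'   homoscedastic noise); priors built with a positive `noisy_fraction`
#'   carry the matching vector in their `noise_scale` field.
#' @param seed optional integer seed.
#' @param mode data mode; defaults to the `mode` attribute of `W_true`.
#' @return a `mixture_matrix`.
#' @export
mix_mixture <- function(W_true, H_true, noise_sd = NULL, noise_scale = 1,
                        seed = NULL, mode = NULL) {
  mode <- .mode_of(W_true, mode)
  M <- W_true %*% H_true
  if (is.null(noise_sd)) {
    noise_sd <- if (mode == "methylation") 0.01 else 0.05 * stats::median(abs(M))
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!length(noise_scale) %in% c(1L, nrow(M))) {
    stop("noise_scale must be scalar or one value per feature")
  }
  Y <- .maybe_seed(seed, M + matrix(stats::rnorm(length(M)),
                                    nrow(M), ncol(M)) * (noise_sd * noise_scale))
  Y <- if (mode == "methylation") pmin(pmax(Y, 0), 1) else pmax(Y, 0)
  dimnames(Y) <- list(rownames(W_true), colnames(H_true))
  mixture_matrix(Y, mode)
}

#' Estimate profile priors from a purified reference matrix
#'
#' For each feature and replicate group: sample mean and variance of the
#' log-values (expression) or method-of-moments beta shapes from the mean and
#' variance of the beta-values (methylation). Pseudo-cell-types are formed by
#' listing several purified types' replicate columns under one group name
#' (their replicates are pooled before estimation).
#'
#' @param ref features x replicates numeric matrix.
#' @param replicate_groups named list mapping group (cell-type) names to the
#'   column names/indices of their replicates; every group needs >= 2.
#' @param mode `"expression"` or `"methylation"`.
#' @param log_transform for expression, whether `ref` is on the linear scale
#'   and should be logged first (default `TRUE`).
#' @param var_floor lower bound applied to per-feature variances so that
#'   degenerate (identical-replicate) features keep a positive scale.
#' @return a `profile_priors` object.
#' @export
estimate_priors_from_reference <- function(ref, replicate_groups,
                                           mode = c("expression", "methylation"),
                                           log_transform = TRUE,
                                           var_floor = 1e-8) {
  mode <- match.arg(mode)
  ref <- as.matrix(ref)
  K <- length(replicate_groups)
  if (is.null(names(replicate_groups))) {
    names(replicate_groups) <- paste0("C", seq_len(K))
  }
  m <- nrow(ref)
  mu <- vr <- matrix(NA_real_, m, K,
                     dimnames = list(rownames(ref), names(replicate_groups)))
  for (k in seq_len(K)) {
    cols <- replicate_groups[[k]]
    sub <- ref[, cols, drop = FALSE]
    if (ncol(sub) < 2L) {
      stop("group '", names(replicate_groups)[k], "' has fewer than 2 replicates")
    }
    if (mode == "expression" && log_transform) sub <- log(sub)
    mu[, k] <- rowMeans(sub)
    vr[, k] <- pmax(apply(sub, 1L, stats::var), var_floor)
  }
  if (mode == "expression") {
    structure(list(mode = "expression", meanlog = mu, sdlog = sqrt(vr),
                   markers = NULL, cts_fraction = NA_real_,
                   effect_size = NA_real_, m = m, K = K),
              class = "profile_priors")
  } else {
    # method of moments: nu = mu(1-mu)/var - 1; floor keeps shapes positive
    mu_c <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    nu <- pmax(mu_c * (1 - mu_c) / vr - 1, 1e-3)
    structure(list(mode = "methylation", shape1 = mu_c * nu,
                   shape2 = (1 - mu_c) * nu, mean = mu_c, precision = nu,
                   markers = NULL, cts_fraction = NA_real_,
                   effect_size = NA_real_, m = m, K = K),
              class = "profile_priors")
  }
}

#' Canonical simulation presets
#'
#' Full synthetic study conditions:
#' \describe{
#'   \item{`expr4`}{expression, K = 4, Dirichlet alpha
#'     (0.968, 4.706, 0.496, 0.347), n = 100, m = 5000 (desk-scaled from a
#'     54,675-probe array while keeping markers rare relative to features).}
#'   \item{`meth4`}{methylation, K = 4, same alpha, n = 100, m = 10000
#'     (desk-scaled from 459,226 CpGs).}
#'   \item{`meth6`}{methylation, K = 6, alpha
#'     (0.89, 4.12, 0.47, 0.33, 0.61, 1.02), n in 50/100/200 (default 100).}
#' }
#'
#' @param name preset name.
#' @param n number of samples; `NULL` for the preset default.
#' @param m number of features; `NULL` for the preset default (override to
#'   run at full array scale).
#' @param seed integer seed; the whole truth object is reproducible from it.
#' @param cts_fraction,effect_size,noise_sd forwarded to the prior and mixing
#'   generators; `NULL` keeps the mode defaults.
#' @return object of class `sim_truth`: list with `Y`, `W_true`, `H_true`,
#'   `alpha`, `noise_sd`, `markers`, `mode`, `seed`.
#' @examples
#' truth <- sim_preset("meth4", m = 500, n = 40, seed = 7)
#' truth
#' range(truth$Y)                       # beta-value domain
#' rowMeans(truth$H_true)               # close to alpha / sum(alpha)
#' @export
sim_preset <- function(name = c("expr4", "meth4", "meth6"), n = NULL, m = NULL,
                       seed = 1L, cts_fraction = 0.2, effect_size = NULL,
                       noise_sd = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    expr4 = list(mode = "expression", K = 4L, alpha = .DIRICHLET_4, m = 5000L,
                 n = 100L),
    meth4 = list(mode = "methylation", K = 4L, alpha = .DIRICHLET_4,
                 m = 10000L, n = 100L),
    meth6 = list(mode = "methylation", K = 6L, alpha = .DIRICHLET_6,
                 m = 10000L, n = 100L))
  if (!is.null(n)) cfg$n <- as.integer(n)
  if (!is.null(m)) cfg$m <- as.integer(m)
  withr::with_seed(seed, {
    priors <- if (cfg$mode == "expression") {
      make_expression_priors(cfg$m, cfg$K, cts_fraction = cts_fraction,
                             effect_size = if (is.null(effect_size)) 2 else effect_size)
    } else {
      make_methylation_priors(cfg$m, cfg$K, cts_fraction = cts_fraction,
                              effect_size = if (is.null(effect_size)) 0.4 else effect_size)
    }
    W <- draw_profiles(priors)
    H <- draw_proportions(cfg$n, cfg$alpha)
    Y <- mix_mixture(W, H, noise_sd = noise_sd,
                     noise_scale = priors$noise_scale)
    used_sd <- if (is.null(noise_sd)) {
      if (cfg$mode == "methylation") 0.01 else 0.05 * stats::median(abs(W %*% H))
    } else noise_sd
    structure(list(Y = Y, W_true = W, H_true = H, alpha = cfg$alpha,
                   noise_sd = used_sd, noise_scale = priors$noise_scale,
                   markers = priors$markers, mode = cfg$mode, preset = name,
                   seed = seed),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Synthetic mixture '%s': %d features x %d samples, K = %d (%s)\n",
              x$preset, nrow(x$Y), ncol(x$Y), nrow(x$H_true), x$mode))
  cat(sprintf("  noise sd %.4g, %d planted markers, seed %d\n", x$noise_sd,
              length(x$markers$index), x$seed))
  invisible(x)
}
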