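# Exact small-K constrained least squares, shared design, many right-hand sides.
#
# All three constrained problems used by the factorization engine reduce to
#   min_x  x' AtA x - 2 x' atb   (+ const)
# over one of
#   x >= lo                      (non-negative profiles, expression mode)
#   lo <= x <= hi                (box profiles, methylation mode)
#   x >= 0, sum(x) = s           (simplex proportions)
# with K small (number of cell types). The global minimum of a convex
# quadratic under these constraints lies on one of the faces obtained by
# fixing each variable at a bound or leaving it free; on the optimal face the
# free variables satisfy the unconstrained (or equality-constrained) normal
# equations. Enumerating all faces, solving each face once for every
# right-hand side (batched), and keeping the feasible candidate with the
# smallest objective is therefore exact. A pre-pass solves the unconstrained
# (or equality-only) problem for all columns at once; columns already feasible
# are optimal and skip enumeration. Ties (e.g. duplicate design columns) are
# resolved toward the minimum-norm solution via a pseudo-inverse face solve.

# upper bound keeping 3^K face enumeration tractable
.K_MAX <- 8L

.solve_or_ginv <- function(M, B) {
  tryCatch(solve(M, B), error = function(e) MASS::ginv(M) %*% B)
}

#' @noRd
#' @param AtA K x K cross-product of the design
#' @param AtB K x r matrix of design' %*% rhs, one column per problem
#' @param lower,upper scalar bounds on every variable
#' @param sum_to if non-NULL, equality constraint sum(x) = sum_to (with
#'   lower bound only; upper must be Inf)
#' @return K x r matrix of minimizers
cls_solve_multi <- function(AtA, AtB, lower = 0, upper = Inf, sum_to = NULL) {
  K <- nrow(AtA)
  if (K > .K_MAX) {
    stop("constrained solver supports at most ", .K_MAX, " cell types (got ",
         K, ")")
  }
  if (!is.null(sum_to) && is.finite(upper)) {
    stop("simplex mode does not combine with a finite upper bound")
  }
  .cls_solve_cpp(AtA, AtB, lower, upper, !is.null(sum_to),
                 if (is.null(sum_to)) 0 else sum_to)
}

# Pure-R reference implementation of the same face enumeration; retained as
# an independent slow path for cross-checking the compiled solver.
.cls_solve_r <- function(AtA, AtB, lower = 0, upper = Inf, sum_to = NULL,
                         feas_tol = 1e-9) {
  K <- nrow(AtA)
  r <- ncol(AtB)
  if (K > .K_MAX) {
    stop("constrained solver supports at most ", .K_MAX, " cell types (got ",
         K, ")")
  }
  if (!is.null(sum_to) && is.finite(upper)) {
    stop("simplex mode does not combine with a finite upper bound")
  }

  # rescale so the quadratic term is O(1): keeps the bordered KKT systems
  # (whose equality rows are 1s) well conditioned on large-intensity data;
  # the minimizer is scale-invariant
  sc <- max(diag(AtA))
  if (is.finite(sc) && sc > 0) {
    AtA <- AtA / sc
    AtB <- AtB / sc
  }

  X <- matrix(NA_real_, K, r)
  obj <- function(x, cols) {
    # objective up to the constant ||b||^2, per column
    colSums(x * (AtA %*% x)) - 2 * colSums(x * AtB[, cols, drop = FALSE])
  }

  # ---- pre-pass: unconstrained / equality-only solution -------------------
  if (is.null(sum_to)) {
    x0 <- .solve_or_ginv(AtA, AtB)
  } else {
    M <- rbind(cbind(2 * AtA, rep(1, K)), c(rep(1, K), 0))
    rhs <- rbind(2 * AtB, rep(sum_to, r))
    x0 <- .solve_or_ginv(M, rhs)[seq_len(K), , drop = FALSE]
  }
  ok <- colSums(x0 < lower - feas_tol) == 0 &
    colSums(x0 > upper + feas_tol) == 0
  X[, ok] <- x0[, ok]
  todo <- which(!ok)
  if (length(todo) == 0L) {
    return(.cls_clamp(X, lower, upper, sum_to, feas_tol))
  }

  # ---- face enumeration for the remaining columns -------------------------
  states <- if (is.finite(upper)) 3L else 2L   # free / at-lower (/ at-upper)
  grid <- as.matrix(expand.grid(rep(list(seq_len(states) - 1L), K)))
  best_obj <- rep(Inf, length(todo))
  best_norm <- rep(Inf, length(todo))
  Xt <- matrix(NA_real_, K, length(todo))
  AtBt <- AtB[, todo, drop = FALSE]

  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    free <- which(st == 0L)
    nf <- length(free)
    if (!is.null(sum_to) && nf == 0L) next   # sum constraint needs a free var
    fixed <- rep(0, K)
    fixed[st == 2L] <- upper
    if (!is.null(sum_to) && sum(fixed) > sum_to + feas_tol) next

    cand <- matrix(rep(fixed, length(todo)), K, length(todo))
    if (nf > 0L) {
      # normal equations on the face; fixed vars shift the rhs
      rhs <- AtBt[free, , drop = FALSE] -
        as.vector(AtA[free, st != 0L, drop = FALSE] %*% fixed[st != 0L])
      if (is.null(sum_to)) {
        sol <- .solve_or_ginv(AtA[free, free, drop = FALSE], rhs)
      } else {
        M <- rbind(cbind(2 * AtA[free, free, drop = FALSE], rep(1, nf)),
                   c(rep(1, nf), 0))
        rhs2 <- rbind(2 * rhs, rep(sum_to - sum(fixed), length(todo)))
        sol <- .solve_or_ginv(M, rhs2)[seq_len(nf), , drop = FALSE]
      }
      cand[free, ] <- sol
    }

    feas <- colSums(cand < lower - feas_tol) == 0 &
      colSums(cand > upper + feas_tol) == 0
    if (!any(feas)) next
    o <- obj(cand, todo)
    nrm <- colSums(cand^2)
    better <- feas & (o < best_obj - 1e-12 |
                        (abs(o - best_obj) <= 1e-12 & nrm < best_norm))
    if (any(better)) {
      Xt[, better] <- cand[, better]
      best_obj[better] <- o[better]
      best_norm[better] <- nrm[better]
    }
  }
  if (anyNA(Xt)) stop("constrained solver found no feasible face (internal)")
  X[, todo] <- Xt
  .cls_clamp(X, lower, upper, sum_to, feas_tol)
}

# snap round-off onto the bounds; renormalize simplex columns
.cls_clamp <- function(X, lower, upper, sum_to, feas_tol) {
  if (min(X) < lower - 1e-8 || max(X) > upper + 1e-8) {
    stop("constrained solver produced an infeasible solution (internal)")
  }
  X[X < lower] <- lower
  if (is.finite(upper)) X[X > upper] <- upper
  if (!is.null(sum_to)) {
    X <- sweep(X, 2, colSums(X) / sum_to, "/")
  }
  X
}
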