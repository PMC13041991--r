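#' Contiguous cross-validation folds over the time axis
#'
#' Splits `1:n_timepoints` into `k` contiguous, non-overlapping blocks whose
#' sizes differ by at most one; any remainder is given to the earliest folds.
#' Contiguous blocks keep temporally autocorrelated samples together, so
#' held-out blocks are closer to independent than random folds would be.
#'
#' @param n_timepoints Number of timepoints (>= k).
#' @param k Number of folds (>= 2).
#' @return List of `k` integer index vectors partitioning the time axis.
#' @export
make_folds <- function(n_timepoints, k) {
  stopifnot(k >= 2)
  if (k > n_timepoints) stop("k exceeds the number of timepoints")
  sizes <- rep(n_timepoints %/% k, k)
  rem <- n_timepoints %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(i) seq.int(starts[i], ends[i]))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' mean of the evaluated segment of the observed series. Can be negative when
#' the prediction is worse than the segment mean.
#'
#' @param predicted,observed Numeric vectors of equal length (>= 2).
#' @return Scalar R^2, or `NA` with a warning when `observed` is constant.
#' @export
score_r2 <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot < 1e-24) {
    warning("observed series is constant; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

## ---- simplex-constrained stacking QP -------------------------------------

#' Solve min ||y - P a||^2 s.t. a >= 0, sum(a) = 1
#'
#' Exact active-set solution by support enumeration: for every nonempty
#' support the equality-constrained KKT system is solved and primal/dual
#' feasibility checked. A tiny ridge term pulling toward the uniform vector
#' (1e-10 x the scale of P'P) makes the objective strictly convex, which
#' both guarantees a unique optimum and implements the documented tie-break:
#' when several weight vectors fit equally well (e.g. identical predictions),
#' the uniform one is returned.
#'
#' @param P Time-by-K matrix of base-model predictions.
#' @param y Observed response vector.
#' @return Numeric weight vector of length K on the probability simplex.
#' @keywords internal
solve_simplex_qp <- function(P, y) {
  K <- ncol(P)
  Q <- crossprod(P)
  cc <- drop(crossprod(P, y))
  eps <- 1e-10 * (mean(diag(Q)) + 1)
  Qe <- Q + diag(eps, K)
  ce <- cc + eps / K
  tol <- 1e-9 * (mean(diag(Qe)) + 1)
  best <- NULL
  for (size in K:1) {
    for (S in utils::combn(K, size, simplify = FALSE)) {
      m <- length(S)
      A <- rbind(cbind(2 * Qe[S, S, drop = FALSE], rep(1, m)),
                 c(rep(1, m), 0))
      b <- c(2 * ce[S], 1)
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      a_S <- sol[seq_len(m)]
      mu <- sol[m + 1]
      if (any(a_S < -1e-9)) next
      alpha <- numeric(K)
      alpha[S] <- a_S
      # dual feasibility for inactive coordinates
      nu <- 2 * (Qe %*% alpha - ce) + mu
      if (any(nu[-S] < -tol) && size < K) next
      best <- alpha
      break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    warning("simplex QP enumeration failed; falling back to grid search")
    best <- simplex_grid_search(P, y, step = 0.005)
  }
  best <- pmax(best, 0)
  best / sum(best)
}

#' Exhaustive grid search over the probability simplex
#'
#' Brute-force minimizer of `||y - P a||^2` over a regular grid on the
#' simplex, used as fallback and as an independent oracle for the QP solver.
#'
#' @param P Time-by-K prediction matrix.
#' @param y Response vector.
#' @param step Grid resolution.
#' @return Weight vector on the simplex grid minimizing the objective.
#' @export
simplex_grid_search <- function(P, y, step = 0.005) {
  K <- ncol(P)
  n_steps <- round(1 / step)
  grid <- simplex_grid_points(K, n_steps) / n_steps
  resid2 <- colSums((y - P %*% t(grid))^2)
  grid[which.min(resid2), ]
}

# integer compositions of n into K nonnegative parts (rows)
simplex_grid_points <- function(K, n) {
  if (K == 1) return(matrix(n, 1, 1))
  out <- vector("list", n + 1)
  for (i in 0:n) {
    rest <- simplex_grid_points(K - 1, n - i)
    out[[i + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

#' Combine base-model predictions with simplex-constrained stacking weights
#'
#' Finds the convex combination of per-feature-space held-out predictions
#' closest (least squares) to the observed response: nonnegative weights
#' summing to one, solved exactly as a quadratic program. Predictions and
#' response are centered first; by default each prediction series is also
#' scaled to unit variance so the weights are interpretable as mixing
#' proportions rather than being confounded with prediction amplitude.
#'
#' @param heldout_predictions Named list (>= 2) of per-space prediction
#'   vectors sharing the time axis, or a time-by-K matrix.
#' @param observed Observed response vector.
#' @param scale_predictions Scale each prediction series to unit SD before
#'   solving (default `TRUE`).
#' @return List with `alpha` (named simplex weights), `stacked_prediction`
#'   (on the scale of `observed`), and `r2` (stacked R^2 on this segment).
#' @export
stack_models <- function(heldout_predictions, observed,
                         scale_predictions = TRUE) {
  P <- if (is.list(heldout_predictions)) {
    do.call(cbind, heldout_predictions)
  } else {
    as.matrix(heldout_predictions)
  }
  if (ncol(P) < 2) stop("stacking needs at least two feature spaces")
  if (nrow(P) != length(observed)) stop("time axes do not match")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  s <- rep(1, ncol(P))
  if (scale_predictions) {
    s <- apply(Pc, 2, stats::sd)
    s[s < 1e-12] <- 1
    Pc <- sweep(Pc, 2, s, "/")
  }
  yc <- observed - mean(observed)
  alpha <- solve_simplex_qp(Pc, yc)
  names(alpha) <- colnames(P)
  pred <- mean(observed) + drop(Pc %*% alpha)
  list(alpha = alpha, stacked_prediction = pred,
       r2 = score_r2(pred, observed), scale = s)
}

## ---- ridge engine --------------------------------------------------------

# Fit ridge on (Xtr, Ytr) and predict Xte for every lambda in one SVD pass.
# X is centered on the training block; responses are centered per column and
# the training mean added back to predictions (unpenalized intercept).
# Returns a list over lambdas of Tte x G prediction matrices.
ridge_path_predict <- function(Xtr, Ytr, Xte, lambdas) {
  xm <- colMeans(Xtr)
  ym <- colMeans(Ytr)
  Xc <- sweep(Xtr, 2, xm)
  Yc <- sweep(Ytr, 2, ym)
  Xte_c <- sweep(Xte, 2, xm)
  sv <- svd(Xc)
  UtY <- crossprod(sv$u, Yc)            # p' x G
  XteV <- Xte_c %*% sv$v                # Tte x p'
  lapply(lambdas, function(lam) {
    shrink <- sv$d / (sv$d^2 + lam)
    sweep(XteV %*% (shrink * UtY), 2, ym, "+")
  })
}

# ridge coefficients (including intercept handling) for one lambda per column
ridge_coefs <- function(Xtr, Ytr, lambda) {
  xm <- colMeans(Xtr)
  ym <- colMeans(Ytr)
  Xc <- sweep(Xtr, 2, xm)
  Yc <- sweep(Ytr, 2, ym)
  sv <- svd(Xc)
  shrink <- sv$d / (sv$d^2 + lambda)
  beta <- sv$v %*% (shrink * crossprod(sv$u, Yc))
  list(beta = beta, intercept = ym - drop(crossprod(beta, xm)))
}

#' Default ridge penalty grid
#' @param n Number of grid points.
#' @return Log-spaced penalties from 1e-2 to 1e5.
#' @export
default_lambda_grid <- function(n = 20) 10^seq(-2, 5, length.out = n)

#' Cross-validated ridge fit for a single response series
#'
#' For each outer fold the penalty is selected by inner cross-validation on
#' the training block only, coefficients are fit on the training block, and
#' predictions are emitted for the held-out block; concatenated held-out
#' predictions cover every timepoint exactly once.
#'
#' @param design A [feature_matrix()] or numeric time-by-feature matrix.
#' @param response Numeric response vector on the same time axis.
#' @param folds Outer folds from [make_folds()]; default 5 folds.
#' @param penalty_grid Positive penalty grid; default [default_lambda_grid()].
#' @param k_inner Number of inner folds for penalty selection (default 4).
#' @return List with `heldout` (predictions, full length), `r2` (held-out
#'   R^2), `lambda` (selected penalty per outer fold), and `coefficients`
#'   (per-fold coefficient vectors).
#' @export
fit_ridge_cv <- function(design, response, folds = NULL,
                         penalty_grid = default_lambda_grid(),
                         k_inner = 4) {
  X <- if (inherits(design, "feature_matrix")) design$values else
    as.matrix(design)
  if (nrow(X) != length(response)) stop("design and response time axes differ")
  if (length(penalty_grid) == 0 || any(penalty_grid <= 0)) {
    stop("penalty_grid must be nonempty and positive")
  }
  if (stats::sd(response) < 1e-12) {
    warning("zero-variance response; fit undefined")
    return(list(heldout = rep(NA_real_, length(response)), r2 = NA_real_,
                lambda = NULL, coefficients = NULL, flagged = TRUE))
  }
  if (is.null(folds)) folds <- make_folds(length(response), 5)
  fit <- fit_encoding(list(space = X), matrix(response, nrow = 1),
                      folds = folds, penalty_grid = penalty_grid,
                      k_inner = k_inner, return_predictions = TRUE)
  list(heldout = fit$pred_space[["space"]][, 1],
       r2 = fit$r2_space[1, "space"],
       lambda = fit$lambda[1, "space", ],
       coefficients = fit$coefficients[["space"]],
       flagged = FALSE)
}

#' Fit stacked ridge encoding models for many grayordinates at once
#'
#' The full per-grayordinate procedure, vectorized over grayordinates. Within
#' each outer training block: (i) an inner cross-validation selects the ridge
#' penalty per grayordinate and feature space; (ii) inner out-of-fold
#' predictions at the selected penalty provide the stacking-training data, on
#' which the simplex-constrained weights are solved, so the stacking stage
#' never sees its own evaluation data; (iii) base models are refit on the
#' whole training block and combined with those weights on the outer held-out
#' block. Held-out R^2 (per space and stacked) uses the concatenated outer
#' test predictions; reported weights are averaged over outer folds (a convex
#' combination of simplex points, hence still on the simplex).
#'
#' @param designs Named list of [feature_matrix()] objects or time-by-feature
#'   matrices, one per feature space, sharing the time axis.
#' @param bold Grayordinate-by-time response matrix (or a vector for one
#'   grayordinate).
#' @param k_outer,k_inner Outer/inner fold counts (defaults 5 and 4).
#' @param penalty_grid Ridge penalty grid; default [default_lambda_grid()].
#' @param scale_predictions Scale base predictions to unit SD before stacking
#'   (default `TRUE`; see [stack_models()]).
#' @param return_predictions Keep held-out prediction matrices (memory).
#' @return Object of class `stacked_fit`: `alpha` (grayordinate-by-space
#'   simplex weights), `r2_stacked`, `r2_space`, `lambda` (grayordinate x
#'   space x fold), `flagged` (zero-variance grayordinates, `NA` results),
#'   and optionally `pred_stacked` / `pred_space`.
#' @export
fit_encoding <- function(designs, bold, k_outer = 5, k_inner = 4,
                         penalty_grid = default_lambda_grid(),
                         scale_predictions = TRUE,
                         return_predictions = FALSE,
                         folds = NULL) {
  Xs <- lapply(designs, function(d) {
    if (inherits(d, "feature_matrix")) d$values else as.matrix(d)
  })
  if (is.null(names(Xs)) || any(!nzchar(names(Xs)))) {
    names(Xs) <- paste0("space", seq_along(Xs))
  }
  K <- length(Xs)
  Tn <- nrow(Xs[[1]])
  if (any(vapply(Xs, nrow, integer(1)) != Tn)) {
    stop("all designs must share the number of timepoints")
  }
  if (is.vector(bold)) bold <- matrix(bold, nrow = 1)
  if (ncol(bold) != Tn) stop("bold time axis does not match the designs")
  G <- nrow(bold)
  Y <- t(bold)                                   # T x G
  flagged <- apply(Y, 2, stats::sd) < 1e-12
  L <- length(penalty_grid)
  if (is.null(folds)) folds <- make_folds(Tn, k_outer)
  k_outer <- length(folds)

  alpha_sum <- matrix(0, G, K, dimnames = list(NULL, names(Xs)))
  lambda_sel <- array(NA_real_, c(G, K, k_outer),
                      dimnames = list(NULL, names(Xs), NULL))
  pred_space <- lapply(Xs, function(x) matrix(NA_real_, Tn, G))
  pred_stacked <- matrix(NA_real_, Tn, G)
  coefs <- if (G == 1) stats::setNames(vector("list", K), names(Xs)) else NULL

  for (f in seq_len(k_outer)) {
    idx_te <- folds[[f]]
    idx_tr <- setdiff(seq_len(Tn), idx_te)
    Ytr <- Y[idx_tr, , drop = FALSE]
    inner <- make_folds(length(idx_tr), k_inner)
    oof <- lapply(seq_len(K), function(k) matrix(NA_real_, length(idx_tr), G))
    te_pred <- vector("list", K)
    for (k in seq_len(K)) {
      X <- Xs[[k]]
      Xtr <- X[idx_tr, , drop = FALSE]
      # inner-CV predictions per lambda
      preds_l <- lapply(seq_len(L), function(l) matrix(NA_real_,
                                                       length(idx_tr), G))
      for (j in seq_along(inner)) {
        rows_te <- inner[[j]]
        rows_tr <- setdiff(seq_along(idx_tr), rows_te)
        pl <- ridge_path_predict(Xtr[rows_tr, , drop = FALSE],
                                 Ytr[rows_tr, , drop = FALSE],
                                 Xtr[rows_te, , drop = FALSE], penalty_grid)
        for (l in seq_len(L)) preds_l[[l]][rows_te, ] <- pl[[l]]
      }
      sse <- vapply(preds_l, function(P) colSums((P - Ytr)^2), numeric(G))
      sse <- matrix(sse, nrow = G)                 # G x L
      lam_idx <- max.col(-sse, ties.method = "first")
      lambda_sel[, k, f] <- penalty_grid[lam_idx]
      for (l in unique(lam_idx)) {
        cols <- which(lam_idx == l)
        oof[[k]][, cols] <- preds_l[[l]][, cols, drop = FALSE]
      }
      # refit on the full training block, predict outer test
      te_pred[[k]] <- matrix(NA_real_, length(idx_te), G)
      for (l in unique(lam_idx)) {
        cols <- which(lam_idx == l)
        p <- ridge_path_predict(Xtr, Ytr[, cols, drop = FALSE],
                                X[idx_te, , drop = FALSE],
                                penalty_grid[l])[[1]]
        te_pred[[k]][, cols] <- p
      }
      pred_space[[k]][idx_te, ] <- te_pred[[k]]
      if (!is.null(coefs)) {
        cf <- ridge_coefs(Xtr, Ytr, penalty_grid[lam_idx[1]])
        coefs[[k]] <- cbind(coefs[[k]], drop(cf$beta))
      }
    }
    # stacking per grayordinate on inner out-of-fold predictions
    if (K == 1) {
      alpha_sum[, 1] <- alpha_sum[, 1] + 1
      pred_stacked[idx_te, ] <- te_pred[[1]]
    } else {
      for (g in seq_len(G)) {
        if (flagged[g]) next
        P <- vapply(oof, function(m) m[, g], numeric(length(idx_tr)))
        st <- stack_models(P, Ytr[, g], scale_predictions = scale_predictions)
        alpha_sum[g, ] <- alpha_sum[g, ] + st$alpha
        Pte <- vapply(te_pred, function(m) m[, g], numeric(length(idx_te)))
        Pte_c <- sweep(Pte, 2, colMeans(P))
        Pte_c <- sweep(Pte_c, 2, st$scale, "/")
        pred_stacked[idx_te, g] <- mean(Ytr[, g]) + drop(Pte_c %*% st$alpha)
      }
    }
  }

  alpha <- alpha_sum / k_outer
  alpha[flagged, ] <- NA_real_
  r2_space <- vapply(seq_len(K), function(k) {
    vapply(seq_len(G), function(g) {
      if (flagged[g]) NA_real_ else score_r2(pred_space[[k]][, g], Y[, g])
    }, numeric(1))
  }, numeric(G))
  r2_space <- matrix(r2_space, nrow = G, dimnames = list(NULL, names(Xs)))
  r2_stacked <- vapply(seq_len(G), function(g) {
    if (flagged[g]) NA_real_ else score_r2(pred_stacked[, g], Y[, g])
  }, numeric(1))

  out <- list(alpha = alpha, r2_stacked = r2_stacked, r2_space = r2_space,
              lambda = lambda_sel, flagged = flagged, folds = folds,
              spaces = names(Xs), coefficients = coefs)
  if (return_predictions) {
    out$pred_stacked <- pred_stacked
    out$pred_space <- pred_space
  }
  class(out) <- "stacked_fit"
  out
}

#' @export
print.stacked_fit <- function(x, ...) {
  cat(sprintf("<stacked_fit> %d grayordinates, %d feature spaces (%s)\n",
              length(x$r2_stacked), length(x$spaces),
              paste(x$spaces, collapse = ", ")))
  cat(sprintf("  mean stacked held-out R^2: %.3f\n",
              mean(x$r2_stacked, na.rm = TRUE)))
  invisible(x)
}

#' Unique explained variance by clipped subtraction
#'
#' The unique R^2 of a feature space is the stacked-model R^2 minus the
#' competing space's component R^2, with two clipping rules: a negative
#' component is clipped to zero (unique = stacked R^2), and a component
#' exceeding the stacked R^2 is set to it (unique = 0). By construction
#' `unique + clipped component = stacked` in every branch.
#'
#' @param stacked_r2 Stacked-model R^2 (scalar or vector).
#' @param component_r2 Competing space's R^2 (same length).
#' @return Unique R^2 of the complementary space.
#' @export
partition_unique_r2 <- function(stacked_r2, component_r2) {
  stopifnot(length(stacked_r2) == length(component_r2))
  comp <- pmin(pmax(component_r2, 0), stacked_r2)
  stacked_r2 - comp
}

#' Weight-difference preference index
#'
#' The difference of two stacking weights from one fit: positive values
#' indicate a high-level (or visual) preference, negative a low-level (or
#' audio) preference. Because stacking weights lie in `[0, 1]` and sum to
#' one, the index lies in `[-1, 1]`.
#'
#' @param fit A `stacked_fit`, or a named numeric vector / matrix of simplex
#'   weights.
#' @param contrast One of `"high_vs_low_audio"`, `"high_vs_low_visual"`,
#'   `"visual_vs_audio"`.
#' @return Numeric preference index (vector over grayordinates for a fit).
#' @export
preference_index <- function(fit, contrast = c("high_vs_low_visual",
                                               "high_vs_low_audio",
                                               "visual_vs_audio")) {
  contrast <- match.arg(contrast)
  pair <- switch(contrast,
    high_vs_low_audio = c("audio-high", "audio-low"),
    high_vs_low_visual = c("visual-high", "visual-low"),
    visual_vs_audio = c("visual", "audio"))
  W <- if (inherits(fit, "stacked_fit")) fit$alpha
       else if (is.matrix(fit)) fit
       else matrix(fit, nrow = 1, dimnames = list(NULL, names(fit)))
  missing_w <- setdiff(pair, colnames(W))
  if (length(missing_w)) {
    stop("fit lacks stacking weight(s): ", paste(missing_w, collapse = ", "))
  }
  unname(drop(W[, pair[1]] - W[, pair[2]]))
}
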