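# Single-response PLS regression (NIPALS), cross-validated Q2, VIP scores
# and autoscaled regression coefficients. Conventions follow the chemometric
# defaults: unit-variance + mean-centering of X and y, coefficients reported
# on the autoscaled metric, seven interleaved CV folds, and each weight
# vector's sign fixed so its largest-magnitude element is positive.

#' Fit a single-response PLS regression by NIPALS
#'
#' Partial least squares regression of a response `y` (e.g. the specific
#' growth rate or the specific butanol production rate) on an
#' autoscaled predictor matrix `X` (metabolite relative abundances).
#' Components are extracted by NIPALS deflation; for a single response the
#' first weight vector is proportional to `X'y`. Constant predictor columns
#' are dropped with a warning before scaling; if the data rank is exhausted
#' before `ncomp` components, the model is truncated with a warning.
#'
#' @param X Numeric matrix or data.frame, samples x predictors, no missing
#'   values, `n >= 3`.
#' @param y Numeric response vector (non-constant).
#' @param ncomp Number of latent components requested.
#' @param center,scale Autoscaling switches (defaults on, the chemometric
#'   convention the VIP > 1 rule assumes).
#' @return An object of class `pls_model`: weights `W`, X-loadings `P`,
#'   scores `T`, y-loadings `q`, autoscaled coefficients `B`,
#'   per-component explained Y sum-of-squares `SS_a`, cumulative `R2X`,
#'   `R2Y`, and the stored scaling parameters.
#' @export
fit_pls <- function(X, y, ncomp = 2L, center = TRUE, scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  ferm_assert(nrow(X) >= 3, "need at least 3 samples")
  ferm_assert(ncol(X) >= 1, "need at least 1 predictor")
  ferm_assert(nrow(X) == length(y), "X rows and y length differ")
  ferm_assert(!anyNA(X) && !anyNA(y),
              "missing values not allowed (impute upstream)")
  ferm_assert(ncomp >= 1, "ncomp must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))

  x_sd_all <- apply(X, 2, stats::sd)
  keep <- x_sd_all > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant column(s): %s", sum(!keep),
                    paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  ferm_assert(ncol(X) >= 1, "no non-constant predictors left")
  ferm_assert(stats::sd(y) > 0, "constant response: nothing to model")

  x_mean <- if (center) colMeans(X) else rep(0, ncol(X))
  x_sd <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  y_mean <- if (center) mean(y) else 0
  y_sd <- if (scale) stats::sd(y) else 1
  Xs <- sweep(sweep(X, 2, x_mean, "-"), 2, x_sd, "/")
  ys <- (y - y_mean) / y_sd

  n <- nrow(Xs); p <- ncol(Xs)
  ssx0 <- sum(Xs^2); ssy0 <- sum(ys^2)
  Xd <- Xs; yd <- ys
  W <- P <- matrix(0, p, 0); Tm <- matrix(0, n, 0)
  q <- ss_a <- numeric(0)
  tol <- 1e-12
  for (a in seq_len(ncomp)) {
    s <- crossprod(Xd, yd)
    ns <- sqrt(sum(s^2))
    if (ns < tol * max(1, ssx0)) {
      warning(sprintf("rank exhausted: truncating to %d component(s)", a - 1L))
      break
    }
    w <- s / ns
    i0 <- which.max(abs(w))
    if (w[i0] < 0) w <- -w
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < tol) {
      warning(sprintf("rank exhausted: truncating to %d component(s)", a - 1L))
      break
    }
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W <- cbind(W, w); P <- cbind(P, p_a); Tm <- cbind(Tm, t_a)
    q <- c(q, q_a); ss_a <- c(ss_a, q_a^2 * tt)
  }
  A <- length(q)
  ferm_assert(A >= 1, "could not extract any component")
  colnames(W) <- colnames(P) <- colnames(Tm) <- sprintf("comp%d", seq_len(A))
  rownames(W) <- rownames(P) <- colnames(Xs)

  PtW <- crossprod(P, W)
  B <- tryCatch(drop(W %*% solve(PtW, q)),
                error = function(e) stop(
                  "singular P'W: collinear components; reduce ncomp",
                  call. = FALSE))
  names(B) <- colnames(Xs)

  structure(list(
    ncomp = A, W = W, P = P, T = Tm, q = q, B = B, SS_a = ss_a,
    R2X = 1 - sum(Xd^2) / ssx0,
    R2Y = 1 - sum(yd^2) / ssy0,
    x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
    predictors = colnames(Xs), n = n
  ), class = "pls_model")
}

# coefficient vector using only the first `a` components
coef_at <- function(model, a) {
  a <- min(a, model$ncomp)
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$q[seq_len(a)]))
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s), %d predictors, n = %d\n",
              x$ncomp, length(x$B), x$n))
  cat(sprintf("  R2X = %.4f  R2Y = %.4f\n", x$R2X, x$R2Y))
  invisible(x)
}

#' Regression coefficients of a PLS model
#'
#' By default returns the coefficients on the autoscaled metric
#' (`B = W (P'W)^{-1} q`), the scale on which their signs are read as
#' favoring (`> 0`) or opposing (`< 0`) the response. `scale = "raw"`
#' back-transforms to the original units and includes an `(Intercept)`.
#'
#' @param object A `pls_model`.
#' @param scale `"autoscaled"` (default) or `"raw"`.
#' @param ncomp Use only the first `ncomp` components (default: all).
#' @param ... Ignored.
#' @return Named numeric vector.
#' @export
coef.pls_model <- function(object, scale = c("autoscaled", "raw"),
                           ncomp = NULL, ...) {
  scale <- match.arg(scale)
  b <- if (is.null(ncomp)) object$B else coef_at(object, ncomp)
  if (scale == "autoscaled") return(b)
  b_raw <- object$y_sd * b / object$x_sd
  c("(Intercept)" = object$y_mean - sum(b_raw * object$x_mean), b_raw)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix/data.frame containing the model's predictor
#'   columns (matched by name when named).
#' @param ncomp Use only the first `ncomp` components (default: all).
#' @param ... Ignored.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  Xn <- as.matrix(newdata)
  if (!is.null(colnames(Xn))) {
    ferm_assert(all(object$predictors %in% colnames(Xn)),
                "newdata is missing predictor columns")
    Xn <- Xn[, object$predictors, drop = FALSE]
  } else {
    ferm_assert(ncol(Xn) == length(object$predictors),
                "newdata has wrong number of columns")
  }
  b <- if (is.null(ncomp)) object$B else coef_at(object, ncomp)
  Xs <- sweep(sweep(Xn, 2, object$x_mean, "-"), 2, object$x_sd, "/")
  drop(object$y_mean + object$y_sd * (Xs %*% b))
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a )`, where
#' `SS_a` is the Y sum-of-squares explained by component `a`. VIPs satisfy
#' `sum_j VIP_j^2 = p`; the conventional significance cut is VIP > 1.
#'
#' @param model A fitted `pls_model`.
#' @return Named numeric vector of VIP scores (one per retained predictor).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ferm_assert(sum(model$SS_a) > 0, "no explained Y variance: VIP undefined")
  W2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  v <- sqrt(length(model$B) * drop(W2 %*% model$SS_a) / sum(model$SS_a))
  names(v) <- model$predictors
  v
}

#' Cross-validated Q2 and component selection
#'
#' Splits samples into `folds` interleaved folds (assignment order permuted
#' deterministically from `seed`), refits on each training split, and
#' accumulates the prediction residual sum of squares PRESS per number of
#' components. `Q2_A = 1 - PRESS_A / SS_tot`. The number of components is
#' chosen as the largest `A` such that every increment
#' `Q2_a - Q2_(a-1)` for `a <= A` is at least `q2_increment` (a SIMCA-like
#' rule; at least one component is always retained).
#'
#' @inheritParams fit_pls
#' @param ncomp_max Maximum number of components scanned.
#' @param folds Number of CV folds (>= 2, <= n).
#' @param seed Seed controlling the fold assignment.
#' @param q2_increment Minimum Q2 gain to accept a further component.
#' @return List with `Q2` (vector over 1..ncomp_max), `PRESS`, `folds`
#'   (assignment vector), and `ncomp` (chosen A).
#' @export
cross_validate <- function(X, y, ncomp_max = 3L, folds = 7L, seed = 1L,
                           q2_increment = 0.01, center = TRUE, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  ferm_assert(folds >= 2, "need at least 2 folds")
  ferm_assert(n >= folds, "more folds than samples (empty fold)")
  perm <- with_seed(seed, sample.int(n))
  fold_id <- integer(n)
  fold_id[perm] <- rep_len(seq_len(folds), n)

  press <- numeric(ncomp_max)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- suppressWarnings(
      fit_pls(X[!test, , drop = FALSE], y[!test], ncomp = ncomp_max,
              center = center, scale = scale))
    for (a in seq_len(ncomp_max)) {
      pred <- predict(fit, X[test, , drop = FALSE], ncomp = a)
      press[a] <- press[a] + sum((y[test] - pred)^2)
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  q2 <- 1 - press / ss_tot
  inc <- diff(c(0, q2))
  ok <- cumprod(inc >= q2_increment) == 1
  ncomp <- max(1L, if (any(ok)) max(which(ok)) else 1L)
  list(Q2 = q2, PRESS = press, folds = fold_id, ncomp = ncomp)
}

#' Fit a PLS model with cross-validated component selection
#'
#' Convenience wrapper: runs [cross_validate()], fits the final model with
#' the chosen number of components, and attaches `Q2` (at the chosen A) and
#' the full CV curve.
#'
#' @inheritParams cross_validate
#' @return A `pls_model` with extra fields `Q2`, `cv`.
#' @export
fit_pls_cv <- function(X, y, ncomp_max = 3L, folds = 7L, seed = 1L,
                       q2_increment = 0.01) {
  cv <- cross_validate(X, y, ncomp_max = ncomp_max, folds = folds,
                       seed = seed, q2_increment = q2_increment)
  model <- fit_pls(X, y, ncomp = cv$ncomp)
  model$Q2 <- cv$Q2[min(cv$ncomp, length(cv$Q2))]
  model$cv <- cv
  model
}
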