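#' Self-consistent regression (SCR)
#'
#' Regularized least squares with a per-variable regularization parameter
#' that is updated self-consistently: coefficients solve
#' `a = (X'X + V)^-1 X'y` with `V = diag(v_k)`, then each `v_k` is reset
#' to `sigma^2 / a_k^2` (the current residual variance over the squared
#' coefficient), so variables with weak, noisy coefficients are shrunk
#' hard while informative ones stay nearly unpenalized. Variables whose
#' t-ratio `|a_k|/se(a_k)` falls below `drop_threshold` are removed; the
#' loop repeats until the selected set and coefficients are stable or
#' `max_iter` is reached. The intercept is never penalized.
#'
#' Zero-variance and exactly duplicated columns are removed up front with
#' a warning. When `v_fixed` is supplied the regularization is held at
#' that value, no variables are dropped and a single solve is performed
#' (`v_fixed = 0` reproduces ordinary least squares; a common positive
#' value reproduces ridge regression).
#'
#' @param X Numeric descriptor matrix (rows = objects). Column names are
#'   the feature schema; unnamed columns get `x1..xm`.
#' @param y Numeric response vector.
#' @param max_iter Maximum self-consistency iterations.
#' @param drop_threshold t-ratio below which a variable is dropped.
#' @param v_fixed Optional fixed regularization (scalar or per-variable).
#' @param intercept Include an (unpenalized) intercept. Default TRUE.
#' @return Object of class `ao_scr`: `selected` (retained feature names),
#'   `a` (coefficients, intercept first), `v` (final regularization
#'   values), `n_train`, `n_vars`, `sigma2`, `feature_names` (full input
#'   schema).
#' @export
fit_scr <- function(X, y, max_iter = 50L, drop_threshold = 2.0,
                    v_fixed = NULL, intercept = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  # the self-consistent loop needs enough objects to estimate sigma^2;
  # fixed-V solves (OLS/ridge) only need a solvable system
  if (n < 5 && is.null(v_fixed)) stop("need at least 5 training objects")
  if (n < 2) stop("need at least 2 training objects")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  schema <- colnames(X)

  # clean: constant columns, exact duplicates
  const <- apply(X, 2, function(col) max(col) == min(col))
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s)")
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("empty model: no non-constant variables")
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate column(s)")
    X <- X[, !dup, drop = FALSE]
  }
  m <- ncol(X)

  solve_penalized <- function(Xs, v) {
    Z <- if (intercept) cbind(`(Intercept)` = 1, Xs) else Xs
    M <- crossprod(Z)
    vv <- if (intercept) c(0, v) else v
    Mi <- tryCatch(solve(M + diag(vv, nrow(M))), error = function(e) NULL)
    bump <- 0
    while (is.null(Mi) && bump < 8) {
      bump <- bump + 1
      vv2 <- vv + 10^(bump - 6) * mean(diag(M))
      Mi <- tryCatch(solve(M + diag(vv2, nrow(M))), error = function(e) NULL)
    }
    if (is.null(Mi)) stop("numerical rank failure: system singular even with regularization")
    a <- as.numeric(Mi %*% crossprod(Z, y))
    fit <- as.numeric(Z %*% a)
    rss <- sum((y - fit)^2)
    sigma2 <- rss / max(n - ncol(Z), 1)
    se <- sqrt(pmax(sigma2 * diag(Mi), 0))
    list(a = a, fitted = fit, sigma2 = sigma2, se = se)
  }

  if (!is.null(v_fixed)) {
    v <- rep_len(v_fixed, m)
    sol <- solve_penalized(X, v)
    sel <- colnames(X)
  } else {
    sel <- colnames(X)
    # start from a light ridge so over-determined starts (m >= n) are solvable
    v <- rep(1e-8 * mean(diag(crossprod(X))) + 1e-12, m)
    names(v) <- sel
    a_prev <- NULL
    for (iter in seq_len(max_iter)) {
      Xs <- X[, sel, drop = FALSE]
      sol <- solve_penalized(Xs, v[sel])
      coefs <- sol$a
      idx <- if (intercept) -1 else TRUE
      a_vars <- if (intercept) coefs[-1] else coefs
      se_vars <- if (intercept) sol$se[-1] else sol$se
      tratio <- abs(a_vars) / pmax(se_vars, .Machine$double.eps)
      keep <- tratio >= drop_threshold
      if (!any(keep)) stop("empty model: all variables dropped")
      new_sel <- sel[keep]
      v_new <- pmin(sol$sigma2 / pmax(a_vars[keep]^2, 1e-300), 1e12)
      stable_sel <- identical(new_sel, sel)
      v[new_sel] <- v_new
      conv <- stable_sel && !is.null(a_prev) &&
        length(a_prev) == length(coefs) &&
        max(abs(a_prev - coefs)) < 1e-10 * (1 + max(abs(coefs)))
      sel <- new_sel
      a_prev <- if (stable_sel) coefs else NULL
      if (conv) break
    }
    sol <- solve_penalized(X[, sel, drop = FALSE], v[sel])
  }

  a <- sol$a
  names(a) <- if (intercept) c("(Intercept)", sel) else sel
  structure(list(
    selected = sel,
    a = a,
    v = stats::setNames(if (is.null(v_fixed)) v[sel] else v, sel),
    n_train = n,
    n_vars = length(schema),
    sigma2 = sol$sigma2,
    intercept = intercept,
    fitted = sol$fitted,
    residuals = y - sol$fitted,
    feature_names = schema
  ), class = "ao_scr")
}

#' @export
print.ao_scr <- function(x, ...) {
  cat("<ao_scr> ", length(x$selected), "/", x$n_vars,
      " variables selected, n = ", x$n_train,
      ", sigma2 = ", signif(x$sigma2, 4), "\n", sep = "")
  invisible(x)
}

# rows of x matched to the model schema, by name when available
align_features <- function(x, features) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) {
    missing <- setdiff(features, colnames(x))
    if (length(missing) > 0) {
      stop("schema mismatch: missing feature(s) ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    x[, features, drop = FALSE]
  } else {
    if (ncol(x) != length(features)) {
      stop("schema mismatch: expected ", length(features), " features, got ",
           ncol(x))
    }
    colnames(x) <- features
    x
  }
}

#' Predict from a fitted SCR model
#'
#' Linear predictor `a0 + sum_k a_k x_k` over the selected variables.
#'
#' @param model An `ao_scr`.
#' @param x Named numeric vector or matrix carrying at least the selected
#'   features.
#' @return Numeric vector of predictions.
#' @export
predict_scr <- function(model, x) {
  xs <- align_features(x, model$selected)
  a0 <- if (model$intercept) model$a[["(Intercept)"]] else 0
  slopes <- model$a[model$selected]
  as.numeric(a0 + xs %*% slopes)
}

# Moore-Penrose pseudo-inverse via SVD (rank-revealing)
pinv <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit an RBF-SCR interpolation model
#'
#' Every training point is a center. Coordinates are first weighted by the
#' SCR regression coefficients (zero for variables SCR dropped), so the
#' radial distance is a similarity criterion that emphasises the
#' descriptors SCR found informative. With the linear kernel phi(r) = r
#' the interpolation matrix is `Phi[i,j] = ||a*x_i - a*x_j||` and the
#' weights solve `Phi w = y`; a rank-revealing pseudo-inverse is used so
#' duplicated centers degrade to least squares instead of failing.
#'
#' @param X Training descriptor matrix (same schema the SCR was fit on).
#' @param y Training responses.
#' @param scr A fitted `ao_scr` supplying the coordinate weights.
#' @return Object of class `ao_rbf_scr` with `centers` (weighted training
#'   coordinates), `w`, `feat_weights`, `feature_names`.
#' @export
fit_rbf_scr <- function(X, y, scr) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) < 2) stop("degenerate geometry: need at least 2 centers")
  fw <- stats::setNames(numeric(length(scr$feature_names)), scr$feature_names)
  fw[scr$selected] <- scr$a[scr$selected]
  xs <- align_features(X, scr$feature_names)
  Z <- sweep(xs, 2, fw, "*")
  if (nrow(unique(round(Z, 12))) < 2) {
    stop("degenerate geometry: fewer than 2 distinct weighted centers")
  }
  Phi <- as.matrix(stats::dist(Z))
  w <- as.numeric(pinv(Phi) %*% y)
  structure(list(
    centers = Z,
    w = w,
    y = y,
    feat_weights = fw,
    feature_names = scr$feature_names
  ), class = "ao_rbf_scr")
}

#' @export
print.ao_rbf_scr <- function(x, ...) {
  cat("<ao_rbf_scr> ", nrow(x$centers), " centers, ",
      sum(x$feat_weights != 0), " active features\n", sep = "")
  invisible(x)
}

#' Predict from an RBF-SCR model
#'
#' `y(x) = sum_i w_i ||a*x - a*x_i||` (linear radial basis function over
#' SCR-weighted coordinates).
#'
#' @param model An `ao_rbf_scr`.
#' @param x Named vector or matrix with the training feature schema.
#' @return Numeric vector of predictions.
#' @export
predict_rbf_scr <- function(model, x) {
  xs <- align_features(x, model$feature_names)
  Z <- sweep(xs, 2, model$feat_weights, "*")
  ctr <- model$centers
  vapply(seq_len(nrow(Z)), function(i) {
    r <- sqrt(colSums((t(ctr) - Z[i, ])^2))
    sum(model$w * r)
  }, numeric(1))
}
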