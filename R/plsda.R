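#' Fit a two-class PLS-DA model
#'
#' Partial least-squares discriminant analysis for a two-class design,
#' computed by the NIPALS PLS1 algorithm on the mean-centered,
#' unit-variance-scaled predictor matrix against a centered two-level class
#' indicator encoded as +1/2 and -1/2. With a single response the NIPALS
#' inner loop converges in one pass, so the fit is fully deterministic: the
#' weight vector of each component is the (deflated) covariance direction
#' between predictors and class, normalized to unit length.
#'
#' Zero-variance predictors cannot be autoscaled and are dropped with a
#' warning before fitting. Components whose score norm falls below `tol`
#' indicate that the rank of the predictor matrix is exhausted; extraction
#' stops there with a warning.
#'
#' @param X Numeric matrix, samples in rows, features (genes) in columns.
#'   Column names identify the features.
#' @param y Class labels: factor or vector with exactly two levels and at
#'   least two samples per class.
#' @param n_components Number of latent components to extract.
#' @param scale Scale columns to unit variance (default TRUE; centering is
#'   always applied).
#' @param tol Numerical tolerance for rank exhaustion.
#' @param max_iter Maximum NIPALS iterations per component (the PLS1 case
#'   converges in one; kept for the algorithm's general form).
#' @return An object of class `plsda_model`: unit-norm `weights` (features
#'   x components), `loadings`, `scores` (samples x components), regression
#'   coefficients `q` per component, response sum of squares explained per
#'   component `ssy`, `var_explained_y` (fractions of the total response
#'   sum of squares), `classes` and the encoded response `y_encoded`.
#' @export
fit_plsda <- function(X, y, n_components = 2, scale = TRUE,
                      tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric")
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    stop(sprintf("PLS-DA requires exactly two classes, got %d", nlevels(y)))
  if (any(table(y) < 2L)) stop("need at least two samples per class")
  if (nrow(X) != length(y)) stop("nrow(X) must match length(y)")
  stopifnot(n_components >= 1L)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  sds <- apply(X, 2L, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance feature(s) before PLS-DA",
                    sum(zero_var)))
    X <- X[, !zero_var, drop = FALSE]
    sds <- sds[!zero_var]
  }
  if (ncol(X) == 0L) stop("no features with non-zero variance")

  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)
  if (scale) Xc <- sweep(Xc, 2L, sds, "/")
  # centered +-1/2 indicator of the second factor level
  u0 <- ifelse(y == levels(y)[2L], 0.5, -0.5)
  u0 <- u0 - mean(u0)
  ss_y <- sum(u0^2)
  if (ss_y <= 0) stop("degenerate class vector")

  n_feat <- ncol(Xc)
  A <- min(n_components, nrow(Xc) - 1L, n_feat)
  W <- matrix(0, n_feat, A, dimnames = list(colnames(Xc), NULL))
  P <- matrix(0, n_feat, A, dimnames = list(colnames(Xc), NULL))
  Tm <- matrix(0, nrow(Xc), A,
               dimnames = list(rownames(X) %||% paste0("s", seq_len(nrow(X))),
                               NULL))
  qv <- numeric(A)
  ssy <- numeric(A)
  Xa <- Xc
  ua <- u0
  a <- 0L
  while (a < A) {
    # NIPALS with a single response: the loop w <- X'u / ||X'u||, t <- Xw,
    # u fixed at the class vector is stationary after one pass, so one
    # normalized covariance step is the converged solution (max_iter and
    # tol only guard degenerate deflation).
    w <- drop(crossprod(Xa, ua))
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_sc <- drop(Xa %*% w)
    tt <- sum(t_sc^2)
    if (tt < tol) break
    a <- a + 1L
    p_load <- drop(crossprod(Xa, t_sc)) / tt
    q_coef <- sum(ua * t_sc) / tt
    W[, a] <- w
    P[, a] <- p_load
    Tm[, a] <- t_sc
    qv[a] <- q_coef
    ssy[a] <- q_coef^2 * tt     # response sum of squares captured by comp a
    Xa <- Xa - tcrossprod(t_sc, p_load)
    ua <- ua - q_coef * t_sc
  }
  if (a == 0L) stop("no PLS component could be extracted")
  if (a < n_components) {
    warning(sprintf("rank exhausted: extracted %d of %d requested components",
                    a, n_components))
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    Tm <- Tm[, seq_len(a), drop = FALSE]
    qv <- qv[seq_len(a)]
    ssy <- ssy[seq_len(a)]
  }
  structure(list(n_components = a, weights = W, loadings = P, scores = Tm,
                 q = qv, ssy = ssy, ss_y_total = ss_y,
                 var_explained_y = ssy / ss_y,
                 classes = levels(y), y_encoded = u0,
                 centers = centers, scales = if (scale) sds else NULL,
                 features = colnames(W)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d component(s), %d features, classes %s vs %s\n",
              x$n_components, nrow(x$weights), x$classes[1L], x$classes[2L]))
  cat("  response variance explained per component:",
      paste(sprintf("%.1f%%", 100 * x$var_explained_y), collapse = ", "), "\n")
  invisible(x)
}

#' Variable Importance in Projection (VIP) scores
#'
#' Per-feature VIP of a fitted PLS-DA model:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{p} is the number of features, \eqn{w_a} the weight vector of
#' component \eqn{a} and \eqn{SSY_a} the response sum of squares that
#' component explains. The mean squared VIP is exactly 1, so VIP > 1 marks
#' features with above-average influence on the class separation.
#'
#' @param model A `plsda_model` from [fit_plsda()].
#' @return Named numeric vector of VIP scores (one per feature).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (sum(model$ssy) <= 0)
    stop("model explains no response variance; VIP undefined")
  W <- model$weights
  # weights are stored unit-norm; normalize defensively
  Wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  p <- nrow(W)
  vip <- sqrt(p * drop(Wn^2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- rownames(W)
  vip
}
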