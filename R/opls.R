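#' @name opls
#' @title OPLS-DA: orthogonal projections to latent structures, two classes
#'
#' @description
#' A two-class OPLS-DA splits the predictor matrix `X` into one predictive
#' component (correlated with class membership) and a sequence of orthogonal
#' components (structured variation unrelated to class — here, typically the
#' culture-time trajectory of a fed-batch process). The orthogonal filter is
#' the NIPALS-style deflation of Trygg-Wold O-PLS:
#'
#' \preformatted{
#'   w   = X'y / ||X'y||                 (predictive weight, unit norm)
#'   t   = X w ;  p = X't / (t't)
#'   w_o = p - (w'p) w, normalized       (orthogonal weight)
#'   t_o = X w_o ; p_o = X't_o / (t_o't_o)
#'   X  <- X - t_o p_o'                  (deflate; repeat per component)
#' }
#'
#' followed by a final one-component PLS on the filtered `X`. With zero
#' orthogonal components the model is exactly a 1-component PLS1-DA.
#' Variance fractions (R2X) are computed against the total sum of squares of
#' the input matrix and sum to one exactly.
NULL

# Encode two-class labels as +1/-1. The positive class defaults to "test"
# when present so score-plot orientation is reproducible.
encode_classes <- function(labels, positive_class = NULL) {
  labs <- as.character(labels)
  u <- unique(labs)
  if (length(u) != 2)
    stop("exactly two classes required, got: ", paste(u, collapse = ", "))
  if (is.null(positive_class))
    positive_class <- if ("test" %in% u) "test" else u[1]
  if (!positive_class %in% u)
    stop("positive_class '", positive_class, "' not among the labels")
  negative_class <- setdiff(u, positive_class)
  y <- ifelse(labs == positive_class, 1, -1)
  if (min(table(labs)) < 2)
    stop("each class needs at least 2 observations")
  list(y = y, class_map = c(stats::setNames(1, positive_class),
                            stats::setNames(-1, negative_class)))
}

# Core O-PLS recursion on a numeric centered response. Returns weights,
# scores, loadings and the R2 decomposition. Internal; no label handling.
opls_core <- function(X, y, n_ortho) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_ortho >= 0)
  ss0 <- sum(X^2)
  if (ss0 < .Machine$double.eps)
    stop("predictor matrix has zero variance")

  Xd <- X
  W_ortho <- P_ortho <- matrix(0, p, 0)
  T_ortho <- matrix(0, n, 0)
  r2x_ortho <- numeric(0)

  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(NULL)
    v / nv
  }

  k <- 0
  while (k < n_ortho) {
    w <- unit(drop(crossprod(Xd, y)))
    if (is.null(w)) stop("no covariance between X and the response")
    t_p <- drop(Xd %*% w)
    p_p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
    w_o <- p_p - sum(w * p_p) * w
    nw_o <- sqrt(sum(w_o^2))
    if (nw_o < 1e-10 * max(1, sqrt(sum(p_p^2)))) break  # no orthogonal variation left
    w_o <- w_o / nw_o
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_ortho <- cbind(W_ortho, w_o)
    P_ortho <- cbind(P_ortho, p_o)
    T_ortho <- cbind(T_ortho, t_o)
    r2x_ortho <- c(r2x_ortho, sum(t_o^2) * sum(p_o^2) / ss0)
    k <- k + 1
  }

  w <- unit(drop(crossprod(Xd, y)))
  if (is.null(w)) stop("no covariance between X and the response")
  t_pred <- drop(Xd %*% w)
  p_pred <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  b <- sum(t_pred * y) / sum(t_pred^2)

  resid <- Xd - tcrossprod(t_pred, p_pred)
  list(
    w = w, t_pred = t_pred, p_pred = p_pred, b = b,
    W_ortho = W_ortho, P_ortho = P_ortho, T_ortho = T_ortho,
    n_ortho = ncol(W_ortho),
    r2x_pred = sum(t_pred^2) * sum(p_pred^2) / ss0,
    r2x_ortho = r2x_ortho,
    r2x_residual = sum(resid^2) / ss0,
    r2y = 1 - sum((y - b * t_pred)^2) / sum(y^2)
  )
}

# Remove the fitted orthogonal components from new observations.
remove_orthogonal <- function(Xnew, W_ortho, P_ortho) {
  if (!is.null(W_ortho) && ncol(W_ortho) > 0) {
    for (j in seq_len(ncol(W_ortho))) {
      t_o <- drop(Xnew %*% W_ortho[, j])
      Xnew <- Xnew - tcrossprod(t_o, P_ortho[, j])
    }
  }
  Xnew
}

#' Fit a two-class OPLS-DA model
#'
#' @param X Numeric matrix, observations x variables, already scaled
#'   (see [pareto_scale()] / [mean_center()]).
#' @param labels Two-class vector of length `nrow(X)` (e.g. "test"/"control"),
#'   each class with at least 2 observations.
#' @param n_ortho Number of orthogonal components, or `"auto"` to keep adding
#'   components while the cross-validated Q2 improves by more than `q2_tol`,
#'   capped at `max_ortho`.
#' @param max_ortho Cap for `"auto"` selection.
#' @param q2_tol Minimum Q2 improvement that justifies another orthogonal
#'   component under `"auto"`.
#' @param folds Cross-validation folds used for the Q2 diagnostic (stratified
#'   by class; the chemometrics default is 7).
#' @param positive_class Label mapped to +1 (default `"test"` when present,
#'   otherwise the first label encountered).
#' @return A list with components
#'   \describe{
#'     \item{model}{`opls_model`: unit-norm predictive weight `w`, predictive
#'       loading `p_pred` and scores `t_pred`, orthogonal `W_ortho`/`P_ortho`/
#'       `T_ortho`, inner-relation coefficient `b`, `class_map`, `y_mean`.}
#'     \item{diagnostics}{`opls_diagnostics`: `r2x_pred`, per-component
#'       `r2x_ortho`, `r2x_residual` (summing to 1), `r2y`, cross-validated
#'       `q2`, `cv_folds`, and a `permutation` slot filled by
#'       [permutation_test()].}
#'   }
#' @seealso [significant_loadings()], [cross_validate_q2()],
#'   [permutation_test()]
#' @export
fit_opls_da <- function(X, labels, n_ortho = "auto", max_ortho = 5,
                        q2_tol = 0.01, folds = 7, positive_class = NULL) {
  X <- as.matrix(X)
  enc <- encode_classes(labels, positive_class)
  y <- enc$y
  y_mean <- mean(y)
  yc <- y - y_mean

  if (identical(n_ortho, "auto")) {
    q2_prev <- cross_validate_q2(X, labels, n_ortho = 0, folds = folds,
                                 positive_class = positive_class)
    n_ortho <- 0
    k <- 0
    while (k < max_ortho) {
      q2_k <- cross_validate_q2(X, labels, n_ortho = k + 1, folds = folds,
                                positive_class = positive_class)
      if (!(q2_k > q2_prev + q2_tol)) break
      q2_prev <- q2_k
      k <- k + 1
    }
    n_ortho <- k
  }
  stopifnot(is.numeric(n_ortho), n_ortho >= 0)

  core <- opls_core(X, yc, n_ortho)
  ids <- colnames(X)
  if (!is.null(ids)) {
    names(core$w) <- names(core$p_pred) <- ids
    if (ncol(core$W_ortho)) rownames(core$W_ortho) <- rownames(core$P_ortho) <- ids
  }
  obs <- rownames(X)
  if (!is.null(obs)) {
    names(core$t_pred) <- obs
    if (ncol(core$T_ortho)) rownames(core$T_ortho) <- obs
  }

  model <- structure(
    list(w = core$w, p_pred = core$p_pred, t_pred = core$t_pred,
         W_ortho = core$W_ortho, P_ortho = core$P_ortho,
         T_ortho = core$T_ortho, b = core$b, n_ortho = core$n_ortho,
         y_mean = y_mean, class_map = enc$class_map,
         labels = as.character(labels)),
    class = "opls_model"
  )
  q2 <- cross_validate_q2(X, labels, n_ortho = core$n_ortho, folds = folds,
                          positive_class = positive_class)
  diagnostics <- structure(
    list(r2x_pred = core$r2x_pred, r2x_ortho = core$r2x_ortho,
         r2x_residual = core$r2x_residual, r2y = core$r2y, q2 = q2,
         cv_folds = folds, n_ortho = core$n_ortho, permutation = NULL),
    class = "opls_diagnostics"
  )
  list(model = model, diagnostics = diagnostics)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %d variables, %d observations, %d orthogonal component(s)\n",
              length(x$w), length(x$t_pred), x$n_ortho))
  cat("  class encoding:",
      paste(sprintf("%s=%+d", names(x$class_map), x$class_map), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.opls_diagnostics <- function(x, ...) {
  cat(sprintf("R2X predictive: %.4f | orthogonal: %s | residual: %.4f\n",
              x$r2x_pred,
              if (length(x$r2x_ortho)) paste(sprintf("%.4f", x$r2x_ortho),
                                             collapse = " + ") else "none",
              x$r2x_residual))
  cat(sprintf("R2Y: %.4f | Q2 (%d-fold): %.4f\n", x$r2y, x$cv_folds, x$q2))
  if (!is.null(x$permutation))
    cat(sprintf("permutation test: p = %.5f (%d permutations)\n",
                x$permutation$p_value, x$permutation$n_perm))
  invisible(x)
}

#' Predict scores and class from a fitted OPLS-DA model
#'
#' New observations must be on the same scale as the training matrix.
#'
#' @param object An `opls_model`.
#' @param newdata Numeric matrix, observations x variables (same variables,
#'   same order, as the training matrix).
#' @param ... Unused.
#' @return A list with `t_pred` (predictive scores after orthogonal
#'   filtering), `y_hat` (numeric prediction on the +1/-1 scale) and `class`
#'   (decoded labels).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xf <- remove_orthogonal(as.matrix(newdata), object$W_ortho, object$P_ortho)
  t_pred <- drop(Xf %*% object$w)
  y_hat <- object$b * t_pred + object$y_mean
  cls <- names(object$class_map)[ifelse(y_hat >= 0, 1, 2)]
  list(t_pred = t_pred, y_hat = y_hat, class = cls)
}

# Deterministic stratified fold assignment: within each class, observations
# are dealt round-robin across folds in order of appearance, so that time
# points spread across folds and repeated calls are reproducible.
stratified_folds <- function(y, folds) {
  n <- length(y)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < 2)
      stop("class '", cls, "' has fewer than 2 observations; cannot stratify")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated Q2
#'
#' Q2 = 1 - PRESS / SS(y) with out-of-fold prediction: folds are stratified by
#' class, the scaling (when requested) and the full O-PLS fit are redone
#' inside every training fold, and held-out observations are predicted after
#' orthogonal filtering with the training-fold components.
#'
#' @inheritParams fit_opls_da
#' @param n_ortho Number of orthogonal components (fixed; no auto here).
#' @param folds Number of folds, between 2 and `nrow(X)`.
#' @param scale Scaling refit inside each training fold: `"none"` (X already
#'   scaled once, globally), `"pareto"` or `"center"` (leakage-free).
#' @return The Q2 statistic (a real number, at most 1; negative means worse
#'   than predicting the class mean).
#' @export
cross_validate_q2 <- function(X, labels, n_ortho = 1, folds = 7,
                              scale = c("none", "pareto", "center"),
                              positive_class = NULL) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  enc <- encode_classes(labels, positive_class)
  y <- enc$y
  fold <- stratified_folds(y, folds)

  press <- 0
  for (f in sort(unique(fold))) {
    te <- fold == f
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    ytr <- y[!te]
    if (length(unique(ytr)) < 2)
      stop("a training fold lost an entire class; reduce folds")
    if (scale != "none") {
      Xtr <- scale_matrix(Xtr, scale)
      Xte <- apply_scaling(Xte, Xtr)
    }
    ytr_m <- mean(ytr)
    yhat <- tryCatch({
      core <- opls_core(Xtr, ytr - ytr_m, n_ortho)
      Xte_f <- remove_orthogonal(Xte, core$W_ortho, core$P_ortho)
      core$b * drop(Xte_f %*% core$w) + ytr_m
    }, error = function(e) rep(ytr_m, sum(te)))  # degenerate fold: class-mean
    press <- press + sum((y[te] - yhat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Permutation test of model validity
#'
#' Class labels are permuted `n_perm` times; R2Y and Q2 are recomputed for
#' every permutation and the p-value is
#' `(1 + #\{permuted Q2 >= observed Q2\}) / (n_perm + 1)`. Permutations that
#' exactly reproduce the observed labeling (or its mirror-image class swap,
#' which yields an identical model) are redrawn, since they carry no
#' information about the null. Default `n_perm = 200`.
#'
#' @inheritParams cross_validate_q2
#' @param n_perm Number of label permutations (default 200).
#' @param seed Optional integer seed for the permutation stream.
#' @return An `opls_permutation` list: `n_perm`, `observed_r2y`,
#'   `observed_q2`, `permuted_r2y`, `permuted_q2`, `p_value`.
#' @export
permutation_test <- function(X, labels, n_ortho = 1, n_perm = 200, folds = 7,
                             scale = c("none", "pareto", "center"),
                             seed = NULL, positive_class = NULL) {
  stopifnot(n_perm >= 1)
  scale <- match.arg(scale)
  X <- as.matrix(X)
  enc <- encode_classes(labels, positive_class)
  y <- enc$y
  Xs <- if (scale == "none") X else scale_matrix(X, scale)

  r2y_of <- function(yv) opls_core(Xs, yv - mean(yv), n_ortho)$r2y
  obs_r2y <- r2y_of(y)
  obs_q2 <- cross_validate_q2(X, labels, n_ortho = n_ortho, folds = folds,
                              scale = scale, positive_class = positive_class)

  if (!is.null(seed)) set.seed(seed)
  perm_r2y <- perm_q2 <- numeric(n_perm)
  labels <- as.character(labels)
  for (i in seq_len(n_perm)) {
    repeat {
      yp <- sample(y)
      if (!identical(yp, y) && !identical(yp, -y)) break
    }
    lp <- names(enc$class_map)[ifelse(yp == 1, 1, 2)]
    perm_r2y[i] <- tryCatch(r2y_of(yp), error = function(e) NA_real_)
    perm_q2[i] <- cross_validate_q2(X, lp, n_ortho = n_ortho, folds = folds,
                                    scale = scale,
                                    positive_class = names(enc$class_map)[1])
  }
  structure(
    list(n_perm = n_perm, observed_r2y = obs_r2y, observed_q2 = obs_q2,
         permuted_r2y = perm_r2y, permuted_q2 = perm_q2,
         p_value = (1 + sum(perm_q2 >= obs_q2, na.rm = TRUE)) / (n_perm + 1)),
    class = "opls_permutation"
  )
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf("permutation test: %d permutations, observed Q2 = %.4f, p = %.5f\n",
              x$n_perm, x$observed_q2, x$p_value))
  invisible(x)
}

#' Significant features by the predictive-loading rule
#'
#' A feature is called statistically significant when the absolute value of
#' its predictive-component loading is strictly greater than the sample
#' standard deviation of the full predictive-loading vector. Degenerate edge:
#' a loading vector with zero spread flags every nonzero entry (all of them,
#' when they are all equal and nonzero) and none when all loadings are zero.
#'
#' @param model A fitted `opls_model`.
#' @return Character vector of feature ids (or integer indices when the
#'   training matrix had no column names).
#' @export
significant_loadings <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  p <- model$p_pred
  s <- stats::sd(p)
  hit <- abs(p) > s
  if (is.null(names(p))) which(hit) else names(p)[hit]
}
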