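# Independent oracle implementations used to cross-check the package.
# These are written against the defining formulas, not against the package
# internals, and must stay independent of the code paths they verify.

# One-component PLS1 on a centered response: the limit that OPLS-DA with
# zero orthogonal components must reproduce.
oracle_pls1 <- function(X, y) {
  w <- drop(t(X) %*% y)
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(t(X) %*% t) / sum(t * t)
  b <- sum(t * y) / sum(t * t)
  list(w = w, t = t, p = p, b = b, y_hat = b * t)
}

# Explicit orthogonal-signal-correction pass followed by 1-component PLS:
# the stated reference route for the OPLS-DA predictive component.
oracle_osc_pls <- function(X, y, k) {
  for (i in seq_len(k)) {
    w <- drop(t(X) %*% y); w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    p <- drop(t(X) %*% t) / sum(t * t)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break
    wo <- wo / nwo
    to <- drop(X %*% wo)
    po <- drop(t(X) %*% to) / sum(to * to)
    X <- X - to %*% t(po)
  }
  c(oracle_pls1(X, y), list(X_filtered = X))
}

# AUC oracle: integrate the piecewise-linear interpolant of the per-day
# means by the midpoint rule, exact for linear segments. Uses approxfun so
# the numerical route differs from the package trapezoid.
oracle_auc <- function(days, means) {
  f <- stats::approxfun(days, means)
  d <- sort(days)
  sum(vapply(seq_len(length(d) - 1), function(i) {
    (d[i + 1] - d[i]) * f((d[i] + d[i + 1]) / 2)
  }, numeric(1)))
}

# Tier oracle: evaluates every rule as an independent predicate and takes
# the best (lowest) tier, instead of the package's first-match cascade.
oracle_tier <- function(in_mass_std, in_rt_std, in_mass_lib, in_mass_tent,
                        in_mass_any, has_msms, match_std, match_lib,
                        manual_structure, msigma, formula_match) {
  hits <- c(
    "1"  = in_mass_std && in_rt_std && match_std,
    "1*" = in_mass_std && in_rt_std && !has_msms,
    "2"  = in_mass_lib && match_lib,
    "3"  = in_mass_tent && manual_structure,
    "4"  = in_mass_any && !is.na(msigma) && msigma < 100 && formula_match
  )
  if (any(hits)) names(hits)[which(hits)[1]] else "5"
}

# Planted two-direction instance for the OPLS oracle-equivalence check:
# a class-aligned direction plus a class-orthogonal structured direction.
make_planted_instance <- function(n, p, seed) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  y <- y - mean(y)
  g <- rnorm(n)
  g <- g - mean(g) - y * sum(g * y) / sum(y * y)  # orthogonal to y
  v1 <- rnorm(p); v2 <- rnorm(p)
  X <- y %*% t(v1) + g %*% t(v2) + 0.05 * matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  list(X = X, y = y,
       labels = ifelse(y > 0, "test", "control"))
}

# Small deterministic feature table used across module tests.
toy_table <- function() {
  ab <- rbind(
    FA = c(10, 12, 20, 22, 30, 32, 40, 44),
    FB = c(100, 90, 80, 70, 60, 50, 40, 30),
    FC = c(5, 5, 5, 5, 5, 5, 5, 5)
  ) * 1000
  colnames(ab) <- paste0("s", 1:8)
  sm <- data.frame(
    sample_id = paste0("s", 1:8),
    condition = rep(c("test", "control"), 4),
    day = rep(c(0, 2, 4, 6), each = 2),
    replicate = 1L
  )
  fm <- data.frame(feature_id = c("FA", "FB", "FC"), rt = c(1.5, 5.0, 8.0))
  feature_table(ab, sm, fm)
}
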