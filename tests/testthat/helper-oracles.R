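# Independent oracles used across the model tests. Nothing here calls
# the package's fitting path: the REML log-likelihood is written out
# directly from the marginal covariance and maximized by grid
# refinement, and the one-way ANOVA estimators come from base aov().

# REML log-likelihood (up to a constant) of y ~ N(Xb, V) with
# V = s2e I + s2j Zj Zj' + s2w Zw Zw'. Dense algebra; tiny n only.
reml_loglik <- function(y, X, Zj, Zw = NULL, s2j, s2w = 0, s2e) {
  n <- length(y)
  V <- s2e * diag(n) + s2j * tcrossprod(Zj)
  if (!is.null(Zw)) V <- V + s2w * tcrossprod(Zw)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtVX, logarithm = TRUE)$modulus +
            t(r) %*% Vi %*% r)[1]
}

# Maximize the REML log-likelihood over (s2j, s2w, s2e) by iterative
# grid refinement around the current best point.
reml_grid_oracle <- function(y, X, Zj, Zw = NULL, upper = 4 * stats::var(y),
                             n_iter = 8L, n_grid = 13L) {
  lo <- c(1e-6, if (!is.null(Zw)) 1e-6, 1e-6)
  hi <- rep(upper, length(lo))
  best <- NULL
  for (it in seq_len(n_iter)) {
    grids <- Map(function(l, h) seq(l, h, length.out = n_grid), lo, hi)
    pts <- as.matrix(do.call(expand.grid, grids))
    ll <- apply(pts, 1L, function(p) {
      if (is.null(Zw)) reml_loglik(y, X, Zj, NULL, p[1L], 0, p[2L])
      else reml_loglik(y, X, Zj, Zw, p[1L], p[2L], p[3L])
    })
    best <- pts[which.max(ll), ]
    step <- vapply(grids, function(g) g[2L] - g[1L], numeric(1))
    lo <- pmax(best - step, 1e-8)
    hi <- best + step
  }
  if (is.null(Zw)) list(s2j = best[1L], s2e = best[2L])
  else list(s2j = best[1L], s2w = best[2L], s2e = best[3L])
}

# Balanced one-way ANOVA method-of-moments variance components via aov().
anova_mom <- function(y, group) {
  n_per <- unique(table(group))
  stopifnot(length(n_per) == 1L)
  tab <- summary(stats::aov(y ~ Error(factor(group))))
  ms_between <- tab[[1]][[1]]["Mean Sq"][[1]]
  ms_within <- tab[[2]][[1]]["Mean Sq"][[1]]
  list(s2j = (ms_between - ms_within) / n_per, s2e = ms_within)
}

# indicator matrix for a grouping factor
zmat <- function(g) {
  g <- factor(g)
  stats::model.matrix(~ 0 + g)
}
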