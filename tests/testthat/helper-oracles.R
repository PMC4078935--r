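# Independent oracles used across the suite. Each one is a deliberately
# naive re-derivation (explicit loops, dense algebra, enumeration or
# Monte-Carlo) kept free of the package's own code paths.

# gap-segment derivative by direct double loop over segment sums
gap_deriv_oracle <- function(x, gap) {
  n <- length(x)
  out <- numeric(0)
  for (i in (gap + 1):(n - gap + 1)) {
    left <- 0
    for (j in (i - gap):(i - 1)) left <- left + x[j]
    right <- 0
    for (j in i:(i + gap - 1)) right <- right + x[j]
    out <- c(out, (right / gap - left / gap) / gap)
  }
  out
}

movavg_oracle <- function(x, w) {
  k <- (w - 1) / 2
  n <- length(x)
  out <- numeric(0)
  for (i in (k + 1):(n - k)) out <- c(out, mean(x[(i - k):(i + k)]))
  out
}

# ordinary least squares predictions (with intercept)
ols_predict_oracle <- function(X, y, Xnew) {
  fit <- stats::lm.fit(cbind(1, X), y)
  as.numeric(cbind(1, Xnew) %*% fit$coefficients)
}

# cross-validation by an explicit loop over held-out groups
secv_loop_oracle <- function(X, y, ncomp, fold) {
  res <- numeric(length(y))
  for (g in unique(fold)) {
    hold <- fold == g
    m <- pls_fit(X[!hold, , drop = FALSE], y[!hold], ncomp)
    res[hold] <- y[hold] - predict(m, X[hold, , drop = FALSE])
  }
  sqrt(mean(res^2))
}

# additive relationships by two-allele gene dropping: each founder carries
# two independent N(0, 1/2) allelic values per locus; offspring inherit one
# allele at random from each parent; cov of genotypic values estimates A.
gene_drop_A_oracle <- function(ped, n_loci = 2e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  a1 <- matrix(0, n, n_loci)
  a2 <- matrix(0, n, n_loci)
  for (i in seq_len(n)) {
    if (si[i] == 0) a1[i, ] <- rnorm(n_loci, 0, sqrt(0.5))
    else {
      pick <- runif(n_loci) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
    }
    if (di[i] == 0) a2[i, ] <- rnorm(n_loci, 0, sqrt(0.5))
    else {
      pick <- runif(n_loci) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  g <- a1 + a2
  tcrossprod(g) / n_loci
}

# marginal posterior of (sigma2_dam, sigma2_sire, sigma2_e) on a grid, with
# fixed effects integrated out under a flat prior and flat priors on the
# variances:  p(v | y) propto |V|^-1/2 |X' V^-1 X|^-1/2 exp(-y'Py/2)
grid_posterior_oracle <- function(y, X, Zd, Ad, Zs, As,
                                  grid_d, grid_s, grid_e) {
  n <- length(y)
  Kd <- Zd %*% Ad %*% t(Zd)
  Ks <- Zs %*% As %*% t(Zs)
  ll <- array(NA_real_, c(length(grid_d), length(grid_s), length(grid_e)))
  for (i in seq_along(grid_d)) for (j in seq_along(grid_s))
    for (k in seq_along(grid_e)) {
      V <- grid_d[i] * Kd + grid_s[j] * Ks + diag(grid_e[k], n)
      cV <- chol(V)
      Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
      Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
      XtViX <- crossprod(X, Vi_X)
      beta <- solve(XtViX, crossprod(X, Vi_y))
      quad <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
      ll[i, j, k] <- -sum(log(diag(cV))) -
        0.5 * determinant(XtViX, logarithm = TRUE)$modulus -
        0.5 * quad
    }
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  list(mean_d = sum(sweep(w, 1, grid_d, `*`)),
       mean_s = sum(sweep(w, 2, grid_s, `*`)),
       mean_e = sum(sweep(w, 3, grid_e, `*`)),
       weights = w)
}

# selection-index accuracy for two predictors by brute-force search over
# weight directions (accuracy is scale-invariant in the weights)
index_grid_oracle <- function(P, g, sigma2, n_angle = 20000) {
  ang <- seq(0, pi, length.out = n_angle)
  best <- -Inf
  for (a in ang) {
    w <- c(cos(a), sin(a))
    denom <- sqrt(as.numeric(t(w) %*% P %*% w) * sigma2)
    r <- abs(sum(w * g)) / denom
    if (r > best) best <- r
  }
  best
}
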