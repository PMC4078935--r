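# inverse-Wishart draw: G ~ IW(nu, S)  <=>  G^{-1} ~ Wishart(nu, S^{-1});
# a flat prior on a t x t covariance corresponds to nu_prior = -(t+1), so the
# full conditional given q effect vectors is IW(q - t - 1, sum-of-squares).
.riwish <- function(nu, S) {
  t <- nrow(S)
  if (nu <= t - 1) stop("inverse-Wishart degrees of freedom too small")
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular scale matrix in covariance update; jittered")
    solve(S + diag(1e-8 * (mean(diag(S)) + 1), t))
  })
  Sinv <- (Sinv + t(Sinv)) / 2
  W <- stats::rWishart(1, nu, Sinv)[, , 1]
  G <- solve(W)
  (G + t(G)) / 2
}

#' Bayesian crossbred sire-dam model by Gibbs sampling
#'
#' Fits the two-parental-line model for crossbred records: for crossbred
#' \eqn{i} with dam \eqn{d} (common line) and sire \eqn{s} (Muscovy line),
#' \deqn{y_i = X_i b + u^{dam}_d + u^{sire}_s + e_i}
#' where the dam-line effects have prior \eqn{N(0, A_{dam} \otimes G_{dam})}
#' with \eqn{A} the pedigree relationship matrix of that line, likewise for
#' the sire line, and residuals \eqn{N(0, R)} absorbing the crossbreds'
#' Mendelian sampling. Fixed effects take a flat prior; the covariance
#' matrices take flat priors (improper inverse-Wishart).
#'
#' The sampler cycles between (i) one joint draw of the complete location
#' vector (all fixed and genetic effects, all traits) from its multivariate
#' normal full conditional via a sparse Cholesky of the mixed-model
#' equations, and (ii) inverse-Wishart draws of `G_dam`, `G_sire` and `R`.
#'
#' @param formula phenotypes on the left (use `cbind()` for multi-trait),
#'   systematic effects on the right, e.g. `cbind(mMR, pMR) ~ factor(level)`.
#' @param data data frame with the phenotype columns and the `dam` / `sire`
#'   id columns.
#' @param dam_pedigree,sire_pedigree [pedigree] objects; every dam / sire
#'   in `data` must appear in its line's pedigree.
#' @param dam,sire names of the parent id columns in `data`.
#' @param chain total chain length (default 100000).
#' @param burn_in discarded iterations (default 20000).
#' @param thin keep every `thin`-th post-burn-in component sample
#'   (default 1; EBV posterior means always use every retained iteration).
#' @param start starting values: every variance `start$variance` (default
#'   1) and every covariance `start$covariance` (default 0.01).
#' @param seed integer seed; fixed seed gives identical retained samples.
#' @param verbose print progress every 2000 iterations.
#' @return Object of class `"cross_gibbs"`: retained `samples` (arrays
#'   `G_dam`, `G_sire`, `R` of dimension traits x traits x kept), posterior
#'   mean EBVs per line (`ebv_dam`, `ebv_sire`), posterior-mean fixed
#'   effects, dimensions and chain settings.
#' @seealso [partial_heritability()], [genetic_correlation()], [ebv()],
#'   [summary.cross_gibbs()]
#' @export
cross_gibbs <- function(formula, data, dam_pedigree, sire_pedigree,
                        dam = "dam", sire = "sire",
                        chain = 100000, burn_in = 20000, thin = 1,
                        start = list(variance = 1, covariance = 0.01),
                        seed = NULL, verbose = FALSE) {
  if (burn_in >= chain) stop("burn_in must be smaller than chain")
  if (!is.null(seed)) set.seed(seed)

  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  Y <- stats::model.response(mf)
  Y <- as.matrix(Y)
  t <- ncol(Y)
  traits <- colnames(Y)
  if (is.null(traits)) traits <- paste0("trait", seq_len(t))
  n <- nrow(Y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  nf <- ncol(X)

  dpos <- match(as.character(data[[dam]]), as.character(dam_pedigree$id))
  spos <- match(as.character(data[[sire]]), as.character(sire_pedigree$id))
  if (anyNA(dpos)) stop("dams absent from dam_pedigree: ",
                        paste(utils::head(unique(data[[dam]][is.na(dpos)]), 5),
                              collapse = ", "))
  if (anyNA(spos)) stop("sires absent from sire_pedigree: ",
                        paste(utils::head(unique(data[[sire]][is.na(spos)]), 5),
                              collapse = ", "))
  qd <- nrow(dam_pedigree); qs <- nrow(sire_pedigree)

  Zd <- Matrix::sparseMatrix(i = seq_len(n), j = dpos, x = 1,
                             dims = c(n, qd))
  Zs <- Matrix::sparseMatrix(i = seq_len(n), j = spos, x = 1,
                             dims = c(n, qs))
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix")
  W <- methods::cbind2(methods::cbind2(Xs, Zd), Zs)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  M <- as.matrix(Matrix::crossprod(W, Y))
  Qd <- build_A_inverse(dam_pedigree)
  Qs <- build_A_inverse(sire_pedigree)
  p <- nf + qd + qs

  sv <- matrix(start$covariance %||% 0.01, t, t)
  diag(sv) <- start$variance %||% 1
  Gd <- sv; Gs <- sv; R <- sv

  # The coefficient matrix of the mixed-model equations is
  #   C = (W'W) x R^-1 + diag(0, A_dam^-1 x G_dam^-1, A_sire^-1 x G_sire^-1)
  # (x = Kronecker, traits nested within effects). Its sparsity pattern is
  # fixed across iterations, so the symbolic work is done once: each of the
  # three symmetric components is expanded to trait-block entries with (a)
  # the index of its parent entry, (b) the index into the t x t multiplier
  # (R^-1 or G^-1), and (c) its position in the unified upper-triangle
  # pattern. Per iteration only the numeric slot is refilled.
  upper_triplets <- function(S, off) {
    Ts <- methods::as(methods::as(S, "symmetricMatrix"), "TsparseMatrix")
    i <- Ts@i + 1L; j <- Ts@j + 1L
    flip <- i > j
    list(i = ifelse(flip, j, i) + off, j = ifelse(flip, i, j) + off,
         x = Ts@x)
  }
  expand_blocks <- function(tr) {
    ne <- length(tr$x)
    a <- rep(rep(seq_len(t), times = t), ne)
    b <- rep(rep(seq_len(t), each = t), ne)
    e <- rep(seq_len(ne), each = t * t)
    i <- (tr$i[e] - 1L) * t + a
    j <- (tr$j[e] - 1L) * t + b
    keep <- i <= j
    list(i = i[keep], j = j[keep], e = e[keep],
         ab = a[keep] + (b[keep] - 1L) * t, x = tr$x)
  }
  comps <- list(expand_blocks(upper_triplets(WtW, 0L)),
                expand_blocks(upper_triplets(Qd, nf)),
                expand_blocks(upper_triplets(Qs, nf + qd)))
  P <- p * t
  C0 <- Matrix::sparseMatrix(i = unlist(lapply(comps, `[[`, "i")),
                             j = unlist(lapply(comps, `[[`, "j")),
                             x = 1, dims = c(P, P), symmetric = TRUE)
  cols0 <- rep(seq_len(P), diff(C0@p))
  key0 <- (C0@i + 1) + (cols0 - 1) * as.double(P)
  for (k in 1:3)
    comps[[k]]$pos <- match(comps[[k]]$i + (comps[[k]]$j - 1) *
                              as.double(P), key0)
  nnz <- length(C0@x)
  fill_C <- function(Rinv, Gdinv, Gsinv) {
    xc <- numeric(nnz)
    mults <- list(Rinv, Gdinv, Gsinv)
    for (k in 1:3) {
      cm <- comps[[k]]
      xc[cm$pos] <- xc[cm$pos] + cm$x[cm$e] * mults[[k]][cm$ab]
    }
    C0@x <- xc
    C0
  }

  C <- fill_C(solve(R), solve(Gd), solve(Gs))
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)

  keep_iters <- seq(burn_in + thin, chain, by = thin)
  nkeep <- length(keep_iters)
  samp <- list(G_dam = array(NA_real_, c(t, t, nkeep)),
               G_sire = array(NA_real_, c(t, t, nkeep)),
               R = array(NA_real_, c(t, t, nkeep)))
  ebv_dam_sum <- matrix(0, qd, t)
  ebv_sire_sum <- matrix(0, qs, t)
  fixed_sum <- matrix(0, nf, t)
  n_acc <- 0L
  ki <- 0L
  dam_rows <- nf + seq_len(qd)
  sire_rows <- nf + qd + seq_len(qs)

  for (it in seq_len(chain)) {
    Rinv <- solve(R)
    C <- fill_C(Rinv, solve(Gd), solve(Gs))
    ch <- Matrix::update(ch, C)
    if (t == 1) rhs <- M[, 1] * Rinv[1, 1]
    else rhs <- as.vector(Rinv %*% t(M))
    mu <- as.numeric(Matrix::solve(ch, rhs))
    z <- stats::rnorm(p * t)
    dev <- as.numeric(Matrix::solve(
      ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
    theta <- mu + dev
    if (any(!is.finite(theta)))
      stop("divergent chain: non-finite location draw at iteration ", it,
           " (G_dam diag = ", paste(signif(diag(Gd), 3), collapse = ","), ")")
    Th <- matrix(theta, nrow = t)   # traits x effects
    U <- t(Th)
    Eres <- Y - as.matrix(W %*% U)
    R <- .riwish(n - t - 1, crossprod(Eres))
    Udam <- U[dam_rows, , drop = FALSE]
    Usire <- U[sire_rows, , drop = FALSE]
    Sd <- as.matrix(Matrix::crossprod(Udam, Qd %*% Udam))
    Ss <- as.matrix(Matrix::crossprod(Usire, Qs %*% Usire))
    Gd <- .riwish(qd - t - 1, (Sd + t(Sd)) / 2)
    Gs <- .riwish(qs - t - 1, (Ss + t(Ss)) / 2)

    if (it > burn_in) {
      n_acc <- n_acc + 1L
      ebv_dam_sum <- ebv_dam_sum + Udam
      ebv_sire_sum <- ebv_sire_sum + Usire
      fixed_sum <- fixed_sum + U[seq_len(nf), , drop = FALSE]
      if ((it - burn_in) %% thin == 0) {
        ki <- ki + 1L
        samp$G_dam[, , ki] <- Gd
        samp$G_sire[, , ki] <- Gs
        samp$R[, , ki] <- R
      }
    }
    if (verbose && it %% 2000 == 0)
      message("iteration ", it, "/", chain)
  }

  ebv_dam <- ebv_dam_sum / n_acc
  ebv_sire <- ebv_sire_sum / n_acc
  rownames(ebv_dam) <- as.character(dam_pedigree$id)
  rownames(ebv_sire) <- as.character(sire_pedigree$id)
  colnames(ebv_dam) <- colnames(ebv_sire) <- traits
  fixed <- fixed_sum / n_acc
  rownames(fixed) <- colnames(X)
  colnames(fixed) <- traits

  structure(list(samples = samp, traits = traits, n = n,
                 ebv_dam = ebv_dam, ebv_sire = ebv_sire, fixed = fixed,
                 chain = chain, burn_in = burn_in, thin = thin,
                 n_kept = nkeep, seed = seed,
                 dims = c(fixed = nf, dam = qd, sire = qs),
                 dam_line = attr(dam_pedigree, "line"),
                 sire_line = attr(sire_pedigree, "line"),
                 call = match.call()),
            class = "cross_gibbs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cross_gibbs <- function(x, ...) {
  cat("Crossbred sire-dam model (Gibbs)\n")
  cat("  traits: ", paste(x$traits, collapse = ", "),
      "  records: ", x$n, "\n", sep = "")
  cat("  pedigrees: ", x$dims["dam"], " dam-line / ", x$dims["sire"],
      " sire-line animals\n", sep = "")
  cat("  chain ", x$chain, " (burn-in ", x$burn_in, ", kept ", x$n_kept,
      ")\n", sep = "")
  h <- vapply(seq_along(x$traits), function(k) c(
    partial_heritability(x, "dam", k)$mean,
    partial_heritability(x, "sire", k)$mean), numeric(2))
  cat("  posterior-mean partial h2 (dam):  ",
      paste(sprintf("%.3f", h[1, ]), collapse = " "), "\n")
  cat("  posterior-mean partial h2 (sire): ",
      paste(sprintf("%.3f", h[2, ]), collapse = " "), "\n")
  invisible(x)
}

#' Posterior-mean (co)variance components
#' @param object a [cross_gibbs] fit.
#' @param ... unused.
#' @return List of posterior means `G_dam`, `G_sire`, `R`.
#' @export
coef.cross_gibbs <- function(object, ...) {
  lapply(object$samples, function(a) {
    m <- apply(a, c(1, 2), mean)
    dimnames(m) <- list(object$traits, object$traits)
    m
  })
}

# effective sample size by Geyer's initial positive sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  maxlag <- min(n - 2, 2000)
  rho <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k < length(rho)) {
    pair <- rho[k] + if (k + 1 <= length(rho)) rho[k + 1] else 0
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

# split-chain potential scale reduction
.split_rhat <- function(x) {
  n2 <- floor(length(x) / 2)
  if (n2 < 5) return(NA_real_)
  h <- list(x[seq_len(n2)], x[n2 + seq_len(n2)])
  m <- vapply(h, mean, 0); v <- vapply(h, stats::var, 0)
  Wv <- mean(v); Bv <- n2 * stats::var(m)
  if (Wv == 0) return(1)
  sqrt(((n2 - 1) / n2 * Wv + Bv / n2) / Wv)
}

#' Summarize a crossbred Gibbs fit
#'
#' Posterior means and SDs of the partial heritabilities per line and
#' trait, genetic correlations per line (multi-trait fits), residual
#' correlations, plus effective sample sizes and split-chain diagnostics
#' for the heritability chains.
#'
#' @param object a [cross_gibbs] fit.
#' @param ... unused.
#' @return A list of class `"summary.cross_gibbs"`.
#' @export
summary.cross_gibbs <- function(object, ...) {
  t <- length(object$traits)
  h2 <- do.call(rbind, lapply(c("dam", "sire"), function(line)
    do.call(rbind, lapply(seq_len(t), function(k) {
      ph <- partial_heritability(object, line, k)
      data.frame(line = line, trait = object$traits[k],
                 mean = ph$mean, sd = ph$sd,
                 ess = .ess(ph$samples), rhat = .split_rhat(ph$samples))
    }))))
  rg <- NULL
  if (t > 1) {
    pairs <- utils::combn(t, 2)
    rg <- do.call(rbind, lapply(c("dam", "sire"), function(line)
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        gc <- genetic_correlation(object, line, pairs[, j])
        data.frame(line = line,
                   trait_i = object$traits[pairs[1, j]],
                   trait_j = object$traits[pairs[2, j]],
                   mean = gc$mean, sd = gc$sd)
      }))))
  }
  structure(list(h2 = h2, rg = rg, components = coef(object),
                 traits = object$traits, chain = object$chain,
                 burn_in = object$burn_in, n = object$n),
            class = "summary.cross_gibbs")
}

#' @export
print.summary.cross_gibbs <- function(x, ...) {
  cat("Partial heritabilities (posterior mean, SD):\n")
  print(x$h2, row.names = FALSE, digits = 3)
  if (!is.null(x$rg)) {
    cat("\nGenetic correlations (posterior mean, SD):\n")
    print(x$rg, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Trace plots of the partial-heritability chains
#' @param x a [cross_gibbs] fit.
#' @param ... passed to [plot()].
#' @export
plot.cross_gibbs <- function(x, ...) {
  t <- length(x$traits)
  op <- graphics::par(mfrow = c(t, 2), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in seq_len(t)) for (line in c("dam", "sire")) {
    s <- partial_heritability(x, line, k)$samples
    plot(s, type = "l", ylab = "partial h2",
         main = paste(x$traits[k], line, "line"), ...)
  }
  invisible(x)
}
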