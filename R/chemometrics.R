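#' PLS1 regression (NIPALS)
#'
#' Fits a single-response partial least squares regression by NIPALS with
#' deflation, on column-centered predictors and centered response. The
#' returned regression vector lives in the original (processed-spectrum)
#' space, so prediction is `intercept + X %*% coefficients`.
#'
#' @param X numeric matrix, samples x variables (processed spectra). Row
#'   names, if present, are kept as training sample ids.
#' @param y numeric response (trait, in trait units).
#' @param ncomp number of latent variables.
#' @return Object of class `"pls_calibration"` with elements
#'   `coefficients`, `intercept`, `ncomp`, `x_mean`, `y_mean`, `scores`,
#'   `loadings`, `weights`, `train_ids`, `fitted`, `sec`, `r2`.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows of X must match length of y")
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (n < ncomp + 2) stop("need at least ncomp + 2 samples")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("ncomp = ", ncomp, " exceeds the effective rank of X")
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) stop("degenerate latent variable at component ", k)
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tt %*% t(pp)
    yd <- yd - tt * qq
    W[, k] <- w; P[, k] <- pp; Tm[, k] <- tt; q[k] <- qq
  }
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- as.numeric(Xc %*% B) + ym
  res <- y - fitted
  sec <- sqrt(sum(res^2) / max(n - ncomp - 1, 1))
  r2 <- if (stats::sd(fitted) > 0) stats::cor(y, fitted)^2 else 0
  structure(list(coefficients = as.numeric(B),
                 intercept = ym - sum(xm * B),
                 ncomp = ncomp, x_mean = xm, y_mean = ym,
                 scores = Tm, loadings = P, weights = W,
                 train_ids = rownames(X), fitted = fitted,
                 sec = sec, r2 = r2, n = n),
            class = "pls_calibration")
}

#' @export
print.pls_calibration <- function(x, ...) {
  cat(sprintf(
    "PLS1 calibration: %d samples, %d variables, %d latent variables\n",
    x$n, length(x$coefficients), x$ncomp))
  cat(sprintf("  SEC = %.4g, calibration R2 = %.4g\n", x$sec, x$r2))
  invisible(x)
}

#' @export
coef.pls_calibration <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.pls_calibration <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_set")) as.matrix(newdata)
       else as.matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("newdata has ", ncol(X), " variables; model expects ",
         length(object$coefficients))
  as.numeric(X %*% object$coefficients) + object$intercept
}

#' Five-group cross-validation of a PLS calibration
#'
#' Splits samples into `n_groups` contiguous blocks after a seeded shuffle;
#' each block is predicted by a model fitted on the others. SECV is the
#' root-mean-square cross-validation residual (uncorrected). The number of
#' latent variables is the SECV minimizer, with a one-standard-error
#' parsimony tie-break (smallest ncomp whose SECV is within one SE of the
#' minimum).
#'
#' @param X predictor matrix (processed spectra).
#' @param y response vector.
#' @param ncomp_grid candidate latent-variable counts.
#' @param n_groups number of cross-validation groups (default 5).
#' @param seed integer seed for the shuffle (NULL = current RNG state).
#' @param one_se apply the 1-SE parsimony rule (default TRUE).
#' @return List with `best_ncomp`, `secv` (for best), `secv_by_ncomp`,
#'   `groups` (fold assignment).
#' @export
pls_cv <- function(X, y, ncomp_grid = 1:10, n_groups = 5, seed = NULL,
                   one_se = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < n_groups) stop("need at least n_groups samples")
  if (!is.null(seed)) set.seed(seed)
  # contiguous blocks of a seeded shuffle
  ord <- sample.int(n)
  fold <- integer(n)
  fold[ord] <- rep(seq_len(n_groups), each = ceiling(n / n_groups))[seq_len(n)]
  ncomp_grid <- ncomp_grid[ncomp_grid <= n - ceiling(n / n_groups) - 2]
  if (!length(ncomp_grid)) stop("no feasible ncomp for this sample size")
  press <- matrix(NA_real_, length(ncomp_grid), n_groups)
  cvres <- matrix(NA_real_, n, length(ncomp_grid))
  for (gidx in seq_len(n_groups)) {
    hold <- fold == gidx
    if (!any(hold)) stop("empty cross-validation group")
    ytr <- y[!hold]
    for (ci in seq_along(ncomp_grid)) {
      if (stats::sd(ytr) == 0) {
        pred <- rep(mean(ytr), sum(hold))  # intercept-only
      } else {
        m <- tryCatch(
          pls_fit(X[!hold, , drop = FALSE], ytr, ncomp_grid[ci]),
          error = function(e) {
            if (grepl("rank|degenerate", conditionMessage(e))) NULL
            else stop(e)
          })
        if (is.null(m)) break  # grid exceeds the training fold's rank
        pred <- predict(m, X[hold, , drop = FALSE])
      }
      r <- y[hold] - pred
      cvres[hold, ci] <- r
      press[ci, gidx] <- mean(r^2)
    }
  }
  feasible <- colSums(is.na(cvres)) == 0
  if (!any(feasible)) stop("no feasible ncomp for these folds")
  secv_by <- sqrt(colMeans(cvres^2))
  se_by <- apply(press, 1, stats::sd) / sqrt(n_groups)
  best_i <- which.min(replace(secv_by, !feasible, Inf))
  if (one_se) {
    thr <- secv_by[best_i] + se_by[best_i]
    best_i <- which(feasible & secv_by <= thr)[1]
  }
  list(best_ncomp = ncomp_grid[best_i], secv = secv_by[best_i],
       secv_by_ncomp = stats::setNames(secv_by, ncomp_grid),
       groups = fold)
}

#' Representative calibration-set selection
#'
#' PCA on the processed spectra followed by Kennard-Stone selection on the
#' leading scores (enough components to explain at least `var_explained` of
#' the variance): start from the sample farthest from the centroid, then
#' repeatedly add the sample maximizing the minimum distance to the current
#' set. Deterministic; exact ties broken by lowest row index. Degenerate
#' inputs (zero spectral variance) fall back to seeded random selection
#' with a warning.
#'
#' @param X processed spectra matrix (one row per sample).
#' @param n_select number of samples to select (< nrow(X) selects a subset;
#'   = nrow(X) returns everything).
#' @param var_explained PCA variance fraction retained (default 0.99).
#' @param seed seed for the degenerate-fallback only.
#' @return Integer vector of selected row indices (or row names if set).
#' @export
select_calibration_set <- function(X, n_select, var_explained = 0.99,
                                   seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select > n) stop("n_select exceeds the number of samples")
  if (n_select == n) return(seq_len(n))
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) {
    warning("spectra have no variance; falling back to random selection")
    if (!is.null(seed)) set.seed(seed)
    return(sort(sample.int(n, n_select)))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1, which(cum >= var_explained)[1])
  S <- pc$x[, seq_len(k), drop = FALSE]
  centroid <- colMeans(S)
  d0 <- sqrt(rowSums(sweep(S, 2, centroid)^2))
  sel <- which.max(d0)
  mind <- sqrt(rowSums(sweep(S, 2, S[sel, ])^2))
  while (length(sel) < n_select) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    dn <- sqrt(rowSums(sweep(S, 2, S[nxt, ])^2))
    mind <- pmin(mind, dn)
  }
  sort(sel)
}

#' External validation of a calibration
#'
#' Applies the model to samples never used in calibration and reports the
#' standard error of prediction: SEP is the standard deviation of the
#' prediction residuals about their mean (bias-corrected, n-1 denominator);
#' the mean residual is reported separately as bias. The calibration R2
#' (squared Pearson correlation of fitted vs observed on the training set)
#' is carried over from the model.
#'
#' @param model a [pls_fit] calibration.
#' @param X_ext external spectra matrix with row names as sample ids.
#' @param y_ext external reference values.
#' @return Object of class `"nirs_validation"`: list with `n`, `mean`,
#'   `sd`, `sep`, `bias`, `rmsep`, `r2_cal`.
#' @export
validate_external <- function(model, X_ext, y_ext) {
  X_ext <- as.matrix(X_ext)
  if (!is.null(model$train_ids) && !is.null(rownames(X_ext))) {
    overlap <- intersect(model$train_ids, rownames(X_ext))
    if (length(overlap))
      stop("external set overlaps the calibration set: ",
           paste(utils::head(overlap, 5), collapse = ", "))
  }
  pred <- predict(model, X_ext)
  res <- y_ext - pred
  n <- length(res)
  structure(list(n = n, mean = mean(y_ext), sd = stats::sd(y_ext),
                 sep = if (n > 1) stats::sd(res) else 0,
                 bias = mean(res),
                 rmsep = sqrt(mean(res^2)),
                 r2_cal = model$r2),
            class = "nirs_validation")
}

#' @export
print.nirs_validation <- function(x, ...) {
  cat(sprintf("external validation: n = %d, mean = %.3g, SD = %.3g\n",
              x$n, x$mean, x$sd))
  cat(sprintf("  SEP = %.4g (bias %.3g), RMSEP = %.4g, cal. R2 = %.3g\n",
              x$sep, x$bias, x$rmsep, x$r2_cal))
  invisible(x)
}

#' Full calibration workflow for one trait
#'
#' The chemometric workflow in one call: preprocess raw spectra with a
#' recipe, select a representative calibration set, choose the number of
#' latent variables by five-group cross-validation, fit the final PLS model
#' on the calibration set and validate it on the remaining samples.
#'
#' @param spectra a raw [spectra_set] (replicates allowed).
#' @param y named numeric vector of reference values; names must match the
#'   sample ids with references available (e.g. the assayed subset).
#' @param recipe a [preprocess_recipe].
#' @param n_select calibration-set size (default: all samples with
#'   reference values, capped at 198).
#' @param ncomp_grid candidate latent-variable counts.
#' @param n_groups CV groups (default 5).
#' @param seed seed for CV fold assignment.
#' @return Object of class `"nirs_calibration"`: the fitted `model`, the
#'   `recipe`, `stats` (n, mean, sd, sec, r2, secv and, when an external
#'   set exists, sep/bias on it), `calibration_ids`, `validation`.
#' @export
nirs_calibration <- function(spectra, y, recipe = preprocess_recipe(),
                             n_select = NULL, ncomp_grid = 1:10,
                             n_groups = 5, seed = NULL) {
  proc <- apply_recipe(spectra, recipe)
  X <- as.matrix(proc)
  if (is.null(names(y))) stop("y must be named by sample id")
  avail <- intersect(rownames(X), names(y))
  if (length(avail) < n_groups + 2) stop("too few referenced samples")
  if (is.null(n_select)) n_select <- min(length(avail), 198)
  Xa <- X[avail, , drop = FALSE]
  sel <- select_calibration_set(Xa, n_select, seed = seed)
  cal_ids <- avail[sel]
  Xc <- Xa[sel, , drop = FALSE]
  yc <- as.numeric(y[cal_ids])
  cv <- pls_cv(Xc, yc, ncomp_grid, n_groups = n_groups, seed = seed)
  model <- pls_fit(Xc, yc, cv$best_ncomp)
  ext_ids <- setdiff(avail, cal_ids)
  val <- if (length(ext_ids) > 1)
    validate_external(model, Xa[ext_ids, , drop = FALSE], y[ext_ids])
  else NULL
  stats <- list(n = length(cal_ids), mean = mean(yc), sd = stats::sd(yc),
                sec = model$sec, r2 = model$r2, secv = cv$secv,
                ncomp = cv$best_ncomp,
                sep = if (!is.null(val)) val$sep else NA_real_,
                bias = if (!is.null(val)) val$bias else NA_real_,
                n_ext = if (!is.null(val)) val$n else 0L)
  structure(list(model = model, recipe = recipe, stats = stats,
                 calibration_ids = cal_ids, validation = val,
                 cv = cv, processed = proc),
            class = "nirs_calibration")
}

#' @export
print.nirs_calibration <- function(x, ...) {
  s <- x$stats
  cat("NIRS calibration (", format(x$recipe), ")\n", sep = "")
  cat(sprintf(
    "  calibration n=%d  mean=%.1f SD=%.1f  SEC=%.2f R2=%.2f SECV=%.2f (%d LV)\n",
    s$n, s$mean, s$sd, s$sec, s$r2, s$secv, s$ncomp))
  if (s$n_ext > 0)
    cat(sprintf("  validation  n=%d  SEP=%.2f (bias %.2f)\n",
                s$n_ext, s$sep, s$bias))
  invisible(x)
}

#' @export
predict.nirs_calibration <- function(object, newdata, ...) {
  proc <- if (inherits(newdata, "spectra_set"))
    apply_recipe(newdata, object$recipe) else newdata
  predict(object$model, proc)
}

#' The preprocessing grid explored during calibration
#'
#' Derivative orders 0/1/2 crossed with 0/5/10/15/20 data points for
#' derivation and smoothing and the normalization treatments (none, SNV,
#' detrend, MSC). Infeasible combinations (derivative with 0 points) are
#' dropped.
#'
#' @param window wavelength window passed to every recipe.
#' @return List of [preprocess_recipe] objects.
#' @export
default_recipe_grid <- function(window = c(800, 2500)) {
  pts <- c(0, 5, 10, 15, 20)
  out <- list()
  for (ord in 0:2) for (g in pts) for (s in pts)
    for (nm in c("none", "snv", "detrend", "msc")) {
      if (ord > 0 && g == 0) next
      if (ord == 0 && g > 0) next
      sw <- if (s == 0) 0 else s + (s %% 2 == 0)  # centered window must be odd
      out[[length(out) + 1]] <-
        preprocess_recipe(ord, max(g, 1), sw, nm, window)
    }
  out
}

#' Search preprocessing recipes by cross-validation error
#'
#' Evaluates each recipe by SECV (via [pls_cv]) on the referenced samples
#' and returns the recipe with the lowest SECV together with the full
#' results table.
#'
#' @param recipes list of [preprocess_recipe] objects.
#' @param spectra raw [spectra_set].
#' @param y named reference values (see [nirs_calibration]).
#' @param ncomp_grid candidate latent-variable counts.
#' @param n_groups CV groups.
#' @param seed CV seed (same folds across recipes).
#' @return List with `best` (recipe), `table` (data frame of recipe label,
#'   secv, ncomp).
#' @export
grid_search_recipes <- function(recipes, spectra, y, ncomp_grid = 1:8,
                                n_groups = 5, seed = NULL) {
  if (!length(recipes)) stop("need at least one recipe")
  rows <- lapply(recipes, function(r) {
    proc <- apply_recipe(spectra, r)
    X <- as.matrix(proc)
    avail <- intersect(rownames(X), names(y))
    cv <- pls_cv(X[avail, , drop = FALSE], as.numeric(y[avail]),
                 ncomp_grid, n_groups = n_groups, seed = seed)
    data.frame(recipe = format(r), secv = cv$secv, ncomp = cv$best_ncomp)
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$secv)
  list(best = recipes[[best]], table = tab)
}
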