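#' Spectra container
#'
#' Holds a set of absorbance spectra on a common, strictly increasing
#' wavelength grid. Rows are individual scans; several replicate scans may
#' share a `sample_id` (six surface scans per liver with the portable
#' instrument, three aliquot scans with the bench instrument).
#'
#' @param values numeric matrix, one row per scan, one column per wavelength.
#' @param wavelengths numeric vector (nm), strictly increasing.
#' @param sample_id vector of sample labels, one per row.
#' @param replicate_id optional replicate labels within sample.
#' @param mode acquisition mode tag, `"surface"` or `"ground"`.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(values, wavelengths, sample_id,
                        replicate_id = NULL, mode = "surface") {
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("ncol(values) must equal length(wavelengths)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (nrow(values) != length(sample_id))
    stop("one sample_id per spectrum required")
  if (anyNA(values)) stop("spectra contain missing values")
  if (is.null(replicate_id)) replicate_id <- stats::ave(
    rep(1, nrow(values)), sample_id, FUN = seq_along)
  structure(list(values = values, wavelengths = wavelengths,
                 sample_id = as.vector(sample_id),
                 replicate_id = as.vector(replicate_id),
                 mode = mode),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set (", x$mode, "): ", nrow(x$values), " scans / ",
      length(unique(x$sample_id)), " samples, ",
      length(x$wavelengths), " wavelengths [",
      min(x$wavelengths), "-", max(x$wavelengths), " nm]\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.spectra_set <- function(x, ...) {
  m <- x$values
  rownames(m) <- if (anyDuplicated(x$sample_id))
    paste(x$sample_id, x$replicate_id, sep = ".") else as.character(x$sample_id)
  colnames(m) <- x$wavelengths
  m
}

.rebuild <- function(ss, values, wavelengths = ss$wavelengths) {
  spectra_set(values, wavelengths, ss$sample_id, ss$replicate_id, ss$mode)
}

#' Average replicate scans into one spectrum per sample
#'
#' The pointwise arithmetic mean of all scans sharing a `sample_id`; the
#' averaged spectrum is what enters calibration.
#'
#' @param ss a [spectra_set].
#' @return A [spectra_set] with one row per sample (order of first
#'   appearance); the number of scans averaged is kept in the
#'   `"n_replicates"` attribute.
#' @export
average_replicates <- function(ss) {
  ids <- unique(ss$sample_id)
  g <- match(ss$sample_id, ids)
  counts <- tabulate(g, nbins = length(ids))
  m <- rowsum(ss$values, g, reorder = TRUE) / counts
  out <- spectra_set(m, ss$wavelengths, ids,
                     replicate_id = rep(1L, length(ids)), mode = ss$mode)
  attr(out, "n_replicates") <- stats::setNames(counts, ids)
  out
}

#' Trim spectra to a wavelength window
#'
#' Visible wavelengths are discarded before modelling; the working range for
#' liver calibration is 800-2500 nm.
#'
#' @param ss a [spectra_set].
#' @param window length-2 numeric, closed interval in nm.
#' @return Trimmed [spectra_set].
#' @export
trim_spectra <- function(ss, window = c(800, 2500)) {
  keep <- ss$wavelengths >= window[1] & ss$wavelengths <= window[2]
  if (!any(keep)) stop("trim window [", window[1], ", ", window[2],
                       "] contains no wavelengths")
  .rebuild(ss, ss$values[, keep, drop = FALSE], ss$wavelengths[keep])
}

#' Standard normal variate (SNV) normalization
#'
#' Centers and scales each spectrum to mean 0 and sample SD 1, removing
#' additive offsets and multiplicative scatter.
#'
#' @param ss a [spectra_set] (or plain numeric vector).
#' @return Same type as the input.
#' @export
snv <- function(ss) {
  f <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("constant spectrum: SNV undefined (zero SD)")
    (x - mean(x)) / s
  }
  if (is.numeric(ss)) return(f(ss))
  .rebuild(ss, t(apply(ss$values, 1, f)))
}

#' Detrend normalization
#'
#' Subtracts the least-squares quadratic polynomial of wavelength from each
#' spectrum, removing curved baselines.
#'
#' @param ss a [spectra_set].
#' @param degree polynomial degree (default 2).
#' @return Detrended [spectra_set].
#' @export
detrend_spectra <- function(ss, degree = 2) {
  X <- stats::poly(ss$wavelengths, degree)
  X1 <- cbind(1, X)
  H <- X1 %*% solve(crossprod(X1), t(X1))
  .rebuild(ss, ss$values - ss$values %*% t(H))
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum (by default the mean
#' spectrum of the set) and returns `(x - intercept) / slope`.
#'
#' @param ss a [spectra_set].
#' @param reference numeric reference spectrum; defaults to the set mean.
#' @return Corrected [spectra_set].
#' @export
msc <- function(ss, reference = NULL) {
  if (is.null(reference)) reference <- colMeans(ss$values)
  if (stats::sd(reference) == 0) stop("degenerate (constant) MSC reference")
  rc <- reference - mean(reference)
  vv <- sum(rc^2)
  out <- t(apply(ss$values, 1, function(x) {
    b <- sum((x - mean(x)) * rc) / vv
    a <- mean(x) - b * mean(reference)
    (x - a) / b
  }))
  .rebuild(ss, out)
}

# gap-segment first derivative of one spectrum: value at i is
# (mean of the `gap` points starting at i) - (mean of the `gap` points
# ending at i-1), divided by gap. Valid for i in [gap+1, n-gap+1].
.gap_deriv1 <- function(x, gap) {
  n <- length(x)
  if (n < 2 * gap + 1) stop("spectrum too short for gap ", gap)
  cs <- c(0, cumsum(x))
  i <- (gap + 1):(n - gap + 1)
  right <- (cs[i + gap] - cs[i]) / gap
  left <- (cs[i] - cs[i - gap]) / gap
  (right - left) / gap
}

# centered moving average, window w (odd); edges dropped
.movavg <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) stop("smoothing window must be odd")
  k <- (w - 1) / 2
  n <- length(x)
  if (n < w) stop("spectrum too short for smoothing window ", w)
  cs <- c(0, cumsum(x))
  i <- (k + 1):(n - k)
  (cs[i + k + 1] - cs[i - k]) / w
}

#' Gap-segment derivative with optional smoothing
#'
#' The chemometrics gap-segment convention: the order-1 derivative at point
#' i is the difference between the mean of the `gap` points to the right and
#' the mean of the `gap` points to the left, divided by `gap` (in data-point
#' units). Order 2 applies the operator recursively. A centered moving
#' average over `smooth_window` points is applied after derivation. Edge
#' points without full support are dropped, so the wavelength grid shrinks
#' by `order * gap` points plus `(smooth_window - 1) / 2` points per side.
#'
#' A centered Savitzky-Golay variant (polynomial order 2) is available
#' behind the same interface for sensitivity checks.
#'
#' @param ss a [spectra_set] (or numeric vector; then a vector is returned
#'   without grid bookkeeping).
#' @param order derivative order, 0, 1 or 2 (0 = smoothing only).
#' @param gap derivative gap in data points (ignored for order 0).
#' @param smooth_window moving-average window in points (odd; 0/1 = none).
#' @param method `"gap-segment"` (default) or `"savitzky-golay"`.
#' @return Same type as input, on the reduced grid.
#' @export
spectral_derivative <- function(ss, order = 1, gap = 10, smooth_window = 5,
                                method = c("gap-segment", "savitzky-golay")) {
  method <- match.arg(method)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  if (order > 0 && gap < 1) stop("gap must be >= 1")
  vec <- is.numeric(ss)
  vals <- if (vec) matrix(ss, nrow = 1) else ss$values
  wl <- if (vec) seq_len(ncol(vals)) else ss$wavelengths

  if (method == "savitzky-golay") {
    if (order == 0 && smooth_window <= 1) {
      out <- vals
    } else {
      w <- max(smooth_window, 2 * floor(gap / 2) + 1, 5)
      if (w %% 2 == 0) w <- w + 1
      out <- t(apply(vals, 1, function(x)
        signal::sgolayfilt(x, p = 2, n = w, m = order)))
      # drop the half-window at each edge where the filter extrapolates
      k <- (w - 1) / 2
      keep <- (k + 1):(ncol(out) - k)
      out <- out[, keep, drop = FALSE]
      wl <- wl[keep]
    }
  } else {
    proc <- function(x) {
      for (o in seq_len(order)) x <- .gap_deriv1(x, gap)
      if (smooth_window > 1) x <- .movavg(x, smooth_window)
      x
    }
    out <- t(apply(vals, 1, proc))
    n <- length(wl)
    idx <- seq_len(n)
    for (o in seq_len(order)) idx <- idx[(gap + 1):(length(idx) - gap + 1)]
    if (smooth_window > 1) {
      k <- (smooth_window - 1) / 2
      idx <- idx[(k + 1):(length(idx) - k)]
    }
    wl <- wl[idx]
  }
  if (vec) return(drop(out))
  .rebuild(ss, out, wl)
}

#' Preprocessing recipe
#'
#' Bundles the spectral pre-treatments explored during calibration:
#' wavelength trimming, a normalization (none, SNV, detrend or MSC), then a
#' gap-segment derivative with smoothing. Normalization is applied before
#' derivation (the retained treatment is a first derivative of SNV spectra).
#'
#' @param derivative_order 0, 1 or 2.
#' @param gap derivative gap in data points.
#' @param smooth_window smoothing window in data points (odd, or 0).
#' @param normalization one of `"none"`, `"snv"`, `"detrend"`, `"msc"`.
#' @param window wavelength window in nm.
#' @param method derivative convention, see [spectral_derivative].
#' @return An object of class `"preprocess_recipe"`.
#' @export
preprocess_recipe <- function(derivative_order = 1, gap = 10,
                              smooth_window = 5, normalization = "snv",
                              window = c(800, 2500),
                              method = "gap-segment") {
  normalization <- match.arg(normalization,
                             c("none", "snv", "detrend", "msc"))
  if (derivative_order > 0 && gap < 1) stop("gap must be >= 1")
  if (smooth_window > 1 && smooth_window %% 2 == 0)
    stop("smooth_window must be odd")
  structure(list(derivative_order = derivative_order, gap = gap,
                 smooth_window = smooth_window,
                 normalization = normalization, window = window,
                 method = method),
            class = "preprocess_recipe")
}

#' @export
print.preprocess_recipe <- function(x, ...) {
  cat(sprintf("recipe: d%d gap=%d smooth=%d %s [%g-%g nm] (%s)\n",
              x$derivative_order, x$gap, x$smooth_window,
              x$normalization, x$window[1], x$window[2], x$method))
  invisible(x)
}

#' @export
format.preprocess_recipe <- function(x, ...) {
  sprintf("d%d.g%d.s%d.%s", x$derivative_order, x$gap, x$smooth_window,
          x$normalization)
}

#' Apply a preprocessing recipe
#'
#' Operator order: trim, replicate averaging (if replicates are present),
#' normalization, derivative/smoothing.
#'
#' @param ss a [spectra_set].
#' @param recipe a [preprocess_recipe].
#' @param average average replicates (default TRUE when replicates exist).
#' @return The processed [spectra_set], one row per sample.
#' @export
apply_recipe <- function(ss, recipe, average = TRUE) {
  out <- trim_spectra(ss, recipe$window)
  if (average && anyDuplicated(out$sample_id)) out <- average_replicates(out)
  out <- switch(recipe$normalization,
                none = out,
                snv = snv(out),
                detrend = detrend_spectra(out),
                msc = msc(out))
  if (recipe$derivative_order > 0 || recipe$smooth_window > 1)
    out <- spectral_derivative(out, recipe$derivative_order, recipe$gap,
                               recipe$smooth_window, recipe$method)
  out
}

#' Read / write spectra in wide CSV format
#'
#' Columns: `sample`, `replicate`, then one column per wavelength (numeric
#' header, nm).
#' @param file path.
#' @param mode acquisition tag for the returned set.
#' @return [spectra_set] for the reader; invisibly `file` for the writer.
#' @export
read_spectra <- function(file, mode = "surface") {
  d <- utils::read.csv(file, check.names = FALSE)
  wl <- as.numeric(names(d)[-(1:2)])
  spectra_set(as.matrix(d[, -(1:2), drop = FALSE]), wl,
              d[[1]], d[[2]], mode = mode)
}

#' @rdname read_spectra
#' @param ss a [spectra_set] to write.
#' @export
write_spectra <- function(ss, file) {
  d <- data.frame(sample = ss$sample_id, replicate = ss$replicate_id,
                  check.names = FALSE)
  m <- as.data.frame(ss$values)
  names(m) <- ss$wavelengths
  utils::write.csv(cbind(d, m), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
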