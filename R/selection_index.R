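#' Selection-index accuracy
#'
#' Classic index theory: given the phenotypic covariance matrix `P` of the
#' predictor traits and the vector `g` of covariances between the predictor
#' phenotypes and the target breeding value, the optimal weights are
#' \eqn{b = P^{-1} g} and the accuracy of the index as a predictor of the
#' target breeding value is \eqn{r = \sqrt{b'g / \sigma^2_A}}.
#'
#' @param P symmetric positive-definite phenotypic covariance matrix of the
#'   predictor traits (squared trait units).
#' @param g covariances between predictor phenotypes and the target
#'   breeding value; `length(g) == nrow(P)`.
#' @param sigma2_target additive variance of the target trait (> 0).
#' @return Object of class `"selection_index"`: list with `weights`,
#'   `accuracy` (in \[0, 1\]).
#' @examples
#' # single predictor = the target's own phenotype: accuracy = h
#' h2 <- 0.25; vp <- 4
#' index_accuracy(P = matrix(vp), g = h2 * vp, sigma2_target = h2 * vp)
#' @export
index_accuracy <- function(P, g, sigma2_target) {
  P <- as.matrix(P)
  g <- as.numeric(g)
  if (nrow(P) != ncol(P) || !isSymmetric(unname(P), tol = 1e-8))
    stop("P must be a symmetric matrix")
  if (length(g) != nrow(P)) stop("length(g) must equal dim(P)")
  if (sigma2_target <= 0) stop("sigma2_target must be positive")
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev)))
    stop("P is singular (or not positive definite)")
  b <- solve(P, g)
  acc2 <- sum(b * g) / sigma2_target
  if (acc2 > 1 + 1e-8)
    stop("inconsistent inputs: implied accuracy exceeds 1 (",
         signif(sqrt(acc2), 4), ")")
  structure(list(weights = b, accuracy = sqrt(max(acc2, 0))),
            class = "selection_index")
}

#' @export
print.selection_index <- function(x, ...) {
  cat(sprintf("selection index: accuracy = %.3f (%d predictors)\n",
              x$accuracy, length(x$weights)))
  invisible(x)
}

#' Build a selection-index problem from fitted variance components
#'
#' Assembles `P` and `g` from the posterior-mean component matrices of a
#' [cross_gibbs] fit: the phenotypic covariance of the predictor traits is
#' `G_dam + G_sire + R` restricted to the predictors. With
#' `source = "genetic"` (the default) the target is the trait's breeding
#' value in the chosen line, so `g = G_line[predictors, target]` and the
#' target variance is `G_line[target, target]`; with
#' `source = "phenotypic"` the target is the trait's phenotype itself, so
#' both come from the phenotypic covariance.
#'
#' @param object a [cross_gibbs] fit (or a list with matrices `G_dam`,
#'   `G_sire`, `R`).
#' @param target target trait (index or name).
#' @param predictors predictor traits (default: all other traits).
#' @param line `"dam"` or `"sire"`: which line's breeding value is the
#'   target.
#' @param source covariance used for `g`, `"genetic"` or `"phenotypic"`.
#' @return A [index_accuracy] result.
#' @export
index_from_components <- function(object, target, predictors = NULL,
                                  line = c("dam", "sire"),
                                  source = c("genetic", "phenotypic")) {
  line <- match.arg(line)
  source <- match.arg(source)
  cmp <- if (inherits(object, "cross_gibbs")) coef(object) else object
  Gl <- if (line == "dam") cmp$G_dam else cmp$G_sire
  Pfull <- cmp$G_dam + cmp$G_sire + cmp$R
  t <- nrow(Pfull)
  ti <- if (is.character(target)) match(target, colnames(Pfull))
        else as.integer(target)
  if (is.null(predictors)) predictors <- setdiff(seq_len(t), ti)
  pi <- if (is.character(predictors)) match(predictors, colnames(Pfull))
        else as.integer(predictors)
  if (source == "genetic")        # target = line-specific breeding value
    index_accuracy(Pfull[pi, pi, drop = FALSE], Gl[pi, ti], Gl[ti, ti])
  else                            # target = the trait's phenotype itself
    index_accuracy(Pfull[pi, pi, drop = FALSE], Pfull[pi, ti],
                   Pfull[ti, ti])
}
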