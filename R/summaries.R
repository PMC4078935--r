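.trait_index <- function(object, trait) {
  if (is.character(trait)) {
    k <- match(trait, object$traits)
    if (is.na(k)) stop("unknown trait: ", trait)
    k
  } else as.integer(trait)
}

.line_samples <- function(object, line) {
  line <- match.arg(line, c("dam", "sire"))
  if (line == "dam") object$samples$G_dam else object$samples$G_sire
}

#' Partial heritability from a crossbred fit
#'
#' Per retained sample, the ratio of one parental line's variance to the
#' total \eqn{h^2 = \sigma^2_{line} / (\sigma^2_{dam} + \sigma^2_{sire} +
#' \sigma^2_e)} for the chosen trait, summarized after taking the ratio
#' (ratio-then-average). These are "partial" heritabilities: the crossbred
#' expresses only the transmitted half of each parental genome, so they
#' under-state conventional heritabilities (see [rescale_heritability()]).
#'
#' @param object a [cross_gibbs] fit.
#' @param line `"dam"` (common line) or `"sire"` (Muscovy line).
#' @param trait trait index or name (default first).
#' @return List with `mean`, `sd` and the per-sample `samples`.
#' @export
partial_heritability <- function(object, line = c("dam", "sire"),
                                 trait = 1) {
  line <- match.arg(line)
  k <- .trait_index(object, trait)
  gd <- object$samples$G_dam[k, k, ]
  gs <- object$samples$G_sire[k, k, ]
  re <- object$samples$R[k, k, ]
  tot <- gd + gs + re
  ok <- tot > 0
  if (!all(ok)) warning(sum(!ok), " samples with zero total variance excluded")
  num <- if (line == "dam") gd else gs
  h <- num[ok] / tot[ok]
  list(mean = mean(h), sd = stats::sd(h), samples = h,
       line = line, trait = object$traits[k])
}

#' Genetic correlation between two traits within a parental line
#'
#' Per retained sample \eqn{r = g_{ij} / \sqrt{g_{ii} g_{jj}}} from the
#' line's genetic covariance matrix, then summarized.
#'
#' @param object a multi-trait [cross_gibbs] fit.
#' @param line `"dam"` or `"sire"`.
#' @param traits length-2 vector of trait indices or names.
#' @return List with `mean`, `sd`, `samples`.
#' @export
genetic_correlation <- function(object, line = c("dam", "sire"),
                                traits = c(1, 2)) {
  line <- match.arg(line)
  if (length(object$traits) < 2) stop("fit has a single trait")
  i <- .trait_index(object, traits[[1]])
  j <- .trait_index(object, traits[[2]])
  G <- .line_samples(object, line)
  vi <- G[i, i, ]; vj <- G[j, j, ]; cij <- G[i, j, ]
  ok <- vi > 0 & vj > 0
  if (!all(ok)) warning(sum(!ok), " samples with non-positive variance excluded")
  r <- cij[ok] / sqrt(vi[ok] * vj[ok])
  list(mean = mean(r), sd = stats::sd(r), samples = r, line = line)
}

#' Rescale a partial heritability to the conventional scale
#'
#' Crossbreds are full sibs on the dam side and a full/half-sib mix on the
#' sire side, so the partial estimate is multiplied by 2 in the common
#' (dam) population and by a value between 2 and 4 in the Muscovy (sire)
#' population; results are capped at 1.
#'
#' @param h2 partial heritability in \[0, 1\].
#' @param line `"common"`/`"dam"` or `"muscovy"`/`"sire"`.
#' @return For the common line a single value (2 h2); for the Muscovy line
#'   a named interval `c(lower = 2 h2, upper = 4 h2)`.
#' @export
rescale_heritability <- function(h2, line = c("common", "muscovy",
                                              "dam", "sire")) {
  line <- match.arg(line)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  if (line %in% c("common", "dam")) pmin(2 * h2, 1)
  else c(lower = pmin(2 * h2, 1), upper = pmin(4 * h2, 1))
}

#' Posterior-mean genetic effects (EBVs)
#'
#' @param object a [cross_gibbs] fit.
#' @param line `"dam"` or `"sire"`.
#' @param trait optional trait index/name; default returns all traits.
#' @return Matrix (animals x traits) or vector, rownames = animal ids.
#' @export
ebv <- function(object, line = c("dam", "sire"), trait = NULL) {
  line <- match.arg(line)
  m <- if (line == "dam") object$ebv_dam else object$ebv_sire
  if (is.null(trait)) return(m)
  m[, .trait_index(object, trait)]
}

#' Spearman rank correlation between two sets of EBVs
#'
#' Measures whether two melting-rate definitions rank the selection
#' candidates identically: the rank correlation of posterior-mean genetic
#' effects for one parental line across two traits (of one bivariate fit)
#' or across two separate fits.
#'
#' @param object_a,object_b [cross_gibbs] fits (may be the same object).
#' @param line `"dam"` or `"sire"`.
#' @param trait_a,trait_b trait index/name within each fit; when a single
#'   bivariate fit is passed the defaults compare its two traits.
#' @return Spearman correlation coefficient.
#' @export
ebv_rank_correlation <- function(object_a, object_b = object_a,
                                 line = c("dam", "sire"),
                                 trait_a = 1,
                                 trait_b = if (identical(object_a, object_b)) 2 else 1) {
  line <- match.arg(line)
  ea <- ebv(object_a, line, trait_a)
  eb <- ebv(object_b, line, trait_b)
  ids <- intersect(names(ea), names(eb))
  if (length(ids) < 3) stop("need at least 3 shared animals")
  stats::cor(ea[ids], eb[ids], method = "spearman")
}

#' Kolmogorov-Smirnov normality screen of the analyzed traits
#'
#' One-sample KS test of each trait against a normal with the trait's
#' estimated mean and SD, at level `alpha`. The screen is a report only
#' (non-blocking): traits failing it are flagged, constant traits are
#' marked degenerate.
#'
#' @param data data frame of phenotypes.
#' @param traits character vector of trait column names.
#' @param alpha test level (default 0.05).
#' @return Data frame with columns `trait`, `n`, `statistic`, `p_value`,
#'   `normal`, `degenerate`.
#' @export
check_normality <- function(data, traits, alpha = 0.05) {
  out <- lapply(traits, function(tn) {
    x <- data[[tn]]
    if (is.null(x)) stop("trait column not found: ", tn)
    x <- x[!is.na(x)]
    if (length(x) < 8) stop("need at least 8 records per trait")
    if (stats::sd(x) == 0)
      return(data.frame(trait = tn, n = length(x), statistic = NA_real_,
                        p_value = NA_real_, normal = NA, degenerate = TRUE))
    ks <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
    data.frame(trait = tn, n = length(x),
               statistic = unname(ks$statistic),
               p_value = ks$p.value, normal = ks$p.value >= alpha,
               degenerate = FALSE)
  })
  do.call(rbind, out)
}
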