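#' Genetic (co)variance components from heritabilities and correlations
#'
#' Builds the dam-line, sire-line and residual covariance matrices used as
#' generating truth. Partial heritabilities are line-variance fractions of
#' the total non-systematic variance, so the fixed-effect variance is first
#' removed from the phenotypic variance.
#'
#' @param h2_dam,h2_sire per-trait partial heritabilities (dam = common
#'   line, sire = Muscovy line).
#' @param phenotypic_sd per-trait phenotypic SD (trait units).
#' @param fixed_effect_sd SD of the systematic (year x batch x force-feeder)
#'   level effects, removed from the phenotypic variance before splitting.
#' @param r_dam,r_sire,r_res trait x trait correlation matrices (default
#'   identity).
#' @param traits trait names.
#' @return List with matrices `G_dam`, `G_sire`, `R`.
#' @export
make_genetic_components <- function(h2_dam, h2_sire, phenotypic_sd,
                                    fixed_effect_sd = 0,
                                    r_dam = NULL, r_sire = NULL,
                                    r_res = NULL, traits = NULL) {
  t <- length(h2_dam)
  stopifnot(length(h2_sire) == t, length(phenotypic_sd) %in% c(1, t))
  vp <- rep(phenotypic_sd, length.out = t)^2 - fixed_effect_sd^2
  if (any(vp <= 0)) stop("fixed_effect_sd exceeds the phenotypic SD")
  if (any(h2_dam + h2_sire >= 1)) stop("h2_dam + h2_sire must be < 1")
  mk <- function(v, C) {
    if (is.null(C)) C <- diag(t)
    s <- sqrt(v)
    M <- C * tcrossprod(s)
    dimnames(M) <- list(traits, traits)
    M
  }
  list(G_dam = mk(h2_dam * vp, r_dam),
       G_sire = mk(h2_sire * vp, r_sire),
       R = mk((1 - h2_dam - h2_sire) * vp, r_res))
}

.default_band_library <- function() {
  # NIR absorption features per constituent: Gaussian centres (nm), widths
  # (nm) and intensities (AU per 100% constituent). Water/O-H features carry
  # dry matter, C-H combination/overtone features carry lipid, N-H features
  # carry protein; the melting rate is given its own weak features so that
  # the forward model is linear in the full composition vector.
  list(
    DM   = list(centers = c(1450, 1940), widths = c(45, 55),
                heights = c(0.35, 0.45)),
    AC   = list(centers = 2100, widths = 60, heights = 0.25),
    Lip  = list(centers = c(1210, 1725, 2310), widths = c(30, 25, 25),
                heights = c(0.50, 0.80, 0.60)),
    Prot = list(centers = c(2055, 2180), widths = c(40, 35),
                heights = c(0.55, 0.45)),
    MR   = list(centers = c(1680, 2250), widths = c(35, 30),
                heights = c(0.30, 0.25)))
}

.default_background_bands <- function() {
  # common tissue-matrix absorption shared by every sample: broad water and
  # fat features that dominate raw absorbance, with composition modulating
  # them; keeps the per-spectrum intensity scale stable, as in real tissue
  list(centers = c(1190, 1450, 1940, 2300),
       widths = c(150, 60, 70, 120),
       heights = c(0.25, 0.45, 0.55, 0.30))
}

#' Simulation configuration
#'
#' Defaults reproduce the structure of the experimental design: 1422
#' crossbred mule ducks from 382 common-duck dams and 56 Muscovy sires,
#' parental pedigrees of 596 and 201 animals over 5 generations, 12
#' systematic-effect levels, and a measured melting rate with mean 35.6 and
#' SD 14.7. Generating variance components default to the published
#' single-trait point estimates (partial h2 0.20 dam line, 0.10 sire line).
#'
#' @param n_crossbreds,n_dams,n_sires crossbred population design.
#' @param n_common,n_muscovy total pedigree sizes per parental line.
#' @param pedigree_generations pedigree depth (<= 5).
#' @param n_fixed_levels number of systematic-effect levels.
#' @param fixed_effect_sd SD of level effects (trait units).
#' @param trait_names,trait_means trait labels and means.
#' @param G_dam,G_sire,R generating covariance matrices; defaults from
#'   [make_genetic_components] at h2 = (0.20, 0.10), SD 14.7.
#' @param spectral_grid wavelengths (nm), strictly increasing.
#' @param band_library per-constituent Gaussian band parameters.
#' @param background_bands common tissue-matrix absorption added to every
#'   spectrum (NULL for none).
#' @param scatter_mult_sd,offset_sd,baseline_sd,noise_sd spectral artifact
#'   magnitudes (multiplicative scatter SD about 1; additive offset SD;
#'   random quadratic-baseline coefficient SD; i.i.d. noise SD, AU).
#' @param replicates_surface,replicates_ground scans per sample.
#' @param seed default seed recorded in the config (functions accept an
#'   explicit seed that takes precedence).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_crossbreds = 1422, n_dams = 382, n_sires = 56,
                       n_common = 596, n_muscovy = 201,
                       pedigree_generations = 5, n_fixed_levels = 12,
                       fixed_effect_sd = 3,
                       trait_names = "mMR", trait_means = 35.6,
                       G_dam = NULL, G_sire = NULL, R = NULL,
                       spectral_grid = seq(350, 2500, by = 2),
                       band_library = .default_band_library(),
                       background_bands = .default_background_bands(),
                       scatter_mult_sd = 0.05, offset_sd = 0.02,
                       baseline_sd = 0.01, noise_sd = 0.005,
                       replicates_surface = 6, replicates_ground = 3,
                       seed = 1L) {
  t <- length(trait_names)
  if (is.null(G_dam) || is.null(G_sire) || is.null(R)) {
    cmp <- make_genetic_components(rep(0.20, t), rep(0.10, t),
                                   rep(14.7, t), fixed_effect_sd,
                                   traits = trait_names)
    if (is.null(G_dam)) G_dam <- cmp$G_dam
    if (is.null(G_sire)) G_sire <- cmp$G_sire
    if (is.null(R)) R <- cmp$R
  }
  for (M in list(G_dam = G_dam, G_sire = G_sire, R = R)) {
    if (!isSymmetric(unname(as.matrix(M)), tol = 1e-8))
      stop("covariance matrices must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("covariance matrices must be positive semi-definite")
  }
  counts <- c(n_crossbreds, n_dams, n_sires, n_common, n_muscovy,
              pedigree_generations, n_fixed_levels)
  if (any(counts < 1)) stop("all design counts must be positive")
  if (pedigree_generations > 5)
    stop("pedigree depth is limited to 5 generations")
  if (any(diff(spectral_grid) <= 0))
    stop("spectral_grid must be strictly increasing")
  structure(list(
    n_crossbreds = n_crossbreds, n_dams = n_dams, n_sires = n_sires,
    n_common = n_common, n_muscovy = n_muscovy,
    pedigree_generations = pedigree_generations,
    n_fixed_levels = n_fixed_levels, fixed_effect_sd = fixed_effect_sd,
    trait_names = trait_names,
    trait_means = rep(trait_means, length.out = t),
    G_dam = as.matrix(G_dam), G_sire = as.matrix(G_sire), R = as.matrix(R),
    spectral_grid = spectral_grid, band_library = band_library,
    background_bands = background_bands,
    scatter_mult_sd = scatter_mult_sd, offset_sd = offset_sd,
    baseline_sd = baseline_sd, noise_sd = noise_sd,
    replicates_surface = replicates_surface,
    replicates_ground = replicates_ground, seed = seed),
    class = "sim_config")
}

# split `total` animals over `gens` generations so that the last generation
# has exactly n_parents animals (the future dams/sires of crossbreds)
.generation_sizes <- function(total, n_parents, gens) {
  if (gens == 1) {
    if (total < n_parents)
      stop("pedigree size smaller than the required number of parents")
    return(total)
  }
  early <- total - n_parents
  if (early < 4 * (gens - 1))
    stop("impossible pedigree sizes: ", total, " animals cannot span ",
         gens, " generations with ", n_parents, " terminal parents")
  # traced-back pedigrees thin out going into the past: allocate ancestor
  # generations with geometric decay (each generation about half the next)
  w <- 2^seq_len(gens - 1)
  sizes <- pmax(4, round(early * w / sum(w)))
  sizes[gens - 1] <- sizes[gens - 1] + (early - sum(sizes))
  if (sizes[gens - 1] < 4)
    stop("impossible pedigree sizes: cannot allocate ", early,
         " ancestors over ", gens - 1, " generations")
  c(sizes, n_parents)
}

#' Simulate the two parental-line pedigrees
#'
#' Builds one pedigree per line over up to five generations. The final
#' generation holds exactly the animals that become parents of the
#' crossbreds (dams in the common line, sires in the Muscovy line); each
#' non-founder draws its sire among males and its dam among females of the
#' previous generation, which creates full- and half-sib family structure.
#'
#' @param config a [sim_config].
#' @param seed integer seed (NULL keeps the current RNG state).
#' @return List with elements `dam` (common-line [pedigree]) and `sire`
#'   (Muscovy-line [pedigree]); each carries a `parent_pool` attribute with
#'   the ids available for crossbred matings and a `generation` column.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build <- function(total, n_parents, line, pool_sex) {
    gens <- config$pedigree_generations
    sizes <- .generation_sizes(total, n_parents, gens)
    id <- seq_len(total)
    sire <- dam <- integer(total)
    generation <- rep(seq_along(sizes), sizes)
    sex <- character(total)
    stop_at <- cumsum(sizes)
    start_at <- c(1, utils::head(stop_at, -1) + 1)
    for (g in seq_along(sizes)) {
      rows <- start_at[g]:stop_at[g]
      if (g == length(sizes) && length(sizes) > 1) {
        sex[rows] <- pool_sex  # terminal generation: future dams or sires
      } else {
        sex[rows] <- rep(c("M", "F"), length.out = length(rows))
      }
      if (g > 1) {
        prev <- start_at[g - 1]:stop_at[g - 1]
        males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
        if (!length(males) || !length(females))
          stop("impossible pedigree sizes: a generation lacks one sex")
        sire[rows] <- sample(males, length(rows), replace = TRUE)
        dam[rows] <- sample(females, length(rows), replace = TRUE)
      }
    }
    ped <- pedigree(id, sire, dam, line = line, sex = sex)
    ped$generation <- generation[match(ped$id, id)]
    attr(ped, "parent_pool") <-
      if (gens == 1) id else id[start_at[length(sizes)]:total]
    ped
  }
  list(dam = build(config$n_common, config$n_dams, "common", "F"),
       sire = build(config$n_muscovy, config$n_sires, "muscovy", "M"))
}

# PSD square root via eigendecomposition (handles singular G, e.g. G = 0)
.psd_sqrt <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw independent effects with covariance `G`; each non-founder
#' receives the mean of its parents' values plus a Mendelian-sampling
#' deviation with covariance `G` scaled by the pedigree rules
#' (\eqn{1/2 - (F_s + F_d)/4} with both parents known, \eqn{3/4 - F_p/4}
#' with one, 1 with none), so that the joint covariance is the Kronecker
#' product of the additive relationship matrix with `G`.
#'
#' @param ped a [pedigree].
#' @param G trait x trait genetic covariance matrix (PSD).
#' @param seed integer seed.
#' @return Numeric matrix, animals x traits, rownames = animal ids.
#' @export
simulate_breeding_values <- function(ped, G, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("G must be positive semi-definite")
  t <- nrow(G)
  n <- nrow(ped)
  Gh <- .psd_sqrt(G)
  Fcoef <- if (all(attr(ped, "founders"))) numeric(nrow(ped))
           else inbreeding(ped)
  pi <- .parent_index(ped)
  bv <- matrix(0, n, t)
  Z <- matrix(stats::rnorm(n * t), n, t)
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    if (s > 0 && d > 0) {
      mu <- (bv[s, ] + bv[d, ]) / 2
      v <- 0.5 - (Fcoef[s] + Fcoef[d]) / 4
    } else if (s > 0 || d > 0) {
      p <- max(s, d)
      mu <- bv[p, ] / 2
      v <- 0.75 - Fcoef[p] / 4
    } else {
      mu <- rep(0, t); v <- 1
    }
    bv[i, ] <- mu + sqrt(v) * as.numeric(Gh %*% Z[i, ])
  }
  rownames(bv) <- ped$id
  colnames(bv) <- colnames(G)
  bv
}

# composition model: fatty-liver biochemistry as linear-in-MR relations
# with independent noise (lipid ~ MR calibrated to R2 ~ 0.58)
.simulate_composition <- function(mr, seed_offset_done = TRUE) {
  n <- length(mr)
  mrc <- mr - 35.6
  Lip <- 55 + 0.35 * mrc + stats::rnorm(n, 0, 4.4)
  DM <- 62 + 0.50 * (Lip - 55) + stats::rnorm(n, 0, 1.5)
  Prot <- 8.0 - 0.08 * mrc + stats::rnorm(n, 0, 0.6)
  AC <- 1.1 + stats::rnorm(n, 0, 0.08)
  out <- cbind(DM = DM, AC = AC, Lip = Lip, Prot = Prot,
               MR = pmax(mr, 0.1))
  out[] <- pmax(out, 0.1)
  out
}

#' Simulate the crossbred phenotype records
#'
#' Each crossbred receives one dam from the common-line parent pool and one
#' sire from the Muscovy pool (dams nested within sires), a systematic
#' level assigned in interleaved balanced blocks, and a phenotype equal to
#' trait mean + level effect + dam transmitted effect + sire transmitted
#' effect + residual with covariance `R`. Transmitted effects are the
#' parents' full line-specific effects as expressed in the crossbred;
#' crossbred Mendelian sampling is part of the residual.
#'
#' @param pedigrees list from [simulate_pedigree].
#' @param bv_dam,bv_sire breeding-value matrices from
#'   [simulate_breeding_values] (rownames = animal ids).
#' @param config a [sim_config].
#' @param seed integer seed.
#' @return List with `phenotypes` (data frame: id, dam, sire, level, one
#'   column per trait) and `truth` (data frame with the exact generated
#'   components per trait plus the composition vector DM, AC, Lip, Prot,
#'   MR in % units).
#' @export
simulate_crossbreds <- function(pedigrees, bv_dam, bv_sire,
                                config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_crossbreds
  t <- length(config$trait_names)
  dams <- attr(pedigrees$dam, "parent_pool")
  sires <- attr(pedigrees$sire, "parent_pool")
  if (length(dams) < config$n_dams || length(sires) < config$n_sires)
    stop("parent pools smaller than the requested numbers of dams/sires")
  dams <- dams[seq_len(config$n_dams)]
  sires <- sires[seq_len(config$n_sires)]
  dof <- sort(rep(seq_len(config$n_dams), length.out = n))  # dam of record
  dam_id <- dams[dof]
  sire_id <- sires[ceiling(dof * config$n_sires / config$n_dams)]
  level <- rep(seq_len(config$n_fixed_levels), length.out = n)

  dpos <- match(as.character(dam_id), rownames(bv_dam))
  spos <- match(as.character(sire_id), rownames(bv_sire))
  if (anyNA(dpos) || anyNA(spos))
    stop("crossbred parent missing from the breeding-value tables")

  beta <- matrix(stats::rnorm(config$n_fixed_levels * t,
                              sd = config$fixed_effect_sd),
                 config$n_fixed_levels, t)
  E <- matrix(stats::rnorm(n * t), n, t) %*% .psd_sqrt(config$R)
  Ud <- bv_dam[dpos, , drop = FALSE]
  Us <- bv_sire[spos, , drop = FALSE]
  Y <- matrix(rep(config$trait_means, each = n), n, t) +
    beta[level, , drop = FALSE] + Ud + Us + E
  colnames(Y) <- config$trait_names

  phen <- data.frame(id = seq_len(n), dam = dam_id, sire = sire_id,
                     level = level)
  phen <- cbind(phen, as.data.frame(Y))

  truth <- data.frame(id = seq_len(n), level = level)
  for (k in seq_len(t)) {
    tn <- config$trait_names[k]
    truth[[paste0("fixed_", tn)]] <- beta[level, k]
    truth[[paste0("dam_", tn)]] <- Ud[, k]
    truth[[paste0("sire_", tn)]] <- Us[, k]
    truth[[paste0("resid_", tn)]] <- E[, k]
  }
  truth <- cbind(truth,
                 as.data.frame(.simulate_composition(Y[, 1])))
  attr(truth, "level_effects") <- beta
  list(phenotypes = phen, truth = truth)
}

#' Simulate NIRS spectra from the true composition
#'
#' Forward model: per-sample absorbance is the sum over constituents of
#' composition (fraction) times a fixed Gaussian band profile; each
#' replicate scan then receives a multiplicative scatter factor (mean 1),
#' a random quadratic baseline, an additive offset and i.i.d. noise.
#'
#' @param truth truth table from [simulate_crossbreds] (needs columns DM,
#'   AC, Lip, Prot, MR).
#' @param config a [sim_config].
#' @param mode `"surface"` (6 replicates) or `"ground"` (3 replicates).
#' @param seed integer seed.
#' @return A [spectra_set] with `replicates` scans per sample.
#' @export
simulate_spectra <- function(truth, config = sim_config(),
                             mode = c("surface", "ground"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  constituents <- names(config$band_library)
  comp <- as.matrix(truth[, constituents, drop = FALSE])
  if (any(comp < 0)) stop("negative composition values")
  wl <- config$spectral_grid
  Bm <- sapply(constituents, function(cn) {
    b <- config$band_library[[cn]]
    prof <- numeric(length(wl))
    for (j in seq_along(b$centers))
      prof <- prof + b$heights[j] *
        exp(-((wl - b$centers[j]) / b$widths[j])^2 / 2)
    prof
  })
  bg <- config$background_bands
  bgprof <- numeric(length(wl))
  if (!is.null(bg))
    for (j in seq_along(bg$centers))
      bgprof <- bgprof + bg$heights[j] *
        exp(-((wl - bg$centers[j]) / bg$widths[j])^2 / 2)
  base <- sweep((comp / 100) %*% t(Bm), 2, bgprof, `+`)  # n x nwl
  r <- if (mode == "surface") config$replicates_surface
       else config$replicates_ground
  n <- nrow(base)
  ns <- n * r
  row_of <- rep(seq_len(n), each = r)
  mult <- 1 + stats::rnorm(ns, 0, config$scatter_mult_sd)
  offset <- stats::rnorm(ns, 0, config$offset_sd)
  u <- (wl - min(wl)) / (max(wl) - min(wl))
  U <- cbind(1, u, u^2)
  bcoef <- matrix(stats::rnorm(ns * 3, 0, config$baseline_sd), ns, 3)
  vals <- base[row_of, , drop = FALSE] * mult +
    bcoef %*% t(U) + offset +
    matrix(stats::rnorm(ns * length(wl), 0, config$noise_sd), ns)
  spectra_set(vals, wl, sample_id = truth$id[row_of],
              replicate_id = rep(seq_len(r), n), mode = mode)
}

#' Simulate a complete study
#'
#' Runs [simulate_pedigree], [simulate_breeding_values] for both lines,
#' [simulate_crossbreds] and (optionally) [simulate_spectra] under one
#' seed, giving a dataset with the full structure the downstream analysis
#' assumes.
#'
#' @param config a [sim_config].
#' @param seed integer seed (default from the config).
#' @param spectra which spectra sets to generate: any of `"surface"`,
#'   `"ground"` (character(0) skips spectra).
#' @return List: `pedigrees`, `bv_dam`, `bv_sire`, `phenotypes`, `truth`,
#'   and `spectra` (named list).
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed,
                           spectra = c("surface", "ground")) {
  if (!is.null(seed)) set.seed(seed)
  peds <- simulate_pedigree(config)
  bvd <- simulate_breeding_values(peds$dam, config$G_dam)
  bvs <- simulate_breeding_values(peds$sire, config$G_sire)
  cb <- simulate_crossbreds(peds, bvd, bvs, config)
  sp <- lapply(stats::setNames(spectra, spectra), function(m)
    simulate_spectra(cb$truth, config, mode = m))
  list(pedigrees = peds, bv_dam = bvd, bv_sire = bvs,
       phenotypes = cb$phenotypes, truth = cb$truth, spectra = sp,
       config = config, seed = seed)
}
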