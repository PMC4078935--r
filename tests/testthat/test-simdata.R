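test_that("configuration validates its invariants", {
  expect_error(sim_config(G_dam = matrix(c(1, 2, 2, 1), 2),
                          trait_names = c("a", "b")), "positive semi-definite")
  expect_error(sim_config(n_dams = 0), "positive")
  expect_error(sim_config(pedigree_generations = 6), "5 generations")
  expect_error(sim_config(spectral_grid = c(800, 700)), "increasing")
  expect_error(make_genetic_components(0.6, 0.5, 10), "< 1")
})

test_that("simulated pedigrees have the experimental sizes and structure", {
  peds <- simulate_pedigree(sim_config(), seed = 1)
  expect_equal(nrow(peds$dam), 596)
  expect_equal(nrow(peds$sire), 201)
  expect_length(attr(peds$dam, "parent_pool"), 382)
  expect_length(attr(peds$sire, "parent_pool"), 56)
  expect_lte(max(peds$dam$generation), 5)
  # every terminal parent resolves in its pedigree, parents precede offspring
  expect_true(all(attr(peds$dam, "parent_pool") %in% peds$dam$id))

  # one generation: founders only
  p1 <- simulate_pedigree(sim_config(pedigree_generations = 1,
                                     n_common = 382, n_muscovy = 56),
                          seed = 2)
  expect_true(all(attr(p1$dam, "founders")))
  expect_equal(nrow(p1$dam), 382)

  # impossible allocation is refused
  expect_error(simulate_pedigree(sim_config(n_common = 383)), "impossible")
})

test_that("pedigree and study generation are deterministic under a seed", {
  cfg <- small_config()
  a <- simulate_study(cfg, seed = 9, spectra = "surface")
  b <- simulate_study(cfg, seed = 9, spectra = "surface")
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$bv_dam, b$bv_dam)
  expect_identical(a$spectra$surface$values, b$spectra$surface$values)
})

test_that("breeding values: zero G collapses, founder variance obeys LLN", {
  ped <- trio_pedigree()
  expect_equal(simulate_breeding_values(ped, matrix(0), seed = 1),
               matrix(0, 3, 1), ignore_attr = TRUE)
  big <- pedigree(1:10000, rep(0, 10000), rep(0, 10000))
  bv <- simulate_breeding_values(big, matrix(1), seed = 2)
  expect_equal(var(bv[, 1]), 1, tolerance = 0.1)
  expect_error(simulate_breeding_values(ped, matrix(-1)), "semi-definite")
})

test_that("simulated BV covariances reproduce the relationship matrix", {
  ped <- six_animal_pedigree()
  A <- build_A(ped)
  G <- matrix(2.5)
  reps <- 3000
  set.seed(33)
  draws <- vapply(seq_len(reps),
                  function(i) simulate_breeding_values(ped, G)[, 1],
                  numeric(6))
  emp <- tcrossprod(draws - rowMeans(draws)) / (reps - 1)
  expect_lt(max(abs(emp - 2.5 * A)), 0.25)  # ~3 Monte-Carlo SEs
  # parent-offspring covariance is half the genetic variance
  expect_equal(emp["1", "4"], 0.5 * 2.5, tolerance = 0.25)
})

test_that("crossbred phenotypes decompose exactly as generated", {
  cfg <- small_config()
  st <- simulate_study(cfg, seed = 5, spectra = character(0))
  tr <- st$truth
  recon <- cfg$trait_means[1] + tr$fixed_mMR + tr$dam_mMR + tr$sire_mMR +
    tr$resid_mMR
  expect_equal(recon, st$phenotypes$mMR, tolerance = 1e-12)
  # parent links resolve
  expect_true(all(st$phenotypes$dam %in% st$pedigrees$dam$id))
  expect_true(all(st$phenotypes$sire %in% st$pedigrees$sire$id))
  expect_lte(max(st$phenotypes$level), cfg$n_fixed_levels)

  # degenerate limit: no variance anywhere -> phenotype = 0
  cfg0 <- small_config(fixed_effect_sd = 0, trait_means = 0,
                       G_dam = matrix(0), G_sire = matrix(0), R = matrix(0))
  st0 <- simulate_study(cfg0, seed = 6, spectra = character(0))
  expect_equal(st0$phenotypes$mMR, rep(0, cfg0$n_crossbreds))

  # missing parent is refused
  used_dam <- as.character(st$phenotypes$dam[1])
  bad_bv <- st$bv_dam[setdiff(rownames(st$bv_dam), used_dam), ,
                      drop = FALSE]
  expect_error(simulate_crossbreds(st$pedigrees, bad_bv, st$bv_sire, cfg),
               "missing|parent")
})

test_that("default design reproduces the melting-rate mean and SD", {
  st <- simulate_study(sim_config(), seed = 7, spectra = character(0))
  expect_equal(nrow(st$phenotypes), 1422)
  expect_length(unique(st$phenotypes$dam), 382)
  expect_length(unique(st$phenotypes$sire), 56)
  expect_length(unique(st$phenotypes$level), 12)
  expect_equal(mean(st$phenotypes$mMR), 35.6, tolerance = 2.5 / 35.6)
  expect_equal(sd(st$phenotypes$mMR), 14.7, tolerance = 2.5 / 14.7)
})

test_that("variance accounting: phenotypic variance splits into components", {
  cfg <- sim_config()
  st <- simulate_study(cfg, seed = 8, spectra = character(0))
  beta <- attr(st$truth, "level_effects")
  expected <- var(beta[st$phenotypes$level, 1]) + cfg$G_dam[1, 1] +
    cfg$G_sire[1, 1] + cfg$R[1, 1]
  expect_equal(var(st$phenotypes$mMR), expected, tolerance = 0.12)
})

test_that("crossbreds sharing a dam covary by the dam-line variance", {
  cfg <- sim_config(n_crossbreds = 400, n_dams = 200, n_sires = 40,
                    n_common = 200, n_muscovy = 40,
                    pedigree_generations = 1, fixed_effect_sd = 0,
                    trait_means = 0)
  set.seed(44)
  covs <- replicate(150, {
    st <- simulate_study(cfg, seed = NULL, spectra = character(0))
    y <- st$phenotypes$mMR
    full1 <- y[seq(1, 400, by = 2)]   # first offspring of dam j
    full2 <- y[seq(2, 400, by = 2)]   # second offspring of dam j
    # dams are nested 5 per sire, so consecutive dams within a sire give
    # pairs sharing the sire only
    j <- which(seq_len(199) %% 5 != 0)
    c(dam = cov(full1, full2), sire = cov(full1[j], full1[j + 1]))
  })
  # full sibs share dam and sire; the half-sib pairs share the sire only
  expect_equal(mean(covs["dam", ]),
               cfg$G_dam[1, 1] + cfg$G_sire[1, 1], tolerance = 0.1)
  expect_equal(mean(covs["sire", ]), cfg$G_sire[1, 1], tolerance = 0.35)
})

test_that("spectra are linear in composition with controllable artifacts", {
  cfg <- small_config(noise_sd = 0, scatter_mult_sd = 0, offset_sd = 0,
                      baseline_sd = 0, background_bands = NULL)
  truth <- data.frame(id = 1:3, DM = c(60, 60, 60), AC = c(1, 1, 1),
                      Lip = c(30, 60, 55), Prot = c(8, 8, 8),
                      MR = c(35, 35, 35))
  sp <- simulate_spectra(truth, cfg, mode = "ground", seed = 10)
  expect_equal(nrow(sp$values), 9)  # 3 replicate scans per sample
  # zero noise and scatter: replicates identical
  expect_equal(sp$values[1, ], sp$values[2, ], tolerance = 1e-14)
  # doubling one constituent doubles its band contribution
  zero <- truth[1, ]; zero[c("DM", "AC", "Lip", "Prot", "MR")] <- 0
  base_l <- simulate_spectra(transform(zero, Lip = 30), cfg, "ground")
  dbl_l <- simulate_spectra(transform(zero, Lip = 60), cfg, "ground")
  expect_equal(2 * base_l$values[1, ], dbl_l$values[1, ], tolerance = 1e-12)

  expect_error(simulate_spectra(transform(truth, Lip = -1), cfg, "ground"),
               "negative")

  # surface mode: six replicates per liver
  sp6 <- simulate_spectra(truth, cfg, mode = "surface")
  expect_equal(nrow(sp6$values), 18)
})

test_that("noise-free spectra recover composition through SNV + PLS", {
  cfg <- small_config(noise_sd = 0, offset_sd = 0.01, baseline_sd = 0,
                      scatter_mult_sd = 0.03)
  st <- simulate_study(cfg, seed = 12, spectra = "ground")
  y <- st$truth$MR
  names(y) <- st$truth$id
  cal <- nirs_calibration(st$spectra$ground, y,
                          recipe = preprocess_recipe(1, 10, 5, "snv"),
                          n_select = 150, ncomp_grid = 1:8, seed = 1)
  expect_gt(cal$stats$r2, 0.99)
})
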