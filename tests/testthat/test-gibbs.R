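# minimal object with the samples/ebv structure of a fit, for unit tests
# of the posterior-summary arithmetic
fake_fit <- function(G_dam, G_sire, R, nkeep = 50, traits = c("t1", "t2"),
                     ebv_dam = NULL, ebv_sire = NULL) {
  t <- nrow(G_dam)
  rep_arr <- function(M) array(rep(M, nkeep), c(t, t, nkeep))
  structure(list(samples = list(G_dam = rep_arr(G_dam),
                                G_sire = rep_arr(G_sire), R = rep_arr(R)),
                 traits = traits[seq_len(t)],
                 ebv_dam = ebv_dam, ebv_sire = ebv_sire),
            class = "cross_gibbs")
}

test_that("partial heritability is the ratio of line to total variance", {
  f <- fake_fit(matrix(0.2), matrix(0.1), matrix(0.7), traits = "t1")
  expect_equal(partial_heritability(f, "dam")$mean, 0.2)
  expect_equal(partial_heritability(f, "sire")$mean, 0.1)
  expect_equal(partial_heritability(f, "dam")$sd, 0)
  # equal components: one third each
  f3 <- fake_fit(matrix(1), matrix(1), matrix(1), traits = "t1")
  expect_equal(partial_heritability(f3, "dam")$mean, 1 / 3)
})

test_that("genetic correlation follows the sampled covariance structure", {
  d <- diag(c(2, 3))
  f <- fake_fit(d, d, d)
  expect_equal(genetic_correlation(f, "dam")$mean, 0)
  r1 <- tcrossprod(c(1, -2))  # rank-1: correlation -1
  f1 <- fake_fit(r1, d, d)
  expect_equal(genetic_correlation(f1, "dam")$mean, -1)
  expect_equal(genetic_correlation(f1, "sire")$mean, 0)
})

test_that("heritability rescaling applies the line-specific factors", {
  expect_equal(rescale_heritability(0.20, "common"), 0.40)
  expect_equal(rescale_heritability(0.10, "muscovy"),
               c(lower = 0.20, upper = 0.40))
  expect_equal(rescale_heritability(0, "common"), 0)
  expect_equal(rescale_heritability(0.6, "muscovy"),
               c(lower = 1, upper = 1))  # capped
  expect_error(rescale_heritability(1.2, "common"), "0, 1")
})

test_that("EBV rank correlation detects identical and reversed rankings", {
  e <- matrix(rnorm(20), 10, 2,
              dimnames = list(letters[1:10], c("t1", "t2")))
  same <- fake_fit(diag(2), diag(2), diag(2),
                   ebv_dam = cbind(t1 = e[, 1], t2 = e[, 1]))
  expect_equal(ebv_rank_correlation(same, line = "dam"), 1)
  rev <- fake_fit(diag(2), diag(2), diag(2),
                  ebv_dam = cbind(t1 = e[, 1], t2 = -e[, 1]))
  expect_equal(ebv_rank_correlation(rev, line = "dam"), -1)
  tiny <- fake_fit(diag(2), diag(2), diag(2), ebv_dam = e[1:2, ])
  expect_error(ebv_rank_correlation(tiny, line = "dam"), "3")
})

test_that("normality screen passes gaussians, fails exponentials, flags constants", {
  set.seed(21)
  pass <- replicate(200, {
    d <- data.frame(x = rnorm(500))
    check_normality(d, "x")$normal
  })
  expect_gte(mean(pass), 0.93)

  fail <- replicate(50, {
    d <- data.frame(x = rexp(1000))
    check_normality(d, "x")$normal
  })
  expect_equal(mean(fail), 0)

  flat <- check_normality(data.frame(x = rep(1, 50)), "x")
  expect_true(flat$degenerate)
  expect_error(check_normality(data.frame(x = rnorm(5)), "x"), "8")
})

test_that("gibbs fit validates inputs and is seed-reproducible", {
  cfg <- small_config()
  st <- simulate_study(cfg, seed = 20, spectra = character(0))
  expect_error(cross_gibbs(mMR ~ factor(level), st$phenotypes,
                           st$pedigrees$dam, st$pedigrees$sire,
                           chain = 100, burn_in = 100), "burn_in")
  bad <- st$phenotypes
  bad$dam[1] <- 99999
  expect_error(cross_gibbs(mMR ~ factor(level), bad,
                           st$pedigrees$dam, st$pedigrees$sire,
                           chain = 100, burn_in = 10), "absent")

  f1 <- cross_gibbs(mMR ~ factor(level), st$phenotypes,
                    st$pedigrees$dam, st$pedigrees$sire,
                    chain = 300, burn_in = 100, seed = 5)
  f2 <- cross_gibbs(mMR ~ factor(level), st$phenotypes,
                    st$pedigrees$dam, st$pedigrees$sire,
                    chain = 300, burn_in = 100, seed = 5)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$ebv_dam, f2$ebv_dam)
  # thinning keeps every k-th retained sample
  f3 <- cross_gibbs(mMR ~ factor(level), st$phenotypes,
                    st$pedigrees$dam, st$pedigrees$sire,
                    chain = 300, burn_in = 100, thin = 10, seed = 5)
  expect_equal(dim(f3$samples$G_dam)[3], 20)
})

test_that("a null dam-line variance is recovered as null", {
  cfg <- sim_config(n_crossbreds = 1000, n_dams = 250, n_sires = 50,
                    n_common = 250, n_muscovy = 50,
                    pedigree_generations = 1, n_fixed_levels = 4,
                    G_dam = matrix(0), G_sire = matrix(20), R = matrix(190))
  st <- simulate_study(cfg, seed = 22, spectra = character(0))
  fit <- cross_gibbs(mMR ~ factor(level), st$phenotypes,
                     st$pedigrees$dam, st$pedigrees$sire,
                     chain = 2500, burn_in = 500, seed = 23)
  expect_lt(partial_heritability(fit, "dam")$mean, 0.02)
})

test_that("with unrelated parents the posterior matches nested-ANOVA moments", {
  # balanced design: 40 unrelated sires x 5 unrelated dams x 5 offspring
  cfg <- sim_config(n_crossbreds = 1000, n_dams = 200, n_sires = 40,
                    n_common = 200, n_muscovy = 40,
                    pedigree_generations = 1, fixed_effect_sd = 0,
                    trait_means = 0)
  st <- simulate_study(cfg, seed = 24, spectra = character(0))
  y <- st$phenotypes$mMR
  sire_f <- factor(st$phenotypes$sire)
  dam_f <- factor(st$phenotypes$dam)
  # dams are nested within sires, so dam_f after sire_f is the nested term
  ms <- anova(lm(y ~ sire_f + dam_f))[["Mean Sq"]]
  mom_e <- ms[3]
  mom_d <- (ms[2] - ms[3]) / 5
  mom_s <- (ms[1] - ms[2]) / 25
  fit <- cross_gibbs(mMR ~ 1, st$phenotypes,
                     st$pedigrees$dam, st$pedigrees$sire,
                     chain = 3000, burn_in = 1000, seed = 25)
  cmp <- coef(fit)
  expect_equal(cmp$R[1, 1], mom_e, tolerance = 0.08)
  expect_equal(cmp$G_dam[1, 1], mom_d, tolerance = 0.35)
  expect_equal(cmp$G_sire[1, 1], mom_s, tolerance = 0.35)
})

test_that("swapping the parental lines swaps the estimates", {
  cfg <- sim_config(n_crossbreds = 600, n_dams = 120, n_sires = 40,
                    n_common = 120, n_muscovy = 40,
                    pedigree_generations = 1, n_fixed_levels = 4,
                    G_dam = matrix(60), G_sire = matrix(25), R = matrix(130))
  st <- simulate_study(cfg, seed = 26, spectra = character(0))
  fit <- cross_gibbs(mMR ~ factor(level), st$phenotypes,
                     st$pedigrees$dam, st$pedigrees$sire,
                     chain = 2500, burn_in = 500, seed = 27)
  swapped <- st$phenotypes
  names(swapped)[match(c("dam", "sire"), names(swapped))] <- c("sire", "dam")
  fit_sw <- cross_gibbs(mMR ~ factor(level), swapped,
                        st$pedigrees$sire, st$pedigrees$dam,
                        chain = 2500, burn_in = 500, seed = 27)
  expect_equal(partial_heritability(fit, "dam")$mean,
               partial_heritability(fit_sw, "sire")$mean,
               tolerance = 0.2)
  expect_equal(partial_heritability(fit, "sire")$mean,
               partial_heritability(fit_sw, "dam")$mean,
               tolerance = 0.2)
})

test_that("posterior means recover the generating parameters across replicates", {
  cfg <- small_config()
  hits <- 0L
  for (r in 1:10) {
    st <- simulate_study(cfg, seed = 300 + r, spectra = character(0))
    fit <- cross_gibbs(mMR ~ factor(level), st$phenotypes,
                       st$pedigrees$dam, st$pedigrees$sire,
                       chain = 2500, burn_in = 500, seed = 400 + r)
    d <- partial_heritability(fit, "dam")
    s <- partial_heritability(fit, "sire")
    hits <- hits + (abs(d$mean - 0.20) < 2 * d$sd) +
      (abs(s$mean - 0.10) < 2 * s$sd)
  }
  expect_gte(hits, 18)  # >= 90% of the 20 line-by-replicate checks
})

test_that("summary and print surface the posterior tables", {
  cfg <- small_config()
  st <- simulate_study(cfg, seed = 28, spectra = character(0))
  ph <- st$phenotypes
  set.seed(29)
  ph$mMR2 <- ph$mMR + rnorm(nrow(ph), 0, 5)
  fit <- cross_gibbs(cbind(mMR, mMR2) ~ factor(level), ph,
                     st$pedigrees$dam, st$pedigrees$sire,
                     chain = 600, burn_in = 200, seed = 30)
  sm <- summary(fit)
  expect_equal(nrow(sm$h2), 4)  # 2 lines x 2 traits
  expect_equal(nrow(sm$rg), 2)
  expect_true(all(is.finite(sm$h2$ess)))
  expect_output(print(fit), "partial h2")
  expect_output(print(sm), "Genetic correlations")
  expect_equal(dim(ebv(fit, "dam")), c(160L, 2L))
  expect_length(ebv(fit, "sire", "mMR"), 50L)
  cmp <- coef(fit)
  expect_true(all(vapply(cmp, function(m) isSymmetric(m, tol = 1e-10),
                         TRUE)))
})
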