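# Shared fixtures: all data are generated in code at test time.

# a reduced study configuration that keeps Gibbs chains affordable in the
# routine suite (full experimental-scale runs live in the acceptance tests)
small_config <- function(...) {
  sim_config(n_crossbreds = 400, n_dams = 100, n_sires = 20,
             n_common = 160, n_muscovy = 50, n_fixed_levels = 4,
             spectral_grid = seq(800, 2500, by = 10), ...)
}

# trio: sire 1, dam 2, offspring 3 (non-inbred)
trio_pedigree <- function() pedigree(id = 1:3, sire = c(0, 0, 1),
                                     dam = c(0, 0, 2))

# 6-animal pedigree with full sibs, half sibs and an inbred mating:
#   founders 1,2,3; 4 = 1x2, 5 = 1x3, 6 = 4x5 (inbred: parents share sire 1)
six_animal_pedigree <- function() {
  pedigree(id = 1:6, sire = c(0, 0, 0, 1, 1, 4), dam = c(0, 0, 0, 2, 3, 5))
}

# random valid pedigree of n animals over a few generations
random_pedigree <- function(n = 50, founders = 12, seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (founders + 1):n) {
    pair <- sample(seq_len(i - 1), 2)
    sire[i] <- pair[1]; dam[i] <- pair[2]
  }
  pedigree(seq_len(n), sire, dam)
}

# flat spectra problem with a known linear composition signal
linear_spectra_fixture <- function(n = 60, p = 80, noise = 0, seed = 1) {
  set.seed(seed)
  wl <- seq(1000, 1000 + 4 * (p - 1), by = 4)
  conc <- runif(n, 10, 60)
  band <- exp(-((wl - mean(wl)) / 60)^2 / 2)
  vals <- outer(conc / 100, band) + matrix(rnorm(n * p, 0, noise), n, p)
  list(spectra = spectra_set(vals, wl, sample_id = seq_len(n)),
       conc = conc, wl = wl)
}
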