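test_that("simulated layers are standardized with the requested cross-correlation", {
  target <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3, 3)
  for (seed in 1:5) {
    spec <- landscape_spec(60, 60, n_env = 3, autocorr_range = 5,
                           env_cross_corr = target, seed = seed)
    land <- simulate_landscape(spec)
    m <- sapply(land$current$layers, as.vector)
    expect_equal(colMeans(m), rep(0, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(apply(m, 2, sd), rep(1, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_lt(max(abs(cor(m) - target)), 0.15)
  }
  # identity target on a large grid: off-diagonals essentially zero
  spec <- landscape_spec(100, 100, n_env = 4, seed = 11)
  m <- sapply(simulate_landscape(spec)$current$layers, as.vector)
  cc <- cor(m)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.15)
})

test_that("future stacks are shifted copies of the current stack", {
  spec <- landscape_spec(20, 20, n_env = 4, seed = 3)
  land <- simulate_landscape(spec, future_shift = c(temp1 = 0, temp2 = 0,
                                                    prec1 = 0, prec2 = 0))
  for (nm in names(land$current$layers))
    expect_identical(land$future$future$layers[[nm]], land$current$layers[[nm]])
  # default scenario: +1 s.d. on temperature-like layers only
  land2 <- simulate_landscape(spec)
  expect_equal(land2$future$future$layers$temp1,
               land2$current$layers$temp1 + 1)
  expect_identical(land2$future$future$layers$prec1, land2$current$layers$prec1)
})

test_that("landscape simulation is deterministic and rejects bad correlation input", {
  spec <- landscape_spec(30, 30, n_env = 3, seed = 99)
  expect_identical(simulate_landscape(spec), simulate_landscape(spec))
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(simulate_landscape(landscape_spec(10, 10, 3, env_cross_corr = bad)),
               "positive definite")
  expect_error(landscape_spec(3, 10, 2), "grid_rows")
})

test_that("sample placement gives distinct localities with in-grid coordinates", {
  spec <- landscape_spec(40, 40, n_env = 2, seed = 1)
  land <- simulate_landscape(spec)
  s1 <- simulate_samples(1, 5, land$current, seed = 2)
  expect_equal(nrow(s1), 5)
  expect_equal(length(unique(s1$locality)), 1)
  s2 <- simulate_samples(35, 12, land$current, seed = 2)
  expect_equal(nrow(s2), 420)
  expect_equal(length(unique(s2$locality)), 35)
  locs <- unique(s2[, c("longitude", "latitude")])
  expect_gt(min(dist(locs)), 0)
  expect_true(all(s2$longitude > 0 & s2$longitude < 40 &
                    s2$latitude > 0 & s2$latitude < 40))
  expect_error(simulate_samples(40 * 40 + 1, 1, land$current), "exceeds")
})

test_that("genotype dosages are valid and missingness behaves as configured", {
  d <- sim_dataset(seed = 7, n_pops = 6, n_per_pop = 5, n_neutral = 100,
                   missing_rate = 0)
  expect_false(anyNA(d$gm$dosages))
  expect_true(all(d$gm$dosages %in% 0:2))
  d2 <- sim_dataset(seed = 7, n_pops = 6, n_per_pop = 5, n_neutral = 100,
                    missing_rate = 0.3)
  expect_equal(mean(is.na(d2$gm$dosages)), 0.3, tolerance = 0.05)
  spec <- landscape_spec(20, 20, 2, seed = 1)
  land <- simulate_landscape(spec)
  s <- simulate_samples(3, 4, land$current, seed = 1)
  expect_error(simulate_genotypes(s, land$current, 10, make_truth(2, 0.1),
                                  missing_rate = 1), "missing_rate")
})

test_that("dosage marginals are consistent with binomial(2, p) sampling", {
  d <- sim_dataset(seed = 13, n_pops = 8, n_per_pop = 25, n_neutral = 200,
                   target_fst = 0.1)
  # within each population the three genotype classes should fit binomial
  # proportions at the population frequency (chi-square GOF, alpha = 0.01)
  loc <- d$gm$sample_meta$locality
  rej <- 0; tested <- 0
  for (j in seq_len(ncol(d$gm$dosages))) {
    x <- d$gm$dosages[loc == "L01", j]
    p <- mean(x) / 2
    if (p <= 0.05 || p >= 0.95) next
    obs <- tabulate(x + 1, 3)
    expd <- length(x) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - expd)^2 / pmax(expd, 1e-9))
    tested <- tested + 1
    if (stat > qchisq(0.99, df = 1)) rej <- rej + 1
  }
  expect_gt(tested, 50)
  expect_lt(rej / tested, 0.10)
})

test_that("realized multi-locus FST matches the generator target", {
  d <- sim_dataset(seed = 31, n_pops = 10, n_per_pop = 20, n_neutral = 500,
                   target_fst = 0.15)
  fst <- wc_fst(d$gm$dosages, d$gm$sample_meta$locality)
  expect_gt(fst, 0.10)
  expect_lt(fst, 0.20)
})

test_that("zero-effect 'adaptive' loci are indistinguishable from neutral loci", {
  d <- sim_dataset(seed = 41, n_pops = 12, n_per_pop = 10, n_neutral = 250,
                   n_adaptive = 5, effect = 0)
  gm <- d$gm
  pf <- apply(gm$dosages, 2, function(x) tapply(x, gm$sample_meta$locality, mean) / 2)
  pe <- tapply(d$env$temp1, gm$sample_meta$locality, mean)
  r <- abs(suppressWarnings(cor(pe, pf)))
  ad <- grepl("^adaptive", gm$snp_meta$id)
  expect_true(all(r[ad] < quantile(r[!ad], 0.975, na.rm = TRUE)))
})

test_that("planted clines of moderate effect outrank the neutral median correlation", {
  wins <- 0; total <- 0
  for (seed in 1:10) {
    d <- sim_dataset(seed = 50 + seed, n_pops = 10, n_per_pop = 8,
                     n_neutral = 200, n_adaptive = 2, effect = 1.5)
    gm <- d$gm
    pf <- apply(gm$dosages, 2, function(x) tapply(x, gm$sample_meta$locality, mean) / 2)
    pe <- tapply(d$env$temp1, gm$sample_meta$locality, mean)
    r <- abs(suppressWarnings(cor(pe, pf)))   # monomorphic loci give NA
    ad <- grepl("^adaptive", gm$snp_meta$id)
    wins <- wins + sum(r[ad] > median(r[!ad], na.rm = TRUE))
    total <- total + sum(ad)
  }
  expect_gte(wins / total, 0.95)
})

test_that("genotype simulation is deterministic and truth reports realized ancestry", {
  spec <- landscape_spec(30, 30, 2, seed = 5)
  land <- simulate_landscape(spec)
  s <- simulate_samples(5, 6, land$current, seed = 6)
  tr <- make_truth(3, 0.1, 2, "temp1", 2)
  g1 <- simulate_genotypes(s, land$current, 50, tr, seed = 77)
  g2 <- simulate_genotypes(s, land$current, 50, tr, seed = 77)
  expect_identical(g1$genotypes$dosages, g2$genotypes$dosages)
  expect_equal(dim(g1$truth$Q_pop), c(5, 3))
  expect_equal(rowSums(g1$truth$Q_pop), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # adaptive ids are a subset of the simulated SNP ids
  expect_true(all(g1$truth$adaptive_locus_ids %in% g1$genotypes$snp_meta$id))
})
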