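fake_grid <- function(tv, nrow_ = NULL) {
  n <- nrow(tv)
  nrow_ <- nrow_ %||% n
  list(turnover = tv, scores = NULL, cells = seq_len(n),
       mask = matrix(TRUE, nrow_, ceiling(n / nrow_)),
       nrow = nrow_, ncol = ceiling(n / nrow_),
       predictor_names = colnames(tv))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("genomic offset is the per-cell Euclidean distance in turnover space", {
  set.seed(1)
  tv1 <- matrix(runif(120), 30, 4, dimnames = list(NULL, letters[1:4]))
  tv2 <- matrix(runif(120), 30, 4, dimnames = list(NULL, letters[1:4]))
  g1 <- fake_grid(tv1); g2 <- fake_grid(tv2)
  off <- genomic_offset(g1, g2)
  # brute-force per-cell loop over predictors
  for (i in seq_len(30)) {
    s <- 0
    for (v in 1:4) s <- s + (tv2[i, v] - tv1[i, v])^2
    expect_equal(unname(off$raw[i]), unname(sqrt(s)), tolerance = 1e-10)
  }
  expect_equal(genomic_offset(g1, g1)$raw, rep(0, 30))
  # single differing coordinate
  tv3 <- tv1; tv3[7, 2] <- tv1[7, 2] + 0.25
  expect_equal(genomic_offset(g1, fake_grid(tv3))$raw[7], 0.25)
  # symmetry and triangle inequality
  expect_equal(genomic_offset(g1, g2)$raw, genomic_offset(g2, g1)$raw)
  g3 <- fake_grid(matrix(runif(120), 30, 4, dimnames = list(NULL, letters[1:4])))
  expect_true(all(genomic_offset(g1, g3)$raw <=
                    genomic_offset(g1, g2)$raw + genomic_offset(g2, g3)$raw + 1e-12))
  # configuration keeping the literal sum-of-squares form
  expect_equal(genomic_offset(g1, g2, sqrt = FALSE)$raw, off$raw^2,
               tolerance = 1e-12)
  bad <- g2; bad$predictor_names <- letters[2:5]
  expect_error(genomic_offset(g1, bad), "predictor")
})

test_that("offset scales linearly with a uniform turnover shift", {
  set.seed(2)
  tv <- matrix(runif(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  delta <- matrix(rnorm(80, sd = 0.1), 20, 4)
  g0 <- fake_grid(tv)
  o1 <- genomic_offset(g0, fake_grid(tv + delta))$raw
  o3 <- genomic_offset(g0, fake_grid(tv + 3 * delta))$raw
  expect_equal(o3, 3 * o1, tolerance = 1e-10)
})

test_that("min-max scaling pools constants across every scenario", {
  g0 <- fake_grid(matrix(0, 3, 1, dimnames = list(NULL, "a")))
  mk <- function(vals) {
    m <- genomic_offset(g0, g0)
    m$raw <- vals
    m
  }
  out <- scale_offsets(list(s1 = mk(c(2, 4, 6)), s2 = mk(c(4, 4, 4))))
  expect_equal(out$s1$scaled, c(0, 0.5, 1))
  expect_equal(out$s2$scaled, c(0.5, 0.5, 0.5))
  # the pooled maximum maps to exactly 1, only in the scenario holding it
  expect_equal(sum(out$s1$scaled == 1), 1)
  expect_equal(sum(out$s2$scaled == 1), 0)
  expect_warning(scale_offsets(list(mk(c(1, 1, 1)))), "degenerate")
  expect_error(scale_offsets(list()), "empty")
})

test_that("variable contributions are normalized squared differences", {
  set.seed(3)
  tv1 <- matrix(runif(60), 15, 4, dimnames = list(NULL, letters[1:4]))
  tv2 <- tv1
  tv2[, 2] <- tv1[, 2] + runif(15, 0.1, 0.5)   # only variable b changes
  vc <- variable_contributions(fake_grid(tv1), fake_grid(tv2))
  expect_equal(unname(vc$fractions[, "b"]), rep(1, 15))
  expect_equal(unname(vc$range_mean["b"]), 1)
  tv3 <- matrix(runif(60), 15, 4, dimnames = list(NULL, letters[1:4]))
  vc2 <- variable_contributions(fake_grid(tv1), fake_grid(tv3))
  expect_equal(rowSums(vc2$fractions), rep(1, 15), tolerance = 1e-12)
  d2 <- (tv3 - tv1)^2
  expect_equal(vc2$fractions, d2 / rowSums(d2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scenario specifications are validated against the fixed sets", {
  sc <- scenario_spec("MIROC6", 370, "2081-2100")
  expect_s3_class(sc, "scenario_spec")
  expect_error(scenario_spec("", 370, "2081-2100"), "gcm")
  expect_error(scenario_spec("MIROC6", 999, "2081-2100"), "ssp")
  expect_error(scenario_spec("MIROC6", 126, "2100-2120"), "period")
})

sim_similarity_setup <- function(seed) {
  d <- sim_dataset(seed = seed, n_pops = 12, n_per_pop = 6, n_neutral = 0,
                   n_adaptive = 40, effect = 2.5, grid = 20)
  sv <- pcnm_vectors(d$coords)
  pred <- cbind(d$env, as.data.frame(sv$vectors))
  fit <- fit_gradient_forest(d$gm, pred, n_trees = 80, seed = seed)
  pl <- pcnm_layers(sv, d$coords, d$land$current)
  cur <- env_stack(c(d$land$current$layers, pl))
  fut <- env_stack(c(d$land$future$future$layers, pl))
  list(fit = fit, cur = cur, fut = fut, d = d)
}

test_that("similarity maps span [0, 1] and honour the reversal rule", {
  s <- sim_similarity_setup(210)
  site <- c(10.5, 10.5)
  sim <- similarity_map(site, s$fit, s$cur, s$fut)
  expect_equal(min(sim$similarity), 0)
  expect_equal(max(sim$similarity), 1)
  # oracle: 1 - min-max-scaled brute-force distances
  fut_vals <- extract_at_points(s$fut, data.frame(x = site[1], y = site[2]))
  fut_vals <- fut_vals[, setdiff(names(fut_vals), "in_mask")]
  target <- turnover_transform(s$fit, fut_vals)
  cells <- which(s$cur$mask)
  cur_tv <- turnover_transform(s$fit, landgea:::stack_matrix(s$cur, cells))
  d <- sqrt(rowSums(sweep(cur_tv, 2, as.vector(target))^2))
  expect_equal(sim$similarity, 1 - (d - min(d)) / (max(d) - min(d)),
               tolerance = 1e-10)
  # cell at maximal distance scores exactly 0
  expect_equal(sim$similarity[which.max(d)], 0)
  expect_error(similarity_map(c(-3, 2), s$fit, s$cur, s$fut), "outside")
})

test_that("with no climate change the site's own cell is maximally similar", {
  s <- sim_similarity_setup(220)
  site <- c(7.5, 12.5)
  sim <- similarity_map(site, s$fit, s$cur, s$cur)
  own <- which(sim$cells == sim$site_cell)
  expect_equal(sim$similarity[own], 1)
})

test_that("offset responds to a shift on the causal variable more than a decoy", {
  diffs <- numeric(10)
  for (rep in 1:10) {
    d <- sim_dataset(seed = 300 + rep, n_pops = 12, n_per_pop = 6,
                     n_neutral = 0, n_adaptive = 30, effect = 3, grid = 20)
    sv <- pcnm_vectors(d$coords)
    pred <- cbind(d$env, as.data.frame(sv$vectors))
    fit <- fit_gradient_forest(d$gm, pred, n_trees = 80, seed = rep)
    pl <- pcnm_layers(sv, d$coords, d$land$current)
    cur <- env_stack(c(d$land$current$layers, pl))
    shift_stack <- function(var) {
      ll <- c(d$land$current$layers, pl)
      ll[[var]] <- ll[[var]] + 1
      env_stack(ll)
    }
    g_cur <- project_turnover(fit, cur)
    off_causal <- mean(genomic_offset(g_cur, project_turnover(fit, shift_stack("temp1")))$raw)
    off_decoy <- mean(genomic_offset(g_cur, project_turnover(fit, shift_stack("prec2")))$raw)
    diffs[rep] <- off_causal - off_decoy
  }
  expect_lt(wilcox.test(diffs, alternative = "greater")$p.value, 0.05)
})
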