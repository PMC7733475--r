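test_that("cohort generation is deterministic under the seed", {
  cfg <- simulation_config(n_per_cluster = c(6L, 6L), n_events = 40L,
                           n_genes = 30L, n_rbp = 8L, n_rbp_coupled = 3L,
                           seed = 11L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$inclusion, c2$inclusion)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth$mu, c2$truth$mu)
})

test_that("matrices have configured shapes and integral non-negative counts", {
  cfg <- simulation_config(n_per_cluster = c(7L, 5L), n_events = 33L,
                           n_genes = 21L, n_rbp = 6L, n_rbp_coupled = 2L,
                           seed = 3L)
  coh <- simulate_cohort(cfg)
  expect_equal(dim(coh$inclusion), c(33L, 12L))
  expect_equal(dim(coh$expression), c(21L, 12L))
  expect_equal(nrow(coh$clinical), 12L)
  expect_true(all(coh$inclusion >= 0) && all(coh$exclusion >= 0))
  expect_true(all(coh$inclusion == round(coh$inclusion)))
  expect_true(all(coh$expression == round(coh$expression)))
})

test_that("planted shifted-event count follows frac_shifted arithmetic", {
  cfg <- simulation_config(n_events = 600L, frac_shifted = 0.3, seed = 1L)
  truth <- simulate_truth(cfg)
  expect_length(truth$shifted_events, 180L)
  # all shifts toward higher PSI in cluster 2 under the default direction
  d <- truth$mu[truth$shifted_events, 2] - truth$mu[truth$shifted_events, 1]
  expect_true(all(d > 0))
})

test_that("no planted effect means no systematic cluster PSI difference", {
  cfg <- simulation_config(n_per_cluster = c(30L, 30L), n_events = 200L,
                           frac_shifted = 0, delta_psi = 0, seed = 9L)
  truth <- simulate_truth(cfg)
  expect_identical(unname(truth$mu[, 1]), unname(truth$mu[, 2]))
  counts <- simulate_event_counts(cfg, truth)
  psi <- compute_psi(counts$inclusion, counts$exclusion)
  gap <- rowMeans(psi[, truth$cluster == 2], na.rm = TRUE) -
    rowMeans(psi[, truth$cluster == 1], na.rm = TRUE)
  expect_lt(abs(mean(gap)), 0.02)
})

test_that("empirical PSI approaches the configured mean at high depth and concentration", {
  cfg <- simulation_config(n_per_cluster = c(10L, 10L), n_events = 50L,
                           mean_depth = 1e5, psi_dispersion = 1e6, seed = 2L)
  truth <- simulate_truth(cfg)
  counts <- simulate_event_counts(cfg, truth)
  psi <- compute_psi(counts$inclusion, counts$exclusion)
  emp <- rowMeans(psi[, truth$cluster == 1])
  expect_true(all(abs(emp - truth$mu[, 1]) < 0.01))
})

test_that("shifted events show higher cluster-2 PSI in nearly all seeds", {
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    cfg <- simulation_config(n_per_cluster = c(40L, 40L), n_events = 10L,
                             frac_shifted = 0.5, delta_psi = 0.2,
                             n_genes = 5L, n_rbp = 2L, n_rbp_coupled = 0L,
                             seed = s)
    truth <- simulate_truth(cfg)
    counts <- simulate_event_counts(cfg, truth)
    psi <- compute_psi(counts$inclusion, counts$exclusion)
    for (ev in truth$shifted_events) {
      m1 <- mean(psi[ev, truth$cluster == 1], na.rm = TRUE)
      m2 <- mean(psi[ev, truth$cluster == 2], na.rm = TRUE)
      total <- total + 1L
      if (m2 > m1) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("increasing delta_psi does not shrink the cluster PSI gap", {
  gap_at <- function(delta) {
    gaps <- vapply(1:5, function(s) {
      cfg <- simulation_config(n_per_cluster = c(20L, 20L), n_events = 60L,
                               frac_shifted = 0.5, delta_psi = delta,
                               n_genes = 5L, n_rbp = 2L, n_rbp_coupled = 0L,
                               seed = s)
      truth <- simulate_truth(cfg)
      counts <- simulate_event_counts(cfg, truth)
      psi <- compute_psi(counts$inclusion, counts$exclusion)
      sh <- truth$shifted_events
      mean(rowMeans(psi[sh, truth$cluster == 2], na.rm = TRUE) -
             rowMeans(psi[sh, truth$cluster == 1], na.rm = TRUE))
    }, numeric(1))
    mean(gaps)
  }
  g <- vapply(c(0, 0.1, 0.2, 0.3), gap_at, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("uncoupled expression shows no correlation with the retention score", {
  ok <- vapply(1:20, function(s) {
    cfg <- simulation_config(coupling_strength = 0, n_events = 100L,
                             n_genes = 50L, n_rbp = 10L, n_rbp_coupled = 3L,
                             seed = s)
    truth <- simulate_truth(cfg)
    counts <- simulate_event_counts(cfg, truth)
    psi <- compute_psi(counts$inclusion, counts$exclusion)
    expr <- simulate_expression(cfg, truth, psi)
    z <- scale(colMeans(psi[truth$shifted_events, ], na.rm = TRUE))
    r <- cor(log1p(expr[truth$coupled_rbps[1], ]), z)
    abs(r) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("strongly coupled RBPs reach r >= 0.7 against sample retention", {
  cfg <- simulation_config(coupling_strength = 2.5, nb_dispersion = 0.05,
                           seed = 4L, n_events = 200L, n_genes = 100L,
                           n_rbp = 15L, n_rbp_coupled = 5L)
  truth <- simulate_truth(cfg)
  counts <- simulate_event_counts(cfg, truth)
  psi <- compute_psi(counts$inclusion, counts$exclusion)
  expr <- simulate_expression(cfg, truth, psi)
  z <- colMeans(psi[truth$shifted_events, ], na.rm = TRUE)
  r <- vapply(truth$coupled_rbps,
              function(g) cor(log1p(expr[g, ]), z), numeric(1))
  expect_true(all(r >= 0.7))
})

test_that("clinical generator honors censoring bounds and rejects bad hazard ratios", {
  expect_error(simulation_config(hazard_ratio = 0), "hazard_ratio")
  expect_error(simulation_config(hazard_ratio = -1), "hazard_ratio")
  cfg <- simulation_config(censor_max = 0, n_events = 10L, n_genes = 5L,
                           n_rbp = 2L, n_rbp_coupled = 0L, seed = 6L)
  truth <- simulate_truth(cfg)
  cl <- simulate_clinical(cfg, truth)
  expect_true(all(cl$pfi_event == 0))
  expect_true(all(cl$os_event == 0))
})

test_that("mutation flags track per-cluster frequencies", {
  cfg <- simulation_config(n_per_cluster = c(400L, 400L), n_events = 10L,
                           n_genes = 5L, n_rbp = 2L, n_rbp_coupled = 0L,
                           seed = 8L)
  truth <- simulate_truth(cfg)
  cl <- simulate_clinical(cfg, truth)
  f1 <- mean(cl$tp53_mut[truth$cluster == 1])
  f2 <- mean(cl$tp53_mut[truth$cluster == 2])
  expect_lt(abs(f1 - 0.85), 0.06)
  expect_lt(abs(f2 - 0.528), 0.06)
})
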