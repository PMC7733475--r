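test_that("Fisher 2x2 handles the enumerable diagonal table and degenerate margins", {
  ft <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))
  expect_equal(ft$p, 1 / 3, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, Inf)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2))
  expect_equal(deg$p, 1)
  expect_true(is.nan(deg$odds_ratio))
  expect_error(fisher_exact_2x2(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("Fisher 2x2 matches hypergeometric enumeration on random small tables", {
  set.seed(1)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) > 30 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("Fisher 2x2 is symmetric under simultaneous row and column swaps", {
  set.seed(2)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(swapped)$p,
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo r x c Fisher behaves on null tables and agrees with the exact 2x2", {
  prop <- matrix(c(10, 20, 30, 5, 10, 15), 2, byrow = TRUE)  # proportional rows
  p <- fisher_rxc_montecarlo(prop, n_perm = 20000, seed = 1)
  expect_gt(p, 1 - 3 * sqrt(0.25 / 20000) - 0.05)
  tab <- matrix(c(8, 2, 3, 9), 2)
  pe <- fisher_exact_2x2(tab)$p
  pm <- fisher_rxc_montecarlo(tab, n_perm = 50000, seed = 2)
  se <- sqrt(pe * (1 - pe) / 50000)
  expect_lt(abs(pm - pe), 3 * se + 1e-4)
  expect_identical(fisher_rxc_montecarlo(tab, n_perm = 5000, seed = 7),
                   fisher_rxc_montecarlo(tab, n_perm = 5000, seed = 7))
  expect_warning(fisher_rxc_montecarlo(tab, n_perm = 500, seed = 1), "1000")
})

test_that("hypergeometric overlap matches closed forms", {
  expect_equal(hypergeometric_overlap(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(6, 6, 6, 6), 1)
  # expected-overlap input sits mid-distribution
  p <- hypergeometric_overlap(10, 10, 5, 20)  # E[overlap] = 5
  enum <- sum(dhyper(5:10, 10, 10, 10))
  expect_equal(p, enum, tolerance = 1e-12)
  expect_gt(p, 0.5); expect_lt(p, 0.75)
  expect_error(hypergeometric_overlap(5, 5, 6, 10), "inconsistent")
})

test_that("intron location classification follows containment rules", {
  regions <- data.frame(
    contig = "chr1",
    start = c(0, 500, 900, 2000),
    end = c(500, 900, 1200, 2500),
    region_type = c("UTR5", "CDS", "UTR3", "CDS"),
    stringsAsFactors = FALSE)
  ev <- function(s, e) list(contig = "chr1", start = s, end = e)
  expect_equal(classify_intron_location(ev(550, 700), regions), "CDS")
  expect_equal(classify_intron_location(ev(100, 300), regions), "UTR5")
  expect_equal(classify_intron_location(ev(950, 1100), regions), "UTR3")
  expect_equal(classify_intron_location(ev(800, 1000), regions), "mixed")
  expect_equal(classify_intron_location(ev(3000, 3100), regions), "intergenic")
  # overlaps one type but extends past its intervals
  expect_equal(classify_intron_location(ev(2400, 2600), regions), "mixed")
  expect_error(classify_intron_location(ev(700, 700), regions), "malformed")
})

test_that("cancer-gene role lists merge with the both rule", {
  a <- c(g1 = "oncogene", g2 = "tumor_suppressor", g3 = "oncogene",
         g5 = "both")
  b <- c(g1 = "tumor_suppressor", g3 = "oncogene", g4 = "tumor_suppressor")
  m <- merge_cancer_gene_roles(a, b)
  expect_equal(m[["g1"]], "both")            # conflict
  expect_equal(m[["g2"]], "tumor_suppressor") # one list only
  expect_equal(m[["g3"]], "oncogene")         # agreement
  expect_equal(m[["g4"]], "tumor_suppressor")
  expect_equal(m[["g5"]], "both")             # both stays both
})

test_that("category enrichment detects planted enrichment and reports fractions", {
  set.seed(3)
  sel <- sprintf("s%03d", 1:200)
  ctrl <- sprintf("c%04d", 1:2000)
  annot <- c(setNames(ifelse(runif(200) < 0.30, "oncogene", "none"), sel),
             setNames(ifelse(runif(2000) < 0.05, "oncogene", "none"), ctrl))
  ce <- category_enrichment(sel, ctrl, annot, "oncogene")
  expect_lt(ce$p, 0.01)
  expect_equal(ce$frac_selected, unname(ce$table["selected", "in_category"]) / 200)
  # identical category rates are unremarkable
  annot2 <- c(setNames(rep(c("oncogene", "none"), 100), sel),
              setNames(rep(c("oncogene", "none"), 1000), ctrl))
  expect_gt(category_enrichment(sel, ctrl, annot2, "oncogene")$p, 0.5)
  expect_error(category_enrichment(sel, c(sel[1], ctrl), annot, "oncogene"),
               "disjoint")
})

test_that("median-of-ratios size factors respond to depth scaling", {
  set.seed(4)
  base <- matrix(rnbinom(500 * 6, mu = 100, size = 5) + 1L, 500, 6)
  sf <- median_ratio_normalize(base)
  sf_same <- median_ratio_normalize(cbind(base[, 1], base[, 1], base[, 1]))
  expect_equal(unname(sf_same), rep(1, 3), tolerance = 1e-12)
  doubled <- base; doubled[, 3] <- 2L * doubled[, 3]
  sf2 <- median_ratio_normalize(doubled)
  expect_equal(sf2[3] / sf2[1], 2 * sf[3] / sf[1], tolerance = 0.02)
  expect_error(median_ratio_normalize(matrix(c(0L, 1L, 1L, 0L), 2)),
               "positive")
})

test_that("size factors recover configured depth multipliers within 5%", {
  set.seed(5)
  mult <- c(0.5, 0.8, 1, 1.25, 2, 1)
  mu <- exp(rnorm(2000, log(200), 1))
  counts <- sapply(mult, function(m) rnbinom(2000, mu = m * mu, size = 10))
  sf <- median_ratio_normalize(counts)
  sf <- sf / exp(mean(log(sf)))
  target <- mult / exp(mean(log(mult)))
  expect_true(all(abs(sf / target - 1) < 0.05))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  counts <- matrix(rnbinom(300 * 5, mu = 50, size = 2) + 1L, 300, 5)
  ours <- unname(median_ratio_normalize(counts))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(counts))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("row-wise Welch test matches t.test and flags degenerate rows", {
  set.seed(7)
  A <- matrix(rnorm(20 * 8, 1), 20, 8)
  B <- matrix(rnorm(20 * 6), 20, 6)
  w <- welch_test_rows(A, B)
  for (i in c(1, 7, 20)) {
    tt <- t.test(A[i, ], B[i, ])
    expect_equal(w$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(w$diff[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  Z <- matrix(1, 2, 5)
  wz <- welch_test_rows(Z, Z[, 1:4])
  expect_equal(wz$p, c(1, 1))
})

test_that("differential expression recovers planted fold changes with correct sign", {
  set.seed(8)
  n <- 40; g <- 300
  mu <- exp(rnorm(g, log(200), 0.5))
  fc <- rep(1, g); fc[1:30] <- 4
  counts <- cbind(
    sapply(seq_len(n), function(j) rnbinom(g, mu = mu * fc, size = 10)),
    sapply(seq_len(n), function(j) rnbinom(g, mu = mu, size = 10)))
  rownames(counts) <- sprintf("g%03d", 1:g)
  part <- rep(1:2, each = n)
  de <- differential_expression(counts, part)
  hits <- de$q[1:30] < 0.05 & de$log2fc[1:30] > 0
  expect_gte(mean(hits), 0.9)
  # anti-symmetry under relabeling
  de2 <- differential_expression(counts, 3 - part)
  expect_equal(de$log2fc, -de2$log2fc, tolerance = 1e-12)
  expect_equal(de$p, de2$p, tolerance = 1e-12)
})

test_that("RBP-event correlation reports affine relationships and honors the inclusive threshold", {
  set.seed(9)
  n <- 30
  x <- rnorm(n)
  expr <- rbind(rbp1 = 2 * x + 5, rbp2 = rnorm(n))
  psi <- rbind(ev1 = (x - min(x)) / diff(range(x)), ev2 = runif(n))
  res <- correlate_rbp_events(expr, psi, c("rbp1", "rbp2"), c("ev1", "ev2"))
  expect_true(any(res$pairs$rbp == "rbp1" & res$pairs$event == "ev1" &
                    abs(res$pairs$r - 1) < 1e-12))
  # inclusive threshold: calling with r_min equal to a pair's exact r reports it
  r_exact <- correlate_rbp_events(expr, psi, "rbp2", "ev2",
                                  r_min = -1, alpha = 1)$pairs$r[1]
  res2 <- correlate_rbp_events(expr, psi, "rbp2", "ev2",
                               r_min = r_exact, alpha = 1)
  expect_equal(nrow(res2$pairs), 1L)
  res3 <- correlate_rbp_events(expr, psi, "rbp2", "ev2",
                               r_min = r_exact + 1e-12, alpha = 1)
  expect_equal(nrow(res3$pairs), 0L)
})

test_that("correlation output is invariant to per-gene affine rescaling", {
  set.seed(10)
  expr <- matrix(rnorm(5 * 25), 5, 25,
                 dimnames = list(paste0("r", 1:5), NULL))
  psi <- matrix(runif(4 * 25), 4, 25,
                dimnames = list(paste0("e", 1:4), NULL))
  a <- correlate_rbp_events(expr, psi, rownames(expr), rownames(psi),
                            r_min = -1, alpha = 1)
  b <- correlate_rbp_events(expr * 3 + 7, psi, rownames(expr), rownames(psi),
                            r_min = -1, alpha = 1)
  expect_equal(a$pairs$r, b$pairs$r, tolerance = 1e-12)
})

test_that("pairs with too few complete observations are skipped", {
  expr <- matrix(rnorm(10), 1, 10, dimnames = list("r1", NULL))
  psi <- matrix(c(0.1, 0.2, rep(NA, 8)), 1, 10,
                dimnames = list("e1", NULL))
  res <- correlate_rbp_events(expr, psi, "r1", "e1", r_min = -1, alpha = 1)
  expect_equal(res$n_tested, 0)
  expect_equal(nrow(res$pairs), 0L)
})

test_that("Spearman correlation handles monotone, reversed and tied input", {
  x <- 1:10
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  set.seed(11)
  a <- sample(1:5, 12, TRUE); b <- sample(1:5, 12, TRUE)
  got <- spearman_correlation(a, b)
  expect_equal(got$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})
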