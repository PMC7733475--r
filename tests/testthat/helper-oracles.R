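# Independent oracle implementations used to cross-check the package.
# These deliberately take different computational routes from the package
# code (pair enumeration, dhyper-based expectations, explicit sorting) so
# agreement is informative.

# ARI by brute-force enumeration of all sample pairs
oracle_ari <- function(p1, p2) {
  n <- length(p1)
  same1 <- outer(p1, p1, "==")[upper.tri(diag(n))]
  same2 <- outer(p2, p2, "==")[upper.tri(diag(n))]
  a <- sum(same1 & same2)   # agree-together
  b <- sum(!same1 & !same2) # agree-apart
  npairs <- n * (n - 1) / 2
  # expected index under fixed margins
  tab <- table(p1, p2)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / npairs
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# AMI with the expected MI computed via dhyper (stats' hypergeometric pmf)
oracle_ami <- function(p1, p2) {
  tab <- table(p1, p2)
  n <- sum(tab)
  a <- unname(rowSums(tab)); b <- unname(colSums(tab))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- ent(a / n); h2 <- ent(b / n)
  if (h1 == 0 || h2 == 0) return(0)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(nij * n / (a[i] * b[j]))
  }
  emi <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      if (nij < 1) next
      pr <- stats::dhyper(nij, bj, n - bj, ai)
      emi <- emi + pr * (nij / n) * log(nij * n / (ai * bj))
    }
  }
  (mi - emi) / ((h1 + h2) / 2 - emi)
}

# BH step-up by explicit sort (independent of stats::p.adjust)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# two-sided Fisher 2x2 p by full enumeration of margin-consistent tables
oracle_fisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) dhyper(a, c1, n - c1, r1), numeric(1))
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  min(1, p)
}

# Kim-Park feature scores by direct per-row loop
oracle_kim_park <- function(W) {
  k <- ncol(W)
  apply(W, 1, function(w) {
    p <- w / sum(w)
    s <- 0
    for (q in seq_len(k)) if (p[q] > 0) s <- s + p[q] * log2(p[q])
    1 + s / log2(k)
  })
}

# within/total sum of squares by double loop (for RMSSTD / RS / SD oracles)
oracle_ss <- function(X, part) {
  ssw <- 0
  for (l in unique(part)) {
    Xi <- X[, part == l, drop = FALSE]
    ctr <- rowMeans(Xi)
    for (j in seq_len(ncol(Xi))) ssw <- ssw + sum((Xi[, j] - ctr)^2)
  }
  gm <- rowMeans(X)
  sst <- 0
  for (j in seq_len(ncol(X))) sst <- sst + sum((X[, j] - gm)^2)
  list(ssw = ssw, sst = sst)
}

# two well-separated sample blocks for consensus-clustering fixtures;
# each block has its own elevated event subset (complementary patterns)
make_two_block <- function(n_events = 30, n_per_block = 8, noise = 0,
                           seed = 1) {
  set.seed(seed)
  half <- n_events %/% 2
  hi <- runif(n_events, 0.6, 0.9)
  lo <- runif(n_events, 0.05, 0.25)
  base1 <- c(hi[1:half], lo[(half + 1):n_events])
  base2 <- c(lo[1:half], hi[(half + 1):n_events])
  X <- cbind(matrix(rep(base1, n_per_block), n_events),
             matrix(rep(base2, n_per_block), n_events))
  if (noise > 0) X <- X + matrix(rnorm(length(X), 0, noise), nrow(X))
  X <- pmin(pmax(X, 0), 1)
  dimnames(X) <- list(sprintf("E%02d", seq_len(n_events)),
                      sprintf("S%02d", seq_len(2 * n_per_block)))
  X
}

# hand-built 20-event fixture: each cascade rule violated by known events
make_cascade_fixture <- function() {
  n <- 20  # samples per cluster
  jit <- function(center, spread = 0.02)
    center + seq(-spread, spread, length.out = n)
  psi <- matrix(NA_real_, 20, 2 * n,
                dimnames = list(sprintf("ev%02d", 1:20),
                                sprintf("s%02d", 1:(2 * n))))
  i1 <- 1:n; i2 <- (n + 1):(2 * n)
  # ev01-ev08: clean strong shift, pass everything
  for (e in 1:8) {
    psi[e, i1] <- jit(0.70); psi[e, i2] <- jit(0.30)
  }
  # ev09: significant but delta exactly 0.1 (strict > fails)
  psi[9, i1] <- rep(0.5, n); psi[9, i2] <- rep(0.4, n)
  # ev10: strong shift but exactly 10% missing overall, balanced 2+2
  psi[10, i1] <- jit(0.8); psi[10, i2] <- jit(0.2)
  psi[10, c(1, 2, n + 1, n + 2)] <- NA
  # ev11: strong shift, 5% total missing but all in cluster 1 (imbalance 10%)
  psi[11, i1] <- jit(0.8); psi[11, i2] <- jit(0.2)
  psi[11, c(3, 4)] <- NA
  # ev12: no difference between clusters (fails significance)
  psi[12, i1] <- jit(0.5); psi[12, i2] <- jit(0.5)
  # ev13-ev20: null filler for the BH family
  for (e in 13:20) {
    psi[e, i1] <- jit(0.45, 0.05); psi[e, i2] <- jit(0.45, 0.05)
  }
  list(psi = psi, partition = rep(1:2, each = n),
       expected_selected = sprintf("ev%02d", 1:8))
}

# memoised default study cohort + pipeline bundle shared by the heavier
# end-to-end checks
.acc_env <- new.env(parent = emptyenv())
acceptance_bundle <- function() {
  if (is.null(.acc_env$bundle)) {
    cfg <- simulation_config(seed = 20201211L)
    .acc_env$cohort <- simulate_cohort(cfg)
    .acc_env$bundle <- run_pipeline(pipeline_config(seed = 20201211L),
                                    .acc_env$cohort)
  }
  list(cohort = .acc_env$cohort, bundle = .acc_env$bundle)
}

# small default-structure cohort for fast unit tests
small_cohort <- function(seed = 5, ...) {
  simulate_cohort(simulation_config(
    n_per_cluster = c(15L, 15L), n_events = 150L, n_genes = 200L,
    n_rbp = 20L, n_rbp_coupled = 5L, seed = seed, ...))
}
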