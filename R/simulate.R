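#' Simulation configuration for a synthetic splicing cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a two-cluster cohort of 40+40 tumors with 600 intron-retention
#' events, 30% of which are shifted upward by 0.2 PSI in cluster 2,
#' beta-binomial PSI noise at concentration 30 and mean spliced depth 50,
#' negative-binomial expression for 1000 genes with 10 RNA-binding-protein
#' (RBP) genes coupled to the sample-level retention score, and exponential
#' survival with hazard ratio 0.49 (cluster 2 vs cluster 1, so cluster 1 has
#' the worse outcome). Mutation-flag frequencies default to TP53 85% / 52.8%
#' and KRAS 92.5% / 86.1% in clusters 1 and 2.
#'
#' @param n_per_cluster integer vector of length 2, samples per cluster.
#' @param n_events number of splice events.
#' @param frac_shifted fraction of events carrying the planted PSI shift.
#' @param delta_psi magnitude of the planted shift (PSI units).
#' @param shift_direction `"up"`: all shifted events move toward higher PSI in
#'   cluster 2 (the asymmetric intron-retention signature); `"random"`: each
#'   shifted event moves up or down with probability 1/2 (symmetric null).
#' @param psi_dispersion beta concentration phi (> 0); larger means less
#'   biological PSI noise.
#' @param mean_depth expected spliced reads per event and sample (Poisson).
#' @param n_genes number of genes in the expression matrix.
#' @param n_rbp number of genes flagged as RBPs.
#' @param n_rbp_coupled number of RBP genes whose log-expression tracks the
#'   sample retention score.
#' @param coupling_strength coefficient on the standardized retention score in
#'   the coupled genes' log mean.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param hazard_ratio true hazard ratio of cluster 2 relative to cluster 1
#'   (< 1 means cluster 1 fares worse); must be > 0.
#' @param baseline_hazard cluster-2 exponential hazard per day.
#' @param censor_max upper bound of the uniform censoring time (days).
#' @param mutation_freqs named list; each element a length-2 vector of
#'   per-cluster Bernoulli frequencies for one mutation flag.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_per_cluster = c(40L, 40L),
                              n_events = 600L,
                              frac_shifted = 0.3,
                              delta_psi = 0.2,
                              shift_direction = c("up", "random"),
                              psi_dispersion = 30,
                              mean_depth = 50,
                              n_genes = 1000L,
                              n_rbp = 50L,
                              n_rbp_coupled = 10L,
                              coupling_strength = 2,
                              nb_dispersion = 0.4,
                              hazard_ratio = 0.49,
                              baseline_hazard = 0.001,
                              censor_max = 3000,
                              mutation_freqs = list(
                                tp53_mut = c(0.85, 0.528),
                                kras_mut = c(0.925, 0.861)),
                              seed = 1L) {
  shift_direction <- match.arg(shift_direction)
  stopifnot(length(n_per_cluster) == 2, all(n_per_cluster >= 1),
            n_events >= 1, frac_shifted >= 0, frac_shifted <= 1,
            delta_psi >= 0, delta_psi <= 1,
            psi_dispersion > 0, mean_depth > 0,
            n_genes >= 1, n_rbp <= n_genes, n_rbp_coupled <= n_rbp,
            nb_dispersion > 0, baseline_hazard > 0, censor_max >= 0)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  for (f in mutation_freqs) {
    stopifnot(length(f) == 2, all(f >= 0), all(f <= 1))
  }
  cfg <- list(n_per_cluster = as.integer(n_per_cluster),
              n_events = as.integer(n_events),
              frac_shifted = frac_shifted, delta_psi = delta_psi,
              shift_direction = shift_direction,
              psi_dispersion = psi_dispersion, mean_depth = mean_depth,
              n_genes = as.integer(n_genes), n_rbp = as.integer(n_rbp),
              n_rbp_coupled = as.integer(n_rbp_coupled),
              coupling_strength = coupling_strength,
              nb_dispersion = nb_dispersion,
              hazard_ratio = hazard_ratio,
              baseline_hazard = baseline_hazard,
              censor_max = censor_max,
              mutation_freqs = mutation_freqs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# one child seed per generator block so e.g. changing n_genes never perturbs
# the event counts; all derived from the single cohort seed
.child_seeds <- function(seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max, 4L)
  names(s) <- c("truth", "counts", "expression", "clinical")
  s
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Ground truth for a synthetic cohort
#'
#' Draws the latent structure every generator conditions on: cluster labels,
#' the shifted-event set with per-cluster true PSI means, the coupled RBP
#' genes with their coefficients, and the true log hazard. Cluster 2 is the
#' high-retention cluster; shifted events move toward higher PSI there (unless
#' `shift_direction = "random"`). True means are clipped to [0.01, 0.99] if
#' the shift would leave (0, 1); clipping is recorded in the result.
#'
#' @param cfg a [simulation_config()] object.
#' @return A list of class `sim_truth` with elements `sample_id`, `cluster`,
#'   `event_id`, `shifted_events`, `mu` (events x 2 matrix of true cluster
#'   means), `coupled_rbps`, `coupling`, `beta` (true log hazard of cluster 1
#'   vs cluster 2), `n_clipped`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.child_seeds(cfg$seed)[["truth"]])

  n <- sum(cfg$n_per_cluster)
  sample_id <- sprintf("S%03d", seq_len(n))
  cluster <- rep(1:2, cfg$n_per_cluster)
  event_id <- sprintf("IR_%04d", seq_len(cfg$n_events))

  n_shift <- round(cfg$frac_shifted * cfg$n_events)
  shifted <- if (n_shift > 0) sort(sample.int(cfg$n_events, n_shift)) else integer(0)

  base_mu <- runif(cfg$n_events, 0.05, 0.65)
  mu <- cbind(base_mu, base_mu)
  if (n_shift > 0) {
    # level-matched shift: each shifted event has a low level (base) and a
    # high level (base + delta); the direction setting only decides which
    # cluster carries the high level, so up- and down-shifted events have
    # identical PSI-level distributions under the symmetric null
    high_in_2 <- if (cfg$shift_direction == "up") rep(TRUE, n_shift)
                 else sample(c(TRUE, FALSE), n_shift, replace = TRUE)
    mu[shifted, 2] <- ifelse(high_in_2, base_mu[shifted] + cfg$delta_psi,
                             base_mu[shifted])
    mu[shifted, 1] <- ifelse(high_in_2, base_mu[shifted],
                             base_mu[shifted] + cfg$delta_psi)
  }
  clipped <- mu < 0.01 | mu > 0.99
  mu[] <- pmin(pmax(mu, 0.01), 0.99)
  dimnames(mu) <- list(event_id, c("cluster1", "cluster2"))

  gene_id <- sprintf("GENE_%04d", seq_len(cfg$n_genes))
  rbp_ids <- gene_id[seq_len(cfg$n_rbp)]
  coupled <- rbp_ids[seq_len(cfg$n_rbp_coupled)]
  coupling <- stats::setNames(rep(cfg$coupling_strength, cfg$n_rbp_coupled), coupled)

  structure(list(sample_id = sample_id, cluster = cluster,
                 event_id = event_id,
                 shifted_events = event_id[shifted],
                 mu = mu,
                 gene_id = gene_id, rbp_ids = rbp_ids,
                 coupled_rbps = coupled, coupling = coupling,
                 beta = -log(cfg$hazard_ratio),
                 n_clipped = sum(clipped)),
            class = "sim_truth")
}

#' Simulate inclusion/exclusion splice-read counts
#'
#' For each event and sample: total spliced depth `T ~ Poisson(mean_depth)`,
#' latent retention `pi ~ Beta(mu*phi, (1-mu)*phi)` with `mu` the sample's
#' cluster-specific true mean, inclusion `~ Binomial(T, pi)`, exclusion
#' `T - inclusion`.
#'
#' @param cfg a [simulation_config()].
#' @param truth a [simulate_truth()] result for `cfg`.
#' @return list with integer matrices `inclusion` and `exclusion`
#'   (events x samples).
#' @export
simulate_event_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.child_seeds(cfg$seed)[["counts"]])

  n <- length(truth$sample_id)
  mu <- truth$mu[, truth$cluster, drop = FALSE]  # events x samples
  phi <- cfg$psi_dispersion
  total <- matrix(stats::rpois(cfg$n_events * n, cfg$mean_depth),
                  cfg$n_events, n)
  pi <- matrix(stats::rbeta(cfg$n_events * n, mu * phi, (1 - mu) * phi),
               cfg$n_events, n)
  incl <- matrix(stats::rbinom(cfg$n_events * n, as.vector(total), as.vector(pi)),
                 cfg$n_events, n)
  excl <- total - incl
  dimnames(incl) <- dimnames(excl) <- list(truth$event_id, truth$sample_id)
  list(inclusion = incl, exclusion = excl)
}

#' Simulate gene-expression counts with RBP-retention coupling
#'
#' Gene counts are negative binomial around a gene-specific base mean; for
#' the coupled RBP genes the log mean additionally contains
#' `coupling_strength * z_s`, where `z_s` is the sample's mean PSI over the
#' shifted events, standardized across samples. This plants RBP genes whose
#' expression rises with sample-level intron retention.
#'
#' @param cfg a [simulation_config()].
#' @param truth matching [simulate_truth()].
#' @param psi PSI matrix (events x samples) from which the retention score is
#'   computed; only rows named in `truth$shifted_events` are used. If no
#'   events are shifted the score is zero for every sample.
#' @return integer matrix genes x samples.
#' @export
simulate_expression <- function(cfg, truth, psi) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.child_seeds(cfg$seed)[["expression"]])

  n <- length(truth$sample_id)
  if (length(truth$shifted_events) > 0) {
    stopifnot(is.matrix(psi), all(truth$shifted_events %in% rownames(psi)))
    z <- colMeans(psi[truth$shifted_events, , drop = FALSE], na.rm = TRUE)
    z <- if (stats::sd(z) > 0) as.vector(scale(z)) else rep(0, n)
  } else {
    z <- rep(0, n)
  }

  base <- stats::rnorm(cfg$n_genes, mean = log(500), sd = 1)
  logmu <- matrix(base, cfg$n_genes, n)
  coupled_idx <- match(truth$coupled_rbps, truth$gene_id)
  if (length(coupled_idx) > 0) {
    logmu[coupled_idx, ] <- logmu[coupled_idx, ] +
      outer(truth$coupling, z)
  }
  counts <- matrix(stats::rnbinom(cfg$n_genes * n,
                                  mu = exp(as.vector(logmu)),
                                  size = 1 / cfg$nb_dispersion),
                   cfg$n_genes, n)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth$gene_id, truth$sample_id)
  counts
}

#' Simulate clinical endpoints and covariates
#'
#' Event times for the PFI, OS and DSS endpoints are exponential with rate
#' `baseline_hazard * exp(beta * I[cluster == 1])`, `beta = -log(hazard_ratio)`,
#' so cluster 1 has the worse outcome when `hazard_ratio < 1`. Censoring is
#' uniform on `(0, censor_max)` and independent per endpoint. Covariates: age
#' ~ Normal(65, 8), sex ~ Bernoulli(1/2), grade in 1..3, stage I-IV,
#' ABSOLUTE-style purity ~ Uniform(0.35, 0.95), pancreatitis history ~
#' Bernoulli(0.1), and one 0/1 flag per entry of `mutation_freqs` drawn at the
#' cluster-specific frequency.
#'
#' @param cfg a [simulation_config()].
#' @param truth matching [simulate_truth()].
#' @return data.frame, one row per sample.
#' @export
simulate_clinical <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.child_seeds(cfg$seed)[["clinical"]])

  n <- length(truth$sample_id)
  rate <- cfg$baseline_hazard * exp(truth$beta * (truth$cluster == 1))

  endpoint <- function() {
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, 0, cfg$censor_max)
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  }
  pfi <- endpoint(); os <- endpoint(); dss <- endpoint()

  cl <- data.frame(sample_id = truth$sample_id,
                   pfi_time = pfi$time, pfi_event = pfi$event,
                   os_time = os$time, os_event = os$event,
                   dss_time = dss$time, dss_event = dss$event,
                   age = stats::rnorm(n, 65, 8),
                   sex = sample(c("M", "F"), n, replace = TRUE),
                   grade = sample(1:3, n, replace = TRUE,
                                  prob = c(0.25, 0.45, 0.30)),
                   stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                                  prob = c(0.1, 0.6, 0.2, 0.1)),
                   purity = stats::runif(n, 0.35, 0.95),
                   pancreatitis = stats::rbinom(n, 1, 0.1),
                   stringsAsFactors = FALSE)
  for (flag in names(cfg$mutation_freqs)) {
    cl[[flag]] <- stats::rbinom(n, 1, cfg$mutation_freqs[[flag]][truth$cluster])
  }
  cl
}

#' Simulate a complete synthetic cohort
#'
#' Composes [simulate_truth()], [simulate_event_counts()],
#' [simulate_expression()] and [simulate_clinical()] into one object carrying
#' everything the analysis pipeline reads, plus the planted ground truth.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `synthetic_cohort`: list with `inclusion`,
#'   `exclusion`, `expression`, `clinical`, `events` (annotation table),
#'   `gene_roles`, and `truth`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- simulate_truth(cfg)
  counts <- simulate_event_counts(cfg, truth)
  psi <- compute_psi(counts$inclusion, counts$exclusion)
  expr <- simulate_expression(cfg, truth, psi)
  clinical <- simulate_clinical(cfg, truth)

  n_ev <- cfg$n_events
  events <- data.frame(event_id = truth$event_id,
                       as_type = "IR",
                       gene_id = truth$gene_id[((seq_len(n_ev) - 1) %% cfg$n_genes) + 1],
                       contig = "chr1",
                       start = 2000L * seq_len(n_ev),
                       end = 2000L * seq_len(n_ev) + 500L,
                       strand = "+",
                       stringsAsFactors = FALSE)

  # deterministic role assignment: 5% oncogene, 5% TSG, 1% both, rest none
  g <- cfg$n_genes
  role <- rep("none", g)
  role[seq_len(max(1, round(0.05 * g)))] <- "oncogene"
  role[seq(round(0.05 * g) + 1, length.out = max(1, round(0.05 * g)))] <- "tumor_suppressor"
  role[seq(round(0.10 * g) + 1, length.out = max(1, round(0.01 * g)))] <- "both"
  gene_roles <- data.frame(gene_id = truth$gene_id,
                           role = role[seq_len(g)],
                           is_rbp = as.integer(truth$gene_id %in% truth$rbp_ids),
                           stringsAsFactors = FALSE)

  structure(list(inclusion = counts$inclusion, exclusion = counts$exclusion,
                 expression = expr, clinical = clinical,
                 events = events, gene_roles = gene_roles,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d events x %d samples, %d genes\n",
              nrow(x$inclusion), ncol(x$inclusion), nrow(x$expression)))
  cat(sprintf("  clusters: %s | shifted events: %d | coupled RBPs: %d\n",
              paste(table(x$truth$cluster), collapse = "+"),
              length(x$truth$shifted_events), length(x$truth$coupled_rbps)))
  invisible(x)
}
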