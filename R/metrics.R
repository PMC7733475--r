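.check_partition_pair <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions must label the same samples")
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions must label the same samples")
    p2 <- p2[names(p1)]
  }
  list(p1 = as.integer(factor(p1)), p2 = as.integer(factor(p2)))
}

.cluster_ss <- function(X, part) {
  # X: features x samples; returns within-cluster and total sums of squares
  labs <- sort(unique(part))
  ssw <- 0
  for (l in labs) {
    Xi <- X[, part == l, drop = FALSE]
    ssw <- ssw + sum((Xi - rowMeans(Xi))^2)
  }
  sst <- sum((X - rowMeans(X))^2)
  list(ssw = ssw, sst = sst, labs = labs,
       sizes = as.integer(table(factor(part, levels = labs))))
}

#' Root mean square standard deviation of a partition
#'
#' Pooled within-cluster standard deviation over all feature dimensions:
#' the square root of the total within-cluster sum of squares divided by the
#' pooled degrees of freedom \eqn{\sum_c \sum_{dims} (n_c - 1)}. Lower values
#' indicate more compact clusters.
#'
#' @param X numeric matrix, features x samples.
#' @param partition integer labels per sample (columns of `X`).
#' @return non-negative scalar.
#' @export
rmsstd <- function(X, partition) {
  stopifnot(is.matrix(X), length(partition) == ncol(X))
  ss <- .cluster_ss(X, partition)
  df <- nrow(X) * sum(ss$sizes - 1L)
  if (df == 0) stop("all clusters are singletons: zero degrees of freedom")
  sqrt(ss$ssw / df)
}

#' R-squared of a partition
#'
#' Fraction of total variance explained by the cluster structure:
#' `(SS_total - SS_within) / SS_total`, both about the grand mean. 0 for a
#' single cluster, 1 when every cluster is internally constant.
#'
#' @inheritParams rmsstd
#' @return scalar in \[0, 1\].
#' @export
r_squared <- function(X, partition) {
  stopifnot(is.matrix(X), length(partition) == ncol(X))
  ss <- .cluster_ss(X, partition)
  if (ss$sst == 0) stop("all samples identical: SS_total is zero")
  (ss$sst - ss$ssw) / ss$sst
}

#' SD validity index
#'
#' `SD(k) = alpha * Scat(k) + Dis(k)` where `Scat` is the average ratio of
#' within-cluster to overall variance-vector norms (compactness; smaller is
#' tighter) and `Dis` penalizes centroid configurations with uneven or small
#' separations:
#' `Dis = (D_max / D_min) * sum_c (sum_c' ||m_c - m_c'||)^-1` with
#' `D_max`/`D_min` the largest/smallest inter-centroid distances. `alpha` is
#' a weighting the caller supplies; the usual convention is `Dis` evaluated
#' at the largest number of clusters examined. Lower SD means better
#' clustering.
#'
#' @inheritParams rmsstd
#' @param alpha weight on the scatter term.
#' @return non-negative scalar.
#' @export
sd_validity <- function(X, partition, alpha) {
  stopifnot(is.matrix(X), length(partition) == ncol(X))
  labs <- sort(unique(partition))
  k <- length(labs)
  if (k < 2) stop("need at least two clusters")
  var_all <- apply(X, 1, .pop_var)
  centroids <- sapply(labs, function(l) rowMeans(X[, partition == l, drop = FALSE]))
  scat <- mean(vapply(labs, function(l) {
    v <- apply(X[, partition == l, drop = FALSE], 1, .pop_var)
    sqrt(sum(v^2)) / sqrt(sum(var_all^2))
  }, numeric(1)))

  dmat <- as.matrix(stats::dist(t(centroids)))
  offdiag <- dmat[upper.tri(dmat)]
  if (min(offdiag) == 0) stop("coincident centroids: D_min is zero")
  dis <- (max(offdiag) / min(offdiag)) *
    sum(1 / rowSums(dmat))
  alpha * scat + dis
}

.pop_var <- function(x) mean((x - mean(x))^2)

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same samples: `(Index - E[Index]) / (Max - E[Index])` from the contingency
#' table. 1 for identical partitions (up to relabeling), about 0 for
#' independent ones.
#'
#' @param p1,p2 label vectors over the same samples (matched by name when
#'   both are named).
#' @return scalar (at most 1).
#' @export
adjusted_rand_index <- function(p1, p2) {
  pp <- .check_partition_pair(p1, p2)
  tab <- table(pp$p1, pp$p2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Adjusted mutual information
#'
#' Mutual information between two partitions corrected for chance under the
#' fixed-margins (hypergeometric) permutation model:
#' `(MI - E[MI]) / (mean(H1, H2) - E[MI])`, natural-log entropies, arithmetic-
#' mean normalizer. When either partition has a single cluster (zero entropy)
#' the index is 0 by convention.
#'
#' @inheritParams adjusted_rand_index
#' @return scalar (at most 1 up to floating point).
#' @export
adjusted_mutual_information <- function(p1, p2) {
  pp <- .check_partition_pair(p1, p2)
  tab <- table(pp$p1, pp$p2)
  n <- sum(tab)
  a <- unname(rowSums(tab)); b <- unname(colSums(tab))
  h1 <- .entropy(a / n); h2 <- .entropy(b / n)
  if (h1 == 0 || h2 == 0) {
    message("partition with a single cluster: AMI set to 0 by convention")
    return(0)
  }
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(nij * n / (a[i] * b[j]))
  }
  emi <- .expected_mi(a, b, n)
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# E[MI] under the hypergeometric fixed-margins model (exact summation)
.expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1L, ai + bj - n)
    hi <- min(ai, bj)
    if (lo > hi) next
    nij <- lo:hi
    logp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
    emi <- emi + sum(exp(logp) * (nij / n) * log(nij * n / (ai * bj)))
  }
  emi
}

#' Asymmetry profile of the top clustering events
#'
#' For a two-cluster partition, computes each top event's
#' `ΔPSI_mean = mean PSI(cluster 1) - mean PSI(cluster 2)` and the fraction
#' of non-zero deltas that are positive. The profile is called asymmetric
#' when strictly more than 70% of the top events have their higher mean PSI
#' in the same cluster — the signature distinguishing intron-retention
#' subtypes from the balanced patterns of other splicing types.
#'
#' @param psi PSI matrix (events x samples), `NA` allowed and ignored
#'   per-group.
#' @param partition two-cluster labels over the columns of `psi`.
#' @param top_events character vector of event ids (rows of `psi`).
#' @param threshold asymmetry cutoff on the majority fraction (strict `>`,
#'   default 0.7).
#' @return list of class `asymmetry_profile`: `deltas` (named),
#'   `fraction_positive`, `asymmetric`, `direction` (1, 2, or NA when not
#'   asymmetric).
#' @export
asymmetry_profile <- function(psi, partition, top_events, threshold = 0.7) {
  stopifnot(is.matrix(psi), length(partition) == ncol(psi))
  labs <- sort(unique(partition))
  if (length(labs) != 2) stop("asymmetry profile requires exactly two clusters")
  if (length(top_events) == 0) stop("top_events is empty")
  if (!all(top_events %in% rownames(psi)))
    stop("top_events contains ids absent from psi")
  sub <- psi[top_events, , drop = FALSE]
  m1 <- rowMeans(sub[, partition == labs[1], drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(sub[, partition == labs[2], drop = FALSE], na.rm = TRUE)
  deltas <- m1 - m2
  nz <- deltas[deltas != 0]
  frac_pos <- if (length(nz) == 0) 0.5 else mean(nz > 0)
  asym <- max(frac_pos, 1 - frac_pos) > threshold
  direction <- if (!asym) NA_integer_
    else if (frac_pos > threshold) labs[1] else labs[2]
  structure(list(deltas = deltas, fraction_positive = frac_pos,
                 asymmetric = asym, direction = direction),
            class = "asymmetry_profile")
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat(sprintf(
    "asymmetry_profile: %d events, fraction positive = %.3f, %s\n",
    length(x$deltas), x$fraction_positive,
    if (x$asymmetric) sprintf("asymmetric toward cluster %d", x$direction)
    else "not asymmetric"))
  invisible(x)
}

#' Cluster validation report
#'
#' Convenience wrapper computing [rmsstd()], [r_squared()] and
#' [sd_validity()] for one partition.
#'
#' @inheritParams rmsstd
#' @param alpha weight for the SD index scatter term.
#' @return data.frame with columns `rmsstd`, `rs`, `sd_index`.
#' @export
validation_report <- function(X, partition, alpha = 1) {
  data.frame(rmsstd = rmsstd(X, partition),
             rs = r_squared(X, partition),
             sd_index = sd_validity(X, partition, alpha))
}
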