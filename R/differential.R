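#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The p-value is exact (null
#' enumeration) when the smaller group has at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections is used. When every value in both groups is identical the
#' test is uninformative and p = 1 is returned.
#'
#' @param a,b numeric vectors (non-empty; `NA` removed).
#' @return list with `U` (statistic for `a`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(c(a, b))) == 1) return(list(U = U, p = 1))
  ties <- any(duplicated(c(a, b)))
  exact <- min(na, nb) <= 8 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(U = U, p = min(p, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; the returned q-values map
#' one-to-one onto the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return numeric vector of the same length.
#' @export
benjamini_hochberg <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Difference in mean PSI between two clusters
#'
#' `ΔPSI_mean` for one event: mean over non-missing cluster-1 values minus
#' mean over non-missing cluster-2 values.
#'
#' @param event event id (row of `psi`).
#' @param psi PSI matrix with `NA` as the missing marker.
#' @param partition two-cluster labels over the columns of `psi`.
#' @return scalar in \[-1, 1\].
#' @export
delta_psi_mean <- function(event, psi, partition) {
  stopifnot(is.matrix(psi), length(partition) == ncol(psi))
  labs <- sort(unique(partition))
  if (length(labs) != 2) stop("requires exactly two clusters")
  if (!event %in% rownames(psi)) stop("event not present in psi")
  x <- psi[event, ]
  v1 <- x[partition == labs[1]]; v2 <- x[partition == labs[2]]
  if (all(is.na(v1)) || all(is.na(v2)))
    stop("a cluster has no quantified values for this event")
  mean(v1, na.rm = TRUE) - mean(v2, na.rm = TRUE)
}

#' Differential intron-retention filter cascade
#'
#' Applies the four-rule selection to every event of a PSI matrix with
#' missing values:
#' \enumerate{
#'   \item per-event two-tailed Mann-Whitney U test between clusters
#'     (missing values dropped per group), Benjamini-Hochberg adjustment
#'     across all tested events, keep `q < alpha`;
#'   \item remove events whose overall missing fraction is `>= na_total`
#'     (inclusive, default 10%);
#'   \item remove events whose absolute difference in per-cluster missing
#'     fractions is `>= na_balance` (inclusive, default 5%);
#'   \item keep events with `|ΔPSI_mean| > min_delta` (strict, default 0.1).
#' }
#' Every tested event is returned with all four pass flags so single-rule
#' effects can be inspected; `selected` is the conjunction.
#'
#' @param psi PSI matrix (events x samples) with `NA` for missing.
#' @param partition two-cluster labels; each cluster must have >= 2 samples.
#' @param alpha adjusted-p significance level.
#' @param na_total inclusive upper bound on the overall missing fraction.
#' @param na_balance inclusive upper bound on the between-cluster missing-
#'   fraction difference.
#' @param min_delta strict lower bound on `|ΔPSI_mean|`.
#' @return data.frame of class `diff_ir` with one row per event: `event_id`,
#'   `p`, `q`, `delta_psi_mean`, `na_frac_total`, `na_frac_c1`, `na_frac_c2`,
#'   the four `pass_*` flags and `selected`. Events untestable in a cluster
#'   (all missing or empty) carry `NA` statistics and all-FALSE flags.
#' @export
differential_cascade <- function(psi, partition, alpha = 0.05,
                                 na_total = 0.10, na_balance = 0.05,
                                 min_delta = 0.1) {
  stopifnot(is.matrix(psi), length(partition) == ncol(psi))
  labs <- sort(unique(partition))
  if (length(labs) != 2) stop("requires exactly two clusters")
  i1 <- partition == labs[1]; i2 <- partition == labs[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("each cluster must have >= 2 samples")

  n <- ncol(psi)
  ids <- rownames(psi)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(psi)))

  res <- lapply(seq_len(nrow(psi)), function(e) {
    x <- psi[e, ]
    v1 <- x[i1][!is.na(x[i1])]; v2 <- x[i2][!is.na(x[i2])]
    na1 <- mean(is.na(x[i1])); na2 <- mean(is.na(x[i2]))
    na_tot <- mean(is.na(x))
    if (length(v1) == 0 || length(v2) == 0) {
      return(c(p = NA_real_, delta = NA_real_,
               na_tot = na_tot, na1 = na1, na2 = na2))
    }
    c(p = mann_whitney_u(v1, v2)$p,
      delta = mean(v1) - mean(v2),
      na_tot = na_tot, na1 = na1, na2 = na2)
  })
  res <- do.call(rbind, res)

  q <- benjamini_hochberg(res[, "p"])
  out <- data.frame(event_id = ids,
                    p = res[, "p"], q = q,
                    delta_psi_mean = res[, "delta"],
                    na_frac_total = res[, "na_tot"],
                    na_frac_c1 = res[, "na1"],
                    na_frac_c2 = res[, "na2"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pass_significance <- !is.na(out$q) & out$q < alpha
  out$pass_na_total <- out$na_frac_total < na_total
  out$pass_na_balance <- abs(out$na_frac_c1 - out$na_frac_c2) < na_balance
  out$pass_effect_size <- !is.na(out$delta_psi_mean) &
    abs(out$delta_psi_mean) > min_delta
  untestable <- is.na(out$p)
  out$pass_na_total[untestable] <- FALSE
  out$pass_na_balance[untestable] <- FALSE
  out$selected <- out$pass_significance & out$pass_na_total &
    out$pass_na_balance & out$pass_effect_size
  class(out) <- c("diff_ir", "data.frame")
  out
}
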