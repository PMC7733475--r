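#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities, conditional on
#' the margins, of all tables no more probable than the observed one. The
#' reported odds ratio is the sample cross-product ratio `ad/bc` (`Inf` when
#' `bc = 0` with `ad > 0`; `NaN` when both products are 0). A degenerate
#' margin (an empty row or column) gives p = 1 with an undefined odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NaN, p = 1))
  }
  or <- (a * d) / (b * c)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p)
}

#' Monte-Carlo Fisher test for r x c tables
#'
#' Freeman-Halton generalization estimated by sampling margin-preserving
#' tables (Patefield's algorithm): the p-value is the plus-one-corrected
#' fraction of sampled tables whose conditional probability does not exceed
#' the observed table's. Used for multi-level clinical contrasts (grade,
#' stage) where exact network algorithms are unnecessary.
#'
#' @param tab r x c matrix of non-negative integers.
#' @param n_perm number of sampled tables (warning below 1000).
#' @param seed integer seed for reproducibility.
#' @return the Monte-Carlo p-value.
#' @export
fisher_rxc_montecarlo <- function(tab, n_perm = 100000L, seed = 20201211L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (n_perm < 1000) warning("n_perm < 1000: Monte-Carlo error will be large")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  stats::fisher.test(tab, simulate.p.value = TRUE, B = n_perm)$p.value
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= overlap) for the overlap of two sets drawn from a common universe,
#' X ~ Hypergeometric(universe, set_a, set_b).
#'
#' @param set_a,set_b set sizes.
#' @param overlap observed intersection size.
#' @param universe universe size (must be stated explicitly; the choice of
#'   universe can move the p-value by orders of magnitude).
#' @return upper-tail p-value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, overlap, universe) {
  stopifnot(set_a >= 0, set_b >= 0, overlap >= 0, universe >= 1)
  if (overlap > min(set_a, set_b) || max(set_a, set_b) > universe)
    stop("inconsistent counts: need overlap <= min(set sizes) <= universe")
  stats::phyper(overlap - 1, set_a, universe - set_a, set_b,
                lower.tail = FALSE)
}

#' Classify an intron's location within a gene model
#'
#' Labels an intron interval by the single region type (CDS, UTR5, UTR3)
#' whose intervals fully contain it; overlap with more than one type, or
#' partial overlap that extends beyond the type's intervals, is `mixed`;
#' no overlap at all is `intergenic`. All coordinates 0-based half-open.
#'
#' @param event a list/row with `contig`, `start`, `end`.
#' @param gene_regions data.frame with columns `contig`, `start`, `end`,
#'   `region_type` (values in CDS/UTR5/UTR3).
#' @return one of `"CDS"`, `"UTR5"`, `"UTR3"`, `"mixed"`, `"intergenic"`.
#' @export
classify_intron_location <- function(event, gene_regions) {
  stopifnot(all(c("contig", "start", "end") %in% names(event)),
            all(c("contig", "start", "end", "region_type") %in%
                  names(gene_regions)))
  s <- as.numeric(event$start); e <- as.numeric(event$end)
  if (is.na(s) || is.na(e) || s >= e) stop("malformed event interval")
  gr <- gene_regions[gene_regions$contig == event$contig, , drop = FALSE]
  if (any(gr$start >= gr$end)) stop("malformed region interval(s)")
  ov <- gr[gr$start < e & gr$end > s, , drop = FALSE]
  if (nrow(ov) == 0) return("intergenic")
  types <- unique(ov$region_type)
  if (length(types) > 1) return("mixed")
  # contained in the union of this type's intervals? (merge then test)
  iv <- ov[order(ov$start), c("start", "end"), drop = FALSE]
  merged <- list()
  cur <- as.numeric(iv[1, ])
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= cur[2]) cur[2] <- max(cur[2], iv$end[i])
    else { merged[[length(merged) + 1]] <- cur; cur <- as.numeric(iv[i, ]) }
  }
  merged[[length(merged) + 1]] <- cur
  contained <- any(vapply(merged, function(m) m[1] <= s && m[2] >= e,
                          logical(1)))
  if (contained) types else "mixed"
}

#' Merge oncogene/tumor-suppressor role lists
#'
#' Combines two curated cancer-gene lists. A gene present in one list keeps
#' its role; a gene called oncogene by one list and tumor suppressor by the
#' other becomes `"both"`, as does any gene already labeled `"both"`.
#'
#' @param list_a,list_b named character vectors, gene id to role in
#'   `{"oncogene", "tumor_suppressor", "both"}`.
#' @return named character vector of merged roles.
#' @export
merge_cancer_gene_roles <- function(list_a, list_b) {
  valid <- c("oncogene", "tumor_suppressor", "both")
  stopifnot(all(list_a %in% valid), all(list_b %in% valid))
  genes <- union(names(list_a), names(list_b))
  vapply(genes, function(g) {
    ra <- list_a[g]; rb <- list_b[g]
    roles <- unique(stats::na.omit(c(ra, rb)))
    if ("both" %in% roles || length(roles) > 1) "both" else roles
  }, character(1))
}

#' Category enrichment of a selected event set
#'
#' Tests whether a category (e.g. oncogene-associated, CDS-located) is over-
#' represented among selected events relative to a disjoint control set,
#' via the 2x2 Fisher test. Reports the in-category fraction of each set
#' alongside the test.
#'
#' @param selected_events,control_events disjoint character vectors of event
#'   ids.
#' @param annotation named character vector mapping event id to a category
#'   label.
#' @param category label(s) counting as in-category.
#' @return list: `odds_ratio`, `p`, `frac_selected`, `frac_control`, `table`.
#' @export
category_enrichment <- function(selected_events, control_events, annotation,
                                category) {
  if (length(intersect(selected_events, control_events)) > 0)
    stop("selected and control sets must be disjoint")
  in_cat <- function(ids) sum(annotation[ids] %in% category, na.rm = TRUE)
  a <- in_cat(selected_events); b <- length(selected_events) - a
  c <- in_cat(control_events);  d <- length(control_events) - c
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(c("selected", "control"),
                                c("in_category", "not")))
  ft <- fisher_exact_2x2(tab)
  list(odds_ratio = ft$odds_ratio, p = ft$p,
       frac_selected = if (length(selected_events)) a / length(selected_events) else NA,
       frac_control = if (length(control_events)) c / length(control_events) else NA,
       table = tab)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over genes with positive
#' counts in every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts non-negative genes x samples count matrix.
#' @return positive numeric vector of size factors, one per sample.
#' @export
median_ratio_normalize <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(col) exp(stats::median(col - loggeo)))
}

#' Two-group differential expression (normalized log scale)
#'
#' A transparent stand-in for a negative-binomial Wald model: counts are
#' divided by median-of-ratios size factors, transformed as
#' `y = log2(count/sf + 1)`, and each gene is compared between the two
#' clusters by Welch's t test. `log2fc` is `mean(y | cluster 1) -
#' mean(y | cluster 2)`; q-values are Benjamini-Hochberg across genes. Genes
#' with zero variance in both groups get p = 1.
#'
#' @param counts genes x samples raw count matrix.
#' @param partition two-cluster labels over samples.
#' @param size_factors optional precomputed size factors.
#' @return data.frame: `gene_id`, `log2fc`, `p`, `q`.
#' @export
differential_expression <- function(counts, partition, size_factors = NULL) {
  stopifnot(is.matrix(counts), length(partition) == ncol(counts))
  labs <- sort(unique(partition))
  if (length(labs) != 2) stop("requires exactly two clusters")
  i1 <- partition == labs[1]; i2 <- partition == labs[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("each cluster needs >= 2 samples")
  if (is.null(size_factors)) size_factors <- median_ratio_normalize(counts)
  y <- log2(sweep(counts, 2, size_factors, "/") + 1)
  w <- welch_test_rows(y[, i1, drop = FALSE], y[, i2, drop = FALSE])
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  data.frame(gene_id = ids, log2fc = w$diff, p = w$p,
             q = benjamini_hochberg(w$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Row-wise Welch two-sample t test
#'
#' Vectorized Welch test over matrix rows; rows with zero variance in both
#' groups (hence zero standard error) return p = 1 when the means agree and
#' p = 0 when they differ.
#'
#' @param A,B numeric matrices with matching rows (features x samples).
#' @return list: `diff` (mean A - mean B), `t`, `df`, `p`.
#' @export
welch_test_rows <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, stats::var); v2 <- apply(B, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  tstat[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign(m1 - m2)[zero])
  list(diff = m1 - m2, t = tstat, df = df, p = p)
}

#' RBP-splicing correlation discovery
#'
#' Computes Pearson correlations between every RNA-binding-protein gene's
#' normalized expression and every splice event's PSI across samples
#' (pairwise-complete when PSI is missing), with t-distribution p-values and
#' Benjamini-Hochberg adjustment over all tested pairs. Reported pairs
#' satisfy `r >= r_min` (inclusive) and `q < alpha`. Pairs with fewer than
#' 3 complete observations are skipped.
#'
#' @param expr_norm normalized expression matrix (genes x samples),
#'   typically `log2(count/sf + 1)`.
#' @param psi PSI matrix (events x samples), same sample order.
#' @param rbp_ids rows of `expr_norm` to test.
#' @param event_ids rows of `psi` to test.
#' @param r_min inclusive lower bound on r for reporting.
#' @param alpha upper bound on the adjusted p for reporting.
#' @return list: `pairs` (data.frame `rbp`, `event`, `r`, `p`, `q` of the
#'   reported pairs), `per_rbp_counts` (named vector, reported pairs per
#'   RBP), `n_tested`.
#' @export
correlate_rbp_events <- function(expr_norm, psi, rbp_ids, event_ids,
                                 r_min = 0.7, alpha = 0.05) {
  stopifnot(ncol(expr_norm) == ncol(psi))
  rbp_ids <- intersect(rbp_ids, rownames(expr_norm))
  event_ids <- intersect(event_ids, rownames(psi))
  if (length(rbp_ids) == 0 || length(event_ids) == 0)
    stop("no RBPs or no events to test")
  E <- t(expr_norm[rbp_ids, , drop = FALSE])
  P <- t(psi[event_ids, , drop = FALSE])
  r <- suppressWarnings(stats::cor(E, P, use = "pairwise.complete.obs"))
  nn <- crossprod(!is.na(E), !is.na(P))
  keep <- nn >= 3 & !is.na(r)
  tt <- r * sqrt(pmax(nn - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- suppressWarnings(2 * stats::pt(-abs(tt), nn - 2))
  p[!keep] <- NA
  q <- matrix(benjamini_hochberg(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  rep_idx <- which(keep & r >= r_min & q < alpha, arr.ind = TRUE)
  pairs <- data.frame(rbp = rbp_ids[rep_idx[, 1]],
                      event = event_ids[rep_idx[, 2]],
                      r = r[rep_idx], p = p[rep_idx], q = q[rep_idx],
                      stringsAsFactors = FALSE, row.names = NULL)
  pairs <- pairs[order(-pairs$r), , drop = FALSE]
  counts <- table(factor(pairs$rbp, levels = rbp_ids))
  list(pairs = pairs,
       per_rbp_counts = sort(stats::setNames(as.integer(counts),
                                             names(counts)),
                             decreasing = TRUE),
       n_tested = sum(keep))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a large-sample t approximation for
#' the p-value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
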