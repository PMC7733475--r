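#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius reconstruction error
#' \eqn{\|X - WH\|_F^2} with Lee-Seung multiplicative updates. Entries of
#' `W` and `H` are initialized Uniform(0, mean(X)); denominators carry an
#' epsilon guard so the iterates stay strictly positive. Iteration stops when
#' the relative objective decrease falls below `tol` or after `max_iter`
#' steps.
#'
#' @param X non-negative numeric matrix (features x samples), no `NA`.
#' @param k factorization rank, `1 <= k < min(dim(X))`.
#' @param seed integer seed controlling the random initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-decrease stopping threshold.
#' @param eps denominator guard.
#' @return list of class `nmf_fit`: `W` (features x k), `H` (k x samples),
#'   `objective_trace` (squared Frobenius error after every sweep), `seed`,
#'   `iterations`, `converged`.
#' @export
nmf_factorize <- function(X, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          eps = 1e-9) {
  stopifnot(is.matrix(X))
  if (anyNA(X)) stop("X contains missing values")
  if (any(X < 0)) stop("X contains negative entries")
  if (k < 1 || k >= min(dim(X))) stop("k must satisfy 1 <= k < min(dim(X))")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m <- nrow(X); n <- ncol(X)
  W <- matrix(stats::runif(m * k, 0, mean(X)), m, k)
  H <- matrix(stats::runif(k * n, 0, mean(X)), k, n)

  obj <- function() sum((X - W %*% H)^2)
  trace <- numeric(0)
  prev <- obj()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- obj()
    trace <- c(trace, cur)
    if (prev > 0 && (prev - cur) / prev < tol) { converged <- TRUE; break }
    prev <- cur
  }
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  structure(list(W = W, H = H, objective_trace = trace, seed = seed,
                 iterations = it, converged = converged),
            class = "nmf_fit")
}

#' Hard sample assignment from an NMF coefficient matrix
#'
#' Each sample goes to the basis component with the largest coefficient in
#' its column of `H`; ties break to the lowest row index.
#'
#' @param H non-negative k x samples matrix.
#' @return integer vector of labels in 1..k, named by the columns of `H`.
#' @export
assign_partition <- function(H) {
  stopifnot(is.matrix(H))
  if (any(H < 0)) stop("H contains negative entries")
  if (any(colSums(H) == 0)) stop("all-zero column(s) in H")
  p <- max.col(t(H), ties.method = "first")
  names(p) <- colnames(H)
  p
}

#' NMF consensus clustering
#'
#' Runs `n_runs` factorizations from distinct seeded initializations, builds
#' the consensus matrix as the mean of the per-run connectivity matrices
#' (samples co-assigned by [assign_partition()]), extracts the final partition
#' by average-linkage hierarchical clustering of `1 - consensus` cut into `k`
#' groups, and summarizes stability by the cophenetic correlation between the
#' consensus-derived distances and the dendrogram's cophenetic distances.
#'
#' Cluster labels are renamed so that cluster 1 has the lowest grand-mean
#' value of `X` over its samples (for PSI input, cluster 1 is the
#' intron-removal-efficient cluster), making labels comparable across seeds.
#' Per-cluster top events come from the best-objective run's basis matrix via
#' [extract_top_events()] (for `k >= 2`).
#'
#' @param X non-negative matrix (events x samples).
#' @param k number of clusters.
#' @param n_runs number of factorizations (>= 2).
#' @param seed master seed; per-run child seeds derive from it.
#' @param ... passed to [nmf_factorize()].
#' @return list of class `consensus_fit`: `k`, `consensus`, `cophenetic`,
#'   `partition`, `top_events`, `runs`, `best_fit`, `degenerate`.
#' @export
consensus_cluster <- function(X, k, n_runs = 50L, seed = 1L, ...) {
  if (n_runs < 2) stop("n_runs must be >= 2 (cophenetic undefined otherwise)")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, n_runs)

  n <- ncol(X)
  # indistinguishable samples carry no cluster structure at all
  if (all(apply(X, 1, stats::sd) == 0)) {
    consensus <- matrix(1, n, n, dimnames = list(colnames(X), colnames(X)))
    part <- stats::setNames(rep(1L, n), colnames(X))
    return(structure(list(k = k, consensus = consensus,
                          cophenetic = NA_real_, partition = part,
                          top_events = NULL, runs = n_runs, best_fit = NULL,
                          degenerate = TRUE),
                     class = "consensus_fit"))
  }
  consensus <- matrix(0, n, n)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(X, k, seed = child[r], ...)
    p <- assign_partition(fit$H)
    consensus <- consensus + outer(p, p, "==")
    final_obj <- fit$objective_trace[length(fit$objective_trace)]
    if (is.null(best) || final_obj < best$objective) {
      best <- list(fit = fit, objective = final_obj)
    }
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(X), colnames(X))

  d <- stats::as.dist(1 - consensus)
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    # all runs agree on a single grouping of everything: no structure to cut
    degenerate <- TRUE
    part <- rep(1L, n)
    names(part) <- colnames(X)
    coph <- NA_real_
  } else {
    hc <- stats::hclust(d, method = "average")
    part <- stats::cutree(hc, k = k)
    coph <- stats::cor(as.vector(d), as.vector(stats::cophenetic(hc)))
    if (length(unique(part)) < k) degenerate <- TRUE
    part <- .relabel_by_grand_mean(X, part)
  }

  top <- if (k >= 2) {
    te <- extract_top_events(best$fit$W)
    # top-event component q refers to the best run's H; map components to
    # final labels via the majority final label among samples argmax'd to q
    bp <- assign_partition(best$fit$H)
    comp_to_label <- vapply(seq_len(k), function(q) {
      s <- which(bp == q)
      if (length(s) == 0) return(NA_integer_)
      as.integer(names(which.max(table(part[s]))))
    }, integer(1))
    out <- stats::setNames(vector("list", k), paste0("cluster", seq_len(k)))
    for (q in seq_len(k)) {
      lab <- comp_to_label[q]
      if (!is.na(lab))
        out[[lab]] <- sort(unique(c(out[[lab]], te[[q]])))
    }
    out
  } else NULL

  structure(list(k = k, consensus = consensus, cophenetic = coph,
                 partition = part, top_events = top, runs = n_runs,
                 best_fit = best$fit, degenerate = degenerate),
            class = "consensus_fit")
}

# relabel clusters in increasing order of grand-mean X over member samples
.relabel_by_grand_mean <- function(X, part) {
  labs <- sort(unique(part))
  gm <- vapply(labs, function(l) mean(X[, part == l, drop = FALSE]), numeric(1))
  map <- stats::setNames(order(order(gm)), labs)
  out <- map[as.character(part)]
  names(out) <- names(part)
  out
}

#' Select the NMF rank by cophenetic correlation
#'
#' Runs [consensus_cluster()] for each candidate rank and returns the rank
#' with the highest cophenetic correlation coefficient; ties (within 1e-12)
#' go to the smallest rank. The per-rank table is attached as attribute
#' `"rank_table"`.
#'
#' @param X non-negative matrix.
#' @param ks candidate ranks (default 2:5).
#' @param n_runs factorizations per rank.
#' @param seed master seed (one child seed per rank).
#' @param ... passed to [consensus_cluster()].
#' @return the selected rank (integer) with attribute `rank_table`.
#' @export
select_rank <- function(X, ks = 2:5, n_runs = 50L, seed = 1L, ...) {
  if (length(ks) == 0) stop("ks must be non-empty")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, length(ks))
  coph <- vapply(seq_along(ks), function(i) {
    consensus_cluster(X, ks[i], n_runs = n_runs, seed = child[i], ...)$cophenetic
  }, numeric(1))
  tab <- data.frame(k = ks, cophenetic = coph)
  score <- ifelse(is.na(coph), -Inf, coph)
  best <- max(score)
  sel <- min(ks[score >= best - 1e-12])
  attr(sel, "rank_table") <- tab
  sel
}

#' Top contributing features per NMF basis component
#'
#' Kim-Park basis-specificity score: with
#' \eqn{p(i,q) = W_{iq} / \sum_{q'} W_{iq'}},
#' \eqn{s(i) = 1 + \frac{1}{\log_2 k} \sum_q p(i,q) \log_2 p(i,q)}.
#' A feature scores 1 when it loads on a single component and 0 when spread
#' evenly. Features are kept when `s > median(s) + 3 * mad(s)` and their
#' largest basis entry is at least the median of all entries of `W`; each
#' kept feature is assigned to its argmax component.
#'
#' @param W non-negative basis matrix (features x k), k >= 2; all-zero rows
#'   are excluded before scoring.
#' @return list of length k of feature names (or row indices if unnamed),
#'   one vector per component; scores attached as attribute `"scores"`.
#' @export
extract_top_events <- function(W) {
  stopifnot(is.matrix(W))
  if (any(W < 0)) stop("W contains negative entries")
  k <- ncol(W)
  if (k < 2) stop("feature score undefined for k = 1")
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  keep_rows <- rowSums(W) > 0
  Wk <- W[keep_rows, , drop = FALSE]
  ids <- ids[keep_rows]

  p <- Wk / rowSums(Wk)
  plog <- p * log2(p)
  plog[p == 0] <- 0
  s <- 1 + rowSums(plog) / log2(k)

  thr <- stats::median(s) + 3 * stats::mad(s)
  keep <- s > thr & apply(Wk, 1, max) >= stats::median(W)
  comp <- max.col(Wk, ties.method = "first")
  out <- lapply(seq_len(k), function(q) ids[keep & comp == q])
  attr(out, "scores") <- stats::setNames(s, ids)
  out
}

#' Comparator clustering (k-means and hierarchical)
#'
#' Reference partitions against which the NMF consensus partition is scored:
#' Lloyd k-means with k-means++ initialization (best of `restarts` seeded
#' restarts) or average-linkage agglomerative clustering on Euclidean
#' distances, both treating samples (columns of `X`) as points in event
#' space.
#'
#' @param X complete numeric matrix (events x samples).
#' @param k number of clusters (`k <= ncol(X)`).
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed seed for the k-means restarts (ignored for hierarchical).
#' @param restarts number of k-means++ restarts.
#' @return integer label vector named by sample.
#' @export
comparator_cluster <- function(X, k, method = c("kmeans", "hierarchical"),
                               seed = 1L, restarts = 20L) {
  method <- match.arg(method)
  stopifnot(is.matrix(X))
  if (anyNA(X)) stop("X contains missing values")
  if (k > ncol(X)) stop("k exceeds the number of samples")
  pts <- t(X)
  if (k == 1) {
    p <- rep(1L, ncol(X)); names(p) <- colnames(X); return(p)
  }
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::dist(pts), method = "average")
    p <- stats::cutree(hc, k = k)
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- .kmeanspp_centers(pts, k)
      km <- suppressWarnings(
        stats::kmeans(pts, centers = centers, algorithm = "Lloyd",
                      iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    p <- best$cluster
  }
  names(p) <- colnames(X)
  p
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
.kmeanspp_centers <- function(pts, k) {
  n <- nrow(pts)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(pts, 1, function(x)
      min(colSums((t(pts[idx, , drop = FALSE]) - x)^2)))
    d2[idx] <- 0
    if (sum(d2) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1L))
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2))
    }
  }
  pts[idx, , drop = FALSE] + matrix(stats::runif(k * ncol(pts), 0, 1e-10),
                                    k, ncol(pts))
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf("consensus_fit: k = %d, %d runs, cophenetic = %s%s\n",
              x$k, x$runs, format(x$cophenetic, digits = 4),
              if (x$degenerate) " [degenerate]" else ""))
  print(table(cluster = x$partition))
  invisible(x)
}
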