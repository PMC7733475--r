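#' Percent-spliced-in from inclusion/exclusion counts
#'
#' PSI = inclusion / (inclusion + exclusion). Events with fewer than
#' `min_reads` total spliced reads in a sample cannot be quantified reliably
#' and are set to `NA` (the missing marker used throughout the package).
#'
#' @param inclusion,exclusion non-negative integer matrices of identical
#'   shape (events x samples).
#' @param min_reads minimum total spliced reads per event and sample
#'   (default 10); totals strictly below it yield `NA`.
#' @return numeric matrix of PSI values in \[0, 1\] with `NA` where coverage
#'   is insufficient; dimnames taken from `inclusion`.
#' @export
compute_psi <- function(inclusion, exclusion, min_reads = 10L) {
  if (!is.matrix(inclusion) || !is.matrix(exclusion) ||
      !all(dim(inclusion) == dim(exclusion)))
    stop("inclusion and exclusion must be matrices of identical shape")
  if (any(inclusion < 0, na.rm = TRUE) || any(exclusion < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  total <- inclusion + exclusion
  psi <- inclusion / total
  psi[total < min_reads] <- NA_real_
  psi[total == 0] <- NA_real_
  dimnames(psi) <- dimnames(inclusion)
  psi
}

#' Drop events with any missing PSI value
#'
#' Events quantified in every sample are the only ones eligible for variable-
#' event selection and NMF clustering; this removes all rows containing `NA`,
#' preserving row order.
#'
#' @param psi PSI matrix with `NA` as the missing marker.
#' @return the complete-row submatrix.
#' @export
drop_incomplete_events <- function(psi) {
  stopifnot(is.matrix(psi))
  psi[stats::complete.cases(psi), , drop = FALSE]
}

#' Select the most variable events
#'
#' Keeps events whose PSI standard deviation across samples is strictly
#' greater than `sd_cutoff`. The intron-retention default cutoff is 0.1;
#' other splicing types use lower cutoffs (see [pipeline_config()]).
#'
#' @param psi complete PSI matrix (no `NA`; run [drop_incomplete_events()]
#'   first).
#' @param sd_cutoff strict lower bound on the per-event standard deviation.
#' @param type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return submatrix of events passing the cutoff, original order; the number
#'   retained is attached as attribute `"n_selected"`.
#' @export
select_variable_events <- function(psi, sd_cutoff = 0.1,
                                   type = c("sample", "population")) {
  type <- match.arg(type)
  stopifnot(is.matrix(psi))
  if (anyNA(psi))
    stop("psi contains missing values; apply drop_incomplete_events() first")
  sds <- apply(psi, 1, stats::sd)
  if (type == "population") sds <- sds * sqrt((ncol(psi) - 1) / ncol(psi))
  out <- psi[sds > sd_cutoff, , drop = FALSE]
  attr(out, "n_selected") <- nrow(out)
  out
}

#' Row-wise z-score transform
#'
#' Standardizes each event (row) to mean 0 and standard deviation 1, the
#' transform used for heatmap display of the clustering events. Not used as
#' NMF input (NMF requires non-negative values).
#'
#' @param psi complete PSI matrix.
#' @param type `"sample"` (n-1 denominator, default) or `"population"` s.d.
#' @return matrix of the same shape with standardized rows.
#' @export
zscore_transform <- function(psi, type = c("sample", "population")) {
  type <- match.arg(type)
  stopifnot(is.matrix(psi))
  if (anyNA(psi)) stop("psi contains missing values")
  sds <- apply(psi, 1, stats::sd)
  if (type == "population") sds <- sds * sqrt((ncol(psi) - 1) / ncol(psi))
  if (any(sds == 0)) stop("zero-variance row(s): ",
                          paste(utils::head(which(sds == 0)), collapse = ", "))
  (psi - rowMeans(psi)) / sds
}
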