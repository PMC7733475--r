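#' Pipeline configuration
#'
#' Collects every threshold and setting of the analysis pipeline with the
#' defaults used for intron-retention subtyping: per-splice-type standard-
#' deviation cutoffs (IR 0.1, ES 0.08, MES 0.07, A5 0.06, A3 0.06), NMF
#' settings, the four cascade thresholds (adjusted p 0.05, total-NA 10%,
#' NA-balance 5%, |ΔPSI_mean| 0.1), correlation thresholds (r 0.7, adjusted
#' p 0.05), survival endpoint, and the inclusive tumor-purity floor 0.33.
#'
#' @param input_dir directory holding the TSV inputs (see [read_inputs()]);
#'   may be `NULL` when the pipeline is run on an in-memory cohort.
#' @param as_type splicing type analyzed (selects the s.d. cutoff).
#' @param sd_cutoff named vector of per-type cutoffs.
#' @param min_reads minimum spliced reads for PSI quantification.
#' @param k number of clusters; ignored when `ks` is given.
#' @param ks optional candidate rank range for cophenetic rank selection.
#' @param n_runs NMF consensus runs.
#' @param seed master seed for every stochastic stage.
#' @param alpha,na_total,na_balance,min_delta cascade thresholds.
#' @param r_min,cor_alpha correlation reporting thresholds.
#' @param endpoint survival endpoint: `"pfi"`, `"os"` or `"dss"`.
#' @param purity_min inclusive minimum tumor purity.
#' @param cutpoint_screen run the per-event/per-RBP survival-cutpoint screen.
#' @param max_cutpoint_markers cap on markers entering the screen.
#' @param outdir optional output directory for [write_outputs()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            as_type = c("IR", "ES", "MES", "A5", "A3"),
                            sd_cutoff = c(IR = 0.1, ES = 0.08, MES = 0.07,
                                          A5 = 0.06, A3 = 0.06),
                            min_reads = 10L,
                            k = 2L, ks = NULL, n_runs = 50L, seed = 1L,
                            alpha = 0.05, na_total = 0.10,
                            na_balance = 0.05, min_delta = 0.1,
                            r_min = 0.7, cor_alpha = 0.05,
                            endpoint = c("pfi", "os", "dss"),
                            purity_min = 0.33,
                            cutpoint_screen = TRUE,
                            max_cutpoint_markers = 200L,
                            outdir = NULL) {
  as_type <- match.arg(as_type)
  endpoint <- match.arg(endpoint)
  stopifnot(alpha > 0, alpha <= 1, na_total >= 0, na_total <= 1,
            na_balance >= 0, na_balance <= 1,
            min_delta >= 0, min_delta <= 1,
            r_min >= -1, r_min <= 1, cor_alpha > 0, cor_alpha <= 1,
            purity_min >= 0, purity_min <= 1,
            n_runs >= 2, min_reads >= 1)
  if (!as_type %in% names(sd_cutoff))
    stop("no sd_cutoff entry for as_type ", as_type)
  structure(list(input_dir = input_dir, as_type = as_type,
                 sd_cutoff = sd_cutoff, min_reads = as.integer(min_reads),
                 k = as.integer(k), ks = ks, n_runs = as.integer(n_runs),
                 seed = as.integer(seed),
                 alpha = alpha, na_total = na_total,
                 na_balance = na_balance, min_delta = min_delta,
                 r_min = r_min, cor_alpha = cor_alpha,
                 endpoint = endpoint, purity_min = purity_min,
                 cutpoint_screen = cutpoint_screen,
                 max_cutpoint_markers = as.integer(max_cutpoint_markers),
                 outdir = outdir),
            class = "pipeline_config")
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.matrix_from_table <- function(df, id_col) {
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

.table_from_matrix <- function(m, id_col) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  df
}

#' Read a PSI table with validation
#'
#' Reads a `psi.tsv`-style table (event_id plus one column per sample, "NA"
#' for missing) and rejects values outside \[0, 1\] with the offending
#' location.
#'
#' @param path file path.
#' @return numeric PSI matrix with `NA` for missing.
#' @export
read_psi_table <- function(path) {
  df <- .read_tsv(path)
  m <- .matrix_from_table(df, names(df)[1])
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed PSI value %g at %s (event %s, sample %s)",
                 m[bad[1, 1], bad[1, 2]], path,
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  m
}

#' Read and cross-validate the pipeline input tables
#'
#' Loads inclusion/exclusion counts, event annotation, expression counts,
#' clinical data and gene roles from `cfg$input_dir`, checks the schemas,
#' intersects the sample sets across tables (dropping and reporting samples
#' missing from any table), and applies the inclusive tumor-purity filter
#' (`purity >= purity_min`).
#'
#' @param cfg a [pipeline_config()] with `input_dir` set.
#' @return list with `inclusion`, `exclusion`, `expression`, `clinical`,
#'   `events`, `gene_roles`, and `log` (character vector of drop reports).
#' @export
read_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$input_dir)) stop("cfg$input_dir is not set")
  d <- cfg$input_dir
  log <- character(0)

  incl_df <- .read_tsv(file.path(d, "inclusion.tsv"))
  excl_df <- .read_tsv(file.path(d, "exclusion.tsv"))
  events <- .read_tsv(file.path(d, "events.tsv"))
  expr_df <- .read_tsv(file.path(d, "expression_counts.tsv"))
  clinical <- .read_tsv(file.path(d, "clinical.tsv"))
  gene_roles <- .read_tsv(file.path(d, "gene_roles.tsv"))

  need <- c("event_id", "as_type", "gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(events)))
    stop("events.tsv: missing column(s) ",
         paste(setdiff(need, names(events)), collapse = ", "))
  need_cl <- c("sample_id", "purity")
  if (!all(need_cl %in% names(clinical)))
    stop("clinical.tsv: missing column(s) ",
         paste(setdiff(need_cl, names(clinical)), collapse = ", "))
  if (!all(c("gene_id", "role", "is_rbp") %in% names(gene_roles)))
    stop("gene_roles.tsv: missing required columns")

  incl <- .matrix_from_table(incl_df, "event_id")
  excl <- .matrix_from_table(excl_df, "event_id")
  expr <- .matrix_from_table(expr_df, "gene_id")
  storage.mode(incl) <- "integer"
  storage.mode(excl) <- "integer"
  storage.mode(expr) <- "integer"
  if (!identical(dim(incl), dim(excl)) ||
      !identical(dimnames(incl), dimnames(excl)))
    stop("inclusion.tsv and exclusion.tsv disagree in shape or labels")

  samples <- Reduce(intersect, list(colnames(incl), colnames(expr),
                                    clinical$sample_id))
  if (length(samples) == 0) stop("sample-set intersection is empty")
  all_samples <- unique(c(colnames(incl), colnames(expr), clinical$sample_id))
  dropped <- setdiff(all_samples, samples)
  if (length(dropped) > 0)
    log <- c(log, sprintf("dropped %d sample(s) absent from some table: %s",
                          length(dropped), paste(dropped, collapse = ", ")))

  clinical <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  keep <- !is.na(clinical$purity) & clinical$purity >= cfg$purity_min
  if (any(!keep))
    log <- c(log, sprintf("purity filter (>= %g) removed %d sample(s)",
                          cfg$purity_min, sum(!keep)))
  samples <- samples[keep]
  clinical <- clinical[keep, , drop = FALSE]

  list(inclusion = incl[, samples, drop = FALSE],
       exclusion = excl[, samples, drop = FALSE],
       expression = expr[, samples, drop = FALSE],
       clinical = clinical, events = events, gene_roles = gene_roles,
       log = log)
}

#' Write a synthetic cohort to the pipeline's TSV formats
#'
#' Emits `inclusion.tsv`, `exclusion.tsv`, `events.tsv`,
#' `expression_counts.tsv`, `clinical.tsv`, `gene_roles.tsv` and `truth.tsv`
#' (plain UTF-8, header row, "NA" for missing) so a generated cohort can be
#' consumed by [read_inputs()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(.table_from_matrix(cohort$inclusion, "event_id"),
             file.path(dir, "inclusion.tsv"))
  .write_tsv(.table_from_matrix(cohort$exclusion, "event_id"),
             file.path(dir, "exclusion.tsv"))
  .write_tsv(cohort$events, file.path(dir, "events.tsv"))
  .write_tsv(.table_from_matrix(cohort$expression, "gene_id"),
             file.path(dir, "expression_counts.tsv"))
  .write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  .write_tsv(cohort$gene_roles, file.path(dir, "gene_roles.tsv"))
  truth <- data.frame(sample_id = cohort$truth$sample_id,
                      cluster = cohort$truth$cluster,
                      stringsAsFactors = FALSE)
  .write_tsv(truth, file.path(dir, "truth.tsv"))
  shifted <- data.frame(event_id = cohort$truth$shifted_events,
                        stringsAsFactors = FALSE)
  .write_tsv(shifted, file.path(dir, "shifted_events.tsv"))
  invisible(dir)
}

#' Write the report bundle
#'
#' Serializes every table of a [run_pipeline()] bundle to TSV (deterministic
#' column order, 6 significant digits, "NA" for missing) plus a plain-text
#' run log of seeds and thresholds.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param outdir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_outputs <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(data.frame(sample_id = names(bundle$partition),
                        cluster = as.integer(bundle$partition),
                        stringsAsFactors = FALSE),
             file.path(outdir, "partition.tsv"))
  .write_tsv(bundle$validation, file.path(outdir, "validation.tsv"))
  .write_tsv(data.frame(event_id = names(bundle$asymmetry$deltas),
                        delta_psi_mean = bundle$asymmetry$deltas,
                        stringsAsFactors = FALSE, row.names = NULL),
             file.path(outdir, "asymmetry_deltas.tsv"))
  .write_tsv(as.data.frame(bundle$diff_ir), file.path(outdir, "diff_ir.tsv"))
  .write_tsv(bundle$enrichment, file.path(outdir, "enrichment.tsv"))
  .write_tsv(bundle$de, file.path(outdir, "de.tsv"))
  .write_tsv(bundle$correlation$pairs,
             file.path(outdir, "correlation_pairs.tsv"))
  .write_tsv(bundle$survival_summary, file.path(outdir, "survival.tsv"))
  if (!is.null(bundle$cutpoint_screen))
    .write_tsv(bundle$cutpoint_screen,
               file.path(outdir, "cutpoint_screen.tsv"))
  writeLines(bundle$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
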