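#' Run the intron-retention subtyping pipeline end to end
#'
#' Executes the full workflow on one cohort: PSI quantification with the
#' minimum-coverage missingness rule, removal of incompletely quantified
#' events, variable-event selection, NMF consensus clustering (with
#' comparator k-means/hierarchical partitions and their agreement scores),
#' cluster validation, the asymmetry profile of the top clustering events,
#' the four-rule differential cascade, cancer-gene-category enrichment,
#' the differential-expression stand-in, RBP-splicing correlation discovery,
#' and survival comparisons (log-rank, multivariate Cox, optional maximally
#' selected cutpoint screen with Benjamini-Hochberg adjustment). Every
#' stochastic stage derives its seed from `cfg$seed`, so identical inputs
#' and config reproduce the bundle exactly.
#'
#' @param cfg a [pipeline_config()].
#' @param cohort optional in-memory input (a [simulate_cohort()] object or a
#'   [read_inputs()] list); when `NULL`, inputs are read from
#'   `cfg$input_dir`.
#' @return list of class `report_bundle`; see Details for elements.
#' @details Elements: `partition` (named integer labels), `consensus`
#'   (the `consensus_fit`), `comparators` (partitions plus AMI/ARI vs NMF),
#'   `validation`, `asymmetry`, `top_events`, `diff_ir`, `enrichment`, `de`,
#'   `correlation`, `survival_summary`, `cox` (the fitted `cox_fit`),
#'   `cutpoint_screen` (or `NULL`), `psi`, `log`.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cohort)) cohort <- read_inputs(cfg)
  log <- c(sprintf("seed=%d as_type=%s sd_cutoff=%g k=%s n_runs=%d",
                   cfg$seed, cfg$as_type, cfg$sd_cutoff[[cfg$as_type]],
                   if (is.null(cfg$ks)) cfg$k else
                     paste(range(cfg$ks), collapse = "-"), cfg$n_runs),
           sprintf("cascade: alpha=%g na_total=%g na_balance=%g min_delta=%g",
                   cfg$alpha, cfg$na_total, cfg$na_balance, cfg$min_delta),
           sprintf("correlation: r_min=%g alpha=%g; endpoint=%s; purity_min=%g",
                   cfg$r_min, cfg$cor_alpha, cfg$endpoint, cfg$purity_min),
           if (!is.null(cohort$log)) cohort$log)

  # --- PSI quantification and event selection -----------------------------
  psi <- compute_psi(cohort$inclusion, cohort$exclusion,
                     min_reads = cfg$min_reads)
  complete <- drop_incomplete_events(psi)
  log <- c(log, sprintf("events: %d total, %d completely quantified",
                        nrow(psi), nrow(complete)))
  var_psi <- select_variable_events(complete,
                                    sd_cutoff = cfg$sd_cutoff[[cfg$as_type]])
  log <- c(log, sprintf("variable events (s.d. > %g): %d",
                        cfg$sd_cutoff[[cfg$as_type]], nrow(var_psi)))
  if (nrow(var_psi) < 3)
    stop("stage select_variable_events: too few variable events (",
         nrow(var_psi), ")")

  # --- clustering ---------------------------------------------------------
  k <- cfg$k
  if (!is.null(cfg$ks)) {
    k <- as.integer(select_rank(var_psi, ks = cfg$ks, n_runs = cfg$n_runs,
                                seed = cfg$seed))
    log <- c(log, sprintf("rank selected by cophenetic correlation: %d", k))
  }
  cc <- consensus_cluster(var_psi, k, n_runs = cfg$n_runs, seed = cfg$seed)
  if (cc$degenerate || length(unique(cc$partition)) < 2)
    stop("stage consensus_cluster: degenerate clustering (single cluster); ",
         "downstream two-group analyses are undefined")
  part <- cc$partition
  log <- c(log, sprintf("consensus: k=%d cophenetic=%.4f sizes=%s",
                        k, cc$cophenetic,
                        paste(table(part), collapse = "+")))

  km_part <- comparator_cluster(var_psi, k, "kmeans", seed = cfg$seed)
  hc_part <- comparator_cluster(var_psi, k, "hierarchical")
  comparators <- list(
    kmeans = km_part, hierarchical = hc_part,
    ami_kmeans = adjusted_mutual_information(part, km_part),
    ami_hierarchical = adjusted_mutual_information(part, hc_part),
    ari_kmeans = adjusted_rand_index(part, km_part),
    ari_hierarchical = adjusted_rand_index(part, hc_part))

  validation <- validation_report(var_psi, part, alpha = 1)

  # --- asymmetry of the top clustering events -----------------------------
  top <- unique(unlist(cc$top_events))
  if (length(top) < 5) {
    log <- c(log, sprintf(
      "top-event extraction yielded %d events; falling back to all %d clustering events",
      length(top), nrow(var_psi)))
    top <- rownames(var_psi)
  }
  asym <- if (k == 2) asymmetry_profile(var_psi, part, top) else NULL
  if (!is.null(asym))
    log <- c(log, sprintf("asymmetry: fraction_positive=%.3f asymmetric=%s",
                          asym$fraction_positive, asym$asymmetric))

  # --- differential cascade and enrichment --------------------------------
  diff_ir <- if (k == 2) {
    differential_cascade(psi, part, alpha = cfg$alpha,
                         na_total = cfg$na_total,
                         na_balance = cfg$na_balance,
                         min_delta = cfg$min_delta)
  } else NULL
  enrichment <- NULL
  if (!is.null(diff_ir)) {
    sel <- diff_ir$event_id[diff_ir$selected]
    ctrl <- setdiff(diff_ir$event_id[!is.na(diff_ir$p)], sel)
    log <- c(log, sprintf("cascade: %d of %d events selected",
                          length(sel), sum(!is.na(diff_ir$p))))
    if (length(sel) > 0 && length(ctrl) > 0) {
      ev2gene <- stats::setNames(cohort$events$gene_id,
                                 cohort$events$event_id)
      role <- stats::setNames(cohort$gene_roles$role,
                              cohort$gene_roles$gene_id)
      annot <- role[ev2gene[diff_ir$event_id]]
      names(annot) <- diff_ir$event_id
      enrichment <- do.call(rbind, lapply(
        c("oncogene", "tumor_suppressor", "both"), function(cat) {
          ce <- category_enrichment(sel, ctrl, annot, cat)
          data.frame(category = cat, odds_ratio = ce$odds_ratio, p = ce$p,
                     frac_selected = ce$frac_selected,
                     frac_control = ce$frac_control,
                     stringsAsFactors = FALSE)
        }))
    }
  }

  # --- expression: DE stand-in and RBP correlations -----------------------
  size_factors <- median_ratio_normalize(cohort$expression)
  de <- differential_expression(cohort$expression, part,
                                size_factors = size_factors)
  expr_norm <- log2(sweep(cohort$expression, 2, size_factors, "/") + 1)
  rbp_ids <- cohort$gene_roles$gene_id[cohort$gene_roles$is_rbp == 1]
  cor_events <- if (!is.null(diff_ir) && sum(diff_ir$selected) >= 3)
    diff_ir$event_id[diff_ir$selected] else top
  correlation <- correlate_rbp_events(expr_norm, psi, rbp_ids, cor_events,
                                      r_min = cfg$r_min,
                                      alpha = cfg$cor_alpha)
  log <- c(log, sprintf("correlation: %d reported pairs over %d tested",
                        nrow(correlation$pairs), correlation$n_tested))

  # --- survival -----------------------------------------------------------
  cl <- cohort$clinical
  stopifnot(identical(cl$sample_id, names(part)) ||
              setequal(cl$sample_id, names(part)))
  cl <- cl[match(names(part), cl$sample_id), , drop = FALSE]
  surv_rows <- list(); cox <- NULL; screen <- NULL
  for (ep in c("pfi", "os", "dss")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(cl))) next
    g1 <- part == 1; g2 <- part == 2
    lr <- tryCatch(
      logrank_test(cl[[tcol]][g1], cl[[ecol]][g1],
                   cl[[tcol]][g2], cl[[ecol]][g2]),
      error = function(e) NULL)
    if (!is.null(lr))
      surv_rows[[ep]] <- data.frame(endpoint = ep, chi2 = lr$chi2, p = lr$p,
                                    stringsAsFactors = FALSE)
  }
  tcol <- paste0(cfg$endpoint, "_time"); ecol <- paste0(cfg$endpoint, "_event")
  if (all(c(tcol, ecol) %in% names(cl)) && k == 2) {
    covs <- data.frame(cluster2 = as.integer(part == 2))
    if ("age" %in% names(cl)) covs$age <- cl$age
    if ("sex" %in% names(cl)) covs$sex <- as.integer(cl$sex == "M")
    if ("pancreatitis" %in% names(cl)) covs$pancreatitis <- cl$pancreatitis
    cox <- tryCatch(cox_ph_fit(cl[[tcol]], cl[[ecol]], covs),
                    error = function(e) { log <<- c(log, paste("cox:", conditionMessage(e))); NULL })
    if (!is.null(cox))
      log <- c(log, sprintf("cox (%s): HR[cluster2]=%.3f p=%.4g",
                            cfg$endpoint, cox$hr[["cluster2"]],
                            cox$p[["cluster2"]]))
    if (cfg$cutpoint_screen) {
      markers <- cor_events
      if (length(markers) > cfg$max_cutpoint_markers)
        markers <- markers[seq_len(cfg$max_cutpoint_markers)]
      rows <- lapply(markers, function(ev) {
        x <- psi[ev, ]
        ok <- !is.na(x)
        if (sum(ok) < 10 || length(unique(x[ok])) < 2) return(NULL)
        cp <- tryCatch(optimal_cutpoint(x[ok], cl[[tcol]][ok], cl[[ecol]][ok]),
                       error = function(e) NULL)
        if (is.null(cp)) return(NULL)
        data.frame(marker = ev, cutpoint = cp$cutpoint,
                   statistic = cp$statistic, p = cp$p_logrank,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      if (!is.null(rows) && nrow(rows) > 0) {
        rows$q <- benjamini_hochberg(rows$p)
        screen <- rows
      }
    }
  }
  survival_summary <- if (length(surv_rows)) do.call(rbind, surv_rows)
    else data.frame(endpoint = character(0), chi2 = numeric(0),
                    p = numeric(0))
  rownames(survival_summary) <- NULL

  structure(list(partition = part, consensus = cc, comparators = comparators,
                 validation = validation, asymmetry = asym,
                 top_events = top, diff_ir = diff_ir,
                 enrichment = if (is.null(enrichment))
                   data.frame(category = character(0)) else enrichment,
                 de = de, correlation = correlation,
                 survival_summary = survival_summary, cox = cox,
                 cutpoint_screen = screen,
                 psi = psi, var_psi = var_psi, log = log),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(sprintf("  partition: k=%d (%s), cophenetic=%.4f\n",
              x$consensus$k, paste(table(x$partition), collapse = "+"),
              x$consensus$cophenetic))
  if (!is.null(x$asymmetry))
    cat(sprintf("  asymmetry: fraction_positive=%.3f, asymmetric=%s\n",
                x$asymmetry$fraction_positive, x$asymmetry$asymmetric))
  if (!is.null(x$diff_ir))
    cat(sprintf("  differential cascade: %d selected of %d tested\n",
                sum(x$diff_ir$selected), sum(!is.na(x$diff_ir$p))))
  if (!is.null(x$cox))
    cat(sprintf("  Cox HR (cluster 2 vs 1): %.3f\n", x$cox$hr[["cluster2"]]))
  invisible(x)
}
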