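# End-to-end orchestration: simulate (or load) -> filter -> fit -> permute ->
# call -> enrich, with every stage's output and counts written to one run
# directory so a run is reproducible from its config alone.

#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Either a
#' `count_table` path (plus optional `annotation_table` /
#' `dependency_table`) or a [sim_config()] must be supplied.
#'
#' @param sim optional [sim_config()] for synthetic runs.
#' @param count_table,annotation_table,dependency_table optional input paths.
#' @param maf_min,min_het SNP inclusion filters, see [filter_loci()].
#' @param n_perms permutation iterations for the null.
#' @param alphas nominal significance levels.
#' @param q_cut q-value threshold for reporting.
#' @param assoc_strength planted annotation association (synthetic runs
#'   without an annotation table).
#' @param enrich whether to run the enrichment stage.
#' @param seed integer seed (mandatory) controlling every random stage.
#' @param priors an [ai_priors()] object.
#' @return Object of class `ai_run_config`.
#' @export
run_config <- function(sim = NULL, count_table = NULL, annotation_table = NULL,
                       dependency_table = NULL, maf_min = 0.005, min_het = 10L,
                       n_perms = 100L, alphas = c(0.05, 0.01, 0.001),
                       q_cut = 0.1, assoc_strength = 0, enrich = TRUE,
                       seed = NULL, priors = ai_priors()) {
  if (is.null(sim) && is.null(count_table))
    stop("provide either a sim_config or a count_table path")
  if (!is.null(sim) && !inherits(sim, "ai_sim_config"))
    stop("sim must come from sim_config()")
  if (is.null(seed)) stop("a seed is mandatory")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (n_perms < 1) stop("n_perms must be >= 1")
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  if (q_cut <= 0 || q_cut > 1) stop("q_cut must lie in (0, 1]")
  structure(list(sim = sim, count_table = count_table,
                 annotation_table = annotation_table,
                 dependency_table = dependency_table,
                 maf_min = maf_min, min_het = as.integer(min_het),
                 n_perms = as.integer(n_perms), alphas = alphas,
                 q_cut = q_cut, assoc_strength = assoc_strength,
                 enrich = isTRUE(enrich), seed = as.integer(seed),
                 priors = priors),
            class = "ai_run_config")
}

#' Run the full selection analysis
#'
#' Chains simulation/loading, heterozygote calling, SNP filtering, per-SNP
#' MAP fitting, the arm-swap permutation null, selection calls and the
#' enrichment statistics. Writes `fits.tsv`, `null.tsv`, `calls.tsv`,
#' `enrichment.tsv`, `freq_calls.tsv`, `filter_report.tsv` and `run_log.txt`
#' to `out_dir`. Rerunning with the same config and seed is byte-identical.
#' On a stage failure the partial outputs are kept and a `FAILED` marker
#' names the stage.
#'
#' @param config an [run_config()] object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohort`, `fit`,
#'   `null`, `calls`, `enrichment`, `freq_calls`, `filter_report`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ai_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) writeLines(sprintf(...), log_con)
  logf("aiselect %s", as.character(utils::packageVersion("aiselect")))
  logf("seed: %d  n_perms: %d  maf_min: %g  min_het: %d",
       config$seed, config$n_perms, config$maf_min, config$min_het)
  logf("priors: %s", paste(vapply(config$priors, function(p)
    sprintf("%s[%g,%g]", p$family, p$lower, p$upper), character(1)),
    collapse = " "))
  stage <- "input"
  fail <- function(e) {
    writeLines(paste0("stage: ", stage), file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    sim <- NULL
    annotations <- dependencies <- NULL
    if (!is.null(config$sim)) {
      stage <- "simulate"
      sim <- simulate_cohort(config$sim)
      cohort <- sim$cohort
      write_count_table(cohort, file.path(out_dir, "counts.tsv"))
      ann <- simulate_annotations(sim, assoc_strength = config$assoc_strength,
                                  seed = config$seed + 1L)
      annotations <- ann$annotations
      dependencies <- ann$dependencies
    } else {
      stage <- "load"
      cohort <- read_count_table(config$count_table)
      if (!is.null(config$annotation_table)) {
        annotations <- read_annotation_table(config$annotation_table)
        cohort <- annotate_cohort(cohort, annotations)
      }
      if (!is.null(config$dependency_table))
        dependencies <- read_dependency_table(config$dependency_table)
    }
    if (!is.null(annotations)) {
      write.table(annotations, file.path(out_dir, "annotations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(dependencies))
        write.table(dependencies, file.path(out_dir, "dependencies.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    logf("loci in: %d  samples: %d", nrow(cohort$loci), length(cohort$samples))

    stage <- "filter"
    fl <- filter_loci(cohort, maf_min = config$maf_min,
                      min_het = config$min_het)
    cohort <- fl$cohort
    write.table(fl$report, file.path(out_dir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logf("filter stages: %s",
         paste(fl$report$stage, fl$report$n_loci, sep = "=", collapse = " "))
    if (nrow(cohort$loci) == 0) stop("no loci survive the filters")

    stage <- "fit"
    fit <- ai_fit(cohort, priors = config$priors, min_het = 1L)
    write.table(format_fit_table(fit), file.path(out_dir, "fits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logf("fitted: %d  converged: %d  failed: %d", nrow(fit$table),
         sum(fit$table$converged), sum(!fit$table$converged))

    stage <- "permute"
    null <- build_null(cohort, fit = fit, n_perms = config$n_perms,
                       seed = config$seed + 2L, priors = config$priors)
    write_null_distribution(null, file.path(out_dir, "null.tsv"))
    logf("null pool: %d values, %d dropped", length(null$stats),
         null$n_dropped)

    stage <- "call"
    calls <- call_selection(fit, null, alphas = config$alphas,
                            q_cut = config$q_cut)
    write_calls_table(calls, file.path(out_dir, "calls.tsv"))
    logf("calls: %d  selected-for@%g: %d  selected-against@%g: %d",
         nrow(calls), max(config$alphas),
         sum(calls$direction == "selected-for" &
               calls$p_emp < max(config$alphas)),
         max(config$alphas),
         sum(calls$direction == "selected-against" &
               calls$p_emp < max(config$alphas)))

    enr <- freq_calls <- NULL
    if (config$enrich && !is.null(annotations)) {
      stage <- "enrich"
      enr <- stratified_fraction_comparison(calls, annotations,
                                            levels = config$alphas,
                                            seed = config$seed + 3L)
      write.table(enr$table, file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      freq_calls <- allele_frequency_calls(cohort, annotations)
      write.table(freq_calls, file.path(out_dir, "freq_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      logf("enrichment strata: %d", nrow(enr$table))
    }
    logf("status: OK")
    invisible(list(cohort = cohort, fit = fit, null = null, calls = calls,
                   enrichment = enr, freq_calls = freq_calls,
                   filter_report = fl$report, out_dir = out_dir))
  }, error = fail)
}

format_fit_table <- function(fit) {
  tab <- fit$table
  data.frame(snp_id = tab$snp_id,
             pi_hat = signif(tab$pi, 8), delta_hat = signif(tab$delta, 8),
             phi_hat = signif(tab$phi, 8), theta_hat = signif(tab$theta, 8),
             n_het = tab$n_het, log_posterior = signif(tab$log_posterior, 10),
             converged = tab$converged, stringsAsFactors = FALSE)
}
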