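#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation), evidence filtering, species
#' classification, cohort construction, the pairwise comparison battery,
#' and — for proteins whose abundance differs significantly between the
#' species-dominated group and a dysbiotic group — the multivariable
#' regression. Exactly one of `sim` or the three input tables must be
#' supplied. Any stage error aborts with the stage name.
#'
#' @param sim A [sim_config()]; when given, inputs are simulated.
#' @param samples,proteins,matrix In-memory tables (or file paths for
#'   `samples`/`proteins` TSVs and a matrix TSV) when not simulating.
#' @param classifier A [classifier_config()].
#' @param sb_threshold Fixed S/B threshold for abundance strata.
#' @param regression_alpha Significance level for CIs and for selecting
#'   proteins into the regression stage.
#' @param out_dir Optional directory; when given, all result tables, the
#'   summary JSON and a provenance manifest are written there (contents
#'   are deterministic for a fixed configuration).
#' @return A list of class `"lacto_report"` with `samples`, `proteins`,
#'   `filter` (included/excluded), `decisions`, `cohorts`, `battery`
#'   (per species, possibly NULL), `regressions`, and `summary`.
#' @export
run_pipeline <- function(sim = NULL, samples = NULL, proteins = NULL,
                         matrix = NULL,
                         classifier = classifier_config(),
                         sb_threshold = 70,
                         regression_alpha = 0.05,
                         out_dir = NULL) {
  if (!is.null(sim) && (!is.null(samples) || !is.null(proteins) ||
                        !is.null(matrix))) {
    stage_stop("ingest", "supply either a simulation config or input ",
               "tables, not both")
  }
  if (is.null(sim) && (is.null(samples) || is.null(proteins) ||
                       is.null(matrix))) {
    stage_stop("ingest", "need samples, proteins and matrix when not ",
               "simulating")
  }
  # -- ingest ---------------------------------------------------------------
  res <- tryCatch({
    if (!is.null(sim)) {
      ds <- simulate_dataset(sim)
      list(samples = ds$samples, proteins = ds$proteins,
           matrix = ds$matrix, truth = ds$truth)
    } else {
      if (is.character(samples)) samples <- read_sample_table(samples)
      if (is.character(proteins)) proteins <- read_protein_table(proteins)
      if (is.character(matrix)) matrix <- read_abundance_matrix(matrix)
      samples <- validate_samples(as.data.frame(samples))
      proteins <- validate_proteins(as.data.frame(proteins))
      validate_matrix(matrix)
      list(samples = samples, proteins = proteins, matrix = matrix,
           truth = NULL)
    }
  }, error = function(e) stage_stop("ingest", conditionMessage(e)))
  samples <- res$samples
  proteins <- res$proteins
  matrix <- res$matrix

  missing_acc <- setdiff(proteins$accession, rownames(matrix))
  if (length(missing_acc)) {
    stage_stop("ingest", "protein(s) missing from matrix: ",
               paste(missing_acc, collapse = ", "))
  }

  # -- evidence filter ------------------------------------------------------
  filt <- tryCatch(suppressWarnings(filter_proteins(proteins)),
                   error = function(e) stage_stop("filter",
                                                  conditionMessage(e)))

  # -- classification -------------------------------------------------------
  decisions <- tryCatch(
    classify_all(filt$included, matrix, samples, classifier),
    error = function(e) stage_stop("classify", conditionMessage(e))
  )

  # -- cohorts --------------------------------------------------------------
  cohorts <- tryCatch(
    lapply(stats::setNames(SPECIES, SPECIES), analysis_cohort,
           samples = samples),
    error = function(e) stage_stop("cohorts", conditionMessage(e))
  )

  # -- comparison battery ---------------------------------------------------
  battery <- lapply(stats::setNames(SPECIES, SPECIES), function(sp) {
    if (!any(decisions$assigned == sp) || cohorts[[sp]]$n_total == 0) {
      return(NULL)
    }
    tryCatch(
      suppressWarnings(
        run_group_battery(decisions, matrix, samples, sp,
                          sb_threshold = sb_threshold)
      ),
      error = function(e) stage_stop("analyze", conditionMessage(e))
    )
  })

  # -- regression for dysbiosis-associated L. iners proteins ----------------
  regressions <- list()
  bat_i <- battery$L_iners
  if (!is.null(bat_i)) {
    home <- SPECIES_HOME_GROUP[["L_iners"]]
    sig <- bat_i[bat_i$factor == "vmb_group" & bat_i$stratum == "all" &
                   (bat_i$level_a == home | bat_i$level_b == home) &
                   (bat_i$level_a %in% DYSBIOSIS_GROUPS |
                      bat_i$level_b %in% DYSBIOSIS_GROUPS) &
                   bat_i$p_value < regression_alpha, , drop = FALSE]
    for (acc in unique(sig$accession)) {
      regressions[[acc]] <- tryCatch(
        suppressWarnings(
          fit_regression(acc, matrix, samples,
                         regression_spec(alpha = regression_alpha))
        ),
        error = function(e) list(accession = acc,
                                 error = conditionMessage(e))
      )
    }
  }

  report <- structure(
    list(samples = samples, proteins = proteins, truth = res$truth,
         filter = filt, decisions = decisions, cohorts = cohorts,
         battery = battery, regressions = regressions,
         config = list(classifier = classifier,
                       sb_threshold = sb_threshold,
                       regression_alpha = regression_alpha,
                       simulated = !is.null(sim),
                       seed = if (!is.null(sim)) sim$seed else NA)),
    class = "lacto_report"
  )
  report$summary <- render_summary(report, format = "json")

  if (!is.null(out_dir)) {
    write_report_bundle(report, out_dir)
  }
  report
}

#' Render a pipeline summary
#'
#' Machine-readable (`"json"`: a named list, serializable with
#' `jsonlite`) or human-readable (`"text"`) rendering of the same
#' counts, so the two never drift: protein counts at each stage,
#' per-group cohort sizes, classification tallies, per-comparison
#' p-values with significance stars (* p < 0.05, ** p < 0.01,
#' *** p < 0.001), and regression coefficients with CIs.
#'
#' @param report A `"lacto_report"` from [run_pipeline()].
#' @param format `"json"` or `"text"`.
#' @return A named list (`"json"`) or a character vector of lines
#'   (`"text"`).
#' @export
render_summary <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  cls <- attr(report$decisions, "summary")
  comparisons <- lapply(report$battery, function(b) {
    if (is.null(b)) return(NULL)
    b$stars <- significance_stars(b$p_value)
    b
  })
  reg <- lapply(report$regressions, function(r) {
    if (!is.null(r$error)) return(list(accession = r$accession,
                                       error = r$error))
    list(accession = r$accession, n = r$n, shapiro_p = r$shapiro_p,
         coefficients = r$coefficients)
  })
  js <- list(
    n_samples = nrow(report$samples),
    n_proteins_in = nrow(report$proteins),
    n_proteins_included = nrow(report$filter$included),
    n_proteins_excluded = nrow(report$filter$excluded),
    exclusion_reasons = as.list(table(report$filter$excluded$reason)),
    classification = cls,
    cohorts = lapply(report$cohorts, function(co) {
      list(n_per_group = as.list(co$n_per_group), n_total = co$n_total)
    }),
    comparisons = comparisons,
    regressions = reg
  )
  if (format == "json") {
    return(js)
  }
  lines <- c(
    "== lactospec pipeline summary ==",
    sprintf("samples: %d", js$n_samples),
    sprintf("proteins: %d in, %d included, %d excluded",
            js$n_proteins_in, js$n_proteins_included,
            js$n_proteins_excluded),
    sprintf("candidates: %d L. iners, %d L. crispatus",
            cls$candidates_iners, cls$candidates_crispatus),
    sprintf("assigned: %d L. iners, %d L. crispatus, %d nonspecific",
            cls$assigned_iners, cls$assigned_crispatus, cls$nonspecific),
    sprintf("analysis cohorts: L. iners n = %d (%s); L. crispatus n = %d",
            js$cohorts$L_iners$n_total,
            paste(sprintf("%s:%d", names(js$cohorts$L_iners$n_per_group),
                          unlist(js$cohorts$L_iners$n_per_group)),
                  collapse = ", "),
            js$cohorts$L_crispatus$n_total)
  )
  for (sp in names(comparisons)) {
    b <- comparisons[[sp]]
    if (is.null(b)) next
    lines <- c(lines, sprintf("-- %s comparisons --", sp))
    lines <- c(lines, sprintf(
      "%s [%s/%s] %s vs %s: p = %.4g %s",
      b$accession, b$factor, b$stratum, b$level_a, b$level_b,
      b$p_value, b$stars))
  }
  for (r in reg) {
    if (!is.null(r$error)) {
      lines <- c(lines, sprintf("regression %s: ERROR %s", r$accession,
                                r$error))
      next
    }
    lines <- c(lines, sprintf("-- regression %s (n = %d, Shapiro p = %.3g) --",
                              r$accession, r$n, r$shapiro_p))
    co <- r$coefficients
    lines <- c(lines, sprintf("%s: beta = %.4g (%.4g, %.4g)",
                              co$term, co$beta, co$ci_low, co$ci_high))
  }
  lines
}

# write all result tables + summary to a directory; file contents depend
# only on the report (no timestamps), so fixed-seed runs are byte-identical
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sample_table(report$samples, file.path(out_dir, "samples.tsv"))
  write_protein_table(report$proteins, file.path(out_dir, "proteins.tsv"))
  write_protein_table(report$filter$included,
                      file.path(out_dir, "included.tsv"))
  utils::write.table(as.data.frame(report$filter$excluded),
                     file.path(out_dir, "excluded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$decisions),
                     file.path(out_dir, "decisions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$truth)) {
    utils::write.table(report$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (sp in names(report$battery)) {
    b <- report$battery[[sp]]
    if (is.null(b)) next
    b$stars <- significance_stars(b$p_value)
    utils::write.table(b, file.path(out_dir,
                                    paste0("comparisons_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(report$regressions)) {
    reg_rows <- do.call(rbind, lapply(report$regressions, function(r) {
      if (!is.null(r$error)) return(NULL)
      cbind(data.frame(accession = r$accession, n = r$n,
                       shapiro_p = r$shapiro_p, stringsAsFactors = FALSE),
            r$coefficients)
    }))
    if (!is.null(reg_rows)) {
      utils::write.table(reg_rows, file.path(out_dir, "regressions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package = "lactospec",
    version = as.character(utils::packageVersion("lactospec")),
    simulated = report$config$simulated,
    seed = report$config$seed,
    classifier = unclass(report$config$classifier),
    sb_threshold = report$config$sb_threshold,
    regression_alpha = report$config$regression_alpha,
    zero_handling = "half-minimum-positive pseudo-value before log10"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
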