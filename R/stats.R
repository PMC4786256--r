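#' Pairwise two-sided Mann-Whitney tests across levels
#'
#' One two-sided Mann-Whitney U (Wilcoxon rank-sum) test per unordered
#' pair of non-empty levels. The exact null distribution is used when the
#' combined sample size of a pair is at most 25 and the pooled values
#' carry no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used — so p-values are reproducible
#' bit-for-bit for a given input. Levels with no observations are skipped
#' with a warning. When all pooled values of a pair are identical there
#' is no evidence of a shift and p = 1. Raw p-values are reported by
#' default (mirroring the reporting convention of pairwise figure
#' panels); Holm adjustment across the returned pairs is available.
#'
#' @param values Named list mapping level -> numeric vector.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame with one row per pair: `level_a`, `level_b`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, `u_statistic`, `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
pairwise_mannwhitney <- function(values, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(values), !is.null(names(values)))
  empty <- vapply(values, length, integer(1)) == 0
  if (any(empty)) {
    warning("skipping empty level(s): ",
            paste(names(values)[empty], collapse = ", "), call. = FALSE)
    values <- values[!empty]
  }
  lev <- names(values)
  if (length(lev) < 2) {
    stop("need at least 2 non-empty levels", call. = FALSE)
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- values[[pr[1]]]
    y <- values[[pr[2]]]
    pooled <- c(x, y)
    use_exact <- (length(pooled) <= 25) && !anyDuplicated(pooled)
    if (length(unique(pooled)) == 1) {
      u <- length(x) * length(y) / 2
      p <- 1
      method <- "degenerate"
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
      )
      u <- unname(wt$statistic)
      p <- min(wt$p.value, 1)
      method <- if (use_exact) "exact" else "normal_approx"
    }
    data.frame(level_a = pr[1], level_b = pr[2],
               n_a = length(x), n_b = length(y),
               median_a = stats::median(x), median_b = stats::median(y),
               u_statistic = u, p_value = p, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality test p-value
#'
#' Thin wrapper used as the residual-normality diagnostic of the
#' regression models. Requires 3 <= n <= 5000; a constant vector is a
#' degenerate input and raises an error.
#'
#' @param residuals Numeric vector.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (length(unique(residuals)) == 1) {
    stop("Shapiro-Wilk undefined for a constant vector", call. = FALSE)
  }
  stats::shapiro.test(residuals)$p.value
}

#' Regression specification
#'
#' Design of the multivariable linear model for one protein:
#' log10 intensity regressed on microbiota-group dummies (reference:
#' the *L. iners*-dominated group), pH-category dummies (reference
#' "4-5"), and log10 taxon S/B abundance.
#'
#' @param species Taxon whose analysis cohort and S/B abundance enter the
#'   model (default `"L_iners"`).
#' @param scheme pH category scheme (default the three-bin scheme).
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @return List of class `"regression_spec"`.
#' @export
regression_spec <- function(species = "L_iners",
                            scheme = ph_scheme("ph3_iners"),
                            alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, inherits(scheme, "ph_scheme"))
  structure(list(species = match.arg(species, SPECIES), scheme = scheme,
                 alpha = alpha),
            class = "regression_spec")
}

#' Multivariable linear regression for one protein
#'
#' Ordinary least squares of log10 protein intensity on microbiota group,
#' pH category, and log10 taxon S/B abundance, within the species'
#' analysis cohort (16S-positive samples). Zero intensities are replaced
#' per protein by half the smallest positive intensity before the log10
#' transform; zero S/B values likewise within the cohort. Confidence
#' intervals use the t-distribution with residual degrees of freedom.
#' Residual normality is checked with the Shapiro-Wilk test; p < 0.05 is
#' reported as a warning, not a failure.
#'
#' @param accession Protein accession (row of `matrix`).
#' @param matrix Abundance matrix.
#' @param samples A validated sample table.
#' @param spec A [regression_spec()].
#' @return List with `accession`, `coefficients` (data frame: `term`,
#'   `beta`, `ci_low`, `ci_high`), `shapiro_p`, `n`, and `terms`.
#' @export
fit_regression <- function(accession, matrix, samples,
                           spec = regression_spec()) {
  stopifnot(inherits(spec, "regression_spec"))
  if (!accession %in% rownames(matrix)) {
    stop("protein ", accession, " absent from abundance matrix",
         call. = FALSE)
  }
  cohort <- analysis_cohort(spec$species, samples)
  ids <- sort(unlist(cohort$groups, use.names = FALSE))
  if (length(ids) == 0) {
    stop("empty analysis cohort for ", spec$species, call. = FALSE)
  }
  sub <- samples[match(ids, samples$sample_id), , drop = FALSE]
  y <- log10(replace_zeros_half_min(matrix[accession, ids]))
  # groups absent from the analysis cohort drop out of the design; the pH
  # scheme's categories are requested by the spec and stay, so an
  # unpopulated category surfaces as a rank-deficiency error
  grp <- droplevels(factor(sub$vmb_group, levels = VMB_GROUPS))
  if (nlevels(grp) < 2) {
    stop("analysis cohort spans fewer than 2 microbiota groups",
         call. = FALSE)
  }
  grp <- stats::relevel(grp, ref = SPECIES_HOME_GROUP[[spec$species]])
  phc <- ph_category(sub$vaginal_ph, spec$scheme)
  empty_ph <- levels(phc)[tabulate(phc, nlevels(phc)) == 0]
  if (length(empty_ph)) {
    stop("rank-deficient design; aliased term(s): ",
         paste0("ph_category", empty_ph, collapse = ", "), call. = FALSE)
  }
  sb <- log10(replace_zeros_half_min(sample_sb(sub, spec$species)))
  df <- data.frame(y = y, vmb_group = grp, ph_category = phc,
                   log_sb = as.numeric(sb))
  n_terms <- (nlevels(grp) - 1) + (nlevels(phc) - 1) + 1
  if (nrow(df) < n_terms + 2) {
    stop("too few samples (", nrow(df), ") for ", n_terms,
         " model terms", call. = FALSE)
  }
  fit <- stats::lm(y ~ vmb_group + ph_category + log_sb, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  ci <- stats::confint(fit, level = 1 - spec$alpha)
  sw <- shapiro_wilk(stats::residuals(fit))
  if (sw < 0.05) {
    warning("residuals of ", accession,
            " deviate from normality (Shapiro-Wilk p = ",
            signif(sw, 3), ")", call. = FALSE)
  }
  list(
    accession = accession,
    coefficients = data.frame(
      term = names(cf), beta = unname(cf),
      ci_low = ci[, 1], ci_high = ci[, 2],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    shapiro_p = sw,
    n = nrow(df),
    terms = c("vmb_group", "ph_category", "log_sb")
  )
}

battery_rows <- function(accession, factor_name, stratum, values) {
  non_empty <- sum(vapply(values, length, integer(1)) > 0)
  if (non_empty < 2) {
    return(NULL)
  }
  res <- suppressWarnings(pairwise_mannwhitney(values))
  cbind(
    data.frame(accession = accession, factor = factor_name,
               stratum = stratum, stringsAsFactors = FALSE),
    res
  )
}

#' Pairwise comparison battery for species-assigned proteins
#'
#' For every protein assigned to `species`, runs the full set of
#' two-sided Mann-Whitney pairwise comparisons used in the study design:
#'
#' * relative abundance across microbiota groups within the species'
#'   analysis cohort (16S-positive samples);
#' * across vaginal pH categories (three bins for *L. iners*, two for
#'   *L. crispatus*);
#' * the group battery repeated within taxon-abundance strata — a median
#'   split of the cohort's S/B ratios and a fixed high-abundance
#'   threshold (S/B > 70);
#' * the pH battery repeated within the species-dominated group only.
#'
#' Groups or categories with no members are skipped pair-wise.
#'
#' @param decisions Output of [classify_all()] (or any data frame with
#'   `accession` and `assigned`).
#' @param matrix Abundance matrix.
#' @param samples A validated sample table.
#' @param species `"L_iners"` or `"L_crispatus"`.
#' @param sb_threshold Fixed S/B threshold for the high-abundance
#'   stratum (default 70).
#' @return Data frame with columns `accession`, `factor` (`"vmb_group"`
#'   or `"ph_category"`), `stratum` (`"all"`, `"sb_high_median"`,
#'   `"sb_low_median"`, `"sb_high_fixed"`, `"sb_low_fixed"`,
#'   `"dominant_group"`), and the [pairwise_mannwhitney()] columns.
#' @export
run_group_battery <- function(decisions, matrix, samples, species,
                              sb_threshold = 70) {
  species <- match.arg(species, SPECIES)
  accs <- decisions$accession[decisions$assigned == species]
  if (length(accs) == 0) {
    stop("no proteins assigned to ", species, call. = FALSE)
  }
  cohort <- analysis_cohort(species, samples)
  ids <- unlist(cohort$groups, use.names = FALSE)
  if (length(ids) == 0) {
    stop("empty analysis cohort for ", species, call. = FALSE)
  }
  sub <- samples[match(ids, samples$sample_id), , drop = FALSE]
  scheme <- if (species == "L_iners") {
    ph_scheme("ph3_iners")
  } else {
    ph_scheme("ph2_crispatus")
  }
  phc <- ph_category(sub$vaginal_ph, scheme)
  strata_med <- abundance_strata(sub, species, "median_split")
  strata_fix <- abundance_strata(sub, species, "fixed_threshold",
                                 threshold = sb_threshold)
  dom_ids <- cohort$groups[[SPECIES_HOME_GROUP[[species]]]]

  group_values <- function(acc, keep_ids) {
    lapply(cohort$groups, function(g) {
      g2 <- intersect(g, keep_ids)
      as.numeric(matrix[acc, g2])
    })
  }
  out <- list()
  for (acc in accs) {
    vals_g <- group_values(acc, ids)
    out[[length(out) + 1]] <- battery_rows(acc, "vmb_group", "all", vals_g)
    vals_ph <- split(as.numeric(matrix[acc, sub$sample_id]), phc)
    out[[length(out) + 1]] <- battery_rows(acc, "ph_category", "all",
                                           vals_ph)
    out[[length(out) + 1]] <- battery_rows(
      acc, "vmb_group", "sb_high_median", group_values(acc, strata_med$high))
    out[[length(out) + 1]] <- battery_rows(
      acc, "vmb_group", "sb_low_median", group_values(acc, strata_med$low))
    out[[length(out) + 1]] <- battery_rows(
      acc, "vmb_group", "sb_high_fixed", group_values(acc, strata_fix$high))
    out[[length(out) + 1]] <- battery_rows(
      acc, "vmb_group", "sb_low_fixed", group_values(acc, strata_fix$low))
    if (length(dom_ids) > 0) {
      dom_ph <- ph_category(
        sub$vaginal_ph[match(dom_ids, sub$sample_id)], scheme)
      vals_dom <- split(as.numeric(matrix[acc, dom_ids]), dom_ph)
      out[[length(out) + 1]] <- battery_rows(acc, "ph_category",
                                             "dominant_group", vals_dom)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    stop("no comparable level pairs for ", species, call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
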