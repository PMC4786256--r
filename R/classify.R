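#' Classifier configuration
#'
#' Settings for the species-specificity criteria.
#'
#' @param fold_threshold Minimum target/reference mean intensity ratio
#'   (inclusive, "at least"). Default 2.
#' @param target_rule How the target group is formed: `"cluster_members"`
#'   (all members of the species' dominated cluster; default) or
#'   `"cluster_members_16s_positive"` (additionally 16S-positive for the
#'   species).
#' @param multispecies_tiebreak How a multispecies-matched protein that
#'   passes both species' criteria is resolved: `"higher_fold"` (default;
#'   larger fold-change wins, an exact tie is nonspecific) or
#'   `"nonspecific"`.
#' @return A list of class `"classifier_config"`.
#' @export
classifier_config <- function(fold_threshold = 2,
                              target_rule = c("cluster_members",
                                              "cluster_members_16s_positive"),
                              multispecies_tiebreak = c("higher_fold",
                                                        "nonspecific")) {
  stopifnot(is.numeric(fold_threshold), length(fold_threshold) == 1,
            fold_threshold > 0)
  cfg <- list(
    fold_threshold = fold_threshold,
    target_rule = match.arg(target_rule),
    multispecies_tiebreak = match.arg(multispecies_tiebreak)
  )
  class(cfg) <- "classifier_config"
  cfg
}

#' Target samples for a species
#'
#' The target group is the species' dominated cluster: group `G2_iners`
#' for *L. iners*, `G1_crispatus` for *L. crispatus*. Under the
#' `cluster_members_16s_positive` rule, cluster members are additionally
#' required to be 16S-positive for the species.
#'
#' @param species `"L_iners"` or `"L_crispatus"`.
#' @param samples A validated sample table.
#' @param config A [classifier_config()].
#' @return Character vector of sample ids.
#' @export
target_samples <- function(species, samples, config = classifier_config()) {
  species <- match.arg(species, SPECIES)
  ids <- samples$sample_id[samples$vmb_group == SPECIES_HOME_GROUP[[species]]]
  if (config$target_rule == "cluster_members_16s_positive") {
    pos <- sample_positive(samples, species)
    ids <- ids[pos[ids]]
  }
  if (length(ids) == 0) {
    stop("no target samples for ", species, call. = FALSE)
  }
  ids
}

#' Reference samples for a species
#'
#' The reference group is every sample with a negative 16S result for the
#' species, across all microbiota groups (in practice: the other
#' *Lactobacillus*-dominated cluster plus species-negative dysbiotic
#' samples).
#'
#' @inheritParams target_samples
#' @return Character vector of sample ids.
#' @export
reference_samples <- function(species, samples) {
  species <- match.arg(species, SPECIES)
  pos <- sample_positive(samples, species)
  ids <- samples$sample_id[!pos[samples$sample_id]]
  if (length(ids) == 0) {
    stop("no reference samples for ", species, call. = FALSE)
  }
  ids
}

#' Evaluate the species-specificity criteria for one intensity vector
#'
#' Computes the target/reference mean intensity ratio and the median
#' comparison. The fold criterion passes when the ratio is at least
#' `fold_threshold` (inclusive); the median criterion when the target
#' median is equal to or higher than the reference median. A reference
#' mean of zero with a positive target mean gives an infinite fold-change
#' and passes the fold criterion; when both means are zero the protein
#' was not observed in either group and the fold criterion fails
#' (`fold_change` is reported as 0).
#'
#' @param target_values,reference_values Nonnegative intensity vectors.
#' @param config A [classifier_config()].
#' @return List with `target_mean`, `reference_mean`, `target_median`,
#'   `reference_median`, `fold_change`, `fold_ok`, `median_ok`.
#' @export
evaluate_species <- function(target_values, reference_values,
                             config = classifier_config()) {
  stopifnot(length(target_values) > 0, length(reference_values) > 0)
  if (any(target_values < 0) || any(reference_values < 0)) {
    stop("negative intensities", call. = FALSE)
  }
  tm <- mean(target_values)
  rm_ <- mean(reference_values)
  if (rm_ == 0) {
    if (tm > 0) {
      fold <- Inf
      fold_ok <- TRUE
    } else {
      fold <- 0
      fold_ok <- FALSE
    }
  } else {
    fold <- tm / rm_
    fold_ok <- fold >= config$fold_threshold
  }
  list(
    target_mean = tm,
    reference_mean = rm_,
    target_median = stats::median(target_values),
    reference_median = stats::median(reference_values),
    fold_change = fold,
    fold_ok = fold_ok,
    median_ok = stats::median(target_values) >= stats::median(reference_values)
  )
}

candidate_species <- function(best_match) {
  switch(best_match,
         L_iners = "L_iners",
         L_crispatus = "L_crispatus",
         multispecies = SPECIES,
         other = character(0))
}

#' Classify one protein as species-specific or nonspecific
#'
#' Applies the two-part criteria: (1) the best database match is the
#' species itself or a *Lactobacillus* multispecies entry; (2) the mean
#' ion intensity in the species' target samples is at least
#' `fold_threshold`-fold higher, and the median equal to or higher, than
#' in the 16S-negative reference samples. A multispecies-matched protein
#' is evaluated against both species but assigned to at most one; if it
#' passes both, the configured tie-break applies.
#'
#' @param protein One-row protein table (must have passed the evidence
#'   filter).
#' @param matrix Abundance matrix containing the protein's row.
#' @param samples A validated sample table.
#' @param config A [classifier_config()].
#' @return List with `accession`, `best_match`, `assigned` (`"L_iners"`,
#'   `"L_crispatus"` or `"nonspecific"`), and `evaluations`: per evaluated
#'   species, the [evaluate_species()] output plus `best_match_ok`.
#' @export
classify_protein <- function(protein, matrix, samples,
                             config = classifier_config()) {
  acc <- protein$accession
  if (!acc %in% rownames(matrix)) {
    stop("protein ", acc, " absent from abundance matrix", call. = FALSE)
  }
  row <- stats::setNames(matrix[acc, ], colnames(matrix))
  cands <- candidate_species(protein$best_match)
  evals <- list()
  passed <- character(0)
  for (sp in cands) {
    tgt <- target_samples(sp, samples, config)
    ref <- reference_samples(sp, samples)
    ev <- evaluate_species(row[tgt], row[ref], config)
    ev$best_match_ok <- TRUE
    evals[[sp]] <- ev
    if (ev$fold_ok && ev$median_ok) passed <- c(passed, sp)
  }
  assigned <- "nonspecific"
  if (length(passed) == 1) {
    assigned <- passed
  } else if (length(passed) == 2) {
    if (config$multispecies_tiebreak == "higher_fold") {
      f <- vapply(evals[passed], `[[`, numeric(1), "fold_change")
      # exact tie (including Inf vs Inf) stays nonspecific
      if (f[1] != f[2]) assigned <- passed[which.max(f)]
    }
  }
  list(accession = acc, best_match = protein$best_match,
       assigned = assigned, evaluations = evals)
}

#' Classify all proteins and tally the outcome
#'
#' @param proteins Protein table (rows that passed the evidence filter).
#' @param matrix Abundance matrix covering all accessions.
#' @param samples A validated sample table.
#' @param config A [classifier_config()].
#' @return A data frame of class `"lacto_decisions"` with one row per
#'   protein: `accession`, `best_match`, `assigned`, and per-species
#'   evidence columns (`iners_fold`, `iners_fold_ok`, `iners_median_ok`,
#'   and the `crispatus_*` equivalents; `NA` for species not evaluated).
#'   The summary — candidate and assigned counts per species — is attached
#'   as attribute `"summary"` and printed by [classification_summary()].
#' @export
classify_all <- function(proteins, matrix, samples,
                         config = classifier_config()) {
  n <- nrow(proteins)
  res <- data.frame(
    accession = character(n), best_match = character(n),
    assigned = character(n),
    iners_fold = rep(NA_real_, n), iners_fold_ok = rep(NA, n),
    iners_median_ok = rep(NA, n),
    crispatus_fold = rep(NA_real_, n), crispatus_fold_ok = rep(NA, n),
    crispatus_median_ok = rep(NA, n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    for (i in seq_len(n)) {
      d <- classify_protein(proteins[i, , drop = FALSE], matrix, samples,
                            config)
      res$accession[i] <- d$accession
      res$best_match[i] <- d$best_match
      res$assigned[i] <- d$assigned
      if (!is.null(d$evaluations$L_iners)) {
        ev <- d$evaluations$L_iners
        res$iners_fold[i] <- ev$fold_change
        res$iners_fold_ok[i] <- ev$fold_ok
        res$iners_median_ok[i] <- ev$median_ok
      }
      if (!is.null(d$evaluations$L_crispatus)) {
        ev <- d$evaluations$L_crispatus
        res$crispatus_fold[i] <- ev$fold_change
        res$crispatus_fold_ok[i] <- ev$fold_ok
        res$crispatus_median_ok[i] <- ev$median_ok
      }
    }
  }
  attr(res, "summary") <- classification_summary(res)
  class(res) <- c("lacto_decisions", class(res))
  res
}

#' Summary counts for a set of classification decisions
#'
#' Candidate counts follow the criteria's first clause: a protein is a
#' candidate for a species when its best match is that species or
#' multispecies, so multispecies proteins count toward both species.
#'
#' @param decisions Output of [classify_all()].
#' @return Named list of counts.
#' @export
classification_summary <- function(decisions) {
  bm <- decisions$best_match
  list(
    n_proteins = nrow(decisions),
    candidates_iners = sum(bm %in% c("L_iners", "multispecies")),
    candidates_crispatus = sum(bm %in% c("L_crispatus", "multispecies")),
    assigned_iners = sum(decisions$assigned == "L_iners"),
    assigned_crispatus = sum(decisions$assigned == "L_crispatus"),
    nonspecific = sum(decisions$assigned == "nonspecific")
  )
}
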