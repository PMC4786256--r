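# Independent re-codings of the decision rules, used as oracles.
# Deliberately written as direct truth tables / arithmetic, not by calling
# the package implementation.

# inclusion rule oracle: >=1 unique peptide and >=2 peptides overall;
# a single unique peptide needs ANOVA p < 0.05 AND a confirmed fragment
# series; missing rescue metadata fails
oracle_inclusion <- function(unique, total, anova_p, fragment_ok) {
  if (unique >= 1 && total >= 2) {
    if (unique >= 2) {
      return(TRUE)
    }
    if (is.na(anova_p) || is.na(fragment_ok)) {
      return(FALSE)
    }
    return(anova_p < 0.05 && isTRUE(fragment_ok))
  }
  FALSE
}

# brute-force specificity oracle over a samples table + intensity row
oracle_decide <- function(best_match, row, samples, fold_threshold = 2,
                          tiebreak = "higher_fold") {
  home <- c(L_iners = "G2_iners", L_crispatus = "G1_crispatus")
  eval_sp <- function(sp) {
    tgt <- samples$sample_id[samples$vmb_group == home[[sp]]]
    ref <- samples$sample_id[!samples[[paste0("pos_", sp)]]]
    if (length(tgt) == 0 || length(ref) == 0) {
      stop("degenerate sample configuration")
    }
    mt <- sum(row[tgt]) / length(tgt)
    mr <- sum(row[ref]) / length(ref)
    fold <- if (mr == 0 && mt > 0) Inf else if (mr == 0) 0 else mt / mr
    list(fold = fold,
         pass = (if (mr == 0) mt > 0 else mt / mr >= fold_threshold) &&
           median(row[tgt]) >= median(row[ref]))
  }
  cands <- switch(best_match,
                  L_iners = "L_iners", L_crispatus = "L_crispatus",
                  multispecies = c("L_iners", "L_crispatus"),
                  other = character(0))
  evs <- lapply(cands, eval_sp)
  names(evs) <- cands
  passed <- cands[vapply(evs, `[[`, logical(1), "pass")]
  if (length(passed) == 1) {
    return(passed)
  }
  if (length(passed) == 2 && tiebreak == "higher_fold") {
    f1 <- evs[[passed[1]]]$fold
    f2 <- evs[[passed[2]]]$fold
    if (f1 > f2) return(passed[1])
    if (f2 > f1) return(passed[2])
  }
  "nonspecific"
}

# small fixed cohorts for classifier oracle checks: 4 and 6 samples with
# varied groups and positivity
oracle_cohort_small <- function() {
  validate_samples(data.frame(
    sample_id = c("a", "b", "c", "d"),
    vmb_group = c("G2_iners", "G2_iners", "G1_crispatus", "G4_severe"),
    vaginal_ph = c(4.5, 5, 4, 6),
    sb_L_iners = c(100, 50, 0, 0),
    sb_L_crispatus = c(0, 0, 120, 0),
    stringsAsFactors = FALSE
  ))
}

oracle_cohort_six <- function() {
  validate_samples(data.frame(
    sample_id = sprintf("s%d", 1:6),
    vmb_group = c("G2_iners", "G2_iners", "G1_crispatus", "G1_crispatus",
                  "G3_moderate", "G4_severe"),
    vaginal_ph = c(4.5, 5, 4, 4.5, 5.5, 6.5),
    sb_L_iners = c(150, 90, 0, 0, 30, 0),
    sb_L_crispatus = c(20, 0, 130, 80, 0, 0),
    stringsAsFactors = FALSE
  ))
}

# one-protein table around an intensity row
protein_row <- function(best_match, accession = "P1") {
  validate_proteins(data.frame(
    accession = accession, best_match = best_match,
    peptide_count = 4L, unique_peptides = 3L,
    stringsAsFactors = FALSE
  ))
}

as_matrix_row <- function(values, sample_ids, accession = "P1") {
  m <- matrix(values, nrow = 1, dimnames = list(accession, sample_ids))
  m
}

# sim_config used by recovery/calibration tests: isolates the planted
# species signal (no group or pH shifts) so specificity is identifiable
recovery_config <- function(seed, n = 25, species_effect = 1,
                            noise_sd = 0.3) {
  sim_config(
    seed = seed,
    n_per_group = c(G1_crispatus = n, G2_iners = n,
                    G3_moderate = n, G4_severe = n),
    n_specific_iners = 10, n_specific_crispatus = 10, n_nonspecific = 20,
    species_effect = species_effect, dysbiosis_effect = 0, ph_effect = 0,
    noise_sd = noise_sd
  )
}

# regression-oriented config: iners-positive everywhere, pH spread over
# all three categories, so the fitted design matches the generative model
regression_config <- function(seed, noise_sd = 0.2, n = 20,
                              dysbiosis_effect = -0.5, ph_effect = -0.3) {
  sim_config(
    seed = seed,
    n_per_group = c(G1_crispatus = 0, G2_iners = n, G3_moderate = n,
                    G4_severe = n),
    n_specific_iners = 1, n_specific_crispatus = 0, n_nonspecific = 0,
    species_effect = 1.2, dysbiosis_effect = dysbiosis_effect,
    ph_effect = ph_effect, noise_sd = noise_sd,
    pos_prob = list(
      L_iners = c(G1_crispatus = 0, G2_iners = 1, G3_moderate = 1,
                  G4_severe = 1),
      L_crispatus = c(G1_crispatus = 1, G2_iners = 0.3, G3_moderate = 0.1,
                      G4_severe = 0.1)
    ),
    ph_distribution = list(
      G1_crispatus = c("4.5" = 1),
      G2_iners = c("4.5" = 0.4, "5" = 0.3, "6" = 0.3),
      G3_moderate = c("4.5" = 0.3, "5" = 0.4, "6" = 0.3),
      G4_severe = c("4.5" = 0.3, "5" = 0.3, "6" = 0.4)
    )
  )
}

# planted coefficient vector matching the fitted design of
# regression_config(): both dysbiotic groups shift by dysbiosis_effect,
# pH categories by multiples of ph_effect, S/B carries no signal
planted_betas <- function(dysbiosis_effect = -0.5, ph_effect = -0.3) {
  c("vmb_groupG3_moderate" = dysbiosis_effect,
    "vmb_groupG4_severe" = dysbiosis_effect,
    "ph_category5-6" = ph_effect,
    "ph_category>=6" = 2 * ph_effect,
    "log_sb" = 0)
}
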