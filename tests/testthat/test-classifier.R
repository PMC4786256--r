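test_that("target and reference groups follow cluster membership and 16S negativity", {
  s <- methods_cohort()
  expect_length(target_samples("L_iners", s), 11)
  expect_length(target_samples("L_crispatus", s), 7)
  cfg <- classifier_config(target_rule = "cluster_members_16s_positive")
  expect_length(target_samples("L_crispatus", s, cfg), 5)
  expect_length(target_samples("L_iners", s, cfg), 11)
  expect_length(reference_samples("L_iners", s), 19)
  expect_length(reference_samples("L_crispatus", s), 37)
  # reference = complement of positivity
  expect_false(any(reference_samples("L_iners", s) %in%
                     s$sample_id[sample_positive(s, "L_iners")]))
  # all positive for a species -> empty reference errors
  all_pos <- s
  all_pos$pos_L_iners <- TRUE
  expect_error(reference_samples("L_iners", validate_samples(all_pos)),
               "no reference samples")
})

test_that("fold and median criteria use inclusive thresholds and zero conventions", {
  ev <- evaluate_species(c(10, 8, 12), c(2, 3, 1))
  expect_equal(ev$fold_change, 5)
  expect_true(ev$fold_ok)
  expect_true(ev$median_ok)

  tie <- evaluate_species(c(4, 4), c(4, 4))
  expect_equal(tie$fold_change, 1)
  expect_false(tie$fold_ok)
  expect_true(tie$median_ok)    # equal medians pass ("equal to or higher")

  exact2 <- evaluate_species(c(4, 4), c(2, 2))
  expect_true(exact2$fold_ok)   # exactly 2-fold passes ("at least 2-fold")

  zr <- evaluate_species(c(5, 5), c(0, 0))
  expect_equal(zr$fold_change, Inf)
  expect_true(zr$fold_ok)
  expect_true(zr$median_ok)

  zz <- evaluate_species(c(0, 0), c(0, 0))
  expect_false(zz$fold_ok)

  expect_error(evaluate_species(c(-1, 2), c(1, 1)), "negative")
})

test_that("classification respects the best-match gate and assigns one species", {
  s <- oracle_cohort_small()
  ids <- s$sample_id
  high_in_iners <- as_matrix_row(c(100, 80, 5, 2), ids)
  # criterion 1: 'other' never assigned, whatever the intensities
  d <- classify_protein(protein_row("other"), high_in_iners, s)
  expect_equal(d$assigned, "nonspecific")
  # iners-matched, strong iners signal
  d <- classify_protein(protein_row("L_iners"), high_in_iners, s)
  expect_equal(d$assigned, "L_iners")
  expect_true(d$evaluations$L_iners$fold_ok)
  # multispecies evaluated for both, settles on the species with signal
  d <- classify_protein(protein_row("multispecies"), high_in_iners, s)
  expect_equal(d$assigned, "L_iners")
  expect_named(d$evaluations, c("L_iners", "L_crispatus"),
               ignore.order = TRUE)
})

test_that("multispecies double-pass resolves by larger fold, exact tie stays nonspecific", {
  # a double pass needs each species' reference not to be dragged up by
  # the other species' target; a double-positive target sample and a
  # crispatus-free reference give one
  overlap <- validate_samples(data.frame(
    sample_id = c("t_i", "t_c", "neg"),
    vmb_group = c("G2_iners", "G1_crispatus", "G4_severe"),
    vaginal_ph = c(4.5, 4.0, 6.0),
    sb_L_iners = c(100, 0, 0),
    sb_L_crispatus = c(50, 120, 0),   # iners-cluster sample also crisp+
    stringsAsFactors = FALSE
  ))
  # iners reference {t_c, neg}, crispatus reference {neg} only
  both <- as_matrix_row(c(10, 4, 0), overlap$sample_id)
  d <- classify_protein(protein_row("multispecies"), both, overlap)
  expect_true(d$evaluations$L_iners$fold_ok)      # 10 / 2 = 5
  expect_equal(d$evaluations$L_crispatus$fold_change, Inf)
  expect_equal(d$assigned, "L_crispatus")         # larger fold wins
  # symmetric cohort: equal finite folds tie -> nonspecific
  sym <- validate_samples(data.frame(
    sample_id = c("a", "b", "z"),
    vmb_group = c("G2_iners", "G1_crispatus", "G4_severe"),
    vaginal_ph = c(4.5, 4.0, 6.0),
    sb_L_iners = c(100, 0, 0), sb_L_crispatus = c(0, 120, 0),
    stringsAsFactors = FALSE
  ))
  tie <- as_matrix_row(c(10, 10, 0), sym$sample_id)
  d2 <- classify_protein(protein_row("multispecies"), tie, sym)
  expect_equal(d2$evaluations$L_iners$fold_change, 2)   # exactly at threshold
  expect_equal(d2$evaluations$L_crispatus$fold_change, 2)
  expect_true(d2$evaluations$L_iners$fold_ok)
  expect_true(d2$evaluations$L_crispatus$fold_ok)
  expect_equal(d2$assigned, "nonspecific")
  d3 <- classify_protein(protein_row("multispecies"), both, overlap,
                         classifier_config(multispecies_tiebreak =
                                             "nonspecific"))
  expect_equal(d3$assigned, "nonspecific")
})

test_that("decisions are scale invariant and monotone in target intensity", {
  s <- oracle_cohort_six()
  ids <- s$sample_id
  set.seed(21)
  for (rep in 1:30) {
    row <- as_matrix_row(round(runif(6, 0, 50)), ids)
    bm <- sample(c("L_iners", "L_crispatus", "multispecies"), 1)
    d <- classify_protein(protein_row(bm), row, s)
    scaled <- row * runif(1, 0.1, 40)
    d2 <- classify_protein(protein_row(bm), scaled, s)
    expect_equal(d2$assigned, d$assigned)
    # raising a target-sample intensity never demotes a passing species
    if (d$assigned %in% c("L_iners", "L_crispatus")) {
      tgt <- target_samples(d$assigned, s)
      bumped <- row
      bumped[1, tgt[1]] <- bumped[1, tgt[1]] + 100
      d3 <- classify_protein(protein_row(bm), bumped, s)
      ev <- d3$evaluations[[d$assigned]]
      expect_true(ev$fold_ok && ev$median_ok)
    }
  }
})

test_that("decisions match the brute-force oracle on enumerated small instances", {
  cohorts <- list(oracle_cohort_small(), oracle_cohort_six())
  # exhaustive intensity grid on the 4-sample cohort
  s4 <- cohorts[[1]]
  grid <- expand.grid(v1 = c(0, 1, 10), v2 = c(0, 1, 10),
                      v3 = c(0, 1, 10), v4 = c(0, 1, 10))
  for (bm in c("L_iners", "L_crispatus", "multispecies", "other")) {
    for (i in seq_len(nrow(grid))) {
      row <- as_matrix_row(as.numeric(grid[i, ]), s4$sample_id)
      got <- classify_protein(protein_row(bm), row, s4)$assigned
      want <- oracle_decide(bm, row[1, ], s4)
      expect_identical(got, want,
                       info = sprintf("bm=%s grid row %d", bm, i))
    }
  }
  # randomized instances on the 6-sample cohort, up to 4 proteins at once
  set.seed(33)
  s6 <- cohorts[[2]]
  for (rep in 1:50) {
    np <- sample(1:4, 1)
    vals <- matrix(sample(c(0, 1, 2, 5, 20, 100), 6 * np, replace = TRUE),
                   nrow = np,
                   dimnames = list(sprintf("P%d", seq_len(np)),
                                   s6$sample_id))
    bms <- sample(c("L_iners", "L_crispatus", "multispecies", "other"),
                  np, replace = TRUE)
    prot <- suppressWarnings(validate_proteins(data.frame(
      accession = rownames(vals), best_match = bms,
      peptide_count = 4L, unique_peptides = 3L, stringsAsFactors = FALSE
    )))
    dec <- classify_all(prot, vals, s6)
    for (k in seq_len(np)) {
      expect_identical(dec$assigned[k],
                       oracle_decide(bms[k], vals[k, ], s6))
    }
  }
})

test_that("summary counts are exclusive and exhaustive", {
  ds <- simulate_dataset(recovery_config(5))
  dec <- classify_all(ds$proteins, ds$matrix, ds$samples)
  cs <- classification_summary(dec)
  expect_equal(cs$assigned_iners + cs$assigned_crispatus + cs$nonspecific,
               cs$n_proteins)
  expect_equal(cs$candidates_iners,
               sum(dec$best_match %in% c("L_iners", "multispecies")))
  # all-zero matrix: everything nonspecific (both-means-zero convention)
  zero <- ds$matrix * 0
  dec0 <- classify_all(ds$proteins, zero, ds$samples)
  expect_true(all(dec0$assigned == "nonspecific"))
  # empty protein list
  dec_empty <- classify_all(ds$proteins[integer(0), ], ds$matrix,
                            ds$samples)
  expect_equal(nrow(dec_empty), 0)
  expect_equal(classification_summary(dec_empty)$n_proteins, 0)
})

test_that("planted species labels are recovered on synthetic data", {
  hits <- vapply(1:5, function(seed) {
    ds <- simulate_dataset(recovery_config(seed, species_effect = 1.5,
                                           noise_sd = 0.2))
    dec <- classify_all(ds$proteins, ds$matrix, ds$samples)
    m <- merge(dec, ds$truth, by = "accession")
    sp <- m$true_species != "none"
    mean(m$assigned[sp] == m$true_species[sp])
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
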