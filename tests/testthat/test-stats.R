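test_that("pairwise Mann-Whitney matches exact enumeration and symmetry", {
  r <- pairwise_mannwhitney(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)    # 2 * 1/20 fully separated arrangements
  expect_equal(r$method, "exact")
  # swapping levels leaves p unchanged
  r2 <- pairwise_mannwhitney(list(b = c(4, 5, 6), a = c(1, 2, 3)))
  expect_equal(r2$p_value, r$p_value)
  # identical samples: no shift
  x <- c(2, 4, 9)
  r3 <- pairwise_mannwhitney(list(a = x, b = x))
  expect_equal(r3$p_value, 1)
  # all values identical across levels
  r4 <- pairwise_mannwhitney(list(a = c(3, 3), b = c(3, 3, 3)))
  expect_equal(r4$p_value, 1)
})

test_that("exact/approximate switch follows combined n and ties", {
  set.seed(5)
  small <- list(a = rnorm(10), b = rnorm(12))
  expect_equal(pairwise_mannwhitney(small)$method, "exact")
  big <- list(a = rnorm(13), b = rnorm(13))
  expect_equal(pairwise_mannwhitney(big)$method, "normal_approx")
  tied <- list(a = c(1, 2, 2), b = c(3, 4, 5))
  expect_equal(pairwise_mannwhitney(tied)$method, "normal_approx")
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rlnorm(8)
    y <- rlnorm(9) * 1.8
    p1 <- pairwise_mannwhitney(list(a = x, b = y))$p_value
    p2 <- pairwise_mannwhitney(list(a = log(x), b = log(y)))$p_value
    p3 <- pairwise_mannwhitney(list(a = x^3, b = y^3))$p_value
    expect_equal(p1, p2)
    expect_equal(p1, p3)
  }
})

test_that("empty levels are skipped and Holm adjustment is available", {
  expect_warning(
    r <- pairwise_mannwhitney(list(a = 1:3, b = numeric(0), c = 7:9)),
    "empty"
  )
  expect_equal(nrow(r), 1)
  r2 <- suppressWarnings(
    pairwise_mannwhitney(list(a = 1:4, b = 6:9, c = c(2, 5, 7, 8)),
                         adjust = "holm")
  )
  expect_true(all(r2$p_adjusted >= r2$p_value))
  expect_error(pairwise_mannwhitney(list(a = 1:3)), "at least 2")
})

test_that("group battery covers groups, pH, strata, and dominant-group panels", {
  ds <- simulate_dataset(recovery_config(3))
  dec <- classify_all(ds$proteins, ds$matrix, ds$samples)
  skip_if(sum(dec$assigned == "L_iners") == 0)
  bat <- suppressWarnings(
    run_group_battery(dec, ds$matrix, ds$samples, "L_iners")
  )
  expect_setequal(unique(bat$factor), c("vmb_group", "ph_category"))
  expect_true(all(c("all", "dominant_group") %in% bat$stratum))
  expect_true(any(grepl("^sb_", bat$stratum)))
  expect_true(all(bat$p_value >= 0 & bat$p_value <= 1))
  # group comparisons never involve a group outside the analysis cohort
  co <- analysis_cohort("L_iners", ds$samples)
  used <- unique(c(bat$level_a[bat$factor == "vmb_group"],
                   bat$level_b[bat$factor == "vmb_group"]))
  expect_true(all(co$n_per_group[used] > 0))
  expect_error(run_group_battery(dec, ds$matrix, ds$samples,
                                 "L_crispatus", sb_threshold = 70),
               NA)
})

test_that("battery detects a planted dysbiosis effect", {
  hits <- vapply(1:5, function(seed) {
    cfg <- regression_config(seed, noise_sd = 0.2, n = 30,
                             dysbiosis_effect = -0.8, ph_effect = 0)
    ds <- simulate_dataset(cfg)
    dec <- data.frame(accession = ds$proteins$accession,
                      assigned = "L_iners", stringsAsFactors = FALSE)
    bat <- suppressWarnings(
      run_group_battery(dec, ds$matrix, ds$samples, "L_iners")
    )
    g23 <- bat[bat$factor == "vmb_group" & bat$stratum == "all" &
                 bat$level_a == "G2_iners" & bat$level_b == "G3_moderate", ]
    all(g23$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("noiseless regression recovers planted coefficients exactly", {
  ds <- simulate_dataset(regression_config(1, noise_sd = 0))
  fit <- suppressWarnings(
    fit_regression(ds$proteins$accession[1], ds$matrix, ds$samples)
  )
  got <- setNames(fit$coefficients$beta, fit$coefficients$term)
  planted <- planted_betas()
  expect_equal(got[names(planted)], planted, tolerance = 1e-8)
  expect_equal(fit$n, 60)
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$beta &
                    fit$coefficients$beta <= fit$coefficients$ci_high))
})

test_that("regression betas for dummies are invariant to intensity rescaling", {
  ds <- simulate_dataset(regression_config(4, noise_sd = 0.2))
  acc <- ds$proteins$accession[1]
  f1 <- suppressWarnings(fit_regression(acc, ds$matrix, ds$samples))
  m2 <- ds$matrix * 1000
  f2 <- suppressWarnings(fit_regression(acc, m2, ds$samples))
  b1 <- setNames(f1$coefficients$beta, f1$coefficients$term)
  b2 <- setNames(f2$coefficients$beta, f2$coefficients$term)
  keep <- setdiff(names(b1), "(Intercept)")
  expect_equal(b1[keep], b2[keep], tolerance = 1e-10)
  expect_equal(b2[["(Intercept)"]] - b1[["(Intercept)"]], 3,
               tolerance = 1e-10)
})

test_that("degenerate regression designs raise informative errors", {
  # pH distribution collapsed to one bin -> empty pH categories alias out
  cfg <- regression_config(2, noise_sd = 0.1)
  cfg$ph_distribution <- list(
    G1_crispatus = c("4.5" = 1), G2_iners = c("4.5" = 1),
    G3_moderate = c("4.5" = 1), G4_severe = c("4.5" = 1)
  )
  ds <- simulate_dataset(cfg)
  expect_error(
    suppressWarnings(
      fit_regression(ds$proteins$accession[1], ds$matrix, ds$samples)
    ),
    "rank-deficient"
  )
  # constant S/B aliases the abundance term
  ds2 <- simulate_dataset(regression_config(2, noise_sd = 0.1))
  s2 <- ds2$samples
  s2$sb_L_iners <- ifelse(s2$sb_L_iners > 0, 10, 0)
  expect_error(
    suppressWarnings(
      fit_regression(ds2$proteins$accession[1], ds2$matrix,
                     validate_samples(s2))
    ),
    "log_sb"
  )
  expect_error(fit_regression("nope", ds2$matrix, ds2$samples), "absent")
})

test_that("Shapiro-Wilk wrapper is calibrated and guards degenerate input", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  set.seed(13)
  rej <- mean(replicate(400, shapiro_wilk(rnorm(50)) < 0.05))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
  pow <- mean(replicate(50, shapiro_wilk(rexp(200)) < 0.01))
  expect_gte(pow, 0.99)
})
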