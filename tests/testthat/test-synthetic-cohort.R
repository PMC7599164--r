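test_that("the template bank covers every profile in the default config and re-grades exactly", {
  bank <- build_template_bank()      # construction itself round-trip checks
  cfg <- default_config()
  for (organ in c("spleen", "liver")) {
    pp <- cfg$profile_probs[[organ]]
    expect_true(all(names(pp) %in% names(bank)))
    expect_equal(sum(pp), 1, tolerance = 1e-12)
  }
  # full-bank round trip under random in-bracket jitter
  set.seed(5)
  for (tpl in bank) {
    for (rep in 1:5) {
      fnd <- tpl$build(function(lo, hi) round(stats::runif(1, lo, hi), 1),
                       function(lo, hi) sample(seq(lo, hi), 1))
      got <- vapply(c("AAST1994", "AAST2018", "CTSI"),
                    function(s) grade_organ(fnd, s)$value, character(1))
      expect_identical(unname(got), unname(tpl$profile),
                       label = sprintf("template %s", tpl$name))
    }
  }
  # all 5 CTSI grades represented per organ
  for (organ in c("spleen", "liver")) {
    ctsi <- vapply(Filter(function(t) t$organ == organ, bank),
                   function(t) t$profile[["CTSI"]], character(1))
    expect_setequal(unique(ctsi), c("I", "II", "III", "IVa", "IVb"))
  }
})

test_that("generation is deterministic given the seed and differs across seeds", {
  cfg <- default_config(n_patients = 150, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  c3 <- generate_cohort(default_config(n_patients = 150, seed = 12))
  expect_false(identical(c1$patients, c3$patients))
  # the generator restores the caller's RNG state
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1); invisible(generate_cohort(default_config(50, seed = 3)))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("default cohorts reproduce the registry structure", {
  co <- generate_cohort(default_config(seed = 2024))
  expect_length(co, 703)
  expect_identical(validate_cohort(co), character(0))
  groups <- vapply(co$patients, `[[`, character(1), "injury_group")
  counts <- table(factor(groups, levels = c("splenic", "hepatic", "combined")))
  # within the 99.9% per-component binomial band around (271, 352, 80)/703
  expected <- c(splenic = 271, hepatic = 352, combined = 80)
  for (g in names(expected)) {
    p <- expected[[g]] / 703
    expect_gte(counts[[g]], stats::qbinom(0.0005, 703, p))
    expect_lte(counts[[g]], stats::qbinom(0.9995, 703, p))
  }
  # secondary OM only among NOM patients
  for (p in co$patients)
    if (isTRUE(p$secondary_om))
      expect_identical(p$primary_management, "NOM")
  # re-grading the stored findings agrees with the generator's bookkeeping
  truth <- attr(co, "truth")
  g <- grade_cohort(co, schemes = "CTSI")
  for (organ in c("spleen", "liver")) {
    got <- table(factor(g$severity[g$organ == organ],
                        levels = c("mild", "severe")))
    expect_equal(as.vector(got), as.vector(truth$severity_counts[[organ]]))
  }
})

test_that("generated grade marginals track the configured joint distribution", {
  co <- generate_cohort(default_config(n_patients = 6000, seed = 31))
  g <- grade_cohort(co)
  cfg <- default_config()
  for (organ in c("spleen", "liver")) {
    pp <- cfg$profile_probs[[organ]]
    # expected CTSI marginal from the template names (suffix after last _)
    ctsi_of <- vapply(strsplit(names(pp), "_"), function(x) x[[4]], character(1))
    expected <- tapply(pp, ctsi_of, sum)
    sub <- g[g$organ == organ & g$scheme == "CTSI", ]
    obs <- table(factor(sub$grade, levels = names(expected))) / nrow(sub)
    for (lvl in names(expected)) {
      se <- sqrt(expected[[lvl]] * (1 - expected[[lvl]]) / nrow(sub))
      expect_lt(abs(obs[[lvl]] - expected[[lvl]]), 4 * se + 1e-9)
    }
  }
})

test_that("invalid configurations are rejected with named violations", {
  cfg <- default_config()
  bad <- cfg; bad$injury_group_probs <- c(splenic = 0.5, hepatic = 0.6, combined = -0.1)
  expect_match(validate_config(bad), "injury_group_probs", all = FALSE)
  bad2 <- cfg; names(bad2$profile_probs$spleen)[1] <- "spleen_no_such_profile"
  expect_match(validate_config(bad2), "no template", all = FALSE)
  bad3 <- cfg; bad3$outcome_rates$death$spleen["severe"] <- 1.7
  expect_match(validate_config(bad3), "death", all = FALSE)
  expect_error(generate_cohort(bad2), class = "trauma_config_error")
  expect_identical(validate_config(cfg), character(0))
})

test_that("combined-injury patients occasionally carry a CT-occult spleen", {
  co <- generate_cohort(default_config(n_patients = 2000, seed = 77))
  occult <- vapply(co$patients, function(p)
    !is.null(p$spleen_findings) && isTRUE(p$spleen_findings$surgical_only),
    logical(1))
  groups <- vapply(co$patients, `[[`, character(1), "injury_group")
  expect_true(all(groups[occult] == "combined"))
  expect_gt(sum(occult), 0)
  # occult spleens never enter the grading denominator
  g <- grade_cohort(co, schemes = "CTSI", organs = "spleen")
  expect_false(any(g$patient_id %in%
                     vapply(co$patients[occult], `[[`, character(1), "patient_id")))
})

test_that("configured outcome rates are recovered at moderate n", {
  cfg <- default_config()
  splenic_only <- cohort_config(
    n_patients = 8000,
    injury_group_probs = c(splenic = 1, hepatic = 0, combined = 0),
    profile_probs = cfg$profile_probs,
    outcome_rates = cfg$outcome_rates,
    seed = 9)
  co <- generate_cohort(splenic_only)
  t <- build_two_by_two(co, "CTSI", "spleen", "death")
  p_cfg <- cfg$outcome_rates$death$spleen[["severe"]]
  se <- sqrt(p_cfg * (1 - p_cfg) / (t$a + t$b))
  expect_lt(abs(t$a / (t$a + t$b) - p_cfg), 3 * se)
  p_mild <- cfg$outcome_rates$death$spleen[["mild"]]
  se_m <- sqrt(p_mild * (1 - p_mild) / (t$c + t$d))
  expect_lt(abs(t$c / (t$c + t$d) - p_mild), 3 * se_m)
})
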