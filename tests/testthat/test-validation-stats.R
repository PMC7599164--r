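test_that("diagnostic metrics reproduce the published splenic mortality analysis", {
  dm <- diagnostic_metrics(two_by_two(9, 78, 8, 254))
  expect_equal(dm$accuracy, 263 / 349, tolerance = 1e-12)
  expect_equal(dm$dor, (9 * 254) / (78 * 8), tolerance = 1e-12)
  expect_equal(dm$dor_ci, c(1.37, 9.82), tolerance = 0.005)
  expect_equal(dm$ppv, 9 / 87, tolerance = 1e-12)
  expect_equal(dm$npv, 254 / 262, tolerance = 1e-12)
  expect_identical(dm$test_used, "chi_square")
  expect_false(dm$corrected)

  dm2 <- diagnostic_metrics(two_by_two(8, 68, 9, 264))
  expect_equal(100 * dm2$accuracy, 77.9, tolerance = 0.05)
  expect_equal(dm2$dor, 3.45, tolerance = 0.005)
})

test_that("symmetric tables give DOR 1 and accuracy one half", {
  for (k in c(1, 5, 20)) {
    dm <- diagnostic_metrics(two_by_two(k, k, k, k))
    expect_equal(dm$dor, 1)
    expect_equal(dm$accuracy, 0.5)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction for the DOR only", {
  dm <- diagnostic_metrics(two_by_two(5, 0, 0, 5))
  expect_true(dm$corrected)
  expect_equal(dm$dor, (5.5 * 5.5) / (0.5 * 0.5))  # 121, by hand
  expect_equal(dm$accuracy, 1)                     # accuracy uncorrected
})

test_that("accuracy and the misclassified fraction sum to one exactly", {
  set.seed(4)
  for (i in 1:20) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) next
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    dm <- suppressWarnings(diagnostic_metrics(t))
    expect_equal(dm$accuracy + (t$b + t$c) / t$n, 1)
  }
})

test_that("the DOR equals the literal odds definition on non-degenerate tables", {
  set.seed(8)
  for (i in 1:25) {
    cells <- sample(1:50, 4, replace = TRUE)
    dm <- diagnostic_metrics(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    odds_severe_in_deaths <- cells[1] / cells[3]
    odds_severe_in_survivors <- cells[2] / cells[4]
    expect_equal(dm$dor, odds_severe_in_deaths / odds_severe_in_survivors)
  }
})

test_that("accuracy CI is the Wilson score interval (closed form)", {
  wilson <- function(x, n, z = stats::qnorm(0.975)) {
    p <- x / n
    centre <- p + z^2 / (2 * n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    c(centre - half, centre + half) / (1 + z^2 / n)
  }
  dm <- diagnostic_metrics(two_by_two(9, 78, 8, 254))
  expect_equal(dm$accuracy_ci, wilson(263, 349), tolerance = 1e-9)
  dm2 <- diagnostic_metrics(two_by_two(4, 29, 20, 379))
  expect_equal(dm2$accuracy_ci, wilson(383, 432), tolerance = 1e-9)
})

test_that("association test selects chi-square (uncorrected) or Fisher by the <5 cases rule", {
  at <- association_test(two_by_two(9, 78, 8, 254))
  expect_identical(at$test_used, "chi_square")
  expect_lt(abs(at$chi_square - 7.49), 0.005)
  expect_lt(abs(at$p_value - 0.006), 0.0005)

  at2 <- association_test(two_by_two(9, 2, 5, 17))
  expect_identical(at2$test_used, "fisher")
  expect_lt(abs(at2$p_value - 0.002), 0.0005)

  # independence: statistic exactly zero, p = 1
  at3 <- association_test(two_by_two(10, 10, 10, 10))
  expect_equal(at3$chi_square, 0)
  expect_equal(at3$p_value, 1)
})

test_that("zero margins are degenerate with p = 1", {
  at <- association_test(two_by_two(0, 0, 8, 254))
  expect_true(at$degenerate)
  expect_equal(at$p_value, 1)
  av <- cramers_v(matrix(c(0, 0, 8, 254), 2, byrow = TRUE))
  expect_true(av$degenerate)
  expect_equal(av$cramer_v, 0)
})

test_that("the 2x2 chi-square closed form matches the generic Pearson computation", {
  set.seed(11)
  for (i in 1:25) {
    cells <- sample(1:60, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- a + b + c + d
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    at <- association_test(two_by_two(a, b, c, d))
    expect_equal(at$chi_square, closed, tolerance = 1e-9)
  }
})

test_that("Fisher p equals brute-force hypergeometric enumeration (margins <= 40)", {
  set.seed(21)
  for (i in 1:40) {
    cells <- sample(0:10, 4, replace = TRUE)
    if (sum(cells) == 0 || any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(stats::fisher.test(m)$p.value,
                 fisher_enumeration_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("Cramer's V reproduces the published operative-management correlations", {
  # spleen, primary OM: CTSI severe 54/87 OM vs mild 42/262
  expect_equal(cramers_v(two_by_two(54, 33, 42, 220))$cramer_v, 0.446,
               tolerance = 5e-4)
  # 2x2 V equals |ad-bc|/sqrt of margin product
  a <- 54; b <- 33; c <- 42; d <- 220
  phi <- abs(a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(cramers_v(two_by_two(a, b, c, d))$cramer_v, phi, tolerance = 1e-9)
})

test_that("Cramer's V is permutation invariant, symmetric, and zero under independence", {
  m <- matrix(c(12, 30, 9, 44, 5, 17), nrow = 2, byrow = TRUE)
  v0 <- cramers_v(m)$cramer_v
  expect_equal(cramers_v(m[2:1, ])$cramer_v, v0)
  expect_equal(cramers_v(m[, c(2, 3, 1)])$cramer_v, v0)
  expect_equal(cramers_v(t(m))$cramer_v, v0)
  ind <- outer(c(30, 60), c(0.2, 0.5, 0.3))  # identical row distributions
  expect_equal(cramers_v(ind)$cramer_v, 0, tolerance = 1e-9)
  expect_error(cramers_v(matrix(1:3, 1)), class = "trauma_bad_table")
})

test_that("2x2 construction counts severity against outcomes over gradeable organs", {
  t <- build_two_by_two(toy_cohort(), "AAST1994", "spleen", "death")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 0, 1, 1))
  # degenerate: all mild survivors
  co <- cohort(list(patient_record("A", "splenic", spleen_findings = spleen_lac(2)),
                    patient_record("B", "splenic", spleen_findings = spleen_lac(0.5))))
  t2 <- build_two_by_two(co, "CTSI", "spleen", "death")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(0, 0, 0, 2))
  # no gradeable livers -> empty-table error
  expect_error(build_two_by_two(co, "CTSI", "liver", "death"),
               class = "trauma_empty_table")
  # any_OM is the composite of primary OM and secondary OM
  co3 <- cohort(list(
    patient_record("A", "splenic", spleen_findings = spleen_lac(2),
                   primary_management = "OM"),
    patient_record("B", "splenic", spleen_findings = spleen_lac(2),
                   primary_management = "NOM", secondary_om = TRUE),
    patient_record("C", "splenic", spleen_findings = spleen_lac(2))))
  t3 <- build_two_by_two(co3, "CTSI", "spleen", "any_OM")
  expect_equal(c(t3$c, t3$d), c(2, 1))
})

test_that("validate_scheme equals the composition of its parts", {
  co <- toy_cohort()
  vs <- validate_scheme(co, "CTSI", "spleen", "death")
  t <- build_two_by_two(co, "CTSI", "spleen", "death")
  expect_equal(vs$table, t)
  expect_equal(vs$diagnostics, diagnostic_metrics(t))
  expect_equal(vs$association, cramers_v(t))
  # single patient: degenerate flags, no crash
  one <- cohort(list(patient_record("A", "splenic",
                                    spleen_findings = spleen_lac(2))))
  expect_no_error(v1 <- validate_scheme(one, "CTSI", "spleen", "death"))
  expect_true(v1$association$degenerate)
  expect_false(v1$diagnostics$ppv_defined)
})

test_that("reclassification matrices conserve patients and track severity changes", {
  co <- toy_cohort()
  same <- reclassification_matrix(co, "spleen", "AAST1994", "AAST1994")
  expect_equal(same$n_changed, 0)
  expect_true(all(same$matrix[row(same$matrix) != col(same$matrix)] == 0))
  expect_equal(sum(same$matrix), length(co))

  # laceration 2 cm + pseudoaneurysm: 1994 II -> 2018 IV, upstaged
  one <- cohort(list(patient_record("A", "splenic",
    spleen_findings = organ_findings("spleen",
      lacerations = list(laceration(2)),
      vascular = vascular_features(pseudoaneurysm = TRUE)))))
  rc <- reclassification_matrix(one, "spleen", "AAST1994", "AAST2018")
  expect_equal(rc$matrix["II", "IV"], 1)
  expect_equal(sum(rc$matrix), 1)
  expect_equal(rc$n_upstaged_mild_to_severe, 1)
  expect_equal(rc$n_changed, 1)

  # CTSI IVa aligns with AAST IV: no "change" for a IV -> IVa move
  sev <- cohort(list(patient_record("A", "splenic",
    spleen_findings = organ_findings("spleen",
      lacerations = list(laceration(4, involves_segmental_or_hilar_vessels = TRUE,
                                    devascularisation_pct = 40)),
      vascular = vascular_features(av_fistula = TRUE)))))
  rc2 <- reclassification_matrix(sev, "spleen", "AAST1994", "CTSI")
  expect_equal(rc2$matrix["IV", "IVa"], 1)
  expect_equal(rc2$n_changed, 0)
  expect_equal(rc2$n_upstaged_mild_to_severe + rc2$n_downstaged_severe_to_mild, 0)
})
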