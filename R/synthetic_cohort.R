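## Seeded synthetic-cohort generator.
##
## Cohorts are assembled from a bank of findings templates.  Each template
## realizes one joint grade profile (1994-AAST, 2018-AAST, CTSI) with
## numeric jitter confined to the open interior of the grade brackets, so
## instantiation can never flip a grade; the generator re-grades every
## instantiated organ with the rule engines and stops on any divergence.
## Outcomes (death, primary OM, secondary OM after failed NOM) are drawn
## conditional on the CTSI mild/severe stratum of the driving organ.

template <- function(name, organ, profile, build) {
  list(name = name, organ = organ,
       profile = c(AAST1994 = profile[[1]], AAST2018 = profile[[2]],
                   CTSI = profile[[3]]),
       build = build)
}

## num(lo, hi): continuous measurement, drawn uniformly and rounded to
## 0.1 cm (the measurement resolution); ranges keep a >= 0.15 cm margin to
## every grading boundary so rounding stays inside the bracket.
## pct(lo, hi): integer percentage.

spleen_templates <- function() list(
  template("spleen_I_I_I", "spleen", c("I", "I", "I"),
    function(num, pct) organ_findings("spleen", haematomas = list(
      haematoma("subcapsular", size_cm = num(0.2, 0.8),
                surface_area_pct = pct(2, 8))))),
  template("spleen_II_II_I", "spleen", c("II", "II", "I"),
    function(num, pct) organ_findings("spleen", lacerations = list(
      laceration(depth_cm = num(0.2, 0.8)),
      laceration(depth_cm = num(0.2, 0.8))))),
  template("spleen_II_II_II", "spleen", c("II", "II", "II"),
    function(num, pct) organ_findings("spleen", lacerations = list(
      laceration(depth_cm = num(1.2, 2.8))))),
  template("spleen_III_III_II", "spleen", c("III", "III", "II"),
    function(num, pct) organ_findings("spleen", lacerations = list(
      laceration(depth_cm = num(1.2, 2.8),
                 involves_trabecular_vessels = TRUE)))),
  template("spleen_IV_IV_II", "spleen", c("IV", "IV", "II"),
    function(num, pct) organ_findings("spleen", lacerations = list(
      laceration(depth_cm = num(1.2, 2.8),
                 involves_segmental_or_hilar_vessels = TRUE,
                 devascularisation_pct = pct(30, 60))))),
  template("spleen_III_III_III", "spleen", c("III", "III", "III"),
    function(num, pct) organ_findings("spleen", lacerations = list(
      laceration(depth_cm = num(3.2, 7.5))))),
  template("spleen_IV_IV_III", "spleen", c("IV", "IV", "III"),
    function(num, pct) organ_findings("spleen", lacerations = list(
      laceration(depth_cm = num(3.2, 7.5),
                 involves_segmental_or_hilar_vessels = TRUE,
                 devascularisation_pct = pct(30, 60))))),
  template("spleen_V_IV_III", "spleen", c("V", "IV", "III"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5))),
      vascular = vascular_features(hilar_devascularising_injury = TRUE))),
  template("spleen_III_IV_IVa", "spleen", c("III", "IV", "IVa"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5))),
      vascular = vascular_features(pseudoaneurysm = TRUE))),
  template("spleen_II_IV_IVa", "spleen", c("II", "IV", "IVa"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(1.2, 2.8))),
      vascular = vascular_features(pseudoaneurysm = TRUE))),
  template("spleen_IV_IV_IVa", "spleen", c("IV", "IV", "IVa"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5),
        involves_segmental_or_hilar_vessels = TRUE,
        devascularisation_pct = pct(30, 60))),
      vascular = vascular_features(av_fistula = TRUE))),
  template("spleen_V_V_IVa", "spleen", c("V", "V", "IVa"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5))),
      vascular = vascular_features(shattered = TRUE))),
  template("spleen_IV_V_IVb", "spleen", c("IV", "V", "IVb"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5),
        involves_segmental_or_hilar_vessels = TRUE,
        devascularisation_pct = pct(30, 60))),
      vascular = vascular_features(active_bleeding = "intraperitoneal"))),
  template("spleen_V_V_IVb", "spleen", c("V", "V", "IVb"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5))),
      vascular = vascular_features(shattered = TRUE,
                                   active_bleeding = "intraperitoneal"))),
  template("spleen_III_V_IVb", "spleen", c("III", "V", "IVb"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(3.2, 7.5))),
      vascular = vascular_features(active_bleeding = "intraperitoneal"))),
  template("spleen_II_V_IVb", "spleen", c("II", "V", "IVb"),
    function(num, pct) organ_findings("spleen",
      lacerations = list(laceration(depth_cm = num(1.2, 2.8))),
      vascular = vascular_features(active_bleeding = "intraperitoneal")))
)

liver_templates <- function() list(
  template("liver_I_I_I", "liver", c("I", "I", "I"),
    function(num, pct) organ_findings("liver", haematomas = list(
      haematoma("subcapsular", size_cm = num(0.2, 0.8),
                surface_area_pct = pct(2, 8))))),
  template("liver_I_I_II", "liver", c("I", "I", "II"),
    function(num, pct) organ_findings("liver", haematomas = list(
      haematoma("subcapsular", size_cm = num(1.2, 4.5),
                surface_area_pct = pct(2, 8))))),
  template("liver_II_II_I", "liver", c("II", "II", "I"),
    function(num, pct) organ_findings("liver", haematomas = list(
      haematoma("subcapsular", size_cm = num(0.2, 0.8),
                surface_area_pct = pct(12, 45))))),
  template("liver_II_II_II", "liver", c("II", "II", "II"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(1.2, 2.8))))),
  template("liver_II_II_III", "liver", c("II", "II", "III"),
    function(num, pct) organ_findings("liver", haematomas = list(
      haematoma("intraparenchymal", size_cm = num(5.2, 9.5))))),
  template("liver_III_III_II", "liver", c("III", "III", "II"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(3.2, 4.8))))),
  template("liver_III_III_III", "liver", c("III", "III", "III"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(5.2, 12))))),
  template("liver_III_III_IVa", "liver", c("III", "III", "IVa"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(3.2, 4.8))),
      vascular = vascular_features(active_bleeding = "intraparenchymal"))),
  template("liver_III_IV_IVb", "liver", c("III", "IV", "IVb"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(3.2, 4.8))),
      vascular = vascular_features(active_bleeding = "intraperitoneal"))),
  template("liver_IV_IV_II", "liver", c("IV", "IV", "II"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(1.2, 2.8),
                 parenchymal_disruption_pct_of_lobe = pct(30, 70),
                 couinaud_segments_involved = 2L)))),
  template("liver_IV_IV_III", "liver", c("IV", "IV", "III"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(5.2, 12),
                 parenchymal_disruption_pct_of_lobe = pct(30, 70),
                 couinaud_segments_involved = 2L)))),
  template("liver_IV_IV_IVa", "liver", c("IV", "IV", "IVa"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(5.2, 12),
        parenchymal_disruption_pct_of_lobe = pct(30, 70),
        couinaud_segments_involved = 2L)),
      vascular = vascular_features(pseudoaneurysm = TRUE))),
  template("liver_IV_IV_IVb", "liver", c("IV", "IV", "IVb"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(5.2, 12),
        parenchymal_disruption_pct_of_lobe = pct(30, 70),
        couinaud_segments_involved = 2L)),
      vascular = vascular_features(active_bleeding = "intraperitoneal"))),
  template("liver_V_IV_III", "liver", c("V", "IV", "III"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(5.2, 12),
                 parenchymal_disruption_pct_of_lobe = pct(30, 70),
                 couinaud_segments_involved = 5L)))),
  template("liver_V_V_III", "liver", c("V", "V", "III"),
    function(num, pct) organ_findings("liver", lacerations = list(
      laceration(depth_cm = num(5.2, 12),
                 parenchymal_disruption_pct_of_lobe = pct(78, 95))))),
  template("liver_V_V_IVa", "liver", c("V", "V", "IVa"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(5.2, 12),
        parenchymal_disruption_pct_of_lobe = pct(78, 95))),
      vascular = vascular_features(shattered = TRUE))),
  template("liver_V_V_IVb", "liver", c("V", "V", "IVb"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(5.2, 12),
        parenchymal_disruption_pct_of_lobe = pct(78, 95))),
      vascular = vascular_features(active_bleeding = "intraperitoneal"))),
  template("liver_V_V_II", "liver", c("V", "V", "II"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(1.2, 2.8))),
      vascular = vascular_features(juxtavenous_injury = TRUE))),
  template("liver_VI_V_IVa", "liver", c("VI", "V", "IVa"),
    function(num, pct) organ_findings("liver",
      lacerations = list(laceration(depth_cm = num(5.2, 12),
        parenchymal_disruption_pct_of_lobe = pct(78, 95))),
      vascular = vascular_features(avulsion = TRUE)))
)

midpoint_num <- function(lo, hi) round((lo + hi) / 2, 1)
midpoint_pct <- function(lo, hi) as.integer(round((lo + hi) / 2))

instantiate_template <- function(tpl, num, pct) tpl$build(num, pct)

check_template_roundtrip <- function(tpl, num = midpoint_num,
                                     pct = midpoint_pct) {
  fnd <- instantiate_template(tpl, num, pct)
  got <- vapply(SCHEMES, function(s) grade_organ(fnd, s)$value, character(1))
  identical(unname(got), unname(tpl$profile))
}

#' Build the findings-template bank
#'
#' One template per joint grade profile (1994-AAST, 2018-AAST, CTSI) used
#' by the default cohort configuration, plus extra profiles exercised in
#' tests (juxtavenous injury, hepatic avulsion).  Every template is
#' round-trip checked at construction: grading its instantiated findings
#' with the rule engines must reproduce the intended profile at the
#' bracket midpoints and at both bracket edges.
#'
#' @param verify Run the round-trip check (default `TRUE`).
#' @return Named list of templates.
#' @export
build_template_bank <- function(verify = TRUE) {
  bank <- c(spleen_templates(), liver_templates())
  names(bank) <- vapply(bank, `[[`, character(1), "name")
  if (verify) {
    for (tpl in bank) {
      ok <- check_template_roundtrip(tpl) &&
        check_template_roundtrip(tpl, num = function(lo, hi) round(lo, 1),
                                 pct = function(lo, hi) as.integer(lo)) &&
        check_template_roundtrip(tpl, num = function(lo, hi) round(hi, 1),
                                 pct = function(lo, hi) as.integer(hi))
      if (!ok)
        trauma_error("trauma_template_error", sprintf(
          "template '%s' does not re-grade to its intended profile", tpl$name))
    }
  }
  bank
}

## Configuration ------------------------------------------------------------

#' Default synthetic-cohort configuration
#'
#' Emulates the structure of the reference registry: 703 patients split
#' 271 splenic / 352 hepatic / 80 combined; per-organ joint grade-profile
#' distributions whose marginals reproduce the published per-scheme grade
#' counts exactly; outcome rates per CTSI severity stratum (death and
#' primary OM) and per injury group (secondary OM among NOM patients); and
#' a 2/80 chance that a combined-injury patient's spleen lesion is visible
#' only intraoperatively (ungradeable, `surgical_only`).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @return An object of class `cohort_config`.
#' @export
default_config <- function(n_patients = 703, seed = 1L) {
  spleen_counts <- c(
    spleen_I_I_I = 38, spleen_II_II_I = 1, spleen_II_II_II = 61,
    spleen_III_III_II = 10, spleen_IV_IV_II = 6, spleen_III_III_III = 127,
    spleen_IV_IV_III = 15, spleen_V_IV_III = 4, spleen_III_IV_IVa = 27,
    spleen_II_IV_IVa = 2, spleen_IV_IV_IVa = 4, spleen_V_V_IVa = 20,
    spleen_IV_V_IVb = 22, spleen_V_V_IVb = 5, spleen_III_V_IVb = 6,
    spleen_II_V_IVb = 1)
  liver_counts <- c(
    liver_I_I_I = 30, liver_I_I_II = 12, liver_II_II_I = 2,
    liver_II_II_II = 81, liver_II_II_III = 8, liver_III_III_II = 42,
    liver_III_III_III = 158, liver_III_III_IVa = 10, liver_III_IV_IVb = 5,
    liver_IV_IV_II = 3, liver_IV_IV_III = 52, liver_IV_IV_IVa = 5,
    liver_IV_IV_IVb = 6, liver_V_IV_III = 3, liver_V_V_III = 8,
    liver_V_V_IVa = 7)
  cohort_config(
    n_patients = n_patients,
    injury_group_probs = c(splenic = 271, hepatic = 352, combined = 80) / 703,
    profile_probs = list(
      spleen = spleen_counts / sum(spleen_counts),
      liver = liver_counts / sum(liver_counts)),
    outcome_rates = list(
      death = list(spleen = c(mild = 8 / 262, severe = 9 / 87),
                   liver = c(mild = 20 / 399, severe = 4 / 33)),
      primary_om = list(spleen = c(mild = 42 / 262, severe = 54 / 87),
                        liver = c(mild = 30 / 399, severe = 12 / 33)),
      secondary_om = c(splenic = 0.057, hepatic = 0.018, combined = 0.051)),
    surgical_only_spleen_prob = 2 / 80,
    seed = seed)
}

#' Construct and validate a cohort configuration
#'
#' @param n_patients Positive integer.
#' @param injury_group_probs Probabilities over splenic/hepatic/combined
#'   (must sum to 1).
#' @param profile_probs Per organ, a named probability vector over joint
#'   grade-profile templates; names must exist in the template bank and the
#'   distribution must sum to 1.
#' @param outcome_rates Nested list: `death` and `primary_om` rates per
#'   organ and CTSI severity stratum, `secondary_om` per injury group
#'   (conditional on primary NOM).
#' @param surgical_only_spleen_prob Probability that a combined-injury
#'   patient's spleen is CT-occult.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, injury_group_probs, profile_probs,
                          outcome_rates, surgical_only_spleen_prob = 0,
                          seed = 1L) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    injury_group_probs = injury_group_probs,
    profile_probs = profile_probs,
    outcome_rates = outcome_rates,
    surgical_only_spleen_prob = surgical_only_spleen_prob,
    seed = as.integer(seed)), class = "cohort_config")
  v <- validate_config(cfg)
  if (length(v))
    trauma_error("trauma_config_error", paste(v, collapse = "; "))
  cfg
}

#' @rdname cohort_config
#' @param config A `cohort_config` candidate.
#' @return `validate_config()`: character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (!is_num(config$n_patients) || config$n_patients < 1)
    v <- c(v, "n_patients: must be a positive integer")
  p <- config$injury_group_probs
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8 ||
      !setequal(names(p), INJURY_GROUPS))
    v <- c(v, "injury_group_probs: must be a named 3-simplex over splenic/hepatic/combined")
  bank <- build_template_bank(verify = FALSE)
  for (organ in ORGANS) {
    pp <- config$profile_probs[[organ]]
    if (is.null(pp) || any(pp < 0) || abs(sum(pp) - 1) > 1e-8) {
      v <- c(v, sprintf("profile_probs$%s: must be a probability distribution", organ))
      next
    }
    missing_tpl <- setdiff(names(pp)[pp > 0], names(bank))
    if (length(missing_tpl))
      v <- c(v, sprintf("profile_probs$%s: no template for profile(s) %s",
                        organ, paste(missing_tpl, collapse = ", ")))
    wrong <- names(pp)[pp > 0][vapply(names(pp)[pp > 0], function(nm)
      !is.null(bank[[nm]]) && bank[[nm]]$organ != organ, logical(1))]
    if (length(wrong))
      v <- c(v, sprintf("profile_probs$%s: template(s) %s belong to another organ",
                        organ, paste(wrong, collapse = ", ")))
  }
  for (ou in c("death", "primary_om")) {
    for (organ in ORGANS) {
      r <- config$outcome_rates[[ou]][[organ]]
      if (length(r) != 2 || any(is.na(r)) || any(r < 0) || any(r > 1) ||
          !setequal(names(r), c("mild", "severe")))
        v <- c(v, sprintf("outcome_rates$%s$%s: must be mild/severe probabilities", ou, organ))
    }
  }
  so <- config$outcome_rates$secondary_om
  if (length(so) != 3 || any(so < 0) || any(so > 1) ||
      !setequal(names(so), INJURY_GROUPS))
    v <- c(v, "outcome_rates$secondary_om: must be per-group probabilities")
  sp <- config$surgical_only_spleen_prob
  if (!is_num(sp) || sp < 0 || sp > 1)
    v <- c(v, "surgical_only_spleen_prob: must be a probability")
  if (!is_num(config$seed))
    v <- c(v, "seed: must be an integer")
  v
}

## Generator ----------------------------------------------------------------

rng_num <- function(lo, hi) round(stats::runif(1, lo, hi), 1)
rng_pct <- function(lo, hi) as.integer(sample(seq(as.integer(lo), as.integer(hi)), 1))

#' Generate a synthetic cohort
#'
#' Deterministic given the configuration (seed included).  Each patient
#' draws an injury group, then per injured organ a joint grade-profile
#' template which is instantiated with in-bracket metric jitter and
#' re-graded with the rule engines (generation stops on any divergence —
#' no silent drift between generator and graders).  Death and primary OM
#' are drawn conditional on the CTSI severity of the driving organ (the
#' organ with the more severe CTSI grade; ties go to the spleen); secondary
#' OM is drawn among NOM patients per injury group.  Ground-truth stratum
#' bookkeeping is attached as `attr(, "truth")`.
#'
#' @param config A [cohort_config()] (default [default_config()]).
#' @return A [cohort()] with per-patient findings and outcomes.
#' @export
generate_cohort <- function(config = default_config()) {
  v <- validate_config(config)
  if (length(v))
    trauma_error("trauma_config_error", paste(v, collapse = "; "))
  bank <- build_template_bank()
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_patients
  groups <- sample(INJURY_GROUPS, n, replace = TRUE,
                   prob = config$injury_group_probs[INJURY_GROUPS])
  patients <- vector("list", n)
  sev <- list(spleen = character(n), liver = character(n))  # "", mild, severe
  for (i in seq_len(n)) {
    grp <- groups[[i]]
    has <- c(spleen = grp %in% c("splenic", "combined"),
             liver = grp %in% c("hepatic", "combined"))
    sp_occult <- grp == "combined" &&
      stats::runif(1) < config$surgical_only_spleen_prob
    findings <- list(spleen = NULL, liver = NULL)
    for (organ in ORGANS) {
      if (!has[[organ]]) next
      if (organ == "spleen" && sp_occult) {
        findings$spleen <- organ_findings("spleen", surgical_only = TRUE)
        next
      }
      pp <- config$profile_probs[[organ]]
      tpl <- bank[[sample(names(pp), 1, prob = pp)]]
      fnd <- instantiate_template(tpl, rng_num, rng_pct)
      for (s in SCHEMES) {
        got <- grade_organ(fnd, s)$value
        if (!identical(got, unname(tpl$profile[[s]])))
          trauma_error("trauma_template_error", sprintf(
            "template '%s': instantiated findings graded %s under %s (expected %s)",
            tpl$name, got, s, tpl$profile[[s]]))
      }
      findings[[organ]] <- fnd
      sev[[organ]][i] <- grade_organ(fnd, "CTSI")$severity
    }
    driver <- if (nzchar(sev$spleen[i]) &&
                  (sev$spleen[i] == "severe" || !nzchar(sev$liver[i]) ||
                   sev$liver[i] == "mild")) "spleen" else "liver"
    dsev <- sev[[driver]][i]
    death <- stats::runif(1) < config$outcome_rates$death[[driver]][[dsev]]
    pom <- stats::runif(1) < config$outcome_rates$primary_om[[driver]][[dsev]]
    som <- !pom && stats::runif(1) < config$outcome_rates$secondary_om[[grp]]
    meta <- list(
      age = max(16L, min(95L, as.integer(round(stats::rnorm(1, 32.9, 18))))),
      sex = if (stats::runif(1) < 0.681) "M" else "F",
      iss = max(1L, min(75L, as.integer(round(stats::rnorm(1, 27, 12.7))))),
      gcs = max(3L, min(15L, as.integer(round(stats::rnorm(1, 13, 3.6))))))
    patients[[i]] <- patient_record(
      patient_id = sprintf("P%05d", i),
      injury_group = grp,
      spleen_findings = findings$spleen,
      liver_findings = findings$liver,
      death_in_hospital = death,
      primary_management = if (pom) "OM" else "NOM",
      secondary_om = som,
      metadata = meta)
  }
  out <- cohort(patients, provenance = sprintf(
    "synthetic cohort: n=%d, seed=%d, default-structure generator", n, config$seed))
  truth <- list(
    config = config,
    group_counts = table(factor(groups, levels = INJURY_GROUPS)),
    severity_counts = lapply(sev, function(s)
      table(factor(s[nzchar(s)], levels = c("mild", "severe")))))
  attr(out, "truth") <- truth
  out
}
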