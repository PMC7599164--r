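# Small builders used across test files.

spleen_lac <- function(depth, ...) {
  organ_findings("spleen", lacerations = list(laceration(depth_cm = depth, ...)))
}

liver_lac <- function(depth, ...) {
  organ_findings("liver", lacerations = list(laceration(depth_cm = depth, ...)))
}

# A valid three-patient toy cohort: one severe death, one mild death,
# one mild survivor (under every scheme).
toy_cohort <- function() {
  shattered <- organ_findings("spleen",
    lacerations = list(laceration(4)),
    vascular = vascular_features(shattered = TRUE))
  cohort(list(
    patient_record("T1", "splenic", spleen_findings = shattered,
                   death_in_hospital = TRUE, primary_management = "OM"),
    patient_record("T2", "splenic", spleen_findings = spleen_lac(2),
                   death_in_hospital = TRUE),
    patient_record("T3", "splenic", spleen_findings = spleen_lac(0.5))))
}

# Random gradeable findings bundle for property-style tests (caller seeds).
random_findings <- function(organ) {
  n_lac <- sample(0:3, 1)
  n_hem <- sample(0:2, 1)
  lacs <- replicate(n_lac, {
    if (organ == "spleen")
      laceration(depth_cm = round(stats::runif(1, 0, 8), 1),
                 involves_trabecular_vessels = stats::runif(1) < 0.2,
                 involves_segmental_or_hilar_vessels = stats::runif(1) < 0.2,
                 devascularisation_pct = sample(0:60, 1))
    else
      laceration(depth_cm = round(stats::runif(1, 0, 8), 1),
                 parenchymal_disruption_pct_of_lobe = sample(c(0, 0, 30, 60, 85), 1),
                 couinaud_segments_involved = sample(0:5, 1))
  }, simplify = FALSE)
  hems <- replicate(n_hem, {
    loc <- sample(c("subcapsular", "intraparenchymal"), 1)
    haematoma(loc, size_cm = round(stats::runif(1, 0, 12), 1),
              surface_area_pct = if (loc == "subcapsular") sample(0:70, 1) else 0,
              ruptured = stats::runif(1) < 0.15,
              expanding = stats::runif(1) < 0.15)
  }, simplify = FALSE)
  vas <- vascular_features(
    pseudoaneurysm = stats::runif(1) < 0.15,
    av_fistula = stats::runif(1) < 0.1,
    active_bleeding = sample(c("none", "none", "intraparenchymal",
                               "subcapsular", "intraperitoneal"), 1),
    juxtavenous_injury = organ == "liver" && stats::runif(1) < 0.1,
    hilar_devascularising_injury = organ == "spleen" && stats::runif(1) < 0.1,
    shattered = stats::runif(1) < 0.1,
    avulsion = organ == "liver" && stats::runif(1) < 0.05)
  f <- organ_findings(organ, lacerations = lacs, haematomas = hems, vascular = vas)
  if (!is_gradeable(f))
    f$lacerations <- list(laceration(depth_cm = round(stats::runif(1, 0.1, 6), 1)))
  f
}
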