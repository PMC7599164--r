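#' @keywords internal
"_PACKAGE"

## Shared vocabulary --------------------------------------------------------

ORGANS <- c("spleen", "liver")
SCHEMES <- c("AAST1994", "AAST2018", "CTSI")
INJURY_GROUPS <- c("splenic", "hepatic", "combined")
BLEEDING_LEVELS <- c("none", "intraparenchymal", "subcapsular", "intraperitoneal")
AAST_VALUES <- c("I", "II", "III", "IV", "V", "VI")
CTSI_VALUES <- c("I", "II", "III", "IVa", "IVb")

`%||%` <- function(x, y) if (is.null(x)) y else x

trauma_error <- function(class, message) {
  stop(structure(
    class = c(class, "trauma_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

## Findings -----------------------------------------------------------------

#' Construct a laceration finding
#'
#' One parenchymal laceration (capsular tear) of the spleen or liver as
#' abstracted from contrast-enhanced CT.  Measurements are in centimetres
#' and percent; vessel-involvement flags refer to the splenic trabecular and
#' segmental/hilar vasculature, while lobe disruption and Couinaud segment
#' counts quantify hepatic parenchymal destruction.
#'
#' @param depth_cm Parenchymal depth of the laceration in cm (>= 0).
#' @param involves_trabecular_vessels Spleen only: laceration reaches a
#'   trabecular vessel.
#' @param involves_segmental_or_hilar_vessels Spleen only: laceration
#'   involves segmental or hilar vessels.
#' @param devascularisation_pct Spleen only: percentage of the organ
#'   devascularised (0-100).
#' @param parenchymal_disruption_pct_of_lobe Liver only: percentage of the
#'   hepatic lobe disrupted (0-100).
#' @param couinaud_segments_involved Liver only: number of Couinaud segments
#'   involved (0-8).
#' @return An object of class `trauma_laceration`.
#' @export
laceration <- function(depth_cm = 0,
                       involves_trabecular_vessels = FALSE,
                       involves_segmental_or_hilar_vessels = FALSE,
                       devascularisation_pct = 0,
                       parenchymal_disruption_pct_of_lobe = 0,
                       couinaud_segments_involved = 0L) {
  structure(list(
    depth_cm = depth_cm,
    involves_trabecular_vessels = involves_trabecular_vessels,
    involves_segmental_or_hilar_vessels = involves_segmental_or_hilar_vessels,
    devascularisation_pct = devascularisation_pct,
    parenchymal_disruption_pct_of_lobe = parenchymal_disruption_pct_of_lobe,
    couinaud_segments_involved = as.integer(couinaud_segments_involved)
  ), class = "trauma_laceration")
}

#' Construct a haematoma finding
#'
#' @param location `"subcapsular"` or `"intraparenchymal"`.
#' @param size_cm Depth (subcapsular) or diameter (intraparenchymal) in cm.
#' @param surface_area_pct Subcapsular only: percentage of organ surface
#'   covered (0-100).
#' @param ruptured Haematoma has ruptured.
#' @param expanding Haematoma is expanding on serial imaging.
#' @return An object of class `trauma_haematoma`.
#' @export
haematoma <- function(location = c("subcapsular", "intraparenchymal"),
                      size_cm = 0,
                      surface_area_pct = 0,
                      ruptured = FALSE,
                      expanding = FALSE) {
  location <- match.arg(location)
  structure(list(
    location = location,
    size_cm = size_cm,
    surface_area_pct = surface_area_pct,
    ruptured = ruptured,
    expanding = expanding
  ), class = "trauma_haematoma")
}

#' Construct the vascular-feature record of one organ
#'
#' Non-morphological CT features: contrast extravasation (active bleeding,
#' by location), non-bleeding vascular injuries (pseudoaneurysm,
#' arteriovenous fistula), shattered organ, and organ-specific features
#' (juxtavenous hepatic injury, hepatic avulsion, hilar devascularising
#' splenic injury).
#'
#' @param pseudoaneurysm,av_fistula Non-bleeding vascular injury flags.
#' @param active_bleeding One of `"none"`, `"intraparenchymal"`,
#'   `"subcapsular"`, `"intraperitoneal"`.
#' @param juxtavenous_injury Liver only: retrohepatic vena cava / central
#'   hepatic vein injury.
#' @param hilar_devascularising_injury Spleen only: hilar vascular injury
#'   devascularising the spleen.
#' @param shattered Completely shattered organ.
#' @param avulsion Liver only: hepatic avulsion.
#' @return An object of class `trauma_vascular`.
#' @export
vascular_features <- function(pseudoaneurysm = FALSE,
                              av_fistula = FALSE,
                              active_bleeding = "none",
                              juxtavenous_injury = FALSE,
                              hilar_devascularising_injury = FALSE,
                              shattered = FALSE,
                              avulsion = FALSE) {
  structure(list(
    pseudoaneurysm = pseudoaneurysm,
    av_fistula = av_fistula,
    active_bleeding = active_bleeding,
    juxtavenous_injury = juxtavenous_injury,
    hilar_devascularising_injury = hilar_devascularising_injury,
    shattered = shattered,
    avulsion = avulsion
  ), class = "trauma_vascular")
}

#' Bundle the CT findings of one organ
#'
#' @param organ `"spleen"` or `"liver"`.
#' @param lacerations List of [laceration()] objects.
#' @param haematomas List of [haematoma()] objects.
#' @param vascular A [vascular_features()] object.
#' @param surgical_only The organ was injured but no lesion was visible on
#'   CT (detected intraoperatively only); such organs are ungradeable and
#'   excluded from grading denominators.
#' @return An object of class `trauma_organ_findings`.
#' @export
organ_findings <- function(organ = c("spleen", "liver"),
                           lacerations = list(),
                           haematomas = list(),
                           vascular = vascular_features(),
                           surgical_only = FALSE) {
  organ <- match.arg(organ)
  structure(list(
    organ = organ,
    lacerations = lacerations,
    haematomas = haematomas,
    vascular = vascular,
    surgical_only = surgical_only
  ), class = "trauma_organ_findings")
}

vascular_nontrivial <- function(v) {
  isTRUE(v$pseudoaneurysm) || isTRUE(v$av_fistula) ||
    (!is.null(v$active_bleeding) && !identical(v$active_bleeding, "none")) ||
    isTRUE(v$juxtavenous_injury) || isTRUE(v$hilar_devascularising_injury) ||
    isTRUE(v$shattered) || isTRUE(v$avulsion)
}

#' Is an organ-findings bundle gradeable?
#'
#' An organ is gradeable when it carries at least one laceration, haematoma,
#' or non-trivial vascular feature.  Organs flagged `surgical_only` carry no
#' CT-visible lesion and are not gradeable.
#'
#' @param findings A [organ_findings()] object (or `NULL`).
#' @return Logical flag.
#' @export
is_gradeable <- function(findings) {
  if (is.null(findings)) return(FALSE)
  if (isTRUE(findings$surgical_only)) return(FALSE)
  length(findings$lacerations) > 0L || length(findings$haematomas) > 0L ||
    vascular_nontrivial(findings$vascular)
}

## Patients and cohorts -----------------------------------------------------

#' Construct a patient record
#'
#' @param patient_id Unique identifier.
#' @param injury_group `"splenic"`, `"hepatic"` or `"combined"`.
#' @param spleen_findings,liver_findings Optional [organ_findings()].
#' @param death_in_hospital In-hospital death flag.
#' @param primary_management `"OM"` (any abdominal surgical intervention as
#'   primary strategy) or `"NOM"`.
#' @param secondary_om Surgery after initially non-operative management;
#'   only meaningful when `primary_management == "NOM"`.
#' @param metadata Opaque named list (age, sex, ISS, GCS, ...), carried but
#'   never used in grading or statistics.
#' @return An object of class `trauma_patient`.
#' @export
patient_record <- function(patient_id,
                           injury_group = c("splenic", "hepatic", "combined"),
                           spleen_findings = NULL,
                           liver_findings = NULL,
                           death_in_hospital = FALSE,
                           primary_management = c("NOM", "OM"),
                           secondary_om = FALSE,
                           metadata = list()) {
  injury_group <- match.arg(injury_group)
  primary_management <- match.arg(primary_management)
  structure(list(
    patient_id = as.character(patient_id),
    injury_group = injury_group,
    spleen_findings = spleen_findings,
    liver_findings = liver_findings,
    death_in_hospital = death_in_hospital,
    primary_management = primary_management,
    secondary_om = secondary_om,
    metadata = metadata
  ), class = "trauma_patient")
}

#' Construct a cohort
#'
#' @param patients List of [patient_record()] objects with unique ids.
#' @param provenance Free-text provenance (seed, config digest, source file).
#' @return An object of class `trauma_cohort`.
#' @export
cohort <- function(patients, provenance = "") {
  structure(list(patients = patients, provenance = provenance),
            class = "trauma_cohort")
}

#' @export
length.trauma_cohort <- function(x) length(x$patients)

#' @export
print.trauma_cohort <- function(x, ...) {
  groups <- vapply(x$patients, function(p) p$injury_group %||% NA_character_,
                   character(1))
  cat("<trauma_cohort> ", length(x$patients), " patients (",
      sum(groups == "splenic"), " splenic / ", sum(groups == "hepatic"),
      " hepatic / ", sum(groups == "combined"), " combined)\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

## Validation ---------------------------------------------------------------

validate_laceration <- function(l, organ, where) {
  v <- character(0)
  note <- function(field, rule) sprintf("%s/%s: %s", where, field, rule)
  if (!is_num(l$depth_cm %||% NA) || l$depth_cm < 0)
    v <- c(v, note("depth_cm", "must be a nonnegative length in cm"))
  for (f in c("devascularisation_pct", "parenchymal_disruption_pct_of_lobe")) {
    x <- l[[f]] %||% NA
    if (!is_num(x) || x < 0 || x > 100)
      v <- c(v, note(f, "must be a percentage in [0,100]"))
  }
  seg <- l$couinaud_segments_involved %||% NA
  if (!is_num(seg) || seg < 0 || seg > 8)
    v <- c(v, note("couinaud_segments_involved", "must be an integer in [0,8]"))
  for (f in c("involves_trabecular_vessels",
              "involves_segmental_or_hilar_vessels")) {
    if (!is_flag(l[[f]] %||% NA)) v <- c(v, note(f, "must be TRUE/FALSE"))
  }
  if (identical(organ, "liver")) {
    if (isTRUE(l$involves_trabecular_vessels))
      v <- c(v, note("involves_trabecular_vessels", "spleen-only field set on liver finding"))
    if (isTRUE(l$involves_segmental_or_hilar_vessels))
      v <- c(v, note("involves_segmental_or_hilar_vessels", "spleen-only field set on liver finding"))
    if (is_num(l$devascularisation_pct %||% NA) && l$devascularisation_pct > 0)
      v <- c(v, note("devascularisation_pct", "spleen-only field nonzero on liver finding"))
  }
  if (identical(organ, "spleen")) {
    if (is_num(l$parenchymal_disruption_pct_of_lobe %||% NA) &&
        l$parenchymal_disruption_pct_of_lobe > 0)
      v <- c(v, note("parenchymal_disruption_pct_of_lobe", "liver-only field nonzero on spleen finding"))
    if (is_num(seg) && seg > 0)
      v <- c(v, note("couinaud_segments_involved", "liver-only field nonzero on spleen finding"))
  }
  v
}

validate_haematoma <- function(h, where) {
  v <- character(0)
  note <- function(field, rule) sprintf("%s/%s: %s", where, field, rule)
  loc <- h$location %||% NA_character_
  if (!is.character(loc) || !loc %in% c("subcapsular", "intraparenchymal"))
    v <- c(v, note("location", "must be subcapsular or intraparenchymal"))
  if (!is_num(h$size_cm %||% NA) || h$size_cm < 0)
    v <- c(v, note("size_cm", "must be a nonnegative length in cm"))
  sa <- h$surface_area_pct %||% NA
  if (!is_num(sa) || sa < 0 || sa > 100)
    v <- c(v, note("surface_area_pct", "must be a percentage in [0,100]"))
  else if (identical(loc, "intraparenchymal") && sa > 0)
    v <- c(v, note("surface_area_pct", "only meaningful for subcapsular haematomas"))
  for (f in c("ruptured", "expanding"))
    if (!is_flag(h[[f]] %||% NA)) v <- c(v, note(f, "must be TRUE/FALSE"))
  v
}

validate_vascular <- function(vv, organ, where) {
  v <- character(0)
  note <- function(field, rule) sprintf("%s/%s: %s", where, field, rule)
  ab <- vv$active_bleeding %||% NA_character_
  if (!is.character(ab) || length(ab) != 1L || !ab %in% BLEEDING_LEVELS)
    v <- c(v, note("active_bleeding", "must be exactly one of none/intraparenchymal/subcapsular/intraperitoneal"))
  for (f in c("pseudoaneurysm", "av_fistula", "juxtavenous_injury",
              "hilar_devascularising_injury", "shattered", "avulsion"))
    if (!is_flag(vv[[f]] %||% NA)) v <- c(v, note(f, "must be TRUE/FALSE"))
  if (identical(organ, "spleen")) {
    if (isTRUE(vv$avulsion))
      v <- c(v, note("avulsion", "liver-only feature set on spleen"))
    if (isTRUE(vv$juxtavenous_injury))
      v <- c(v, note("juxtavenous_injury", "liver-only feature set on spleen"))
  }
  if (identical(organ, "liver") && isTRUE(vv$hilar_devascularising_injury))
    v <- c(v, note("hilar_devascularising_injury", "spleen-only feature set on liver"))
  v
}

validate_organ_findings <- function(f, where) {
  v <- character(0)
  if (is.null(f)) return(v)
  organ <- f$organ %||% NA_character_
  if (!is.character(organ) || !organ %in% ORGANS)
    return(sprintf("%s/organ: must be spleen or liver", where))
  for (i in seq_along(f$lacerations))
    v <- c(v, validate_laceration(f$lacerations[[i]], organ,
                                  sprintf("%s/lacerations[%d]", where, i)))
  for (i in seq_along(f$haematomas))
    v <- c(v, validate_haematoma(f$haematomas[[i]],
                                 sprintf("%s/haematomas[%d]", where, i)))
  v <- c(v, validate_vascular(f$vascular %||% list(), organ,
                              paste0(where, "/vascular")))
  empty <- length(f$lacerations) == 0L && length(f$haematomas) == 0L &&
    !vascular_nontrivial(f$vascular %||% list())
  if (empty && !isTRUE(f$surgical_only))
    v <- c(v, sprintf("%s: no laceration, haematoma or vascular feature (set surgical_only for CT-occult organs)", where))
  v
}

#' Validate a patient record against all type invariants
#'
#' Total function: violations are returned as a character vector, never
#' raised.  An empty vector means the record is well formed.
#'
#' @param record A [patient_record()] object.
#' @return Character vector of violation descriptions, each naming the field
#'   and the rule broken.
#' @export
validate_record <- function(record) {
  tryCatch({
    v <- character(0)
    if (!is.character(record$patient_id %||% NA_character_) ||
        !nzchar(record$patient_id %||% ""))
      v <- c(v, "patient_id: must be a non-empty identifier")
    grp <- record$injury_group %||% NA_character_
    if (!is.character(grp) || length(grp) != 1L || !grp %in% INJURY_GROUPS) {
      v <- c(v, "injury_group: must be splenic, hepatic or combined")
      grp <- NA_character_
    }
    has_sp <- !is.null(record$spleen_findings)
    has_lv <- !is.null(record$liver_findings)
    if (identical(grp, "splenic") && (!has_sp || has_lv))
      v <- c(v, "injury_group: splenic records must carry spleen findings only")
    if (identical(grp, "hepatic") && (!has_lv || has_sp))
      v <- c(v, "injury_group: hepatic records must carry liver findings only")
    if (identical(grp, "combined") && (!has_sp || !has_lv))
      v <- c(v, "injury_group: combined records must carry both organ findings")
    if (has_sp) {
      if (!identical(record$spleen_findings$organ %||% NA_character_, "spleen"))
        v <- c(v, "spleen_findings/organ: must be spleen")
      v <- c(v, validate_organ_findings(record$spleen_findings, "spleen_findings"))
    }
    if (has_lv) {
      if (!identical(record$liver_findings$organ %||% NA_character_, "liver"))
        v <- c(v, "liver_findings/organ: must be liver")
      v <- c(v, validate_organ_findings(record$liver_findings, "liver_findings"))
    }
    if (!is_flag(record$death_in_hospital %||% NA))
      v <- c(v, "death_in_hospital: must be TRUE/FALSE")
    pm <- record$primary_management %||% NA_character_
    if (!is.character(pm) || length(pm) != 1L || !pm %in% c("OM", "NOM"))
      v <- c(v, "primary_management: must be OM or NOM")
    if (!is_flag(record$secondary_om %||% NA))
      v <- c(v, "secondary_om: must be TRUE/FALSE")
    else if (isTRUE(record$secondary_om) && identical(pm, "OM"))
      v <- c(v, "secondary_om: may be TRUE only when primary_management is NOM")
    v
  }, error = function(e) sprintf("record: not interpretable (%s)", conditionMessage(e)))
}

#' Validate every record of a cohort
#'
#' @param x A [cohort()] object.
#' @return Character vector of violations prefixed with the patient index,
#'   plus duplicate-id violations; empty when the cohort is valid.
#' @export
validate_cohort <- function(x) {
  v <- character(0)
  ids <- vapply(x$patients, function(p) p$patient_id %||% NA_character_,
                character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, sprintf("patient_id: duplicated identifier '%s'", dup))
  for (i in seq_along(x$patients)) {
    vi <- validate_record(x$patients[[i]])
    if (length(vi)) v <- c(v, sprintf("patient %d (%s): %s", i, ids[[i]], vi))
  }
  v
}
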