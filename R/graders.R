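## Rule engines: 1994-AAST, 2018-AAST and CTSI grading of spleen and liver.
##
## Every criterion row of the three published grading tables is encoded as a
## standalone predicate over an organ-findings bundle; the engine evaluates
## all of them, returns the maximum satisfied grade, and records the fired
## rules as a trace.  Interval convention, fixed globally: "a-b cm" means
## a <= x <= b, "> b" strictly greater, "< a" strictly smaller, so a value
## on a printed boundary falls in the lower bracket and brackets partition.

grade_rank_map <- function(scheme) {
  if (scheme == "CTSI") CTSI_VALUES else AAST_VALUES
}

#' @rdname grade_organ
#' @param rank Integer grade rank.
#' @export
grade_value <- function(scheme, rank) grade_rank_map(scheme)[rank]

#' @rdname grade_organ
#' @param value Grade value string (e.g. `"III"`, `"IVa"`).
#' @export
grade_rank <- function(scheme, value) {
  r <- match(value, grade_rank_map(scheme))
  if (any(is.na(r)))
    trauma_error("trauma_bad_grade",
                 sprintf("unknown %s grade value '%s'", scheme,
                         paste(value[is.na(r)], collapse = ", ")))
  r
}

new_grade <- function(scheme, organ, rank, trace, warnings = character(0)) {
  structure(list(
    scheme = scheme,
    organ = organ,
    value = grade_value(scheme, rank),
    rank = as.integer(rank),
    severity = if (rank >= 4L) "severe" else "mild",
    trace = trace,
    warnings = warnings
  ), class = "injury_grade")
}

#' @export
print.injury_grade <- function(x, ...) {
  cat(sprintf("<injury_grade> %s %s grade %s (%s)\n",
              x$scheme, x$organ, x$value, x$severity))
  for (tr in x$trace)
    cat(sprintf("  [%s] %s\n", grade_value(x$scheme, tr$grade), tr$label))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

## Predicate helpers --------------------------------------------------------

any_lac <- function(f, p) {
  length(f$lacerations) > 0L &&
    any(vapply(f$lacerations, function(l) isTRUE(p(l)), logical(1)))
}

any_hem <- function(f, p) {
  length(f$haematomas) > 0L &&
    any(vapply(f$haematomas, function(h) isTRUE(p(h)), logical(1)))
}

subcap <- function(h) identical(h$location, "subcapsular")
parench <- function(h) identical(h$location, "intraparenchymal")

contained_bleeding <- function(v)
  v$active_bleeding %in% c("intraparenchymal", "subcapsular")

rule <- function(grade, label, test) list(grade = grade, label = label, test = test)

## Criterion tables ---------------------------------------------------------

rules_spleen_aast1994 <- function() list(
  rule(1L, "subcapsular haematoma < 10% surface area",
       function(f) any_hem(f, function(h) subcap(h) && h$surface_area_pct < 10)),
  rule(1L, "capsular tear < 1 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm < 1)),
  rule(2L, "subcapsular haematoma 10-50% surface area",
       function(f) any_hem(f, function(h) subcap(h) &&
                             h$surface_area_pct >= 10 && h$surface_area_pct <= 50)),
  rule(2L, "intraparenchymal haematoma < 5 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm < 5)),
  rule(2L, "laceration 1-3 cm depth not involving a trabecular vessel",
       function(f) any_lac(f, function(l) l$depth_cm >= 1 && l$depth_cm <= 3 &&
                             !isTRUE(l$involves_trabecular_vessels))),
  rule(3L, "subcapsular haematoma > 50% surface area or expanding",
       function(f) any_hem(f, function(h) subcap(h) &&
                             (h$surface_area_pct > 50 || isTRUE(h$expanding)))),
  rule(3L, "ruptured subcapsular or parenchymal haematoma",
       function(f) any_hem(f, function(h) isTRUE(h$ruptured))),
  rule(3L, "intraparenchymal haematoma >= 5 cm or expanding",
       function(f) any_hem(f, function(h) parench(h) &&
                             (h$size_cm >= 5 || isTRUE(h$expanding)))),
  rule(3L, "laceration > 3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm > 3)),
  rule(3L, "laceration involving trabecular vessels",
       function(f) any_lac(f, function(l) isTRUE(l$involves_trabecular_vessels))),
  rule(3L, "laceration involving segmental/hilar vessels, <= 25% devascularisation",
       function(f) any_lac(f, function(l)
         isTRUE(l$involves_segmental_or_hilar_vessels) &&
           l$devascularisation_pct <= 25)),
  rule(4L, "laceration involving segmental or hilar vessels with major devascularisation (> 25%)",
       function(f) any_lac(f, function(l)
         isTRUE(l$involves_segmental_or_hilar_vessels) &&
           l$devascularisation_pct > 25)),
  rule(5L, "completely shattered spleen",
       function(f) isTRUE(f$vascular$shattered)),
  rule(5L, "hilar vascular injury devascularising the spleen",
       function(f) isTRUE(f$vascular$hilar_devascularising_injury))
)

rules_spleen_aast2018 <- function() list(
  rule(1L, "subcapsular haematoma < 10% surface area",
       function(f) any_hem(f, function(h) subcap(h) && h$surface_area_pct < 10)),
  rule(1L, "capsular tear < 1 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm < 1)),
  rule(2L, "subcapsular haematoma 10-50% surface area",
       function(f) any_hem(f, function(h) subcap(h) &&
                             h$surface_area_pct >= 10 && h$surface_area_pct <= 50)),
  rule(2L, "intraparenchymal haematoma < 5 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm < 5)),
  rule(2L, "laceration 1-3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm >= 1 && l$depth_cm <= 3)),
  rule(3L, "subcapsular haematoma > 50% surface area",
       function(f) any_hem(f, function(h) subcap(h) && h$surface_area_pct > 50)),
  rule(3L, "ruptured subcapsular or parenchymal haematoma",
       function(f) any_hem(f, function(h) isTRUE(h$ruptured))),
  rule(3L, "intraparenchymal haematoma >= 5 cm",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm >= 5)),
  rule(3L, "laceration > 3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm > 3)),
  rule(3L, "laceration involving trabecular vessels",
       function(f) any_lac(f, function(l) isTRUE(l$involves_trabecular_vessels))),
  rule(3L, "laceration involving segmental/hilar vessels, <= 25% devascularisation",
       function(f) any_lac(f, function(l)
         isTRUE(l$involves_segmental_or_hilar_vessels) &&
           l$devascularisation_pct <= 25)),
  rule(4L, "laceration involving segmental or hilar vessels producing > 25% devascularisation",
       function(f) any_lac(f, function(l)
         isTRUE(l$involves_segmental_or_hilar_vessels) &&
           l$devascularisation_pct > 25)),
  rule(4L, "splenic vascular injury (pseudoaneurysm or AV fistula)",
       function(f) isTRUE(f$vascular$pseudoaneurysm) || isTRUE(f$vascular$av_fistula)),
  rule(4L, "active bleeding confined within the splenic capsule",
       function(f) contained_bleeding(f$vascular)),
  rule(4L, "hilar devascularising vascular injury",
       function(f) isTRUE(f$vascular$hilar_devascularising_injury)),
  rule(5L, "shattered spleen",
       function(f) isTRUE(f$vascular$shattered)),
  rule(5L, "active bleeding extending beyond the spleen into the peritoneum",
       function(f) identical(f$vascular$active_bleeding, "intraperitoneal"))
)

rules_spleen_ctsi <- function() list(
  rule(1L, "subcapsular haematoma < 1 cm depth",
       function(f) any_hem(f, function(h) subcap(h) && h$size_cm < 1)),
  rule(1L, "laceration < 1 cm depth",
       function(f) any_lac(f, function(l) l$depth_cm < 1)),
  rule(1L, "parenchymal haematoma < 1 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm < 1)),
  rule(2L, "subcapsular haematoma 1-3 cm depth",
       function(f) any_hem(f, function(h) subcap(h) &&
                             h$size_cm >= 1 && h$size_cm <= 3)),
  rule(2L, "laceration 1-3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm >= 1 && l$depth_cm <= 3)),
  rule(2L, "parenchymal haematoma 1-3 cm diameter",
       function(f) any_hem(f, function(h) parench(h) &&
                             h$size_cm >= 1 && h$size_cm <= 3)),
  rule(3L, "laceration > 3 cm depth",
       function(f) any_lac(f, function(l) l$depth_cm > 3)),
  rule(3L, "parenchymal haematoma > 3 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm > 3)),
  rule(3L, "subcapsular haematoma > 3 cm depth",
       function(f) any_hem(f, function(h) subcap(h) && h$size_cm > 3)),
  rule(4L, "active intraparenchymal or subcapsular splenic bleeding",
       function(f) contained_bleeding(f$vascular)),
  rule(4L, "splenic vascular injury (pseudoaneurysm or AV fistula)",
       function(f) isTRUE(f$vascular$pseudoaneurysm) || isTRUE(f$vascular$av_fistula)),
  rule(4L, "shattered spleen",
       function(f) isTRUE(f$vascular$shattered)),
  rule(5L, "active intraperitoneal bleeding",
       function(f) identical(f$vascular$active_bleeding, "intraperitoneal"))
)

rules_liver_aast1994 <- function() list(
  rule(1L, "subcapsular haematoma < 10% surface area",
       function(f) any_hem(f, function(h) subcap(h) && h$surface_area_pct < 10)),
  rule(1L, "capsular tear < 1 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm < 1)),
  rule(2L, "subcapsular haematoma 10-50% surface area",
       function(f) any_hem(f, function(h) subcap(h) &&
                             h$surface_area_pct >= 10 && h$surface_area_pct <= 50)),
  rule(2L, "intraparenchymal haematoma < 10 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm < 10)),
  rule(2L, "laceration 1-3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm >= 1 && l$depth_cm <= 3)),
  rule(3L, "subcapsular haematoma > 50% surface area or expanding",
       function(f) any_hem(f, function(h) subcap(h) &&
                             (h$surface_area_pct > 50 || isTRUE(h$expanding)))),
  rule(3L, "ruptured subcapsular or parenchymal haematoma",
       function(f) any_hem(f, function(h) isTRUE(h$ruptured))),
  rule(3L, "intraparenchymal haematoma >= 10 cm or expanding",
       function(f) any_hem(f, function(h) parench(h) &&
                             (h$size_cm >= 10 || isTRUE(h$expanding)))),
  rule(3L, "laceration > 3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm > 3)),
  rule(4L, "parenchymal disruption involving 25-75% of a hepatic lobe",
       function(f) any_lac(f, function(l)
         l$parenchymal_disruption_pct_of_lobe >= 25 &&
           l$parenchymal_disruption_pct_of_lobe <= 75)),
  rule(4L, "parenchymal disruption involving 1-3 Couinaud segments",
       function(f) any_lac(f, function(l)
         l$couinaud_segments_involved >= 1 && l$couinaud_segments_involved <= 3)),
  rule(5L, "parenchymal disruption involving > 75% of a hepatic lobe",
       function(f) any_lac(f, function(l)
         l$parenchymal_disruption_pct_of_lobe > 75)),
  rule(5L, "parenchymal disruption involving > 3 Couinaud segments",
       function(f) any_lac(f, function(l) l$couinaud_segments_involved > 3)),
  rule(5L, "juxtavenous hepatic injury (retrohepatic vena cava / central hepatic veins)",
       function(f) isTRUE(f$vascular$juxtavenous_injury)),
  rule(6L, "hepatic avulsion",
       function(f) isTRUE(f$vascular$avulsion))
)

rules_liver_aast2018 <- function() list(
  rule(1L, "subcapsular haematoma < 10% surface area",
       function(f) any_hem(f, function(h) subcap(h) && h$surface_area_pct < 10)),
  rule(1L, "capsular tear < 1 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm < 1)),
  rule(2L, "subcapsular haematoma 10-50% surface area",
       function(f) any_hem(f, function(h) subcap(h) &&
                             h$surface_area_pct >= 10 && h$surface_area_pct <= 50)),
  rule(2L, "intraparenchymal haematoma < 10 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm < 10)),
  rule(2L, "laceration 1-3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm >= 1 && l$depth_cm <= 3)),
  rule(3L, "subcapsular haematoma > 50% surface area",
       function(f) any_hem(f, function(h) subcap(h) && h$surface_area_pct > 50)),
  rule(3L, "ruptured subcapsular or parenchymal haematoma",
       function(f) any_hem(f, function(h) isTRUE(h$ruptured))),
  rule(3L, "intraparenchymal haematoma > 10 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm > 10)),
  rule(3L, "laceration > 3 cm parenchymal depth",
       function(f) any_lac(f, function(l) l$depth_cm > 3)),
  rule(3L, "vascular injury with active bleeding contained within the liver parenchyma",
       function(f) contained_bleeding(f$vascular)),
  rule(4L, "parenchymal disruption involving 25-75% of a hepatic lobe",
       function(f) any_lac(f, function(l)
         l$parenchymal_disruption_pct_of_lobe >= 25 &&
           l$parenchymal_disruption_pct_of_lobe <= 75)),
  rule(4L, "parenchymal disruption involving 1-3 Couinaud segments",
       function(f) any_lac(f, function(l)
         l$couinaud_segments_involved >= 1 && l$couinaud_segments_involved <= 3)),
  rule(4L, "vascular injury with active bleeding breaching into the peritoneum",
       function(f) identical(f$vascular$active_bleeding, "intraperitoneal")),
  rule(5L, "parenchymal disruption involving > 75% of a hepatic lobe",
       function(f) any_lac(f, function(l)
         l$parenchymal_disruption_pct_of_lobe > 75)),
  rule(5L, "juxtavenous hepatic injury (retrohepatic vena cava / central hepatic veins)",
       function(f) isTRUE(f$vascular$juxtavenous_injury))
)

rules_liver_ctsi <- function() list(
  rule(1L, "subcapsular haematoma < 1 cm depth",
       function(f) any_hem(f, function(h) subcap(h) && h$size_cm < 1)),
  rule(1L, "laceration < 1 cm depth",
       function(f) any_lac(f, function(l) l$depth_cm < 1)),
  rule(1L, "parenchymal haematoma < 1 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm < 1)),
  rule(2L, "subcapsular haematoma 1-5 cm depth",
       function(f) any_hem(f, function(h) subcap(h) &&
                             h$size_cm >= 1 && h$size_cm <= 5)),
  rule(2L, "laceration 1-5 cm depth",
       function(f) any_lac(f, function(l) l$depth_cm >= 1 && l$depth_cm <= 5)),
  rule(2L, "parenchymal haematoma 1-5 cm diameter",
       function(f) any_hem(f, function(h) parench(h) &&
                             h$size_cm >= 1 && h$size_cm <= 5)),
  rule(3L, "laceration > 5 cm depth",
       function(f) any_lac(f, function(l) l$depth_cm > 5)),
  rule(3L, "parenchymal haematoma > 5 cm diameter",
       function(f) any_hem(f, function(h) parench(h) && h$size_cm > 5)),
  rule(3L, "subcapsular haematoma > 5 cm depth",
       function(f) any_hem(f, function(h) subcap(h) && h$size_cm > 5)),
  rule(4L, "active intraparenchymal or subcapsular hepatic bleeding",
       function(f) contained_bleeding(f$vascular)),
  rule(4L, "hepatic vascular injury (pseudoaneurysm or AV fistula)",
       function(f) isTRUE(f$vascular$pseudoaneurysm) || isTRUE(f$vascular$av_fistula)),
  rule(4L, "shattered liver",
       function(f) isTRUE(f$vascular$shattered)),
  rule(5L, "active intraperitoneal bleeding",
       function(f) identical(f$vascular$active_bleeding, "intraperitoneal"))
)

.rule_cache <- new.env(parent = emptyenv())

grading_rules <- function(scheme, organ) {
  key <- paste(scheme, organ, sep = "_")
  if (is.null(.rule_cache[[key]])) {
    .rule_cache[[key]] <- switch(key,
      AAST1994_spleen = rules_spleen_aast1994(),
      AAST2018_spleen = rules_spleen_aast2018(),
      CTSI_spleen     = rules_spleen_ctsi(),
      AAST1994_liver  = rules_liver_aast1994(),
      AAST2018_liver  = rules_liver_aast2018(),
      CTSI_liver      = rules_liver_ctsi(),
      trauma_error("trauma_bad_scheme", sprintf("no rule table for %s", key))
    )
  }
  .rule_cache[[key]]
}

## Engine -------------------------------------------------------------------

#' Grade the CT findings of one organ under a classification scheme
#'
#' Evaluates every criterion of the requested scheme's grading table as a
#' standalone predicate and returns the maximum satisfied grade together
#' with an ordered trace of all fired rules.  For the AAST schemes the
#' multiple-injury upgrade ("advance one grade for multiple injuries up to
#' grade III") is applied afterwards; the CTSI has no such rule.
#'
#' A hepatic avulsion under a scheme without a grade VI (2018-AAST, CTSI)
#' is graded at the scheme maximum (V / IVa) with a warning in the trace.
#'
#' @param findings An [organ_findings()] bundle.
#' @param scheme `"AAST1994"`, `"AAST2018"` or `"CTSI"`.
#' @return An `injury_grade`: scheme, organ, `value` (ordinal grade),
#'   `rank`, `severity` (`"mild"`/`"severe"`), `trace` (list of fired rules
#'   with their grades) and `warnings`.
#' @export
grade_organ <- function(findings, scheme = c("AAST1994", "AAST2018", "CTSI")) {
  scheme <- match.arg(scheme)
  if (!inherits(findings, "trauma_organ_findings") ||
      !findings$organ %in% ORGANS)
    trauma_error("trauma_organ_mismatch", "findings must be a spleen or liver organ_findings bundle")
  if (!is_gradeable(findings))
    trauma_error("trauma_ungradeable",
                 sprintf("%s findings carry no gradeable lesion", findings$organ))
  organ <- findings$organ
  rules <- grading_rules(scheme, organ)
  fired <- Filter(function(r) isTRUE(r$test(findings)), rules)
  warnings <- character(0)
  if (length(fired)) {
    base_rank <- max(vapply(fired, `[[`, integer(1), "grade"))
  } else {
    base_rank <- 1L
    fired <- list(rule(1L, "no criterion satisfied; floor grade I", NULL))
  }
  trace <- lapply(fired, function(r) list(grade = r$grade, label = r$label))
  if (organ == "liver" && isTRUE(findings$vascular$avulsion) &&
      scheme != "AAST1994") {
    max_rank <- if (scheme == "CTSI") 4L else 5L
    if (base_rank < max_rank) {
      base_rank <- max_rank
      trace <- c(trace, list(list(grade = max_rank,
                                  label = "hepatic avulsion (scheme maximum)")))
    }
    warnings <- c(warnings, sprintf(
      "hepatic avulsion has no grade under %s; graded at the scheme maximum (%s)",
      scheme, grade_value(scheme, max_rank)))
  }
  g <- new_grade(scheme, organ, base_rank, trace, warnings)
  if (scheme != "CTSI") {
    n_inj <- length(findings$lacerations) + length(findings$haematomas)
    g <- apply_multiple_injury_upgrade(g, n_inj)
  }
  g
}

#' @rdname grade_organ
#' @export
grade_spleen <- function(findings, scheme = c("AAST1994", "AAST2018", "CTSI")) {
  if (!is.null(findings$organ) && !identical(findings$organ, "spleen"))
    trauma_error("trauma_organ_mismatch", "grade_spleen called on non-spleen findings")
  grade_organ(findings, scheme)
}

#' @rdname grade_organ
#' @export
grade_liver <- function(findings, scheme = c("AAST1994", "AAST2018", "CTSI")) {
  if (!is.null(findings$organ) && !identical(findings$organ, "liver"))
    trauma_error("trauma_organ_mismatch", "grade_liver called on non-liver findings")
  grade_organ(findings, scheme)
}

#' Apply the AAST multiple-injury upgrade
#'
#' "Advance one grade for multiple injuries up to grade III": with two or
#' more morphological injuries (lacerations plus haematomas), grades I and
#' II are advanced by one.  The rule never produces a grade above III and
#' does not exist for the CTSI.
#'
#' @param base An `injury_grade` under an AAST scheme.
#' @param injury_count Positive integer count of morphological injuries.
#' @return The (possibly upgraded) `injury_grade`.
#' @export
apply_multiple_injury_upgrade <- function(base, injury_count) {
  if (identical(base$scheme, "CTSI"))
    trauma_error("trauma_unsupported_rule",
                 "the multiple-injury upgrade does not exist for the CTSI")
  if (injury_count >= 2L && base$rank %in% c(1L, 2L)) {
    rank <- base$rank + 1L
    trace <- c(base$trace, list(list(
      grade = rank,
      label = sprintf("multiple injuries (%d): advanced one grade", injury_count))))
    return(new_grade(base$scheme, base$organ, rank, trace, base$warnings))
  }
  base
}

#' Dichotomize a grade into mild vs severe injury
#'
#' Grade I-III injuries are mild; everything above grade III (AAST IV-VI,
#' CTSI IVa/IVb) is severe.
#'
#' @param grade An `injury_grade`.
#' @return `"mild"` or `"severe"`.
#' @export
dichotomize <- function(grade) {
  if (!inherits(grade, "injury_grade"))
    trauma_error("trauma_bad_grade", "dichotomize expects an injury_grade")
  grade$severity
}

#' Grade every patient of a cohort under one or more schemes
#'
#' @param x A [cohort()] object.
#' @param schemes Character vector of schemes to apply.
#' @param organs Organs to grade (default both).
#' @return A data frame with one row per gradeable patient-organ-scheme:
#'   `patient_id`, `injury_group`, `organ`, `scheme`, `grade`, `rank`,
#'   `severity`.
#' @export
grade_cohort <- function(x, schemes = SCHEMES, organs = ORGANS) {
  schemes <- match.arg(schemes, SCHEMES, several.ok = TRUE)
  organs <- match.arg(organs, ORGANS, several.ok = TRUE)
  nmax <- length(x$patients) * length(organs) * length(schemes)
  id <- grp <- org <- sch <- val <- sev <- character(nmax)
  rnk <- integer(nmax)
  k <- 0L
  for (p in x$patients) {
    for (organ in organs) {
      fnd <- p[[paste0(organ, "_findings")]]
      if (!is_gradeable(fnd)) next
      for (scheme in schemes) {
        g <- grade_organ(fnd, scheme)
        k <- k + 1L
        id[k] <- p$patient_id; grp[k] <- p$injury_group
        org[k] <- organ; sch[k] <- scheme
        val[k] <- g$value; rnk[k] <- g$rank; sev[k] <- g$severity
      }
    }
  }
  i <- seq_len(k)
  data.frame(patient_id = id[i], injury_group = grp[i], organ = org[i],
             scheme = sch[i], grade = val[i], rank = rnk[i],
             severity = sev[i], stringsAsFactors = FALSE)
}
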