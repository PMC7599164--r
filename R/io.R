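## Cohort readers/writers (strict-schema CSV with numbered finding-column
## groups, and a nested JSON mirror) plus a fixed-precision report writer.
## Units are centimetres and percent throughout; files carrying other units
## are not supported.

META_FIELDS <- c("age", "sex", "iss", "gcs")

organ_prefix <- c(spleen = "sp", liver = "lv")

lac_fields <- function(organ) {
  if (organ == "spleen")
    c(depth_cm = "depth_cm", trabecular = "involves_trabecular_vessels",
      seg_hilar = "involves_segmental_or_hilar_vessels",
      devasc_pct = "devascularisation_pct")
  else
    c(depth_cm = "depth_cm",
      disruption_pct = "parenchymal_disruption_pct_of_lobe",
      segments = "couinaud_segments_involved")
}

hem_fields <- c(location = "location", size_cm = "size_cm",
                surface_pct = "surface_area_pct", ruptured = "ruptured",
                expanding = "expanding")

vas_fields <- function(organ) {
  common <- c(pseudoaneurysm = "pseudoaneurysm", av_fistula = "av_fistula",
              active_bleeding = "active_bleeding", shattered = "shattered")
  if (organ == "spleen") c(common, hilar_devasc = "hilar_devascularising_injury")
  else c(common, juxtavenous = "juxtavenous_injury", avulsion = "avulsion")
}

as01 <- function(x) as.integer(isTRUE(x))

cohort_column_dictionary <- function(n_lac, n_hem) {
  cols <- c("patient_id", "injury_group", "death_in_hospital",
            "primary_management", "secondary_om", META_FIELDS)
  for (organ in ORGANS) {
    p <- organ_prefix[[organ]]
    cols <- c(cols, paste0(p, "_present"), paste0(p, "_surgical_only"))
    for (k in seq_len(n_lac[[organ]]))
      cols <- c(cols, paste0(p, "_lac", k, "_", names(lac_fields(organ))))
    for (k in seq_len(n_hem[[organ]]))
      cols <- c(cols, paste0(p, "_hem", k, "_", names(hem_fields)))
    cols <- c(cols, paste0(p, "_", names(vas_fields(organ))))
  }
  cols
}

#' Write a cohort to disk
#'
#' CSV flattens findings into repeated numbered column groups
#' (`sp_lac1_depth_cm`, `lv_hem2_size_cm`, ...) plus per-organ vascular
#' flag columns; JSON mirrors the nested record structure.  Both formats
#' round-trip through [read_cohort()] field-for-field.
#'
#' @param x A [cohort()].
#' @param path Output file.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    payload <- list(provenance = x$provenance,
                    patients = lapply(x$patients, record_to_list))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = FALSE)
    return(invisible(path))
  }
  n_lac <- n_hem <- c(spleen = 1L, liver = 1L)
  for (p in x$patients) for (organ in ORGANS) {
    f <- p[[paste0(organ, "_findings")]]
    if (is.null(f)) next
    n_lac[[organ]] <- max(n_lac[[organ]], length(f$lacerations))
    n_hem[[organ]] <- max(n_hem[[organ]], length(f$haematomas))
  }
  cols <- cohort_column_dictionary(n_lac, n_hem)
  rows <- lapply(x$patients, function(p) {
    row <- stats::setNames(as.list(rep(NA, length(cols))), cols)
    row$patient_id <- p$patient_id
    row$injury_group <- p$injury_group
    row$death_in_hospital <- as01(p$death_in_hospital)
    row$primary_management <- p$primary_management
    row$secondary_om <- as01(p$secondary_om)
    for (mf in META_FIELDS) row[[mf]] <- p$metadata[[mf]] %||% NA
    for (organ in ORGANS) {
      pre <- organ_prefix[[organ]]
      f <- p[[paste0(organ, "_findings")]]
      row[[paste0(pre, "_present")]] <- as.integer(!is.null(f))
      if (is.null(f)) next
      row[[paste0(pre, "_surgical_only")]] <- as01(f$surgical_only)
      lf <- lac_fields(organ)
      for (k in seq_along(f$lacerations))
        for (short in names(lf)) {
          val <- f$lacerations[[k]][[lf[[short]]]]
          if (is.logical(val)) val <- as01(val)
          row[[paste0(pre, "_lac", k, "_", short)]] <- val
        }
      for (k in seq_along(f$haematomas))
        for (short in names(hem_fields)) {
          val <- f$haematomas[[k]][[hem_fields[[short]]]]
          if (is.logical(val)) val <- as01(val)
          row[[paste0(pre, "_hem", k, "_", short)]] <- val
        }
      vf <- vas_fields(organ)
      for (short in names(vf)) {
        val <- f$vascular[[vf[[short]]]]
        if (is.logical(val)) val <- as01(val)
        row[[paste0(pre, "_", short)]] <- val
      }
    }
    row
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

record_to_list <- function(p) {
  findings_to_list <- function(f) {
    if (is.null(f)) return(NULL)
    list(organ = f$organ,
         surgical_only = f$surgical_only,
         lacerations = lapply(f$lacerations, unclass),
         haematomas = lapply(f$haematomas, unclass),
         vascular = unclass(f$vascular))
  }
  list(patient_id = p$patient_id,
       injury_group = p$injury_group,
       spleen_findings = findings_to_list(p$spleen_findings),
       liver_findings = findings_to_list(p$liver_findings),
       death_in_hospital = p$death_in_hospital,
       primary_management = p$primary_management,
       secondary_om = p$secondary_om,
       metadata = p$metadata)
}

list_to_record <- function(l) {
  findings_from_list <- function(fl) {
    if (is.null(fl)) return(NULL)
    organ_findings(
      organ = fl$organ,
      lacerations = lapply(fl$lacerations, function(x) do.call(laceration, x)),
      haematomas = lapply(fl$haematomas, function(x) do.call(haematoma, x)),
      vascular = do.call(vascular_features, fl$vascular),
      surgical_only = isTRUE(fl$surgical_only))
  }
  patient_record(
    patient_id = l$patient_id,
    injury_group = l$injury_group,
    spleen_findings = findings_from_list(l$spleen_findings),
    liver_findings = findings_from_list(l$liver_findings),
    death_in_hospital = isTRUE(l$death_in_hospital),
    primary_management = l$primary_management,
    secondary_om = isTRUE(l$secondary_om),
    metadata = lapply(l$metadata, function(x) x))
}

known_column <- function(nm) {
  fixed <- c("patient_id", "injury_group", "death_in_hospital",
             "primary_management", "secondary_om", META_FIELDS)
  if (nm %in% fixed) return(TRUE)
  pat <- c(
    "^(sp|lv)_(present|surgical_only)$",
    "^sp_lac[0-9]+_(depth_cm|trabecular|seg_hilar|devasc_pct)$",
    "^lv_lac[0-9]+_(depth_cm|disruption_pct|segments)$",
    "^(sp|lv)_hem[0-9]+_(location|size_cm|surface_pct|ruptured|expanding)$",
    "^(sp|lv)_(pseudoaneurysm|av_fistula|active_bleeding|shattered)$",
    "^sp_hilar_devasc$", "^lv_(juxtavenous|avulsion)$")
  any(vapply(pat, function(p) grepl(p, nm), logical(1)))
}

cell <- function(df, i, col, default = NA) {
  if (!col %in% names(df)) return(default)
  x <- df[[col]][i]
  if (is.na(x) || identical(x, "")) default else x
}

row_to_findings <- function(df, i, organ) {
  pre <- organ_prefix[[organ]]
  present <- cell(df, i, paste0(pre, "_present"), 0)
  if (!isTRUE(as.numeric(present) == 1)) return(NULL)
  if (isTRUE(as.numeric(cell(df, i, paste0(pre, "_surgical_only"), 0)) == 1))
    return(organ_findings(organ, surgical_only = TRUE))
  lf <- lac_fields(organ)
  lacs <- list()
  k <- 1L
  repeat {
    cols <- paste0(pre, "_lac", k, "_", names(lf))
    if (!any(cols %in% names(df))) break
    vals <- lapply(cols, function(cn) cell(df, i, cn))
    if (all(vapply(vals, function(v) is.na(v), logical(1)))) { k <- k + 1L; next }
    args <- list()
    for (j in seq_along(lf)) {
      v <- vals[[j]]
      field <- lf[[j]]
      if (field %in% c("involves_trabecular_vessels",
                       "involves_segmental_or_hilar_vessels"))
        v <- isTRUE(as.numeric(v %||% 0) == 1)
      else v <- as.numeric(v %||% 0)
      if (is.na(suppressWarnings(v)) && !is.logical(v)) v <- 0
      args[[field]] <- if (is.logical(v)) v else ifelse(is.na(v), 0, v)
    }
    lacs[[length(lacs) + 1L]] <- do.call(laceration, args)
    k <- k + 1L
    if (k > 50L) break
  }
  hems <- list()
  k <- 1L
  repeat {
    cols <- paste0(pre, "_hem", k, "_", names(hem_fields))
    if (!any(cols %in% names(df))) break
    vals <- stats::setNames(lapply(cols, function(cn) cell(df, i, cn)),
                            names(hem_fields))
    if (all(vapply(vals, function(v) is.na(v), logical(1)))) { k <- k + 1L; next }
    hems[[length(hems) + 1L]] <- haematoma(
      location = as.character(vals$location %||% "subcapsular"),
      size_cm = ifelse(is.na(as.numeric(vals$size_cm)), 0, as.numeric(vals$size_cm)),
      surface_area_pct = ifelse(is.na(as.numeric(vals$surface_pct)), 0,
                                as.numeric(vals$surface_pct)),
      ruptured = isTRUE(as.numeric(vals$ruptured %||% 0) == 1),
      expanding = isTRUE(as.numeric(vals$expanding %||% 0) == 1))
    k <- k + 1L
    if (k > 50L) break
  }
  vf <- vas_fields(organ)
  vargs <- list()
  for (short in names(vf)) {
    v <- cell(df, i, paste0(pre, "_", short))
    field <- vf[[short]]
    if (field == "active_bleeding")
      vargs[[field]] <- as.character(v %||% "none")
    else vargs[[field]] <- isTRUE(as.numeric(v %||% 0) == 1)
  }
  if (is.na(vargs$active_bleeding)) vargs$active_bleeding <- "none"
  organ_findings(organ, lacerations = lacs, haematomas = hems,
                 vascular = do.call(vascular_features, vargs))
}

#' Read a cohort from disk
#'
#' Every record must pass [validate_record()]; the reader fails listing all
#' violations with their row numbers.  Unknown columns are rejected unless
#' `allow_extra = TRUE` (strict schema).  Patients with missing outcome
#' fields are rejected unless `outcomes_optional = TRUE`, in which case
#' they are dropped with a message.
#'
#' @param path Input file (CSV or JSON).
#' @param format `"csv"`, `"json"` or `"auto"` (by extension).
#' @param allow_extra Tolerate unknown columns.
#' @param outcomes_optional Drop (rather than reject) patients with missing
#'   outcome fields.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json"),
                        allow_extra = FALSE, outcomes_optional = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path))
    trauma_error("trauma_io_error", sprintf("file not found: %s", path))
  if (format == "json") {
    payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    patients <- lapply(payload$patients, list_to_record)
    out <- cohort(patients, provenance = payload$provenance %||% path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    unknown <- Filter(Negate(known_column), names(df))
    if (length(unknown) && !allow_extra)
      trauma_error("trauma_io_error", sprintf(
        "unknown column(s) rejected by strict schema: %s",
        paste(unknown, collapse = ", ")))
    has_outcomes <- !is.na(df$death_in_hospital) & !is.na(df$primary_management) &
      df$primary_management != "" & !is.na(df$secondary_om)
    if (any(!has_outcomes)) {
      if (!outcomes_optional)
        trauma_error("trauma_io_error", sprintf(
          "missing outcome fields in row(s) %s (use outcomes_optional to drop them)",
          paste(which(!has_outcomes), collapse = ", ")))
      message(sprintf("read_cohort: dropping %d patient(s) with missing outcomes",
                      sum(!has_outcomes)))
      df <- df[has_outcomes, , drop = FALSE]
    }
    patients <- lapply(seq_len(nrow(df)), function(i) {
      meta <- list()
      for (mf in META_FIELDS) {
        v <- cell(df, i, mf)
        if (!is.na(v)) meta[[mf]] <- v
      }
      patient_record(
        patient_id = as.character(df$patient_id[i]),
        injury_group = as.character(df$injury_group[i]),
        spleen_findings = row_to_findings(df, i, "spleen"),
        liver_findings = row_to_findings(df, i, "liver"),
        death_in_hospital = as.numeric(df$death_in_hospital[i]) == 1,
        primary_management = as.character(df$primary_management[i]),
        secondary_om = as.numeric(df$secondary_om[i]) == 1,
        metadata = meta)
    })
    out <- cohort(patients, provenance = path)
  }
  violations <- validate_cohort(out)
  if (length(violations))
    trauma_error("trauma_validation_error", paste0(
      "cohort failed validation:\n  ", paste(violations, collapse = "\n  ")))
  out
}

#' Write a results report
#'
#' Numeric metric columns are serialized at 4 significant digits, p-value
#' columns at 3; column order is preserved (deterministic output).
#'
#' @param results Non-empty data frame of results.
#' @param path Output file.
#' @param format `"csv"`, `"json"` or `"md"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json", "md")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0L)
    trauma_error("trauma_io_error", "results must be a non-empty data frame")
  fmt <- results
  for (nm in names(fmt)) {
    if (!is.numeric(fmt[[nm]])) next
    digits <- if (grepl("^p_value$|^p$", nm)) 3 else 4
    fmt[[nm]] <- signif(fmt[[nm]], digits)
  }
  if (format == "csv") {
    utils::write.csv(fmt, path, row.names = FALSE, na = "")
  } else if (format == "json") {
    jsonlite::write_json(fmt, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    header <- paste0("| ", paste(names(fmt), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|")
    body <- apply(fmt, 1, function(r)
      paste0("| ", paste(as.character(r), collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}
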