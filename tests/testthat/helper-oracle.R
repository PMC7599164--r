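# Independent brute-force grader: a hand-written if-cascade per scheme and
# organ, evaluated from the highest criterion row downwards, kept separate
# from the package's data-driven rule engine on purpose.  Shares the
# engine's documented interval conventions (closed printed brackets,
# strict < / >) and design choices (segmental/hilar involvement without
# major devascularisation grades III; hilar devascularising injury grades
# IV under 2018; avulsion grades at the scheme maximum outside 1994).

oracle_features <- function(f) {
  lac <- f$lacerations; hem <- f$haematomas
  pick <- function(xs, fld, default) {
    if (!length(xs)) return(default[0])
    vapply(xs, function(x) x[[fld]], default)
  }
  loc <- pick(hem, "location", character(1))
  list(
    depth = pick(lac, "depth_cm", numeric(1)),
    trab = pick(lac, "involves_trabecular_vessels", logical(1)),
    seg = pick(lac, "involves_segmental_or_hilar_vessels", logical(1)),
    dev = pick(lac, "devascularisation_pct", numeric(1)),
    disr = pick(lac, "parenchymal_disruption_pct_of_lobe", numeric(1)),
    cseg = pick(lac, "couinaud_segments_involved", integer(1)),
    sub_sa = pick(hem, "surface_area_pct", numeric(1))[loc == "subcapsular"],
    sub_sz = pick(hem, "size_cm", numeric(1))[loc == "subcapsular"],
    sub_exp = pick(hem, "expanding", logical(1))[loc == "subcapsular"],
    par_sz = pick(hem, "size_cm", numeric(1))[loc == "intraparenchymal"],
    par_exp = pick(hem, "expanding", logical(1))[loc == "intraparenchymal"],
    rupt = pick(hem, "ruptured", logical(1)),
    v = f$vascular,
    ninj = length(lac) + length(hem))
}

oracle_upgrade <- function(g, ninj) {
  if (ninj >= 2 && g <= 2) g + 1L else g
}

oracle_spleen_1994 <- function(x) {
  v <- x$v
  g <- if (isTRUE(v$shattered) || isTRUE(v$hilar_devascularising_injury)) 5L
  else if (any(x$seg & x$dev > 25)) 4L
  else if (any(x$depth > 3) || any(x$trab) || any(x$seg & x$dev <= 25) ||
           any(x$rupt) || any(x$sub_sa > 50) || any(x$sub_exp) ||
           any(x$par_sz >= 5) || any(x$par_exp)) 3L
  else if (any(x$depth >= 1 & x$depth <= 3 & !x$trab) ||
           length(x$par_sz) && any(x$par_sz < 5) ||
           any(x$sub_sa >= 10 & x$sub_sa <= 50)) 2L
  else 1L
  oracle_upgrade(g, x$ninj)
}

oracle_spleen_2018 <- function(x) {
  v <- x$v
  contained <- v$active_bleeding %in% c("intraparenchymal", "subcapsular")
  g <- if (isTRUE(v$shattered) ||
           identical(v$active_bleeding, "intraperitoneal")) 5L
  else if (any(x$seg & x$dev > 25) || isTRUE(v$pseudoaneurysm) ||
           isTRUE(v$av_fistula) || contained ||
           isTRUE(v$hilar_devascularising_injury)) 4L
  else if (any(x$depth > 3) || any(x$trab) || any(x$seg & x$dev <= 25) ||
           any(x$rupt) || any(x$sub_sa > 50) || any(x$par_sz >= 5)) 3L
  else if (any(x$depth >= 1 & x$depth <= 3) ||
           length(x$par_sz) && any(x$par_sz < 5) ||
           any(x$sub_sa >= 10 & x$sub_sa <= 50)) 2L
  else 1L
  oracle_upgrade(g, x$ninj)
}

oracle_ctsi <- function(x, cut) {  # cut = 3 (spleen) or 5 (liver)
  v <- x$v
  sizes <- c(x$depth, x$sub_sz, x$par_sz)
  if (identical(v$active_bleeding, "intraperitoneal")) return(5L)
  if (v$active_bleeding %in% c("intraparenchymal", "subcapsular") ||
      isTRUE(v$pseudoaneurysm) || isTRUE(v$av_fistula) ||
      isTRUE(v$shattered) || isTRUE(v$avulsion)) return(4L)
  if (any(sizes > cut)) return(3L)
  if (any(sizes >= 1 & sizes <= cut)) return(2L)
  1L
}

oracle_liver_1994 <- function(x) {
  v <- x$v
  g <- if (isTRUE(v$avulsion)) 6L
  else if (isTRUE(v$juxtavenous_injury) || any(x$disr > 75) ||
           any(x$cseg > 3)) 5L
  else if (any(x$disr >= 25 & x$disr <= 75) ||
           any(x$cseg >= 1 & x$cseg <= 3)) 4L
  else if (any(x$depth > 3) || any(x$rupt) || any(x$sub_sa > 50) ||
           any(x$sub_exp) || any(x$par_sz >= 10) || any(x$par_exp)) 3L
  else if (any(x$depth >= 1 & x$depth <= 3) ||
           length(x$par_sz) && any(x$par_sz < 10) ||
           any(x$sub_sa >= 10 & x$sub_sa <= 50)) 2L
  else 1L
  oracle_upgrade(g, x$ninj)
}

oracle_liver_2018 <- function(x) {
  v <- x$v
  contained <- v$active_bleeding %in% c("intraparenchymal", "subcapsular")
  g <- if (isTRUE(v$juxtavenous_injury) || any(x$disr > 75) ||
           isTRUE(v$avulsion)) 5L
  else if (any(x$disr >= 25 & x$disr <= 75) ||
           any(x$cseg >= 1 & x$cseg <= 3) ||
           identical(v$active_bleeding, "intraperitoneal")) 4L
  else if (any(x$depth > 3) || any(x$rupt) || any(x$sub_sa > 50) ||
           any(x$par_sz > 10) || contained) 3L
  else if (any(x$depth >= 1 & x$depth <= 3) ||
           length(x$par_sz) && any(x$par_sz < 10) ||
           any(x$sub_sa >= 10 & x$sub_sa <= 50)) 2L
  else 1L
  oracle_upgrade(g, x$ninj)
}

oracle_grade <- function(findings, scheme) {
  x <- oracle_features(findings)
  rank <- switch(paste(scheme, findings$organ, sep = "_"),
    AAST1994_spleen = oracle_spleen_1994(x),
    AAST2018_spleen = oracle_spleen_2018(x),
    AAST1994_liver = oracle_liver_1994(x),
    AAST2018_liver = oracle_liver_2018(x),
    CTSI_spleen = oracle_ctsi(x, 3),
    CTSI_liver = oracle_ctsi(x, 5))
  grade_value(scheme, rank)
}

# Exhaustive boundary grid: one laceration x one subcapsular haematoma x
# vascular flag combinations, with organ-specific extra fields.
oracle_grid <- function(organ) {
  depths <- c(0.5, 1, 2, 3, 3.5, 5, 5.5, 10, 12)
  surfaces <- c(5, 10, 30, 50, 60)
  bleeds <- c("none", "intraparenchymal", "subcapsular", "intraperitoneal")
  cases <- list()
  if (organ == "spleen") {
    for (d in depths) for (s in surfaces) for (b in bleeds)
      for (psa in c(FALSE, TRUE)) for (sh in c(FALSE, TRUE))
        for (hil in c(FALSE, TRUE)) for (trab in c(FALSE, TRUE))
          for (seg in c(FALSE, TRUE)) {
            cases[[length(cases) + 1L]] <- organ_findings("spleen",
              lacerations = list(laceration(
                depth_cm = d, involves_trabecular_vessels = trab,
                involves_segmental_or_hilar_vessels = seg,
                devascularisation_pct = if (seg) 40 else 0)),
              haematomas = list(haematoma("subcapsular", size_cm = d / 2,
                                          surface_area_pct = s)),
              vascular = vascular_features(
                pseudoaneurysm = psa, active_bleeding = b,
                hilar_devascularising_injury = hil, shattered = sh))
          }
  } else {
    extras <- list(c(0, 0), c(50, 2), c(80, 5), c(50, 0), c(0, 5))
    vasc <- list(vascular_features(),
                 vascular_features(pseudoaneurysm = TRUE),
                 vascular_features(shattered = TRUE),
                 vascular_features(juxtavenous_injury = TRUE),
                 vascular_features(avulsion = TRUE))
    for (d in depths) for (s in surfaces) for (b in bleeds)
      for (e in extras) for (v0 in vasc) {
        v0$active_bleeding <- b
        cases[[length(cases) + 1L]] <- organ_findings("liver",
          lacerations = list(laceration(
            depth_cm = d, parenchymal_disruption_pct_of_lobe = e[1],
            couinaud_segments_involved = as.integer(e[2]))),
          haematomas = list(haematoma("subcapsular", size_cm = d / 2,
                                      surface_area_pct = s)),
          vascular = v0)
      }
  }
  cases
}

# Number of grid cases where engine and oracle disagree (0 when equivalent).
oracle_grid_mismatches <- function(organ) {
  bad <- 0L
  for (f in oracle_grid(organ)) {
    for (s in c("AAST1994", "AAST2018", "CTSI")) {
      if (!identical(grade_organ(f, s)$value, oracle_grade(f, s)))
        bad <- bad + 1L
    }
  }
  bad
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (probability-not-exceeding-observed rule).
fisher_enumeration_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
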