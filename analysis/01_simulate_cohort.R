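#!/usr/bin/env Rscript
# Step 1: simulate a registry-sized synthetic cohort (703 patients, the
# structure of the reference registry: 271 splenic / 352 hepatic / 80
# combined injuries) and write it to results/ in both CSV and JSON form.

suppressPackageStartupMessages(library(traumagrade))

dir.create("results", showWarnings = FALSE)

cfg <- default_config(seed = 1203L)
co <- generate_cohort(cfg)

stopifnot(length(validate_cohort(co)) == 0)

groups <- vapply(co$patients, `[[`, character(1), "injury_group")
deaths <- vapply(co$patients, function(p) isTRUE(p$death_in_hospital), logical(1))
nom <- vapply(co$patients, function(p)
  identical(p$primary_management, "NOM"), logical(1))

cat(sprintf("simulated %d patients (seed %d): %d splenic / %d hepatic / %d combined\n",
            length(co), cfg$seed, sum(groups == "splenic"),
            sum(groups == "hepatic"), sum(groups == "combined")))
cat(sprintf("primary NOM %.1f%%, in-hospital mortality %.1f%%\n",
            100 * mean(nom), 100 * mean(deaths)))

write_cohort(co, "results/cohort.csv")
write_cohort(co, "results/cohort.json")
cat("wrote results/cohort.csv and results/cohort.json\n")
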