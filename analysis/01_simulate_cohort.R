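#!/usr/bin/env Rscript
# Step 1: simulate the two-group gait study this analysis emulates.
#
# Generates a synthetic cohort of 10 asymptomatic ("normal") and 11 OA-like
# subjects (medial load-line shift 0.04 m plus the slaved stiff-knee
# signatures), and writes each subject's trial to disk in the pipeline's
# interchange formats: TRC-style marker trajectories at 100 Hz and per-foot
# force-plate CSVs at 1000 Hz, plus a cohort manifest.  Everything
# downstream reads these files, never the in-memory objects, so the full
# I/O path is exercised.

suppressMessages(library(oagait))

seed <- as.integer(Sys.getenv("OAGAIT_SEED", "1"))
out_dir <- file.path("results", "analysis", "cohort")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating cohort (seed ", seed, ") ...")
coh <- generate_cohort(n_normal = 10, n_oa = 11, severity = 0.04,
                       seed = seed, n_cycles = 1)

for (s in coh$subjects) {
  write_markers(s$trial$markers, file.path(out_dir, paste0(s$id, "_markers.trc")))
  for (p in s$trial$plates) {
    write_forceplate(p, file.path(out_dir, sprintf("%s_plate%d.csv", s$id,
                                                   p$plate_id)))
  }
}

manifest <- coh$manifest
manifest$severity <- ifelse(manifest$group == "oa", coh$severity, 0)
# segment lengths so step 2 can rebuild each subject's scaled model exactly
for (seg in c("pelvis", "thigh", "shank", "foot")) {
  manifest[[paste0("len_", seg)]] <- vapply(coh$subjects, function(s)
    unname(s$model$segment_lengths[seg]), numeric(1))
}
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
jsonlite::write_json(list(seed = seed, n_normal = 10, n_oa = 11,
                          severity = coh$severity, n_cycles = 1),
                     file.path(out_dir, "cohort_config.json"),
                     auto_unbox = TRUE)

message("Wrote ", nrow(manifest), " subjects (",
        sum(manifest$group == "normal"), " normal, ",
        sum(manifest$group == "oa"), " OA-like) to ", out_dir)
message("Body mass: normal ", round(mean(manifest$mass[manifest$group == "normal"]), 1),
        " kg, OA ", round(mean(manifest$mass[manifest$group == "oa"]), 1), " kg")
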