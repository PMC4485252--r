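#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Builds the data the downstream stages consume:
#   * 30 gaze-centred images (bright, uniform sky above; variegated 1/f
#     ground below),
#   * a base 7-participant x 10-run session whose generative percent-signal-
#     change amplitudes carry the presentation x source interaction (lower
#     field: 0.80 below-source vs 0.72 above; upper field: 0.84 vs 0.85),
#   * a second session with an additional image-level plant: an upper-field
#     preference proportional to each patch's luminance, which ties the
#     image-level exploratory analyses (stages 3-4) to the image set.
# Writes example event tables and the truth record alongside.

suppressPackageStartupMessages(library(vfasym))

seed <- 2026
out <- "results"
dir.create(file.path(out, "events"), showWarnings = FALSE, recursive = TRUE)

message("generating 30 synthetic gaze-centred images ...")
images <- synth_image_set(scene_model(seed = seed))
saveRDS(images, file.path(out, "images.rds"))

message("simulating the base event-related session ...")
session <- simulate_session(seed = seed)
saveRDS(session, file.path(out, "session.rds"))
write_truth(session, file.path(out, "truth.yml"))

message("simulating the image-plant session ...")
# plant: upper-field preference proportional to patch luminance (pixel mean
# of each quadrant patch, z-scored over the 60 image x source entries)
lum <- do.call(rbind, lapply(seq_along(images), function(i) {
  p4 <- extract_quadrant_patches(images[[i]], 128, image_id = i)
  agg <- tapply(vapply(p4, function(p) mean(p$pixels), 0),
                vapply(p4, function(p) p$source_v, ""), mean)
  data.frame(image = i, source = names(agg), value = as.numeric(agg))
}))
z <- (lum$value - mean(lum$value)) / sd(lum$value)
effects <- setNames(0.3 * z, sprintf("%s_img%02d", lum$source, lum$image))
session_img <- simulate_session(condition_spec = "source_by_image",
                                image_effects = effects, seed = seed + 1)
saveRDS(session_img, file.path(out, "session_img.rds"))

# BIDS-style event tables for the first participant
for (r in seq_along(session$participants[[1]]$runs)) {
  write_events(session$participants[[1]]$runs[[r]],
               file.path(out, "events",
                         sprintf("sub-01_run-%02d_events.tsv", r)))
}

r1 <- session$participants[[1]]$runs[[1]]
message(sprintf("run 1: %d events per sequence, %d s, %s sequence advanced",
                nrow(r1$upper_seq), r1$duration, r1$advanced_seq))
message("done; images, sessions, truth and event tables are under results/")
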