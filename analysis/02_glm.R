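#!/usr/bin/env Rscript
# Stage 2 — response estimation.
#
# Runs the estimation chain: a localiser GLM per voxel (one regressor for
# all image events, two-sided p < 0.01 mask), spatial averaging within each
# mask, then condition GLMs on the averaged timecourses. The source-level
# fits on the base session use ARMA(1,1) prewhitening; the 60-regressor
# per-image fits on the planted session use OLS (the second-level analyses
# operate on the psc table). Betas are converted to percent signal change
# and written as CSV, together with the residual-by-lag diagnostic.

suppressPackageStartupMessages(library(vfasym))

out <- "results"
session <- readRDS(file.path(out, "session.rds"))
session_img <- readRDS(file.path(out, "session_img.rds"))

message("source-level GLMs (localiser mask, ARMA(1,1) prewhitening) ...")
resp <- fit_session(session, condition_spec = "source", whiten = "arma11",
                    localise = TRUE, localiser_whiten = "none")
write.csv(resp, file.path(out, "psc_by_source.csv"), row.names = FALSE)
print(aggregate(psc ~ presentation + source, resp, mean), digits = 3)

message("per-image GLMs (60 condition regressors) ...")
resp_img <- fit_session(session_img, condition_spec = "source_by_image")
write.csv(resp_img, file.path(out, "psc_by_image.csv"), row.names = FALSE)

message("model-quality diagnostic (residual error vs time after onset) ...")
p1 <- session$participants[[1]]
dm <- build_design_matrix(p1$runs, "lower", "source")
fit <- fit_glm(roi_average(p1$data$V1$lower), dm, whiten = "arma11")
curve <- residual_by_time_after_onset(fit, p1$runs)
write.csv(curve, file.path(out, "residual_by_lag.csv"), row.names = FALSE)
print(curve, digits = 3)
message("done; psc tables and diagnostics are under results/")
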