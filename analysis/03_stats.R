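#!/usr/bin/env Rscript
# Stage 3 — inference.
#
# Three-way repeated-measures ANOVA (area x presentation x source) with
# Huynh-Feldt correction on the image-averaged response table; paired
# comparisons of above vs below sources within each presentation location
# (areas combined); display normalisation; and the upper-/lower-preferred
# ranking of image patch pairs.

suppressPackageStartupMessages(library(vfasym))

out <- "results"
resp <- read.csv(file.path(out, "psc_by_source.csv"))
resp_img <- read.csv(file.path(out, "psc_by_image.csv"))

message("three-way repeated-measures ANOVA ...")
an <- rm_anova_3way(resp)
write.csv(as.data.frame(an), file.path(out, "anova.csv"), row.names = FALSE)
print(an[, c("effect", "F", "df1_corr", "df2_corr", "epsilon", "p")],
      digits = 3)

message("paired comparisons across participants (areas combined) ...")
part <- aggregate(psc ~ participant + presentation + source, resp, mean)
pick <- function(pres, src) {
  d <- part[part$presentation == pres & part$source == src, ]
  d$psc[order(d$participant)]
}
for (pres in c("lower", "upper")) {
  tt <- paired_t(pick(pres, "below"), pick(pres, "above"))
  message(sprintf("%s field, below vs above: t(%d) = %.2f, p = %.4f",
                  pres, tt$dof, tt$t, tt$p))
}

norm <- normalize_for_display(resp)
write.csv(norm, file.path(out, "psc_by_source_normalized.csv"),
          row.names = FALSE)

message("ranking image patch pairs on upper-minus-lower differences ...")
diffs <- response_diffs(resp_img)
write.csv(diffs, file.path(out, "presentation_diffs.csv"), row.names = FALSE)
ranks <- rank_preference(diffs, k = 5)
message("top-5 upper-preferred sources: ",
        paste(ranks$upper_preferred$source, collapse = ", "))
message("top-5 lower-preferred sources: ",
        paste(ranks$lower_preferred$source, collapse = ", "))
write.csv(rbind(cbind(list = "upper_preferred", ranks$upper_preferred),
                cbind(list = "lower_preferred", ranks$lower_preferred)),
          file.path(out, "preference_ranking.csv"), row.names = FALSE)
message("done; ANOVA, paired tests and rankings are under results/")
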