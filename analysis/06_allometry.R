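#!/usr/bin/env Rscript
# Stage 6: body condition allometry. Standardised major axis regressions of
# body mass on incisor width (and on body length) comparing single females
# with in-group non-breeding females, with bootstrap confidence intervals
# and the common-versus-separate allometry comparison.
#
#   Rscript analysis/06_allometry.R [seed]

suppressMessages(library(moleratdemog))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
out_dir <- "results/allometry"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
captures <- read_captures("results/synthetic/captures.csv")

fem <- captures[captures$sex == "F" & !captures$breeder, ]
fem$group_size <- moleratdemog:::group_capture_sizes(fem)
fem$class <- ifelse(fem$group_size == 1, "single", "ingroup")

for (xvar in c("incisor_width", "body_length")) {
  d <- fem[!is.na(fem[[xvar]]) & !is.na(fem$body_mass), ]
  fit <- sma_fit(d[[xvar]], d$body_mass, group = d$class, B = 1000,
                 seed = seed)
  cat(sprintf("\n== body mass ~ %s (n = %d)\n", xvar, nrow(d)))
  print(fit)
  write.csv(fit$lines,
            file.path(out_dir, paste0("sma_", xvar, ".csv")),
            row.names = FALSE)
  jsonlite::write_json(fit$comparison,
                       file.path(out_dir, paste0("sma_", xvar,
                                                 "_comparison.json")),
                       auto_unbox = TRUE, digits = NA)
}
cat("\nAllometry outputs written to", out_dir, "\n")
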