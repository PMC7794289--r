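#!/usr/bin/env Rscript
# Build the five redundant matched control groups and verify that each
# replicates the AD group's (age, sex, eye) multiset exactly.

library(retvasc)

dir.create("results/match", recursive = TRUE, showWarnings = FALSE)
tab <- read_subject_table("results/simulate/subjects.csv")

asg <- match_controls(tab, n_groups = 5, seed = 11)
jsonlite::write_json(asg$assignment, "results/match/assignment.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

ad <- tab[tab$diagnosis == "AD", ]
cat(sprintf("AD group: %d images, age %.2f (%.2f)\n",
            nrow(ad), mean(ad$age), sd(ad$age)))
for (g in 1:5) {
  rows <- tab[match(control_group_ids(asg, g), tab$image_id), ]
  stopifnot(identical(sort(paste(rows$age, rows$sex, rows$eye)),
                      sort(paste(ad$age, ad$sex, ad$eye))))
  cat(sprintf("control group %d: %d images, age %.2f (%.2f) -- identical multiset\n",
              g, nrow(rows), mean(rows$age), sd(rows$age)))
}
stopifnot(anyDuplicated(asg$assignment$nc_image_id) == 0)
cat("no NC image reused across groups\n")
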