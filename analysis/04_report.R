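#!/usr/bin/env Rscript
# Collect the headline numbers of the preceding analyses into one report.
# Run after 01-03; reads only files under results/.

suppressPackageStartupMessages(library(axokin))

need <- c("results/frap_fits.csv", "results/motility_summary.csv",
          "results/morphology_summary.csv")
missing <- need[!file.exists(need)]
if (length(missing))
  stop("run analysis scripts 01-03 first; missing: ",
       paste(missing, collapse = ", "))

frap <- read.csv("results/frap_fits.csv")
moti <- read.csv("results/motility_summary.csv")
morph <- read.csv("results/morphology_summary.csv")

speed <- moti[moti$statistic == "mean_run_speed", ]
ctrl <- speed$mean[speed$condition == "control"]
fl <- speed$mean[speed$condition == "map7_fl"]

report <- list(
  frap = lapply(seq_len(nrow(frap)), function(i) as.list(frap[i, ])),
  motility = list(
    run_speed = lapply(seq_len(nrow(speed)), function(i)
      as.list(speed[i, c("condition", "mean", "sem", "n_cells")])),
    speed_percent_decrease_fl = percent_change(ctrl, fl)
  ),
  morphology = lapply(seq_len(nrow(morph)), function(i) as.list(morph[i, ]))
)
write_summary_json(report, "results/report.json")
cat(sprintf("MAP7-FL run-speed decrease vs control: %.0f%%\n",
            percent_change(ctrl, fl)))
cat("wrote results/report.json\n")
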