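#!/usr/bin/env Rscript
# Thin command-line wrapper over frailpa::run_pipeline(): generates (or
# loads) a cohort, runs exclusions, frailty-index construction, epoch
# aggregation, joint/spline/interaction Cox models and life-expectancy
# estimation, and writes all tables to --out.

suppressPackageStartupMessages({
  library(optparse)
  library(frailpa)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 5000L,
              help = "participants to simulate [default %default]"),
  make_option("--seed", type = "integer", default = 20250L),
  make_option("--cohort", type = "character", default = NULL,
              help = "existing cohort CSV instead of simulating"),
  make_option("--awake-window", type = "character", default = "06:00-22:00",
              dest = "awake_window"),
  make_option("--exposures", type = "character", default = "tvpa,mvpa,lpa,st"),
  make_option("--exposure-source", type = "character", default = "epochs",
              dest = "exposure_source"),
  make_option("--impute", type = "character", default = "simple"),
  make_option("--bootstrap-runs", type = "integer", default = 10000L,
              dest = "bootstrap_runs"),
  make_option("--landmark", action = "store_true", default = FALSE),
  make_option("--exclude-shift-workers", action = "store_true",
              default = FALSE, dest = "exclude_shift_workers"),
  make_option("--complete-case", action = "store_true", default = FALSE,
              dest = "complete_case"),
  make_option("--out", type = "character", default = "frailpa_run")
)))

config <- pipeline_config(
  generator = cohort_config(n_participants = opts$n, seed = opts$seed,
                            n_epoch_participants = opts$n),
  cohort_path = opts$cohort,
  awake_window = opts$awake_window,
  exposures = strsplit(opts$exposures, ",")[[1]],
  exposure_source = opts$exposure_source,
  impute_method = opts$impute,
  bootstrap_runs = opts$bootstrap_runs,
  landmark = opts$landmark,
  exclude_shift_workers = opts$exclude_shift_workers,
  complete_case = opts$complete_case,
  seed = opts$seed,
  out_dir = opts$out
)

res <- run_pipeline(config)
message("Run complete: ", res$out_dir)
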