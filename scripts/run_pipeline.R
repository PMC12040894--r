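#!/usr/bin/env Rscript

# Thin command-line wrapper over agrisoc::run_all():
#   Rscript scripts/run_pipeline.R --out <dir> [--seed <int>]
#     [--profiles <csv> [--yields <csv>]] [--scope year|pooled]
#     [--max-depth <cm>] [--c-extra next-layer|same-layer]
# Without --profiles, the demonstration trial design is simulated.

suppressPackageStartupMessages(library(agrisoc))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = "pipeline-output", seed = 1L, profiles = NULL,
            yields = NULL, scope = "year", max_depth = 40,
            c_extra = "next-layer")
i <- 1
while (i <= length(args)) {
  key <- args[i]
  val <- args[i + 1]
  switch(key,
    "--out" = opt$out <- val,
    "--seed" = opt$seed <- as.integer(val),
    "--profiles" = opt$profiles <- val,
    "--yields" = opt$yields <- val,
    "--scope" = opt$scope <- val,
    "--max-depth" = opt$max_depth <- as.numeric(val),
    "--c-extra" = opt$c_extra <- val,
    stop("unknown argument: ", key)
  )
  i <- i + 2
}

cfg <- run_config(
  output_dir = opt$out,
  design = if (is.null(opt$profiles)) demo_design_spec(seed = opt$seed),
  profiles_path = opt$profiles,
  yields_path = opt$yields,
  esm = list(scope = opt$scope, max_depth_cm = opt$max_depth,
             c_extra = opt$c_extra),
  seed = opt$seed
)
manifest <- run_all(cfg)
cat("artifacts written to", opt$out, "(", length(manifest$files),
    "files )\n")
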