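#!/usr/bin/env Rscript
# Optional clinical-scale reproduction on PTB-XL v1.0.3.  Requires a local
# download of the corpus (https://physionet.org/content/ptb-xl/1.0.3/),
# several hours of CPU/GPU time, and is NOT part of the test surface.
#
# Usage: Rscript scripts/reproduce_ptbxl.R --data <ptbxl_dir> [--fs 100]
#                [--arch cnn|vgg] [--seed 1] [--out results/ptbxl]
#
# Runs the binary superclass scenarios and the 5-class scenario end-to-end
# and writes test-set evaluation reports for qualitative comparison with
# published accuracies.

suppressPackageStartupMessages(library(ecgfusion))

args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
data_dir <- opt("--data")
if (is.null(data_dir)) stop("--data <ptbxl_dir> is required", call. = FALSE)
fs <- as.integer(opt("--fs", "100"))
arch <- if (identical(opt("--arch", "cnn"), "vgg")) "vgg_style" else "custom_cnn"
seed <- as.integer(opt("--seed", "1"))
out_dir <- opt("--out", "results/ptbxl")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

message("loading corpus (this reads every waveform; expect several minutes)")
corp <- load_corpus(data_dir, fs = fs)

scenarios <- c(lapply(c("MI", "CD", "STTC", "HYP"), binary_superclass),
               list(binary_normal_abnormal(), multiclass(5)))
for (sc in scenarios) {
  message("=== scenario ", sc$name, " ===")
  sets <- materialize_splits(sc, corp)
  cfg <- model_config(arch, num_classes = sc$k, input_length = 10L * fs)
  fit <- train(build_model(cfg, seed = seed), sets$train, sets$validation,
               train_config(seed = seed, verbose = TRUE))
  rep <- evaluate(fit, sets$test)
  print(rep)
  report_to_json(rep, file.path(out_dir, paste0(sc$name, ".json")))
}
message("reports written to ", out_dir)
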