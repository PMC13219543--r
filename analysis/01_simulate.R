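#!/usr/bin/env Rscript
# Stage 1 -- generate the three synthetic datasets the downstream analyses
# consume, each with known ground truth:
#   * aequorin luminescence traces carrying planted Ca2+ transients,
#   * paired transcript/protein fold-change tables with planted quadrant
#     memberships,
#   * a monosome/polysome count matrix with planted TE shifts.
# All outputs land under results/data/ in the same TSV dialects the
# analysis stages read.

suppressPackageStartupMessages(library(mitoprostat))

seed <- 20260923L
data_dir <- "results/data"
dir.create(file.path(data_dir, "traces"), recursive = TRUE, showWarnings = FALSE)

## -- calcium traces: a small amplitude series ------------------------------
amps <- c(0.2, 0.5, 0.8, 1.2, 1.6) * 1e-6  # molar
meta <- NULL; truths <- NULL
for (i in seq_along(amps)) {
  g <- gen_luminescence_trace(trace_spec(amplitude = amps[i], seed = seed + i))
  id <- sprintf("trace_%02d", i)
  row <- write_trace(g$trace, file.path(data_dir, "traces", paste0(id, ".tsv")))
  meta <- rbind(meta, cbind(data.frame(trace_id = id), row))
  truths <- rbind(truths, data.frame(trace_id = id,
                                     amplitude_M = g$truth$amplitude,
                                     peak_time_s = g$truth$peak_time,
                                     curve_area_Ms = g$truth$curve_area))
}
write_tsv(meta, file.path(data_dir, "traces_meta.tsv"))
write_tsv(truths, file.path(data_dir, "traces_truth.tsv"))
cat(sprintf("wrote %d traces (planted amplitudes %s uM)\n",
            length(amps), paste(amps * 1e6, collapse = ", ")))

## -- co-regulation tables --------------------------------------------------
om <- gen_coreg_table(omics_spec(seed = seed))
write_tsv(om$transcripts, file.path(data_dir, "transcripts.tsv"))
write_tsv(om$proteins, file.path(data_dir, "proteins.tsv"))
write_tsv(om$truth, file.path(data_dir, "coreg_truth.tsv"))
cat(sprintf("wrote co-regulation tables: %d genes, planted %s\n",
            nrow(om$truth),
            paste(names(table(om$truth$label)), table(om$truth$label),
                  sep = "=", collapse = " ")))

## -- polysome counts -------------------------------------------------------
cs <- gen_polysome_counts(count_spec(seed = seed))
write_counts(cs$experiment$counts, file.path(data_dir, "counts.tsv"))
write_tsv(cs$experiment$samples, file.path(data_dir, "samples.tsv"))
write_tsv(cs$truth, file.path(data_dir, "te_truth.tsv"))
cat(sprintf("wrote polysome counts: %d genes x %d libraries, %d planted TE shifts\n",
            nrow(cs$experiment$counts), ncol(cs$experiment$counts),
            sum(cs$truth$planted)))
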