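# shared fixture builders; everything is generated in code, no stored data

# minimal 4-cell polysome experiment from per-cell count vectors (one gene
# per element); reps columns are exact copies unless jitter is supplied
tiny_experiment <- function(case_poly, case_mono, ctrl_poly, ctrl_mono,
                            reps = 2) {
  n <- length(case_poly)
  cells <- list(case.polysome = case_poly, case.monosome = case_mono,
                control.polysome = ctrl_poly, control.monosome = ctrl_mono)
  counts <- NULL; meta <- NULL
  for (cell in names(cells)) {
    gt <- sub("\\..*", "", cell); fr <- sub(".*\\.", "", cell)
    for (r in seq_len(reps)) {
      id <- sprintf("%s_%s_r%d", gt, fr, r)
      counts <- cbind(counts, cells[[cell]])
      colnames(counts)[ncol(counts)] <- id
      meta <- rbind(meta, data.frame(sample_id = id, genotype = gt,
                                     fraction = fr, replicate = r))
    }
  }
  rownames(counts) <- sprintf("g%02d", seq_len(n))
  polysome_experiment(counts, meta)
}

# calcium trace with an exactly known concentration curve (bypasses counts)
make_calcium_trace <- function(times, concentration, resting_level,
                               stimulus_time) {
  structure(list(times = times, concentration = concentration,
                 resting_level = resting_level,
                 stimulus_time = stimulus_time, mode = "aggregate",
                 label = "fixture"),
            class = "calcium_trace")
}

# brute-force upper-tail hypergeometric p by exhaustive enumeration of all
# C(N, n) draws; independent oracle for small universes
enumerate_hypergeom_p <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  in_term <- draws <= K  # term genes are 1..K wlog
  overlaps <- colSums(in_term)
  mean(overlaps >= x)
}
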