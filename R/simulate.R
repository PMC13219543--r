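`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic aequorin trace
#'
#' Parameters of a simulated luminometer recording: a resting Ca2+ baseline
#' carrying a single stimulus-induced transient with fast rise and slower
#' decay (difference of exponentials, time-rescaled so its maximum falls at
#' `peak_time` seconds after the stimulus), read from a finite aequorin
#' pool that the luminescence itself consumes. The defaults mirror the
#' recording protocol the analysis expects: ~60 s of resting luminescence,
#' stimulus, then 100 s of response read at 1 s intervals, with a pool
#' large enough that the discharge remains well measurable.
#'
#' @param resting Resting Ca2+ concentration (M).
#' @param amplitude Planted peak amplitude above resting (M).
#' @param peak_time Planted time of the concentration peak (s after
#'   stimulus); must be < `duration - stimulus_time`.
#' @param rise_tau,decay_tau Rise / decay time constants (s) of the pulse
#'   shape before time-rescaling.
#' @param duration Total trace duration (s).
#' @param interval Sampling interval (s).
#' @param stimulus_time Stimulus application time (s).
#' @param pool Total aequorin pool (expected total counts available).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(resting = 1e-7, amplitude = 5e-7, peak_time = 12,
                       rise_tau = 3, decay_tau = 12, duration = 160,
                       interval = 1, stimulus_time = 60, pool = 1e6,
                       seed = 1) {
  stopifnot(resting > 0, amplitude >= 0, peak_time > 0, rise_tau > 0,
            decay_tau > rise_tau, duration > 0, interval > 0,
            stimulus_time > 0, stimulus_time < duration, pool > 0,
            peak_time < duration - stimulus_time)
  structure(list(resting = resting, amplitude = amplitude,
                 peak_time = peak_time, rise_tau = rise_tau,
                 decay_tau = decay_tau, duration = duration,
                 interval = interval, stimulus_time = stimulus_time,
                 pool = pool, seed = seed),
            class = "trace_spec")
}

# double-exponential pulse, unit peak height at s = peak_time
pulse_shape <- function(s, rise_tau, decay_tau, peak_time) {
  s_star <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  u <- pmax(s, 0) * s_star / peak_time
  g <- exp(-u / decay_tau) - exp(-u / rise_tau)
  g_max <- exp(-s_star / decay_tau) - exp(-s_star / rise_tau)
  ifelse(s <= 0, 0, g / g_max)
}

#' Simulate an aequorin luminescence trace with known ground truth
#'
#' Constructs the true Ca2+ concentration curve of the spec, inverts the
#' aequorin calibration to the per-interval rate constant k(t), and emits
#' counts from a finite aequorin pool: the expected counts in interval t
#' are k(t) times the pool still available, the observed counts are Poisson
#' draws (capped by the integer pool so aequorin is conserved), and the
#' discharge counts are whatever remains at the end — exactly the
#' consumption accounting the pointwise calibration mode inverts.
#'
#' @param spec A [trace_spec()].
#' @param params [calibration_params()] used for the forward model.
#' @return List with `trace` (a [luminescence_trace()]), `truth` (the
#'   noise-free `ca_signature` on the sampled grid: planted amplitude, peak
#'   time, curve area, resting level) and `concentration` (the true curve
#'   at the sample times).
#' @export
gen_luminescence_trace <- function(spec, params = calibration_params()) {
  stopifnot(inherits(spec, "trace_spec"))
  times <- seq(0, spec$duration, by = spec$interval)
  conc <- spec$resting + spec$amplitude *
    pulse_shape(times - spec$stimulus_time, spec$rise_tau, spec$decay_tau,
                spec$peak_time)
  pca <- concentration_to_pca(conc)
  # invert pCa = slope * (-log_b k) + intercept for the per-interval rate
  k <- params$log_base^(-(pca - params$intercept) / params$slope)
  if (any(k > 1))
    stop("spec implies k > 1; peak concentration exceeds the calibration range")
  # expected (noise-free) consumption of the pool
  pool_exp <- spec$pool
  lambda <- numeric(length(times))
  for (i in seq_along(times)) {
    lambda[i] <- k[i] * pool_exp
    pool_exp <- pool_exp - lambda[i]
  }
  if (pool_exp < 1)
    stop("aequorin pool exhausted before trace end; increase `pool`")
  counts <- numeric(length(times))
  pool <- spec$pool
  with_seed(spec$seed, {
    for (i in seq_along(times)) {
      counts[i] <- min(stats::rpois(1L, k[i] * pool), floor(pool))
      pool <- pool - counts[i]
    }
  })
  trace <- luminescence_trace(times, counts, discharge_counts = pool,
                              stimulus_time = spec$stimulus_time,
                              label = sprintf("synthetic(seed=%g)", spec$seed))
  post <- times >= spec$stimulus_time
  excess <- pmax(conc - spec$resting, 0)
  truth <- structure(list(amplitude = spec$amplitude,
                          curve_area = trapezoid(times[post], excess[post]),
                          peak_time = spec$peak_time,
                          resting_level = spec$resting),
                     class = "ca_signature")
  list(trace = trace, truth = truth, concentration = conc)
}

#' Specification of a synthetic co-regulation table pair
#'
#' Planted quadrant memberships for the transcript/protein fold-change
#' tables: each planted gene gets transcript and protein log2 fold changes
#' whose signs match its quadrant and whose magnitudes are centered on
#' `effect` (spread `fc_sd`; 0 gives the noise-free setting), with protein
#' p-values far below any reasonable cutoff. Null genes get small
#' zero-centered fold changes and uniform p-values.
#'
#' @param n_genes Number of genes.
#' @param fractions Named planted fractions for Q1..Q4; must sum to <= 1,
#'   the remainder being null genes.
#' @param effect Planted |log2 fold change|.
#' @param fc_sd Spread of planted fold-change magnitudes (0 = noise-free).
#' @param null_sd Spread of null-gene log2 fold changes.
#' @param planted_p_max Upper bound of planted protein/transcript p-values.
#' @param seed RNG seed.
#' @return An object of class `omics_spec`.
#' @export
omics_spec <- function(n_genes = 1000,
                       fractions = c(Q1 = 0.4, Q2 = 0.1, Q3 = 0.1, Q4 = 0.4),
                       effect = 1.5, fc_sd = 0.2, null_sd = 0.3,
                       planted_p_max = 1e-4, seed = 1) {
  fractions <- unlist(fractions)  # accept YAML-parsed lists
  stopifnot(n_genes >= 1, length(fractions) == 4L,
            all(names(fractions) == c("Q1", "Q2", "Q3", "Q4")),
            all(fractions >= 0), sum(fractions) <= 1 + 1e-12,
            effect > 0, fc_sd >= 0, null_sd >= 0,
            planted_p_max > 0, planted_p_max < 1)
  structure(list(n_genes = as.integer(n_genes), fractions = fractions,
                 effect = effect, fc_sd = fc_sd, null_sd = null_sd,
                 planted_p_max = planted_p_max, seed = seed),
            class = "omics_spec")
}

#' Generate transcript/protein tables with planted quadrant memberships
#'
#' @param spec An [omics_spec()].
#' @return List: `transcripts` (`gene_id`, `log2fc`, `padj`), `proteins`
#'   (`gene_id`, `log2fc`, `pval`), `truth` (`gene_id`, `label` in
#'   Q1..Q4/null). The number of genes planted in each quadrant is exactly
#'   `round(fraction * n_genes)`.
#' @export
gen_coreg_table <- function(spec) {
  stopifnot(inherits(spec, "omics_spec"))
  n <- spec$n_genes
  n_quad <- round(spec$fractions * n)
  if (sum(n_quad) > n) stop("rounded quadrant counts exceed n_genes")
  labels <- rep("null", n)
  idx <- 1L
  for (qd in names(n_quad)) {
    take <- n_quad[[qd]]
    if (take > 0) labels[idx:(idx + take - 1L)] <- qd
    idx <- idx + take
  }
  gene_id <- sprintf("g%04d", seq_len(n))
  # quadrant sign conventions: (transcript, protein)
  signs <- list(Q1 = c(1, 1), Q2 = c(-1, 1), Q3 = c(-1, -1), Q4 = c(1, -1))
  with_seed(spec$seed, {
    mag_t <- abs(stats::rnorm(n, spec$effect, spec$fc_sd))
    mag_p <- abs(stats::rnorm(n, spec$effect, spec$fc_sd))
    t_lfc <- stats::rnorm(n, 0, spec$null_sd)
    p_lfc <- stats::rnorm(n, 0, spec$null_sd)
    t_p <- stats::runif(n)
    p_p <- stats::runif(n)
    for (qd in names(signs)) {
      sel <- labels == qd
      t_lfc[sel] <- signs[[qd]][1L] * mag_t[sel]
      p_lfc[sel] <- signs[[qd]][2L] * mag_p[sel]
      t_p[sel] <- stats::runif(sum(sel), 0, spec$planted_p_max)
      p_p[sel] <- stats::runif(sum(sel), 0, spec$planted_p_max)
    }
  })
  list(transcripts = data.frame(gene_id = gene_id, log2fc = t_lfc,
                                padj = t_p, stringsAsFactors = FALSE),
       proteins = data.frame(gene_id = gene_id, log2fc = p_lfc,
                             pval = p_p, stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_id, label = labels,
                          stringsAsFactors = FALSE))
}

#' Specification of a synthetic polysome-profiling count matrix
#'
#' Negative-binomial gene x library counts for a 2 genotype x 2 fraction
#' design with planted translational-efficiency shifts: every gene draws a
#' baseline expected abundance from a log-normal distribution (median
#' `baseline_median_cpm`, log-sd `baseline_sdlog`), shared by all four
#' cells; planted genes have their case-polysome mean multiplied by
#' `2^(s * effect_te_log2)` with a random sign `s`, which is exactly a TE
#' shift of that magnitude. Counts are NB with variance
#' `mu + dispersion * mu^2`.
#'
#' @param n_genes Number of genes.
#' @param reps Replicates per (genotype, fraction) cell (>= 2).
#' @param baseline_median_cpm Median of the log-normal baseline abundance
#'   (nominal CPM units).
#' @param baseline_sdlog Log-scale sd of the baseline distribution.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param planted_fraction Fraction of genes given a TE shift, in \[0, 1).
#' @param effect_te_log2 Planted |te_log2| effect size.
#' @param lib_size Expected library size used to turn nominal CPM into
#'   expected counts (counts = cpm * lib_size / 1e6).
#' @param seed RNG seed.
#' @return An object of class `count_spec`.
#' @export
count_spec <- function(n_genes = 2000, reps = 3, baseline_median_cpm = 100,
                       baseline_sdlog = 1, dispersion = 0.1,
                       planted_fraction = 0.2, effect_te_log2 = 1,
                       lib_size = 1e6, seed = 1) {
  stopifnot(n_genes >= 1, reps >= 2, baseline_median_cpm > 0,
            baseline_sdlog >= 0, dispersion > 0,
            planted_fraction >= 0, planted_fraction < 1,
            effect_te_log2 >= 0, lib_size > 0)
  structure(list(n_genes = as.integer(n_genes), reps = as.integer(reps),
                 baseline_median_cpm = baseline_median_cpm,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 planted_fraction = planted_fraction,
                 effect_te_log2 = effect_te_log2, lib_size = lib_size,
                 seed = seed),
            class = "count_spec")
}

#' Generate a polysome experiment with planted TE shifts
#'
#' @param spec A [count_spec()].
#' @return List: `experiment` (a [polysome_experiment()]) and `truth`
#'   (`gene_id`, `planted`, `te_log2_true` — signed planted effect, 0 for
#'   null genes). Exactly `round(planted_fraction * n_genes)` genes are
#'   planted.
#' @export
gen_polysome_counts <- function(spec) {
  stopifnot(inherits(spec, "count_spec"))
  n <- spec$n_genes
  n_planted <- round(spec$planted_fraction * n)
  gene_id <- sprintf("g%05d", seq_len(n))
  design <- expand.grid(replicate = seq_len(spec$reps),
                        fraction = c("monosome", "polysome"),
                        genotype = c("control", "case"),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d",
                              ifelse(design$genotype == "case", "mut", "wt"),
                              ifelse(design$fraction == "monosome", "mono", "poly"),
                              design$replicate)
  size <- 1 / spec$dispersion
  with_seed(spec$seed, {
    base_cpm <- stats::rlnorm(n, log(spec$baseline_median_cpm),
                              spec$baseline_sdlog)
    planted <- sample.int(n, n_planted)
    sgn <- sample(c(-1, 1), n_planted, replace = TRUE)
    te_true <- numeric(n)
    te_true[planted] <- sgn * spec$effect_te_log2
    mu_base <- base_cpm * spec$lib_size / 1e6
    counts <- matrix(0, n, nrow(design),
                     dimnames = list(gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu <- mu_base
      if (design$genotype[j] == "case" && design$fraction[j] == "polysome")
        mu <- mu * 2^te_true
      counts[, j] <- stats::rnbinom(n, size = size, mu = mu)
    }
  })
  samples <- design[, c("sample_id", "genotype", "fraction", "replicate")]
  list(experiment = polysome_experiment(counts, samples),
       truth = data.frame(gene_id = gene_id,
                          planted = te_true != 0,
                          te_log2_true = te_true,
                          stringsAsFactors = FALSE))
}
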