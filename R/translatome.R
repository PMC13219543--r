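#' A polysome-profiling RNA-seq experiment
#'
#' Container for the gene x sample count matrix of monosomal and polysomal
#' RNA-seq libraries together with the sample metadata. Each library is one
#' (genotype, fraction, replicate) combination; `genotype` distinguishes
#' the perturbed line (`"case"`) from its control (`"control"`), `fraction`
#' the sucrose-gradient pool the RNA came from.
#'
#' @param counts Non-negative numeric matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param samples data.frame with columns `sample_id`, `genotype` (`case` /
#'   `control`), `fraction` (`monosome` / `polysome`), `replicate`
#'   (integer index). One row per column of `counts`.
#' @return An object of class `polysome_experiment`.
#' @export
polysome_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), is.data.frame(samples),
            all(c("sample_id", "genotype", "fraction", "replicate") %in%
                  names(samples)))
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (is.null(colnames(counts))) stop("counts must carry sample ids as colnames")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("every counts column needs a row in `samples`")
  if (!all(samples$genotype %in% c("case", "control")))
    stop("genotype must be 'case' or 'control'")
  if (!all(samples$fraction %in% c("monosome", "polysome")))
    stop("fraction must be 'monosome' or 'polysome'")
  cells <- table(samples$genotype, samples$fraction)
  if (any(cells < 1L))
    stop("every (genotype, fraction) cell needs at least one replicate")
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "polysome_experiment")
}

#' @export
print.polysome_experiment <- function(x, ...) {
  cat(sprintf("polysome experiment: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(genotype = x$samples$genotype, fraction = x$samples$fraction))
  invisible(x)
}

#' Library-size (CPM) normalization
#'
#' Scales each library to counts per million so that libraries of different
#' sequencing depth are comparable.
#'
#' @param x A `polysome_experiment` or a gene x sample count matrix.
#' @param method Normalization method; only `"cpm"` is implemented.
#' @return Matrix of the same shape with each column summing to 1e6.
#' @export
normalize_counts <- function(x, method = "cpm") {
  method <- match.arg(method, "cpm")
  counts <- if (inherits(x, "polysome_experiment")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop(sprintf("all-zero sample(s): %s",
                 paste(colnames(counts)[totals <= 0], collapse = ", ")))
  sweep(counts, 2L, totals, "/") * 1e6
}

cell_means <- function(experiment, pseudocount = 0) {
  cpm <- normalize_counts(experiment)
  s <- experiment$samples
  cells <- expand.grid(genotype = c("case", "control"),
                       fraction = c("monosome", "polysome"),
                       stringsAsFactors = FALSE)
  m <- sapply(seq_len(nrow(cells)), function(i) {
    sel <- s$genotype == cells$genotype[i] & s$fraction == cells$fraction[i]
    rowMeans(cpm[, sel, drop = FALSE])
  })
  colnames(m) <- paste(cells$genotype, cells$fraction, sep = ".")
  m + pseudocount
}

#' Per-gene translational efficiency
#'
#' Translational efficiency (TE) compares, per gene, how strongly a
#' transcript is loaded onto polysomes relative to monosomes in the case
#' genotype versus its control:
#' \deqn{TE = \log_2 \frac{case_{poly}/case_{mono}}{control_{poly}/control_{mono}}}
#' Replicate means are taken on the CPM scale before forming the ratios; a
#' pseudocount is added to every cell mean to stabilize ratios of
#' low-abundance genes. A positive `te_log2` means the transcript shifts
#' toward polysomes (higher TE) in the case genotype; negative means it
#' shifts toward monosomes (lower TE).
#'
#' Genes whose mean CPM is below `min_cpm` in all four (genotype, fraction)
#' cells — including genes with zero counts everywhere — get a missing TE
#' rather than a misleading 0.
#'
#' @param experiment A [polysome_experiment()] with all four
#'   (genotype, fraction) cells present.
#' @param pseudocount Added to each cell-mean CPM (default 0.5).
#' @param min_cpm Abundance floor: genes below this mean CPM in every cell
#'   are reported as `NA` (default 1).
#' @return data.frame `gene_id`, `te_log2`, `te_fc` where
#'   `te_fc = 2^|te_log2|` is the linear TE fold change (>= 1).
#' @export
compute_te <- function(experiment, pseudocount = 0.5, min_cpm = 1) {
  stopifnot(inherits(experiment, "polysome_experiment"),
            pseudocount >= 0, min_cpm >= 0)
  raw_means <- cell_means(experiment, pseudocount = 0)
  m <- raw_means + pseudocount
  # two-ratio difference (not a single 4-term quotient) so that swapping
  # case and control negates te_log2 exactly, bit for bit
  te_log2 <- log2(m[, "case.polysome"] / m[, "case.monosome"]) -
    log2(m[, "control.polysome"] / m[, "control.monosome"])
  low <- apply(raw_means < min_cpm, 1L, all)
  te_log2[low] <- NA_real_
  data.frame(gene_id = rownames(experiment$counts),
             te_log2 = unname(te_log2),
             te_fc = unname(2^abs(te_log2)),
             stringsAsFactors = FALSE)
}

#' Per-replicate polysome/monosome log-ratio matrix
#'
#' Pairs monosome and polysome libraries of the same genotype by replicate
#' index and returns the per-gene log2 CPM ratio of each pair, the matrix
#' on which the default saTE-gating PLS-DA is fit. Replicates present in
#' only one fraction are dropped with a warning.
#'
#' @inheritParams compute_te
#' @return List: `X` (pairs x genes matrix of log2 ratios), `genotype`
#'   (class label per pair), `replicate`.
#' @export
ratio_matrix <- function(experiment, pseudocount = 0.5) {
  stopifnot(inherits(experiment, "polysome_experiment"))
  cpm <- normalize_counts(experiment)
  s <- experiment$samples
  rows <- list(); labs <- character(); reps <- integer()
  dropped <- 0L
  for (g in c("case", "control")) {
    r_mono <- s$replicate[s$genotype == g & s$fraction == "monosome"]
    r_poly <- s$replicate[s$genotype == g & s$fraction == "polysome"]
    shared <- intersect(r_mono, r_poly)
    dropped <- dropped + length(setdiff(union(r_mono, r_poly), shared))
    for (r in sort(shared)) {
      mono <- s$sample_id[s$genotype == g & s$fraction == "monosome" &
                            s$replicate == r][1L]
      poly <- s$sample_id[s$genotype == g & s$fraction == "polysome" &
                            s$replicate == r][1L]
      rows[[length(rows) + 1L]] <-
        log2((cpm[, poly] + pseudocount) / (cpm[, mono] + pseudocount))
      labs <- c(labs, g)
      reps <- c(reps, r)
    }
  }
  if (dropped > 0L)
    warning(sprintf("%d unpaired replicate(s) dropped from the ratio matrix",
                    dropped))
  if (length(rows) < 4L)
    stop("need at least two paired replicates per genotype")
  X <- do.call(rbind, rows)
  rownames(X) <- paste(labs, reps, sep = ".")
  list(X = X, genotype = labs, replicate = reps)
}

#' Fit a PLS-DA model to a polysome experiment
#'
#' Builds the predictor matrix from the experiment and fits a two-class
#' (case vs control) PLS-DA via [fit_plsda()]. Three constructions are
#' available:
#' * `"ratio"` (default): per-replicate polysome/monosome log2-CPM ratios
#'   ([ratio_matrix()]); the only construction whose per-gene VIP gates a
#'   per-gene TE directly.
#' * `"monosome"` / `"polysome"`: log2(CPM + 1) of the libraries of that
#'   fraction, the per-fraction ordination view of the libraries.
#'
#' @inheritParams compute_te
#' @param source Predictor construction (see above).
#' @param n_components Number of PLS components.
#' @return A `plsda_model`; the construction used is attached as attribute
#'   `source`.
#' @export
fit_te_plsda <- function(experiment, source = c("ratio", "monosome", "polysome"),
                         n_components = 2, pseudocount = 0.5) {
  source <- match.arg(source)
  if (source == "ratio") {
    rm_ <- ratio_matrix(experiment, pseudocount = pseudocount)
    X <- rm_$X
    y <- rm_$genotype
  } else {
    cpm <- normalize_counts(experiment)
    sel <- experiment$samples$fraction == source
    if (sum(sel) < 4L) stop(sprintf("too few %s libraries", source))
    X <- t(log2(cpm[, sel, drop = FALSE] + 1))
    y <- experiment$samples$genotype[sel]
  }
  model <- suppressWarnings(fit_plsda(X, y, n_components = n_components))
  attr(model, "source") <- source
  model
}

#' Select genes with significantly altered translational efficiency (saTE)
#'
#' A gene is flagged saTE when its linear TE fold change reaches
#' `fc_cutoff` and its VIP score from the PLS-DA model reaches
#' `vip_threshold` (the conventional VIP >= 1 rule for "significant" VIP).
#' Direction is `low` for te_log2 < 0 (translationally repressed) and
#' `high` otherwise.
#'
#' @param te TE table from [compute_te()].
#' @param vip Named VIP vector from [vip_scores()]; genes must match `te`
#'   (genes dropped from the PLS fit for zero variance are allowed to be
#'   absent and get `NA` VIP, never selected).
#' @param fc_cutoff Minimal linear TE fold change (default 1.25, i.e.
#'   |te_log2| >= log2 1.25 = 0.3219).
#' @param vip_threshold Minimal VIP score (default 1.0).
#' @return data.frame `gene_id`, `te_log2`, `te_fc`, `vip`, `selected`,
#'   `direction`.
#' @export
select_sate <- function(te, vip, fc_cutoff = 1.25, vip_threshold = 1.0) {
  stopifnot(is.data.frame(te), all(c("gene_id", "te_log2", "te_fc") %in% names(te)),
            is.numeric(vip), !is.null(names(vip)),
            fc_cutoff >= 1, vip_threshold >= 0)
  alien <- setdiff(names(vip), te$gene_id)
  if (length(alien))
    stop(sprintf("VIP genes absent from the TE table: %s%s",
                 paste(utils::head(alien, 5L), collapse = ", "),
                 if (length(alien) > 5L) sprintf(" (+%d more)", length(alien) - 5L) else ""))
  out <- te
  out$vip <- unname(vip[match(te$gene_id, names(vip))])
  out$selected <- !is.na(out$te_log2) & !is.na(out$vip) &
    out$te_fc >= fc_cutoff & out$vip >= vip_threshold
  out$direction <- ifelse(is.na(out$te_log2), NA_character_,
                          ifelse(out$te_log2 < 0, "low", "high"))
  out
}

#' Total polysomal-to-monosomal RNA ratio per genotype
#'
#' The bulk translational-status readout of a polysome profile: total
#' polysomal RNA divided by total monosomal RNA. Reported per genotype from
#' the summed library counts, together with the mean and standard error of
#' the per-replicate-pair ratios.
#'
#' @inheritParams compute_te
#' @return data.frame `genotype`, `ratio` (pooled totals), `mean`
#'   (of per-replicate ratios), `sem`, `n` (replicate pairs).
#' @export
polysome_monosome_ratio <- function(experiment) {
  stopifnot(inherits(experiment, "polysome_experiment"))
  s <- experiment$samples
  totals <- colSums(experiment$counts)
  rows <- lapply(c("case", "control"), function(g) {
    mono_tot <- sum(totals[s$genotype == g & s$fraction == "monosome"])
    poly_tot <- sum(totals[s$genotype == g & s$fraction == "polysome"])
    if (mono_tot <= 0) stop(sprintf("zero monosomal total for genotype %s", g))
    shared <- intersect(s$replicate[s$genotype == g & s$fraction == "monosome"],
                        s$replicate[s$genotype == g & s$fraction == "polysome"])
    per_rep <- vapply(sort(shared), function(r) {
      m <- sum(totals[s$genotype == g & s$fraction == "monosome" & s$replicate == r])
      p <- sum(totals[s$genotype == g & s$fraction == "polysome" & s$replicate == r])
      p / m
    }, numeric(1))
    data.frame(genotype = g, ratio = poly_tot / mono_tot,
               mean = mean(per_rep),
               sem = if (length(per_rep) > 1L)
                 stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_,
               n = length(per_rep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
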