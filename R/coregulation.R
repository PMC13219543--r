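#' Merge transcript and protein fold-change tables
#'
#' Inner join of a transcript differential-expression table and a protein
#' differential-abundance table on `gene_id`, producing the paired records
#' on which co-regulation quadrants are classified. Unmatched identifiers on
#' either side are counted and reported (attribute `unmatched` and a
#' warning when the intersection is empty), never silently dropped without
#' count.
#'
#' @param transcripts data.frame with columns `gene_id`, `log2fc` and
#'   optionally `padj`.
#' @param proteins data.frame with columns `gene_id`, `log2fc`, `pval`.
#' @return data.frame with columns `gene_id`, `t_log2fc`, `t_padj`,
#'   `p_log2fc`, `p_pval`; attribute `unmatched` holds the per-side counts
#'   of identifiers without a partner.
#' @export
merge_coreg_tables <- function(transcripts, proteins) {
  check_coreg_input(transcripts, c("gene_id", "log2fc"), "transcripts")
  check_coreg_input(proteins, c("gene_id", "log2fc", "pval"), "proteins")
  t_tab <- data.frame(gene_id = as.character(transcripts$gene_id),
                      t_log2fc = as.numeric(transcripts$log2fc),
                      t_padj = if ("padj" %in% names(transcripts))
                        as.numeric(transcripts$padj) else NA_real_,
                      stringsAsFactors = FALSE)
  p_tab <- data.frame(gene_id = as.character(proteins$gene_id),
                      p_log2fc = as.numeric(proteins$log2fc),
                      p_pval = as.numeric(proteins$pval),
                      stringsAsFactors = FALSE)
  merged <- merge(t_tab, p_tab, by = "gene_id", sort = TRUE)
  unmatched <- c(transcripts = nrow(t_tab) - nrow(merged),
                 proteins = nrow(p_tab) - nrow(merged))
  if (nrow(merged) == 0L)
    warning("no gene_id shared between the transcript and protein tables")
  message(sprintf("merged %d protein-transcript pairs (%d transcript-only, %d protein-only)",
                  nrow(merged), unmatched[["transcripts"]], unmatched[["proteins"]]))
  attr(merged, "unmatched") <- unmatched
  merged
}

check_coreg_input <- function(tab, cols, what) {
  stopifnot(is.data.frame(tab))
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing, collapse = ", ")))
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    stop(sprintf("duplicate gene_id in %s table: %s%s", what,
                 paste(utils::head(dup, 5L), collapse = ", "),
                 if (length(dup) > 5L) sprintf(" (+%d more)", length(dup) - 5L) else ""))
  invisible(tab)
}

#' Classify protein-transcript pairs into co-regulation quadrants
#'
#' Assigns each merged gene to one of the four co-regulation quadrants of a
#' protein-FC vs transcript-FC plot, or to `excluded`:
#'
#' * Q1 — co-upregulated (transcript up, protein up)
#' * Q2 — post-transcriptionally increased (transcript down, protein up)
#' * Q3 — co-downregulated (transcript down, protein down)
#' * Q4 — post-transcriptionally repressed (transcript up, protein down)
#'
#' Eligibility is gated on the protein side only: |FC| > `fc_cutoff`
#' (linear scale, i.e. |log2FC| > log2(fc_cutoff)) and p < `p_cutoff`. No
#' criteria are applied to transcripts unless `strict_transcripts = TRUE`,
#' in which case the same fold-change cutoff and an adjusted-p cutoff are
#' also required of the transcript. A transcript log2FC of exactly 0 has no
#' quadrant sign and is excluded. The `"relaxed"` preset lowers the protein
#' fold-change cutoff to 1.2 (used when inspecting sparsely populated
#' quadrants).
#'
#' @param records Merged records from [merge_coreg_tables()].
#' @param fc_cutoff Protein fold-change cutoff on the linear scale (> 1).
#' @param p_cutoff Protein p-value cutoff in (0, 1).
#' @param strict_transcripts Also require `|t_log2fc| > log2(fc_cutoff)` and
#'   `t_padj < p_cutoff`.
#' @param preset `"default"` (|FC| > 1.5) or `"relaxed"` (|FC| > 1.2); an
#'   explicitly supplied `fc_cutoff` wins over the preset.
#' @return An object of class `quadrant_result`: `assignments` (data.frame
#'   `gene_id`, `quadrant`), `counts`, `percentages` (over assigned,
#'   non-excluded genes), `n_assigned`, `n_excluded` and the thresholds
#'   used.
#' @export
classify_quadrants <- function(records, fc_cutoff = NULL, p_cutoff = 0.05,
                               strict_transcripts = FALSE,
                               preset = c("default", "relaxed")) {
  preset <- match.arg(preset)
  if (is.null(fc_cutoff)) fc_cutoff <- if (preset == "relaxed") 1.2 else 1.5
  stopifnot(is.data.frame(records),
            all(c("gene_id", "t_log2fc", "p_log2fc", "p_pval") %in% names(records)),
            is.numeric(fc_cutoff), length(fc_cutoff) == 1L,
            is.numeric(p_cutoff), length(p_cutoff) == 1L)
  if (fc_cutoff <= 1) stop("`fc_cutoff` must be > 1 (linear fold change)")
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("`p_cutoff` must be in (0, 1)")
  lfc <- log2(fc_cutoff)

  p_missing <- is.na(records$p_pval)
  if (any(p_missing))
    warning(sprintf("%d record(s) lack a protein p-value and were excluded",
                    sum(p_missing)))
  eligible <- !p_missing &
    abs(records$p_log2fc) > lfc & records$p_pval < p_cutoff
  if (strict_transcripts) {
    t_missing <- is.na(records$t_padj)
    eligible <- eligible & !t_missing &
      abs(records$t_log2fc) > lfc & records$t_padj < p_cutoff
  }
  q <- rep("excluded", nrow(records))
  up_t <- records$t_log2fc > 0
  dn_t <- records$t_log2fc < 0
  up_p <- records$p_log2fc > 0
  q[eligible & up_t & up_p]  <- "Q1"
  q[eligible & dn_t & up_p]  <- "Q2"
  q[eligible & dn_t & !up_p] <- "Q3"
  q[eligible & up_t & !up_p] <- "Q4"
  # t_log2fc == 0 stays excluded: the quadrant sign is undefined

  assignments <- data.frame(gene_id = records$gene_id, quadrant = q,
                            stringsAsFactors = FALSE)
  quads <- c("Q1", "Q2", "Q3", "Q4")
  counts <- vapply(quads, function(x) sum(q == x), integer(1))
  n_assigned <- sum(counts)
  structure(list(assignments = assignments,
                 counts = counts,
                 percentages = if (n_assigned > 0) 100 * counts / n_assigned
                               else counts * NA_real_,
                 n_assigned = n_assigned,
                 n_excluded = nrow(records) - n_assigned,
                 fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                 strict_transcripts = strict_transcripts),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat(sprintf("co-regulation quadrants (|FC| > %g, p < %g%s): %d assigned, %d excluded\n",
              x$fc_cutoff, x$p_cutoff,
              if (x$strict_transcripts) ", strict transcript filter" else "",
              x$n_assigned, x$n_excluded))
  if (x$n_assigned > 0)
    for (qd in names(x$counts))
      cat(sprintf("  %s: %4d (%5.1f%%)\n", qd, x$counts[[qd]], x$percentages[[qd]]))
  invisible(x)
}

#' Summarize quadrant membership
#'
#' Per-quadrant counts and percentages over the assigned (non-excluded)
#' genes, optionally with the quadrant split inside a user-supplied gene
#' subset (e.g. the cytosolic ribosomal proteins), whose percentages are
#' normalized over the subset members assigned to any quadrant.
#'
#' @param result A `quadrant_result` from [classify_quadrants()].
#' @param subset Optional character vector of gene identifiers.
#' @return A list with `summary` (data.frame `quadrant`, `count`,
#'   `percentage`, plus totals as attributes) and, when `subset` is given,
#'   `subset_summary` with the same shape computed within the subset.
#' @export
quadrant_summary <- function(result, subset = NULL) {
  stopifnot(inherits(result, "quadrant_result"))
  if (result$n_assigned == 0L)
    stop("all genes were excluded; nothing to summarize")
  tab <- data.frame(quadrant = names(result$counts),
                    count = as.integer(result$counts),
                    percentage = as.numeric(result$percentages),
                    stringsAsFactors = FALSE)
  out <- list(summary = tab, n_assigned = result$n_assigned,
              n_excluded = result$n_excluded)
  if (!is.null(subset)) {
    a <- result$assignments
    sub <- a[a$gene_id %in% subset & a$quadrant != "excluded", , drop = FALSE]
    quads <- c("Q1", "Q2", "Q3", "Q4")
    cnt <- vapply(quads, function(x) sum(sub$quadrant == x), integer(1))
    n <- sum(cnt)
    out$subset_summary <- data.frame(
      quadrant = quads, count = as.integer(cnt),
      percentage = if (n > 0) 100 * cnt / n else cnt * NA_real_,
      stringsAsFactors = FALSE)
    out$subset_n_assigned <- n
  }
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of the over-
#' representation of each annotation term in a selected gene set, with
#' Benjamini-Hochberg adjustment across terms. The p-value for a term with
#' `K` genes in a universe of `N`, given `n` selected genes and `x` of them
#' in the term, is `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `universe`.
#' @param annotation Named list mapping term id to a character vector of
#'   member genes, or a two-column data.frame `term_id`, `gene_id`.
#' @param universe Character vector, the gene universe. Term memberships
#'   are intersected with it.
#' @return data.frame sorted by p-value: `term_id`, `overlap`,
#'   `selected_size`, `term_size`, `universe_size`, `pval`, `padj`.
#' @examples
#' hypergeom_enrichment(paste0("g", 1:4),
#'                      list(t1 = paste0("g", 1:5)),
#'                      paste0("g", 1:10))
#' @export
hypergeom_enrichment <- function(selected, annotation, universe) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (length(universe) == 0L) stop("empty universe")
  if (length(selected) == 0L) stop("empty selection")
  extra <- setdiff(selected, universe)
  if (length(extra))
    stop(sprintf("selected genes outside the universe: %s",
                 paste(utils::head(extra, 5L), collapse = ", ")))
  if (is.data.frame(annotation)) {
    stopifnot(all(c("term_id", "gene_id") %in% names(annotation)))
    annotation <- split(as.character(annotation$gene_id),
                        as.character(annotation$term_id))
  }
  stopifnot(is.list(annotation), length(annotation) > 0L,
            !is.null(names(annotation)))
  rows <- lapply(names(annotation), function(tid) {
    term <- intersect(unique(as.character(annotation[[tid]])), universe)
    x <- length(intersect(term, selected))
    data.frame(term_id = tid, overlap = x,
               selected_size = length(selected), term_size = length(term),
               universe_size = length(universe),
               pval = stats::phyper(x - 1L, length(term),
                                    length(universe) - length(term),
                                    length(selected), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$pval, method = "BH")
  res[order(res$pval, res$term_id), , drop = FALSE]
}
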