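#' Derive intron intervals from a gene model
#'
#' Introns are the maximal intervals of the gene span not covered by any
#' exon, 1-based inclusive, sorted.
#'
#' @param model a [gene_model()].
#' @return data frame with columns `start`, `end` (possibly 0 rows).
#' @export
derive_introns <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  span <- IRanges::IRanges(model$start, model$end)
  ex <- IRanges::reduce(IRanges::IRanges(model$exons$start,
                                         model$exons$end))
  intr <- IRanges::setdiff(span, ex)
  data.frame(start = IRanges::start(intr), end = IRanges::end(intr))
}

# reference-space aligned-base ranges per read: M/=/X consume reference
# with aligned bases; N (skip) and D (deletion) consume reference
# without aligned bases and are excluded
aligned_ranges <- function(cigar, pos) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
}

#' Intronic read and coverage counts for one gene
#'
#' A read counts as intronic when at least `min_overlap` of its aligned
#' bases (skip and deletion segments excluded) fall inside an intron;
#' with `rule = "majority"` a read counts only when more than half of
#' its aligned bases are intronic. Covered intronic positions are the
#' intronic bases overlapped by at least one aligned base.
#'
#' @param alignments alignment records: a data frame with columns
#'   `rname`, `pos`, `cigar` (e.g. from [gen_reads()] or
#'   [read_alignments()]), or a path to a SAM/BAM file.
#' @param model a [gene_model()].
#' @param rule `"any"` (default, >= `min_overlap` intronic bases) or
#'   `"majority"`.
#' @param min_overlap minimum intronic aligned bases for the `"any"`
#'   rule.
#' @return a one-row data frame of class `coverage_counts`: `gene_id`,
#'   `intronic_read_count`, `intronic_position_total`,
#'   `covered_intronic_positions`, `uncovered_intronic_positions`.
#' @export
intronic_coverage <- function(alignments, model,
                              rule = c("any", "majority"),
                              min_overlap = 1L) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "gene_model"))
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_alignments(alignments)
  needed <- c("rname", "pos", "cigar")
  if (!all(needed %in% names(alignments)))
    stop("input error: alignments need columns ",
         paste(needed, collapse = ", "))
  intr <- derive_introns(model)
  total <- sum(intr$end - intr$start + 1L)
  al <- alignments[alignments$rname == model$seqname, , drop = FALSE]
  if (nrow(al) == 0L) {
    out <- data.frame(gene_id = model$gene_id, intronic_read_count = 0L,
                      intronic_position_total = total,
                      covered_intronic_positions = 0L,
                      uncovered_intronic_positions = total)
    class(out) <- c("coverage_counts", "data.frame")
    return(out)
  }
  if (total == 0L) {
    out <- data.frame(gene_id = model$gene_id, intronic_read_count = 0L,
                      intronic_position_total = 0L,
                      covered_intronic_positions = 0L,
                      uncovered_intronic_positions = 0L)
    class(out) <- c("coverage_counts", "data.frame")
    return(out)
  }
  ir_intr <- IRanges::IRanges(intr$start, intr$end)
  blocks <- aligned_ranges(al$cigar, al$pos)   # IRangesList, per read
  flat <- unlist(blocks, use.names = FALSE)
  read_of <- rep(seq_len(nrow(al)), S4Vectors::elementNROWS(blocks))
  # per-block intronic overlap width
  hits <- IRanges::findOverlaps(flat, ir_intr)
  ovl <- IRanges::pintersect(flat[S4Vectors::queryHits(hits)],
                             ir_intr[S4Vectors::subjectHits(hits)])
  w_intr_block <- tapply(IRanges::width(ovl),
                         S4Vectors::queryHits(hits), sum)
  w_intr <- numeric(length(flat))
  w_intr[as.integer(names(w_intr_block))] <- w_intr_block
  intr_per_read <- tapply(w_intr, read_of, sum)
  aligned_per_read <- tapply(IRanges::width(flat), read_of, sum)
  is_intronic <- switch(rule,
    any = intr_per_read >= min_overlap,
    majority = intr_per_read > aligned_per_read / 2)
  covered <- sum(IRanges::width(IRanges::intersect(
    IRanges::reduce(flat), ir_intr)))
  out <- data.frame(gene_id = model$gene_id,
                    intronic_read_count = sum(is_intronic),
                    intronic_position_total = total,
                    covered_intronic_positions = covered,
                    uncovered_intronic_positions = total - covered)
  class(out) <- c("coverage_counts", "data.frame")
  out
}

#' RINP: intronic reads per not-covered intronic position
#'
#' `RINP = intronic_read_count / (uncovered_intronic_positions +
#' epsilon)`. The pseudocount (default 1) guards the fully-covered
#' denominator; RINP is 0 exactly when there are no intronic reads.
#' High RINP indicates unspliced, nascent transcripts and is used as a
#' proxy for the onset of embryonic genome activation.
#'
#' @param counts a `coverage_counts` row (or a data frame of them).
#' @param epsilon denominator pseudocount.
#' @return numeric RINP value(s).
#' @export
compute_rinp <- function(counts, epsilon = 1) {
  counts$intronic_read_count /
    (counts$uncovered_intronic_positions + epsilon)
}

#' Aggregate RINP over gene sets, stages and replicates
#'
#' For each gene set and replicate the counts are pooled
#' (`sum(reads) / (sum(uncovered) + epsilon)`), then averaged over the
#' replicates of each stage — matching how combined gene-set RINP
#' profiles across developmental stages are reported.
#'
#' @param counts data frame of per-gene coverage counts with additional
#'   columns `stage` and `replicate`.
#' @param gene_sets named list of character vectors of gene ids;
#'   defaults to one set holding all genes.
#' @param epsilon denominator pseudocount.
#' @return an object of class `rinp_table`: list with `replicates`
#'   (gene_set x stage x replicate pooled RINP), `stage_means` and
#'   `per_gene` (per gene x stage x replicate RINP).
#' @export
aggregate_rinp <- function(counts, gene_sets = NULL, epsilon = 1) {
  stopifnot(is.data.frame(counts),
            all(c("gene_id", "stage", "replicate",
                  "intronic_read_count",
                  "uncovered_intronic_positions") %in% names(counts)))
  if (is.null(gene_sets))
    gene_sets <- list(all = unique(counts$gene_id))
  if (any(!vapply(gene_sets, length, 1L)))
    stop("empty gene set")
  per_gene <- counts[, c("gene_id", "stage", "replicate")]
  per_gene$rinp <- compute_rinp(counts, epsilon)
  reps <- do.call(rbind, lapply(names(gene_sets), function(gs) {
    sub <- counts[counts$gene_id %in% gene_sets[[gs]], , drop = FALSE]
    if (nrow(sub) == 0L) stop("gene set ", gs, " matches no genes")
    agg <- stats::aggregate(
      cbind(reads = sub$intronic_read_count,
            uncovered = sub$uncovered_intronic_positions),
      by = list(stage = sub$stage, replicate = sub$replicate), FUN = sum)
    data.frame(gene_set = gs, stage = agg$stage,
               replicate = agg$replicate,
               rinp = agg$reads / (agg$uncovered + epsilon))
  }))
  means <- stats::aggregate(rinp ~ gene_set + stage, data = reps,
                            FUN = mean)
  names(means)[names(means) == "rinp"] <- "mean_rinp"
  structure(list(replicates = reps, stage_means = means,
                 per_gene = per_gene, epsilon = epsilon),
            class = "rinp_table")
}

#' @export
print.rinp_table <- function(x, ...) {
  cat("RINP (intronic reads per not-covered intronic position)\n")
  cat("Stage means by gene set:\n")
  print(x$stage_means, row.names = FALSE, digits = 4)
  invisible(x)
}
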