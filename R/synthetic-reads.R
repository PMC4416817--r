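#' Gene model
#'
#' Minimal exon-level gene model for intron coverage analysis.
#' Coordinates are 1-based inclusive, as in GTF.
#'
#' @param gene_id gene identifier, e.g. `"NUP153"`.
#' @param seqname reference sequence name.
#' @param start,end gene span.
#' @param exons data frame with columns `start`, `end` (sorted,
#'   non-overlapping, within the span).
#' @param strand `"+"`, `"-"` or `"*"` (strand is ignored by the
#'   coverage counting).
#' @return a `gene_model` list.
#' @export
gene_model <- function(gene_id, seqname, start, end, exons,
                       strand = "+") {
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (end < start) stop("model error: gene end before start")
  if (nrow(exons) == 0) stop("model error: gene needs at least one exon")
  if (any(exons$end < exons$start))
    stop("model error: exon end before start")
  if (any(exons$start < start) || any(exons$end > end))
    stop("model error: exons exceed the gene span")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("model error: overlapping exons")
  structure(list(gene_id = gene_id, seqname = seqname,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons, strand = strand),
            class = "gene_model")
}

#' Read gene models from a GTF file
#'
#' Collects `exon` features grouped by `gene_id`; the gene span is the
#' range of its exons unless a `gene` feature is present.
#'
#' @param path GTF file.
#' @param genes optional character vector restricting to these gene ids.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models_gtf <- function(path, genes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  ids <- as.character(ex$gene_id)
  if (!is.null(genes)) ex <- ex[ids %in% genes]
  ids <- as.character(ex$gene_id)
  out <- list()
  for (g in unique(ids)) {
    eg <- ex[ids == g]
    e <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(eg),
                                          GenomicRanges::end(eg)))
    gspan <- gr[gr$type == "gene" & as.character(gr$gene_id) == g]
    s <- if (length(gspan)) GenomicRanges::start(gspan)[1] else
      min(IRanges::start(e))
    en <- if (length(gspan)) GenomicRanges::end(gspan)[1] else
      max(IRanges::end(e))
    out[[g]] <- gene_model(
      g, as.character(GenomicRanges::seqnames(eg))[1], s, en,
      data.frame(start = IRanges::start(e), end = IRanges::end(e)),
      strand = as.character(GenomicRanges::strand(eg))[1])
  }
  out
}

#' Parameters for the spliced/unspliced read simulator
#'
#' @param gene_models list of [gene_model()] objects.
#' @param unspliced_fraction fraction `u` of reads drawn from unspliced
#'   pre-mRNA (uniform over the gene span); the remainder are spliced
#'   (uniform over the exonic transcript, junction reads carry `N` skip
#'   segments over the introns).
#' @param n_reads total number of reads.
#' @param read_length read length in bases (default 80, single-end).
#' @param seed master seed; identical parameters and seed give an
#'   identical record set.
#' @return a validated `read_sim_params` list.
#' @export
read_sim_params <- function(gene_models, unspliced_fraction, n_reads,
                            read_length = 80L, seed = 1L) {
  if (!length(gene_models))
    stop("parameter error: empty gene model list")
  if (unspliced_fraction < 0 || unspliced_fraction > 1)
    stop("parameter error: unspliced_fraction must lie in [0, 1]")
  read_length <- as.integer(read_length)
  for (gm in gene_models) {
    stopifnot(inherits(gm, "gene_model"))
    tx_len <- sum(gm$exons$end - gm$exons$start + 1L)
    if (read_length > tx_len)
      stop("parameter error: read_length exceeds the spliced transcript ",
           "length of ", gm$gene_id)
    if (read_length > gm$end - gm$start + 1L)
      stop("parameter error: read_length exceeds the span of ", gm$gene_id)
  }
  structure(list(gene_models = gene_models,
                 unspliced_fraction = unspliced_fraction,
                 n_reads = as.integer(n_reads),
                 read_length = read_length, seed = as.integer(seed)),
            class = "read_sim_params")
}

# map a spliced (transcript-coordinate) read start to genomic blocks and
# a CIGAR with N skips
spliced_blocks <- function(gm, t_start, len) {
  w <- gm$exons$end - gm$exons$start + 1L
  cum <- cumsum(w)
  remaining <- len
  pos <- t_start
  blocks <- list()
  repeat {
    ex_i <- which(pos <= cum)[1]
    off_in_ex <- pos - c(0L, cum)[ex_i] - 1L
    gstart <- gm$exons$start[ex_i] + off_in_ex
    avail <- gm$exons$end[ex_i] - gstart + 1L
    take <- min(avail, remaining)
    blocks[[length(blocks) + 1L]] <- c(gstart, gstart + take - 1L)
    remaining <- remaining - take
    if (remaining == 0L) break
    pos <- cum[ex_i] + 1L
  }
  blocks
}

blocks_to_cigar <- function(blocks) {
  parts <- character(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (i > 1) {
      gap <- b[1] - blocks[[i - 1]][2] - 1L
      parts <- c(parts, paste0(gap, "N"))
    }
    parts <- c(parts, paste0(b[2] - b[1] + 1L, "M"))
  }
  paste(parts, collapse = "")
}

#' Simulate spliced and unspliced read alignments
#'
#' @param params a [read_sim_params()] object.
#' @return data frame of class `sim_alignments` with SAM-like columns
#'   `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, plus `gene_id`
#'   and the truth column `unspliced`; reference lengths in attribute
#'   `"refs"`.
#' @export
gen_reads <- function(params) {
  p <- if (inherits(params, "read_sim_params")) params
       else do.call(read_sim_params, params)
  L <- p$read_length
  gms <- p$gene_models
  recs <- with_seed(p$seed, {
    gi <- sample.int(length(gms), p$n_reads, replace = TRUE)
    unspliced <- stats::runif(p$n_reads) < p$unspliced_fraction
    pos <- integer(p$n_reads)
    cigar <- character(p$n_reads)
    for (r in seq_len(p$n_reads)) {
      gm <- gms[[gi[r]]]
      if (unspliced[r]) {
        pos[r] <- gm$start +
          sample.int(gm$end - gm$start + 1L - L + 1L, 1L) - 1L
        cigar[r] <- paste0(L, "M")
      } else {
        tx_len <- sum(gm$exons$end - gm$exons$start + 1L)
        t0 <- sample.int(tx_len - L + 1L, 1L)
        blocks <- spliced_blocks(gm, t0, L)
        pos[r] <- blocks[[1]][1]
        cigar[r] <- blocks_to_cigar(blocks)
      }
    }
    data.frame(qname = sprintf("r%06d", seq_len(p$n_reads)),
               flag = 0L,
               rname = vapply(gms[gi], function(g) g$seqname, ""),
               pos = pos, mapq = 60L, cigar = cigar,
               gene_id = vapply(gms[gi], function(g) g$gene_id, ""),
               unspliced = unspliced,
               stringsAsFactors = FALSE)
  })
  refs <- tapply(vapply(gms, function(g) g$end + 1000L, 0L),
                 vapply(gms, function(g) g$seqname, ""), max)
  attr(recs, "refs") <- refs
  attr(recs, "read_length") <- L
  class(recs) <- c("sim_alignments", "data.frame")
  recs
}

#' Write simulated alignments as a SAM file
#'
#' Emits a valid header (`@HD`, one `@SQ` per reference) and one record
#' per read with placeholder sequence/quality strings.
#'
#' @param alignments a `sim_alignments` data frame from [gen_reads()].
#' @param path output file (`.sam`).
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, path) {
  refs <- attr(alignments, "refs")
  L <- attr(alignments, "read_length") %||% 80L
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  seqs <- strrep("A", L)
  qual <- strrep("I", L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  alignments$qname, alignments$flag, alignments$rname,
                  alignments$pos, alignments$mapq, alignments$cigar,
                  seqs, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM text is converted on the fly; duplicate, secondary,
#' supplementary and unmapped records are excluded by default.
#'
#' @param path a `.sam` or `.bam` file.
#' @param drop_flags SAM flag bits to exclude (default: unmapped 0x4,
#'   secondary 0x100, duplicate 0x400, supplementary 0x800).
#' @return data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`.
#' @export
read_alignments <- function(path, drop_flags = 0x4 + 0x100 + 0x400 + 0x800) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  df <- data.frame(qname = res$qname, flag = res$flag,
                   rname = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, cigar = res$cigar,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$pos) & bitwAnd(df$flag, drop_flags) == 0L, ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
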