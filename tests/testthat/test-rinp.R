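# Intron derivation, coverage counting and the RINP statistic

test_that("introns are the span minus the exons", {
  expect_equal(derive_introns(toy_gene()),
               data.frame(start = 201L, end = 800L))
  single <- gene_model("S", "chr1", 1, 500,
                       data.frame(start = 1, end = 500))
  expect_equal(nrow(derive_introns(single)), 0L)
  three <- gene_model("T", "chr1", 1, 900,
                      data.frame(start = c(1, 301, 701),
                                 end = c(100, 400, 900)))
  expect_equal(derive_introns(three),
               data.frame(start = c(101L, 401L), end = c(300L, 700L)))
})

test_that("gene model validation catches malformed exon structures", {
  expect_error(gene_model("X", "c", 1, 100,
                          data.frame(start = 50, end = 150)), "exceed")
  expect_error(gene_model("X", "c", 1, 100,
                          data.frame(start = c(1, 20),
                                     end = c(30, 60))), "overlap")
})

test_that("tiled reads reproduce the interval-arithmetic oracle", {
  al <- data.frame(qname = sprintf("r%d", 1:5), flag = 0L,
                   rname = "chr1", pos = c(201, 251, 301, 351, 401),
                   mapq = 60L, cigar = "50M")
  cc <- intronic_coverage(al, toy_gene())
  expect_equal(cc$intronic_read_count, 5L)
  expect_equal(cc$intronic_position_total, 600L)
  expect_equal(cc$covered_intronic_positions, 250L)
  expect_equal(cc$uncovered_intronic_positions, 350L)
  expect_equal(compute_rinp(cc), 5 / 351)
})

test_that("skip segments are not aligned bases", {
  # read spanning the whole intron via an N segment
  al <- data.frame(qname = "s", flag = 0L, rname = "chr1", pos = 151,
                   mapq = 60L, cigar = "50M600N30M")
  cc <- intronic_coverage(al, toy_gene())
  expect_equal(cc$intronic_read_count, 0L)
  expect_equal(cc$covered_intronic_positions, 0L)
  # a deletion inside the intron consumes reference without alignment
  al2 <- data.frame(qname = "d", flag = 0L, rname = "chr1", pos = 195,
                    mapq = 60L, cigar = "10M20D10M")
  cc2 <- intronic_coverage(al2, toy_gene())
  expect_equal(cc2$intronic_read_count, 1L)   # 10 aligned intronic bases
  expect_equal(cc2$covered_intronic_positions, 4L + 10L)
})

test_that("no reads gives the zero-coverage record", {
  al <- data.frame(qname = character(0), flag = integer(0),
                   rname = character(0), pos = integer(0),
                   mapq = integer(0), cigar = character(0))
  cc <- intronic_coverage(al, toy_gene())
  expect_equal(unname(unlist(cc[, -1])), c(0, 600, 0, 600))
})

test_that("rinp formula and its edge cases", {
  cc <- data.frame(intronic_read_count = 5,
                   uncovered_intronic_positions = 350)
  expect_equal(compute_rinp(cc), 5 / 351)
  expect_equal(compute_rinp(data.frame(intronic_read_count = 0,
                                       uncovered_intronic_positions = 600)),
               0)
  expect_equal(compute_rinp(data.frame(intronic_read_count = 100,
                                       uncovered_intronic_positions = 0)),
               100)
})

test_that("aggregation pools counts then averages replicates", {
  counts <- data.frame(
    gene_id = rep(c("A", "B"), each = 3),
    stage = rep("s1", 6),
    replicate = rep(1:3, 2),
    intronic_read_count = c(10, 20, 30, 10, 20, 30),
    uncovered_intronic_positions = c(999, 999, 999, 999, 999, 999))
  rt <- aggregate_rinp(counts, gene_sets = list(AB = c("A", "B"),
                                                onlyA = "A"))
  reps <- rt$replicates
  ab1 <- reps$rinp[reps$gene_set == "AB" & reps$replicate == 1]
  expect_equal(ab1, 20 / 1999)          # pooled counts per replicate
  a1 <- reps$rinp[reps$gene_set == "onlyA" & reps$replicate == 1]
  expect_equal(a1, 10 / 1000)           # single gene: per-gene value
  # two genes with identical counts: pooled ~ per-gene for large u
  expect_equal(ab1, a1, tolerance = 2 / 1000)
  # stage mean over replicates
  m <- rt$stage_means
  expect_equal(m$mean_rinp[m$gene_set == "onlyA"],
               mean(c(10, 20, 30) / 1000))
  expect_error(aggregate_rinp(counts, gene_sets = list(none = "ZZZ")),
               "no genes")
})

test_that("three replicates with RINP 0.1/0.2/0.3 average to 0.2", {
  counts <- data.frame(gene_id = "G", stage = "s", replicate = 1:3,
                       intronic_read_count = c(100, 200, 300),
                       uncovered_intronic_positions = rep(999, 3))
  rt <- aggregate_rinp(counts)
  expect_equal(rt$stage_means$mean_rinp, 0.2)
})

test_that("SAM round trip and flag filtering via Rsamtools", {
  gm <- toy_gene()
  al <- gen_reads(read_sim_params(list(gm), 0.6, 300, 50, seed = 71))
  sam <- tempfile(fileext = ".sam")
  write_sam(al, sam)
  back <- read_alignments(sam)
  expect_equal(nrow(back), 300L)
  cc_direct <- intronic_coverage(al, gm)
  cc_file <- intronic_coverage(back, gm)
  expect_equal(cc_file$intronic_read_count, cc_direct$intronic_read_count)
  expect_equal(cc_file$covered_intronic_positions,
               cc_direct$covered_intronic_positions)
  # a secondary alignment is dropped on read
  al2 <- al
  al2$flag[1] <- bitwOr(al2$flag[1], 256L)
  sam2 <- tempfile(fileext = ".sam")
  write_sam(al2, sam2)
  expect_equal(nrow(read_alignments(sam2)), 299L)
})

test_that("expected RINP rises with the unspliced fraction", {
  gm <- gene_model("LONG", "chr1", 1, 20000,
                   data.frame(start = c(1, 18001), end = c(2000, 20000)))
  rinp_at <- function(u, seed) {
    al <- gen_reads(read_sim_params(list(gm), u, 300, 80, seed = seed))
    compute_rinp(intronic_coverage(al, gm))
  }
  rhos <- vapply(1:5, function(s) {
    r <- vapply(c(0, 0.25, 0.5, 1), rinp_at, 0, seed = s)
    suppressWarnings(cor(c(0, 0.25, 0.5, 1), r, method = "spearman"))
  }, 0)
  expect_gt(mean(rhos), 0.95)
  # u = 0 is exactly zero
  expect_identical(rinp_at(0, 9), 0)
})

test_that("doubling depth does not decrease RINP at fixed u", {
  gm <- gene_model("LONG", "chr1", 1, 20000,
                   data.frame(start = c(1, 18001), end = c(2000, 20000)))
  r1 <- vapply(1:4, function(s) {
    al <- gen_reads(read_sim_params(list(gm), 0.3, 200, 80, seed = s))
    compute_rinp(intronic_coverage(al, gm))
  }, 0)
  r2 <- vapply(1:4, function(s) {
    al <- gen_reads(read_sim_params(list(gm), 0.3, 400, 80, seed = s))
    compute_rinp(intronic_coverage(al, gm))
  }, 0)
  expect_gte(mean(r2), mean(r1))
})

test_that("GTF import reconstructs gene models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "test", "gene", "1", "1000", ".", "+", ".",
          "gene_id \"TOY\";", sep = "\t"),
    paste("chr1", "test", "exon", "1", "200", ".", "+", ".",
          "gene_id \"TOY\";", sep = "\t"),
    paste("chr1", "test", "exon", "801", "1000", ".", "+", ".",
          "gene_id \"TOY\";", sep = "\t")), gtf)
  gms <- read_gene_models_gtf(gtf)
  expect_named(gms, "TOY")
  expect_equal(derive_introns(gms$TOY),
               data.frame(start = 201L, end = 800L))
})
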