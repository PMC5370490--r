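test_that("SAM ingestion preserves records, flags and coordinates", {
  # coordinate-sorted fixture so the BAM conversion keeps file order
  recs <- make_reads(
    qname = c("a", "b", "c", "a", "b", "c"),
    flag = c(99L, 99L, 97L, 147L, 147L, 145L),
    rname = c("chr1", "chr1", "chr1", "chr1", "chr1", "chrM"),
    pos = c(100L, 200L, 300L, 350L, 450L, 5000L),
    mapq = c(60L, 50L, 40L, 60L, 50L, 40L),
    mrnm = c("chr1", "chr1", "chrM", "chr1", "chr1", "chr1"),
    mpos = c(350L, 450L, 5000L, 100L, 200L, 300L))
  sam <- write_sam_fixture(recs, tempfile(fileext = ".sam"))
  got <- read_alignments(sam)
  expect_equal(nrow(got), 6L)
  expect_equal(got[order(got$qname, got$pos), c("qname", "flag", "pos")],
               recs[order(recs$qname, recs$pos), c("qname", "flag", "pos")],
               ignore_attr = TRUE)
  expect_equal(got$rname[got$qname == "c" & got$pos == 5000L], "chrM")
  expect_named(attr(got, "contigs"))

  empty <- write_sam_fixture(recs[0, ], tempfile(fileext = ".sam"))
  expect_equal(nrow(read_alignments(empty)), 0L)
})

test_that("secondary records can be excluded at ingest", {
  base <- make_reads(qname = sprintf("r%02d", 1:10),
                     flag = c(rep(99L, 8L), 355L, 355L),
                     rname = "chr1", pos = 1000L + 1:10)
  sam <- write_sam_fixture(base, tempfile(fileext = ".sam"))
  expect_equal(nrow(read_alignments(sam)), 10L)
  expect_equal(nrow(read_alignments(sam, primary_only = TRUE)), 8L)
})

test_that("read filters drop duplicates, secondaries, and low MAPQ", {
  recs <- make_reads(qname = sprintf("r%02d", 1:10),
                     flag = c(rep(99L, 7L), rep(1123L, 3L)),  # 3 dup-flagged
                     rname = "chr1", pos = 1:10,
                     mapq = c(0L, 10L, 20L, 30L, 60L, rep(60L, 5L)))
  expect_equal(nrow(filter_reads(recs, drop_duplicates = TRUE)), 7L)
  # min_mapq = 0 leaves the stream unchanged
  expect_equal(filter_reads(recs, drop_duplicates = FALSE, min_mapq = 0L),
               recs, ignore_attr = TRUE)
  # of mapq {0,10,20,30,60} three are >= 20
  sub <- recs[1:5, ]
  expect_equal(nrow(filter_reads(sub, drop_duplicates = FALSE,
                                 min_mapq = 20L)), 3L)
})

test_that("filtering is idempotent and duplicate removal is monotone", {
  sim <- small_sim(seed = 5, n = 2, background = 3000)
  for (sid in names(sim$samples)[1:2]) {
    reads <- sim$samples[[sid]]
    f1 <- filter_reads(reads, drop_duplicates = TRUE, min_mapq = 10L)
    f2 <- filter_reads(f1, drop_duplicates = TRUE, min_mapq = 10L)
    expect_identical(f1, f2)
    part <- sim$partitions$chromosomes
    m_with <- count_mapped_reads(filter_reads(reads, drop_duplicates = FALSE),
                                 part)
    m_without <- count_mapped_reads(f1, part)
    expect_true(all(m_without <= m_with))
  }
})

test_that("chimeric pair extraction follows the mito-nuclear definition", {
  p1 <- make_pair("q1", "chr1", 1000L, "chrM", 5000L)
  got <- extract_numt_pairs(p1, sample_id = "s1", genome_type = "t")
  expect_equal(nrow(got), 1L)
  expect_equal(got$nuclear_contig, "chr1")
  expect_equal(got$nuclear_pos, 1000L)
  expect_equal(got$mito_pos, 5000L)
  expect_equal(got$min_mapq, 60L)

  # nuclear-nuclear and mito-mito pairs are not chimeric
  both <- bind_reads(make_pair("q2", "chr1", 10L, "chr2", 20L),
                     make_pair("q3", "chrM", 30L, "chrM", 40L))
  expect_equal(nrow(extract_numt_pairs(both, sample_id = "s1")), 0L)

  # a pair is reconstructed from a single surviving mate, and never
  # double-counted when both mates survive
  orphan <- make_reads("q4", 97L, "chrM", 700L, mapq = 13L,
                       mrnm = "chr2", mpos = 4242L)
  got <- extract_numt_pairs(orphan, sample_id = "s1")
  expect_equal(got$nuclear_contig, "chr2")
  expect_equal(got$nuclear_pos, 4242L)
  expect_equal(got$mito_pos, 700L)
  expect_equal(got$min_mapq, 13L)
  two <- make_pair("q5", "chr1", 1L, "chrM", 2L, mapq1 = 60L, mapq2 = 7L)
  got <- extract_numt_pairs(two, sample_id = "s1")
  expect_equal(nrow(got), 1L)
  expect_equal(got$min_mapq, 7L)
})

test_that("unknown mitochondrial contig configuration is rejected", {
  p1 <- make_pair("q1", "chr1", 1000L, "chrM", 5000L)
  expect_error(extract_numt_pairs(p1, mito_names = "chrMito"),
               "chrMito.*header contigs|header contigs", ignore.case = TRUE)
})

test_that("mapped-read counting assigns leftmost coordinates to intervals", {
  b <- genome_build(toy_contigs, sex_chromosomes = "chrX")
  win <- build_windows(b, size = 5e5)
  reads <- make_reads(sprintf("r%03d", 1:100), 99L, "chr1", 100L + 1:100)
  m <- count_mapped_reads(reads, win)
  expect_equal(unname(m["chr1:0-500000"]), 100L)
  expect_equal(sum(m), 100L)
  expect_equal(sum(count_mapped_reads(reads[0, ], win)), 0L)

  # 50 reads straddling a window boundary: counts equal a brute-force rescan
  set.seed(42)
  pos <- as.integer(5e5 + sample(-50:49, 50))
  straddle <- make_reads(sprintf("s%03d", 1:50), 99L, "chr1", pos)
  m2 <- count_mapped_reads(straddle, win)
  oracle <- oracle_interval_counts("chr1", pos, win)
  expect_equal(as.integer(m2), as.integer(oracle))
})

test_that("coordinate convention round-trips at interval boundaries", {
  part <- new_partition(data.frame(interval_id = c("w1", "w2"),
                                   contig = "chr1", start = c(0, 100),
                                   end = c(100, 200)), "win")
  # SAM 1-based position p is in [start, end) iff start <= p-1 < end
  reads <- make_reads(c("a", "b", "c", "d"), 99L, "chr1",
                      c(1L, 100L, 101L, 200L))
  m <- count_mapped_reads(reads, part)
  expect_equal(unname(m), c(2L, 2L))
})

test_that("per-sample counts join pairs and mapped reads per interval", {
  b <- genome_build(toy_contigs, sex_chromosomes = "chrX")
  win <- build_windows(b, size = 5e5)
  empty <- extract_numt_pairs(make_reads(character(), integer(),
                                         character(), integer()),
                              sample_id = "s1")
  m0 <- stats::setNames(rep(0L, length(unique(win$interval_id))),
                        unique(win$interval_id))
  cnt <- build_sample_counts(empty, m0, win, "s1", "t")
  expect_true(all(cnt$numt_count == 0L))

  pairs <- extract_numt_pairs(bind_reads(
    make_pair("p1", "chr1", 10L, "chrM", 1L),
    make_pair("p2", "chr1", 20L, "chrM", 2L),
    make_pair("p3", "chr1", 30L, "chrM", 3L),
    make_pair("p4", "chr1", 40L, "chrM", 4L),
    make_pair("p5", "chr1", 50L, "chrM", 5L)), sample_id = "s1")
  m <- m0; m["chr1:0-500000"] <- 1000000L
  cnt <- build_sample_counts(pairs, m, win, "s1", "t")
  expect_equal(cnt$numt_count[cnt$interval_id == "chr1:0-500000"], 5L)
  expect_equal(cnt$mapped_count[cnt$interval_id == "chr1:0-500000"],
               1000000L)
})

test_that("counts are conserved across nesting levels on simulated data", {
  sim <- small_sim(seed = 9, n = 2, background = 10000)
  quant <- quantify_cohort(sim, levels = c("gen", "chr", "win"))
  for (sid in sim$metadata$sample_id) {
    gen <- quant$counts$gen[quant$counts$gen$sample_id == sid, ]
    chr <- quant$counts$chr[quant$counts$chr$sample_id == sid, ]
    win <- quant$counts$win[quant$counts$win$sample_id == sid, ]
    # genome N = sum of chromosome N (sex chromosomes included)
    expect_equal(gen$numt_count, sum(chr$numt_count))
    # genome M = sum of chromosome M over autosomes only
    auto <- setdiff(sim$build$nuclear, sim$build$sex_chromosomes)
    expect_equal(gen$mapped_count,
                 sum(chr$mapped_count[chr$interval_id %in% auto]))
    # windows within a chromosome sum to the chromosome (tiling windows)
    for (ctg in sim$build$nuclear) {
      wsel <- win[startsWith(win$interval_id, paste0(ctg, ":")), ]
      expect_equal(sum(wsel$mapped_count),
                   chr$mapped_count[chr$interval_id == ctg])
      expect_equal(sum(wsel$numt_count),
                   chr$numt_count[chr$interval_id == ctg])
    }
    # per-chromosome N matches the truth-table tally
    truth <- sim$truth[sim$truth$sample_id == sid & !sim$truth$is_duplicate, ]
    tally <- table(factor(truth$nuclear_contig, levels = chr$interval_id))
    expect_equal(chr$numt_count, as.integer(tally))
  }
})

test_that("extraction equals the brute-force query-name scan on a SAM file", {
  dir <- tempfile()
  sim <- simulate_cohort(sim_config(seed = 21, n_participants = 1,
                                    background_pairs = 4000), dir = dir,
                         write_fasta = FALSE)
  for (sid in sim$metadata$sample_id) {
    f <- file.path(dir, paste0(sid, ".sam"))
    det <- extract_numt_pairs(filter_reads(read_alignments(f)),
                              sample_id = sid)
    expect_equal(pair_keys(det), oracle_chimeric_keys(f))
  }
  unlink(dir, recursive = TRUE)
})
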