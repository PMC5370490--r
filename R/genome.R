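#' Describe a genome build
#'
#' A genome build names the contigs and their lengths, which chromosomes are
#' sex chromosomes (excluded from genome-level mapped-read normalization),
#' and the mitochondrial contig. Contig lengths typically come from a SAM/BAM
#' header or a FASTA index; any named integer vector works.
#'
#' @param contigs Named numeric vector of contig lengths (bases).
#' @param sex_chromosomes Character vector of sex-chromosome names.
#' @param mito_name Name of the mitochondrial contig.
#' @return An object of class `genome_build`.
#' @examples
#' genome_build(c(chr1 = 1e6, chrX = 5e5, chrM = 16569))
#' @export
genome_build <- function(contigs, sex_chromosomes = c("chrX", "chrY"),
                         mito_name = "chrM") {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stopf("contigs must be a named vector of lengths")
  if (any(contigs <= 0)) stopf("contig lengths must be positive")
  if (!mito_name %in% names(contigs))
    stopf("mitochondrial contig '%s' not among contigs (%s)", mito_name,
          paste(names(contigs), collapse = ", "))
  structure(list(
    contigs = contigs,
    sex_chromosomes = intersect(sex_chromosomes, names(contigs)),
    mito_name = mito_name,
    nuclear = setdiff(names(contigs), mito_name)
  ), class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", length(x$contigs), " contigs, ",
      sum(x$contigs), " bp total\n", sep = "")
  cat("  mito: ", x$mito_name, " (", x$contigs[[x$mito_name]], " bp); sex: ",
      paste(x$sex_chromosomes, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Construct an interval partition
#'
#' Partitions are plain data frames with columns `interval_id`, `contig`,
#' `start`, `end` (0-based half-open, as in BED) plus optional attribute
#' columns (`stain` for cytobands, `gene`/`strand` for mitochondrial genes,
#' `in_M` for the genome level). A `level` attribute records which of the
#' nested partitions it represents. Within a level, intervals on one contig
#' must be non-overlapping, except sliding windows built with `step < size`,
#' which are counted independently. One `interval_id` may span several rows
#' (e.g. the two arcs of the origin-wrapping D-loop); counts are aggregated
#' by id.
#'
#' @param df Data frame with `interval_id`, `contig`, `start`, `end`.
#' @param level One of `gen`, `chr`, `arm`, `cyt`, `win`, `mtg`, `mst`, `mgn`.
#' @param allow_overlap Skip the disjointness check (sliding windows).
#' @return The data frame, classed `numt_partition`, with a `level` attribute.
#' @export
new_partition <- function(df, level, allow_overlap = identical(level, "win")) {
  level <- match.arg(level, c(NUCLEAR_LEVELS, MITO_LEVELS))
  need <- c("interval_id", "contig", "start", "end")
  if (!all(need %in% names(df)))
    stopf("partition needs columns %s", paste(need, collapse = ", "))
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$start >= df$end)) stopf("partition has start >= end")
  if (any(df$start < 0)) stopf("partition has negative start")
  if (!allow_overlap) {
    for (ctg in unique(df$contig)) {
      rows <- df[df$contig == ctg, , drop = FALSE]
      rows <- rows[order(rows$start), , drop = FALSE]
      if (nrow(rows) > 1L && any(rows$start[-1L] < rows$end[-nrow(rows)]))
        stopf("overlapping intervals on %s in level '%s'", ctg, level)
    }
  }
  rownames(df) <- NULL
  structure(df, level = level, class = c("numt_partition", "data.frame"))
}

#' @export
print.numt_partition <- function(x, ...) {
  cat("<numt_partition> level '", attr(x, "level"), "': ",
      length(unique(x$interval_id)), " intervals (", nrow(x), " rows)\n",
      sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

partition_level <- function(partition) attr(partition, "level")

#' Genome-level partition
#'
#' One row per nuclear contig, all sharing the meta-interval id `"gen"` in
#' spirit: NUMT pairs on every nuclear contig (sex chromosomes included)
#' count toward genome-level N, while the `in_M` column marks contigs whose
#' mapped reads enter genome-level M. Sex chromosomes are excluded from M to
#' avoid the representation bias tied to chromosome-length differences
#' between the sexes.
#'
#' @param build A [genome_build()].
#' @return A `numt_partition` of level `gen` with an `in_M` column.
#' @export
partition_genome <- function(build) {
  ctg <- build$nuclear
  new_partition(data.frame(
    interval_id = ctg, contig = ctg, start = 0,
    end = as.numeric(build$contigs[ctg]),
    in_M = !ctg %in% build$sex_chromosomes,
    stringsAsFactors = FALSE
  ), "gen")
}

#' Chromosome-level partition
#'
#' @param build A [genome_build()].
#' @return A `numt_partition` of level `chr`, one interval per nuclear contig.
#' @export
partition_chromosomes <- function(build) {
  ctg <- build$nuclear
  new_partition(data.frame(
    interval_id = ctg, contig = ctg, start = 0,
    end = as.numeric(build$contigs[ctg]),
    stringsAsFactors = FALSE
  ), "chr")
}

#' Sliding-window partition
#'
#' Tiles every nuclear chromosome with windows of `size` bases advancing by
#' `step`. With the default `step = size` the windows tile the chromosome
#' exactly (pairwise disjoint, union = chromosome), which is what the
#' conservation invariants and pooled normalization assume; with
#' `step < size` overlapping windows are produced and each window is counted
#' independently. The last window of each chromosome is clipped at the
#' chromosome end.
#'
#' @param build A [genome_build()].
#' @param size Window size in bases (default 2.5 Mb).
#' @param step Step in bases; `0 < step <= size`. Default `size` (tiling).
#' @return A `numt_partition` of level `win` with ids `"contig:start-end"`.
#' @examples
#' b <- genome_build(c(chr1 = 6e6, chrM = 16569), sex_chromosomes = character())
#' build_windows(b, size = 2.5e6)  # 3 windows, last clipped to 1 Mb
#' @export
build_windows <- function(build, size = 2.5e6, step = size) {
  if (!is.numeric(size) || size <= 0) stopf("window size must be > 0")
  if (!is.numeric(step) || step <= 0 || step > size)
    stopf("window step must satisfy 0 < step <= size")
  out <- lapply(build$nuclear, function(ctg) {
    len <- as.numeric(build$contigs[[ctg]])
    starts <- seq(0, len - 1, by = step)
    ends <- pmin(starts + size, len)
    data.frame(
      interval_id = sprintf("%s:%d-%d", ctg, as.integer(starts),
                            as.integer(ends)),
      contig = ctg, start = starts, end = ends, stringsAsFactors = FALSE)
  })
  new_partition(do.call(rbind, out), "win", allow_overlap = step < size)
}

GIEMSA_STAINS <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100",
                   "acen", "gvar", "stalk")

#' Load a UCSC-style cytoband table
#'
#' Reads a 5-column tab-separated cytoband table (chrom, start, end, band
#' name, Giemsa stain), 0-based half-open as distributed by UCSC, and returns
#' the cytoband partition. Interval ids are `paste0(chrom, band)` (e.g.
#' `"chr1p11"`).
#'
#' @param path Path to the cytoband TSV (no header).
#' @return A `numt_partition` of level `cyt` with `band` and `stain` columns.
#' @export
load_cytobands <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(new_partition(data.frame(interval_id = character(),
                                    contig = character(), start = numeric(),
                                    end = numeric(), band = character(),
                                    stain = character(),
                                    stringsAsFactors = FALSE)[0, ], "cyt"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stopf("malformed cytoband line %d: expected 5 tab-separated fields",
          bad[1L])
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(start) || anyNA(end))
    stopf("malformed cytoband line %d: non-numeric coordinates",
          which(is.na(start) | is.na(end))[1L])
  stain <- m[, 5L]
  if (any(!stain %in% GIEMSA_STAINS))
    stopf("malformed cytoband line %d: unknown stain '%s'",
          which(!stain %in% GIEMSA_STAINS)[1L],
          stain[!stain %in% GIEMSA_STAINS][1L])
  new_partition(data.frame(
    interval_id = paste0(m[, 1L], m[, 4L]), contig = m[, 1L],
    start = start, end = end, band = m[, 4L], stain = stain,
    stringsAsFactors = FALSE), "cyt")
}

#' Derive chromosome arms from cytobands
#'
#' Band names must begin with `p` or `q`; per chromosome, the p arm spans
#' from the smallest start to the largest end of its p bands, likewise q.
#' Centromeric (`acen`) bands belong to the arm their prefix names.
#'
#' @param cyt A cytoband partition from [load_cytobands()].
#' @return A `numt_partition` of level `arm` with ids like `"chr1p"`.
#' @export
derive_arms <- function(cyt) {
  if (partition_level(cyt) != "cyt") stopf("derive_arms expects a cyt partition")
  arm <- substr(cyt$band, 1L, 1L)
  bad <- which(!arm %in% c("p", "q"))
  if (length(bad))
    stopf("band '%s' has neither 'p' nor 'q' prefix", cyt$band[bad[1L]])
  key <- paste0(cyt$contig, arm)
  agg_s <- tapply(cyt$start, key, min)
  agg_e <- tapply(cyt$end, key, max)
  ids <- unique(key)  # keep input (genomic) order, p before q within a chrom
  new_partition(data.frame(
    interval_id = ids,
    contig = cyt$contig[match(ids, key)],
    start = as.numeric(agg_s[ids]), end = as.numeric(agg_e[ids]),
    arm = substr(ids, nchar(ids), nchar(ids)), stringsAsFactors = FALSE),
    "arm")
}

#' Bundled rCRS-style mitochondrial gene table
#'
#' A synthetic, rCRS-style annotation of the 16,569-bp human mitochondrial
#' genome: the 13 protein-coding genes, the two rRNAs, and the D-loop control
#' region (16 intervals). Where real genes overlap by a few dozen bases
#' (ATP8/ATP6, ND4L/ND4) the downstream gene's start is trimmed so the
#' partition is disjoint; the shared bases are assigned to the upstream gene.
#' The D-loop wraps the replication origin and is represented as two arcs
#' sharing one id. All genes are heavy-strand (`+`) except ND6 (`-`).
#' Coordinates are 0-based half-open.
#'
#' @param mito_name Contig name to stamp on the records.
#' @return Data frame with columns `gene`, `contig`, `start`, `end`, `strand`.
#' @export
rcrs_mito_genes <- function(mito_name = "chrM") {
  g <- function(gene, s1, e1, strand = "+")  # 1-based closed -> 0-based half-open
    data.frame(gene = gene, contig = mito_name, start = s1 - 1, end = e1,
               strand = strand, stringsAsFactors = FALSE)
  rbind(
    g("DLOOP", 16024, 16569, "."),  # arc 1 (wraps origin)
    g("DLOOP", 1, 576, "."),        # arc 2
    g("RNR1", 648, 1601), g("RNR2", 1671, 3229),
    g("ND1", 3307, 4262), g("ND2", 4470, 5511),
    g("CO1", 5904, 7445), g("CO2", 7586, 8269),
    g("ATP8", 8366, 8572), g("ATP6", 8573, 9207),  # ATP6 start trimmed
    g("CO3", 9208, 9990),                           # CO3 start trimmed
    g("ND3", 10059, 10404), g("ND4L", 10470, 10766),
    g("ND4", 10767, 12137),                         # ND4 start trimmed
    g("ND5", 12337, 14148), g("ND6", 14149, 14673, "-"),
    g("CYB", 14747, 15887))
}

#' Load mitochondrial gene annotation (BED6) and build mito partitions
#'
#' Reads a BED6 file (contig, start, end, name, score, strand; 0-based
#' half-open) of mitochondrial genes and returns the three nested
#' mitochondrial partitions: per-gene (`mgn`), per-replication-strand
#' (`mst`), and whole mitochondrial genome (`mtg`). Records sharing a name
#' are treated as arcs of one interval (the origin-wrapping D-loop). Strand
#' `+` maps to the heavy strand by default; records with strand `.` (the
#' D-loop) are excluded from the strand partition.
#'
#' @param path BED6 file path.
#' @param mito_name Mitochondrial contig name.
#' @param mito_length Mitochondrial genome length in bases.
#' @param heavy_strand Which BED strand symbol denotes the heavy strand.
#' @return List with elements `mgn`, `mst`, `mtg` (each a `numt_partition`).
#' @export
load_mito_annotation <- function(path, mito_name = "chrM",
                                 mito_length = 16569, heavy_strand = "+") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6L)
  if (length(bad))
    stopf("malformed mito BED line %d: expected 6 fields", bad[1L])
  m <- do.call(rbind, parts)
  df <- data.frame(gene = m[, 4L], contig = m[, 1L],
                   start = as.numeric(m[, 2L]), end = as.numeric(m[, 3L]),
                   strand = m[, 6L], stringsAsFactors = FALSE)
  mito_partitions(df, mito_name = mito_name, mito_length = mito_length,
                  heavy_strand = heavy_strand)
}

#' Build the three mitochondrial partitions from a gene table
#'
#' @param genes Data frame as returned by [rcrs_mito_genes()].
#' @inheritParams load_mito_annotation
#' @return List with elements `mgn`, `mst`, `mtg`.
#' @export
mito_partitions <- function(genes, mito_name = "chrM", mito_length = 16569,
                            heavy_strand = "+") {
  if (any(genes$end > mito_length))
    stopf("mito annotation interval exceeds mitochondrial length %d",
          mito_length)
  genes$contig <- mito_name
  mgn <- new_partition(data.frame(
    interval_id = genes$gene, contig = genes$contig, start = genes$start,
    end = genes$end, gene = genes$gene, strand = genes$strand,
    stringsAsFactors = FALSE), "mgn")
  stranded <- genes[genes$strand %in% c("+", "-"), , drop = FALSE]
  mst <- new_partition(data.frame(
    interval_id = ifelse(stranded$strand == heavy_strand, "heavy", "light"),
    contig = stranded$contig, start = stranded$start, end = stranded$end,
    strand = stranded$strand, stringsAsFactors = FALSE), "mst")
  mtg <- new_partition(data.frame(
    interval_id = "mtg", contig = mito_name, start = 0, end = mito_length,
    stringsAsFactors = FALSE), "mtg")
  list(mgn = mgn, mst = mst, mtg = mtg)
}

#' GC fraction per partition interval
#'
#' Computes (G+C)/(A+C+G+T) per interval from a FASTA file, case-insensitive;
#' ambiguity codes (N etc.) are excluded from the denominator. Intervals with
#' zero unambiguous bases are omitted from the result. Multi-row ids (arcs)
#' are aggregated by pooling base counts.
#'
#' @param fasta Path to a FASTA file containing the partition's contigs.
#' @param partition A `numt_partition`.
#' @return Named numeric vector: `interval_id` -> GC fraction in `[0, 1]`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTGGCC"), fa)
#' p <- new_partition(data.frame(interval_id = "w1", contig = "chr1",
#'                               start = 0, end = 8), "win")
#' gc_per_interval(fa, p)  # 6/8
#' @export
gc_per_interval <- function(fasta, partition) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(partition$contig), names(seqs))
  if (length(missing))
    stopf("contig '%s' missing from FASTA %s", missing[1L], fasta)
  n <- nrow(partition)
  gcs <- numeric(n); atgc <- numeric(n)
  for (i in seq_len(n)) {
    s <- Biostrings::subseq(seqs[[partition$contig[i]]],
                            start = partition$start[i] + 1L,
                            end = partition$end[i])
    f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    gcs[i] <- f[["C"]] + f[["G"]]
    atgc[i] <- sum(f)
  }
  num <- tapply(gcs, partition$interval_id, sum)
  den <- tapply(atgc, partition$interval_id, sum)
  out <- num / den
  out <- out[den > 0]
  ids <- unique(partition$interval_id)
  res <- as.numeric(out[ids[ids %in% names(out)]])
  names(res) <- ids[ids %in% names(out)]
  res
}

# Assign 1-based point coordinates to partition rows. Returns an integer
# count per partition *row*; callers aggregate by interval_id. A SAM 1-based
# position p lies in [start, end) (0-based half-open) iff start <= p-1 < end,
# i.e. start+1 <= p <= end in 1-based closed coordinates. Overlapping
# sliding windows each receive the point independently.
assign_points <- function(contig, pos, partition) {
  counts <- integer(nrow(partition))
  if (length(pos) == 0L) return(counts)
  for (ctg in unique(partition$contig)) {
    rows <- which(partition$contig == ctg)
    sel <- which(contig == ctg & !is.na(pos))
    if (!length(sel)) next
    ir_part <- IRanges::IRanges(start = partition$start[rows] + 1L,
                                end = partition$end[rows])
    ir_pts <- IRanges::IRanges(start = pos[sel], width = 1L)
    counts[rows] <- counts[rows] +
      IRanges::countOverlaps(ir_part, ir_pts)
  }
  counts
}

# For each point, the interval_id of the containing partition row (first
# containing row in partition order), or NA if none contains it. Used by the
# hotspot histograms, which need per-point assignment to report an
# "unannotated" catch-all.
locate_points <- function(contig, pos, partition) {
  out <- rep(NA_character_, length(pos))
  for (ctg in unique(partition$contig)) {
    rows <- which(partition$contig == ctg)
    sel <- which(contig == ctg & !is.na(pos))
    if (!length(sel)) next
    ir_part <- IRanges::IRanges(start = partition$start[rows] + 1L,
                                end = partition$end[rows])
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos[sel], width = 1L),
                                  ir_part, select = "first")
    out[sel] <- partition$interval_id[rows[hits]]
  }
  out
}

#' Export a partition as BED
#'
#' Writes the partition's intervals 0-based half-open; the name column is the
#' interval id, score 0, and strand from the `strand` column when present.
#'
#' @param partition A `numt_partition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, path) {
  strand <- if ("strand" %in% names(partition)) partition$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", partition$contig,
                   as.integer(partition$start), as.integer(partition$end),
                   partition$interval_id, strand)
  writeLines(lines, path)
  invisible(path)
}
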