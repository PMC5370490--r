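#' Read paired-end alignment records from SAM or BAM
#'
#' Ingests a SAM or BAM file into a plain data frame of read records with the
#' fields the NUMT pipeline needs: `qname`, `flag`, `rname`, `pos` (1-based
#' leftmost, as stored in SAM), `mapq`, `mrnm` (mate contig), `mpos`.
#' Coordinates are passed through unchanged. SAM text input is converted to
#' BAM on the fly with `Rsamtools::asBam` (coordinate-sorted and indexed in a
#' temporary location); region queries on BAM input require an index.
#'
#' The returned frame carries a `contigs` attribute (named lengths from the
#' header) used downstream to validate mitochondrial contig configuration.
#'
#' @param path SAM or BAM file path.
#' @param region Optional region as a `GRanges` of length 1 or a string
#'   `"contig:start-end"` (1-based, closed); requires an indexed BAM.
#' @param primary_only Drop secondary and supplementary records at ingest.
#' @return Data frame of read records, one row per alignment record.
#' @export
read_alignments <- function(path, region = NULL, primary_only = FALSE) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else bam <- path
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  contigs <- hdr$targets
  which <- NULL
  if (!is.null(region)) {
    if (is.character(region)) {
      m <- regmatches(region,
                      regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
      if (length(m) != 4L) stopf("bad region string '%s'", region)
      region <- GenomicRanges::GRanges(m[2L], IRanges::IRanges(
        as.integer(m[3L]), as.integer(m[4L])))
    }
    which <- region
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "mrnm", "mpos")
  param <- if (is.null(which)) Rsamtools::ScanBamParam(what = what)
           else Rsamtools::ScanBamParam(what = what, which = which)
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  df <- data.frame(
    qname = as.character(res$qname), flag = as.integer(res$flag),
    rname = as.character(res$rname), pos = as.integer(res$pos),
    mapq = as.integer(res$mapq), mrnm = as.character(res$mrnm),
    mpos = as.integer(res$mpos), stringsAsFactors = FALSE)
  if (primary_only)
    df <- df[!(has_flag(df$flag, FLAG_SECONDARY) |
               has_flag(df$flag, FLAG_SUPPLEMENTARY)), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "contigs") <- contigs
  df
}

#' Quality-control filter on read records
#'
#' Pure, order-preserving filter: drops duplicate-flagged records (the
#' Picard-style duplicate elimination step), secondary/supplementary
#' records, and records below a mapping-quality floor. Applying the filter
#' twice with the same parameters is a no-op.
#'
#' @param reads Read-record frame from [read_alignments()].
#' @param drop_duplicates Drop records with the duplicate flag (default TRUE).
#' @param drop_secondary_supplementary Drop secondary and supplementary
#'   records (default TRUE; including them would double-count pairs).
#' @param min_mapq Minimum mapping quality to retain (default 0: no filter,
#'   matching a pipeline with no stated MAPQ cut-off). Raising it trades
#'   repeat-mediated false chimeras against sensitivity.
#' @return Filtered read-record frame (attributes preserved).
#' @export
filter_reads <- function(reads, drop_duplicates = TRUE,
                         drop_secondary_supplementary = TRUE, min_mapq = 0L) {
  keep <- rep(TRUE, nrow(reads))
  if (drop_duplicates) keep <- keep & !has_flag(reads$flag, FLAG_DUPLICATE)
  if (drop_secondary_supplementary)
    keep <- keep & !(has_flag(reads$flag, FLAG_SECONDARY) |
                     has_flag(reads$flag, FLAG_SUPPLEMENTARY))
  if (min_mapq > 0L)
    keep <- keep & !is.na(reads$mapq) & reads$mapq >= min_mapq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contigs") <- attr(reads, "contigs")
  out
}

#' Mark duplicates by alignment signature
#'
#' Optional internal duplicate marker for inputs whose duplicate flag was
#' never set: records sharing an identical (contig, position, mate contig,
#' mate position, first/second-of-pair) signature after the first occurrence
#' get the duplicate flag set. This is a coordinate-signature approximation
#' of library-duplicate marking, not a replacement for a dedicated tool.
#'
#' @param reads Read-record frame.
#' @return The frame with the duplicate flag set on signature repeats.
#' @export
mark_duplicates <- function(reads) {
  sig <- paste(reads$rname, reads$pos, reads$mrnm, reads$mpos,
               bitwAnd(reads$flag, FLAG_FIRST + FLAG_SECOND), sep = "\r")
  dup <- duplicated(sig) & !is.na(reads$pos)
  reads$flag <- ifelse(dup, bitwOr(reads$flag, FLAG_DUPLICATE), reads$flag)
  reads
}

#' Extract mito-nuclear chimeric (NUMT-supporting) read pairs
#'
#' Scans a filtered read stream for pairs in which exactly one mate maps to
#' the mitochondrial contig and the other to a nuclear contig — the
#' discordant-pair signature of a NUMT insertion. The nuclear-side mate's
#' leftmost coordinate is used as the insertion-site proxy (junction
#' breakpoints are not resolved); the mito-side leftmost coordinate is the
#' mtDNA breakpoint proxy. One pair yields one record regardless of whether
#' one or both mates survived filtering: a pair is reconstructed from either
#' mate's mate fields and deduplicated by query name. `min_mapq` is the
#' minimum of the mapping qualities of the mates present in the stream.
#'
#' @param reads Filtered read-record frame ([filter_reads()]).
#' @param mito_names Contig names accepted as mitochondrial.
#' @param sample_id Sample identifier stamped on the output.
#' @param genome_type `"t"` (tumor) or `"h"` (blood-derived healthy).
#' @return Data frame with one row per chimeric pair: `sample_id`,
#'   `genome_type`, `nuclear_contig`, `nuclear_pos`, `mito_pos`, `min_mapq`.
#' @examples
#' reads <- data.frame(qname = c("p1", "p1"), flag = c(97L, 145L),
#'                     rname = c("chr1", "chrM"), pos = c(1000L, 5000L),
#'                     mapq = c(60L, 60L), mrnm = c("chrM", "chr1"),
#'                     mpos = c(5000L, 1000L))
#' extract_numt_pairs(reads, sample_id = "s1", genome_type = "t")
#' @export
extract_numt_pairs <- function(reads, mito_names = c("chrM", "MT", "chrMT"),
                               sample_id = "sample",
                               genome_type = c("t", "h")) {
  genome_type <- match.arg(genome_type)
  contigs <- names(attr(reads, "contigs")) %||%
    unique(stats::na.omit(c(reads$rname, reads$mrnm)))
  if (length(contigs) && !any(mito_names %in% contigs))
    stopf("none of the mitochondrial contig names (%s) occur in this file; header contigs: %s",
          paste(mito_names, collapse = ", "), paste(contigs, collapse = ", "))
  empty <- data.frame(sample_id = character(), genome_type = character(),
                      nuclear_contig = character(), nuclear_pos = integer(),
                      mito_pos = integer(), min_mapq = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  mapped <- !is.na(reads$pos) & !is.na(reads$mpos) & !is.na(reads$mrnm) &
    !has_flag(reads$flag, FLAG_UNMAPPED) &
    !has_flag(reads$flag, FLAG_MATE_UNMAPPED)
  self_mito <- reads$rname %in% mito_names
  mate_mito <- reads$mrnm %in% mito_names
  chim <- mapped & xor(self_mito, mate_mito)
  if (!any(chim)) return(empty)
  r <- reads[chim, , drop = FALSE]
  s_mito <- self_mito[chim]
  cand <- data.frame(
    qname = r$qname,
    nuclear_contig = ifelse(s_mito, r$mrnm, r$rname),
    nuclear_pos = ifelse(s_mito, r$mpos, r$pos),
    mito_pos = ifelse(s_mito, r$pos, r$mpos),
    mapq = r$mapq, stringsAsFactors = FALSE)
  minq <- tapply(cand$mapq, cand$qname, function(q) {
    q <- q[!is.na(q)]
    if (length(q)) min(q) else NA_integer_
  })
  first <- cand[!duplicated(cand$qname), , drop = FALSE]
  data.frame(
    sample_id = sample_id, genome_type = genome_type,
    nuclear_contig = first$nuclear_contig,
    nuclear_pos = as.integer(first$nuclear_pos),
    mito_pos = as.integer(first$mito_pos),
    min_mapq = as.integer(minq[first$qname]),
    stringsAsFactors = FALSE)
}

#' Count mapped reads per partition interval
#'
#' Each mapped, retained read contributes 1 to the interval containing its
#' leftmost coordinate. Reads on contigs absent from the partition contribute
#' to no interval, so the total over intervals never exceeds the number of
#' retained reads. With overlapping sliding windows, a read counts in every
#' window containing it.
#'
#' @param reads Filtered read-record frame.
#' @param partition A `numt_partition`.
#' @return Named integer vector: `interval_id` -> mapped read count (zeros
#'   included), in partition order.
#' @export
count_mapped_reads <- function(reads, partition) {
  mapped <- !is.na(reads$pos) & !has_flag(reads$flag, FLAG_UNMAPPED)
  row_counts <- assign_points(reads$rname[mapped], reads$pos[mapped],
                              partition)
  agg <- tapply(row_counts, partition$interval_id, sum)
  ids <- unique(partition$interval_id)
  out <- as.integer(agg[ids])
  names(out) <- ids
  out
}

#' Assemble per-interval NUMT and mapped-read counts for one sample
#'
#' Joins chimeric-pair evidence with mapped-read totals on one partition:
#' N is the number of NUMT pairs whose nuclear-side proxy coordinate (nuclear
#' levels) or mtDNA breakpoint coordinate (mitochondrial levels) falls in the
#' interval; M is the mapped read count. At the genome level, N sums over
#' every nuclear contig (sex chromosomes included) while M excludes
#' sex-chromosome reads, and a single `"gen"` row is returned.
#'
#' @param numt_pairs Chimeric pairs from [extract_numt_pairs()].
#' @param mapped_counts Named vector from [count_mapped_reads()] on the same
#'   partition and the same filtered stream.
#' @param partition A `numt_partition`.
#' @param sample_id,genome_type Identifiers stamped on the output (defaults
#'   taken from `numt_pairs` when available).
#' @return Data frame with columns `sample_id`, `genome_type`, `interval_id`,
#'   `numt_count`, `mapped_count`, one row per interval id.
#' @export
build_sample_counts <- function(numt_pairs, mapped_counts, partition,
                                sample_id = NULL, genome_type = NULL) {
  level <- partition_level(partition)
  sample_id <- sample_id %||%
    (if (nrow(numt_pairs)) numt_pairs$sample_id[1L] else "sample")
  genome_type <- genome_type %||%
    (if (nrow(numt_pairs)) numt_pairs$genome_type[1L] else "t")
  if (level %in% MITO_LEVELS) {
    ctg <- rep(partition$contig[1L] %||% "chrM", nrow(numt_pairs))
    pos <- numt_pairs$mito_pos
  } else {
    ctg <- numt_pairs$nuclear_contig
    pos <- numt_pairs$nuclear_pos
  }
  n_rows <- assign_points(ctg, pos, partition)
  if (level == "gen") {
    if (!"in_M" %in% names(partition))
      stopf("gen-level partition needs an in_M column (see partition_genome)")
    m_gen <- sum(mapped_counts[partition$interval_id[partition$in_M]])
    return(data.frame(sample_id = sample_id, genome_type = genome_type,
                      interval_id = "gen", numt_count = as.integer(sum(n_rows)),
                      mapped_count = as.integer(m_gen),
                      stringsAsFactors = FALSE))
  }
  n_agg <- tapply(n_rows, partition$interval_id, sum)
  ids <- unique(partition$interval_id)
  if (!all(ids %in% names(mapped_counts)))
    stopf("mapped_counts missing interval ids for level '%s'", level)
  data.frame(sample_id = sample_id, genome_type = genome_type,
             interval_id = ids, numt_count = as.integer(n_agg[ids]),
             mapped_count = as.integer(mapped_counts[ids]),
             stringsAsFactors = FALSE)
}

#' Write chimeric pairs as TSV or BED
#'
#' The TSV has the pair table's columns verbatim. The BED form uses the
#' nuclear insertion-site proxy padded by `pad` bases on each side
#' (0-based half-open), with `sample:mito_pos` as the name field.
#'
#' @param pairs Pair table from [extract_numt_pairs()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param pad Padding in bases around the proxy coordinate for BED output.
#' @return `path`, invisibly.
#' @export
write_numt_pairs <- function(pairs, path, format = c("tsv", "bed"), pad = 0L) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s:%d\t0\t.", pairs$nuclear_contig,
                     pmax(0L, pairs$nuclear_pos - 1L - as.integer(pad)),
                     pairs$nuclear_pos + as.integer(pad),
                     pairs$sample_id, pairs$mito_pos)
    writeLines(lines, path)
  }
  invisible(path)
}
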