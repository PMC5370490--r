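#' Breakpoint histogram over a partition, split by source
#'
#' Bins chimeric pairs into a partition's intervals by their mtDNA
#' breakpoint proxy (mitochondrial partitions) or their nuclear
#' insertion-site proxy (nuclear partitions), counting tumor- and
#' healthy-derived pairs separately. Pairs falling outside every interval of
#' a mitochondrial partition are collected in an `"unannotated"` catch-all
#' bin (and reported via a message), so counts are conserved.
#'
#' @param pairs Chimeric pair table ([extract_numt_pairs()] rows for the
#'   whole cohort; the `genome_type` column is the source).
#' @param partition A `numt_partition` (e.g. the `mgn` gene partition or a
#'   window partition).
#' @return Data frame of class `numt_hist`: `interval_id`, `tumor_count`,
#'   `healthy_count`, in partition order (catch-all last).
#' @export
mito_breakpoint_histogram <- function(pairs, partition) {
  level <- partition_level(partition)
  if (level %in% MITO_LEVELS) {
    ctg <- rep(partition$contig[1L] %||% "chrM", nrow(pairs))
    pos <- pairs$mito_pos
  } else {
    ctg <- pairs$nuclear_contig
    pos <- pairs$nuclear_pos
  }
  loc <- locate_points(ctg, pos, partition)
  unassigned <- is.na(loc)
  if (level %in% MITO_LEVELS && any(unassigned)) {
    message(sum(unassigned),
            " breakpoint(s) outside the annotation span -> 'unannotated' bin")
    loc[unassigned] <- "unannotated"
  }
  ids <- unique(partition$interval_id)
  if (level %in% MITO_LEVELS) ids <- c(ids, "unannotated")
  tum <- table(factor(loc[pairs$genome_type == "t"], levels = ids))
  hea <- table(factor(loc[pairs$genome_type == "h"], levels = ids))
  structure(data.frame(interval_id = ids,
                       tumor_count = as.integer(tum),
                       healthy_count = as.integer(hea),
                       stringsAsFactors = FALSE),
            class = c("numt_hist", "data.frame"), level = level)
}

#' Nuclear landing-site profile over windows
#'
#' Window histogram of the nuclear insertion-site proxies by source; the
#' tumor/healthy window counts feed pooled window-level fold changes and the
#' GC association analysis.
#'
#' @param pairs Chimeric pair table for the cohort.
#' @param win_partition Window partition from [build_windows()].
#' @return A `numt_hist` over windows (no catch-all: pairs on contigs absent
#'   from the partition are ignored, consistent with mapped-read counting).
#' @export
nuclear_landing_profile <- function(pairs, win_partition) {
  if (partition_level(win_partition) %in% MITO_LEVELS)
    stopf("nuclear_landing_profile expects a nuclear partition")
  mito_breakpoint_histogram(pairs, win_partition)
}

#' Rank breakpoint hotspots
#'
#' Orders intervals by breakpoint count (tumor + healthy by default),
#' descending, keeping those with at least `min_count`; ties are broken by
#' genomic order (the partition's interval order), so the ranking is
#' deterministic. The `"unannotated"` catch-all is never ranked.
#'
#' @param hist A `numt_hist`.
#' @param min_count Minimum total count to report.
#' @param source `"both"`, `"tumor"`, or `"healthy"`.
#' @return The histogram rows, ranked, with a `count` column.
#' @export
rank_hotspots <- function(hist, min_count = 1L,
                          source = c("both", "tumor", "healthy")) {
  source <- match.arg(source)
  h <- hist[hist$interval_id != "unannotated", , drop = FALSE]
  h$count <- switch(source,
                    both = h$tumor_count + h$healthy_count,
                    tumor = h$tumor_count,
                    healthy = h$healthy_count)
  h <- h[h$count >= min_count, , drop = FALSE]
  h <- h[order(-h$count, seq_len(nrow(h))), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Tumor-unique numtogenesis regions
#'
#' Flags intervals supported by at least `k_min` tumor-derived pairs while
#' no healthy-derived pair in the whole cohort falls there — candidate
#' regions of strictly somatic numtogenesis. A single supporting pair is
#' weak evidence, hence the conservative default of 2.
#'
#' @param hist A `numt_hist` built over the full cohort.
#' @param k_min Minimum tumor-pair support (default 2).
#' @return Data frame: `interval_id`, `tumor_count`, `healthy_count`.
#' @export
tumor_unique_regions <- function(hist, k_min = 2L) {
  h <- hist[hist$interval_id != "unannotated" & hist$healthy_count == 0L &
            hist$tumor_count >= k_min, , drop = FALSE]
  rownames(h) <- NULL
  as.data.frame(h)
}
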