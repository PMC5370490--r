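#' NUMT proportion per interval
#'
#' Normalizes the NUMT pair count to the mapped read count of the same
#' interval: P = N / M. Rows with zero mapped reads and zero NUMT pairs are
#' dropped (the proportion is undefined there); zero mapped reads alongside a
#' positive NUMT count is an inconsistency (pairs imply mapped reads) and
#' raises an error.
#'
#' @param counts Per-interval count table from [build_sample_counts()]
#'   (columns `numt_count`, `mapped_count`).
#' @return The table with a `proportion` column appended; undefined rows
#'   removed.
#' @export
numt_proportion <- function(counts) {
  bad <- counts$mapped_count == 0 & counts$numt_count > 0
  if (any(bad))
    stopf("interval '%s' has NUMT pairs but zero mapped reads",
          counts$interval_id[which(bad)[1L]])
  out <- counts[counts$mapped_count > 0, , drop = FALSE]
  out$proportion <- out$numt_count / out$mapped_count
  rownames(out) <- NULL
  out
}

#' Plate-pooled healthy baseline
#'
#' For sparse partitions a matched healthy genome may carry no NUMT pairs at
#' all in an interval, making the per-individual ratio undefined. The pooled
#' baseline replaces the individual healthy proportion with the arithmetic
#' mean proportion (zeros included) over all blood-derived healthy samples
#' sharing a plate barcode.
#'
#' @param healthy_props Healthy-sample proportion table ([numt_proportion()]
#'   rows with `genome_type == "h"`).
#' @param metadata Sample metadata with `sample_id` and `plate` columns.
#' @return Data frame: `plate`, `interval_id`, `mean_healthy_proportion`,
#'   `n_samples`.
#' @export
pooled_healthy_baseline <- function(healthy_props, metadata) {
  plate <- metadata$plate[match(healthy_props$sample_id, metadata$sample_id)]
  if (anyNA(plate))
    stopf("sample '%s' missing from metadata",
          healthy_props$sample_id[which(is.na(plate))[1L]])
  key <- paste(plate, healthy_props$interval_id, sep = "\r")
  agg <- tapply(healthy_props$proportion, key, mean)
  n <- tapply(healthy_props$proportion, key, length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(plate = vapply(parts, `[`, "", 1L),
             interval_id = vapply(parts, `[`, "", 2L),
             mean_healthy_proportion = as.numeric(agg),
             n_samples = as.integer(n), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Proportional fold change R = P_t / P_h
#'
#' @param p_t Tumor proportion(s).
#' @param p_h Healthy proportion(s); must be positive (use a pooled baseline
#'   or exclude the interval when the matched healthy proportion is zero).
#' @return `p_t / p_h`.
#' @examples
#' fold_ratio(2e-6, 1e-6)  # 2: twice as many NUMTs in tumor
#' fold_ratio(1e-6, 2e-6)  # 0.5: twice as many in healthy
#' @export
fold_ratio <- function(p_t, p_h) {
  if (any(p_h <= 0))
    stopf("fold_ratio undefined for non-positive healthy proportion")
  p_t / p_h
}

#' Direction indicator S = sign of the paired difference
#'
#' `+1` when the tumor proportion exceeds the healthy one, `-1` when it falls
#' below, and `0` at exact equality (the sign formula is 0/0 there; zero is
#' the convention that collapses no-change intervals to zero after
#' rescaling).
#'
#' @param delta_p Paired difference(s) `P_t - P_h`.
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
direction_indicator <- function(delta_p) as.integer(sign(delta_p))

#' Rescaled fold change R' = R^S * S
#'
#' Fold ratios are asymmetric: a halving (0.5) and a doubling (2) are equal
#' evidence in opposite directions but unequal distances from 1. The
#' rescaled value maps doublings to +2, halvings to -2, and no change to 0,
#' so that `|R'| >= 1` or `R' = 0` and the sign carries the direction.
#'
#' @param ratio Fold ratio(s) `R > 0`.
#' @param direction Direction indicator(s) in `{-1, 0, 1}`.
#' @return Rescaled fold change(s).
#' @examples
#' rescale_ratio(2, 1L)     #  2
#' rescale_ratio(0.5, -1L)  # -2
#' rescale_ratio(1, 0L)     #  0
#' @export
rescale_ratio <- function(ratio, direction) {
  if (any(!is.na(ratio) & ratio <= 0))
    stopf("rescale_ratio requires positive ratios")
  n <- max(length(ratio), length(direction))
  ratio <- rep_len(as.numeric(ratio), n)
  direction <- rep_len(as.integer(direction), n)
  out <- numeric(n)
  out[direction > 0L] <- ratio[direction > 0L]
  out[direction < 0L] <- -1 / ratio[direction < 0L]
  out
}

#' Tumor-versus-healthy ratio table over one partition
#'
#' Computes, per interval, the full metric set: tumor and healthy
#' proportions, paired difference, fold ratio, direction, and rescaled fold
#' change.
#'
#' Two baselines are supported. In `matched` mode each participant's tumor
#' sample is compared against their own blood-derived healthy sample (joined
#' on participant id from the metadata); intervals where the matched healthy
#' proportion is zero while the tumor one is positive are omitted (and
#' reported via a message) because the ratio is undefined — the pooled mode
#' is the supported path for sparse partitions. In `pooled` mode, samples
#' sharing a plate barcode are pooled: tumor counts are summed before
#' normalization (sum N / sum M per plate) and the healthy side is the
#' plate-pooled mean proportion, yielding one record per (plate, interval).
#' If the metadata has no `plate` column, a single global pool is used with a
#' warning.
#'
#' @param tumor_counts,healthy_counts Per-interval count tables from
#'   [build_sample_counts()] for tumor / healthy samples (all samples row-
#'   bound), on one partition level.
#' @param metadata Sample table with `sample_id`, `participant`,
#'   `genome_type` and (for pooled mode) `plate` columns.
#' @param mode `"matched"` or `"pooled"`.
#' @return Data frame of ratio records: `unit` (participant or plate),
#'   `interval_id`, `p_t`, `p_h`, `delta_p`, `ratio`, `direction`,
#'   `rescaled`, `baseline_kind`.
#' @export
ratio_table <- function(tumor_counts, healthy_counts, metadata,
                        mode = c("matched", "pooled")) {
  mode <- match.arg(mode)
  t_prop <- numt_proportion(tumor_counts)
  h_prop <- numt_proportion(healthy_counts)
  if (mode == "matched") {
    part_t <- metadata$participant[match(t_prop$sample_id,
                                         metadata$sample_id)]
    part_h <- metadata$participant[match(h_prop$sample_id,
                                         metadata$sample_id)]
    if (anyNA(part_t) || anyNA(part_h))
      stopf("sample ids missing from metadata in matched mode")
    key_t <- paste(part_t, t_prop$interval_id, sep = "\r")
    key_h <- paste(part_h, h_prop$interval_id, sep = "\r")
    idx <- match(key_t, key_h)
    keep <- !is.na(idx)
    out <- data.frame(unit = part_t[keep],
                      interval_id = t_prop$interval_id[keep],
                      p_t = t_prop$proportion[keep],
                      p_h = h_prop$proportion[idx[keep]],
                      stringsAsFactors = FALSE)
    out$baseline_kind <- "matched"
  } else {
    if (!"plate" %in% names(metadata)) {
      warning("metadata has no 'plate' column; using a single global pool")
      metadata$plate <- "pool"
    }
    plate_t <- metadata$plate[match(tumor_counts$sample_id,
                                    metadata$sample_id)]
    key <- paste(plate_t, tumor_counts$interval_id, sep = "\r")
    n_sum <- tapply(tumor_counts$numt_count, key, sum)
    m_sum <- tapply(tumor_counts$mapped_count, key, sum)
    parts <- strsplit(names(n_sum), "\r", fixed = TRUE)
    pool_t <- data.frame(plate = vapply(parts, `[`, "", 1L),
                         interval_id = vapply(parts, `[`, "", 2L),
                         p_t = as.numeric(n_sum) / as.numeric(m_sum),
                         stringsAsFactors = FALSE)
    pool_t <- pool_t[is.finite(pool_t$p_t), , drop = FALSE]
    base <- pooled_healthy_baseline(h_prop, metadata)
    idx <- match(paste(pool_t$plate, pool_t$interval_id, sep = "\r"),
                 paste(base$plate, base$interval_id, sep = "\r"))
    keep <- !is.na(idx)
    if (any(!keep))
      message(sum(!keep), " pooled interval(s) lacked a healthy baseline ",
              "and were omitted")
    out <- data.frame(unit = pool_t$plate[keep],
                      interval_id = pool_t$interval_id[keep],
                      p_t = pool_t$p_t[keep],
                      p_h = base$mean_healthy_proportion[idx[keep]],
                      stringsAsFactors = FALSE)
    out$baseline_kind <- "pooled"
  }
  out$delta_p <- out$p_t - out$p_h
  out$direction <- direction_indicator(out$delta_p)
  undef <- out$p_h == 0 & out$p_t > 0
  if (any(undef))
    message(sum(undef), " interval record(s) omitted: zero ", out$baseline_kind[1L],
            " healthy proportion with positive tumor proportion")
  out <- out[!undef, , drop = FALSE]
  out$ratio <- ifelse(out$p_h > 0, out$p_t / out$p_h, NA_real_)
  out$rescaled <- ifelse(out$direction == 0L, 0,
                  ifelse(out$direction > 0L, out$ratio, -1 / out$ratio))
  rownames(out) <- NULL
  out[, c("unit", "interval_id", "p_t", "p_h", "delta_p", "ratio",
          "direction", "rescaled", "baseline_kind")]
}
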