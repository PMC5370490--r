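#' Run the extraction and counting stages over a cohort
#'
#' For every sample: read the alignment records, apply the QC read filters,
#' extract mito-nuclear chimeric pairs, and count NUMT pairs and mapped
#' reads on the requested partition levels. Dispatches on a `numt_sim`
#' object (in-memory records or the written workspace) or on a sample table
#' (`sample_id`, `genome_type`, `participant`, `path`) plus explicit build
#' and partitions.
#'
#' @param x A `numt_sim` or a sample-table data frame.
#' @param ... Passed to methods.
#' @return List of class `numt_quant`: `pairs` (cohort pair table),
#'   `counts` (per level, row-bound [build_sample_counts()] tables),
#'   `metadata`, `partitions`, `params`.
#' @export
quantify_cohort <- function(x, ...) UseMethod("quantify_cohort")

quantify_core <- function(get_reads, metadata, partitions, drop_duplicates,
                          min_mapq, mito_names) {
  pairs <- list(); counts <- lapply(partitions, function(p) list())
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    reads <- filter_reads(get_reads(i), drop_duplicates = drop_duplicates,
                          min_mapq = min_mapq)
    p <- extract_numt_pairs(reads, mito_names = mito_names,
                            sample_id = sid,
                            genome_type = metadata$genome_type[i])
    pairs[[sid]] <- p
    for (lev in names(partitions)) {
      m <- count_mapped_reads(reads, partitions[[lev]])
      counts[[lev]][[sid]] <- build_sample_counts(
        p, m, partitions[[lev]], sample_id = sid,
        genome_type = metadata$genome_type[i])
    }
  }
  structure(list(
    pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
    counts = lapply(counts, function(l)
      do.call(rbind, c(l, list(make.row.names = FALSE)))),
    metadata = metadata, partitions = partitions,
    params = list(drop_duplicates = drop_duplicates, min_mapq = min_mapq,
                  mito_names = mito_names)), class = "numt_quant")
}

#' @rdname quantify_cohort
#' @param levels Partition levels to count on (subset of
#'   `gen, chr, arm, cyt, win, mtg, mst, mgn`).
#' @param drop_duplicates,min_mapq Passed to [filter_reads()].
#' @param mito_names Mitochondrial contig names for pair extraction.
#' @export
quantify_cohort.numt_sim <- function(x, levels = c("gen", "chr", "mgn"),
                                     drop_duplicates = TRUE, min_mapq = 0L,
                                     mito_names = x$build$mito_name, ...) {
  levels <- match.arg(levels, ALL_LEVELS, several.ok = TRUE)
  parts <- list(gen = x$partitions$genome, chr = x$partitions$chromosomes,
                arm = x$partitions$arms, cyt = x$partitions$cytobands,
                win = x$partitions$windows, mtg = x$partitions$mito$mtg,
                mst = x$partitions$mito$mst, mgn = x$partitions$mito$mgn)
  get_reads <- function(i) {
    sid <- x$metadata$sample_id[i]
    if (!is.null(x$samples) && !is.null(x$samples[[sid]]))
      x$samples[[sid]]
    else if (!is.null(x$paths))
      read_alignments(file.path(x$paths$dir, paste0(sid, ".sam")))
    else stopf("simulation kept no records and wrote no files")
  }
  quantify_core(get_reads, x$metadata, parts[levels], drop_duplicates,
                min_mapq, mito_names)
}

#' @rdname quantify_cohort
#' @param build A [genome_build()] (sample-table method).
#' @param partitions Named list of `numt_partition`s keyed by level.
#' @export
quantify_cohort.data.frame <- function(x, build, partitions,
                                       drop_duplicates = TRUE,
                                       min_mapq = 0L,
                                       mito_names = build$mito_name, ...) {
  need <- c("sample_id", "genome_type", "path")
  if (!all(need %in% names(x)))
    stopf("sample table needs columns %s", paste(need, collapse = ", "))
  get_reads <- function(i) read_alignments(x$path[i])
  quantify_core(get_reads, x, partitions, drop_duplicates, min_mapq,
                mito_names)
}

#' @export
print.numt_quant <- function(x, ...) {
  cat("<numt_quant> ", nrow(x$metadata), " samples, ", nrow(x$pairs),
      " chimeric pairs; levels: ", paste(names(x$counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assemble the cohort table and fold changes
#'
#' Builds the per-participant cohort table from genome-level counts: tumor
#' and healthy NUMT proportions, the paired metric set (difference, fold
#' ratio, direction, rescaled fold change), and the participant covariates.
#' The per-sample fold change is the genome-level ratio R (tumor over
#' matched healthy).
#'
#' @param quant A `numt_quant` containing the `gen` level.
#' @return Object of class `numt_cohort` whose `table` element is the cohort
#'   data frame (one row per participant).
#' @export
numt_cohort <- function(quant) {
  if (!"gen" %in% names(quant$counts))
    stopf("quantification lacks the 'gen' level")
  cnt <- quant$counts$gen
  md <- quant$metadata
  rt <- ratio_table(cnt[cnt$genome_type == "t", , drop = FALSE],
                    cnt[cnt$genome_type == "h", , drop = FALSE],
                    md, mode = "matched")
  names(rt)[names(rt) == "unit"] <- "participant"
  rt$fold_change <- rt$ratio
  cov_cols <- intersect(c("sex", "disease", "vital_status", "stage", "age",
                          "race", "plate"), names(md))
  covs <- md[md$genome_type == "t",
             c("participant", cov_cols), drop = FALSE]
  tab <- merge(rt, covs, by = "participant", sort = TRUE)
  structure(list(table = tab, quant = quant), class = "numt_cohort")
}

#' @export
print.numt_cohort <- function(x, ...) {
  cat("<numt_cohort> ", nrow(x$table), " matched participants\n", sep = "")
  ok <- is.finite(x$table$fold_change)
  if (any(ok))
    cat(sprintf("  mean fold change (mean of per-sample R_gen): %.3f\n",
                mean(x$table$fold_change[ok])))
  print(utils::head(x$table[, c("participant", "p_t", "p_h", "fold_change")]))
  invisible(x)
}

#' @export
summary.numt_cohort <- function(object, ...) {
  tab <- object$table
  ok <- is.finite(tab$fold_change)
  t_ok <- tab[ok, , drop = FALSE]
  out <- list(
    n = nrow(tab), n_with_fold = sum(ok),
    mean_fold_change = mean(t_ok$fold_change),
    median_fold_change = stats::median(t_ok$fold_change),
    fold_change_of_means = mean(t_ok$p_t) / mean(t_ok$p_h),
    paired_t_one = paired_t_log(t_ok$p_t, t_ok$p_h, tails = "one"),
    paired_t_two = paired_t_log(t_ok$p_t, t_ok$p_h, tails = "two"),
    regression = if (nrow(t_ok) >= 3L) regress_log2(t_ok$p_t, t_ok$p_h),
    by_sex = if ("sex" %in% names(tab)) stratified_summary(t_ok, "sex"),
    by_vital = if ("vital_status" %in% names(tab) &&
                   length(unique(t_ok$vital_status)) == 2L)
      stratified_summary(t_ok, "vital_status"))
  class(out) <- "summary.numt_cohort"
  out
}

#' @export
print.summary.numt_cohort <- function(x, ...) {
  cat("Cohort of", x$n, "matched participants (", x$n_with_fold,
      "with defined fold change )\n")
  cat(sprintf("  mean per-sample fold change: %.3f (median %.3f; ratio of cohort means %.3f)\n",
              x$mean_fold_change, x$median_fold_change,
              x$fold_change_of_means))
  cat("  paired t on log2 proportions:\n")
  cat(sprintf("    one-tailed p = %.3g; two-tailed p = %.3g\n",
              x$paired_t_one$p_value, x$paired_t_two$p_value))
  if (!is.null(x$regression))
    cat(sprintf("  tumor-on-blood regression: slope %.3f, R^2 %.3f, p %.3g\n",
                x$regression$slope, x$regression$r_squared,
                x$regression$p_value))
  if (!is.null(x$by_sex)) {
    cat("  fold change by sex:\n")
    print(x$by_sex$summary, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.numt_cohort <- function(x, ...) {
  tab <- x$table
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::boxplot(list(healthy = log10(tab$p_h[tab$p_h > 0]),
                         tumor = log10(tab$p_t[tab$p_t > 0])),
                    ylab = "log10 NUMT proportion",
                    main = "NUMT proportion by genome type", ...)
  ok <- tab$p_t > 0 & tab$p_h > 0
  graphics::plot(log2(tab$p_h[ok]), log2(tab$p_t[ok]),
                 xlab = "log2 P (healthy)", ylab = "log2 P (tumor)",
                 main = "Tumor vs blood NUMT abundance")
  if (sum(ok) >= 3L)
    graphics::abline(stats::lm(log2(tab$p_t[ok]) ~ log2(tab$p_h[ok])),
                     col = "red")
  invisible(x)
}
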