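#' Configuration for the synthetic matched-cohort simulator
#'
#' Defines the statistical structure of a simulated cohort of matched
#' tumor/blood-derived-normal paired-end alignments on a small toy genome:
#' background concordant pairs uniform over the nuclear contigs with a short
#' mate gap; mito-nuclear chimeric pairs implanted at a healthy baseline
#' rate and an elevated tumor rate; mtDNA-side breakpoints drawn from a
#' gene-hotspot mixture over an rCRS-style annotation; nuclear landing sites
#' optionally GC-biased across windows; a duplicate-flagged fraction; and
#' plate/covariate metadata.
#'
#' Defaults are the package's study conditions: 20 participants, 1e5
#' background pairs per genome, read length 100, mean mate gap 150 bp
#' (sd 30, truncated at 0), tumor/healthy rate ratio 4.42, mtDNA hotspot
#' mixture 50% ND1 / 30% CO1 / 20% uniform, a 5% duplicate fraction, and a
#' healthy chimera rate of 5e-4 per mapped read chosen so a healthy genome
#' carries ~100 expected chimeric pairs at this depth (see the methods
#' vignette for the scaling rationale).
#'
#' @param seed Root RNG seed; per-sample substreams are derived by stable
#'   hashing of the sample id, so adding or removing participants does not
#'   reshuffle other samples.
#' @param n_participants Number of matched tumor/healthy pairs.
#' @param contigs Named lengths of the toy genome (nuclear contigs + mito).
#' @param sex_chromosomes,mito_name Passed to [genome_build()].
#' @param read_length Read length in bases.
#' @param mate_gap_mean,mate_gap_sd Inner mate-gap distribution (bp), normal
#'   truncated at 0.
#' @param background_pairs Concordant pairs per genome.
#' @param healthy_chimera_rate Expected chimeric pairs per mapped read in a
#'   healthy genome.
#' @param tumor_ratio Tumor/healthy chimera-rate ratio (rho).
#' @param sex_ratio Optional named vector `c(female = , male = )` overriding
#'   `tumor_ratio` per sex.
#' @param mito_mixture Named weights of mtDNA gene hotspots (rCRS-style gene
#'   ids); the remaining mass is uniform over the mitochondrial genome.
#' @param tumor_only_hotspots Gene ids receiving extra tumor-only weight;
#'   healthy breakpoints never fall in these genes.
#' @param tumor_hotspot_weight Weight added per tumor-only hotspot gene.
#' @param gc_bias Landing-site bias: window weight proportional to
#'   `width * exp(gc_bias * gc(window))`; 0 means uniform per base.
#' @param window_size,window_step Window partition used for landing sites.
#' @param duplicate_rate Probability that a pair is cloned with the
#'   duplicate flag set.
#' @param plate_size Participants per plate barcode.
#' @param female_prob,coad_prob,deceased_prob Covariate frequencies
#'   (defaults mirror a 57-participant colorectal cohort: 34 women, 36
#'   colon / 21 rectum, 4 deceased).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 20L,
                       contigs = c(chr1 = 10e6, chr2 = 8e6, chr3 = 6e6,
                                   chrX = 5e6, chrM = 16569),
                       sex_chromosomes = "chrX",
                       mito_name = "chrM",
                       read_length = 100L,
                       mate_gap_mean = 150,
                       mate_gap_sd = 30,
                       background_pairs = 1e5,
                       healthy_chimera_rate = 5e-4,
                       tumor_ratio = 4.42,
                       sex_ratio = NULL,
                       mito_mixture = c(ND1 = 0.5, CO1 = 0.3),
                       tumor_only_hotspots = character(),
                       tumor_hotspot_weight = 0.1,
                       gc_bias = 0,
                       window_size = 2.5e6,
                       window_step = window_size,
                       duplicate_rate = 0.05,
                       plate_size = 8L,
                       female_prob = 34 / 57,
                       coad_prob = 36 / 57,
                       deceased_prob = 4 / 57) {
  cfg <- as.list(environment())
  bad <- character()
  chk <- function(ok, field) if (!ok) bad <<- c(bad, field)
  chk(is_count(seed), "seed")
  chk(is_count(n_participants) && n_participants >= 1, "n_participants")
  chk(!is.null(names(contigs)) && all(contigs > 0), "contigs")
  chk(mito_name %in% names(contigs), "mito_name")
  chk(all(contigs[setdiff(names(contigs), mito_name)] >= 1e4),
      "contigs (nuclear contigs must be >= 10 kb)")
  chk(is_count(read_length) && read_length > 0, "read_length")
  chk(mate_gap_mean >= 0 && mate_gap_sd >= 0, "mate_gap")
  chk(is_count(background_pairs) && background_pairs > 0, "background_pairs")
  chk(healthy_chimera_rate >= 0, "healthy_chimera_rate")
  chk(tumor_ratio > 0, "tumor_ratio")
  if (!is.null(sex_ratio))
    chk(all(c("female", "male") %in% names(sex_ratio)) && all(sex_ratio > 0),
        "sex_ratio")
  mito_genes <- rcrs_mito_genes(mito_name)
  chk(all(names(mito_mixture) %in% mito_genes$gene), "mito_mixture (genes)")
  chk(all(tumor_only_hotspots %in% mito_genes$gene), "tumor_only_hotspots")
  total_w <- sum(mito_mixture) +
    length(tumor_only_hotspots) * tumor_hotspot_weight
  chk(total_w <= 1, "mito_mixture (weights must sum to <= 1)")
  chk(gc_bias >= -50 && gc_bias <= 50, "gc_bias")
  chk(window_size > 0 && window_step > 0 && window_step <= window_size,
      "window_size/window_step")
  chk(duplicate_rate >= 0 && duplicate_rate < 1, "duplicate_rate")
  chk(is_count(plate_size) && plate_size >= 1, "plate_size")
  chk(female_prob >= 0 && female_prob <= 1, "female_prob")
  chk(coad_prob >= 0 && coad_prob <= 1, "coad_prob")
  chk(deceased_prob >= 0 && deceased_prob <= 1, "deceased_prob")
  if (length(bad))
    stopf("invalid sim_config field(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

# Draw n mtDNA breakpoint coordinates (1-based) from a gene-hotspot mixture
# with uniform remainder. `exclude` is a gene table subset whose intervals
# must never be hit (tumor-only hotspots, when drawing for healthy genomes).
draw_mito_positions <- function(n, mixture, genes, mito_length,
                                exclude = NULL) {
  if (n == 0L) return(integer())
  comps <- c(names(mixture), ".uniform")
  probs <- c(mixture, 1 - sum(mixture))
  comp <- sample(comps, n, replace = TRUE, prob = probs)
  pos <- integer(n)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (g == ".uniform") {
      p <- sample.int(mito_length, length(idx), replace = TRUE)
      if (!is.null(exclude) && nrow(exclude)) {
        repeat {
          inside <- rep(FALSE, length(p))
          for (k in seq_len(nrow(exclude)))
            inside <- inside | (p > exclude$start[k] & p <= exclude$end[k])
          if (!any(inside)) break
          p[inside] <- sample.int(mito_length, sum(inside), replace = TRUE)
        }
      }
      pos[idx] <- p
    } else {
      arcs <- genes[genes$gene == g, , drop = FALSE]
      w <- arcs$end - arcs$start
      a <- sample.int(nrow(arcs), length(idx), replace = TRUE, prob = w)
      pos[idx] <- as.integer(arcs$start[a] +
                               ceiling(stats::runif(length(idx)) *
                                         (arcs$end[a] - arcs$start[a])))
    }
  }
  pos
}

# Simulate one genome's read records (and the chimeric-pair truth rows).
sim_sample_records <- function(sample_id, participant, genome_type,
                               chimera_rate, cfg, build, windows,
                               window_gc, genes) {
  set.seed(derive_seed(cfg$seed, sample_id))
  rl <- cfg$read_length
  nuc <- build$nuclear
  lens <- as.numeric(build$contigs[nuc])
  n_bg <- as.integer(cfg$background_pairs)

  # background concordant pairs, uniform over nuclear contigs by length
  ctg_i <- sample.int(length(nuc), n_bg, replace = TRUE, prob = lens)
  span <- lens[ctg_i] - 2 * rl - 1000
  pos1 <- 1L + as.integer(floor(stats::runif(n_bg) * span))
  gap <- pmax(0, round(stats::rnorm(n_bg, cfg$mate_gap_mean,
                                    cfg$mate_gap_sd)))
  pos2 <- as.integer(pos1 + rl + gap)
  bg_ctg <- nuc[ctg_i]
  bg_qname <- sprintf("%s.bg%07d", sample_id, seq_len(n_bg))

  # implanted chimeric pairs
  n_ch <- stats::rpois(1L, chimera_rate * n_bg * 2)
  mixture <- cfg$mito_mixture
  exclude <- NULL
  if (length(cfg$tumor_only_hotspots)) {
    if (genome_type == "t") {
      extra <- stats::setNames(rep(cfg$tumor_hotspot_weight,
                                   length(cfg$tumor_only_hotspots)),
                               cfg$tumor_only_hotspots)
      mixture <- c(mixture, extra)
    } else {
      exclude <- genes[genes$gene %in% cfg$tumor_only_hotspots, ,
                       drop = FALSE]
    }
  }
  mito_pos <- draw_mito_positions(n_ch, mixture, genes,
                                  as.integer(build$contigs[[build$mito_name]]),
                                  exclude)
  if (n_ch > 0L) {
    w <- (windows$end - windows$start) *
      exp(cfg$gc_bias * window_gc[windows$interval_id])
    win_i <- sample.int(nrow(windows), n_ch, replace = TRUE, prob = w)
    hi <- pmax(windows$start[win_i] + 1, windows$end[win_i] - rl)
    ch_pos <- as.integer(windows$start[win_i] + 1 +
                           floor(stats::runif(n_ch) *
                                   (hi - windows$start[win_i])))
    ch_ctg <- windows$contig[win_i]
  } else {
    ch_pos <- integer(); ch_ctg <- character()
  }
  ch_qname <- sprintf("%s.ch%05d", sample_id, seq_len(n_ch))
  mt <- build$mito_name

  r1 <- data.frame(
    qname = c(bg_qname, ch_qname),
    flag = c(rep(99L, n_bg), rep(97L, n_ch)),
    rname = c(bg_ctg, ch_ctg),
    pos = c(pos1, ch_pos),
    mapq = 60L,
    mrnm = c(bg_ctg, rep(mt, n_ch)),
    mpos = c(pos2, mito_pos), stringsAsFactors = FALSE)
  r2 <- data.frame(
    qname = c(bg_qname, ch_qname),
    flag = c(rep(147L, n_bg), rep(145L, n_ch)),
    rname = c(bg_ctg, rep(mt, n_ch)),
    pos = c(pos2, mito_pos),
    mapq = 60L,
    mrnm = c(bg_ctg, ch_ctg),
    mpos = c(pos1, ch_pos), stringsAsFactors = FALSE)

  # duplicate clones share coordinates, get the duplicate flag
  n_pairs <- n_bg + n_ch
  dup <- stats::runif(n_pairs) < cfg$duplicate_rate
  if (any(dup)) {
    d1 <- r1[dup, , drop = FALSE]; d2 <- r2[dup, , drop = FALSE]
    d1$qname <- paste0(d1$qname, "d"); d2$qname <- paste0(d2$qname, "d")
    d1$flag <- bitwOr(d1$flag, FLAG_DUPLICATE)
    d2$flag <- bitwOr(d2$flag, FLAG_DUPLICATE)
    records <- rbind(r1, d1, r2, d2)
  } else records <- rbind(r1, r2)
  attr(records, "contigs") <- cfg$contigs

  ch_dup <- dup[n_bg + seq_len(n_ch)]
  dup_names <- if (any(ch_dup)) paste0(ch_qname[ch_dup], "d") else character()
  truth <- data.frame(
    participant = rep(participant, n_ch + sum(ch_dup)),
    sample_id = rep(sample_id, n_ch + sum(ch_dup)),
    genome_type = rep(genome_type, n_ch + sum(ch_dup)),
    qname = c(ch_qname, dup_names),
    nuclear_contig = c(ch_ctg, ch_ctg[ch_dup]),
    nuclear_pos = c(ch_pos, ch_pos[ch_dup]),
    mito_pos = c(mito_pos, mito_pos[ch_dup]),
    is_duplicate = c(rep(FALSE, n_ch), rep(TRUE, sum(ch_dup))),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

# Toy cytoband table: eight equal bands per nuclear chromosome (p4..p1,
# q1..q4) with a stain pattern that covers the five Giemsa groups plus a
# centromeric acen pair.
toy_cytobands <- function(build) {
  stains <- c("gneg", "gpos25", "gpos50", "acen", "acen", "gpos75",
              "gpos100", "gneg")
  bands <- c("p4", "p3", "p2", "p1", "q1", "q2", "q3", "q4")
  out <- lapply(build$nuclear, function(ctg) {
    len <- as.numeric(build$contigs[[ctg]])
    edges <- round(seq(0, len, length.out = 9L))
    data.frame(interval_id = paste0(ctg, bands), contig = ctg,
               start = edges[1:8], end = edges[2:9], band = bands,
               stain = stains, stringsAsFactors = FALSE)
  })
  new_partition(do.call(rbind, out), "cyt")
}

write_sam_file <- function(records, path, contigs) {
  rl <- 100L
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  seqs <- strrep("A", attr(records, "read_length") %||% rl)
  rnext <- ifelse(records$mrnm == records$rname, "=", records$mrnm)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, paste0(nchar(seqs), "M"), rnext,
                  records$mpos, seqs, strrep("I", nchar(seqs)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_toy_fasta <- function(build, windows, window_gc, path, seed) {
  set.seed(derive_seed(seed, "fasta"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(build$contigs)) {
    writeLines(paste0(">", ctg), con)
    if (ctg == build$mito_name) {
      len <- as.integer(build$contigs[[ctg]])
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                        prob = c(0.28, 0.22, 0.22, 0.28)), collapse = "")
    } else {
      rows <- which(windows$contig == ctg)
      chunks <- vapply(rows, function(i) {
        gc <- window_gc[[windows$interval_id[i]]]
        w <- as.integer(windows$end[i] - windows$start[i])
        paste(sample(c("A", "C", "G", "T"), w, replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
              collapse = "")
      }, "")
      s <- paste(chunks, collapse = "")
    }
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Simulate a matched tumor/healthy cohort with full ground truth
#'
#' Generates, per participant, one tumor and one blood-derived healthy
#' genome of paired-end read records: `background_pairs` concordant pairs
#' uniform over the nuclear contigs (mate gap normal, truncated at 0),
#' plus a Poisson number of implanted mito-nuclear chimeric pairs —
#' `Poisson(rate * background_pairs * 2)`, the rate being
#' `healthy_chimera_rate` for healthy genomes and `rho` times that for
#' tumor genomes — with mtDNA breakpoints from the hotspot mixture,
#' GC-weighted nuclear landing windows, and duplicate clones at
#' `duplicate_rate`. Covariates (sex, disease, vital status, stage, age,
#' race) and plate barcodes are drawn per participant. Everything is
#' reproducible from the root seed.
#'
#' With `dir` set, a complete self-contained workspace is written: one SAM
#' per sample, the toy genome FASTA (+ index), a cytoband TSV, the
#' mitochondrial gene BED, a metadata TSV, and the truth TSV.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for a file-based workspace.
#' @param write_fasta Write the toy FASTA (only meaningful with `dir`).
#' @param keep_records Keep per-sample record frames in the returned object
#'   (default: only when no `dir` is given).
#' @return List of class `numt_sim`: `config`, `build`, partitions
#'   (`windows`, `cytobands`, `arms`, `genome`, `chromosomes`, `mito`),
#'   `window_gc`, `metadata`, `truth`, `sample_rates`, `samples` (record
#'   frames, if kept), and `paths` (if written).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL,
                            write_fasta = !is.null(dir),
                            keep_records = is.null(dir)) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  build <- genome_build(config$contigs, config$sex_chromosomes,
                        config$mito_name)
  windows <- build_windows(build, config$window_size, config$window_step)
  set.seed(derive_seed(config$seed, "window_gc"))
  window_gc <- stats::setNames(
    pmin(0.65, pmax(0.25, stats::rnorm(nrow(windows), 0.45, 0.07))),
    windows$interval_id)
  genes <- rcrs_mito_genes(config$mito_name)
  cytobands <- toy_cytobands(build)

  n <- as.integer(config$n_participants)
  participants <- sprintf("P%03d", seq_len(n))
  set.seed(derive_seed(config$seed, "cohort"))
  sex <- ifelse(stats::runif(n) < config$female_prob, "female", "male")
  disease <- ifelse(stats::runif(n) < config$coad_prob, "COAD", "READ")
  vital <- ifelse(stats::runif(n) < config$deceased_prob, "deceased",
                  "alive")
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.18, 0.38, 0.30, 0.14))
  age <- as.integer(round(stats::runif(n, 30, 90)))
  race <- sample(c("white", "black"), n, replace = TRUE, prob = c(0.8, 0.2))
  plate <- sprintf("plate%02d", ceiling(seq_len(n) / config$plate_size))

  rho <- if (!is.null(config$sex_ratio)) unname(config$sex_ratio[sex])
         else rep(config$tumor_ratio, n)

  metadata <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample_id = paste0(participants[i], c("_t", "_h")),
               participant = participants[i], genome_type = c("t", "h"),
               plate = plate[i], sex = sex[i], disease = disease[i],
               vital_status = vital[i], stage = stage[i], age = age[i],
               race = race[i], stringsAsFactors = FALSE)
  }))
  rates <- ifelse(metadata$genome_type == "t",
                  config$healthy_chimera_rate *
                    rho[match(metadata$participant, participants)],
                  config$healthy_chimera_rate)
  sample_rates <- data.frame(sample_id = metadata$sample_id,
                             chimera_rate = rates,
                             expected_pairs = rates *
                               config$background_pairs * 2,
                             stringsAsFactors = FALSE)

  samples <- list()
  truth <- list()
  paths <- NULL
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    res <- sim_sample_records(sid, metadata$participant[i],
                              metadata$genome_type[i],
                              sample_rates$chimera_rate[i], config, build,
                              windows, window_gc, genes)
    attr(res$records, "read_length") <- config$read_length
    truth[[sid]] <- res$truth
    if (!is.null(dir))
      write_sam_file(res$records, file.path(dir, paste0(sid, ".sam")),
                     config$contigs)
    if (keep_records) samples[[sid]] <- res$records
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  if (!is.null(dir)) {
    metadata$path <- paste0(metadata$sample_id, ".sam")
    utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(cytobands$contig, as.integer(cytobands$start),
                 as.integer(cytobands$end), cytobands$band, cytobands$stain),
      file.path(dir, "cytobands.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    write_partition_bed(
      new_partition(data.frame(interval_id = genes$gene,
                               contig = genes$contig, start = genes$start,
                               end = genes$end, strand = genes$strand,
                               stringsAsFactors = FALSE), "mgn"),
      file.path(dir, "mito_genes.bed"))
    if (write_fasta) {
      fa <- file.path(dir, "genome.fa")
      write_toy_fasta(build, windows, window_gc, fa, config$seed)
      Rsamtools::indexFa(fa)
    }
    paths <- list(dir = dir,
                  sam = file.path(dir, paste0(metadata$sample_id, ".sam")),
                  metadata = file.path(dir, "metadata.tsv"),
                  truth = file.path(dir, "truth.tsv"),
                  cytobands = file.path(dir, "cytobands.tsv"),
                  mito_bed = file.path(dir, "mito_genes.bed"),
                  fasta = if (write_fasta) file.path(dir, "genome.fa"))
  }

  structure(list(
    config = config, build = build,
    partitions = list(genome = partition_genome(build),
                      chromosomes = partition_chromosomes(build),
                      arms = derive_arms(cytobands), cytobands = cytobands,
                      windows = windows,
                      mito = mito_partitions(genes, config$mito_name,
                                             as.integer(
                                               config$contigs[[config$mito_name]]))),
    window_gc = window_gc, genes = genes, metadata = metadata,
    truth = truth, sample_rates = sample_rates,
    samples = if (keep_records) samples, paths = paths
  ), class = "numt_sim")
}

#' @export
print.numt_sim <- function(x, ...) {
  cat("<numt_sim> ", nrow(x$metadata), " samples (",
      x$config$n_participants, " participants), ",
      nrow(x$truth), " implanted chimeric pair records\n", sep = "")
  cat("  healthy rate ", x$config$healthy_chimera_rate, "/read, rho = ",
      x$config$tumor_ratio, ", ", x$config$background_pairs,
      " background pairs/genome\n", sep = "")
  if (!is.null(x$paths)) cat("  workspace:", x$paths$dir, "\n")
  invisible(x)
}

#' Compare pipeline detections against simulator ground truth
#'
#' Matches detected chimeric pairs to the implanted truth on
#' (sample, nuclear contig, nuclear position, mtDNA position) as multisets
#' and reports detection sensitivity (matched / expected), false
#' detections, and per-sample counts with the generating rates. When the
#' pipeline dropped duplicate-flagged reads, duplicate clones are excluded
#' from the expectation.
#'
#' @param pairs Detected pair table ([extract_numt_pairs()] rows for the
#'   cohort).
#' @param sim The `numt_sim` the pipeline ran on.
#' @param drop_duplicates Whether the pipeline ran with duplicate removal.
#' @return List of class `numt_recovery`: `sensitivity`,
#'   `false_detections`, `n_expected`, `n_detected`, `per_sample`.
#' @export
truth_compare <- function(pairs, sim, drop_duplicates = TRUE) {
  truth <- sim$truth
  if (drop_duplicates) truth <- truth[!truth$is_duplicate, , drop = FALSE]
  if (length(setdiff(unique(pairs$sample_id),
                     sim$metadata$sample_id)))
    stopf("detected pairs reference samples absent from the simulation")
  tkey <- paste(truth$sample_id, truth$nuclear_contig, truth$nuclear_pos,
                truth$mito_pos, sep = "\r")
  dkey <- paste(pairs$sample_id, pairs$nuclear_contig, pairs$nuclear_pos,
                pairs$mito_pos, sep = "\r")
  tt <- table(tkey); dd <- table(dkey)
  common <- intersect(names(tt), names(dd))
  matched <- sum(pmin(tt[common], dd[common]))
  per_sample <- merge(
    data.frame(sample_id = sim$metadata$sample_id,
               stringsAsFactors = FALSE),
    merge(stats::aggregate(list(n_expected = tkey),
                           by = list(sample_id = truth$sample_id), length),
          stats::aggregate(list(n_detected = dkey),
                           by = list(sample_id = pairs$sample_id), length),
          all = TRUE),
    all.x = TRUE)
  per_sample[is.na(per_sample)] <- 0L
  per_sample <- merge(per_sample, sim$sample_rates, by = "sample_id")
  structure(list(sensitivity = if (nrow(truth)) matched / nrow(truth) else 1,
                 false_detections = nrow(pairs) - matched,
                 n_expected = nrow(truth), n_detected = nrow(pairs),
                 per_sample = per_sample), class = "numt_recovery")
}

#' @export
print.numt_recovery <- function(x, ...) {
  cat(sprintf("<numt_recovery> sensitivity %.4f (%d/%d), %d false detection(s)\n",
              x$sensitivity, x$n_detected - x$false_detections,
              x$n_expected, x$false_detections))
  invisible(x)
}
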