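# Fixture builders and independent oracles. The oracles deliberately avoid
# the package's code paths: the SAM oracle hand-parses the text format and
# groups records by query name; the counting oracle loops intervals; the
# OLS oracle solves the normal equations; the rank-test oracle enumerates
# assignments.

toy_contigs <- c(chr1 = 2e6, chr2 = 1e6, chrX = 5e5, chrM = 16569)

make_reads <- function(qname, flag, rname, pos, mapq = 60L, mrnm = rname,
                       mpos = pos, contigs = toy_contigs) {
  n <- length(qname)
  df <- data.frame(qname = qname, flag = rep_len(as.integer(flag), n),
                   rname = rep_len(rname, n),
                   pos = rep_len(as.integer(pos), n),
                   mapq = rep_len(as.integer(mapq), n),
                   mrnm = rep_len(mrnm, n),
                   mpos = rep_len(as.integer(mpos), n),
                   stringsAsFactors = FALSE)
  attr(df, "contigs") <- contigs
  df
}

# Two records forming one pair; flags: 97/145 discordant, 99/147 proper.
make_pair <- function(qname, ctg1, pos1, ctg2, pos2, mapq1 = 60L,
                      mapq2 = 60L, flag1 = 97L, flag2 = 145L) {
  make_reads(qname = c(qname, qname), flag = c(flag1, flag2),
             rname = c(ctg1, ctg2), pos = c(pos1, pos2),
             mapq = c(mapq1, mapq2), mrnm = c(ctg2, ctg1),
             mpos = c(pos2, pos1))
}

bind_reads <- function(...) {
  dfs <- list(...)
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  attr(out, "contigs") <- attr(dfs[[1L]], "contigs")
  out
}

# Independent plain-text SAM writer for fixtures.
write_sam_fixture <- function(records, path, contigs = toy_contigs,
                              read_length = 100L) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  sq <- strrep("A", read_length)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t%s\t%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, read_length,
                  ifelse(records$mrnm == records$rname, "=", records$mrnm),
                  records$mpos, sq, strrep("I", read_length))
  writeLines(c(hdr, body), path)
  path
}

# Brute-force chimeric-pair oracle: parse SAM text directly, apply the QC
# filters, group records by query name, and keep pairs where exactly one
# mate's contig is mitochondrial. Returns sorted multiset keys
# "nuclear_contig:nuclear_pos:mito_pos".
oracle_chimeric_keys <- function(sam_path,
                                 mito_names = c("chrM", "MT", "chrMT"),
                                 drop_duplicates = TRUE, min_mapq = 0L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(character())
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  rname <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  mapq <- as.integer(vapply(f, `[`, "", 5L))
  rnext <- vapply(f, `[`, "", 7L)
  pnext <- as.integer(vapply(f, `[`, "", 8L))
  rnext[rnext == "="] <- rname[rnext == "="]
  keep <- rep(TRUE, length(qname))
  if (drop_duplicates) keep <- keep & bitwAnd(flag, 1024L) == 0L
  keep <- keep & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  if (min_mapq > 0L) keep <- keep & mapq >= min_mapq
  keep <- keep & bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 8L) == 0L
  self_mt <- rname %in% mito_names
  mate_mt <- rnext %in% mito_names
  chim <- keep & xor(self_mt, mate_mt)
  if (!any(chim)) return(character())
  key_of <- ifelse(self_mt[chim],
                   paste(rnext[chim], pnext[chim], pos[chim], sep = ":"),
                   paste(rname[chim], pos[chim], pnext[chim], sep = ":"))
  sort(unname(vapply(split(key_of, qname[chim]), `[`, "", 1L)))
}

pair_keys <- function(pairs)
  sort(paste(pairs$nuclear_contig, pairs$nuclear_pos, pairs$mito_pos,
             sep = ":"))

# Brute-force interval counting: one loop over partition rows.
oracle_interval_counts <- function(contig, pos, partition) {
  out <- integer(nrow(partition))
  for (i in seq_len(nrow(partition))) {
    out[i] <- sum(contig == partition$contig[i] &
                    partition$start[i] <= pos - 1 & pos - 1 < partition$end[i])
  }
  tapply(out, partition$interval_id, sum)[unique(partition$interval_id)]
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  res <- y - alpha - beta * x
  ss_res <- sum(res^2); ss_tot <- sum((y - mean(y))^2)
  se <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  tstat <- beta / se
  list(slope = beta, intercept = alpha, r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments,
# mirroring the tail-doubling convention of R's exact wilcoxon p-value.
oracle_u_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(sel) {
    ra <- rank(pool)[sel]
    sum(ra) - n1 * (n1 + 1) / 2
  }
  u_all <- apply(idx, 2L, u_of)
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(lo, hi)))
}

# Small in-memory simulated cohort shared by several tests.
small_sim <- function(seed = 11, n = 4, background = 20000, ...) {
  simulate_cohort(sim_config(seed = seed, n_participants = n,
                             background_pairs = background, ...))
}
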