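## Small-RNA integration.
##
## Reads are mapped by exact sequence match; only reads with exactly one
## occurrence in the genome (both strands counted together) are kept, per
## the unique-mapping policy.  Downstream: length distributions, the
## positional methylated-cytosine association around 24-nt siRNA loci
## (mC on the alignment sense strand, mC* on the antisense strand), the
## genome-binned Spearman correlation between siRNA abundance and
## context-specific methylation, and siRNA abundance metaprofiles over
## genes and TEs.

#' Length distribution of a small-RNA library
#'
#' Copy-weighted read counts and fractions per read length.
#'
#' @param reads data.frame with `sequence` and `copies` (see
#'   [read_srna_fasta()]).
#' @return data.frame: `length`, `count`, `fraction` (fractions sum to 1).
#' @export
length_distribution <- function(reads) {
  if (!nrow(reads)) {
    return(data.frame(length = integer(), count = numeric(),
                      fraction = numeric()))
  }
  len <- nchar(reads$sequence)
  cnt <- rowsum(reads$copies, len)
  out <- data.frame(length = as.integer(rownames(cnt)), count = cnt[, 1L])
  out$fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Map reads to the genome by exact unique match
#'
#' Each distinct read sequence is searched on both strands of every
#' chromosome; reads with exactly one occurrence genome-wide are kept with
#' their placement, all others (unmapped or multi-mapped) are dropped and
#' tallied.
#'
#' @param reads data.frame with `read_id`, `sequence`, `copies`.
#' @param genome A [Biostrings::DNAStringSet].
#' @return data.frame of alignments: `read_id`, `chrom`, `start` (0-based
#'   plus-strand coordinate of the leftmost base), `strand`, `length`,
#'   `sequence`, `copies`.  Attributes `n_unmapped` and `n_multi` count the
#'   dropped reads.
#' @export
map_exact_unique <- function(reads, genome) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      start = integer(), strand = character(),
                      length = integer(), sequence = character(),
                      copies = integer(), stringsAsFactors = FALSE)
  if (!nrow(reads)) {
    attr(empty, "n_unmapped") <- 0L
    attr(empty, "n_multi") <- 0L
    return(empty)
  }
  rc_genome <- Biostrings::reverseComplement(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  widths <- nchar(reads$sequence)
  n_reads <- nrow(reads)
  hit_chrom <- rep(NA_character_, n_reads)
  hit_start <- rep(NA_integer_, n_reads)
  hit_strand <- rep(NA_character_, n_reads)
  n_occ <- integer(n_reads)
  first1 <- function(v) if (is.null(v)) NA_integer_ else v[1L]
  for (w in sort(unique(widths))) {
    ridx <- which(widths == w)
    dict <- Biostrings::DNAStringSet(reads$sequence[ridx])
    pd <- Biostrings::PDict(dict)
    cnt_p <- Biostrings::vcountPDict(pd, genome)
    cnt_m <- Biostrings::vcountPDict(pd, rc_genome)
    n_occ[ridx] <- rowSums(cnt_p) + rowSums(cnt_m)
    uniq <- which(n_occ[ridx] == 1L)
    if (!length(uniq)) next
    for (ci in seq_along(genome)) {
      cm <- names(genome)[ci]
      on_p <- uniq[cnt_p[uniq, ci] == 1L]
      if (length(on_p)) {
        st <- Biostrings::startIndex(
          Biostrings::matchPDict(pd, genome[[ci]]))
        g <- ridx[on_p]
        hit_chrom[g] <- cm
        hit_start[g] <- vapply(st[on_p], first1, integer(1)) - 1L
        hit_strand[g] <- "+"
      }
      on_m <- uniq[cnt_m[uniq, ci] == 1L]
      if (length(on_m)) {
        st <- Biostrings::startIndex(
          Biostrings::matchPDict(pd, rc_genome[[ci]]))
        g <- ridx[on_m]
        ## position on the reversed sequence -> plus-strand coordinate
        hit_chrom[g] <- cm
        hit_start[g] <- lens[[cm]] -
          (vapply(st[on_m], first1, integer(1)) - 1L) - w
        hit_strand[g] <- "-"
      }
    }
  }
  keep <- which(n_occ == 1L)
  attr_unmapped <- sum(n_occ == 0L)
  attr_multi <- sum(n_occ > 1L)
  if (!length(keep)) {
    attr(empty, "n_unmapped") <- attr_unmapped
    attr(empty, "n_multi") <- attr_multi
    return(empty)
  }
  out <- data.frame(read_id = reads$read_id[keep],
                    chrom = hit_chrom[keep],
                    start = hit_start[keep], strand = hit_strand[keep],
                    length = widths[keep],
                    sequence = reads$sequence[keep],
                    copies = reads$copies[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- attr_unmapped
  attr(out, "n_multi") <- attr_multi
  out
}

#' Positional base and methylated-cytosine association around sRNA loci
#'
#' For each alignment, genome positions are indexed in the read's 5'->3'
#' orientation from `-flank` to `length + flank - 1`.  `mc` counts
#' alignments whose sense-strand cytosine at a position is a called mC,
#' `mc_star` the same on the antisense strand; base frequencies (T reported
#' as U) are defined only inside the read.  Positions truncated at a
#' chromosome end are skipped, not zero-filled.
#'
#' @param alignments data.frame from [map_exact_unique()] (typically the
#'   24-nt subset).
#' @param sample A [methylome()] with a computed conversion rate, or a
#'   precomputed [call_mc()] result via `mc_calls`.
#' @param flank Flanking bases on each side (default 10).
#' @param mc_calls Optional result of [call_mc()] to reuse.
#' @param mc_rule Rule passed to [call_mc()] when `mc_calls` is missing.
#' @param genome Optional genome, used to skip positions truncated at
#'   chromosome ends; without it only the lower bound is enforced.
#' @return data.frame: `position` (-flank .. length+flank-1), `n` (number
#'   of alignments covering the position), `freq_a`, `freq_c`, `freq_g`,
#'   `freq_u` (within-read only, else NA), `mc`, `mc_star`.
#' @export
positional_association <- function(alignments, sample, flank = 10,
                                   mc_calls = NULL,
                                   mc_rule = c("binomial", "any_meth"),
                                   genome = NULL) {
  mc_rule <- match.arg(mc_rule)
  flank <- as.integer(flank)
  if (!nrow(alignments)) stopf("no alignments supplied")
  L <- unique(alignments$length)
  if (length(L) != 1L) stopf("alignments must share one read length")
  if (is.null(mc_calls)) mc_calls <- call_mc(sample, rule = mc_rule)
  mc <- mc_calls$calls
  mc_keys <- site_key(mc$chrom, mc$pos, mc$strand)[mc$is_mc]
  npos <- L + 2L * flank
  rel <- seq_len(npos) - flank - 1L            # -flank .. L+flank-1
  nal <- nrow(alignments)
  off <- rep(seq_len(npos) - 1L, times = nal)  # position index - 1
  ai <- rep(seq_len(nal), each = npos)
  plus <- alignments$strand[ai] == "+"
  gpos <- ifelse(plus, alignments$start[ai] - flank + off,
                 alignments$start[ai] + L - 1L + flank - off)
  chrom <- alignments$chrom[ai]
  sense <- alignments$strand[ai]
  anti <- ifelse(sense == "+", "-", "+")
  ok <- gpos >= 0L
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    ok <- ok & gpos < lens[chrom]
  }
  is_mc_sense <- ok & site_key(chrom, gpos, sense) %in% mc_keys
  is_mc_anti <- ok & site_key(chrom, gpos, anti) %in% mc_keys
  pos_id <- off + 1L
  n_cov <- as.integer(rowsum(as.integer(ok), pos_id))
  mc_count <- as.integer(rowsum(as.integer(is_mc_sense), pos_id))
  mcs_count <- as.integer(rowsum(as.integer(is_mc_anti), pos_id))
  seq_mat <- matrix(unlist(strsplit(alignments$sequence, "")),
                    nrow = L)                  # L x nal, 5'->3'
  base_tab <- matrix(0L, nrow = npos, ncol = 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T")) {
    base_tab[flank + seq_len(L), b] <- rowSums(seq_mat == b)
  }
  inread <- rel >= 0L & rel < L
  tot <- rowSums(base_tab)
  freq <- base_tab / ifelse(tot > 0, tot, 1)
  data.frame(position = rel, n = n_cov,
             freq_a = ifelse(inread, freq[, "A"], NA_real_),
             freq_c = ifelse(inread, freq[, "C"], NA_real_),
             freq_g = ifelse(inread, freq[, "G"], NA_real_),
             freq_u = ifelse(inread, freq[, "T"], NA_real_),
             mc = mc_count, mc_star = mcs_count)
}

#' Genome-binned correlation between sRNA abundance and methylation
#'
#' Tiles the genome into `bin_size` windows; per bin, the copy-weighted
#' abundance of the supplied alignments in RPM (a read is assigned to the
#' bin holding its 5' end) and the weighted methylation level of the
#' context.  Bins without covered context cytosines are excluded.
#'
#' @param alignments data.frame from [map_exact_unique()] (typically the
#'   24-nt subset).
#' @param sample A [methylome()].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param bin_size Bin width in bases (default 2000).
#' @param min_coverage Per-site coverage filter for levels.
#' @param total_mapped Copy total of all uniquely mapped reads (the RPM
#'   denominator); defaults to the copies in `alignments`.
#' @param genome Optional genome for chromosome lengths (else inferred
#'   from the sample's sites).
#' @return List: `rho` (Spearman), `p`, `n_bins`, `bins` (per-bin table
#'   with `rpm` and `level`).
#' @export
binned_srna_methylation_correlation <- function(alignments, sample,
                                                context, bin_size = 2000,
                                                min_coverage = 4,
                                                total_mapped = NULL,
                                                genome = NULL) {
  if (is.null(total_mapped)) total_mapped <- sum(alignments$copies)
  s <- genomic_sites(sample)
  s <- s[!is.na(s$context) & s$context == context, , drop = FALSE]
  s <- s[s$n_meth + s$n_unmeth >= min_coverage, , drop = FALSE]
  if (!nrow(s)) stopf("no covered %s sites", context)
  chroms <- unique(s$chrom)
  lens <- if (!is.null(genome)) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(split(s$pos, s$chrom), max, numeric(1)) + 1
  }
  out <- lapply(chroms, function(cm) {
    bins <- tile_bins(lens[[cm]], bin_size)
    bins$chrom <- cm
    sc <- s[s$chrom == cm, , drop = FALSE]
    b <- pmin(sc$pos %/% as.integer(bin_size) + 1L, nrow(bins))
    m <- rowsum(cbind(sc$n_meth, sc$n_meth + sc$n_unmeth), b)
    bins$level <- NA_real_
    bins$level[as.integer(rownames(m))] <- m[, 1L] / m[, 2L]
    al <- alignments[alignments$chrom == cm, , drop = FALSE]
    bins$count <- 0
    if (nrow(al)) {
      five_prime <- ifelse(al$strand == "+", al$start,
                           al$start + al$length - 1L)
      ab <- pmin(five_prime %/% as.integer(bin_size) + 1L, nrow(bins))
      cs <- rowsum(al$copies, ab)
      bins$count[as.integer(rownames(cs))] <- cs[, 1L]
    }
    bins[, c("chrom", "start", "end", "level", "count")]
  })
  bins <- do.call(rbind, out)
  bins <- bins[!is.na(bins$level), , drop = FALSE]
  if (nrow(bins) < 3L) stopf("fewer than 3 eligible bins")
  bins$rpm <- bins$count / total_mapped * 1e6
  ct <- suppressWarnings(cor.test(bins$rpm, bins$level,
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_bins = nrow(bins),
       bins = bins)
}

#' sRNA abundance metaprofile over genes or TEs
#'
#' Same 60-bin geometry as [meta_profile()]; per feature-bin the
#' copy-weighted count of read 5' ends, normalised to RPM per kilobase of
#' bin width, averaged over all features (zero abundance counts as data,
#' so every feature contributes to every bin it spans).
#'
#' @param alignments data.frame from [map_exact_unique()].
#' @param features Regions data.frame (strand-aware).
#' @param flank Flank width (default 2000).
#' @param n_bins Bins per segment (default 20).
#' @param total_mapped RPM denominator; defaults to the copies in
#'   `alignments`.
#' @return data.frame: `bin`, `region`, `mean_rpm_per_kb`, `n_features`.
#' @export
srna_metaprofile <- function(alignments, features, flank = 2000,
                             n_bins = 20, total_mapped = NULL) {
  if (is.null(total_mapped)) total_mapped <- sum(alignments$copies)
  nb3 <- 3L * n_bins
  acc <- rep(0, nb3)
  n_feat <- 0L
  five_prime <- if (nrow(alignments)) {
    ifelse(alignments$strand == "+", alignments$start,
           alignments$start + alignments$length - 1L)
  } else integer(0)
  by_chr <- split(data.frame(pos = five_prime,
                             copies = alignments$copies),
                  alignments$chrom)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    n_feat <- n_feat + 1L
    len <- f$end - f$start
    widths <- c(rep(flank / n_bins, n_bins),
                rep(len / n_bins, n_bins),
                rep(flank / n_bins, n_bins))
    vals <- rep(0, nb3)
    ac <- by_chr[[f$chrom]]
    if (!is.null(ac)) {
      sel <- ac$pos >= f$start - flank & ac$pos < f$end + flank
      if (any(sel)) {
        idx <- profile_bin_index(ac$pos[sel], f$start, f$end, f$strand,
                                 flank, n_bins)
        ok <- !is.na(idx)
        if (any(ok)) {
          cs <- rowsum(ac$copies[sel][ok], idx[ok])
          vals[as.integer(rownames(cs))] <- cs[, 1L]
        }
      }
    }
    acc <- acc + (vals / total_mapped * 1e6) / (widths / 1000)
  }
  data.frame(bin = seq_len(nb3),
             region = rep(c("upstream", "body", "downstream"),
                          each = n_bins),
             mean_rpm_per_kb = if (n_feat > 0) acc / n_feat else acc,
             n_features = n_feat)
}
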