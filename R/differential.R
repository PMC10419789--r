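## Differential methylation between two samples.
##
## DMCs: per-cytosine 2x2 Fisher exact tests on (methylated, unmethylated)
## counts, BH-adjusted per context over all tested sites; a DMC needs
## q < 0.05 and an absolute level difference of at least 0.2.  DMRs: the
## genome is partitioned into fixed 1000-bp bins, counts are pooled per bin
## over context cytosines covered in both samples, and a bin is a DMR at
## q < 0.01 with a context-specific minimum difference of 0.2 (CG),
## 0.15 (CHG) or 0.1 (CHH).  "Hyper" always means higher in the test
## sample.

#' Vectorised two-sided Fisher exact test for 2x2 tables
#'
#' Exact two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one, with a relative tolerance of
#' 1e-7 for ties.  All four arguments recycle; tables with an all-zero
#' margin return p = 1.
#'
#' @param a,b,c,d Non-negative integer counts, `rbind(c(a, b), c(c, d))`;
#'   for methylation calls, `a`/`b` are the methylated/unmethylated counts
#'   of the test sample and `c`/`d` of the reference.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)   # 2/choose(20, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stopf("negative count")
  m <- a + b                      # white balls (row 1 total)
  nn <- c + d                     # black balls (row 2 total)
  k <- a + c                      # drawn (column 1 total)
  p <- rep(1, n)
  live <- m > 0L & nn > 0L & k > 0L & (b + d) > 0L
  if (!any(live)) return(p)
  lo <- pmax(0L, k - nn)
  hi <- pmin(k, m)
  sup_len <- hi - lo + 1L
  idx <- which(live)
  reps <- sup_len[idx]
  tab <- rep(idx, reps)
  x <- sequence(reps) - 1L + lo[tab]
  dens <- dhyper(x, m[tab], nn[tab], k[tab])
  obs <- dhyper(a[idx], m[idx], nn[idx], k[idx])
  keep <- dens <= obs[match(tab, idx)] * (1 + 1e-7)
  ps <- rowsum(dens * keep, tab)
  p[as.integer(rownames(ps))] <- pmin(ps[, 1L], 1)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_i = min_{p_(j) >= p_(i)} m p_(j) / j`,
#' capped at 1), preserving input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

## sites of one context covered >= min_coverage in both samples, matched
matched_sites <- function(test, ref, context, min_coverage) {
  st <- genomic_sites(test)
  sr <- genomic_sites(ref)
  st <- st[!is.na(st$context) & st$context == context, , drop = FALSE]
  sr <- sr[!is.na(sr$context) & sr$context == context, , drop = FALSE]
  st <- st[st$n_meth + st$n_unmeth >= min_coverage, , drop = FALSE]
  sr <- sr[sr$n_meth + sr$n_unmeth >= min_coverage, , drop = FALSE]
  i <- match(site_key(st$chrom, st$pos, st$strand),
             site_key(sr$chrom, sr$pos, sr$strand))
  keep <- !is.na(i)
  if (!any(keep)) return(NULL)
  data.frame(chrom = st$chrom[keep], pos = st$pos[keep],
             strand = st$strand[keep], context = context,
             meth_test = st$n_meth[keep], unmeth_test = st$n_unmeth[keep],
             meth_ref = sr$n_meth[i[keep]],
             unmeth_ref = sr$n_unmeth[i[keep]], stringsAsFactors = FALSE)
}

#' Call differentially methylated cytosines
#'
#' Sites covered by at least `min_coverage` reads in both samples are
#' tested with [fisher_exact_2x2()] on their count pairs; p-values are
#' BH-adjusted over all tested sites of the context, and sites passing
#' `q < fdr` with `|level_test - level_ref| >= min_delta` are reported.
#'
#' @param test,ref Two [methylome()] samples on the same genome.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage Per-site coverage floor in both samples (default 4).
#' @param min_delta Minimum absolute level difference (default 0.2).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame of DMCs: `chrom`, `pos`, `strand`, `context`,
#'   `level_test`, `level_ref`, `delta`, `p`, `q`, `direction`
#'   (`hyper` = higher in `test`).  Attribute `n_tested` records the number
#'   of tested sites.
#' @export
call_dmcs <- function(test, ref, context, min_coverage = 4,
                      min_delta = 0.2, fdr = 0.05) {
  ms <- matched_sites(test, ref, context, min_coverage)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      level_test = numeric(), level_ref = numeric(),
                      delta = numeric(), p = numeric(), q = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (is.null(ms)) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  ms$level_test <- ms$meth_test / (ms$meth_test + ms$unmeth_test)
  ms$level_ref <- ms$meth_ref / (ms$meth_ref + ms$unmeth_ref)
  ms$delta <- ms$level_test - ms$level_ref
  ms$p <- fisher_exact_2x2(ms$meth_test, ms$unmeth_test,
                           ms$meth_ref, ms$unmeth_ref)
  ms$q <- bh_adjust(ms$p)
  out <- ms[ms$q < fdr & abs(ms$delta) >= min_delta, , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  res <- out[, c("chrom", "pos", "strand", "context", "level_test",
                 "level_ref", "delta", "p", "q", "direction")]
  rownames(res) <- NULL
  attr(res, "n_tested") <- nrow(ms)
  res
}

#' Call differentially methylated regions in fixed 1-kb bins
#'
#' The genome is partitioned into `bin_size` tiling windows from
#' coordinate 0.  Within each bin, counts of context cytosines covered by
#' at least `min_coverage` reads in both samples are pooled into one 2x2
#' Fisher table; bins with fewer than `min_sites` such cytosines are not
#' tested.  BH adjustment is per context over tested bins, and a DMR needs
#' `q < fdr` and a pooled level difference of at least the context's
#' `min_delta`.
#'
#' @inheritParams call_dmcs
#' @param bin_size Bin width in bases (default 1000).
#' @param fdr FDR threshold (default 0.01).
#' @param min_delta Named per-context minimum absolute pooled-level
#'   difference (default `c(CG = 0.2, CHG = 0.15, CHH = 0.1)`).
#' @param min_sites Minimum eligible cytosines per bin (default 4).
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `context`,
#'   `n_sites`, pooled counts, `level_test`, `level_ref`, `delta`, `p`,
#'   `q`, `direction`.  Attribute `n_tested` records tested bins.
#' @export
call_dmrs <- function(test, ref, context, bin_size = 1000,
                      min_coverage = 4, fdr = 0.01,
                      min_delta = c(CG = 0.2, CHG = 0.15, CHH = 0.1),
                      min_sites = 4) {
  delta_thr <- if (length(min_delta) == 1L && is.null(names(min_delta)))
    min_delta else unname(min_delta[context])
  if (is.na(delta_thr)) stopf("no delta threshold for context %s", context)
  ms <- matched_sites(test, ref, context, min_coverage)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_sites = integer(), meth_test = integer(),
                      unmeth_test = integer(), meth_ref = integer(),
                      unmeth_ref = integer(), level_test = numeric(),
                      level_ref = numeric(), delta = numeric(),
                      p = numeric(), q = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (is.null(ms)) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  bin <- ms$pos %/% as.integer(bin_size)
  key <- paste(ms$chrom, bin, sep = "\r")
  agg <- rowsum(cbind(ms$meth_test, ms$unmeth_test, ms$meth_ref,
                      ms$unmeth_ref, 1L), key)
  kk <- strsplit(rownames(agg), "\r", fixed = TRUE)
  bins <- data.frame(
    chrom = vapply(kk, `[`, character(1), 1L),
    start = as.integer(vapply(kk, `[`, character(1), 2L)) *
      as.integer(bin_size),
    meth_test = agg[, 1L], unmeth_test = agg[, 2L],
    meth_ref = agg[, 3L], unmeth_ref = agg[, 4L],
    n_sites = as.integer(agg[, 5L]), stringsAsFactors = FALSE)
  bins$end <- bins$start + as.integer(bin_size)
  bins <- bins[bins$n_sites >= min_sites, , drop = FALSE]
  if (!nrow(bins)) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  bins$level_test <- bins$meth_test / (bins$meth_test + bins$unmeth_test)
  bins$level_ref <- bins$meth_ref / (bins$meth_ref + bins$unmeth_ref)
  bins$delta <- bins$level_test - bins$level_ref
  bins$p <- fisher_exact_2x2(bins$meth_test, bins$unmeth_test,
                             bins$meth_ref, bins$unmeth_ref)
  bins$q <- bh_adjust(bins$p)
  bins$context <- context
  n_tested <- nrow(bins)
  out <- bins[bins$q < fdr & abs(bins$delta) >= delta_thr, , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "context", "n_sites", "meth_test",
               "unmeth_test", "meth_ref", "unmeth_ref", "level_test",
               "level_ref", "delta", "p", "q", "direction")]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

#' Assign DMRs to gene promoters, bodies and downstream flanks
#'
#' A DMR is assigned to a gene region when their intervals overlap by at
#' least one base; promoter and downstream are the strand-aware 2-kb flanks
#' beyond the TSS / TES.  One DMR can yield several assignments (several
#' genes and several regions).
#'
#' @param dmrs data.frame from [call_dmrs()].
#' @param genes Regions data.frame of genes (strand-annotated).
#' @param flank Flank width in bases (default 2000).
#' @return data.frame: `gene_id`, `region`, `context`, `direction`,
#'   `dmr_chrom`, `dmr_start`, `dmr_end`, `delta`, `q`.
#' @export
assign_dmrs_to_genes <- function(dmrs, genes, flank = 2000) {
  empty <- data.frame(gene_id = character(), region = character(),
                      context = character(), direction = character(),
                      dmr_chrom = character(), dmr_start = integer(),
                      dmr_end = integer(), delta = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (!nrow(dmrs) || !nrow(genes)) return(empty)
  gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L,
                                                  dmrs$end))
  regs <- list(promoter = promoter_region(genes, flank),
               body = genes,
               downstream = downstream_region(genes, flank))
  out <- list()
  for (rg in names(regs)) {
    r <- regs[[rg]]
    if (!nrow(r)) next
    gr_r <- GenomicRanges::GRanges(r$chrom,
                                   IRanges::IRanges(r$start + 1L, r$end))
    ov <- GenomicRanges::findOverlaps(gr_d, gr_r)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    out[[rg]] <- data.frame(
      gene_id = r$feature_id[sh], region = rg,
      context = dmrs$context[qh], direction = dmrs$direction[qh],
      dmr_chrom = dmrs$chrom[qh], dmr_start = dmrs$start[qh],
      dmr_end = dmrs$end[qh], delta = dmrs$delta[qh], q = dmrs$q[qh],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric term enrichment of a gene set
#'
#' Per term, the upper-tail hypergeometric probability of observing at
#' least `k` annotated genes among the `n` selected, given `K` annotated in
#' the universe of `N`; BH adjustment across terms.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all background gene ids.
#' @param gene2term data.frame with `gene_id`, `term_id`.
#' @param fdr FDR threshold for the `enriched` flag (default 0.05).
#' @return data.frame: `term_id`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `enriched`; terms with no annotated gene in the universe are skipped.
#' @export
term_enrichment <- function(selected, universe, gene2term, fdr = 0.05) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) {
    stopf("selected genes must be a subset of the universe")
  }
  g2t <- gene2term[gene2term$gene_id %in% universe, , drop = FALSE]
  terms <- sort(unique(g2t$term_id))
  N <- length(universe)
  n <- length(selected)
  out <- lapply(terms, function(tm) {
    ann <- unique(g2t$gene_id[g2t$term_id == tm])
    K <- length(ann)
    if (K == 0L) return(NULL)
    k <- sum(selected %in% ann)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < fdr
  out[order(out$p), ]
}

#' Export DMCs or DMRs as BED6
#'
#' Name is `context:direction`, score is `-log10(q)` (capped at 1000).
#'
#' @param x data.frame from [call_dmcs()] or [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(x, path) {
  if (!nrow(x)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  start <- if ("start" %in% names(x)) x$start else x$pos
  end <- if ("end" %in% names(x)) x$end else x$pos + 1L
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  score <- pmin(round(-log10(pmax(x$q, 1e-300)), 3), 1000)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, start, end,
                     paste0(x$context, ":", x$direction),
                     format(score, trim = TRUE), strand), path)
  invisible(path)
}
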