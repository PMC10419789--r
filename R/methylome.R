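## Per-sample methylation quantification.
##
## A methylome sample holds one count record per cytosine (per strand; CpG
## strands are never merged).  The methylation level of a site is the number
## of methylated read calls (Cs) divided by total calls (Cs plus Ts), and is
## only estimated for sites with at least `min_coverage` (default 4) reads.
## The weighted level of a set of sites pools counts before dividing.

#' Construct a methylome sample
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `n_meth`, `n_unmeth`, `context`, `subcontext` (as from
#'   [read_cx_report()]).
#' @param name Sample name.
#' @param spikein_chrom Name of the unmethylated spike-in chromosome used
#'   for conversion-rate estimation, or `NULL`.
#' @return An object of class `"methylome"`.
#' @export
methylome <- function(sites, name = "sample", spikein_chrom = NULL) {
  req <- c("chrom", "pos", "strand", "n_meth", "n_unmeth",
           "context", "subcontext")
  if (!all(req %in% names(sites))) {
    stopf("sites is missing columns: %s",
          paste(setdiff(req, names(sites)), collapse = ", "))
  }
  key <- site_key(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) stopf("duplicate site records")
  obj <- list(name = name, sites = sites, spikein_chrom = spikein_chrom,
              conversion_rate = NA_real_)
  class(obj) <- "methylome"
  if (!is.null(spikein_chrom) && spikein_chrom %in% sites$chrom) {
    sp <- sites[sites$chrom == spikein_chrom, , drop = FALSE]
    if (sum(sp$n_meth) + sum(sp$n_unmeth) > 0) {
      obj$conversion_rate <- conversion_rate(obj)
    }
  }
  obj
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s: %d cytosine records on %d sequence(s)\n",
              x$name, nrow(x$sites), length(unique(x$sites$chrom))))
  cov <- x$sites$n_meth + x$sites$n_unmeth
  cat(sprintf("  covered (>=1 read): %d; median coverage %s\n",
              sum(cov > 0), stats::median(cov[cov > 0])))
  if (!is.na(x$conversion_rate)) {
    cat(sprintf("  spike-in '%s': bisulfite conversion rate %.4f\n",
                x$spikein_chrom, x$conversion_rate))
  }
  invisible(x)
}

## sites on the nuclear genome (spike-in excluded)
genomic_sites <- function(sample) {
  s <- sample$sites
  if (!is.null(sample$spikein_chrom)) {
    s <- s[s$chrom != sample$spikein_chrom, , drop = FALSE]
  }
  s
}

#' Per-site methylation level
#'
#' `n_meth / (n_meth + n_unmeth)`, or `NA` for sites covered by fewer than
#' `min_coverage` reads.
#'
#' @param n_meth,n_unmeth Methylated / unmethylated call counts (vectors).
#' @param min_coverage Minimum total reads required (default 4).
#' @return Numeric vector of levels in `[0, 1]` with `NA` for low coverage.
#' @examples
#' site_level(5, 15)   # 0.25
#' site_level(2, 1)    # NA, coverage 3 < 4
#' @export
site_level <- function(n_meth, n_unmeth, min_coverage = 4) {
  tot <- n_meth + n_unmeth
  ifelse(tot >= min_coverage, n_meth / tot, NA_real_)
}

#' Bisulfite conversion rate from the spike-in chromosome
#'
#' One minus the pooled methylated fraction over every spike-in cytosine,
#' all contexts, with no coverage filter.  The spike-in genome carries no
#' true methylation, so any methylated call is a conversion failure.
#'
#' @param sample A [methylome()] with `spikein_chrom` set.
#' @return Conversion rate in `[0, 1]`.
#' @export
conversion_rate <- function(sample) {
  if (is.null(sample$spikein_chrom)) stopf("no spike-in chromosome set")
  s <- sample$sites[sample$sites$chrom == sample$spikein_chrom, ,
                    drop = FALSE]
  tot <- sum(s$n_meth) + sum(s$n_unmeth)
  if (tot == 0) stopf("zero spike-in reads; cannot estimate conversion rate")
  1 - sum(s$n_meth) / tot
}

#' Weighted methylation level of a set of sites
#'
#' Pooled methylated calls divided by pooled total calls over all records
#' passing the coverage filter.
#'
#' @param sites data.frame with `n_meth`, `n_unmeth` columns (and anything
#'   else), or a [methylome()] whose genomic sites are used.
#' @param min_coverage Minimum per-site coverage (default 4).
#' @return A single level in `[0, 1]`, or `NA` if no record passes.
#' @export
weighted_level <- function(sites, min_coverage = 4) {
  if (inherits(sites, "methylome")) sites <- genomic_sites(sites)
  tot <- sites$n_meth + sites$n_unmeth
  keep <- tot >= min_coverage
  if (!any(keep)) return(NA_real_)
  sum(sites$n_meth[keep]) / sum(tot[keep])
}

#' Mean of per-site methylation levels
#'
#' The unweighted alternative to [weighted_level()]: sites passing the
#' coverage filter contribute equally regardless of depth.
#'
#' @inheritParams weighted_level
#' @return Mean site level, or `NA` if no site passes.
#' @export
mean_site_level <- function(sites, min_coverage = 4) {
  if (inherits(sites, "methylome")) sites <- genomic_sites(sites)
  lv <- site_level(sites$n_meth, sites$n_unmeth, min_coverage)
  if (all(is.na(lv))) return(NA_real_)
  mean(lv, na.rm = TRUE)
}

#' Global per-context level summary
#'
#' @param sample A [methylome()].
#' @param min_coverage Minimum per-site coverage.
#' @return data.frame: `context`, `n_sites`, `n_sites_covered`,
#'   `weighted_level`, `mean_site_level`.
#' @export
context_levels <- function(sample, min_coverage = 4) {
  s <- genomic_sites(sample)
  out <- lapply(.CONTEXTS, function(ctx) {
    sub <- s[!is.na(s$context) & s$context == ctx, , drop = FALSE]
    covered <- sum(sub$n_meth + sub$n_unmeth >= min_coverage)
    data.frame(context = ctx, n_sites = nrow(sub),
               n_sites_covered = covered,
               weighted_level = weighted_level(sub, min_coverage),
               mean_site_level = mean_site_level(sub, min_coverage))
  })
  do.call(rbind, out)
}

#' Density and methylation level of each trinucleotide sub-context
#'
#' For all 16 trinucleotides (4 CG, 3 CHG, 9 CHH): the genomic density in
#' sites per kilobase (both strands; spike-in excluded) and the weighted
#' methylation level.
#'
#' @param sample A [methylome()].
#' @param genome The genome the sample was quantified on (for densities).
#' @param min_coverage Minimum per-site coverage for the level.
#' @return data.frame: `context`, `subcontext`, `n_sites`,
#'   `density_per_kb`, `weighted_level`.
#' @export
subcontext_stats <- function(sample, genome, min_coverage = 4) {
  s <- genomic_sites(sample)
  s <- s[!is.na(s$context), , drop = FALSE]
  chroms <- setdiff(names(genome),
                    if (is.null(sample$spikein_chrom)) character()
                    else sample$spikein_chrom)
  gsize <- sum(Biostrings::width(genome)[names(genome) %in% chroms])
  sets <- subcontext_sets()
  out <- lapply(.CONTEXTS, function(ctx) {
    tris <- sort(sets[[ctx]])
    do.call(rbind, lapply(tris, function(tri) {
      sub <- s[s$subcontext %in% tri, , drop = FALSE]
      data.frame(context = ctx, subcontext = tri, n_sites = nrow(sub),
                 density_per_kb = nrow(sub) / gsize * 1000,
                 weighted_level = weighted_level(sub, min_coverage))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Histogram of single-site methylation levels
#'
#' Site levels (coverage-filtered) binned over `[0, 1]` into right-closed
#' bins; the first bin includes 0.  Counts sum to the number of covered
#' sites of the context.
#'
#' @param sample A [methylome()].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param bins Number of bins (default 20).
#' @param min_coverage Minimum per-site coverage.
#' @return data.frame: `bin_low`, `bin_high`, `count`.
#' @export
site_level_histogram <- function(sample, context, bins = 20,
                                 min_coverage = 4) {
  s <- genomic_sites(sample)
  s <- s[!is.na(s$context) & s$context == context, , drop = FALSE]
  lv <- site_level(s$n_meth, s$n_unmeth, min_coverage)
  lv <- lv[!is.na(lv)]
  br <- seq(0, 1, length.out = bins + 1L)
  idx <- pmax(1L, ceiling(lv * bins))          # right-closed, 0 -> bin 1
  counts <- tabulate(idx, nbins = bins)
  data.frame(bin_low = br[-length(br)], bin_high = br[-1L], count = counts)
}

#' Call methylated cytosines against the conversion-error background
#'
#' A covered site is called methylated (mC) when a one-sided binomial test
#' of its methylated calls against the measured non-conversion rate rejects
#' at a Benjamini-Hochberg FDR below `fdr`, adjusted per context over all
#' covered sites.  A simpler `rule = "any_meth"` (at least one methylated
#' call) is available.
#'
#' @param sample A [methylome()] with a computed conversion rate (or pass
#'   `error_rate`).
#' @param fdr FDR threshold (default 0.05).
#' @param min_coverage Minimum per-site coverage (default 4).
#' @param rule `"binomial"` (default) or `"any_meth"`.
#' @param error_rate Optional per-call false-methylation probability;
#'   default `1 - sample$conversion_rate`.
#' @return List: `calls` (the covered sites with `p`, `q`, logical `is_mc`),
#'   `counts` (per-context mC counts) and `mc_levels` (per-context weighted
#'   level restricted to mC sites).
#' @export
call_mc <- function(sample, fdr = 0.05, min_coverage = 4,
                    rule = c("binomial", "any_meth"), error_rate = NULL) {
  rule <- match.arg(rule)
  if (is.null(error_rate)) {
    if (is.na(sample$conversion_rate)) {
      stopf("conversion rate not computed; set spikein_chrom or error_rate")
    }
    error_rate <- 1 - sample$conversion_rate
  }
  s <- genomic_sites(sample)
  s <- s[!is.na(s$context), , drop = FALSE]
  tot <- s$n_meth + s$n_unmeth
  s <- s[tot >= min_coverage, , drop = FALSE]
  tot <- s$n_meth + s$n_unmeth
  if (rule == "binomial") {
    s$p <- pbinom(s$n_meth - 1L, tot, error_rate, lower.tail = FALSE)
    s$q <- NA_real_
    for (ctx in .CONTEXTS) {
      i <- s$context == ctx
      s$q[i] <- p.adjust(s$p[i], method = "BH")
    }
    s$is_mc <- s$q < fdr & s$n_meth > 0L
  } else {
    s$p <- NA_real_
    s$q <- NA_real_
    s$is_mc <- s$n_meth >= 1L
  }
  counts <- vapply(.CONTEXTS, function(ctx) {
    sum(s$is_mc[s$context == ctx])
  }, numeric(1))
  mc_levels <- vapply(.CONTEXTS, function(ctx) {
    weighted_level(s[s$is_mc & s$context == ctx, , drop = FALSE],
                   min_coverage)
  }, numeric(1))
  list(calls = s, counts = counts, mc_levels = mc_levels)
}

#' Genome-wide per-bin summary track
#'
#' Tiles each chromosome into fixed bins from position 0 (last partial bin
#' kept and flagged) and computes one of: the weighted methylation level of
#' a context, the fraction of bases covered by supplied features (e.g. TE
#' coverage), or the number of features starting in the bin (e.g. gene
#' density).
#'
#' @param sample A [methylome()] (needed for `metric = "level"`).
#' @param genome The genome (chromosome lengths).
#' @param bin_size Bin width in bases (default 1e6).
#' @param metric `"level"`, `"feature_coverage"` or `"feature_count"`.
#' @param context Context for `metric = "level"`.
#' @param features Regions data.frame for the feature metrics.
#' @param min_coverage Coverage filter for levels.
#' @param chroms Chromosomes to tile; default all non-spike-in.
#' @return data.frame: `chrom`, `start`, `end`, `partial`, `value` (bins
#'   with no eligible site have `NA` level).
#' @export
binned_track <- function(sample = NULL, genome, bin_size = 1e6,
                         metric = c("level", "feature_coverage",
                                    "feature_count"),
                         context = "CG", features = NULL, min_coverage = 4,
                         chroms = NULL) {
  metric <- match.arg(metric)
  if (bin_size <= 0) stopf("bin_size must be positive")
  if (is.null(chroms)) {
    chroms <- names(genome)
    if (!is.null(sample) && !is.null(sample$spikein_chrom)) {
      chroms <- setdiff(chroms, sample$spikein_chrom)
    }
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  out <- lapply(chroms, function(cm) {
    bins <- tile_bins(lens[[cm]], bin_size)
    bins$chrom <- cm
    bins$value <- NA_real_
    if (metric == "level") {
      s <- sample$sites
      s <- s[s$chrom == cm & !is.na(s$context) & s$context == context, ,
             drop = FALSE]
      tot <- s$n_meth + s$n_unmeth
      s <- s[tot >= min_coverage, , drop = FALSE]
      if (nrow(s)) {
        b <- pmin(s$pos %/% bin_size + 1L, nrow(bins))
        m <- rowsum(cbind(s$n_meth, s$n_meth + s$n_unmeth), b)
        bins$value[as.integer(rownames(m))] <- m[, 1L] / m[, 2L]
      }
    } else {
      f <- features[features$chrom == cm, , drop = FALSE]
      if (metric == "feature_count") {
        bins$value <- 0
        if (nrow(f)) {
          b <- pmin(f$start %/% bin_size + 1L, nrow(bins))
          tb <- table(b)
          bins$value[as.integer(names(tb))] <- as.vector(tb)
        }
      } else {
        cov_ranges <- IRanges::reduce(
          IRanges::IRanges(start = f$start + 1L, end = f$end))
        binr <- IRanges::IRanges(start = bins$start + 1L, end = bins$end)
        ov <- IRanges::findOverlaps(binr, cov_ranges)
        w <- IRanges::width(IRanges::pintersect(
          binr[S4Vectors::queryHits(ov)],
          cov_ranges[S4Vectors::subjectHits(ov)]))
        acc <- rep(0, nrow(bins))
        if (length(ov)) {
          sm <- rowsum(w, S4Vectors::queryHits(ov))
          acc[as.integer(rownames(sm))] <- sm[, 1L]
        }
        bins$value <- acc / (bins$end - bins$start)
      }
    }
    bins[, c("chrom", "start", "end", "partial", "value")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
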