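## Metagene / meta-TE methylation profiles and expression stratification.
##
## Profile geometry: each feature contributes 60 bins in 5'->3' feature
## orientation -- 20 fixed-width bins over the upstream 2 kb, 20
## proportional bins over the body, 20 fixed-width bins over the downstream
## 2 kb.  Within a feature-bin the methylation level is the weighted
## (pooled-count) level; across features each feature carries equal weight,
## and a feature enters a bin's denominator only if it has at least one
## covered site there.

#' Strand-aware gene regions
#'
#' Promoter = 2 kb upstream of the TSS, downstream = 2 kb past the TES, in
#' feature orientation; flanks are truncated at chromosome ends when
#' lengths are supplied.
#'
#' @param genes Regions data.frame (`chrom`, `start`, `end`, `strand`, ...).
#' @param flank Flank width in bases (default 2000).
#' @param chrom_lens Optional named chromosome lengths for truncation.
#' @return data.frame like `genes` with `start`/`end` replaced by the
#'   region's coordinates.
#' @export
promoter_region <- function(genes, flank = 2000, chrom_lens = NULL) {
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$start - flank, genes$end)
  end <- ifelse(plus, genes$start, genes$end + flank)
  clamp_region(genes, start, end, chrom_lens)
}

#' @rdname promoter_region
#' @export
downstream_region <- function(genes, flank = 2000, chrom_lens = NULL) {
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$end, genes$start - flank)
  end <- ifelse(plus, genes$end + flank, genes$start)
  clamp_region(genes, start, end, chrom_lens)
}

clamp_region <- function(genes, start, end, chrom_lens) {
  start <- pmax(start, 0L)
  if (!is.null(chrom_lens)) end <- pmin(end, chrom_lens[genes$chrom])
  out <- genes
  out$start <- as.integer(start)
  out$end <- as.integer(end)
  out[out$start < out$end, , drop = FALSE]
}

## Assign profile bin indices (1..3*n_bins) to site positions for one
## feature; returns NA for positions outside the profiled span.
profile_bin_index <- function(pos, start, end, strand, flank, n_bins) {
  len <- end - start
  fb <- flank / n_bins                      # fixed flank bin width
  if (strand != "-") {
    up <- pos >= start - flank & pos < start
    body <- pos >= start & pos < end
    down <- pos >= end & pos < end + flank
    idx <- rep(NA_integer_, length(pos))
    idx[up] <- floor((pos[up] - (start - flank)) / fb) + 1L
    idx[body] <- n_bins + pmin(floor((pos[body] - start) * n_bins / len),
                               n_bins - 1L) + 1L
    idx[down] <- 2L * n_bins + floor((pos[down] - end) / fb) + 1L
  } else {
    up <- pos >= end & pos < end + flank
    body <- pos >= start & pos < end
    down <- pos >= start - flank & pos < start
    idx <- rep(NA_integer_, length(pos))
    idx[up] <- floor((end + flank - 1L - pos[up]) / fb) + 1L
    idx[body] <- n_bins + pmin(floor((end - 1L - pos[body]) * n_bins / len),
                               n_bins - 1L) + 1L
    idx[down] <- 2L * n_bins + floor((start - 1L - pos[down]) / fb) + 1L
  }
  idx
}

#' Metagene / meta-TE methylation profile
#'
#' Average methylation over all features in 60 bins (upstream flank, body,
#' downstream flank; see the module header).  Features with no covered site
#' in a bin are excluded from that bin's average.
#'
#' @param sample A [methylome()].
#' @param features Regions data.frame (strand-aware).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank Flank width in bases (default 2000).
#' @param n_bins Bins per segment (default 20).
#' @param min_coverage Per-site coverage filter.
#' @return data.frame: `bin` (1..3*n_bins), `region`
#'   (`upstream`/`body`/`downstream`), `mean_level`, `n_features`.
#' @export
meta_profile <- function(sample, features, context, flank = 2000,
                         n_bins = 20, min_coverage = 4) {
  s <- genomic_sites(sample)
  s <- s[!is.na(s$context) & s$context == context, , drop = FALSE]
  tot <- s$n_meth + s$n_unmeth
  s <- s[tot >= min_coverage, , drop = FALSE]
  if (any(features$end - features$start < n_bins)) {
    warnf("%d feature(s) shorter than %d bases: body bins coarser than sites",
          sum(features$end - features$start < n_bins), n_bins)
  }
  nb3 <- 3L * n_bins
  acc_lv <- rep(0, nb3)
  acc_n <- rep(0L, nb3)
  by_chr <- split(s, s$chrom)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    sc <- by_chr[[f$chrom]]
    if (is.null(sc)) next
    lo <- f$start - flank
    hi <- f$end + flank
    sel <- sc$pos >= lo & sc$pos < hi
    if (!any(sel)) next
    sub <- sc[sel, , drop = FALSE]
    idx <- profile_bin_index(sub$pos, f$start, f$end, f$strand, flank,
                             n_bins)
    ok <- !is.na(idx)
    if (!any(ok)) next
    m <- rowsum(cbind(sub$n_meth[ok],
                      sub$n_meth[ok] + sub$n_unmeth[ok]), idx[ok])
    bins <- as.integer(rownames(m))
    acc_lv[bins] <- acc_lv[bins] + m[, 1L] / m[, 2L]
    acc_n[bins] <- acc_n[bins] + 1L
  }
  data.frame(bin = seq_len(nb3),
             region = rep(c("upstream", "body", "downstream"),
                          each = n_bins),
             mean_level = ifelse(acc_n > 0, acc_lv / pmax(acc_n, 1L),
                                 NA_real_),
             n_features = acc_n)
}

#' Stratify genes by expression level
#'
#' Two schemes: `"five_group"` splits genes into silent (FPKM = 0),
#' (0, 1], (1, 10], (10, 50] and (50, Inf) strata; `"tertile"` labels the
#' third of genes with the lowest FPKM `low` and the third with the highest
#' `high` (rank-based, middle third dropped).
#'
#' @param expression data.frame with `gene_id`, `fpkm`.
#' @param scheme `"five_group"` or `"tertile"`.
#' @return data.frame: `gene_id`, `fpkm`, `stratum` (`NA` for the middle
#'   tertile), with the stratum labels ordered low to high expression.
#' @export
stratify_by_expression <- function(expression,
                                   scheme = c("five_group", "tertile")) {
  scheme <- match.arg(scheme)
  if (!nrow(expression)) stopf("empty expression table")
  f <- expression$fpkm
  if (scheme == "five_group") {
    labels <- c("FPKM=0", "0<FPKM<=1", "1<FPKM<=10", "10<FPKM<=50",
                "FPKM>50")
    stratum <- cut(f, breaks = c(-Inf, 0, 1, 10, 50, Inf),
                   labels = labels, right = TRUE)
    stratum <- factor(as.character(stratum), levels = labels)
  } else {
    n <- length(f)
    k <- floor(n / 3)
    r <- rank(f, ties.method = "first")
    stratum <- rep(NA_character_, n)
    stratum[r <= k] <- "low"
    stratum[r > n - k] <- "high"
    stratum <- factor(stratum, levels = c("low", "high"))
  }
  data.frame(gene_id = expression$gene_id, fpkm = f, stratum = stratum,
             stringsAsFactors = FALSE)
}

## Weighted level of one genomic interval
interval_level <- function(sites_by_chr, chrom, start, end, context,
                           min_coverage) {
  sc <- sites_by_chr[[chrom]]
  if (is.null(sc)) return(NA_real_)
  sel <- sc$pos >= start & sc$pos < end & sc$context == context
  if (!any(sel)) return(NA_real_)
  weighted_level(sc[sel, , drop = FALSE], min_coverage)
}

#' Per-gene regional methylation levels
#'
#' Weighted level of the promoter (2 kb upstream), body and downstream
#' (2 kb) region of each gene, per context.
#'
#' @param sample A [methylome()].
#' @param genes Regions data.frame of genes.
#' @param flank Flank width (default 2000).
#' @param min_coverage Per-site coverage filter.
#' @return data.frame: `gene_id`, `region`, `context`, `level` (NA where no
#'   covered site).
#' @export
gene_region_levels <- function(sample, genes, flank = 2000,
                               min_coverage = 4) {
  s <- genomic_sites(sample)
  s <- s[!is.na(s$context), , drop = FALSE]
  tot <- s$n_meth + s$n_unmeth
  s <- s[tot >= min_coverage, , drop = FALSE]
  by_chr <- split(s, s$chrom)
  regs <- list(promoter = promoter_region(genes, flank),
               body = genes,
               downstream = downstream_region(genes, flank))
  out <- list()
  for (rg in names(regs)) {
    r <- regs[[rg]]
    for (ctx in .CONTEXTS) {
      lv <- vapply(seq_len(nrow(r)), function(i) {
        interval_level(by_chr, r$chrom[i], r$start[i], r$end[i], ctx,
                       min_coverage)
      }, numeric(1))
      out[[paste(rg, ctx)]] <- data.frame(
        gene_id = r$feature_id, region = rg, context = ctx, level = lv,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regional methylation by expression stratum
#'
#' Mean (over genes, equal weight) of each gene's regional weighted level,
#' per stratum x region x context.
#'
#' @param sample A [methylome()].
#' @param genes Regions data.frame of genes.
#' @param strata Output of [stratify_by_expression()].
#' @param flank Flank width (default 2000).
#' @param min_coverage Per-site coverage filter.
#' @return data.frame: `stratum`, `region`, `context`, `mean_level`,
#'   `n_genes` (strata with no genes give an `NA` row).
#' @export
region_level_by_stratum <- function(sample, genes, strata, flank = 2000,
                                    min_coverage = 4) {
  grl <- gene_region_levels(sample, genes, flank, min_coverage)
  grl$stratum <- strata$stratum[match(grl$gene_id, strata$gene_id)]
  out <- list()
  for (st in levels(strata$stratum)) {
    for (rg in c("promoter", "body", "downstream")) {
      for (ctx in .CONTEXTS) {
        sub <- grl[!is.na(grl$stratum) & grl$stratum == st &
                     grl$region == rg & grl$context == ctx, , drop = FALSE]
        lv <- sub$level[!is.na(sub$level)]
        out[[paste(st, rg, ctx)]] <- data.frame(
          stratum = st, region = rg, context = ctx,
          mean_level = if (length(lv)) mean(lv) else NA_real_,
          n_genes = length(lv), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
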