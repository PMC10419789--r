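## Seeded synthetic data generator.
##
## Emits a complete toy study: a random genome with gene and TE annotations
## plus an unmethylated spike-in chromosome, two-condition per-cytosine
## count tables with planted DMRs, a 24-nt siRNA library coupled to CHH
## methylation, and FPKM values anti-correlated with promoter methylation.
## Every emitted quantity is recorded in a ground-truth manifest so that
## downstream stages can be scored against what was planted.
##
## Site model: the true methylation level of a cytosine is drawn once per
## site from a Beta distribution centred on its compartment x context mean
## (concentration `level_dispersion`); both conditions share that draw, and
## condition B is shifted by the planted delta inside DMR regions only.
## Read counts are Binomial(coverage ~ Poisson, observed probability), with
## the observed probability folding in the bisulfite conversion error (an
## unmethylated C misread as methylated).

#' Simulation configuration
#'
#' Builds the configuration object consumed by all `simulate_*` functions.
#' Defaults describe a compact plant-like methylome: heavily methylated
#' TEs, gene-body CG methylation, mostly-unmethylated CHH with low levels,
#' bimodal CG/CHG site-level distributions, and a conversion error
#' corresponding to a >99.5% bisulfite conversion rate.
#'
#' @param seed Integer seed; every simulation stage derives its own stream
#'   from it.
#' @param genome_length Total autosome length in bases (split over
#'   `n_chroms`).
#' @param n_chroms Number of autosomes.
#' @param n_genes,n_tes Feature counts (placed without overlap).
#' @param gene_length,te_length Length ranges (min, max) in bases.
#' @param coverage_mean Expected reads per cytosine (Poisson mean).
#' @param conversion_error Probability that a truly unmethylated cytosine
#'   is read as methylated (1 - bisulfite conversion rate).
#' @param meth_error Probability that a truly methylated cytosine is read
#'   as unmethylated (default 0).
#' @param base_levels 3 x 3 matrix of mean methylation, rows
#'   `gene`/`TE`/`intergenic`, columns `CG`/`CHG`/`CHH`.
#' @param level_dispersion Named per-context Beta concentration of the
#'   between-site level distribution (values < 1 give bimodal levels).
#' @param planted_dmrs `NULL` or data.frame with columns `chrom`, `start`,
#'   `end`, `context`, `delta`, `direction` (`"hyper"`/`"hypo"`, realised
#'   in condition B).
#' @param srna_coupling List `base`, `slope`: expected 24-nt read intensity
#'   of a 2-kb bin is `base + slope * bin CHH level`.
#' @param n_srna_reads Total sRNA reads to draw.
#' @param frac_24 Fraction of reads that are 24-nt siRNAs (the rest are
#'   21-23-nt background placed uniformly).
#' @param expression_coupling List `baseline`, `slope`, `sd`:
#'   `log(1 + FPKM) = baseline - slope * promoter mCG + N(0, sd)`,
#'   truncated at 0.
#' @param spikein_chrom,spikein_length Name and length of the unmethylated
#'   spike-in chromosome.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       genome_length = 200000,
                       n_chroms = 2,
                       n_genes = 20,
                       n_tes = 20,
                       gene_length = c(1000, 3000),
                       te_length = c(500, 2000),
                       coverage_mean = 20,
                       conversion_error = 0.004,
                       meth_error = 0,
                       base_levels = NULL,
                       level_dispersion = c(CG = 0.35, CHG = 0.35,
                                            CHH = 2),
                       planted_dmrs = NULL,
                       srna_coupling = list(base = 0.2, slope = 8),
                       n_srna_reads = 50000,
                       frac_24 = 0.7,
                       expression_coupling = list(baseline = log(30),
                                                  slope = 4, sd = 0.8),
                       spikein_chrom = "lambda",
                       spikein_length = 40000) {
  if (is.null(base_levels)) {
    base_levels <- rbind(gene = c(0.35, 0.10, 0.05),
                         TE = c(0.85, 0.65, 0.30),
                         intergenic = c(0.50, 0.30, 0.10))
    colnames(base_levels) <- .CONTEXTS
  }
  stopifnot(all(base_levels >= 0 & base_levels <= 1),
            conversion_error >= 0, conversion_error <= 1,
            meth_error >= 0, meth_error <= 1,
            frac_24 >= 0, frac_24 <= 1,
            coverage_mean > 0)
  if (!is.null(planted_dmrs)) {
    req <- c("chrom", "start", "end", "context", "delta", "direction")
    if (!all(req %in% names(planted_dmrs))) {
      stopf("planted_dmrs needs columns: %s", paste(req, collapse = ", "))
    }
    if (any(abs(planted_dmrs$delta) > 1)) {
      stopf("planted DMR delta outside [-1, 1]")
    }
  }
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_chroms = n_chroms, n_genes = n_genes, n_tes = n_tes,
              gene_length = gene_length, te_length = te_length,
              coverage_mean = coverage_mean,
              conversion_error = conversion_error, meth_error = meth_error,
              base_levels = base_levels,
              level_dispersion = level_dispersion,
              planted_dmrs = planted_dmrs, srna_coupling = srna_coupling,
              n_srna_reads = n_srna_reads, frac_24 = frac_24,
              expression_coupling = expression_coupling,
              spikein_chrom = spikein_chrom,
              spikein_length = spikein_length)
  class(cfg) <- "sim_config"
  cfg
}

## place non-overlapping features on chromosomes; `spec` has one row per
## feature (columns len_min, len_max, feature_type), all sharing one
## occupancy structure
place_features <- function(chrom_lens, spec, max_tries = 5000) {
  if (!nrow(spec)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_type = character(), stringsAsFactors = FALSE))
  }
  lens <- unlist(chrom_lens)
  occupied <- lapply(chrom_lens, function(...) IRanges::IRanges())
  out <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      cm <- sample(names(lens), 1L, prob = lens / sum(lens))
      len <- sample(spec$len_min[i]:spec$len_max[i], 1L)
      if (lens[[cm]] <= len) next
      start <- sample.int(lens[[cm]] - len, 1L) - 1L
      cand <- IRanges::IRanges(start + 1L, start + len)
      if (length(IRanges::findOverlaps(cand, occupied[[cm]])) == 0L) {
        occupied[[cm]] <- c(occupied[[cm]], cand)
        out[[i]] <- data.frame(chrom = cm, start = start,
                               end = start + len,
                               strand = sample(c("+", "-"), 1L),
                               feature_type = spec$feature_type[i],
                               stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done) {
      stopf("could not place %d features without overlap", nrow(spec))
    }
  }
  do.call(rbind, out)
}

#' Simulate a genome with gene and TE annotations
#'
#' Uniform i.i.d. A/C/G/T sequence over `n_chroms` autosomes, plus the
#' unmethylated spike-in chromosome appended; non-overlapping gene and TE
#' regions with random strands.
#'
#' @param config A [sim_config()].
#' @return List: `genome` ([Biostrings::DNAStringSet]) and `regions`
#'   (data.frame with `feature_type` `"gene"`/`"TE"`).
#' @export
simulate_genome <- function(config) {
  set.seed(sub_seed(config$seed, 11))
  per <- rep(config$genome_length %/% config$n_chroms, config$n_chroms)
  per[config$n_chroms] <- per[config$n_chroms] +
    config$genome_length %% config$n_chroms
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  seqs <- vapply(per, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  spike <- paste(sample(c("A", "C", "G", "T"), config$spikein_length,
                        replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(setNames(seqs, chroms),
                                       setNames(spike,
                                                config$spikein_chrom)))
  chrom_lens <- setNames(as.list(per), chroms)
  spec <- rbind(
    data.frame(len_min = config$gene_length[1L],
               len_max = config$gene_length[2L], feature_type = "gene"),
    data.frame(len_min = config$te_length[1L],
               len_max = config$te_length[2L], feature_type = "TE"))
  spec <- spec[rep(1:2, c(config$n_genes, config$n_tes)), , drop = FALSE]
  regions <- place_features(chrom_lens, spec)
  regions$feature_id <- character(nrow(regions))
  for (ft in c("gene", "TE")) {
    i <- regions$feature_type == ft
    regions$feature_id[i] <- sprintf("%s_%04d", ft, seq_len(sum(i)))
  }
  regions <- regions[order(regions$chrom, regions$start),
                     c("chrom", "start", "end", "strand", "feature_type",
                       "feature_id")]
  rownames(regions) <- NULL
  list(genome = genome, regions = regions)
}

## compartment (gene / TE / intergenic) of each site
site_compartment <- function(sites, regions) {
  comp <- rep("intergenic", nrow(sites))
  for (ft in c("gene", "TE")) {
    f <- regions[regions$feature_type == ft, , drop = FALSE]
    if (!nrow(f)) next
    gr_f <- GenomicRanges::GRanges(f$chrom,
                                   IRanges::IRanges(f$start + 1L, f$end))
    gr_s <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos + 1L,
                                                    width = 1L))
    hit <- GenomicRanges::countOverlaps(gr_s, gr_f) > 0L
    comp[hit] <- ft
  }
  comp
}

## true per-site levels for both conditions; shared Beta draw, condition B
## shifted inside planted DMRs
simulate_truth <- function(config, genome, regions) {
  set.seed(sub_seed(config$seed, 13))
  auto <- setdiff(names(genome), config$spikein_chrom)
  sites <- all_cytosines(genome, auto)
  comp <- site_compartment(sites, regions)
  mu <- config$base_levels[cbind(comp, sites$context)]
  conc <- config$level_dispersion[sites$context]
  eps <- 1e-6
  a <- pmax(mu, eps) * conc
  b <- pmax(1 - mu, eps) * conc
  lv <- rbeta(nrow(sites), a, b)
  ## degenerate means are exact, not Beta-jittered
  lv[mu == 0] <- 0
  lv[mu == 1] <- 1
  lv <- pmin(pmax(lv, 0), 1)
  sites$true_level_A <- lv
  sites$true_level_B <- lv
  sites$in_dmr <- FALSE
  warnings <- character()
  pd <- config$planted_dmrs
  if (!is.null(pd) && nrow(pd)) {
    pd$realized_A <- NA_real_
    pd$realized_B <- NA_real_
    pd$n_sites <- 0L
    for (i in seq_len(nrow(pd))) {
      sel <- sites$chrom == pd$chrom[i] & sites$pos >= pd$start[i] &
        sites$pos < pd$end[i] & sites$context == pd$context[i]
      if (!any(sel)) {
        warnings <- c(warnings, sprintf(
          "planted DMR %d (%s:%d-%d %s) contains no cytosine of its context",
          i, pd$chrom[i], pd$start[i], pd$end[i], pd$context[i]))
        next
      }
      sgn <- if (pd$direction[i] == "hyper") 1 else -1
      sites$true_level_B[sel] <- pmin(pmax(
        sites$true_level_A[sel] + sgn * pd$delta[i], 0), 1)
      sites$in_dmr[sel] <- TRUE
      pd$n_sites[i] <- sum(sel)
      pd$realized_A[i] <- mean(sites$true_level_A[sel])
      pd$realized_B[i] <- mean(sites$true_level_B[sel])
    }
  }
  ## spike-in: truly unmethylated everywhere
  sp <- all_cytosines(genome, config$spikein_chrom)
  sp$true_level_A <- 0
  sp$true_level_B <- 0
  sp$in_dmr <- FALSE
  list(sites = rbind(sites, sp), planted_dmrs = pd, warnings = warnings)
}

#' Simulate a two-condition methylome experiment
#'
#' Draws the shared per-site truth once, then samples per-condition read
#' counts.  `simulate_methylome()` returns one condition;
#' `simulate_methylome_pair()` returns both with the common manifest.
#'
#' @param config A [sim_config()].
#' @param genome,regions Output of [simulate_genome()].
#' @param condition `"A"` or `"B"` (planted DMRs are realised in B).
#' @param name Sample name (defaults to the condition letter).
#' @return `simulate_methylome()`: list `sample` ([methylome()]) and
#'   `manifest` (ground truth).  `simulate_methylome_pair()`: list
#'   `A`, `B`, `manifest`.
#' @export
simulate_methylome <- function(config, genome, regions,
                               condition = c("A", "B"), name = NULL) {
  condition <- match.arg(condition)
  truth <- simulate_truth(config, genome, regions)
  sample_reads(config, truth, condition,
               name %||% paste0("condition_", condition))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sample_reads <- function(config, truth, condition, name) {
  set.seed(sub_seed(config$seed, if (condition == "A") 21 else 22))
  st <- truth$sites
  lv <- if (condition == "A") st$true_level_A else st$true_level_B
  cov <- rpois(nrow(st), config$coverage_mean)
  p_obs <- lv * (1 - config$meth_error) + (1 - lv) * config$conversion_error
  n_meth <- rbinom(nrow(st), cov, p_obs)
  sites <- data.frame(chrom = st$chrom, pos = st$pos, strand = st$strand,
                      n_meth = n_meth, n_unmeth = cov - n_meth,
                      context = st$context, subcontext = st$subcontext,
                      stringsAsFactors = FALSE)
  manifest <- list(sites = st, planted_dmrs = truth$planted_dmrs,
                   conversion_error = config$conversion_error,
                   warnings = truth$warnings,
                   srna_bins = NULL, expression = NULL)
  class(manifest) <- "sim_manifest"
  list(sample = methylome(sites, name = name,
                          spikein_chrom = config$spikein_chrom),
       manifest = manifest)
}

#' @rdname simulate_methylome
#' @param names Length-2 sample names for the pair.
#' @export
simulate_methylome_pair <- function(config, genome, regions,
                                    names = c("condition_A",
                                              "condition_B")) {
  truth <- simulate_truth(config, genome, regions)
  a <- sample_reads(config, truth, "A", names[1L])
  b <- sample_reads(config, truth, "B", names[2L])
  list(A = a$sample, B = b$sample, manifest = a$manifest)
}

## mean true CHH level of 2-kb bins (condition A), used as sRNA intensity
srna_bin_truth <- function(config, genome, manifest, bin_size = 2000) {
  auto <- setdiff(names(genome), config$spikein_chrom)
  lens <- setNames(Biostrings::width(genome), names(genome))
  st <- manifest$sites
  st <- st[st$chrom %in% auto & st$context == "CHH", , drop = FALSE]
  out <- lapply(auto, function(cm) {
    bins <- tile_bins(lens[[cm]], bin_size)
    bins$chrom <- cm
    s <- st[st$chrom == cm, , drop = FALSE]
    b <- pmin(s$pos %/% bin_size + 1L, nrow(bins))
    mlv <- rep(NA_real_, nrow(bins))
    if (nrow(s)) {
      m <- rowsum(cbind(s$true_level_A, 1), b)
      mlv[as.integer(rownames(m))] <- m[, 1L] / m[, 2L]
    }
    bins$chh_level <- mlv
    bins[, c("chrom", "start", "end", "chh_level")]
  })
  do.call(rbind, out)
}

#' Simulate a small-RNA library coupled to CHH methylation
#'
#' 24-nt reads are drawn from 2-kb genomic bins with intensity
#' `base + slope * bin CHH level` (positions uniform within the bin, strand
#' random, sequence copied from the genome strand of origin); a
#' `1 - frac_24` fraction of 21-23-nt background reads is placed uniformly.
#' Identical draws collapse into one read with a copy count.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @param manifest Manifest from [simulate_methylome()] (per-site truth).
#' @return List: `reads` (data.frame `read_id`, `sequence`, `copies`) and
#'   `manifest` updated with the per-bin true intensity (`srna_bins`).
#' @export
simulate_srna <- function(config, genome, manifest) {
  set.seed(sub_seed(config$seed, 31))
  bins <- srna_bin_truth(config, genome, manifest)
  cp <- config$srna_coupling
  bins$intensity <- cp$base + cp$slope * ifelse(is.na(bins$chh_level), 0,
                                                bins$chh_level)
  n24 <- round(config$n_srna_reads * config$frac_24)
  nbg <- config$n_srna_reads - n24
  draw_from_bins <- function(n, len) {
    ok <- bins$end - bins$start > len
    idx <- sample.int(sum(ok), n, replace = TRUE,
                      prob = bins$intensity[ok])
    bsel <- which(ok)[idx]
    start <- bins$start[bsel] +
      floor(runif(n) * (bins$end[bsel] - bins$start[bsel] - len + 1))
    data.frame(chrom = bins$chrom[bsel], start = as.integer(start),
               strand = sample(c("+", "-"), n, replace = TRUE),
               length = len, stringsAsFactors = FALSE)
  }
  reads24 <- draw_from_bins(n24, 24L)
  bg <- NULL
  if (nbg > 0) {
    auto <- setdiff(names(genome), config$spikein_chrom)
    lens <- setNames(Biostrings::width(genome), names(genome))[auto]
    lenv <- sample(21:23, nbg, replace = TRUE)
    cm <- sample(auto, nbg, replace = TRUE, prob = lens / sum(lens))
    start <- floor(runif(nbg) * (lens[cm] - lenv))
    bg <- data.frame(chrom = cm, start = as.integer(start),
                     strand = sample(c("+", "-"), nbg, replace = TRUE),
                     length = lenv, stringsAsFactors = FALSE)
  }
  locs <- rbind(reads24, bg)
  seqs <- character(nrow(locs))
  for (cm in unique(locs$chrom)) {
    i <- which(locs$chrom == cm)
    s <- as.character(genome[[cm]])
    seqs[i] <- substring(s, locs$start[i] + 1L,
                         locs$start[i] + locs$length[i])
  }
  mins <- locs$strand == "-"
  seqs[mins] <- revcomp(seqs[mins])
  tab <- table(seqs)
  reads <- data.frame(
    read_id = sprintf("read_%d_x%d", seq_along(tab), as.vector(tab)),
    sequence = names(tab), copies = as.vector(tab),
    stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  manifest$srna_bins <- bins
  list(reads = reads, manifest = manifest)
}

#' Write a collapsed small-RNA FASTA
#'
#' Headers carry the copy count in the `read_<i>_x<count>` convention.
#'
#' @param reads data.frame with `read_id`, `sequence`, `copies`.
#' @param path Output path.
#' @export
write_srna_fasta <- function(reads, path) {
  writeLines(paste0(">", reads$read_id, "\n", reads$sequence), path)
  invisible(path)
}

#' Read a collapsed small-RNA FASTA
#'
#' Copy counts are parsed from a trailing `_x<count>` (or `_<count>` after
#' `x`) in the header; headers without one count as single reads.
#'
#' @param path Path to the FASTA.
#' @return data.frame with `read_id`, `sequence`, `copies`.
#' @export
read_srna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  m <- regmatches(ids, regexpr("_x[0-9]+$", ids))
  copies <- rep(1L, length(ids))
  has <- grepl("_x[0-9]+$", ids)
  copies[has] <- as.integer(sub("^_x", "", m))
  data.frame(read_id = ids, sequence = as.character(x), copies = copies,
             stringsAsFactors = FALSE)
}

#' Simulate gene expression anti-correlated with promoter methylation
#'
#' `log(1 + FPKM) = baseline - slope * promoter mCG + N(0, sd)`, truncated
#' at zero, where promoter mCG is the mean true CG level over the
#' strand-aware 2-kb promoter of each gene (condition A truth).
#'
#' @param config A [sim_config()].
#' @param regions Regions from [simulate_genome()] (genes are used).
#' @param manifest Manifest from [simulate_methylome()].
#' @param flank Promoter length in bases (default 2000).
#' @return List: `expression` (data.frame `gene_id`, `fpkm`) and `manifest`
#'   updated with per-gene truth (`expression`).
#' @export
simulate_expression <- function(config, regions, manifest, flank = 2000) {
  set.seed(sub_seed(config$seed, 41))
  genes <- regions[regions$feature_type == "gene", , drop = FALSE]
  if (!nrow(genes)) stopf("no genes in regions")
  st <- manifest$sites
  st <- st[st$context == "CG", , drop = FALSE]
  prom <- promoter_region(genes, flank)
  pm <- vapply(seq_len(nrow(genes)), function(i) {
    sel <- st$chrom == prom$chrom[i] & st$pos >= prom$start[i] &
      st$pos < prom$end[i]
    if (!any(sel)) return(NA_real_)
    mean(st$true_level_A[sel])
  }, numeric(1))
  pm[is.na(pm)] <- mean(pm, na.rm = TRUE)
  ec <- config$expression_coupling
  logf <- ec$baseline - ec$slope * pm + rnorm(nrow(genes), 0, ec$sd)
  fpkm <- pmax(0, expm1(logf))
  expression <- data.frame(gene_id = genes$feature_id, fpkm = fpkm,
                           stringsAsFactors = FALSE)
  manifest$expression <- data.frame(gene_id = genes$feature_id,
                                    promoter_mcg = pm, true_fpkm = fpkm,
                                    stringsAsFactors = FALSE)
  list(expression = expression, manifest = manifest)
}

#' Write and re-load a ground-truth manifest
#'
#' The manifest is serialised as JSON; `read_manifest()` restores it
#' losslessly (within double precision printed at full precision).
#'
#' @param manifest A manifest from the `simulate_*` functions.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, digits = NA, null = "null",
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @return `read_manifest()`: the manifest list.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("sites", "planted_dmrs", "srna_bins", "expression")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.data.frame(x[[nm]])
  }
  class(x) <- "sim_manifest"
  x
}

#' Simulate and write a complete toy dataset
#'
#' Runs the whole generator and writes genome FASTA, gene/TE/planted-DMR
#' BED, per-condition CX reports, sRNA FASTA, expression TSV and the
#' ground-truth manifest JSON into a directory.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  pair <- simulate_methylome_pair(config, gen$genome, gen$regions)
  sr <- simulate_srna(config, gen$genome, pair$manifest)
  ex <- simulate_expression(config, gen$regions, sr$manifest)
  p <- list(
    genome = file.path(outdir, "genome.fa"),
    genes = file.path(outdir, "genes.bed"),
    tes = file.path(outdir, "tes.bed"),
    cx_a = file.path(outdir, "condition_A.cx.tsv"),
    cx_b = file.path(outdir, "condition_B.cx.tsv"),
    srna = file.path(outdir, "srna.fa"),
    expression = file.path(outdir, "expression.tsv"),
    manifest = file.path(outdir, "manifest.json"))
  write_fasta(gen$genome, p$genome)
  write_bed(gen$regions[gen$regions$feature_type == "gene", ], p$genes)
  write_bed(gen$regions[gen$regions$feature_type == "TE", ], p$tes)
  if (!is.null(config$planted_dmrs)) {
    pd <- config$planted_dmrs
    pd$feature_id <- sprintf("dmr_%04d", seq_len(nrow(pd)))
    pd$strand <- "."
    write_bed(pd, file.path(outdir, "planted_dmrs.bed"))
    p$planted_dmrs <- file.path(outdir, "planted_dmrs.bed")
  }
  write_cx_report(pair$A$sites, p$cx_a)
  write_cx_report(pair$B$sites, p$cx_b)
  write_srna_fasta(sr$reads, p$srna)
  write_expression(ex$expression, p$expression)
  write_manifest(ex$manifest, p$manifest)
  invisible(list(paths = p, genome = gen$genome, regions = gen$regions,
                 A = pair$A, B = pair$B, reads = sr$reads,
                 expression = ex$expression, manifest = ex$manifest))
}
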