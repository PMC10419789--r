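cfg_small <- function(seed = 1, ...) {
  sim_config(seed = seed, genome_length = 30000, n_chroms = 2,
             n_genes = 5, n_tes = 5, spikein_length = 4000,
             n_srna_reads = 4000, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  g1 <- simulate_genome(cfg_small())
  g2 <- simulate_genome(cfg_small())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$regions, g2$regions)
  expect_false(identical(as.character(simulate_genome(cfg_small(2))$genome),
                         as.character(g1$genome)))
  m1 <- simulate_methylome(cfg_small(), g1$genome, g1$regions, "A")
  m2 <- simulate_methylome(cfg_small(), g1$genome, g1$regions, "A")
  expect_identical(m1$sample$sites, m2$sample$sites)
  s1 <- simulate_srna(cfg_small(), g1$genome, m1$manifest)
  s2 <- simulate_srna(cfg_small(), g1$genome, m1$manifest)
  expect_identical(s1$reads, s2$reads)
  e1 <- simulate_expression(cfg_small(), g1$regions, m1$manifest)
  e2 <- simulate_expression(cfg_small(), g1$regions, m1$manifest)
  expect_identical(e1$expression, e2$expression)
})

test_that("genome simulation places the requested features without overlap", {
  cfg <- cfg_small(3)
  gen <- simulate_genome(cfg)
  expect_identical(sum(gen$regions$feature_type == "gene"), 5L)
  expect_identical(sum(gen$regions$feature_type == "TE"), 5L)
  expect_true(cfg$spikein_chrom %in% names(gen$genome))
  by_chr <- split(gen$regions, gen$regions$chrom)
  for (r in by_chr) {
    r <- r[order(r$start), ]
    if (nrow(r) > 1L) expect_true(all(r$start[-1L] >= r$end[-nrow(r)]))
  }
  ## CG-site count close to the binomial expectation for uniform base draw
  cfgL <- sim_config(seed = 5, genome_length = 1e5, n_chroms = 1,
                     n_genes = 0, n_tes = 0, spikein_length = 1000)
  genL <- simulate_genome(cfgL)
  cs <- all_cytosines(genL$genome, "chr1")
  n_cg_pairs <- sum(cs$context == "CG") / 2   # one pair -> 2 strand sites
  n <- 1e5 - 1
  expect_lt(abs(n_cg_pairs - n / 16), 5 * sqrt(n * (1 / 16) * (15 / 16)))
})

test_that("read sampling follows the planted truth and noise model", {
  cfg <- cfg_small(7, conversion_error = 0)
  gen <- simulate_genome(cfg)
  ## degenerate noise: fully methylated truth gives all-methylated reads
  cfg1 <- cfg
  cfg1$base_levels[] <- 1
  cfg1$level_dispersion[] <- 1e6
  m <- simulate_methylome(cfg1, gen$genome, gen$regions, "A")
  auto <- m$sample$sites[m$sample$sites$chrom != "lambda", ]
  expect_true(all(auto$n_unmeth == 0L))        # no unmethylated calls
  ## spike-in recovers the conversion error within 3 binomial SE
  cfg2 <- sim_config(seed = 8, genome_length = 30000, n_chroms = 2,
                     n_genes = 5, n_tes = 5, conversion_error = 0.005,
                     spikein_length = 40000)
  gen2 <- simulate_genome(cfg2)
  m2 <- simulate_methylome(cfg2, gen2$genome, gen2$regions, "A")
  sp <- m2$sample$sites[m2$sample$sites$chrom == "lambda", ]
  ncalls <- sum(sp$n_meth + sp$n_unmeth)
  expect_gt(ncalls, 200000)
  frac <- sum(sp$n_meth) / ncalls
  se <- sqrt(0.005 * 0.995 / ncalls)
  expect_lt(abs(frac - 0.005), 3 * se)
  ## manifest covers every emitted site
  expect_identical(nrow(m2$manifest$sites), nrow(m2$sample$sites))
  expect_identical(site_key(m2$manifest$sites$chrom, m2$manifest$sites$pos,
                            m2$manifest$sites$strand),
                   site_key(m2$sample$sites$chrom, m2$sample$sites$pos,
                            m2$sample$sites$strand))
})

test_that("site levels track the manifest truth at deep coverage", {
  cfg <- sim_config(seed = 19, genome_length = 30000, n_chroms = 1,
                    n_genes = 5, n_tes = 5, spikein_length = 2000,
                    coverage_mean = 40)
  gen <- simulate_genome(cfg)
  m <- simulate_methylome(cfg, gen$genome, gen$regions, "A")
  s <- m$sample$sites
  truth <- m$manifest$sites$true_level_A
  tot <- s$n_meth + s$n_unmeth
  deep <- tot >= 30
  lv <- site_level(s$n_meth, s$n_unmeth)[deep]
  ## expected read fraction includes the conversion error
  p <- truth[deep] * 1 + (1 - truth[deep]) * cfg$conversion_error
  se <- sqrt(pmax(p * (1 - p), 1e-6) / tot[deep])
  within <- abs(lv - p) <= 3 * se
  ## where the normal band is valid (expected counts >= 5) coverage is
  ## near-complete; extreme p suffers binomial discreteness
  mid <- tot[deep] * p >= 5 & tot[deep] * (1 - p) >= 5
  expect_gt(mean(within[mid]), 0.99)
  expect_gt(mean(within), 0.97)
})

test_that("planted DMRs shift condition B only, warn when empty", {
  pd <- data.frame(chrom = "chr1", start = c(2000L, 9000L),
                   end = c(4000L, 10000L), context = c("CHH", "CG"),
                   delta = c(0.3, 0.4), direction = c("hyper", "hypo"))
  cfg <- cfg_small(9, planted_dmrs = pd)
  gen <- simulate_genome(cfg)
  pair <- simulate_methylome_pair(cfg, gen$genome, gen$regions)
  mt <- pair$manifest$sites
  in1 <- mt$chrom == "chr1" & mt$pos >= 2000 & mt$pos < 4000 &
    mt$context == "CHH"
  out <- !mt$in_dmr
  expect_true(all(mt$true_level_B[out] == mt$true_level_A[out]))
  expect_equal(mt$true_level_B[in1],
               pmin(1, mt$true_level_A[in1] + 0.3))
  realized <- pair$manifest$planted_dmrs
  expect_equal(realized$realized_B[1] - realized$realized_A[1], 0.3,
               tolerance = 0.02)
  expect_lt(realized$realized_B[2], realized$realized_A[2])
  ## a DMR whose region holds no cytosine of its context is flagged
  pd_empty <- data.frame(chrom = "lambda", start = 0L, end = 10L,
                         context = "CG", delta = 0.2,
                         direction = "hyper")
  cfg2 <- cfg_small(9, planted_dmrs = pd_empty)
  pair2 <- simulate_methylome_pair(cfg2, gen$genome, gen$regions)
  expect_match(pair2$manifest$warnings, "no cytosine")
})

test_that("sRNA and expression couplings are monotone by construction", {
  cfg <- cfg_small(11)
  gen <- simulate_genome(cfg)
  m <- simulate_methylome(cfg, gen$genome, gen$regions, "A")
  sr <- simulate_srna(cfg, gen$genome, m$manifest)
  bins <- sr$manifest$srna_bins
  ## intensity is a strictly increasing map of the bin CHH level
  expect_gt(cor(bins$intensity, bins$chh_level, method = "spearman",
                use = "complete.obs"), 0.9999)
  ## 24-nt majority
  ld <- length_distribution(sr$reads)
  expect_identical(ld$length[which.max(ld$count)], 24L)
  expect_equal(ld$fraction[ld$length == 24L], cfg$frac_24,
               tolerance = 0.02)
  ## noiseless expression coupling reverses the promoter-methylation order
  cfg0 <- cfg_small(11)
  cfg0$expression_coupling$sd <- 0
  cfg0$expression_coupling$slope <- 2       # keep all FPKM above zero
  ex <- simulate_expression(cfg0, gen$regions, m$manifest)
  tr <- ex$manifest$expression
  expect_identical(order(tr$true_fpkm), rev(order(tr$promoter_mcg)))
})

test_that("a written dataset round-trips through the package readers", {
  td <- withr::local_tempdir()
  cfg <- cfg_small(13)
  ds <- simulate_dataset(cfg, td)
  gen <- read_fasta(ds$paths$genome)
  expect_identical(as.character(gen), as.character(ds$genome))
  sites <- read_cx_report(ds$paths$cx_a, gen)   # validates vs genome
  expect_identical(nrow(sites), nrow(ds$A$sites))
  genes <- read_regions(ds$paths$genes, feature_type = "gene")
  expect_identical(genes$start,
                   ds$regions$start[ds$regions$feature_type == "gene"])
  reads <- read_srna_fasta(ds$paths$srna)
  expect_identical(sum(reads$copies), sum(ds$reads$copies))
  man <- read_manifest(ds$paths$manifest)
  expect_equal(man$conversion_error, cfg$conversion_error)
  expect_equal(nrow(man$sites), nrow(ds$manifest$sites))
  expect_equal(man$sites$true_level_A, ds$manifest$sites$true_level_A)
})
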