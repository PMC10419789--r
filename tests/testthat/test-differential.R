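test_that("the exact test reproduces enumerable two-sided p-values", {
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(4, 0, 0, 4), 2 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  ## all-zero margins fall back to p = 1
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  ## agreement with the reference implementation on random tables
  set.seed(10)
  a <- rpois(300, 6); b <- rpois(300, 6)
  cc <- rpois(300, 6); d <- rpois(300, 6)
  ours <- fisher_exact_2x2(a, b, cc, d)
  ref <- mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
  }, a, b, cc, d)
  expect_equal(ours, unname(ref), tolerance = 1e-9)
  expect_error(fisher_exact_2x2(-1, 0, 0, 0), "negative")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.026667, 0.04), tolerance = 1e-4)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("DMC calling applies both the FDR and the delta rule", {
  gen <- rand_genome(500, seed = 71)
  cs <- all_cytosines(gen)
  ## single tested site: the fisher example
  t1 <- sites_methylome(gen, cs$chrom[1], cs$pos[1], cs$strand[1], 10L, 0L)
  r1 <- sites_methylome(gen, cs$chrom[1], cs$pos[1], cs$strand[1], 0L, 10L)
  d <- call_dmcs(t1, r1, cs$context[1])
  expect_identical(nrow(d), 1L)
  expect_equal(d$q, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(d$delta, 1)
  expect_identical(d$direction, "hyper")
  ## identical samples: no DMC
  expect_identical(nrow(call_dmcs(t1, t1, cs$context[1])), 0L)
  ## anti-symmetry: swapping samples flips direction, keeps p
  cs$n_meth <- rbinom(nrow(cs), 12, 0.5)
  cs$n_unmeth <- 12L - cs$n_meth
  cs2 <- cs
  cs2$n_meth <- rbinom(nrow(cs), 12, 0.2)
  cs2$n_unmeth <- 12L - cs2$n_meth
  ma <- methylome(cs); mb <- methylome(cs2)
  fwd <- call_dmcs(ma, mb, "CHH", fdr = 0.5, min_delta = 0.1)
  rev <- call_dmcs(mb, ma, "CHH", fdr = 0.5, min_delta = 0.1)
  expect_identical(nrow(fwd), nrow(rev))
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$delta, -rev$delta)
  expect_identical(fwd$direction,
                   ifelse(rev$direction == "hyper", "hypo", "hyper"))
  ## a site must be covered in BOTH samples to be tested
  low <- cs
  low$n_meth <- 1L; low$n_unmeth <- 1L
  expect_identical(attr(call_dmcs(methylome(low), mb, "CHH"), "n_tested"),
                   0L)
})

test_that("DMR calling enforces per-context delta thresholds", {
  ## build one 1-kb bin with exactly controlled pooled levels
  gen <- rand_genome(1200, seed = 72)
  cs <- all_cytosines(gen)
  chh <- cs[cs$context == "CHH" & cs$pos < 1000, ][1:10, ]
  mk <- function(level) {
    n <- nrow(chh)
    methylome(transform(chh, n_meth = as.integer(round(20 * level)),
                        n_unmeth = as.integer(20 - round(20 * level))))
  }
  ## CHH: |delta| = 0.25 >= 0.1 -> DMR
  d_chh <- call_dmrs(mk(0.05), mk(0.30), "CHH", min_sites = 4)
  expect_identical(nrow(d_chh), 1L)
  expect_identical(d_chh$direction, "hypo")
  expect_identical(d_chh$n_sites, 10L)
  expect_identical(d_chh$end - d_chh$start, 1000L)
  ## same counts relabelled CG: 0.25 >= 0.2 still emitted
  cg <- transform(chh, context = "CG")
  mk_cg <- function(level) {
    methylome(transform(cg, n_meth = as.integer(round(20 * level)),
                        n_unmeth = as.integer(20 - round(20 * level))))
  }
  expect_identical(nrow(call_dmrs(mk_cg(0.05), mk_cg(0.30), "CG")), 1L)
  ## CG delta 0.15 < 0.2 -> rejected even at tiny q
  expect_identical(nrow(call_dmrs(mk_cg(0.05), mk_cg(0.20), "CG")), 0L)
  ## but the same 0.15 passes as CHG (threshold 0.15)
  chg <- transform(chh, context = "CHG")
  mk_chg <- function(level) {
    methylome(transform(chg, n_meth = as.integer(round(20 * level)),
                        n_unmeth = as.integer(20 - round(20 * level))))
  }
  expect_identical(nrow(call_dmrs(mk_chg(0.05), mk_chg(0.20), "CHG")), 1L)
  ## min_sites gate
  few <- chh[1:3, ]
  m1 <- methylome(transform(few, n_meth = 20L, n_unmeth = 0L))
  m2 <- methylome(transform(few, n_meth = 0L, n_unmeth = 20L))
  expect_identical(nrow(call_dmrs(m1, m2, "CHH")), 0L)
})

test_that("planted DMRs are recovered with matching direction", {
  pd <- data.frame(chrom = "chr1",
                   start = c(2000L, 6000L), end = c(3000L, 7000L),
                   context = "CHH", delta = 0.3,
                   direction = c("hyper", "hypo"))
  ## hypo needs headroom: raise the intergenic CHH base level
  bl <- rbind(gene = c(0.35, 0.10, 0.40), TE = c(0.85, 0.65, 0.40),
              intergenic = c(0.50, 0.30, 0.40))
  colnames(bl) <- c("CG", "CHG", "CHH")
  cfg <- sim_config(seed = 73, genome_length = 20000, n_chroms = 1,
                    n_genes = 3, n_tes = 3, spikein_length = 2000,
                    base_levels = bl, planted_dmrs = pd)
  gen <- simulate_genome(cfg)
  pair <- simulate_methylome_pair(cfg, gen$genome, gen$regions)
  dmr <- call_dmrs(pair$B, pair$A, "CHH")
  hit_hyper <- dmr[dmr$start == 2000, ]
  hit_hypo <- dmr[dmr$start == 6000, ]
  expect_identical(hit_hyper$direction, "hyper")
  expect_identical(hit_hypo$direction, "hypo")
  ## every emitted record obeys its thresholds (post-hoc audit)
  expect_true(all(abs(dmr$delta) >= 0.1 & dmr$q < 0.01))
})

test_that("DMR-to-gene assignment is strand-aware over three regions", {
  genes <- data.frame(chrom = "chr1", start = 5000L, end = 8000L,
                      strand = "+", feature_type = "gene",
                      feature_id = "g1")
  dmr <- function(s, e) {
    data.frame(chrom = "chr1", start = s, end = e, context = "CHH",
               n_sites = 5L, meth_test = 1L, unmeth_test = 9L,
               meth_ref = 5L, unmeth_ref = 5L, level_test = 0.1,
               level_ref = 0.5, delta = -0.4, p = 1e-6, q = 1e-5,
               direction = "hypo", stringsAsFactors = FALSE)
  }
  a1 <- assign_dmrs_to_genes(dmr(2500L, 3100L), genes)
  expect_identical(a1$region, "promoter")    # overlap [3000, 3100)
  genes_m <- genes
  genes_m$strand <- "-"
  a2 <- assign_dmrs_to_genes(dmr(8100L, 8900L), genes_m)
  expect_identical(a2$region, "promoter")    # minus-strand promoter is 3'
  a3 <- assign_dmrs_to_genes(dmr(4900L, 5900L), genes)
  expect_setequal(a3$region, c("promoter", "body"))
  expect_identical(nrow(a3), 2L)
  ## no overlap -> no assignment
  expect_identical(nrow(assign_dmrs_to_genes(dmr(100L, 200L), genes)), 0L)
})

test_that("term enrichment is the hypergeometric upper tail", {
  g2t <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1")
  universe <- paste0("g", 1:10)
  e <- term_enrichment(paste0("g", 1:3), universe, g2t)
  expect_equal(e$p, choose(5, 3) / choose(10, 3), tolerance = 1e-12)
  expect_identical(e$k, 3L)
  ## selected = universe: conditional tail is always 1
  e2 <- term_enrichment(universe, universe, g2t)
  expect_equal(e2$p, 1)
  ## k = 0 can never be enriched
  e3 <- term_enrichment(paste0("g", 6:8), universe, g2t)
  expect_gte(e3$p, 0.5)
  expect_false(e3$enriched)
  ## unknown selected genes are refused
  expect_error(term_enrichment("gX", universe, g2t), "subset")
})
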