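test_that("length distribution weights by copy count", {
  reads <- data.frame(read_id = c("a_x2", "b_x8"),
                      sequence = c(strrep("A", 21), strrep("G", 24)),
                      copies = c(2L, 8L))
  ld <- length_distribution(reads)
  expect_equal(ld$fraction[ld$length == 21], 0.2)
  expect_equal(ld$fraction[ld$length == 24], 0.8)
  expect_equal(sum(ld$fraction), 1)
  expect_identical(nrow(length_distribution(reads[0, ])), 0L)
})

test_that("exact mapping keeps only unique placements, both strands", {
  gen <- tiny_genome(chr1 = "AAACCCGGGTTTACGTACGTAGCTAGCTGATC",
                     chr2 = "TTTTGGGGCCCCAAAAATATATATGCGCGCGC")
  uniq_plus <- "CCCGGGTTTACG"              # once, plus strand of chr1
  uniq_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGGTTTACGTAC")))
  multi <- "ACGTACGT"                      # overlapping occurrences
  absent <- "CCCCCCCCCCCC"
  reads <- data.frame(read_id = paste0("r", 1:4),
                      sequence = c(uniq_plus, uniq_minus, multi, absent),
                      copies = c(1L, 2L, 1L, 1L))
  aln <- map_exact_unique(reads, gen)
  expect_identical(aln$read_id, c("r1", "r2"))
  expect_identical(aln$strand, c("+", "-"))
  expect_identical(aln$chrom, c("chr1", "chr1"))
  expect_identical(aln$start, c(3L, 6L))
  expect_identical(attr(aln, "n_unmapped"), 1L)
  expect_identical(attr(aln, "n_multi"), 1L)
})

test_that("exact mapping agrees with a naive substring-search oracle", {
  set.seed(81)
  for (rep in 1:6) {
    gen <- rand_genome(20000, seed = 81 + rep)
    gs <- list(chr1 = as.character(gen[[1L]]))
    reads <- character(60)
    for (i in 1:60) {
      kind <- sample(c("fwd", "rc", "random"), 1)
      w <- sample(18:24, 1)
      s <- sample.int(20000 - w, 1)
      sq <- substr(gs$chr1, s, s + w - 1L)
      if (kind == "rc") {
        sq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sq)))
      } else if (kind == "random") {
        sq <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                    collapse = "")
      }
      reads[i] <- sq
    }
    reads <- unique(reads)
    rdf <- data.frame(read_id = paste0("r", seq_along(reads)),
                      sequence = reads, copies = 1L)
    aln <- map_exact_unique(rdf, gen)
    for (i in seq_along(reads)) {
      occ <- oracle_occurrences(reads[i], gs)
      hit <- aln[aln$read_id == rdf$read_id[i], ]
      if (nrow(occ) == 1L) {
        expect_identical(nrow(hit), 1L)
        expect_identical(hit$start, occ$start)
        expect_identical(hit$strand, occ$strand)
      } else {
        expect_identical(nrow(hit), 0L)
      }
    }
  }
})

test_that("positional association counts sense and antisense mC separately", {
  ## plant one 24-nt read over a region whose sense-strand Cs are all mC
  gen <- tiny_genome(chr1 = paste0(strrep("A", 30),
                                   "AATCAAATTCAAAAAAAAAAAAAA",
                                   strrep("A", 30)))
  read <- data.frame(read_id = "r1_x1",
                     sequence = "AATCAAATTCAAAAAAAAAAAAAA", copies = 1L)
  aln <- map_exact_unique(read, gen)
  expect_identical(nrow(aln), 1L)
  cs <- all_cytosines(gen)
  cs$n_meth <- 10L
  cs$n_unmeth <- 0L
  m <- methylome(cs)
  pa <- positional_association(aln, m, mc_calls = call_mc(m, error_rate = 0.005),
                               genome = gen)
  expect_identical(nrow(pa), 44L)
  expect_identical(pa$position, -10:33)
  ## read has C at read positions 4 and 10 (1-based) -> indices 3 and 9
  expect_identical(pa$mc[pa$position %in% c(3L, 9L)], c(1L, 1L))
  expect_identical(sum(pa$mc[pa$position >= 0 & pa$position < 24]), 2L)
  expect_equal(pa$freq_c[pa$position == 3], 1)
  expect_equal(pa$freq_a[pa$position == 0], 1)
  ## antisense: Gs in the read sit over minus-strand Cs
  expect_identical(sum(pa$mc_star[pa$position >= 0 & pa$position < 24]),
                   0L)                      # the read has no G
  ## no mC anywhere -> zero vectors
  cs0 <- cs
  cs0$n_meth <- 0L
  cs0$n_unmeth <- 10L
  m0 <- methylome(cs0)
  pa0 <- positional_association(aln, m0,
                                mc_calls = call_mc(m0, error_rate = 0.005),
                                genome = gen)
  expect_true(all(pa0$mc == 0L) && all(pa0$mc_star == 0L))
})

test_that("binned sRNA-methylation correlation handles signs and RPM", {
  gen <- rand_genome(30000, seed = 91)
  cs <- all_cytosines(gen)
  ## methylation level increasing along the chromosome
  cs$n_meth <- as.integer(round(19 * cs$pos / 30000)) + 1L
  cs$n_unmeth <- 20L - cs$n_meth
  m <- methylome(cs)
  mk_aln <- function(counts) {
    starts <- as.integer(seq(500, 29000, length.out = length(counts)))
    data.frame(read_id = paste0("r", seq_along(counts)), chrom = "chr1",
               start = starts, strand = "+", length = 24L,
               sequence = "N", copies = as.integer(counts))
  }
  up <- binned_srna_methylation_correlation(mk_aln(1:15), m, "CHH",
                                            genome = gen)
  expect_gt(up$rho, 0.9)
  down <- binned_srna_methylation_correlation(mk_aln(15:1), m, "CHH",
                                              genome = gen)
  expect_lt(down$rho, -0.9)
  ## RPM is invariant to duplicating the library composition
  a1 <- mk_aln(1:15)
  a2 <- a1
  a2$copies <- a2$copies * 2L
  r1 <- binned_srna_methylation_correlation(a1, m, "CHH", genome = gen)
  r2 <- binned_srna_methylation_correlation(a2, m, "CHH", genome = gen)
  expect_equal(r1$bins$rpm, r2$bins$rpm)
  expect_error(binned_srna_methylation_correlation(a1[1, ], m, "CHH",
                                                   bin_size = 30000,
                                                   genome = gen),
               "fewer than 3")
})

test_that("sRNA metaprofiles concentrate where the reads are", {
  gen <- rand_genome(20000, seed = 92)
  tes <- data.frame(chrom = "chr1", start = c(4000L, 12000L),
                    end = c(6000L, 14000L), strand = c("+", "-"),
                    feature_type = "TE", feature_id = c("t1", "t2"))
  set.seed(3)
  inside <- data.frame(read_id = paste0("i", 1:40), chrom = "chr1",
                       start = c(sample(4000:5950, 20, TRUE),
                                 sample(12000:13950, 20, TRUE)),
                       strand = "+", length = 24L, sequence = "N",
                       copies = 1L)
  mp <- srna_metaprofile(inside, tes)
  body <- mp$mean_rpm_per_kb[mp$region == "body"]
  flank <- mp$mean_rpm_per_kb[mp$region != "body"]
  expect_gt(mean(body), mean(flank))
  expect_identical(nrow(mp), 60L)
  ## zero reads -> all-zero profile
  mp0 <- srna_metaprofile(inside[0, ], tes, total_mapped = 1)
  expect_true(all(mp0$mean_rpm_per_kb == 0))
})
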