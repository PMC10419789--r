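## Shared fixture builders: everything is generated in code at test time.

tiny_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

rand_genome <- function(len, chroms = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_along(chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, chroms))
}

## methylome with every cytosine at the same (n_meth, n_unmeth)
uniform_methylome <- function(genome, n_meth, n_unmeth, name = "uniform",
                              spikein_chrom = NULL) {
  sites <- all_cytosines(genome)
  sites$n_meth <- n_meth
  sites$n_unmeth <- n_unmeth
  methylome(sites, name = name, spikein_chrom = spikein_chrom)
}

## methylome from an explicit site table (context filled from genome)
sites_methylome <- function(genome, chrom, pos, strand, n_meth, n_unmeth,
                            name = "manual", spikein_chrom = NULL) {
  cls <- classify_context(genome, chrom, pos, strand)
  methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       n_meth = n_meth, n_unmeth = n_unmeth,
                       context = cls$context, subcontext = cls$subcontext,
                       stringsAsFactors = FALSE),
            name = name, spikein_chrom = spikein_chrom)
}

## independent regex-based context scan (oracle for classify_context):
## look-ahead matches on the forward string and on the reverse complement,
## minus-strand positions mapped back to plus coordinates
oracle_contexts <- function(seq_string) {
  L <- nchar(seq_string)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_string)))
  scan <- function(s, pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  ## a site needs its full trinucleotide: two bases after the C
  pats <- c(CG = "(?=CG[ACGT])", CHG = "(?=C[ACT]G)",
            CHH = "(?=C[ACT][ACT])")
  out <- list()
  for (ctx in names(pats)) {
    fwd <- scan(seq_string, pats[[ctx]])
    rev <- scan(rc, pats[[ctx]])
    out[[ctx]] <- rbind(
      if (length(fwd)) data.frame(pos = fwd, strand = "+", context = ctx),
      if (length(rev)) data.frame(pos = L - 1L - rev, strand = "-",
                                  context = ctx))
  }
  res <- do.call(rbind, out)
  res[order(res$pos, res$strand), ]
}

## naive exact-occurrence counter (oracle for map_exact_unique): perl
## look-ahead so overlapping matches count
oracle_occurrences <- function(read, genome_strings) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  hits <- list()
  for (cm in names(genome_strings)) {
    s <- genome_strings[[cm]]
    for (q in unique(c(read, rc))) {
      m <- gregexpr(paste0("(?=", q, ")"), s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      strands <- if (q == read && q == rc) c("+", "-")
        else if (q == read) "+" else "-"
      for (std in strands) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = cm, start = as.integer(m) - 1L, strand = std,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character()))
  }
  do.call(rbind, hits)
}

## reference step-up FDR (oracle for bh_adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

## exhaustive two-sided Fisher p from first principles (choose(), no dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  dens <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}
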