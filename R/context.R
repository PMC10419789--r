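## Cytosine sequence-context classification.
##
## Plant methylomes are described in three sequence contexts determined by
## the two bases 3' of a cytosine on its own strand: CG, CHG and CHH
## (H = A, C or T).  The sub-context is the full trinucleotide starting at
## the cytosine.  Classification near chromosome ends or over N bases is
## undefined and yields NA.

## Split one chromosome into a character vector once; callers reuse it.
chrom_chars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stopf("unknown chromosome '%s'", chrom)
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
}

## Vectorised classification given the plus-strand character vector of one
## chromosome.  `pos` is 0-based; strand "+" requires base C at pos, strand
## "-" requires base G (a cytosine on the reverse strand).
classify_from_chars <- function(v, pos, strand) {
  n <- length(pos)
  L <- length(v)
  base <- v[pos + 1L]
  ok <- (strand == "+" & base == "C") | (strand == "-" & base == "G")
  if (any(!ok)) {
    bad <- which(!ok)[1L]
    stopf("position %d (%s strand) is not a cytosine (plus-strand base '%s')",
          pos[bad], strand[bad], base[bad])
  }
  nxt <- rep(NA_character_, n)
  nxt2 <- rep(NA_character_, n)
  plus <- strand == "+"
  i1 <- pos + 2L; i2 <- pos + 3L              # 1-based indices of next bases
  nxt[plus] <- ifelse(i1[plus] <= L, v[pmin(i1[plus], L)], NA_character_)
  nxt2[plus] <- ifelse(i2[plus] <= L, v[pmin(i2[plus], L)], NA_character_)
  j1 <- pos; j2 <- pos - 1L                    # 1-based indices on minus side
  nxt[!plus] <- ifelse(j1[!plus] >= 1L, comp_base(v[pmax(j1[!plus], 1L)]),
                       NA_character_)
  nxt2[!plus] <- ifelse(j2[!plus] >= 1L, comp_base(v[pmax(j2[!plus], 1L)]),
                        NA_character_)
  undef <- is.na(nxt) | is.na(nxt2) | nxt == "N" | nxt2 == "N"
  context <- ifelse(undef, NA_character_,
             ifelse(nxt == "G", "CG",
             ifelse(nxt2 == "G", "CHG", "CHH")))
  subcontext <- ifelse(undef, NA_character_, paste0("C", nxt, nxt2))
  list(context = context, subcontext = subcontext)
}

#' Classify the sequence context of cytosines
#'
#' Reads the two bases 3' of each cytosine in strand orientation and assigns
#' the CG / CHG / CHH context together with the strand-oriented trinucleotide
#' sub-context starting at the cytosine.  Within two bases of a chromosome
#' end, or when any of the three bases is N, both values are `NA`.
#'
#' @param genome A [Biostrings::DNAStringSet] as returned by [read_fasta()].
#' @param chrom,pos,strand Parallel vectors: chromosome name, 0-based
#'   position of the cytosine, and strand (`"+"` or `"-"`).  On the minus
#'   strand the plus-strand base at `pos` must be G.
#' @return A data.frame with columns `context` (`"CG"`, `"CHG"`, `"CHH"` or
#'   `NA`) and `subcontext` (trinucleotide or `NA`).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTA"))
#' classify_context(g, "chr1", 1, "+")   # CG, "CGT"
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  if (any(pos < 0L | pos >= lens[chrom])) {
    stopf("position outside chromosome bounds")
  }
  context <- character(n)
  subcontext <- character(n)
  for (cm in unique(chrom)) {
    idx <- which(chrom == cm)
    v <- chrom_chars(genome, cm)
    cls <- classify_from_chars(v, pos[idx], strand[idx])
    context[idx] <- cls$context
    subcontext[idx] <- cls$subcontext
  }
  data.frame(context = context, subcontext = subcontext,
             stringsAsFactors = FALSE)
}

#' Enumerate all cytosines of a genome with their contexts
#'
#' Scans both strands of every chromosome and returns one row per cytosine
#' (plus-strand C, and plus-strand G for reverse-strand cytosines).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chroms Optional subset of chromosome names.
#' @param drop_undefined Drop sites whose context is undefined (chromosome
#'   ends, N bases).  Default `TRUE`.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `subcontext`, ordered by chromosome then position.
#' @export
all_cytosines <- function(genome, chroms = names(genome),
                          drop_undefined = TRUE) {
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    cm <- chroms[[k]]
    v <- chrom_chars(genome, cm)
    pos_p <- which(v == "C") - 1L
    pos_m <- which(v == "G") - 1L
    pos <- c(pos_p, pos_m)
    strand <- rep(c("+", "-"), c(length(pos_p), length(pos_m)))
    o <- order(pos, strand)
    pos <- pos[o]; strand <- strand[o]
    cls <- classify_from_chars(v, pos, strand)
    df <- data.frame(chrom = rep(cm, length(pos)), pos = pos,
                     strand = strand, context = cls$context,
                     subcontext = cls$subcontext, stringsAsFactors = FALSE)
    if (drop_undefined) df <- df[!is.na(df$context), , drop = FALSE]
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The trinucleotide sub-contexts of each methylation context
#'
#' @return Named list: four CG, three CHG and nine CHH trinucleotides.
#' @export
subcontext_sets <- function() {
  H <- c("A", "C", "T")
  list(CG = paste0("C", "G", c("A", "C", "G", "T")),
       CHG = paste0("C", H, "G"),
       CHH = as.vector(outer(H, H, function(a, b) paste0("C", a, b))))
}
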