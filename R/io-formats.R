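## Readers and writers for the external formats the pipeline touches.
##
## Coordinate convention: everything inside the package is 0-based
## half-open.  Only these I/O routines convert: CX reports and GFF3 are
## 1-based on disk, BED and bedGraph are already 0-based half-open.

#' Read a genome FASTA file
#'
#' Sequences are uppercased; soft-masked (lowercase) stretches are recorded
#' as an [IRanges::IRangesList] in `S4Vectors::metadata(x)$softmask`.
#' Duplicate headers and non-IUPAC characters are rejected; ambiguity codes
#' other than N are refused rather than coerced.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet], one element per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stopf("duplicate FASTA header: %s", nm[duplicated(nm)][1L])
  }
  names(x) <- nm
  chars <- as.character(x)
  mask <- IRanges::IRangesList(lapply(chars, function(s) {
    r <- gregexpr("[acgtn]+", s)[[1L]]
    if (r[1L] == -1L) IRanges::IRanges()
    else IRanges::IRanges(start = as.integer(r),
                          width = attr(r, "match.length"))
  }))
  up <- toupper(chars)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stopf("chromosome '%s': unsupported character '%s' at base %d",
          nm[i], substr(up[i], bad[i], bad[i]), bad[i])
  }
  out <- Biostrings::DNAStringSet(up)
  names(out) <- nm
  S4Vectors::metadata(out)$softmask <- mask
  out
}

#' Write a genome FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Read a per-cytosine methylation count report
#'
#' Consumes the tab-separated per-cytosine report emitted by bisulfite
#' methylation extractors (one row per cytosine: chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide).  Reports covering every cytosine (including zero-coverage
#' rows) and reports restricted to covered sites are both accepted; absent
#' sites are never inferred.
#'
#' @param path Path to the report (plain or gzip).
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, each
#'   record's context and trinucleotide are cross-checked against the
#'   genome and disagreements raise a validation error.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `n_meth`, `n_unmeth`, `context`, `subcontext`, in file order.
#' @export
read_cx_report <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, quote = "",
               comment.char = "",
               colClasses = c("character", "integer", "character",
                              "integer", "integer", "character",
                              "character")),
    error = function(e) {
      n <- length(readLines(path))
      if (n == 0L) return(NULL)
      stopf("malformed CX report %s: %s", path, conditionMessage(e))
    })
  cols <- c("chrom", "pos", "strand", "n_meth", "n_unmeth",
            "context", "subcontext")
  if (is.null(df)) {
    df <- data.frame(chrom = character(), pos = integer(),
                     strand = character(), n_meth = integer(),
                     n_unmeth = integer(), context = character(),
                     subcontext = character(), stringsAsFactors = FALSE)
    return(df)
  }
  names(df) <- cols
  df$pos <- df$pos - 1L                       # 1-based on disk -> 0-based
  if (any(df$n_meth < 0L | df$n_unmeth < 0L)) {
    stopf("CX record %d: negative count",
          which(df$n_meth < 0L | df$n_unmeth < 0L)[1L])
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stopf("CX record %d: invalid strand",
          which(!df$strand %in% c("+", "-"))[1L])
  }
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    if (!all(df$chrom %in% names(genome))) {
      stopf("CX record %d: unknown chromosome '%s'",
            which(!df$chrom %in% names(genome))[1L],
            df$chrom[!df$chrom %in% names(genome)][1L])
    }
    off <- df$pos < 0L | df$pos >= lens[df$chrom]
    if (any(off)) stopf("CX record %d: position off chromosome",
                        which(off)[1L])
    cls <- classify_context(genome, df$chrom, df$pos, df$strand)
    mism <- !is.na(cls$context) & !is.na(df$context) &
      df$context != "NA" & cls$context != df$context
    if (any(mism)) {
      i <- which(mism)[1L]
      stopf("CX record %d: context '%s' disagrees with genome ('%s')",
            i, df$context[i], cls$context[i])
    }
  }
  df$context[df$context == "NA"] <- NA_character_
  df$subcontext[df$subcontext == "NA"] <- NA_character_
  df
}

#' Write a per-cytosine methylation count report
#'
#' Inverse of [read_cx_report()]: positions are written 1-based, `NA`
#' context/trinucleotide as the literal string `"NA"`.
#'
#' @param sites data.frame as returned by [read_cx_report()].
#' @param path Output path (a `.gz` suffix gzips transparently).
#' @export
write_cx_report <- function(sites, path) {
  out <- data.frame(sites$chrom, sites$pos + 1L, sites$strand,
                    sites$n_meth, sites$n_unmeth,
                    ifelse(is.na(sites$context), "NA", sites$context),
                    ifelse(is.na(sites$subcontext), "NA", sites$subcontext))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic feature annotations from BED6 or GFF3
#'
#' All coordinates are normalised to the package's 0-based half-open
#' convention.  For GFF3 the feature `type` column and `ID` attribute map to
#' `feature_type` / `feature_id`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` or `"gff3"`; default guessed from the extension.
#' @param feature_type Optional value overriding/filling the feature type
#'   (e.g. `"gene"` or `"TE"` for a plain BED track).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `feature_type`, `feature_id`.
#' @export
read_regions <- function(path, dialect = c("auto", "bed", "gff3"),
                         feature_type = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path,
                            format = if (dialect == "bed") "BED" else "GFF3")
  n <- length(gr)
  ftype <- if (!is.null(feature_type)) rep(feature_type, n)
    else if (dialect == "gff3") as.character(gr$type)
    else rep("other", n)
  fid <- if (dialect == "gff3" && !is.null(gr$ID)) as.character(gr$ID)
    else if (!is.null(gr$name)) as.character(gr$name)
    else sprintf("feature_%06d", seq_len(n))
  fid[is.na(fid)] <- sprintf("feature_%06d", which(is.na(fid)))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = ftype, feature_id = fid, stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  if (any(out$start >= out$end)) {
    stopf("region %d: start >= end after normalisation",
          which(out$start >= out$end)[1L])
  }
  out
}

#' Write regions as BED6
#'
#' @param regions data.frame as from [read_regions()].
#' @param path Output path.
#' @param score Optional numeric score vector (default 0).
#' @export
write_bed <- function(regions, path, score = NULL) {
  if (is.null(score)) score <- rep(0, nrow(regions))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   regions$chrom, regions$start, regions$end,
                   regions$feature_id, format(score, trim = TRUE),
                   ifelse(regions$strand %in% c("+", "-"),
                          regions$strand, "."))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-bin value track as bedGraph
#'
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open bins).
#' @param path Output path.
#' @param sort_bins Sort bins before writing (`TRUE`, default) or raise an
#'   error on unsorted input (`FALSE`).
#' @export
write_bedgraph <- function(track, path, sort_bins = TRUE) {
  o <- order(track$chrom, track$start)
  if (!identical(o, seq_len(nrow(track)))) {
    if (!sort_bins) stopf("bins are not sorted")
    track <- track[o, , drop = FALSE]
  }
  by_chr <- split(track, track$chrom)
  for (tr in by_chr) {
    if (nrow(tr) > 1L && any(tr$start[-1L] < tr$end[-nrow(tr)])) {
      stopf("overlapping bins on %s", tr$chrom[1L])
    }
  }
  keep <- !is.na(track$value)
  lines <- c("track type=bedGraph",
             sprintf("%s\t%d\t%d\t%.6f", track$chrom[keep],
                     track$start[keep], track$end[keep], track$value[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path Path to a bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' Read a gene expression table
#'
#' Two tab-separated columns, `gene_id` and `fpkm`; a header line is
#' detected and skipped.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `gene_id`, `fpkm`.
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1L, 2L])))) {
    df <- df[-1L, , drop = FALSE]
  }
  out <- data.frame(gene_id = df[[1L]], fpkm = as.numeric(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$fpkm)) || any(out$fpkm < 0)) {
    stopf("expression table %s: FPKM must be non-negative numbers", path)
  }
  out
}

#' Write a gene expression table
#' @param expression data.frame with `gene_id`, `fpkm`.
#' @param path Output path.
#' @export
write_expression <- function(expression, path) {
  write.table(expression[, c("gene_id", "fpkm")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a flat gene-to-term annotation map
#'
#' Two tab-separated columns, `gene_id` and `term_id`; one row per
#' annotation.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
read_gene2term <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   colClasses = c("character", "character"))
  if (nrow(df) && identical(tolower(df[1L, 1L]), "gene_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  data.frame(gene_id = df[[1L]], term_id = df[[2L]],
             stringsAsFactors = FALSE)
}

#' Write a generic TSV with header
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
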