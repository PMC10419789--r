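## Configuration-driven end-to-end orchestration.
##
## A YAML config declares the genome, per-sample cytosine reports, optional
## annotations, expression table, sRNA library and gene-to-term map, the
## comparisons to run and the threshold block.  Every stage writes plain
## tab-separated (or bedGraph) intermediates into a fixed directory layout
## so any reported number can be recomputed from files; stages whose inputs
## are absent are skipped with a log notice.

default_thresholds <- function() {
  list(min_coverage = 4, mc_fdr = 0.05, dmc_fdr = 0.05,
       dmc_min_delta = 0.2, dmr_fdr = 0.01,
       dmr_min_delta = c(CG = 0.2, CHG = 0.15, CHH = 0.1),
       dmr_bin_size = 1000, dmr_min_sites = 4, flank = 2000,
       srna_bin_size = 2000, track_bin_size = 1e6,
       enrichment_fdr = 0.05)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), checks it
#' against the schema -- required keys, file existence, threshold ranges,
#' comparisons referencing declared samples, unknown keys -- and reports
#' every problem at once rather than failing on the first.
#'
#' @param config Path to a YAML file or a configuration list.
#' @return The validated configuration (class `"pipeline_config"`), with
#'   thresholds completed by defaults.  On any validation problem an error
#'   listing all collected issues is raised.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("no such config file: %s", config)
    cfg_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.dir <- cfg_dir
  }
  errors <- character()
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))
  known <- c("genome", "spikein_chrom", "annotations", "samples",
             "comparisons", "expression", "srna", "gene2term",
             "thresholds", "outdir", "seed", ".dir")
  unknown <- setdiff(names(config), known)
  for (k in unknown) note("unknown config key '%s'", k)
  resolve <- function(p) {
    if (!is.null(config$.dir) && !grepl("^(/|[A-Za-z]:)", p)) {
      file.path(config$.dir, p)
    } else p
  }
  need_file <- function(key, p) {
    p <- resolve(p)
    if (!file.exists(p)) note("%s: no such file '%s'", key, p)
    p
  }
  if (is.null(config$genome)) note("missing required key 'genome'")
  else config$genome <- need_file("genome", config$genome)
  if (is.null(config$samples) || !length(config$samples)) {
    note("missing required key 'samples'")
  } else {
    for (i in seq_along(config$samples)) {
      sm <- config$samples[[i]]
      if (is.null(sm$name)) note("sample %d: missing 'name'", i)
      if (is.null(sm$cx)) note("sample %d: missing 'cx'", i)
      else config$samples[[i]]$cx <- need_file(
        sprintf("sample %d cx", i), sm$cx)
    }
  }
  sample_names <- vapply(config$samples, function(s) s$name %||% "",
                         character(1))
  if (anyDuplicated(sample_names[nzchar(sample_names)])) {
    note("duplicate sample names")
  }
  if (!is.null(config$comparisons)) {
    for (i in seq_along(config$comparisons)) {
      cp <- config$comparisons[[i]]
      for (side in c("test", "ref")) {
        if (is.null(cp[[side]])) {
          note("comparison %d: missing '%s'", i, side)
        } else if (!cp[[side]] %in% sample_names) {
          note("comparison %d: %s sample '%s' is not declared", i, side,
               cp[[side]])
        }
      }
    }
  }
  for (key in c("annotations")) {
    if (!is.null(config[[key]])) {
      for (nm in names(config[[key]])) {
        config[[key]][[nm]] <- need_file(paste0(key, "$", nm),
                                         config[[key]][[nm]])
      }
    }
  }
  for (key in c("expression", "srna", "gene2term")) {
    if (!is.null(config[[key]])) {
      config[[key]] <- need_file(key, config[[key]])
    }
  }
  thr <- utils::modifyList(default_thresholds(),
                           config$thresholds %||% list())
  thr$dmr_min_delta <- unlist(thr$dmr_min_delta)
  for (k in c("mc_fdr", "dmc_fdr", "dmr_fdr", "enrichment_fdr",
              "dmc_min_delta")) {
    v <- thr[[k]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      note("threshold %s = %s outside [0, 1]", k,
           paste(v, collapse = ","))
    }
  }
  if (any(thr$dmr_min_delta < 0) || any(thr$dmr_min_delta > 1)) {
    note("threshold dmr_min_delta outside [0, 1]")
  }
  for (k in c("min_coverage", "dmr_bin_size", "dmr_min_sites", "flank",
              "srna_bin_size", "track_bin_size")) {
    if (!is.numeric(thr[[k]]) || thr[[k]] <= 0) {
      note("threshold %s must be positive", k)
    }
  }
  config$thresholds <- thr
  config$seed <- config$seed %||% 1L
  config$outdir <- config$outdir %||% "methylscape_out"
  if (length(errors)) {
    stopf("invalid configuration:\n- %s", paste(errors, collapse = "\n- "))
  }
  config$.dir <- NULL
  class(config) <- "pipeline_config"
  config
}

#' Run the full methylome analysis pipeline
#'
#' Executes every stage the configuration enables: per-sample QC
#' (conversion rate, coverage, global levels), sub-context statistics,
#' genome tracks, metagene/meta-TE profiles (expression-stratified when an
#' expression table is given), DMC/DMR calling with gene assignment and
#' optional term enrichment for each declared comparison, and the sRNA
#' stage (length distribution, unique mapping, methylation correlation,
#' metaprofiles) when a library is supplied.  All intermediates are plain
#' text under `outdir`; the consolidated report is written as JSON.
#'
#' @param config Path to a YAML config, a list, or a validated
#'   `"pipeline_config"`.
#' @return The run report (named list, class `"methylscape_report"`),
#'   invisibly also written to `outdir/report/report.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  thr <- config$thresholds
  out <- config$outdir
  for (d in c("qc", "levels", "tracks", "profiles", "dmr", "srna",
              "enrichment", "report")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  log_stage <- function(fmt, ...) message(sprintf(paste0("[methylscape] ",
                                                         fmt), ...))
  log_stage("loading genome %s", config$genome)
  genome <- read_fasta(config$genome)
  regions <- NULL
  for (nm in names(config$annotations %||% list())) {
    ft <- if (tolower(nm) %in% c("te", "tes")) "TE" else "gene"
    r <- read_regions(config$annotations[[nm]], feature_type = ft)
    regions <- rbind(regions, r)
  }
  no_regions <- data.frame(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           feature_type = character(),
                           feature_id = character(),
                           stringsAsFactors = FALSE)
  if (is.null(regions)) regions <- no_regions
  genes <- regions[regions$feature_type == "gene", , drop = FALSE]
  tes <- regions[regions$feature_type == "TE", , drop = FALSE]

  report <- list(tool = "methylscape",
                 version = as.character(utils::packageVersion("methylscape")),
                 seed = config$seed, samples = list(), comparisons = list())

  samples <- list()
  for (sm in config$samples) {
    log_stage("sample %s: reading %s", sm$name, sm$cx)
    sites <- read_cx_report(sm$cx, genome)
    samp <- methylome(sites, name = sm$name,
                      spikein_chrom = config$spikein_chrom)
    samples[[sm$name]] <- samp
    lv <- context_levels(samp, thr$min_coverage)
    write_tsv(lv, file.path(out, "levels",
                            sprintf("%s_context_levels.tsv", sm$name)))
    write_tsv(subcontext_stats(samp, genome, thr$min_coverage),
              file.path(out, "levels",
                        sprintf("%s_subcontext_stats.tsv", sm$name)))
    mc <- tryCatch(call_mc(samp, fdr = thr$mc_fdr,
                           min_coverage = thr$min_coverage),
                   error = function(e) NULL)
    cov <- sites$n_meth + sites$n_unmeth
    qc <- data.frame(
      sample = sm$name,
      conversion_rate = samp$conversion_rate,
      n_sites = nrow(sites),
      covered_fraction = mean(cov >= thr$min_coverage))
    write_tsv(qc, file.path(out, "qc", sprintf("%s_qc.tsv", sm$name)))
    for (ctx in .CONTEXTS) {
      tr <- binned_track(samp, genome, thr$track_bin_size, "level",
                         context = ctx, min_coverage = thr$min_coverage)
      write_bedgraph(tr[, c("chrom", "start", "end", "value")],
                     file.path(out, "tracks",
                               sprintf("%s_%s_level.bedGraph",
                                       sm$name, ctx)))
    }
    prof <- NULL
    if (nrow(genes %||% data.frame())) {
      for (ctx in .CONTEXTS) {
        pg <- meta_profile(samp, genes, ctx, thr$flank,
                           min_coverage = thr$min_coverage)
        pg$feature_class <- "gene"
        pg$context <- ctx
        prof <- rbind(prof, pg)
      }
    }
    if (nrow(tes %||% data.frame())) {
      for (ctx in .CONTEXTS) {
        pt <- meta_profile(samp, tes, ctx, thr$flank,
                           min_coverage = thr$min_coverage)
        pt$feature_class <- "TE"
        pt$context <- ctx
        prof <- rbind(prof, pt)
      }
    }
    if (!is.null(prof)) {
      write_tsv(prof, file.path(out, "profiles",
                                sprintf("%s_metaprofiles.tsv", sm$name)))
    }
    report$samples[[sm$name]] <- list(
      conversion_rate = samp$conversion_rate,
      covered_fraction = qc$covered_fraction,
      global_levels = setNames(as.list(lv$weighted_level), lv$context),
      mc_counts = if (!is.null(mc)) as.list(mc$counts) else NULL,
      mc_levels = if (!is.null(mc)) as.list(mc$mc_levels) else NULL)
  }

  if (!is.null(config$expression) && nrow(genes %||% data.frame())) {
    log_stage("expression stratification")
    expr <- read_expression(config$expression)
    for (scheme in c("five_group", "tertile")) {
      strata <- stratify_by_expression(expr, scheme)
      for (sm in names(samples)) {
        rl <- region_level_by_stratum(samples[[sm]], genes, strata,
                                      thr$flank, thr$min_coverage)
        write_tsv(rl, file.path(out, "profiles",
                                sprintf("%s_%s_region_levels.tsv",
                                        sm, scheme)))
      }
    }
  } else if (!is.null(config$expression)) {
    log_stage("expression given but no gene annotation; stage skipped")
  } else {
    log_stage("no expression table; profiles left unstratified")
  }

  gene2term <- if (!is.null(config$gene2term))
    read_gene2term(config$gene2term) else NULL

  for (cp in config$comparisons %||% list()) {
    tag <- sprintf("%s_vs_%s", cp$test, cp$ref)
    log_stage("comparison %s", tag)
    rep_cp <- list(test = cp$test, ref = cp$ref, dmc = list(),
                   dmr = list(), assignments = list())
    all_dmrs <- NULL
    for (ctx in .CONTEXTS) {
      dmc <- call_dmcs(samples[[cp$test]], samples[[cp$ref]], ctx,
                       thr$min_coverage, thr$dmc_min_delta, thr$dmc_fdr)
      dmr <- call_dmrs(samples[[cp$test]], samples[[cp$ref]], ctx,
                       thr$dmr_bin_size, thr$min_coverage, thr$dmr_fdr,
                       thr$dmr_min_delta, thr$dmr_min_sites)
      write_tsv(dmc, file.path(out, "dmr",
                               sprintf("%s_%s_dmc.tsv", tag, ctx)))
      write_tsv(dmr, file.path(out, "dmr",
                               sprintf("%s_%s_dmr.tsv", tag, ctx)))
      write_dmr_bed(dmr, file.path(out, "dmr",
                                   sprintf("%s_%s_dmr.bed", tag, ctx)))
      rep_cp$dmc[[ctx]] <- list(n_tested = attr(dmc, "n_tested"),
                                hyper = sum(dmc$direction == "hyper"),
                                hypo = sum(dmc$direction == "hypo"))
      rep_cp$dmr[[ctx]] <- list(n_tested = attr(dmr, "n_tested"),
                                hyper = sum(dmr$direction == "hyper"),
                                hypo = sum(dmr$direction == "hypo"))
      all_dmrs <- rbind(all_dmrs, dmr)
    }
    if (nrow(genes %||% data.frame()) && !is.null(all_dmrs) &&
        nrow(all_dmrs)) {
      asg <- assign_dmrs_to_genes(all_dmrs, genes, thr$flank)
      write_tsv(asg, file.path(out, "dmr",
                               sprintf("%s_gene_assignments.tsv", tag)))
      for (rg in c("promoter", "body", "downstream")) {
        for (dr in c("hyper", "hypo")) {
          gset <- unique(asg$gene_id[asg$region == rg &
                                       asg$direction == dr])
          rep_cp$assignments[[paste(rg, dr, sep = "_")]] <- length(gset)
          if (!is.null(gene2term) && length(gset)) {
            enr <- term_enrichment(gset, genes$feature_id, gene2term,
                                   thr$enrichment_fdr)
            write_tsv(enr, file.path(out, "enrichment",
                                     sprintf("%s_%s_%s_enrichment.tsv",
                                             tag, rg, dr)))
          }
        }
      }
    }
    report$comparisons[[tag]] <- rep_cp
  }

  if (!is.null(config$srna)) {
    log_stage("sRNA stage: %s", config$srna)
    reads <- read_srna_fasta(config$srna)
    ld <- length_distribution(reads)
    write_tsv(ld, file.path(out, "srna", "length_distribution.tsv"))
    aln <- map_exact_unique(reads, genome)
    write_tsv(aln[, setdiff(names(aln), "sequence")],
              file.path(out, "srna", "alignments.tsv"))
    aln24 <- aln[aln$length == 24L, , drop = FALSE]
    ref_sample <- samples[[1L]]
    srna_rep <- list(n_reads = sum(reads$copies),
                     n_unique_mapped = sum(aln$copies),
                     modal_length = ld$length[which.max(ld$count)])
    if (nrow(aln24) >= 3L) {
      cors <- lapply(.CONTEXTS, function(ctx) {
        cc <- tryCatch(
          binned_srna_methylation_correlation(
            aln24, ref_sample, ctx, thr$srna_bin_size,
            thr$min_coverage, total_mapped = sum(aln$copies),
            genome = genome),
          error = function(e) NULL)
        if (is.null(cc)) return(NULL)
        write_tsv(cc$bins, file.path(out, "srna",
                                     sprintf("bins_%s.tsv", ctx)))
        data.frame(context = ctx, rho = cc$rho, p = cc$p,
                   n_bins = cc$n_bins)
      })
      cors <- do.call(rbind, cors)
      if (!is.null(cors)) {
        write_tsv(cors, file.path(out, "srna", "correlation.tsv"))
        srna_rep$correlation <- cors
      }
      for (fs in c("gene", "TE")) {
        f <- if (fs == "gene") genes else tes
        if (nrow(f %||% data.frame())) {
          mp <- srna_metaprofile(aln24, f, thr$flank,
                                 total_mapped = sum(aln$copies))
          write_tsv(mp, file.path(out, "srna",
                                  sprintf("metaprofile_%s.tsv", fs)))
        }
      }
    }
    report$srna <- srna_rep
  } else {
    log_stage("no sRNA library; stage skipped")
  }

  class(report) <- "methylscape_report"
  jsonlite::write_json(unclass(report),
                       file.path(out, "report", "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(report)
}

#' @export
print.methylscape_report <- function(x, ...) {
  cat("<methylscape run report>\n")
  for (nm in names(x$samples)) {
    s <- x$samples[[nm]]
    cat(sprintf("  %s: conversion %.4f; CG/CHG/CHH = %.3f/%.3f/%.3f\n",
                nm, s$conversion_rate %||% NA,
                s$global_levels$CG, s$global_levels$CHG,
                s$global_levels$CHH))
  }
  for (nm in names(x$comparisons)) {
    cp <- x$comparisons[[nm]]
    for (ctx in names(cp$dmr)) {
      cat(sprintf("  %s %s: %d hyper / %d hypo DMRs\n", nm, ctx,
                  cp$dmr[[ctx]]$hyper, cp$dmr[[ctx]]$hypo))
    }
  }
  invisible(x)
}
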