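# manifest: flat key<TAB>value file; fully determines a run
write_manifest <- function(kv, file) {
  kv <- kv[order(names(kv))]
  writeLines(paste(names(kv), unname(unlist(kv)), sep = "\t"), file)
  invisible(file)
}

#' Read a pipeline run manifest
#' @param file Path to `manifest.txt` inside a run directory.
#' @return Named character vector of parameters and stage records.
#' @export
read_manifest <- function(file) {
  if (!file.exists(file)) stop("no manifest at ", file)
  lines <- readLines(file)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  structure(vapply(kv, `[`, character(1), 2), names = vapply(kv, `[`, character(1), 1))
}

read_sample_sheet <- function(x) {
  df <- if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
  need <- c("file", "sample", "label")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  df
}

write_counts_tsv <- function(counts, file) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_counts_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

pipeline_stages <- c("overlap", "normalize", "statistics", "summarize")

#' Run the full differential-expression pipeline
#'
#' Executes the stage sequence overlap (gene models + anchored counting),
#' normalize (expression filter + per-sample factors), statistics
#' (per-gene GLM likelihood-ratio / permutation tests) and summarize
#' (p/q-value tables, histogram, RPKM, top genes and their overlap
#' records), writing all outputs and a manifest into `out_dir`. Each
#' stage can be re-run individually with [run_stage()]; identical
#' parameters and seed reproduce every output byte-for-byte regardless of
#' `threads`.
#'
#' @param annotation GTF/GFF3 path.
#' @param sample_sheet data.frame or TSV path with columns `file`
#'   (SAM/BAM, one per sample), `sample`, `label`.
#' @param out_dir Output directory (created if needed).
#' @param gene_model `"union_intersection"` or `"union"`.
#' @param anchor `"three_prime_base"` or `"five_prime_k"`.
#' @param k Bases for the 5' anchor policy.
#' @param family,norm_mode,pseudocount,inference,B,seed,threads See
#'   [de_test()].
#' @param norm_method,quantile See [normalization_factors()].
#' @param label_type `"factor"` (group outcome) or `"continuous"`.
#' @param top_n Genes reported in the top-gene table.
#' @return Invisibly, `out_dir`.
#' @export
run_pipeline <- function(annotation, sample_sheet, out_dir,
                         gene_model = "union_intersection",
                         anchor = "three_prime_base", k = 5L,
                         family = "poisson", norm_mode = "offset",
                         norm_method = "quantile", quantile = 0.75,
                         inference = "lrt", B = 100L, top_n = 100L,
                         pseudocount = 0.5, label_type = "factor",
                         seed = 1L, threads = 1L) {
  if (!file.exists(annotation)) stop("missing input: annotation ", annotation)
  sheet <- read_sample_sheet(sample_sheet)
  missing <- sheet$file[!file.exists(sheet$file)]
  if (length(missing) > 0) {
    stop("missing input alignment file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  kv <- list(
    `param.annotation` = annotation, `param.sample_sheet` = sheet_path,
    `param.gene_model` = gene_model, `param.anchor` = anchor, `param.k` = k,
    `param.family` = family, `param.norm_mode` = norm_mode,
    `param.norm_method` = norm_method, `param.quantile` = quantile,
    `param.inference` = inference, `param.B` = B, `param.top_n` = top_n,
    `param.pseudocount` = pseudocount, `param.label_type` = label_type,
    `param.seed` = seed, `param.threads` = threads,
    `tool.version` = as.character(utils::packageVersion("anchorde"))
  )
  write_manifest(kv, file.path(out_dir, "manifest.txt"))
  for (stage in pipeline_stages) run_stage(stage, out_dir)
  invisible(out_dir)
}

#' Run one pipeline stage from a run directory's manifest
#'
#' @param stage One of `"overlap"`, `"normalize"`, `"statistics"`,
#'   `"summarize"`.
#' @param out_dir Run directory containing `manifest.txt` (and the
#'   outputs of any prerequisite stages).
#' @return Invisibly, the updated manifest.
#' @export
run_stage <- function(stage, out_dir) {
  if (!stage %in% pipeline_stages) {
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(pipeline_stages, collapse = ", "))
  }
  mf_path <- file.path(out_dir, "manifest.txt")
  mf <- as.list(read_manifest(mf_path))
  p <- function(x) file.path(out_dir, x)
  need <- function(files) {
    miss <- files[!file.exists(p(files))]
    if (length(miss) > 0) {
      stop("stage '", stage, "' needs missing input(s): ",
           paste(miss, collapse = ", "), "; run earlier stages first")
    }
  }
  if (stage == "overlap") {
    models <- gene_models(mf$param.annotation, mode = mf$param.gene_model)
    export_bed(models, p("intervals.bed"))
    utils::write.table(models$table, p("gene_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sheet <- read_sample_sheet(mf$param.sample_sheet)
    aln <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
      read_alignments(sheet$file[i], sample = sheet$sample[i])
    }))
    res <- count_anchored_overlaps(aln, models, policy = mf$param.anchor,
                                   k = as.integer(mf$param.k),
                                   samples = sheet$sample)
    write_counts_tsv(res$counts, p("counts.tsv"))
    ov <- res$overlaps[order(res$overlaps$gene_id, res$overlaps$sample,
                             res$overlaps$anchor), , drop = FALSE]
    utils::write.table(ov, p("overlaps.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mf$stage.overlap.n_genes <- nrow(models$table)
    mf$stage.overlap.n_alignments <- nrow(aln)
    mf$stage.overlap.n_assigned <- nrow(res$overlaps)
  } else if (stage == "normalize") {
    need("counts.tsv")
    counts <- read_counts_tsv(p("counts.tsv"))
    expr <- filter_expressed_genes(counts)
    write_counts_tsv(expr, p("expressed_counts.tsv"))
    q <- normalization_factors(expr, method = mf$param.norm_method,
                               p = as.numeric(mf$param.quantile))
    write_factors(q, p("factors.tsv"))
    mf$stage.normalize.n_expressed <- nrow(expr)
    mf$stage.normalize.n_filtered <- length(attr(expr, "removed"))
  } else if (stage == "statistics") {
    need(c("expressed_counts.tsv", "factors.tsv"))
    counts <- read_counts_tsv(p("expressed_counts.tsv"))
    q <- read_factors(p("factors.tsv"))
    sheet <- read_sample_sheet(mf$param.sample_sheet)
    labels <- stats::setNames(sheet$label, sheet$sample)[colnames(counts)]
    if (identical(mf$param.label_type, "continuous")) labels <- as.numeric(labels)
    res <- de_test(counts, labels, q[colnames(counts)],
                   family = mf$param.family, norm_mode = mf$param.norm_mode,
                   inference = mf$param.inference, B = as.integer(mf$param.B),
                   seed = as.integer(mf$param.seed),
                   pseudocount = as.numeric(mf$param.pseudocount),
                   threads = as.integer(mf$param.threads))
    utils::write.table(res, p("stats.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mf$stage.statistics.n_tested <- nrow(res)
  } else if (stage == "summarize") {
    need(c("stats.tsv", "expressed_counts.tsv", "gene_table.tsv", "overlaps.tsv"))
    res <- utils::read.delim(p("stats.tsv"), stringsAsFactors = FALSE)
    counts <- read_counts_tsv(p("expressed_counts.tsv"))
    gtab <- utils::read.delim(p("gene_table.tsv"), stringsAsFactors = FALSE)
    pv <- ifelse(is.na(res$p_permutation), res$p_asymptotic, res$p_permutation)
    ptab <- data.frame(gene_id = res$gene_id, p = pv)[order(pv, res$gene_id), ]
    utils::write.table(ptab, p("pvalues.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    qtab <- data.frame(gene_id = res$gene_id, q = qvalues(pv))
    qtab <- qtab[order(qtab$q, qtab$gene_id), ]
    utils::write.table(qtab, p("qvalues.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pvalue_histogram(pv), p("pvalue_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    L <- stats::setNames(gtab$length, gtab$gene_id)
    rpkm <- rpkm_table(counts, L)
    df <- data.frame(gene_id = rownames(rpkm), rpkm, check.names = FALSE)
    utils::write.table(df, p("rpkm.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    top <- top_genes(res, as.integer(mf$param.top_n))
    utils::write.table(top, p("top_genes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ov <- utils::read.delim(p("overlaps.tsv"), stringsAsFactors = FALSE)
    ov <- ov[ov$gene_id %in% top$gene_id, , drop = FALSE]
    utils::write.table(ov, p("top_overlaps.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mf$stage.summarize.n_top <- nrow(top)
  }
  mf[[paste0("stage.", stage, ".done")]] <- 1
  write_manifest(mf, mf_path)
  invisible(mf)
}
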