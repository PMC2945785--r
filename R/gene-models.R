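#' Parse exon annotation into per-gene transcript models
#'
#' Reads a GTF or GFF3 annotation and returns, for every gene, the exon
#' intervals of each of its transcripts. Only `exon` features are used.
#' GTF records must carry `gene_id` and `transcript_id` attributes; GFF3
#' exons are attached to transcripts through their `Parent` attribute and
#' transcripts to genes through theirs.
#'
#' @param file Path to a GTF or GFF3 file (plain text).
#' @param format `"auto"` (sniff `##gff-version` / extension), `"gtf"` or
#'   `"gff3"`.
#' @return A named list (one element per gene). Each element is a named
#'   list of transcripts; each transcript is a
#'   [GenomicRanges::GRanges-class] of its exons, sorted by start
#'   coordinate, all on one chromosome and strand.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tx\texon\t1\t100\t.\t+\t.",
#'                  'gene_id "G1"; transcript_id "T1";'), gtf)
#' parse_annotation(gtf)
#' @export
parse_annotation <- function(file, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(file)) stop("annotation file not found: ", file)
  lines <- readLines(file)
  if (format == "auto") {
    format <- if (any(grepl("^##gff-version\\s*3", lines[seq_len(min(5, length(lines)))])) ||
                  grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3" else "gtf"
  }
  body <- !grepl("^#", lines) & nzchar(lines)
  if (!any(body)) return(structure(list(), names = character(0)))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1]]
    stop("malformed annotation record at line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(file, format = format)
  if (length(gr) == 0 || !("type" %in% names(S4Vectors::mcols(gr)))) {
    return(structure(list(), names = character(0)))
  }
  if (format == "gtf") {
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0) return(structure(list(), names = character(0)))
    gid <- ex$gene_id
    tid <- ex$transcript_id
    if (is.null(gid) || anyNA(gid)) stop("exon record lacking gene_id attribute")
    if (is.null(tid) || anyNA(tid)) stop("exon record lacking transcript_id attribute")
  } else {
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0) return(structure(list(), names = character(0)))
    par <- ex$Parent
    if (is.null(par) || any(lengths(par) == 0)) {
      stop("exon record lacking Parent attribute")
    }
    tid <- unlist(lapply(as.list(par), `[`, 1))
    # map transcript feature IDs to their gene via the transcript's Parent
    feat <- gr[!is.na(gr$ID) & lengths(gr$Parent) > 0]
    t2g <- structure(unlist(lapply(as.list(feat$Parent), `[`, 1)), names = feat$ID)
    gid <- unname(t2g[tid])
    if (anyNA(gid)) {
      stop("exon Parent(s) ", paste(unique(tid[is.na(gid)]), collapse = ", "),
           " have no transcript feature linking them to a gene")
    }
  }
  ex <- GenomicRanges::granges(ex)
  by_gene <- split(seq_along(ex), gid)
  out <- lapply(by_gene, function(ix) {
    by_tx <- split(ix, tid[ix])
    lapply(by_tx, function(jx) {
      e <- ex[jx]
      e[order(GenomicRanges::start(e))]
    })
  })
  out[order(names(out))]
}

#' Build one gene's interval set from its transcripts
#'
#' Under the union-intersection model the gene's interval set is the
#' minimal set of intervals whose bases are covered by *every* transcript
#' of the gene (the constitutive bases). Under the union model it contains
#' every base present in *any* exon of the gene. The result is normalized:
#' intervals sorted, disjoint, with adjacent runs merged.
#'
#' @param transcripts A list of `GRanges`, one per transcript, all on one
#'   chromosome and strand (as produced by [parse_annotation()]).
#' @param mode `"union_intersection"` (default) or `"union"`.
#' @return A `GRanges` of sorted disjoint intervals, or `NULL` (with a
#'   warning) when the transcripts span several chromosomes or strands.
#' @export
build_gene_model <- function(transcripts, mode = c("union_intersection", "union")) {
  mode <- match.arg(mode)
  if (length(transcripts) == 0) stop("empty transcript list")
  all_ex <- suppressWarnings(do.call(c, unname(transcripts)))
  chroms <- unique(as.character(GenomicRanges::seqnames(all_ex)))
  strands <- unique(as.character(GenomicRanges::strand(all_ex)))
  if (length(chroms) > 1 || length(strands) > 1) {
    warning("transcripts on multiple chromosomes/strands; gene skipped")
    return(NULL)
  }
  merged <- lapply(transcripts, GenomicRanges::reduce)
  res <- if (mode == "union") {
    GenomicRanges::reduce(all_ex)
  } else {
    Reduce(function(a, b) GenomicRanges::intersect(a, b, ignore.strand = FALSE), merged)
  }
  GenomicRanges::reduce(sort(res))
}

#' Remove bases shared between genes from every gene's interval set
#'
#' Any base covered by the interval sets of two or more genes is omitted
#' from all of them, so the final sets are pairwise disjoint. Genes whose
#' set becomes empty are retained with zero length.
#'
#' @param models A named `GRangesList`, one internally-disjoint element per
#'   gene.
#' @return A named `GRangesList` of the same genes, pairwise disjoint.
#' @export
subtract_cross_gene_overlaps <- function(models) {
  if (length(models) == 0) return(models)
  flat <- unlist(models, use.names = FALSE)
  cov <- GenomicRanges::coverage(flat)
  irl <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
  shared <- GenomicRanges::GRanges(rep(names(irl), lengths(irl)),
                                   unlist(irl, use.names = FALSE))
  if (length(shared) == 0) return(models)
  out <- lapply(seq_along(models), function(i) {
    g <- models[[i]]
    if (length(g) == 0) return(g)
    res <- GenomicRanges::setdiff(g, shared, ignore.strand = TRUE)
    # overlap between genes is a genomic (strand-blind) question; restore
    # the gene's own strand on what is left
    GenomicRanges::strand(res) <- as.character(GenomicRanges::strand(g))[1]
    res
  })
  names(out) <- names(models)
  GenomicRanges::GRangesList(out)
}

#' Build the full gene interval model from an annotation
#'
#' Convenience constructor running [parse_annotation()],
#' [build_gene_model()] per gene and [subtract_cross_gene_overlaps()],
#' returning a `GeneModelSet`: the per-gene interval sets plus a gene
#' table with chromosome, strand, interval count and total length
#' \eqn{L_i} (the exon-model length used for RPKM).
#'
#' @param annotation Path to GTF/GFF3, or a parsed mapping from
#'   [parse_annotation()].
#' @param mode Gene model: `"union_intersection"` (default) or `"union"`.
#' @param format Passed to [parse_annotation()] when `annotation` is a path.
#' @return An object of class `GeneModelSet` with elements `intervals`
#'   (named `GRangesList`) and `table` (data.frame: gene_id, chrom, strand,
#'   n_intervals, length).
#' @export
gene_models <- function(annotation, mode = c("union_intersection", "union"),
                        format = "auto") {
  mode <- match.arg(mode)
  parsed <- if (is.character(annotation)) parse_annotation(annotation, format) else annotation
  built <- lapply(parsed, function(txs) build_gene_model(txs, mode))
  keep <- !vapply(built, is.null, logical(1))
  built <- built[keep]
  info <- lapply(built, function(g) {
    if (length(g) > 0) {
      c(chrom = as.character(GenomicRanges::seqnames(g))[1],
        strand = as.character(GenomicRanges::strand(g))[1])
    } else c(chrom = NA_character_, strand = NA_character_)
  })
  models <- subtract_cross_gene_overlaps(GenomicRanges::GRangesList(built))
  tab <- data.frame(
    gene_id = names(models),
    chrom = vapply(info, `[[`, character(1), "chrom"),
    strand = vapply(info, `[[`, character(1), "strand"),
    n_intervals = lengths(models),
    length = vapply(models, function(g) sum(GenomicRanges::width(g)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(intervals = models, table = tab), class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", nrow(x$table), "genes,",
      sum(x$table$n_intervals), "intervals,",
      sum(x$table$length), "bases\n")
  invisible(x)
}

#' Total interval-set length per gene
#' @param models A `GeneModelSet`.
#' @return Named numeric vector of lengths \eqn{L_i} in bases.
#' @export
gene_lengths <- function(models) {
  structure(models$table$length, names = models$table$gene_id)
}

#' Export gene interval sets as BED6
#'
#' One line per interval, `name` = gene id, 0-based half-open coordinates,
#' sorted by chromosome then start. Zero-length genes emit no lines.
#'
#' @param models A `GeneModelSet`.
#' @param file Output path.
#' @return Invisibly, the number of lines written.
#' @export
export_bed <- function(models, file) {
  grl <- models$intervals
  flat <- unlist(grl, use.names = FALSE)
  if (length(flat) == 0) {
    writeLines(character(0), file)
    return(invisible(0L))
  }
  gene <- rep(names(grl), lengths(grl))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat),
    name = gene,
    score = 0L,
    strand = as.character(GenomicRanges::strand(flat)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  con <- file(file, open = "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}

#' Re-import a BED6 export as per-gene interval sets
#'
#' Inverse of [export_bed()]: groups BED intervals by name into a named
#' `GRangesList` (1-based closed internal coordinates).
#'
#' @param file BED path.
#' @return Named `GRangesList` keyed by gene id.
#' @export
import_bed_models <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  grl <- GenomicRanges::split(GenomicRanges::granges(gr), gr$name)
  GenomicRanges::GRangesList(lapply(grl, sort))
}
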