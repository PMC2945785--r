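# reference-consuming CIGAR ops: M, D, N, =, X
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read aligned reads from SAM/BAM into alignment records
#'
#' Streams mapped records and derives, for each, the 1-based closed
#' reference span from the alignment position and the reference-consuming
#' CIGAR length (soft clips excluded). Unmapped records are skipped and
#' tallied. When `sample` is given every record belongs to it (file-level
#' assignment); otherwise the label comes from the `RG` tag, optionally
#' translated through `sample_map`.
#' Reads flagged multi-mapped (`NH` tag > 1) are marked non-unique;
#' without such metadata the input is trusted as pre-filtered to unique
#' alignments.
#'
#' @param file SAM or BAM path (SAM is converted internally).
#' @param sample Sample label for file-level assignment (overrides RG).
#' @param sample_map Optional named character vector, read-group id ->
#'   sample label. An RG id absent from the map is an error.
#' @return A data.frame (read_id, sample, chrom, start, end, strand,
#'   unique) with attribute `n_skipped` = unmapped records dropped.
#' @export
read_alignments <- function(file, sample = NULL, sample_map = NULL) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand"),
    tag = c("RG", "NH"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  n_skipped <- sum(!mapped)
  rg <- x$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, length(x$qname))
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(x$qname))
  keep <- which(mapped)
  samp <- if (!is.null(sample)) rep(sample, length(keep)) else rg[keep]
  if (!is.null(sample_map)) {
    unknown <- setdiff(stats::na.omit(unique(samp)), names(sample_map))
    if (length(unknown) > 0) {
      stop("unknown read group(s): ", paste(unknown, collapse = ", "))
    }
    samp <- ifelse(is.na(samp), NA_character_, unname(sample_map[samp]))
  }
  if (any(is.na(samp))) {
    stop("records without RG tag and no `sample` label given")
  }
  w <- cigar_ref_width(x$cigar[keep])
  out <- data.frame(
    read_id = x$qname[keep],
    sample = samp,
    chrom = as.character(x$rname[keep]),
    start = x$pos[keep],
    end = x$pos[keep] + w - 1L,
    strand = as.character(x$strand[keep]),
    unique = is.na(nh[keep]) | nh[keep] <= 1L,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Anchor position(s) of one alignment
#'
#' The default anchor is the 3'-most aligned base: the highest reference
#' coordinate of the span on the plus strand, the lowest on the minus
#' strand (the biological 3' end of a minus-strand read sits at the lower
#' coordinate). The alternative `five_prime_k` policy anchors on the
#' 5'-most `k` aligned bases, truncated to the span.
#'
#' @param start,end 1-based closed reference span of the alignment.
#' @param strand `"+"` or `"-"`.
#' @param policy `"three_prime_base"` or `"five_prime_k"`.
#' @param k Number of 5' bases for the `five_prime_k` policy.
#' @return Integer vector of genomic coordinates (1-based).
#' @export
anchor_positions <- function(start, end, strand,
                             policy = c("three_prime_base", "five_prime_k"),
                             k = 5L) {
  policy <- match.arg(policy)
  stopifnot(length(start) == 1, start <= end)
  if (policy == "three_prime_base") {
    return(if (strand == "-") start else end)
  }
  if (k <= 0) stop("five_prime_k policy requires k > 0")
  k <- min(k, end - start + 1L)
  if (strand == "-") seq.int(end - k + 1L, end) else seq.int(start, start + k - 1L)
}

#' Count anchored overlaps of alignments with gene interval sets
#'
#' An alignment contributes one count to gene \eqn{i} for its sample
#' \eqn{j} when any of its anchor bases falls inside gene \eqn{i}'s
#' interval set (strand-blind membership). Because the sets are pairwise
#' disjoint, the single-base 3' anchor can hit at most one gene; when a
#' 5' k-base anchor straddles two genes' sets the gene containing the
#' 5'-most anchored base wins. Non-unique alignments are dropped.
#'
#' @param alignments data.frame from [read_alignments()] (possibly several
#'   concatenated with `rbind`).
#' @param models A `GeneModelSet` from [gene_models()].
#' @param policy,k Anchor policy, see [anchor_positions()].
#' @param samples Declared sample order for the count matrix columns;
#'   defaults to sorted unique sample labels seen. A label outside this
#'   list is an error.
#' @return List with `counts` (integer gene x sample matrix over all genes
#'   in `models`) and `overlaps` (data.frame: gene_id, sample, chrom,
#'   anchor) with one row per counted alignment.
#' @export
count_anchored_overlaps <- function(alignments, models,
                                    policy = c("three_prime_base", "five_prime_k"),
                                    k = 5L, samples = NULL) {
  policy <- match.arg(policy)
  if (policy == "five_prime_k" && k <= 0) stop("five_prime_k policy requires k > 0")
  aln <- alignments[alignments$unique, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(alignments$sample))
  extra <- setdiff(unique(aln$sample), samples)
  if (length(extra) > 0) {
    stop("sample(s) not in declared sample list: ", paste(extra, collapse = ", "))
  }
  grl <- models$intervals
  flat <- unlist(grl, use.names = FALSE)
  gene_of <- rep(names(grl), lengths(grl))
  genes <- models$table$gene_id
  counts <- matrix(0L, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  empty <- data.frame(gene_id = character(0), sample = character(0),
                      chrom = character(0), anchor = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(aln) == 0 || length(flat) == 0) {
    return(list(counts = counts, overlaps = empty))
  }
  minus <- aln$strand == "-"
  if (policy == "three_prime_base") {
    a_start <- ifelse(minus, aln$start, aln$end)
    a_end <- a_start
  } else {
    kk <- pmin(k, aln$end - aln$start + 1L)
    a_start <- ifelse(minus, aln$end - kk + 1L, aln$start)
    a_end <- ifelse(minus, aln$end, aln$start + kk - 1L)
  }
  # the base recorded as "anchor": the 3'-most base under the default
  # policy, the 5'-most anchored base under five_prime_k
  anchor_base <- ifelse(minus, a_end, a_start)
  anchors <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(a_start, a_end))
  hits <- GenomicRanges::findOverlaps(anchors, flat, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (any(duplicated(qh))) {
    # 5'-k anchor straddling two genes: keep the hit covering the most-5'
    # anchored base (read 5' end: a_start on +, a_end on -)
    five_base <- anchor_base[qh]
    d5 <- abs(pmax(GenomicRanges::start(flat)[sh],
                   pmin(GenomicRanges::end(flat)[sh], five_base)) - five_base)
    o <- order(qh, d5, gene_of[sh])
    qh <- qh[o]; sh <- sh[o]
    keep1 <- !duplicated(qh)
    qh <- qh[keep1]; sh <- sh[keep1]
  }
  if (length(qh) == 0) return(list(counts = counts, overlaps = empty))
  ov <- data.frame(
    gene_id = gene_of[sh],
    sample = aln$sample[qh],
    chrom = aln$chrom[qh],
    anchor = anchor_base[qh],
    stringsAsFactors = FALSE
  )
  tab <- table(factor(ov$gene_id, levels = genes),
               factor(ov$sample, levels = samples))
  counts[] <- as.integer(tab)
  list(counts = counts, overlaps = ov)
}
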