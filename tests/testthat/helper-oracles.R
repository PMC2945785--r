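# Independent per-base oracles and toy-data builders. These deliberately
# avoid the package's interval code paths: membership is computed on
# logical base vectors.

# logical vector over bases 1..L marking coverage of a GRanges
gr_bitmap <- function(gr, L) {
  v <- logical(L)
  if (length(gr) == 0) return(v)
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  for (i in seq_along(s)) v[s[i]:e[i]] <- TRUE
  v
}

# bitmap oracle for one gene: intersection (ui) or union of the
# transcripts' exon base sets
oracle_gene_bitmap <- function(transcripts, L, mode) {
  sets <- lapply(transcripts, gr_bitmap, L = L)
  if (mode == "union") Reduce(`|`, sets) else Reduce(`&`, sets)
}

# bitmap oracle for cross-gene subtraction: drop bases covered by >= 2
# genes from every gene's bitmap
oracle_subtract_bitmaps <- function(bitmaps) {
  cov <- Reduce(`+`, lapply(bitmaps, as.integer))
  shared <- cov >= 2
  lapply(bitmaps, function(b) b & !shared)
}

# random toy annotation on one chromosome: parsed mapping + matching GTF
rand_toy_annotation <- function(max_coord = 1000, max_genes = 5, max_tx = 4) {
  n_genes <- sample(1:max_genes, 1)
  parsed <- list()
  gtf <- character(0)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%d", g)
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample(1:max_tx, 1)
    txs <- list()
    for (t in seq_len(n_tx)) {
      tid <- sprintf("%s.T%d", gid, t)
      n_ex <- sample(1:3, 1)
      s <- sort(sample(seq_len(max_coord - 20), n_ex))
      e <- pmin(s + sample(5:60, n_ex, replace = TRUE), max_coord)
      ex <- GenomicRanges::reduce(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, e), strand = strand))
      txs[[tid]] <- ex
      gtf <- c(gtf, sprintf(
        "chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        GenomicRanges::start(ex), GenomicRanges::end(ex), strand, gid, tid))
    }
    parsed[[gid]] <- txs
  }
  list(parsed = parsed, gtf = gtf, max_coord = max_coord)
}

# models built from a parsed toy annotation checked against the bitmap
# oracle end to end (per-gene model + cross-gene subtraction)
expect_models_match_oracle <- function(toy, mode) {
  models <- gene_models(toy$parsed, mode = mode)
  oracle <- oracle_subtract_bitmaps(lapply(
    toy$parsed, oracle_gene_bitmap, L = toy$max_coord, mode = mode))
  for (gid in names(toy$parsed)) {
    got <- gr_bitmap(models$intervals[[gid]], toy$max_coord)
    expect_identical(got, oracle[[gid]])
  }
  models
}

# small two-gene fixture used across counter/pipeline tests:
# G1 constitutive {1..100, 251..279}, G2 {301..400} after subtraction
toy_gtf_file <- function() {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chr1\ttoy\texon\t201\t300\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T2\";",
    "chr1\ttoy\texon\t251\t300\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T2\";",
    "chr1\ttoy\texon\t280\t400\t.\t-\t.\tgene_id \"G2\"; transcript_id \"T3\";"
  ), f)
  f
}

# one-line SAM writer for counter tests
toy_sam_file <- function(records, chrom_len = 10000) {
  f <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:chr1\tLN:%d", chrom_len),
    records
  ), f)
  f
}

sam_record <- function(qname, pos, len = 35, minus = FALSE, mapped = TRUE,
                       rg = NULL, nh = NULL) {
  flag <- if (!mapped) 4L else if (minus) 16L else 0L
  line <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                  qname, flag, if (mapped) "chr1" else "*",
                  if (mapped) pos else 0L,
                  if (mapped) paste0(len, "M") else "*",
                  strrep("A", len))
  if (!is.null(rg)) line <- paste0(line, "\tRG:Z:", rg)
  if (!is.null(nh)) line <- paste0(line, "\tNH:i:", nh)
  line
}

# brute-force pooled permutation p-values (quadratic)
brute_perm_pvalues <- function(observed, nulls) {
  nulls <- as.numeric(nulls)
  vapply(observed, function(d) (sum(nulls > d) + 1) / (length(nulls) + 1),
         numeric(1))
}

# closed-form two-group Poisson LRT with equal factors: group-mean MLEs,
# 0*log(0) := 0
closed_form_two_group_D <- function(y, grp) {
  xlogx <- function(s, n) if (s == 0) 0 else s * log(s / n)
  sA <- sum(y[grp == "A"]); nA <- sum(grp == "A")
  sB <- sum(y[grp == "B"]); nB <- sum(grp == "B")
  2 * (xlogx(sA, nA) + xlogx(sB, nB) - xlogx(sA + sB, nA + nB))
}

binomial_band <- function(alpha, m, level = 0.99) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  alpha + c(-1, 1) * z * sqrt(alpha * (1 - alpha) / m)
}
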