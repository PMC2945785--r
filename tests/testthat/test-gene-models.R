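test_that("GTF exons parse into per-gene transcripts with sorted coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";"
  ), gtf)
  p <- parse_annotation(gtf)
  expect_named(p, "G1")
  ex <- p$G1$T1
  # 1-based closed convention: a 100-base exon spanning bases 1..100
  expect_equal(GenomicRanges::start(ex), c(1, 201))
  expect_equal(GenomicRanges::end(ex), c(100, 300))
  expect_equal(sum(GenomicRanges::width(ex)), 200)
})

test_that("empty annotation yields an empty mapping", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines("# no records", gtf)
  expect_length(parse_annotation(gtf), 0)
})

test_that("malformed records and missing attributes are rejected with context", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
    "chr1\tx\texon\t1\t100"
  ), bad)
  expect_error(parse_annotation(bad), "line 2")
  noattr <- tempfile(fileext = ".gtf")
  writeLines("chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id \"G1\";", noattr)
  expect_error(parse_annotation(noattr), "transcript_id")
})

test_that("GFF3 Parent chains resolve exons to genes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=G1",
    "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tParent=T1",
    "chr1\tx\texon\t201\t300\t.\t+\t.\tParent=T1"
  ), gff)
  p <- parse_annotation(gff)
  expect_named(p, "G1")
  expect_equal(sum(GenomicRanges::width(p$G1$T1)), 200)
})

test_that("union-intersection keeps constitutive bases, union keeps all", {
  t1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)), "+")
  t2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 251), c(100, 300)), "+")
  ui <- build_gene_model(list(T1 = t1, T2 = t2), "union_intersection")
  un <- build_gene_model(list(T1 = t1, T2 = t2), "union")
  # verified against the per-base membership oracle
  expect_identical(gr_bitmap(ui, 300),
                   oracle_gene_bitmap(list(t1, t2), 300, "union_intersection"))
  expect_identical(gr_bitmap(un, 300),
                   oracle_gene_bitmap(list(t1, t2), 300, "union"))
  expect_equal(GenomicRanges::start(ui), c(1, 251))
  expect_equal(GenomicRanges::start(un), c(1, 201))
})

test_that("a single transcript is its own model in either mode", {
  t1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)), "+")
  for (mode in c("union_intersection", "union")) {
    g <- build_gene_model(list(T1 = t1), mode)
    expect_equal(GenomicRanges::start(g), c(1, 201))
    expect_equal(GenomicRanges::end(g), c(100, 300))
  }
})

test_that("adjacent intervals merge to canonical form", {
  t1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), c(100, 200)), "+")
  g <- build_gene_model(list(T1 = t1), "union")
  expect_length(g, 1)
  expect_equal(GenomicRanges::width(g), 200)
})

test_that("transcripts straddling chromosomes or strands skip the gene", {
  t1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+")
  t2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 100), "+")
  expect_warning(g <- build_gene_model(list(t1, t2)), "skipped")
  expect_null(g)
  expect_error(build_gene_model(list()), "empty")
})

test_that("cross-gene subtraction removes shared bases from all genes", {
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+")
  g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150), "-")
  out <- subtract_cross_gene_overlaps(
    GenomicRanges::GRangesList(G1 = g1, G2 = g2))
  expect_equal(GenomicRanges::start(out$G1), 1)
  expect_equal(GenomicRanges::end(out$G1), 50)
  expect_equal(GenomicRanges::start(out$G2), 101)
  expect_equal(GenomicRanges::end(out$G2), 150)
  expect_equal(as.character(GenomicRanges::strand(out$G2)), "-")

  # disjoint genes pass through unchanged
  g3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600), "+")
  out2 <- subtract_cross_gene_overlaps(GenomicRanges::GRangesList(G1 = g1, G3 = g3))
  expect_equal(GenomicRanges::start(out2$G1), 1)
  expect_equal(GenomicRanges::end(out2$G3), 600)

  # total overlap leaves both genes empty but present
  out3 <- subtract_cross_gene_overlaps(GenomicRanges::GRangesList(A = g1, B = g1))
  expect_length(out3$A, 0)
  expect_length(out3$B, 0)
  expect_named(out3, c("A", "B"))
})

test_that("random toy annotations agree with the per-base bitmap oracle", {
  set.seed(101)
  for (i in 1:60) {
    toy <- rand_toy_annotation(max_coord = 1000)
    for (mode in c("union_intersection", "union")) {
      models <- expect_models_match_oracle(toy, mode)
      # final sets are pairwise disjoint
      bitmaps <- lapply(models$intervals, gr_bitmap, L = toy$max_coord)
      expect_true(all(Reduce(`+`, lapply(bitmaps, as.integer)) <= 1))
    }
  }
})

test_that("the union-intersection set is contained in the union set", {
  set.seed(202)
  for (i in 1:20) {
    toy <- rand_toy_annotation(max_coord = 600)
    for (gid in names(toy$parsed)) {
      ui <- build_gene_model(toy$parsed[[gid]], "union_intersection")
      un <- build_gene_model(toy$parsed[[gid]], "union")
      bui <- gr_bitmap(ui, toy$max_coord)
      bun <- gr_bitmap(un, toy$max_coord)
      expect_true(all(!bui | bun))
    }
  }
})

test_that("BED export is definitional and round-trips exactly", {
  models <- gene_models(toy_gtf_file())
  bed <- tempfile(fileext = ".bed")
  export_bed(models, bed)
  lines <- readLines(bed)
  # 0-based half-open with name and strand columns
  expect_equal(lines[1], "chr1\t0\t100\tG1\t0\t+")
  expect_true(all(diff(as.integer(vapply(strsplit(lines, "\t"), `[`, "", 2))) >= 0))
  back <- import_bed_models(bed)
  for (gid in names(back)) {
    expect_identical(gr_bitmap(back[[gid]], 400),
                     gr_bitmap(models$intervals[[gid]], 400))
  }
})

test_that("zero-length genes stay in the gene table with length 0", {
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+")
  parsed <- list(A = list(t1 = g1), B = list(t1 = g1))
  models <- gene_models(parsed)
  expect_equal(sort(models$table$gene_id), c("A", "B"))
  expect_equal(models$table$length, c(0, 0))
  bed <- tempfile(fileext = ".bed")
  export_bed(models, bed)
  expect_length(readLines(bed), 0)
})
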