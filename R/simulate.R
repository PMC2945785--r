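#' Configuration for the synthetic RNA-seq generator
#'
#' Defines the study conditions emulated by the generator: per-gene
#' baseline expression drawn log-normal, per-sample sequencing-depth
#' multipliers drawn log-uniform, and replicate variation that is Poisson
#' (`phi = 0`, technical replication) or Gamma-Poisson with
#' \eqn{Var = \mu + \phi \mu^2} (`phi > 0`, biological replication).
#' An optional fraction of genes receives a fold change in the last
#' group.
#'
#' @param m Number of genes.
#' @param n Number of samples (split as evenly as possible into `K`
#'   groups, in order).
#' @param K Number of groups.
#' @param depth_range Range of the log-uniform depth multipliers
#'   \eqn{d_j}.
#' @param lambda_meanlog,lambda_sdlog Log-normal parameters of baseline
#'   expression \eqn{\lambda_i} (expected counts at depth 1).
#' @param phi Dispersion of the Gamma-Poisson draw; 0 gives Poisson.
#' @param de_fraction Fraction of genes that are differentially
#'   expressed.
#' @param fold Fold change applied to DE genes in the last group.
#' @param read_length Read length for simulated alignments (bases).
#' @param seed Seed governing every random draw.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(m = 2000L, n = 20L, K = 2L,
                              depth_range = c(0.5, 2),
                              lambda_meanlog = log(100), lambda_sdlog = 1.5,
                              phi = 0, de_fraction = 0, fold = 1,
                              read_length = 35L, seed = 1L) {
  if (m < 1 || n < 1 || K < 1 || K > n) stop("invalid m/n/K configuration")
  if (any(depth_range <= 0) || depth_range[1] > depth_range[2]) {
    stop("depth_range must be positive and ordered")
  }
  if (phi < 0) stop("dispersion phi must be >= 0")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must lie in [0, 1]")
  if (fold <= 0) stop("fold must be > 0")
  if (read_length < 1) stop("read_length must be >= 1")
  structure(list(m = as.integer(m), n = as.integer(n), K = as.integer(K),
                 depth_range = as.numeric(depth_range),
                 lambda_meanlog = lambda_meanlog, lambda_sdlog = lambda_sdlog,
                 phi = phi, de_fraction = de_fraction, fold = fold,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_group_labels <- function(n, K) {
  sort(rep_len(paste0("g", seq_len(K)), n))
}

#' Simulate a gene x sample count matrix
#'
#' Counts are drawn with mean \eqn{\mu_{ij} = d_j \lambda_i} (times the
#' fold change for DE genes in the last group): Poisson when `phi = 0`,
#' Gamma-Poisson (negative binomial, `size = 1/phi`) otherwise. The draw
#' is fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_counts`: `counts` (integer m x n matrix),
#'   `labels` (group per sample), `truth` (data.frame gene_id, de, fold),
#'   `depths` (the multipliers \eqn{d_j}), `lambda`, `config`.
#' @export
simulate_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    m <- config$m; n <- config$n
    genes <- sprintf("gene%05d", seq_len(m))
    samples <- sprintf("s%03d", seq_len(n))
    labels <- sim_group_labels(n, config$K)
    d <- exp(stats::runif(n, log(config$depth_range[1]), log(config$depth_range[2])))
    lambda <- stats::rlnorm(m, config$lambda_meanlog, config$lambda_sdlog)
    n_de <- round(config$de_fraction * m)
    de <- rep(FALSE, m)
    if (n_de > 0) de[sample.int(m, n_de)] <- TRUE
    mu <- outer(lambda, d)
    last <- labels == paste0("g", config$K)
    mu[de, last] <- mu[de, last] * config$fold
    draws <- if (config$phi == 0) {
      stats::rpois(m * n, as.vector(mu))
    } else {
      stats::rnbinom(m * n, mu = as.vector(mu), size = 1 / config$phi)
    }
    counts <- matrix(as.integer(draws), nrow = m, ncol = n,
                     dimnames = list(genes, samples))
    truth <- data.frame(gene_id = genes, de = de,
                        fold = ifelse(de, config$fold, 1),
                        stringsAsFactors = FALSE)
    structure(list(counts = counts, labels = labels, truth = truth,
                   depths = stats::setNames(d, samples),
                   lambda = stats::setNames(lambda, genes),
                   config = config),
              class = "sim_counts")
  })
}

#' Simulate uniquely-placed reads over gene interval sets as SAM
#'
#' For every gene with a non-empty interval set and every sample, a read
#' count is drawn under the [simulate_counts()] model (or taken from
#' `counts` when supplied), and each read is placed so that its 3'-most
#' aligned base falls uniformly over the gene's interval bases; strands
#' are random. Records carry per-sample read groups and a valid header.
#' Output is byte-identical under a fixed seed.
#'
#' @param models A `GeneModelSet`.
#' @param config A [simulation_config()]; `n`, depth/expression
#'   parameters and `read_length` are used.
#' @param file Output SAM path.
#' @param counts Optional gene x sample matrix of exact read numbers to
#'   plant (rownames must be gene ids of `models`).
#' @return Invisibly, a list with `counts` (the planted gene x sample
#'   matrix over non-empty genes), `labels`, and `file`.
#' @export
simulate_alignments <- function(models, config = simulation_config(),
                                file, counts = NULL) {
  stopifnot(inherits(models, "GeneModelSet"))
  tab <- models$table[models$table$length > 0, , drop = FALSE]
  if (nrow(tab) == 0) stop("no gene with a non-empty interval set")
  n <- if (is.null(counts)) config$n else ncol(counts)
  samples <- if (is.null(counts) || is.null(colnames(counts))) {
    sprintf("s%03d", seq_len(n))
  } else colnames(counts)
  labels <- sim_group_labels(n, config$K)
  with_local_seed(config$seed, {
    if (is.null(counts)) {
      d <- exp(stats::runif(n, log(config$depth_range[1]), log(config$depth_range[2])))
      lambda <- stats::rlnorm(nrow(tab), config$lambda_meanlog, config$lambda_sdlog)
      mu <- outer(lambda, d)
      draws <- if (config$phi == 0) {
        stats::rpois(length(mu), as.vector(mu))
      } else {
        stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$phi)
      }
      counts <- matrix(as.integer(draws), nrow = nrow(tab),
                       dimnames = list(tab$gene_id, samples))
    } else {
      missing <- setdiff(rownames(counts), tab$gene_id)
      if (length(missing) > 0) {
        warning("zero-length or unknown gene(s) skipped: ",
                paste(missing, collapse = ", "))
      }
      counts <- counts[intersect(rownames(counts), tab$gene_id), , drop = FALSE]
      colnames(counts) <- samples
    }
    rl <- config$read_length
    chrom_len <- tapply(
      vapply(models$intervals, function(g) {
        if (length(g) == 0) 0L else max(GenomicRanges::end(g))
      }, integer(1))[tab$gene_id],
      tab$chrom, max)
    chrom_len <- chrom_len + rl + 100L
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), as.integer(chrom_len)),
                sprintf("@RG\tID:%s\tSM:%s", samples, samples))
    chunks <- list()
    for (gi in seq_len(nrow(counts))) {
      gene <- rownames(counts)[gi]
      g <- models$intervals[[gene]]
      chrom <- as.character(GenomicRanges::seqnames(g))[1]
      bases <- unlist(Map(seq.int, GenomicRanges::start(g), GenomicRanges::end(g)),
                      use.names = FALSE)
      clen <- chrom_len[[chrom]]
      for (sj in seq_len(ncol(counts))) {
        cnt <- counts[gi, sj]
        if (cnt == 0) next
        anchor <- bases[sample.int(length(bases), cnt, replace = TRUE)]
        minus <- stats::runif(cnt) < 0.5
        # 3' anchor: highest coordinate of the span on +, lowest on -
        start <- ifelse(minus, anchor, pmax(1L, anchor - rl + 1L))
        end <- ifelse(minus, pmin(clen, anchor + rl - 1L), anchor)
        w <- end - start + 1L
        chunks[[length(chunks) + 1L]] <- sprintf(
          "%s_%s_r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tRG:Z:%s",
          gene, samples[sj], seq_len(cnt), ifelse(minus, 16L, 0L), chrom,
          as.integer(start), as.integer(w),
          vapply(w, function(x) strrep("A", x), character(1)), samples[sj])
      }
    }
    writeLines(c(header, unlist(chunks)), file)
    invisible(list(counts = counts, labels = labels, file = file))
  })
}

#' Type-I error calibration under randomized group labels
#'
#' Simulates a global-null count matrix (`fold = 1`), assigns each sample
#' to one of two groups, and measures, for each testing strategy, the
#' fraction of genes reaching `p < alpha`. Under a correct model the
#' p-values are uniform, so the observed significant count should match
#' the expected `round(alpha * m)`; an anti-conservative strategy exceeds
#' it.
#'
#' @param config A [simulation_config()]; `fold` must be 1.
#' @param strategies List of strategies, each a list with `family`,
#'   `norm_mode`, `inference`. Default: the six-strategy panel
#'   Poisson-LRT, Gaussian-LRT and Gaussian-permutation, each with
#'   normalization as offset and as model term.
#' @param alpha Significance levels to report.
#' @param B Label permutations for permutation-inference strategies.
#' @param counts Optional precomputed `sim_counts` object (overrides
#'   `config` for the data).
#' @return Object of class `calibration_report`: `report` (data.frame:
#'   strategy, family, norm_mode, inference, alpha, m, observed, fraction,
#'   expected), `histograms` (per-strategy p-value histogram tables),
#'   `config`.
#' @export
null_calibration_experiment <- function(config = simulation_config(),
                                        strategies = default_strategies(),
                                        alpha = c(0.01, 0.05), B = 100L,
                                        counts = NULL) {
  if (is.null(counts)) {
    if (config$fold != 1 && config$de_fraction > 0) {
      stop("calibration requires a global null: set fold = 1 or de_fraction = 0")
    }
    counts <- simulate_counts(config)
  }
  cm <- filter_expressed_genes(counts$counts)
  q <- normalization_factors(cm)
  labels <- counts$labels
  m <- nrow(cm)
  rows <- list(); hists <- list()
  for (s in strategies) {
    res <- de_test(cm, labels, q, family = s$family, norm_mode = s$norm_mode,
                   inference = s$inference, B = B, seed = counts$config$seed)
    p <- if (s$inference == "permutation") res$p_permutation else res$p_asymptotic
    name <- paste(s$family, s$norm_mode, s$inference, sep = "_")
    hists[[name]] <- pvalue_histogram(p)
    for (a in alpha) {
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = name, family = s$family, norm_mode = s$norm_mode,
        inference = s$inference, alpha = a, m = m,
        observed = sum(p < a), fraction = mean(p < a),
        expected = expected_null_count(m, a),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(report = do.call(rbind, rows), histograms = hists,
                 config = counts$config),
            class = "calibration_report")
}

#' The six-strategy significance panel
#'
#' Poisson and Gaussian likelihood-ratio tests plus the Gaussian statistic
#' with permutation inference, each crossed with normalization as offset
#' and as estimated model term.
#' @return List of strategy descriptors for
#'   [null_calibration_experiment()].
#' @export
default_strategies <- function() {
  list(
    list(family = "poisson", norm_mode = "offset", inference = "lrt"),
    list(family = "poisson", norm_mode = "term", inference = "lrt"),
    list(family = "gaussian", norm_mode = "offset", inference = "lrt"),
    list(family = "gaussian", norm_mode = "term", inference = "lrt"),
    list(family = "gaussian", norm_mode = "offset", inference = "permutation"),
    list(family = "gaussian", norm_mode = "term", inference = "permutation")
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Null-calibration experiment:", x$report$m[1], "genes\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
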