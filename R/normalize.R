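#' Drop genes with no counts in any sample
#'
#' Genes whose total count over all samples is zero carry no evidence and
#' are removed before normalization and testing; a gene with a single
#' count in one sample is retained. Gene order is otherwise preserved.
#'
#' @param counts Integer gene x sample matrix.
#' @return The filtered matrix, with attribute `removed` holding the
#'   dropped gene ids.
#' @export
filter_expressed_genes <- function(counts) {
  tot <- rowSums(counts)
  keep <- tot > 0
  if (!any(keep)) stop("all genes have zero counts; nothing to test")
  removed <- rownames(counts)[!keep]
  if (length(removed) > 0) {
    message(length(removed), " gene(s) without any counts removed")
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Per-sample normalization factors from the gene-count distribution
#'
#' The default factor is the 75th percentile of the sample's *non-zero*
#' gene counts (upper-quartile normalization); alternatives are another
#' quantile, the median of non-zero counts, or the total count (zeros
#' included). Quantiles interpolate linearly between order statistics by
#' default; `type = "nearest"` uses the nearest-rank order statistic.
#'
#' @param counts Gene x sample count matrix (typically post-filter).
#' @param method `"quantile"`, `"median"` or `"total"`.
#' @param p Quantile probability for `method = "quantile"` (default 0.75).
#' @param type Quantile estimator: `"interpolation"` (default) or
#'   `"nearest"` (nearest rank).
#' @return Named numeric vector \eqn{q_j > 0}, one per sample, with
#'   attributes `method` and `p`.
#' @examples
#' m <- rbind(a = c(1, 2), b = c(2, 4), c = c(3, 6), d = c(4, 8))
#' colnames(m) <- c("s1", "s2")
#' normalization_factors(m)  # 3.25, 6.5
#' @export
normalization_factors <- function(counts, method = c("quantile", "median", "total"),
                                  p = 0.75, type = c("interpolation", "nearest")) {
  method <- match.arg(method)
  type <- match.arg(type)
  if (method == "median") p <- 0.5
  samples <- colnames(counts)
  q <- vapply(seq_len(ncol(counts)), function(j) {
    col <- counts[, j]
    if (method == "total") {
      tot <- sum(col)
      if (tot <= 0) stop("total count is zero for sample ", samples[j])
      return(as.numeric(tot))
    }
    nz <- col[col > 0]
    if (length(nz) == 0) {
      stop("sample ", samples[j], " has no non-zero gene counts; cannot take a quantile")
    }
    qtype <- if (type == "interpolation") 7 else 1
    unname(stats::quantile(nz, probs = p, type = qtype, names = FALSE))
  }, numeric(1))
  names(q) <- samples
  attr(q, "method") <- method
  attr(q, "p") <- if (method == "total") NA_real_ else p
  q
}

#' Write / read normalization factors as TSV
#' @param q Factors from [normalization_factors()].
#' @param file Path.
#' @return `write_factors` invisibly returns `file`; `read_factors`
#'   returns the named numeric vector with its attributes.
#' @export
write_factors <- function(q, file) {
  df <- data.frame(sample = names(q),
                   method = attr(q, "method"),
                   p = attr(q, "p"),
                   value = as.numeric(q),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_factors
#' @export
read_factors <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  q <- structure(df$value, names = df$sample)
  attr(q, "method") <- df$method[1]
  attr(q, "p") <- df$p[1]
  q
}
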