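#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, capped at 1 and mapped
#' back to the input order, optionally scaled by an estimate of the null
#' proportion \eqn{\pi_0}.
#'
#' @param p P-values in `(0, 1]`.
#' @param pi0 Null-proportion multiplier in `(0, 1]` (1 = classical BH).
#' @return Q-values in input order.
#' @export
qvalues <- function(p, pi0 = 1) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' RPKM expression table
#'
#' \eqn{RPKM_{ij} = c_{ij} / ((L_i/10^3)(N_j/10^6))} with \eqn{L_i} the
#' gene's interval-set length and \eqn{N_j} the sample's depth. The
#' default depth is the total of reads assigned to any gene in the matrix
#' (column sums); externally determined totals (e.g. all uniquely aligned
#' reads) may be supplied instead. Zero-length genes get `NA`.
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Named vector of gene lengths \eqn{L_i} in bases
#'   (see [gene_lengths()]); must cover all rownames of `counts`.
#' @param depth_totals Optional named per-sample totals \eqn{N_j};
#'   defaults to `colSums(counts)`. Any zero total is an error.
#' @return Numeric matrix of RPKM values, dimnames as `counts`.
#' @export
rpkm_table <- function(counts, lengths, depth_totals = NULL) {
  if (is.null(depth_totals)) depth_totals <- colSums(counts)
  if (any(depth_totals <= 0)) {
    bad <- colnames(counts)[depth_totals <= 0]
    stop("zero depth total for sample(s): ", paste(bad, collapse = ", "))
  }
  L <- lengths[rownames(counts)]
  if (anyNA(L)) stop("missing gene length(s) for: ",
                     paste(rownames(counts)[is.na(L)], collapse = ", "))
  out <- sweep(counts, 2, depth_totals / 1e6, "/")
  out <- sweep(out, 1, L / 1e3, "/")
  out[L == 0, ] <- NA_real_
  out
}

#' Top-N genes by significance
#'
#' Genes sorted by p-value ascending (ties broken by gene id for
#' determinism); every gene tied at the Nth p-value is included.
#'
#' @param results data.frame from [de_test()]; ranking uses
#'   `p_permutation` where available, else `p_asymptotic`.
#' @param N Number of top genes requested.
#' @return The selected rows, ranked, with a `rank` column.
#' @export
top_genes <- function(results, N) {
  if (N < 1) stop("N must be >= 1")
  p <- ifelse(is.na(results$p_permutation), results$p_asymptotic,
              results$p_permutation)
  o <- order(p, results$gene_id)
  ranked <- results[o, , drop = FALSE]
  p <- p[o]
  cutoff <- p[min(N, length(p))]
  keep <- which(p <= cutoff)
  out <- ranked[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' P-value histogram table
#'
#' Bin counts of p-values on fixed edges, as written by the pipeline's
#' postprocess stage (rendering is left to the caller).
#'
#' @param p P-values.
#' @param breaks Bin edges spanning `[0, 1]`.
#' @return data.frame: bin_start, bin_end, count.
#' @export
pvalue_histogram <- function(p, breaks = seq(0, 1, by = 0.05)) {
  h <- graphics::hist(p, breaks = breaks, plot = FALSE)
  data.frame(bin_start = h$breaks[-length(h$breaks)],
             bin_end = h$breaks[-1],
             count = h$counts)
}

#' Expected number of null genes significant at level alpha
#'
#' Under a global null with uniform p-values, the expected count of genes
#' reaching `p < alpha` is `alpha * m`, reported to the nearest integer
#' (the yardstick the calibration experiment compares observed counts
#' against).
#'
#' @param m Number of genes tested.
#' @param alpha Significance level.
#' @return Nearest-integer expected count.
#' @export
expected_null_count <- function(m, alpha = 0.05) {
  if (m < 1 || alpha <= 0 || alpha >= 1) stop("need m >= 1 and alpha in (0, 1)")
  round(alpha * m)
}
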