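#' Model specification for the differential-expression GLM
#'
#' The test relates counts \eqn{c_{ij}} to the outcome \eqn{y_j} through
#' \deqn{g(E[f(c_{ij}) | y_j]) = b_{i0} + \eta_i \log(q_j) + \sum_k b_{ik} s_k(y_j)}
#' with a log link and identity transform for the Poisson family, and an
#' identity link with log-transformed counts for the Gaussian family.
#' The normalization factor enters either as an offset (\eqn{\eta_i = 1}
#' for every gene) or as a regression term with a gene-specific estimated
#' coefficient.
#'
#' @param family `"poisson"` or `"gaussian"`.
#' @param norm_mode `"offset"` (coefficient on `log(q)` fixed at 1) or
#'   `"term"` (estimated per gene under both null and full models).
#' @param pseudocount Added inside the Gaussian log transform,
#'   `f(c) = log(c + pseudocount)`; must be positive.
#' @return A list of class `de_model_spec`.
#' @export
model_spec <- function(family = c("poisson", "gaussian"),
                       norm_mode = c("offset", "term"),
                       pseudocount = 0.5) {
  family <- match.arg(family)
  norm_mode <- match.arg(norm_mode)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  structure(list(
    family = family,
    link = if (family == "poisson") "log" else "identity",
    transform = if (family == "poisson") "identity" else "log",
    norm_mode = norm_mode,
    pseudocount = pseudocount
  ), class = "de_model_spec")
}

#' Full and null design matrices for the per-gene GLM
#'
#' A K-group factor outcome is encoded with reference-level dummies
#' (K - 1 test columns); a numeric outcome contributes one column. The
#' null design keeps the intercept (and, in term mode, the `log(q)`
#' column) and drops only the outcome columns. In offset mode `log(q)`
#' is returned as a fixed offset vector rather than a column.
#'
#' @param labels Outcome \eqn{y_j}: factor/character (groups) or numeric
#'   (continuous).
#' @param factors Positive per-sample normalization factors \eqn{q_j}
#'   (from [normalization_factors()]).
#' @param spec A [model_spec()].
#' @return List: `full`, `null` (matrices), `offset` (numeric vector),
#'   `df_test` (number of outcome columns).
#' @export
design_matrices <- function(labels, factors, spec = model_spec()) {
  n <- length(labels)
  if (length(factors) != n) stop("labels and factors disagree in length")
  if (any(factors <= 0)) stop("all normalization factors must be > 0")
  if (is.numeric(labels)) {
    if (stats::var(labels) == 0) stop("no contrast: outcome is constant")
    outcome <- matrix(as.numeric(labels), ncol = 1, dimnames = list(NULL, "y"))
  } else {
    f <- factor(labels)
    if (nlevels(f) < 2) stop("no contrast: outcome has a single level")
    outcome <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(outcome) <- paste0("y", levels(f)[-1])
  }
  logq <- log(factors)
  null <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "intercept"))
  offset <- rep(0, n)
  if (spec$norm_mode == "term") {
    if (diff(range(logq)) < 1e-12) {
      warning("log(q) is constant; normalization term dropped from the model")
    } else {
      null <- cbind(null, logq = logq)
    }
  } else {
    offset <- logq
  }
  full <- cbind(null, outcome)
  list(full = full, null = null, offset = offset, df_test = ncol(outcome))
}

# Poisson log-likelihood with the 0*log(0) := 0 convention (dpois handles it)
pois_loglik <- function(y, mu) sum(stats::dpois(y, mu, log = TRUE))

fit_poisson_pair <- function(y, designs) {
  ctl <- list(epsilon = 1e-8, maxit = 50, trace = FALSE)
  f1 <- suppressWarnings(stats::glm.fit(designs$full, y, family = stats::poisson(),
                                        offset = designs$offset, control = ctl))
  f0 <- suppressWarnings(stats::glm.fit(designs$null, y, family = stats::poisson(),
                                        offset = designs$offset, control = ctl))
  D <- max(0, 2 * (pois_loglik(y, f1$fitted.values) - pois_loglik(y, f0$fitted.values)))
  c(D = D, converged = as.numeric(f1$converged && f0$converged))
}

# Residual sums of squares of every column of Z under design X, via the
# thin-QR projection; Z is n x m.
rss_under <- function(X, Z) {
  Q <- qr.Q(qr(X))
  pmax(colSums(Z^2) - colSums((crossprod(Q, Z))^2), 0)
}

lrt_statistics <- function(counts, designs, spec, threads = 1L) {
  m <- nrow(counts)
  n <- ncol(counts)
  if (spec$family == "gaussian") {
    Z <- t(log(counts + spec$pseudocount)) - designs$offset
    rss1 <- rss_under(designs$full, Z)
    rss0 <- rss_under(designs$null, Z)
    eps <- 1e-300
    D <- pmax(0, n * (log(rss0 + eps) - log(rss1 + eps)))
    # no between-sample variation at all: nothing to explain
    D[rss0 < 1e-12 & rss1 < 1e-12] <- 0
    return(list(D = D, converged = rep(TRUE, m)))
  }
  if (any(counts < 0)) stop("negative counts are not valid for the Poisson family")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("Poisson family requires integer counts")
  }
  one <- function(i) fit_poisson_pair(counts[i, ], designs)
  idx <- seq_len(m)
  if (threads > 1L && m > 1L) {
    chunks <- split(idx, cut(idx, breaks = threads, labels = FALSE))
    res <- do.call(rbind, parallel::mclapply(chunks, function(ix) {
      t(vapply(ix, one, c(D = 0, converged = 0)))
    }, mc.cores = threads))
  } else {
    res <- t(vapply(idx, one, c(D = 0, converged = 0)))
  }
  list(D = unname(res[, "D"]), converged = unname(res[, "converged"]) > 0)
}

#' Per-gene differential-expression test
#'
#' Fits the full and null generalized linear models of [model_spec()] to
#' every gene and reports the likelihood-ratio statistic
#' \eqn{D_i = 2(\ell_{full} - \ell_{null})} (clamped at zero), its
#' asymptotic chi-square p-value, and optionally pooled permutation
#' p-values. Poisson models are fitted by iteratively reweighted least
#' squares; Gaussian models by least squares on `log(c + pseudocount)`
#' with the Gaussian profile log-likelihood, so
#' \eqn{D_i = n \log(RSS_0 / RSS_1)}.
#'
#' @param counts Gene x sample count matrix (rownames = gene ids).
#' @param labels Outcome per sample: factor/character groups or numeric.
#' @param factors Per-sample normalization factors \eqn{q_j}; defaults to
#'   the 75th-percentile factors of `counts`.
#' @param family,norm_mode,pseudocount See [model_spec()].
#' @param inference `"lrt"` (asymptotic only) or `"permutation"` (adds
#'   pooled permutation p-values from `B` label permutations).
#' @param B Number of label permutations for `inference = "permutation"`.
#' @param seed Seed for the permutation draws (recorded in the result).
#' @param threads Worker count for the per-gene fits; results are
#'   identical for any value.
#' @return data.frame: gene_id, D, df, p_asymptotic, p_permutation (NA
#'   unless permutation inference), converged. When permutation inference
#'   is used the `null_statistics` attribute holds the m x B null matrix
#'   and the permutations.
#' @export
de_test <- function(counts, labels, factors = NULL,
                    family = c("poisson", "gaussian"),
                    norm_mode = c("offset", "term"),
                    inference = c("lrt", "permutation"),
                    B = 100L, seed = 1L, pseudocount = 0.5, threads = 1L) {
  family <- match.arg(family)
  norm_mode <- match.arg(norm_mode)
  inference <- match.arg(inference)
  if (length(labels) != ncol(counts)) stop("one label per sample required")
  if (is.null(factors)) factors <- normalization_factors(counts)
  spec <- model_spec(family, norm_mode, pseudocount)
  designs <- design_matrices(labels, factors, spec)
  fit <- lrt_statistics(counts, designs, spec, threads)
  res <- data.frame(
    gene_id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts))) else rownames(counts),
    D = fit$D,
    df = designs$df_test,
    p_asymptotic = stats::pchisq(fit$D, df = designs$df_test, lower.tail = FALSE),
    p_permutation = NA_real_,
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
  if (inference == "permutation") {
    nulls <- permute_null(counts, labels, factors, family = family,
                          norm_mode = norm_mode, B = B, seed = seed,
                          pseudocount = pseudocount, threads = threads)
    res$p_permutation <- permutation_pvalues(res$D, nulls)
    attr(res, "null_statistics") <- nulls
  }
  res
}

#' Null likelihood-ratio statistics from permuted outcome labels
#'
#' Draws `B` random permutations of the outcome vector (the normalization
#' factors stay attached to their samples), reapplies the identical
#' fitting procedure for each, and collects the resulting statistics
#' \eqn{D^{0b}_i} into an m x B matrix. One permutation per replicate is
#' shared across all genes, preserving cross-gene structure.
#'
#' @inheritParams de_test
#' @return Object of class `null_statistics`: list with `D0` (m x B
#'   matrix), `perms` (n x B permutation indices), `seed`.
#' @export
permute_null <- function(counts, labels, factors = NULL,
                         family = c("poisson", "gaussian"),
                         norm_mode = c("offset", "term"),
                         B = 100L, seed = 1L, pseudocount = 0.5, threads = 1L) {
  family <- match.arg(family)
  norm_mode <- match.arg(norm_mode)
  if (B < 1) stop("B must be >= 1")
  m <- nrow(counts)
  if (as.double(m) * B >= 2^31) stop("m * B too large for the null-statistic store")
  if (is.null(factors)) factors <- normalization_factors(counts)
  spec <- model_spec(family, norm_mode, pseudocount)
  n <- ncol(counts)
  perms <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) sample.int(n), integer(n))
  })
  D0 <- matrix(NA_real_, nrow = m, ncol = B)
  for (b in seq_len(B)) {
    designs_b <- design_matrices(labels[perms[, b]], factors, spec)
    D0[, b] <- lrt_statistics(counts, designs_b, spec, threads)$D
  }
  structure(list(D0 = D0, perms = perms, seed = seed), class = "null_statistics")
}

#' Pooled permutation p-values
#'
#' \deqn{p_i = \frac{\#\{D^{0b}_j > D_i\} + 1}{mB + 1}} pooling the null
#' statistics over all genes and all permutations; the inequality is
#' strict, so null values tied with \eqn{D_i} do not count as exceeding
#' it, and the smallest attainable p-value is \eqn{1/(mB+1)}. Computed by
#' one linear scan of the merged, sorted observed and null statistics.
#'
#' @param observed Numeric vector of observed statistics \eqn{D_i}.
#' @param nulls A `null_statistics` object or a numeric matrix/vector of
#'   null statistics.
#' @return Numeric vector of p-values in `(0, 1]`, aligned with
#'   `observed`.
#' @export
permutation_pvalues <- function(observed, nulls) {
  if (inherits(nulls, "null_statistics")) nulls <- nulls$D0
  nulls <- as.numeric(nulls)
  if (length(nulls) == 0) stop("empty null statistic matrix")
  ns <- sort(nulls)
  total <- length(ns)
  ord <- order(observed)
  n_greater <- integer(length(observed))
  j <- 0L
  for (i in ord) {
    while (j < total && ns[j + 1L] <= observed[i]) j <- j + 1L
    n_greater[i] <- total - j
  }
  (n_greater + 1) / (total + 1)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
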