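# Linking SILAC newly-synthesized-protein fold changes (and delta-TE) to
# serine codon composition: fold changes, bin averages, Spearman
# correlation, quadratic trend fits, two-stage Benjamini-Hochberg.

#' SILAC log2 fold changes between two heavy-channel intensity maps
#'
#' Heavy-labelled intensities mark newly synthesized protein;
#' `log2_fc = log2(heavy_a / heavy_b)` for proteins quantified (> 0) on
#' both sides. Under the default `"drop"` policy, proteins missing or zero
#' on either side are removed and their count recorded (imputation would
#' inject structure the downstream correlation then measures).
#'
#' @param heavy_a,heavy_b Named non-negative numeric vectors,
#'   protein/gene -> heavy-channel intensity.
#' @param policy Missing-data policy; only `"drop"` is implemented.
#' @return `data.frame` with `gene_id`, `heavy_a`, `heavy_b`, `log2_fc`;
#'   attribute `n_dropped`.
#' @export
silac_fold_change <- function(heavy_a, heavy_b, policy = "drop") {
  policy <- match.arg(policy, "drop")
  if (is.null(names(heavy_a)) || is.null(names(heavy_b))) {
    stop("intensity vectors must be named by protein/gene", call. = FALSE)
  }
  if (any(heavy_a < 0, na.rm = TRUE) || any(heavy_b < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  shared <- intersect(names(heavy_a), names(heavy_b))
  a <- heavy_a[shared]
  b <- heavy_b[shared]
  keep <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  n_dropped <- (length(heavy_a) - length(shared)) +
    (length(heavy_b) - length(shared)) + sum(!keep)
  out <- data.frame(
    gene_id = shared[keep],
    heavy_a = as.numeric(a[keep]),
    heavy_b = as.numeric(b[keep]),
    log2_fc = as.numeric(log2(a[keep] / b[keep])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-bin averages of a gene-level quantity
#'
#' Mean and standard error of `values` within each bin of a scheme; bins
#' without genes are reported with `n = 0` and `NA` summaries, and the SEM
#' is defined only for `n >= 2`.
#'
#' @param values Named numeric vector, gene -> value.
#' @param bins Named character vector, gene -> bin label (e.g. from
#'   [assign_bin()]); genes must be keyed consistently with `values`.
#' @param scheme Optional [bin_scheme()] fixing the label order (labels not
#'   in the scheme are an error); default: sorted unique labels.
#' @return `data.frame` with `bin`, `n`, `mean_fc`, `sem`.
#' @export
bin_average <- function(values, bins, scheme = NULL) {
  if (is.null(names(values)) || is.null(names(bins))) {
    stop("values and bins must be named by gene", call. = FALSE)
  }
  shared <- intersect(names(values), names(bins))
  v <- values[shared]
  b <- bins[shared]
  keep <- !is.na(v) & !is.na(b)
  v <- v[keep]
  b <- b[keep]
  labels <- if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "bin_scheme"))
    extra <- setdiff(unique(b), scheme$labels)
    if (length(extra) > 0L) {
      stop("bin label(s) not in scheme: ", paste(extra, collapse = ", "), call. = FALSE)
    }
    scheme$labels
  } else {
    sort(unique(b))
  }
  out <- data.frame(bin = labels, n = 0L, mean_fc = NA_real_, sem = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    x <- v[b == labels[i]]
    n <- length(x)
    out$n[i] <- n
    if (n >= 1L) out$mean_fc[i] <- mean(x)
    if (n >= 2L) out$sem[i] <- stats::sd(x) / sqrt(n)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via
#' `stats::cor(method = "spearman")`. Requires at least 3 finite pairs; a
#' constant vector yields an undefined (`NA`) coefficient with a flag.
#'
#' @param x,y Paired numeric vectors.
#' @param basis Label recording whether the pairs are individual genes or
#'   bin summaries (`"individual"` or `"binned"`).
#' @return List with `r`, `n`, `basis`, `flag` (`NA` when clean).
#' @export
spearman_r <- function(x, y, basis = c("individual", "binned")) {
  basis <- match.arg(basis)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 finite pairs for a reported correlation", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = n, basis = basis, flag = "constant_vector"))
  }
  list(r = stats::cor(x, y, method = "spearman"), n = n, basis = basis,
       flag = NA_character_)
}

#' Binned Spearman correlation of a gene quantity against a percentage
#'
#' The binned variant the composition analysis relies on: genes are binned
#' by their class percentage, per-bin means are computed, and Spearman's r
#' is taken between the bin midpoints and the bin means over non-empty
#' bins.
#'
#' @param values Named numeric vector, gene -> value (e.g. SILAC `log2_fc`
#'   or `delta_log2_te`).
#' @param pct Named numeric vector, gene -> class percentage in \[0, 100\].
#' @param scheme A [bin_scheme()] (default fine deciles).
#' @param min_bins Minimum number of non-empty bins required (default 3).
#' @return List with `r`, `n` (bins used), `basis = "binned"`, `flag`, and
#'   the `bin_summary` data frame.
#' @export
binned_spearman <- function(values, pct, scheme = ser_bin_scheme("fine"), min_bins = 3L) {
  bins <- stats::setNames(assign_bin(pct, scheme), names(pct))
  summary <- bin_average(values, bins, scheme = scheme)
  mids <- bin_midpoints(scheme)
  use <- summary$n > 0L
  if (sum(use) < min_bins) {
    stop("fewer than ", min_bins, " non-empty bins", call. = FALSE)
  }
  res <- spearman_r(mids[summary$bin[use]], summary$mean_fc[use], basis = "binned")
  res$bin_summary <- summary
  res
}

#' Quadratic trend over bin summaries
#'
#' Ordinary least-squares quadratic `y ~ x + x^2` over retained bins, with
#' explicit bin-label exclusion standing in for outlier removal (the
#' highest-percentage bin is typically the outlier in these analyses, being
#' populated by short, serine-poor CDSs).
#'
#' @param bin_midpoints Numeric x values (typically [bin_midpoints()] of
#'   the scheme), named by bin label when `exclude_bins` is used.
#' @param bin_means Numeric y values, same length/order.
#' @param exclude_bins Character vector of bin labels to exclude.
#' @return List with `coefficients` (`intercept`, `linear`, `quadratic`),
#'   `excluded` labels, `n_used`, and the underlying `stats::lm` fit.
#' @export
fit_trend <- function(bin_midpoints, bin_means, exclude_bins = character(0)) {
  stopifnot(length(bin_midpoints) == length(bin_means))
  keep <- rep(TRUE, length(bin_midpoints))
  if (length(exclude_bins) > 0L) {
    if (is.null(names(bin_midpoints))) {
      stop("bin_midpoints must be named to use exclude_bins", call. = FALSE)
    }
    keep <- !(names(bin_midpoints) %in% exclude_bins)
  }
  keep <- keep & is.finite(bin_midpoints) & is.finite(bin_means)
  x <- as.numeric(bin_midpoints[keep])
  y <- as.numeric(bin_means[keep])
  if (length(x) < 3L) {
    stop("fewer than 3 points retained; refusing to fit a quadratic", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  list(
    coefficients = c(intercept = unname(cf[1]), linear = unname(cf[2]),
                     quadratic = unname(cf[3])),
    excluded = exclude_bins,
    n_used = length(x),
    fit = fit
  )
}

#' Two-stage Benjamini-Hochberg adjusted p-values
#'
#' The two-stage step-up FDR procedure: a first-stage linear step-up at
#' level `alpha / (1 + alpha)` estimates the number of true nulls
#' `m0 = max(m - r1, 1)` (floored at 1 so a fully rejected first stage
#' degenerates gracefully and a single p-value adjusts to itself), and the
#' final adjusted values are the ordinary BH step-up values rescaled by
#' `m0 / m` and capped at 1 (so they remain monotone non-decreasing in
#' rank order). With `two_stage = FALSE` this is plain BH.
#'
#' @param p P-values in \[0, 1\].
#' @param alpha Target FDR level used by the first stage (default 0.05).
#' @param two_stage Apply the two-stage m0 estimate (default `TRUE`).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, alpha = 0.05, two_stage = TRUE) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  padj <- stats::p.adjust(p, method = "BH")
  if (!two_stage || m == 0L) {
    return(padj)
  }
  alpha1 <- alpha / (1 + alpha)
  r1 <- sum(padj <= alpha1)
  m0 <- max(m - r1, 1L)
  pmin(1, padj * m0 / m)
}
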