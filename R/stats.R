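# Metagene aggregation, windowed coverage, log2 fold changes, the
# rank-sum (two-sample Wilcoxon / Mann-Whitney) test, replicate PCA and
# qPCR fold enrichment.

#' Metagene profile of a site group
#'
#' Column-wise arithmetic mean of the flank matrix over the selected
#' rows, with the standard error of the mean (sample SD / sqrt(n)).
#'
#' @param matrix A `flank_matrix`.
#' @param site_subset Character vector of site ids (default: all rows).
#' @param label Group label carried into the result.
#' @return `data.frame` with `offset` (bp, bin start relative to anchor),
#'   `mean`, `sem`, `group`, `n_sites`.
#' @export
metagene_profile <- function(matrix, site_subset = NULL, label = "all") {
  stopifnot(inherits(matrix, "flank_matrix"))
  if (is.null(site_subset)) site_subset <- matrix$site_ids
  if (!length(site_subset)) stop("empty site subset")
  sub <- subset_sites(matrix, site_subset)
  v <- sub$values
  n <- nrow(v)
  mu <- colMeans(v)
  sem <- if (n > 1) apply(v, 2, stats::sd) / sqrt(n) else rep(0, ncol(v))
  data.frame(offset = bin_offsets(matrix$flank, matrix$bin_size),
             mean = mu, sem = sem, group = label, n_sites = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# bin selection for a signed window [center - width/2, center + width/2)
window_bins <- function(fm, center_offset, width) {
  lo <- center_offset - width / 2
  hi <- center_offset + width / 2
  if (lo < -fm$flank || hi > fm$flank)
    stop(sprintf("window [%g, %g) outside the +/-%d bp flank",
                 lo, hi, fm$flank))
  off <- bin_offsets(fm$flank, fm$bin_size)
  which(off >= lo & off < hi)
}

#' Per-site windowed coverage
#'
#' Sums flank-matrix bin values over a signed window relative to the
#' anchor — e.g. `center_offset = 0, width = 500` gives the DSB-centred
#' 500 bp quantity used for box plots, and offsets 1000/2000/3000 the
#' distance-resolved variant.
#'
#' @param matrix A `flank_matrix`.
#' @param center_offset Signed centre of the window, bp from the anchor.
#' @param width Window width in bp.
#' @return Named numeric vector of per-site sums.
#' @export
window_coverage <- function(matrix, center_offset = 0, width = 500) {
  stopifnot(inherits(matrix, "flank_matrix"))
  bins <- window_bins(matrix, center_offset, width)
  stats::setNames(rowSums(matrix$values[, bins, drop = FALSE]),
                  matrix$site_ids)
}

#' Windowed log2 fold changes between condition and control
#'
#' Per site, `log2((W_cond + pseudocount) / (W_ctrl + pseudocount))`
#' where `W` is [window_coverage()]. Sites with zero coverage in both
#' matrices are flagged (`zero_both`) for exclusion from downstream tests.
#'
#' @param cond,ctrl `flank_matrix` objects sharing sites and shape.
#' @param center_offset,width Window as in [window_coverage()].
#' @param pseudocount Added to both windowed coverages (CPM; default 0.01).
#' @return `data.frame` with `site_id`, `cov_cond`, `cov_ctrl`, `log2fc`,
#'   `zero_both`; attributes record the window and pseudocount.
#' @export
log2_fold_change <- function(cond, ctrl, center_offset = 0, width = 500,
                             pseudocount = 0.01) {
  stopifnot(inherits(cond, "flank_matrix"), inherits(ctrl, "flank_matrix"))
  if (!identical(cond$site_ids, ctrl$site_ids) ||
      !all(dim(cond$values) == dim(ctrl$values)) ||
      cond$flank != ctrl$flank || cond$bin_size != ctrl$bin_size)
    stop("condition and control matrices do not share sites/shape")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  w_cond <- window_coverage(cond, center_offset, width)
  w_ctrl <- window_coverage(ctrl, center_offset, width)
  res <- data.frame(site_id = cond$site_ids,
                    cov_cond = unname(w_cond), cov_ctrl = unname(w_ctrl),
                    log2fc = log2((w_cond + pseudocount) /
                                  (w_ctrl + pseudocount)),
                    zero_both = w_cond == 0 & w_ctrl == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "window") <- c(center_offset = center_offset, width = width)
  attr(res, "pseudocount") <- pseudocount
  res
}

#' Two-sample rank-sum (Mann-Whitney / Wilcoxon) test
#'
#' Computes the Mann-Whitney U statistic for `x` via midranks. The
#' p-value is exact (full enumeration of all label assignments) when
#' `n + m <= 12` and there are no ties; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (`"greater"`: `x` tends larger than `y`).
#' @param exact_limit Largest `n + m` for which the exact branch is used
#'   (default 12).
#' @return List of class `rank_sum_result`: `U`, `p_value`, `method`
#'   (`"exact"` or `"normal-approximation"`), `n`, `m`, `alternative`.
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "less", "greater"),
                          exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && N <= exact_limit) {
    method <- "exact"
    # enumerate all C(N, n) assignments of ranks to the x-labelled sample
    combs <- utils::combn(N, n)
    u_all <- colSums(matrix(seq_len(N)[combs], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - n * m / 2) >= abs(U - n * m / 2)),
      greater = mean(u_all >= U),
      less = mean(u_all <= U))
  } else {
    method <- "normal-approximation"
    mu <- n * m / 2
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      cc <- function(d) sign(d) * min(abs(d), 0.5)  # continuity correction
      z <- switch(alternative,
        two.sided = (U - mu - cc(U - mu)) / sigma,
        greater = (U - mu - 0.5) / sigma,
        less = (U - mu + 0.5) / sigma)
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm(-abs(z)),
        greater = stats::pnorm(z, lower.tail = FALSE),
        less = stats::pnorm(z))
      p <- min(1, p)
    }
  }
  structure(list(U = U, p_value = p, method = method, n = n, m = m,
                 alternative = alternative),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): U = %g (n = %d, m = %d), p = %.4g [%s]\n",
              x$alternative, x$U, x$n, x$m, x$p_value, x$method))
  invisible(x)
}

#' PCA of sample replicates over per-site coverage
#'
#' Samples are observations, per-site coverages features. Features are
#' centred (not scaled) before the eigendecomposition; constant features
#' are dropped with a warning. The sign of each component is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param per_site_coverage Numeric matrix, sites x samples (column names
#'   are sample labels).
#' @return List of class `pca_result`: `coords` (samples x PCs),
#'   `explained` (variance fractions, non-increasing), `loadings`.
#' @export
pca_samples <- function(per_site_coverage) {
  m <- as.matrix(per_site_coverage)
  if (ncol(m) < 2) stop("need >= 2 samples")
  if (nrow(m) < 2) stop("need >= 2 sites")
  x <- t(m)                                 # samples as observations
  const <- apply(x, 2, function(v) max(v) == min(v))
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s)", sum(const)))
    x <- x[, !const, drop = FALSE]
  }
  if (!ncol(x)) stop("no non-constant features")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = coords, explained = explained,
                 loadings = loadings),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$coords), 100 * x$explained[1],
              100 * ifelse(length(x$explained) > 1, x$explained[2], 0)))
  invisible(x)
}

#' qPCR fold enrichment by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_IP - Ct_target_input) - (Ct_ref_IP - Ct_ref_input)`;
#' the returned enrichment is `2^(-ddCt)`.
#'
#' @param ct_target_ip,ct_target_input,ct_ref_ip,ct_ref_input Finite
#'   cycle-threshold values (vectorised).
#' @return Numeric fold enrichment.
#' @export
fold_enrichment_ddct <- function(ct_target_ip, ct_target_input,
                                 ct_ref_ip, ct_ref_input) {
  vals <- c(ct_target_ip, ct_target_input, ct_ref_ip, ct_ref_input)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_target_ip - ct_target_input) - (ct_ref_ip - ct_ref_input)
  2^(-ddct)
}
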