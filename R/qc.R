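# Multi-layered volume quality control: robust intensity screening before
# normalization, PCA + Mahalanobis and Isolation Forest on normalized scans,
# each applied separately within every biomarker subgroup.

robust_z <- function(x) {
  med <- stats::median(x)
  mad <- stats::mad(x)
  if (mad == 0) return(rep(0, length(x)))
  (x - med) / mad
}

#' Intensity-based outlier screening
#'
#' Flags scans whose global mean intensity, intensity SD, or standardized
#' intensity extremes diverge from the sample by more than `z_thresh` robust
#' z-scores (median/MAD). With zero spread (e.g., identical volumes) no scan
#' is flagged.
#'
#' @param x Matrix of flattened volumes (one scan per row).
#' @param z_thresh Robust z-score threshold (default 3).
#' @return Data frame: per-scan mean/SD robust z-scores, extreme-intensity
#'   score, and the `flag` column.
#' @export
intensity_outliers <- function(x, z_thresh = 3) {
  if (nrow(x) < 3L) stop("need at least 3 volumes for robust statistics")
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  zm <- robust_z(m); zs <- robust_z(s)
  # standardized-intensity extremes: fraction of a scan's voxels lying
  # beyond 2 * z_thresh pooled SDs (6 SD at the default threshold); under a
  # roughly Gaussian intensity model this is essentially zero for clean scans
  mu <- mean(x); sd_all <- stats::sd(as.vector(x))
  extreme_frac <- if (sd_all > 0 && is.finite(z_thresh)) {
    rowMeans(abs(x - mu) / sd_all > 2 * z_thresh)
  } else rep(0, nrow(x))
  data.frame(mean_z = zm, sd_z = zs, extreme_frac = extreme_frac,
             flag = abs(zm) > z_thresh | abs(zs) > z_thresh |
               extreme_frac > 0.01)
}

#' PCA + Mahalanobis outlier detection
#'
#' Projects flattened (normalized) volumes onto the principal components
#' capturing `variance_retained` of the variance and flags scans whose
#' squared Mahalanobis distance in component space exceeds the chi-square
#' quantile with k degrees of freedom.
#'
#' @param x Matrix of flattened volumes (one scan per row).
#' @param variance_retained Fraction of variance the retained components must
#'   capture (default 0.95).
#' @param chi2_quantile Chi-square quantile for the flag cut (default 0.999).
#' @return Data frame with squared distances `md2`, the number of retained
#'   components `k` (as an attribute), and `flag`.
#' @export
pca_mahalanobis_outliers <- function(x, variance_retained = 0.95,
                                     chi2_quantile = 0.999) {
  n <- nrow(x)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  pos <- ev > 1e-12 * ev[1]
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  k <- which(cum >= variance_retained)[1]
  if (is.na(k)) k <- sum(pos)
  if (n < k + 2L) stop("need n >= k + 2 scans for ", k, " components")
  scores <- p$x[, seq_len(k), drop = FALSE]
  lam <- ev[seq_len(k)]
  # diagonal loading guards against numerically singular directions
  tiny <- lam < 1e-10 * max(lam)
  if (any(tiny)) {
    warning("near-singular covariance; applying diagonal loading")
    lam <- lam + 1e-10 * max(lam)
  }
  md2 <- rowSums(sweep(scores^2, 2, lam, "/"))
  cut <- stats::qchisq(chi2_quantile, df = k)
  res <- data.frame(md2 = md2, flag = md2 > cut)
  attr(res, "k") <- k
  attr(res, "cut") <- cut
  res
}

#' Isolation-forest outlier detection on PCA scores
#'
#' Scores scans with an isolation forest on the same principal-component
#' representation as the Mahalanobis stage and flags the
#' `ceiling(contamination * n)` most isolable scans. Deterministic given the
#' seed.
#'
#' @param x Matrix of flattened volumes (one scan per row).
#' @param contamination Fraction of scans to flag, in (0, 0.5].
#' @param seed Integer seed.
#' @param variance_retained Variance fraction for the PCA feature space.
#' @return Data frame with anomaly `score` and `flag`.
#' @export
isoforest_outliers <- function(x, contamination = 0.02, seed = 1L,
                               variance_retained = 0.95) {
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 volumes")
  if (contamination <= 0 || contamination > 0.5) {
    stop("contamination must be in (0, 0.5]")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- max(which(cum >= variance_retained)[1], 2L, na.rm = TRUE)
  k <- min(k, ncol(p$x))
  feats <- p$x[, seq_len(k), drop = FALSE]
  score <- isolation_forest_score(feats, seed = seed)
  n_flag <- ceiling(contamination * n)
  cut_rank <- n - n_flag
  ord <- order(score, seq_len(n))  # deterministic tie-break by row index
  flag <- logical(n)
  flag[ord[(cut_rank + 1L):n]] <- TRUE
  data.frame(score = score, flag = flag)
}

#' Run the full multi-layered QC within subgroups
#'
#' Applies the three detectors independently within each subgroup (the CU
#' reference counts as one stratum); a scan flagged by any stage is marked
#' for manual review. Subgroups smaller than `min_n` are skipped with a
#' warning.
#'
#' @param meta Data frame with `scan_id` and `group` columns, one row per
#'   scan, aligned to `x`.
#' @param x Matrix of flattened volumes.
#' @param z_thresh,variance_retained,chi2_quantile,contamination Stage
#'   parameters.
#' @param seed Integer seed (isolation forest).
#' @param min_n Minimum subgroup size to run QC.
#' @return A `qc_report` data frame: one row per scan with per-stage scores
#'   and flags, the subgroup, and `review` (union of flags).
#' @export
run_qc <- function(meta, x, z_thresh = 3, variance_retained = 0.95,
                   chi2_quantile = 0.999, contamination = 0.02, seed = 1L,
                   min_n = 10L) {
  stopifnot(nrow(meta) == nrow(x), all(c("scan_id", "group") %in% names(meta)))
  out <- data.frame(scan_id = meta$scan_id, group = meta$group,
                    intensity_flag = NA, mahalanobis_flag = NA,
                    isoforest_flag = NA, mean_z = NA_real_, sd_z = NA_real_,
                    md2 = NA_real_, iso_score = NA_real_, review = NA,
                    stringsAsFactors = FALSE)
  for (g in unique(meta$group)) {
    rows <- which(meta$group == g)
    if (length(rows) < min_n) {
      warning("subgroup ", g, " has fewer than ", min_n, " scans; skipped")
      next
    }
    xg <- x[rows, , drop = FALSE]
    it <- intensity_outliers(xg, z_thresh)
    mh <- pca_mahalanobis_outliers(xg, variance_retained, chi2_quantile)
    isf <- isoforest_outliers(xg, contamination, seed, variance_retained)
    out$intensity_flag[rows] <- it$flag
    out$mean_z[rows] <- it$mean_z
    out$sd_z[rows] <- it$sd_z
    out$mahalanobis_flag[rows] <- mh$flag
    out$md2[rows] <- mh$md2
    out$isoforest_flag[rows] <- isf$flag
    out$iso_score[rows] <- isf$score
    out$review[rows] <- it$flag | mh$flag | isf$flag
  }
  class(out) <- c("qc_report", "data.frame")
  out
}
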