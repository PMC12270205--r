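# Biomarker subgroup classification, one-scan-per-subject selection,
# age-stratified splitting, and split balance checks.

#' Classify a record into an AD/LB pathology subgroup
#'
#' AD positivity is defined by the CSF p-tau181/Abeta42 ratio at or above the
#' threshold (default 0.021; the boundary value itself counts as positive);
#' LB positivity by a positive alpha-synuclein seed amplification assay
#' (SAA). Records with an intermediate SAA readout are excluded regardless of
#' the ratio; records with a missing biomarker are excluded with a reason
#' code.
#'
#' @param ptau181 CSF p-tau181 concentration.
#' @param abeta42 CSF Abeta42 concentration (must be positive).
#' @param saa SAA status: "positive", "negative", or "intermediate".
#' @param threshold AD-positivity threshold on the ratio.
#' @return Character vector over `AD-LB-`, `AD-LB+`, `AD+LB-`, `AD+LB+`,
#'   `excluded`, with an attribute `reason` for excluded records.
#' @export
classify_subgroup <- function(ptau181, abeta42, saa, threshold = 0.021) {
  n <- max(length(ptau181), length(abeta42), length(saa))
  ptau181 <- rep_len(ptau181, n); abeta42 <- rep_len(abeta42, n)
  saa <- rep_len(saa, n)
  if (any(!is.na(abeta42) & abeta42 <= 0)) {
    stop("abeta42 must be positive")
  }
  bad_saa <- !saa %in% c("positive", "negative", "intermediate") & !is.na(saa)
  if (any(bad_saa)) stop("unknown SAA status: ", saa[which(bad_saa)[1]])
  out <- character(n); reason <- rep(NA_character_, n)
  missing <- is.na(ptau181) | is.na(abeta42) | is.na(saa)
  out[missing] <- "excluded"; reason[missing] <- "missing_biomarker"
  inter <- !missing & saa == "intermediate"
  out[inter] <- "excluded"; reason[inter] <- "intermediate_saa"
  ok <- !missing & !inter
  ad <- ifelse(ptau181[ok] / abeta42[ok] >= threshold, "AD+", "AD-")
  lb <- ifelse(saa[ok] == "positive", "LB+", "LB-")
  out[ok] <- paste0(ad, lb)
  structure(out, reason = reason)
}

#' Select each subject's first scan
#'
#' Retains the earliest-dated scan per subject; date ties are broken by
#' lexicographic scan ID.
#'
#' @param scans Data frame with columns `subject_id`, `scan_id`, and `date`
#'   (sortable: Date, numeric, or comparable character).
#' @return The input rows restricted to one scan per subject.
#' @export
select_first_scan <- function(scans) {
  stopifnot(all(c("subject_id", "scan_id", "date") %in% names(scans)))
  if (anyNA(scans$date)) stop("missing scan dates; supply a visit order")
  ord <- order(scans$subject_id, scans$date, scans$scan_id)
  s <- scans[ord, , drop = FALSE]
  s[!duplicated(s$subject_id), , drop = FALSE]
}

# Largest-remainder allocation of n_bin records per bin to splits, matching
# exact global targets: start from floor(n_bin * fraction), then hand out the
# remaining units by descending fractional remainder, respecting how many
# each bin and each split still needs.
allocate_counts <- function(bin_sizes, targets) {
  n_bins <- length(bin_sizes); n_splits <- length(targets)
  frac <- targets / sum(targets)
  ideal <- outer(bin_sizes, frac)
  alloc <- floor(ideal)
  # never allocate more to a split than its global target
  for (s in seq_len(n_splits)) {
    while (sum(alloc[, s]) > targets[s]) {
      i <- which.max(alloc[, s] - ideal[, s])
      alloc[i, s] <- alloc[i, s] - 1
    }
  }
  rem_bin <- bin_sizes - rowSums(alloc)
  rem_split <- targets - colSums(alloc)
  rmd <- ideal - alloc
  while (sum(rem_bin) > 0) {
    cand <- which(rem_bin > 0)
    best <- NULL; best_v <- -Inf
    for (i in cand) for (s in which(rem_split > 0)) {
      if (rmd[i, s] > best_v) { best_v <- rmd[i, s]; best <- c(i, s) }
    }
    if (is.null(best)) stop("allocation failed: no split accepts more records")
    alloc[best[1], best[2]] <- alloc[best[1], best[2]] + 1
    rmd[best[1], best[2]] <- rmd[best[1], best[2]] - 1
    rem_bin[best[1]] <- rem_bin[best[1]] - 1
    rem_split[best[2]] <- rem_split[best[2]] - 1
  }
  alloc
}

#' Age-stratified train/validation/test split
#'
#' Discretizes age into bins of `bin_width` years, then assigns records to
#' splits so that (a) global split sizes are exactly `train = round(f1 * N)`,
#' `validation = floor(f2 * N)`, `test = N - train - validation`, and (b)
#' within-bin allocations follow floor plus largest-remainder, shuffled with
#' the given seed. For N = 4,355 at the default fractions this yields
#' (3,484, 435, 436).
#'
#' @param table Data frame with an `age` column (years).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param bin_width Age bin width in years.
#' @param seed Integer seed for within-bin shuffling.
#' @return A list of class `split_assignment`: `split` (factor over train/
#'   validation/test, aligned to the input rows), `counts`, `bin_edges`,
#'   `seed`.
#' @export
stratified_split <- function(table, fractions = c(0.8, 0.1, 0.1),
                             bin_width = 5, seed = 1L) {
  stopifnot(is.data.frame(table), "age" %in% names(table),
            length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0), bin_width > 0)
  age <- table$age
  if (anyNA(age)) stop("every record needs an age")
  n <- length(age)
  labels <- c("train", "validation", "test")
  if (n == 0L) {
    return(structure(list(split = factor(character(), levels = labels),
                          counts = stats::setNames(c(0L, 0L, 0L), labels),
                          bin_edges = numeric(), seed = seed),
                     class = "split_assignment"))
  }
  n_train <- round(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  targets <- c(n_train, n_val, n_test)
  lo <- floor(min(age) / bin_width) * bin_width
  hi <- ceiling((max(age) + 1e-9) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2L) edges <- c(lo, lo + bin_width)
  bin <- cut(age, breaks = edges, include.lowest = TRUE, right = FALSE)
  bin_sizes <- as.integer(table(bin))
  keep <- bin_sizes > 0
  alloc <- allocate_counts(bin_sizes[keep], targets)
  split <- character(n)
  bins_used <- levels(bin)[keep]
  with_seed(seed, {
    for (bi in seq_along(bins_used)) {
      rows <- which(bin == bins_used[bi])
      rows <- rows[sample.int(length(rows))]
      lab <- rep(labels, times = alloc[bi, ])
      split[rows] <- lab
    }
  })
  structure(list(split = factor(split, levels = labels),
                 counts = stats::setNames(as.integer(targets), labels),
                 bin_edges = edges, seed = seed),
            class = "split_assignment")
}

#' Check demographic balance across splits
#'
#' One-way ANOVA of age across splits and a chi-square test of sex by split,
#' mirroring the balance checks run before model training.
#'
#' @param split A [stratified_split()] result (or a factor of split labels).
#' @param table Data frame with `age` and `sex` columns aligned to the split.
#' @return List with `age_anova` (F, p) and `sex_chisq` (statistic, p).
#' @export
balance_check <- function(split, table) {
  s <- if (inherits(split, "split_assignment")) split$split else factor(split)
  stopifnot(length(s) == nrow(table))
  keep <- !is.na(s)
  s <- droplevels(s[keep]); tab <- table[keep, , drop = FALSE]
  if (nlevels(s) < 2L) stop("need at least 2 non-empty splits")
  age_res <- NULL
  if (min(table(s)) >= 2L) {
    fit <- stats::aov(tab$age ~ s)
    a <- summary(fit)[[1]]
    age_res <- list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
  } else {
    warning("a split has fewer than 2 records; age ANOVA skipped")
  }
  sex_res <- NULL
  if ("sex" %in% names(tab)) {
    ct <- table(tab$sex, s)
    chi <- suppressWarnings(stats::chisq.test(ct))
    sex_res <- list(statistic = unname(chi$statistic), p = chi$p.value)
  }
  list(age_anova = age_res, sex_chisq = sex_res)
}
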