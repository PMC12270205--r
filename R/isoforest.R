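# Isolation Forest (Liu, Ting & Zhou) on a numeric feature matrix. No
# installed package provides this detector, so it is implemented here:
# random axis-parallel splits isolate anomalies in short paths; the anomaly
# score is 2^(-E[h(x)] / c(n)) with c(n) the average unsuccessful-search
# path length of a binary search tree.

avg_path_length <- function(n) {
  ifelse(n > 2, 2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n,
         ifelse(n == 2, 1, 0))
}

grow_itree <- function(x, idx, depth, max_depth) {
  n <- length(idx)
  if (depth >= max_depth || n <= 1L) {
    return(list(leaf = TRUE, size = n))
  }
  spread <- apply(x[idx, , drop = FALSE], 2, function(v) diff(range(v)))
  usable <- which(spread > 0)
  if (!length(usable)) return(list(leaf = TRUE, size = n))
  f <- if (length(usable) == 1L) usable else sample(usable, 1L)
  v <- x[idx, f]
  sp <- stats::runif(1, min(v), max(v))
  left <- idx[v < sp]; right <- idx[v >= sp]
  if (!length(left) || !length(right)) return(list(leaf = TRUE, size = n))
  list(leaf = FALSE, feature = f, split = sp,
       left = grow_itree(x, left, depth + 1L, max_depth),
       right = grow_itree(x, right, depth + 1L, max_depth))
}

itree_depth <- function(tree, x_row, depth = 0) {
  if (tree$leaf) return(depth + avg_path_length(tree$size))
  if (x_row[tree$feature] < tree$split) {
    itree_depth(tree$left, x_row, depth + 1)
  } else {
    itree_depth(tree$right, x_row, depth + 1)
  }
}

#' Isolation-forest anomaly scores
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param n_trees Number of isolation trees.
#' @param sample_size Sub-sample size per tree.
#' @param seed Integer seed; scores are deterministic given the seed.
#' @return Numeric anomaly scores in (0, 1); larger = more isolable.
#' @export
isolation_forest_score <- function(x, n_trees = 100L, sample_size = 256L,
                                   seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(sample_size, n)
  max_depth <- ceiling(log2(max(psi, 2)))
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      idx <- sample.int(n, psi)
      grow_itree(x, idx, 0L, max_depth)
    })
    depths <- vapply(seq_len(n), function(i) {
      mean(vapply(trees, itree_depth, numeric(1), x_row = x[i, ]))
    }, numeric(1))
    2^(-depths / avg_path_length(psi))
  })
}
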