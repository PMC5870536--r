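# Correlated mutation analysis: mutual information between alignment columns,
# the average-product correction (MIp), Z-scores over all column pairs, and
# selection of highly correlated pairs.
#
# Conventions (documented prominently): natural logarithm throughout; the
# symbol alphabet at a column is exactly the set of symbols observed there
# (amino acids and the gap both count); frequencies are unsmoothed; Z-scores
# standardize with the population SD over all pairs.

#' Mutual information between two alignment columns
#'
#' \eqn{MI(i,j) = \sum_X \sum_Y p_{ij}(X,Y) \log[p_{ij}(X,Y) /
#' (p_i(X) p_j(Y))]} over the symbols observed at each column (gap included),
#' with unsmoothed empirical frequencies, natural log, and `0 log 0` terms
#' skipped.
#'
#' @param column_i,column_j Character vectors of single symbols, equal length
#'   `>= 2`.
#' @return Non-negative numeric MI in nats.
#' @examples
#' mutual_information(c("A", "A", "R", "R"), c("D", "D", "E", "E"))  # log(2)
#' @export
mutual_information <- function(column_i, column_j) {
  if (length(column_i) != length(column_j)) {
    abort("columns differ in length")
  }
  stopifnot(length(column_i) >= 2L)
  n <- length(column_i)
  joint <- table(column_i, column_j) / n
  pi_ <- rowSums(joint)
  pj <- colSums(joint)
  terms <- joint * log(joint / outer(pi_, pj))
  sum(terms[joint > 0])
}

#' Mutual-information matrix over all column pairs of an alignment
#'
#' Computes `MI(i, j)` for every pair of columns at once via the entropy
#' identity `MI = H_i + H_j - H_ij`; equals [mutual_information()] applied
#' pairwise.
#'
#' @param alignment A [ppap_alignment] (typically the `alignment` element of
#'   a [filter_columns()] result).
#' @return Symmetric `n_cols x n_cols` matrix with zero diagonal.
#' @export
mi_matrix <- function(alignment) {
  mat <- alignment$mat
  n <- nrow(mat)
  p <- ncol(mat)
  stopifnot(n >= 2L, p >= 2L)
  syms <- sort(unique(as.vector(mat)))
  ind <- lapply(syms, function(s) (mat == s) * 1)
  # column entropies
  cnt <- vapply(ind, colSums, numeric(p))          # p x n_syms
  pr <- cnt / n
  H <- -rowSums(ifelse(pr > 0, pr * log(pr), 0))
  # joint entropies over all pairs
  Hj <- matrix(0, p, p)
  for (a in seq_along(syms)) {
    for (b in seq_along(syms)) {
      nab <- crossprod(ind[[a]], ind[[b]])          # p x p joint counts
      pos <- nab > 0
      if (any(pos)) {
        pab <- nab[pos] / n
        tmp <- matrix(0, p, p)
        tmp[pos] <- -pab * log(pab)
        Hj <- Hj + tmp
      }
    }
  }
  mi <- outer(H, H, "+") - Hj
  mi <- (mi + t(mi)) / 2
  mi[mi < 0] <- 0  # guard against rounding at ~1e-15
  diag(mi) <- 0
  mi
}

#' Average-product correction of an MI matrix
#'
#' `MIp(i,j) = MI(i,j) - APC(i,j)` with
#' `APC(i,j) = mean_i * mean_j / overall_mean`, where `mean_i` is the mean MI
#' of column `i` against all other columns and `overall_mean` the mean MI
#' over all pairs. The correction removes the shared background (phylogeny,
#' column entropy) component of raw MI.
#'
#' @param mi Symmetric non-negative MI matrix with at least 3 columns.
#' @return A `pair_statistics` object: list with `n_cols`, `mi`, `mip`,
#'   `row_means`, `overall_mean`.
#' @export
compute_mip <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi), nrow(mi) >= 3L)
  if (any(mi < 0)) abort("MI matrix must be non-negative")
  if (max(abs(mi - t(mi))) > 1e-8) abort("MI matrix must be symmetric")
  n <- nrow(mi)
  mi0 <- mi
  diag(mi0) <- 0
  row_means <- rowSums(mi0) / (n - 1)
  overall_mean <- sum(mi0) / (n * (n - 1))
  if (overall_mean == 0) {
    abort("overall mean MI is zero; no signal to correct")
  }
  apc <- outer(row_means, row_means) / overall_mean
  mip <- mi0 - apc
  diag(mip) <- 0
  structure(list(n_cols = n, mi = mi0, mip = mip, row_means = row_means,
                 overall_mean = overall_mean),
            class = "pair_statistics")
}

#' @export
print.pair_statistics <- function(x, ...) {
  cat("<pair_statistics> ", x$n_cols, " columns, mean MI ",
      signif(x$overall_mean, 4), "\n", sep = "")
  invisible(x)
}

#' Z-scores of MIp over all column pairs
#'
#' `Z(i,j) = (MIp(i,j) - mu) / SD` where `mu` and `SD` are the mean and
#' population standard deviation of MIp over all pairs `i < j`.
#'
#' @param pair_statistics A [compute_mip()] result.
#' @return Symmetric matrix of Z values (diagonal `NA`), with `mu` and `sd`
#'   attached as attributes.
#' @export
pair_zscores <- function(pair_statistics) {
  mip <- pair_statistics$mip
  vals <- mip[upper.tri(mip)]
  stopifnot(length(vals) >= 2L)
  mu <- mean(vals)
  sd_pop <- sqrt(mean((vals - mu)^2))
  if (sd_pop == 0) abort("MIp is constant over all pairs; Z-scores undefined")
  z <- (mip - mu) / sd_pop
  diag(z) <- NA_real_
  attr(z, "mu") <- mu
  attr(z, "sd") <- sd_pop
  z
}

#' Select highly correlated column pairs
#'
#' Keeps every pair `(i, j)`, `i < j`, whose MIp Z-score exceeds the
#' threshold (default 3.0).
#'
#' @param pair_statistics A [compute_mip()] result.
#' @param threshold Z-score cutoff; pairs with `Z > threshold` are selected.
#' @return A `pair_selection`: tibble with columns `i`, `j`, `mi`, `mip`,
#'   `z` (in the coordinates of the analysed alignment), plus attributes
#'   `threshold`, `mu`, `sd` and `C` (the number of selected pairs).
#' @export
select_correlated_pairs <- function(pair_statistics, threshold = 3.0) {
  stopifnot(!is.na(threshold), threshold < Inf)  # -Inf selects every pair
  z <- pair_zscores(pair_statistics)
  ut <- upper.tri(z)
  hits <- which(ut & z > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    abort(paste0("no pair exceeds Z > ", threshold,
                 "; lower the threshold or review the alignment"))
  }
  sel <- tibble(i = as.integer(hits[, 1L]), j = as.integer(hits[, 2L]),
                mi = pair_statistics$mi[hits],
                mip = pair_statistics$mip[hits],
                z = z[hits]) |>
    arrange(.data$i, .data$j)
  attr(sel, "threshold") <- threshold
  attr(sel, "mu") <- attr(z, "mu")
  attr(sel, "sd") <- attr(z, "sd")
  attr(sel, "C") <- nrow(sel)
  class(sel) <- c("pair_selection", class(sel))
  sel
}
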