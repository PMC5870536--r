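# Correlation models: smoothed residue and residue-pair frequencies over the
# selected high-MIp column pairs of one reaction type, and the correlation
# score S_cor of an aligned query.

#' Additive-smoothing parameters
#'
#' The single-residue pseudocount weight is `alpha = 1/21` (21 symbols: 20
#' amino acids plus the gap) and the pair weight is
#' `beta = alpha^2 / (N + 2 * alpha * d_s)`, chosen so that a never-observed
#' pair of never-observed residues satisfies
#' `p_ij(X,Y) / (p_i(X) p_j(Y)) = 1` exactly and so contributes nothing to
#' the correlation score.
#'
#' @param N Number of training sequences (>= 1).
#' @return List with `alpha`, `beta`, `N`, `d_s = 21`, `d_p = 441`.
#' @examples
#' smoothing_params(10)
#' @export
smoothing_params <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1) {
    abort("N must be a single integer >= 1")
  }
  N <- as.integer(N)
  d_s <- 21L
  alpha <- 1 / 21
  beta <- alpha^2 / (N + 2 * alpha * d_s)
  list(alpha = alpha, beta = beta, N = N, d_s = d_s, d_p = d_s^2)
}

#' Build a correlation model for one reaction type
#'
#' Tabulates single-symbol counts `n_i(X)` at every filtered column and
#' pair counts `n_ij(X, Y)` at every selected pair, exactly from the
#' alignment rows. `X` (unknown residue) counts toward `N` but toward no
#' symbol class, so it always receives the pure pseudocount when scored.
#'
#' @param filtered_alignment A [filter_columns()] result for the reaction
#'   type's family alignment.
#' @param pair_selection A [select_correlated_pairs()] result computed on
#'   the same filtered alignment (coordinates are filtered-column indices).
#' @param reaction_type Optional label recorded on the model.
#' @return A `correlation_model` object.
#' @export
build_correlation_model <- function(filtered_alignment, pair_selection,
                                    reaction_type = NULL) {
  aln <- filtered_alignment$alignment
  mat <- aln$mat
  p <- ncol(mat)
  if (max(pair_selection$j) > p) {
    abort("pair selection indexes columns beyond the filtered alignment")
  }
  N <- nrow(mat)
  sm <- smoothing_params(N)
  single_counts <- matrix(0L, nrow = 21L, ncol = p,
                          dimnames = list(AA21, NULL))
  for (s in AA21) single_counts[s, ] <- as.integer(colSums(mat == s))
  # sparse pair counts: one named count vector entry per observed (pair, X, Y)
  keys <- character(0)
  vals <- integer(0)
  for (k in seq_len(nrow(pair_selection))) {
    xi <- mat[, pair_selection$i[k]]
    yj <- mat[, pair_selection$j[k]]
    tab <- table(paste0(k, ":", xi, yj))
    keys <- c(keys, names(tab))
    vals <- c(vals, as.integer(tab))
  }
  pair_counts <- setNames(vals, keys)
  rt <- reaction_type %||% aln$family_label
  structure(list(reaction_type = rt,
                 N = N,
                 kept_columns = filtered_alignment$kept_columns,
                 n_filtered_cols = p,
                 pairs = pair_selection,
                 single_counts = single_counts,
                 pair_counts = pair_counts,
                 smoothing = sm,
                 training_ids = aln_ids(aln),
                 provenance = provenance_stamp(aln_ids(aln))),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat("<correlation_model>", x$reaction_type %||% "(unlabelled)", "-",
      x$N, "sequences,", nrow(x$pairs), "selected pairs over",
      x$n_filtered_cols, "filtered columns\n")
  invisible(x)
}

#' Smoothed single or pair frequency from a correlation model
#'
#' `p_i(X) = (n_i(X) + alpha) / (N + alpha d_s)`;
#' `p_ij(X,Y) = (n_ij(X,Y) + beta) / (N + beta d_p)`. Symbols must belong to
#' the 21-letter alphabet (20 amino acids + gap); the unknown-residue symbol
#' `X` is accepted and treated as never observed.
#'
#' @param model A [build_correlation_model()] result.
#' @param i Filtered column index (for pairs, the index into the model's
#'   selected-pair table).
#' @param x,y Symbols; give `y` (and set `pair = TRUE`) for a pair frequency.
#' @param pair Query a pair frequency (`i` indexes the selected-pair table)?
#' @return Numeric frequency.
#' @export
smoothed_frequency <- function(model, i, x, y = NULL, pair = !is.null(y)) {
  sm <- model$smoothing
  check_symbol <- function(s) {
    if (!s %in% c(AA21, "X")) {
      abort(paste0("symbol '", s, "' is outside the 21-letter alphabet"))
    }
  }
  check_symbol(x)
  if (!pair) {
    n <- if (x == "X") 0L else unname(model$single_counts[x, i])
    return((n + sm$alpha) / (sm$N + sm$alpha * sm$d_s))
  }
  check_symbol(y)
  n <- if (x == "X" || y == "X") {
    0L
  } else {
    model$pair_counts[paste0(i, ":", x, y)]
  }
  n <- if (is.na(n)) 0L else unname(n)
  (n + sm$beta) / (sm$N + sm$beta * sm$d_p)
}

#' Correlation score of an aligned query
#'
#' \eqn{S_{cor} = (1/C) \sum_{(i,j) \in A} \log[p_{ij}(X_q, Y_q) /
#' (p_i(X_q) p_j(Y_q))]} over the model's selected pairs `A`, with smoothed
#' frequencies and natural log. `C = |A|` standardizes models with different
#' numbers of selected pairs. Residue pairs never seen in training, composed
#' of residues never seen in training, contribute exactly 0.
#'
#' @param model A [build_correlation_model()] result.
#' @param aligned_query_row The query's gapped row over the **original**
#'   columns of the model's family alignment (string or symbol vector), as
#'   produced by [add_query_to_alignment()]; it is projected onto the
#'   model's filtered columns internally.
#' @param projected Set `TRUE` if the row is already in filtered-column
#'   coordinates.
#' @return Numeric S_cor (nats).
#' @export
correlation_score <- function(model, aligned_query_row, projected = FALSE) {
  row <- if (length(aligned_query_row) > 1L) {
    aligned_query_row
  } else {
    chars(as.character(aligned_query_row))
  }
  if (!projected) {
    if (length(row) < max(model$kept_columns)) {
      abort(paste0("aligned query row has ", length(row), " columns; the ",
                   "model's column map needs at least ",
                   max(model$kept_columns)))
    }
    row <- row[model$kept_columns]
  } else if (length(row) != model$n_filtered_cols) {
    abort("projected query row does not match the filtered column count")
  }
  sm <- model$smoothing
  prs <- model$pairs
  xi <- row[prs$i]
  yj <- row[prs$j]
  bad <- !(xi %in% c(AA21, "X")) | !(yj %in% c(AA21, "X"))
  if (any(bad)) {
    abort(paste0("query symbols outside the alphabet at filtered columns: ",
                 paste(unique(c(prs$i[bad], prs$j[bad])), collapse = ", ")))
  }
  if (any(xi == "X" | yj == "X")) {
    inform("correlation_score: 'X' in query treated as an unobserved residue")
  }
  # single counts (X -> 0)
  ix <- match(xi, AA21)
  iy <- match(yj, AA21)
  ix[is.na(ix)] <- 1L
  iy[is.na(iy)] <- 1L
  n_i <- model$single_counts[cbind(ix, prs$i)]
  n_j <- model$single_counts[cbind(iy, prs$j)]
  n_i[xi == "X"] <- 0L
  n_j[yj == "X"] <- 0L
  # pair counts via sparse lookup (missing or X -> 0)
  key <- paste0(seq_len(nrow(prs)), ":", xi, yj)
  n_ij <- unname(model$pair_counts[key])
  n_ij[is.na(n_ij)] <- 0L
  n_ij[xi == "X" | yj == "X"] <- 0L
  p_i <- (n_i + sm$alpha) / (sm$N + sm$alpha * sm$d_s)
  p_j <- (n_j + sm$alpha) / (sm$N + sm$alpha * sm$d_s)
  p_ij <- (n_ij + sm$beta) / (sm$N + sm$beta * sm$d_p)
  sum(log(p_ij / (p_i * p_j))) / nrow(prs)
}
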