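# Aligning a query sequence into an existing family alignment.
#
# The adapter of choice is `mafft --add`, which is how family alignments are
# extended in practice. The builtin method is a profile-to-sequence global
# alignment with affine gaps (BLOSUM62, open 11, extend 1): it maps the query
# onto the existing columns without creating new ones, which keeps every
# stored model column valid. Query residues that would need a new column
# (insertions) are dropped with a message.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Per-column BLOSUM62 profile scores: n_cols x 20 matrix, entry (c, a) =
# mean BLOSUM62 score of residue a against the non-gap residues in column c.
profile_score_matrix <- function(aln) {
  bl <- blosum62_matrix()[AA20, AA20]
  mat <- aln$mat
  n_cols <- ncol(mat)
  counts <- matrix(0L, nrow = 20L, ncol = n_cols, dimnames = list(AA20, NULL))
  for (a in AA20) counts[a, ] <- colSums(mat == a)
  depth <- colSums(counts)
  depth[depth == 0L] <- 1L  # all-gap/X column: flat zero score
  sc <- t(crossprod(bl, counts)) / depth  # n_cols x 20
  colnames(sc) <- AA20
  sc
}

#' Add a query sequence to an existing alignment
#'
#' Aligns one query into a family alignment without disturbing the mutual
#' residue correspondences of the existing rows.
#'
#' With `method = "mafft"` the external `mafft --add` adapter is used and may
#' introduce new columns; these are then reconciled away (columns that are
#' all-gap across the original rows are dropped, see Details) so the result
#' has exactly the original columns. With `method = "builtin"` the query is
#' mapped onto the existing columns by a profile-to-sequence global alignment
#' with affine gaps (BLOSUM62, gap open 11, extend 1). `method = "auto"`
#' uses mafft when it is on the `PATH` and the builtin alignment otherwise.
#'
#' @details Column reconciliation: positions where the aligner placed query
#' residues between existing columns have no counterpart in any stored model,
#' so those query residues are dropped (a message reports how many). After
#' reconciliation the returned alignment has the same columns as the input,
#' plus one new row for the query.
#'
#' @param query A one-row tibble (or list) with `id` and `residues`.
#' @param alignment A [ppap_alignment].
#' @param method `"auto"`, `"builtin"` or `"mafft"`.
#' @return A [ppap_alignment] with the query as the last row.
#' @export
add_query_to_alignment <- function(query, alignment,
                                   method = c("auto", "builtin", "mafft")) {
  method <- match.arg(method)
  if (nrow(alignment$mat) == 0L) abort("alignment is empty")
  qid <- as.character(query$id[[1L]])
  qres <- toupper(as.character(query$residues[[1L]]))
  qres <- degap(qres)
  if (nchar(qres) == 0L) abort("query has no residues")
  if (qid %in% aln_ids(alignment)) {
    abort(paste0("query id '", qid, "' already present in the alignment"))
  }
  if (method == "auto") {
    method <- if (mafft_available()) "mafft" else "builtin"
  }
  if (method == "mafft") {
    if (!mafft_available()) {
      abort(paste0("mafft is not on the PATH; install it or call with ",
                   "method = \"builtin\""))
    }
    add_query_mafft(qid, qres, alignment)
  } else {
    add_query_builtin(qid, qres, alignment)
  }
}

mafft_available <- function() nzchar(Sys.which("mafft"))

add_query_builtin <- function(qid, qres, alignment) {
  sc <- profile_score_matrix(alignment)
  q_chars <- chars(qres)
  q_idx <- match(q_chars, AA20) - 1L   # -1 for X/unknown -> flat score
  q_idx[is.na(q_idx)] <- -1L
  map <- profile_align_c(sc, as.integer(q_idx), 11, 1)
  row <- rep(GAP, aln_n_cols(alignment))
  row[map > 0L] <- q_chars[map[map > 0L]]
  dropped <- length(q_chars) - sum(map > 0L)
  if (dropped > 0L) {
    inform(paste0("add_query_to_alignment: ", dropped,
                  " query residue(s) fell between existing columns and were",
                  " dropped"))
  }
  aln_append_row(alignment, qid, row)
}

add_query_mafft <- function(qid, qres, alignment) {
  dir <- tempfile("mafft_add_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  aln_fa <- file.path(dir, "aln.fasta")
  q_fa <- file.path(dir, "query.fasta")
  write_fasta(alignment, aln_fa)
  write_fasta(tibble(id = qid, residues = qres), q_fa)
  out <- system2("mafft", c("--add", shQuote(q_fa), "--keeplength",
                            "--anysymbol", "--quiet", shQuote(aln_fa)),
                 stdout = TRUE, stderr = FALSE)
  if (is.null(attr(out, "status")) || identical(attr(out, "status"), 0L)) {
    res_fa <- file.path(dir, "out.fasta")
    writeLines(out, res_fa)
    res <- read_sequences(res_fa, "aligned-fasta")
  } else {
    abort("mafft --add failed")
  }
  # --keeplength clips query insertions, so columns already match; verify.
  if (aln_n_cols(res) != aln_n_cols(alignment)) {
    abort("mafft --add changed the column count unexpectedly")
  }
  res$family_label <- alignment$family_label
  # preserve original row order and content
  orig <- aln_subset(res, rows = aln_ids(alignment))
  if (!identical(orig$mat, alignment$mat)) {
    warn("mafft --add modified original rows; check the alignment")
  }
  res
}

aln_append_row <- function(aln, id, row_chars) {
  mat <- rbind(aln$mat, matrix(row_chars, nrow = 1L,
                               dimnames = list(id, NULL)))
  structure(list(mat = mat, family_label = aln$family_label),
            class = "ppap_alignment")
}
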