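# Per-reaction-type profiles over Area segment alignments.
#
# Two backends sit behind one surface:
#  * "pssm": a position-specific score model — log-odds of match-state
#    emissions with Laplace smoothing over the 20 standard residues against a
#    uniform background, no insert/delete states. Deterministic, pure R.
#  * "hmmer": HMMER 3 (hmmbuild/hmmsearch) when the engine is on the PATH;
#    the score is the engine's bit score of the best hit.
# Scores below zero, and "no match", are clamped to zero before any
# downstream use.

#' Build a profile from an Area segment alignment
#'
#' @param area_alignment A [ppap_alignment] of concatenated Area segments
#'   (>= 2 rows).
#' @param reaction_type Reaction-type label the profile represents.
#' @param area_combo Character vector of area names, in concatenation order.
#' @param backend `"pssm"` (default, deterministic) or `"hmmer"`.
#' @return A `ppap_profile` object carrying the model, its backend, the
#'   training ids and a provenance stamp.
#' @export
build_area_profile <- function(area_alignment, reaction_type, area_combo,
                               backend = c("pssm", "hmmer")) {
  backend <- match.arg(backend)
  if (nrow(area_alignment$mat) < 2L) {
    abort("profile construction needs at least 2 training sequences")
  }
  if (ncol(area_alignment$mat) < 1L) abort("empty segment alignment")
  stopifnot(length(area_combo) >= 1L)
  data <- switch(backend,
                 pssm = pssm_build(area_alignment),
                 hmmer = hmmer_build(area_alignment))
  structure(list(reaction_type = reaction_type,
                 area_combo = area_combo,
                 backend = backend,
                 n_cols = ncol(area_alignment$mat),
                 data = data,
                 training_ids = aln_ids(area_alignment),
                 provenance = provenance_stamp(aln_ids(area_alignment))),
            class = "ppap_profile")
}

#' @export
print.ppap_profile <- function(x, ...) {
  cat("<ppap_profile> ", x$reaction_type, " [",
      paste(x$area_combo, collapse = "+"), "], ", x$n_cols,
      " columns, backend ", x$backend, ", ", length(x$training_ids),
      " training sequences\n", sep = "")
  invisible(x)
}

# Laplace-smoothed match emission probabilities, 20 x n_cols.
pssm_build <- function(aln) {
  mat <- aln$mat
  counts <- matrix(0, nrow = 20L, ncol = ncol(mat),
                   dimnames = list(AA20, NULL))
  for (a in AA20) counts[a, ] <- colSums(mat == a)
  depth <- colSums(counts)
  probs <- sweep(counts + 1, 2L, depth + 20, "/")
  list(log_odds = log2(probs / (1 / 20)))
}

#' Score a query segment against a profile
#'
#' The query segment is the query's residues over the profile's area columns
#' (after [add_query_to_alignment()] and [extract_area_segments()]); gaps and
#' `X` in the segment contribute nothing. The raw score is the backend's bit
#' score (`NA` when the engine reports no significant match); the clamped
#' score is `max(raw, 0)` with no-match mapping to 0.
#'
#' @param profile A `ppap_profile`.
#' @param query_segment Gapped or ungapped residue string (or character
#'   vector of symbols) over the profile columns.
#' @return A list with `raw` (numeric or `NA` for no match) and `clamped`
#'   (numeric, >= 0), of class `hmm_score`.
#' @export
score_with_profile <- function(profile, query_segment) {
  seg <- if (length(query_segment) > 1L) {
    paste(query_segment, collapse = "")
  } else {
    as.character(query_segment)
  }
  if (is.na(seg) || nchar(degap(seg)) == 0L) {
    abort("empty query segment")
  }
  raw <- switch(profile$backend,
                pssm = pssm_score(profile, seg),
                hmmer = hmmer_score(profile, seg))
  clamp_hmm_score(raw)
}

#' Clamp a raw profile score
#'
#' @param raw Numeric bit score, or `NA` for "no match".
#' @return An `hmm_score` list: `raw` as given, `clamped = max(raw, 0)` with
#'   `NA` mapped to 0.
#' @export
clamp_hmm_score <- function(raw) {
  clamped <- if (is.na(raw)) 0 else max(raw, 0)
  structure(list(raw = raw, clamped = clamped), class = "hmm_score")
}

pssm_score <- function(profile, seg) {
  sym <- chars(seg)
  if (length(sym) != profile$n_cols) {
    # segment given ungapped relative to the profile columns is not
    # meaningful for a match-state-only model
    abort(paste0("query segment has ", length(sym), " symbols but the ",
                 "profile has ", profile$n_cols, " columns"))
  }
  idx <- match(sym, AA20)
  keep <- !is.na(idx)
  if (!any(keep)) return(NA_real_)
  lo <- profile$data$log_odds
  sum(lo[cbind(idx[keep], which(keep))])
}

# ---- HMMER adapter -------------------------------------------------------

hmmer_available <- function() {
  nzchar(Sys.which("hmmbuild")) && nzchar(Sys.which("hmmsearch"))
}

hmmer_build <- function(aln) {
  if (!hmmer_available()) {
    abort("HMMER (hmmbuild/hmmsearch) is not on the PATH; use backend = \"pssm\"")
  }
  dir <- tempfile("hmmbuild_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  msa <- file.path(dir, "msa.fasta")
  hmm <- file.path(dir, "model.hmm")
  write_fasta(aln, msa)
  status <- system2("hmmbuild", c("--amino", shQuote(hmm), shQuote(msa)),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) abort("hmmbuild failed")
  txt <- readLines(hmm)
  # strip the DATE line so identical alignments give identical profiles
  list(hmm_text = txt[!grepl("^DATE ", txt)])
}

hmmer_score <- function(profile, seg) {
  dir <- tempfile("hmmsearch_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  hmm <- file.path(dir, "model.hmm")
  fa <- file.path(dir, "query.fasta")
  tbl <- file.path(dir, "hits.tbl")
  writeLines(profile$data$hmm_text, hmm)
  writeLines(c(">query", degap(seg)), fa)
  status <- system2("hmmsearch",
                    c("--tblout", shQuote(tbl), "-E", "1000", "--max",
                      shQuote(hmm), shQuote(fa)),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) abort("hmmsearch failed")
  lines <- readLines(tbl)
  hits <- lines[!startsWith(lines, "#")]
  if (length(hits) == 0L) return(NA_real_)
  fields <- strsplit(trimws(hits[1L]), "\\s+")[[1L]]
  as.numeric(fields[6L])  # full-sequence bit score
}

#' Predict a reaction type by the best-scoring profile
#'
#' @param profiles List of `ppap_profile` objects with distinct reaction
#'   types.
#' @param query_segments List (same length/order) of query segments, one per
#'   profile's area combination.
#' @return A list with `label` (the winning reaction type, or
#'   `"UNCLASSIFIED"` when every clamped score is 0) and `scores`, a tibble
#'   of per-profile raw and clamped scores.
#' @details Ties on the maximal clamped score are broken by the fixed label
#'   order `R-4-A`, `R-4-C`, `R-2-X` (then alphabetically), with a warning.
#' @export
best_profile_label <- function(profiles, query_segments) {
  stopifnot(length(profiles) >= 2L, length(profiles) == length(query_segments))
  types <- vapply(profiles, function(p) p$reaction_type, "")
  if (anyDuplicated(types)) abort("profiles must have distinct reaction types")
  scored <- purrr::map2(profiles, query_segments, score_with_profile)
  scores <- tibble(reaction_type = types,
                   raw = vapply(scored, function(s) {
                     if (is.na(s$raw)) NA_real_ else s$raw
                   }, 1.0),
                   clamped = vapply(scored, function(s) s$clamped, 1.0))
  if (all(scores$clamped == 0)) {
    return(list(label = UNCLASSIFIED, scores = scores))
  }
  best <- scores$clamped == max(scores$clamped)
  if (sum(best) > 1L) {
    ord <- order(match(types, TARGET_TYPES, nomatch = length(TARGET_TYPES) + 1L),
                 types)
    winner <- types[ord][types[ord] %in% types[best]][1L]
    warn(paste0("profile score tie; broken by fixed label order in favour of ",
                winner))
  } else {
    winner <- types[best]
  }
  list(label = winner, scores = scores)
}
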