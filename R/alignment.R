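# Sequence and alignment containers.
#
# Sequences travel as tibbles (id, residues, description) so they pipe
# through dplyr naturally. Alignments are a light S3 object wrapping a
# character matrix (rows = sequences, columns = alignment positions) because
# almost every operation downstream is column arithmetic.

#' Read protein sequences from FASTA
#'
#' Reads plain or aligned FASTA. Residues are uppercased; the rare ambiguity
#' codes `B`, `Z`, `U`, `J` and `O` are mapped to `X` (unknown) with a
#' warning, so downstream frequency models see a fixed 20-letter alphabet
#' plus `X` and the gap.
#'
#' @param path Path to a FASTA file.
#' @param format `"fasta"` for unaligned sequences, `"aligned-fasta"` for an
#'   alignment (all records must have equal gapped length).
#' @return For `"fasta"`, a tibble with columns `id`, `residues`,
#'   `description`. For `"aligned-fasta"`, a [ppap_alignment] object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "MKTAY", ">s2", "MKSAY"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("fasta", "aligned-fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort(paste0("empty FASTA file: ", path))
  nm <- names(aa)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  res <- toupper(as.character(aa))
  res <- gsub("\\.", "-", res)
  if (any(grepl("[BZUJO]", res))) {
    warn("non-standard residues (B/Z/U/J/O) mapped to 'X'")
    res <- chartr("BZUJO", "XXXXX", res)
  }
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X-]"), res)
  if (any(bad)) {
    abort(paste0("unrecognised residue symbols in: ",
                 paste(id[bad], collapse = ", ")))
  }
  seqs <- tibble(id = id, residues = unname(res), description = unname(desc))
  if (anyDuplicated(seqs$id)) abort("duplicate sequence ids in FASTA")
  if (format == "fasta") return(seqs)
  lens <- nchar(seqs$residues)
  if (length(unique(lens)) != 1L) {
    off <- seqs$id[lens != lens[1L]][1L]
    abort(paste0("ragged aligned FASTA: record '", off,
                 "' differs in length"))
  }
  ppap_alignment(seqs$id, seqs$residues)
}

#' Construct an alignment object
#'
#' @param ids Character vector of unique sequence ids.
#' @param gapped Character vector of equal-length gapped residue strings
#'   (gap symbol `-`).
#' @param family_label Optional reaction-type label for the family.
#' @return A `ppap_alignment`: a character matrix (rows named by id) with the
#'   family label as an attribute.
#' @export
ppap_alignment <- function(ids, gapped, family_label = NULL) {
  stopifnot(length(ids) == length(gapped), !anyDuplicated(ids))
  lens <- nchar(gapped)
  if (length(gapped) == 0L) abort("alignment must contain at least one row")
  if (length(unique(lens)) != 1L) {
    abort(paste0("rows differ in length; first offender: ",
                 ids[lens != lens[1L]][1L]))
  }
  mat <- matrix(unlist(strsplit(gapped, "", fixed = TRUE), use.names = FALSE),
                nrow = length(gapped), byrow = TRUE,
                dimnames = list(ids, NULL))
  structure(list(mat = mat, family_label = family_label),
            class = "ppap_alignment")
}

#' @export
print.ppap_alignment <- function(x, ...) {
  cat("<ppap_alignment> ", nrow(x$mat), " sequences x ", ncol(x$mat),
      " columns", sep = "")
  if (!is.null(x$family_label)) cat(" [", x$family_label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.ppap_alignment <- function(x) dim(x$mat)

aln_ids <- function(aln) rownames(aln$mat)

aln_n_cols <- function(aln) ncol(aln$mat)

# Gapped row as a single string.
aln_row_string <- function(aln, id) {
  paste(aln$mat[id, ], collapse = "")
}

#' Convert an alignment to a tibble of gapped rows
#'
#' @param x A [ppap_alignment].
#' @param ... Unused.
#' @return Tibble with columns `id` and `aligned` (gapped residue string).
#' @export
as_tibble.ppap_alignment <- function(x, ...) {
  tibble(id = aln_ids(x),
         aligned = apply(x$mat, 1L, paste, collapse = ""))
}

# Subset rows (by id or index) and/or columns, dropping nothing else.
aln_subset <- function(aln, rows = NULL, cols = NULL) {
  mat <- aln$mat
  if (!is.null(rows)) mat <- mat[rows, , drop = FALSE]
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  structure(list(mat = mat, family_label = aln$family_label),
            class = "ppap_alignment")
}

# Drop a row and then any columns that became all-gap.
aln_drop_row <- function(aln, id) {
  keep <- setdiff(aln_ids(aln), id)
  if (length(keep) == length(aln_ids(aln))) return(aln)
  out <- aln_subset(aln, rows = keep)
  all_gap <- colSums(out$mat != GAP) == 0L
  if (any(all_gap)) out <- aln_subset(out, cols = which(!all_gap))
  out
}

#' Remove redundant sequences with an external clusterer
#'
#' Training sets are conventionally thinned so that no two sequences of the
#' same reaction type share more than 90% identity. This is a documented
#' data-preparation step, exposed as a thin wrapper around the `cd-hit`
#' program; clustering itself is not re-implemented. One representative per
#' cluster is kept, in input order.
#'
#' @param sequences Tibble with `id` and `residues`.
#' @param identity Identity threshold passed to the clusterer (default 0.9).
#' @param tool Path or name of the cd-hit executable.
#' @return The subset of `sequences` kept as cluster representatives.
#' @export
filter_redundant_sequences <- function(sequences, identity = 0.9,
                                       tool = "cd-hit") {
  stopifnot(identity > 0.4, identity <= 1)
  if (!nzchar(Sys.which(tool))) {
    abort(paste0("external clusterer '", tool, "' is not on the PATH; ",
                 "install CD-HIT or pre-filter the input (identity < ",
                 identity * 100, "% between sequences of one type)"))
  }
  dir <- tempfile("cdhit_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  in_fa <- file.path(dir, "in.fasta")
  out_fa <- file.path(dir, "out.fasta")
  write_fasta(sequences, in_fa)
  status <- system2(tool, c("-i", shQuote(in_fa), "-o", shQuote(out_fa),
                            "-c", format(identity), "-n", "5"),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) abort(paste0(tool, " failed"))
  kept <- read_sequences(out_fa)
  sequences[sequences$id %in% kept$id, , drop = FALSE]
}

#' Write sequences or an alignment to FASTA
#'
#' @param x A tibble with `id` and `residues` columns, or a
#'   [ppap_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "ppap_alignment")) {
    tb <- as_tibble(x)
    aa <- Biostrings::AAStringSet(setNames(tb$aligned, tb$id))
  } else {
    aa <- Biostrings::AAStringSet(setNames(x$residues, x$id))
  }
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
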