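# Area maps: reference-anchored segment definitions.
#
# The four "Areas" are short protein segments whose 3D structure differs
# between Claisen-cyclizing (R-4-C) and aldol-cyclizing (R-4-A) enzymes.
# An area map pins them down as 1-based inclusive residue ranges on one
# reference sequence; alignment columns are recovered by walking the
# reference row of the family MSA.

#' Define an area map
#'
#' @param reference_id Id of the reference sequence (a row of the alignments
#'   the map will be applied to).
#' @param segments A data frame with columns `name`, `start`, `end`
#'   (1-based inclusive residue coordinates on the ungapped reference).
#'   Segments must be non-overlapping and ascending, names unique.
#' @return An `area_map` object.
#' @examples
#' area_map("ref", tibble::tibble(name = c("Area1", "Area2"),
#'                                start = c(5L, 20L), end = c(10L, 26L)))
#' @export
area_map <- function(reference_id, segments) {
  segments <- as_tibble(segments)
  stopifnot(all(c("name", "start", "end") %in% names(segments)),
            nrow(segments) >= 1L)
  segments <- segments |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  if (anyDuplicated(segments$name)) abort("area names must be unique")
  if (any(segments$start > segments$end) || any(segments$start < 1L)) {
    abort("each segment needs 1 <= start <= end")
  }
  if (is.unsorted(segments$start, strictly = TRUE) ||
      any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
    abort("segments must be ascending and non-overlapping")
  }
  structure(list(reference_id = as.character(reference_id),
                 segments = segments),
            class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  cat("<area_map> reference:", x$reference_id, "\n")
  print(x$segments)
  invisible(x)
}

#' Read / write an area map as JSON
#'
#' The JSON layout is `{"reference_id": ..., "segments": [{"name": ...,
#' "start": ..., "end": ...}, ...]}`.
#'
#' @param path JSON file path.
#' @return [read_area_map()] returns an `area_map`;
#'   [write_area_map()] returns `path` invisibly.
#' @export
read_area_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  area_map(j$reference_id, as_tibble(j$segments))
}

#' @rdname read_area_map
#' @param map An `area_map`.
#' @export
write_area_map <- function(map, path) {
  jsonlite::write_json(list(reference_id = map$reference_id,
                            segments = map$segments),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Map area residue ranges to alignment columns
#'
#' Walks the reference row of the alignment, counting residues (skipping the
#' reference's gap columns), and returns for each area the alignment columns
#' at which the reference carries residues `start..end`. The per-area column
#' count therefore equals the segment's residue count.
#'
#' @param alignment A [ppap_alignment] containing the reference row.
#' @param map An [area_map()].
#' @return A named list of strictly ascending 1-based column index vectors,
#'   one per area (a column index set).
#' @export
map_reference_positions <- function(alignment, map) {
  if (!map$reference_id %in% aln_ids(alignment)) {
    abort(paste0("reference id '", map$reference_id,
                 "' is not a row of the alignment"))
  }
  ref <- alignment$mat[map$reference_id, ]
  residue_cols <- which(ref != GAP)
  n_res <- length(residue_cols)
  out <- lapply(seq_len(nrow(map$segments)), function(k) {
    seg <- map$segments[k, ]
    if (seg$end > n_res) {
      abort(paste0("segment '", seg$name, "' (", seg$start, "..", seg$end,
                   ") exceeds reference length ", n_res))
    }
    residue_cols[seg$start:seg$end]
  })
  setNames(out, map$segments$name)
}

#' Extract and concatenate area segments from an alignment
#'
#' @param alignment A [ppap_alignment].
#' @param column_index_set Named list of column indices, as returned by
#'   [map_reference_positions()].
#' @param area_names Areas to extract, in the order they should be
#'   concatenated (e.g. `c("Area1", "Area3", "Area4")`).
#' @return A [ppap_alignment] restricted to the selected areas' columns.
#' @export
extract_area_segments <- function(alignment, column_index_set, area_names) {
  stopifnot(length(area_names) >= 1L)
  unknown <- setdiff(area_names, names(column_index_set))
  if (length(unknown) > 0L) {
    abort(paste0("unknown area name(s): ", paste(unknown, collapse = ", ")))
  }
  cols <- unlist(column_index_set[area_names], use.names = FALSE)
  aln_subset(alignment, cols = cols)
}

#' Filter gappy alignment columns
#'
#' Removes terminal gappy columns and internal columns whose gap fraction
#' exceeds `max_gap_fraction` (the correlated-mutation analysis works on the
#' filtered columns). Terminal trimming drops leading and trailing columns
#' until the first column whose gap fraction is at or below the threshold —
#' a deterministic stand-in for trimming gapped terminal positions by hand.
#'
#' @param alignment A [ppap_alignment].
#' @param max_gap_fraction Columns with gap fraction strictly greater than
#'   this are removed (default 0.8).
#' @param trim_terminal Apply the terminal-trimming rule first?
#' @return A `filtered_alignment`: list with `alignment` (the kept columns)
#'   and `kept_columns` (1-based map from filtered index to original column).
#' @export
filter_columns <- function(alignment, max_gap_fraction = 0.8,
                           trim_terminal = TRUE) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  mat <- alignment$mat
  gap_frac <- colSums(mat == GAP) / nrow(mat)
  keep <- gap_frac <= max_gap_fraction
  if (trim_terminal && any(keep)) {
    first <- which(keep)[1L]
    last <- which(keep)[length(which(keep))]
    keep[seq_len(ncol(mat)) < first | seq_len(ncol(mat)) > last] <- FALSE
  }
  if (!any(keep)) abort("all columns removed by gap filtering")
  kept <- which(keep)
  structure(list(alignment = aln_subset(alignment, cols = kept),
                 kept_columns = kept,
                 max_gap_fraction = max_gap_fraction),
            class = "filtered_alignment")
}

#' @export
print.filtered_alignment <- function(x, ...) {
  cat("<filtered_alignment> ", nrow(x$alignment$mat), " sequences x ",
      length(x$kept_columns), " kept columns (gap fraction <= ",
      x$max_gap_fraction, ")\n", sep = "")
  invisible(x)
}

#' Reconstructed default area map for the M. sativa CHS2 reference
#'
#' The exact Area 1-4 residue ranges on the *Medicago sativa* CHS2 reference
#' are defined in the structural literature comparing CHS and STS and are not
#' bundled as verified data here. This helper loads the reconstructed ranges
#' shipped in `inst/extdata/area_map_chs2_reconstructed.json`; they are
#' approximate anchors (Area 1 contains Met98, Area 2 contains Thr132 and the
#' TTSGVDM motif) and **must be verified against the structural reference**
#' before use on real sequences. Synthetic benchmarks use their own map.
#'
#' @return An [area_map()].
#' @export
default_area_map <- function() {
  read_area_map(system.file("extdata", "area_map_chs2_reconstructed.json",
                            package = "ppap", mustWork = TRUE))
}
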