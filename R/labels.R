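#' Parse a reaction-type label
#'
#' Reaction types of type III polyketide synthases are written as a
#' hyphen-joined triplet `starter-extension-cyclization`, e.g. `"R-4-C"`:
#' a ring-type starter substrate, four keto groups in the linear intermediate,
#' and Claisen cyclization.
#'
#' The grammar is:
#' * starter: one of `R` (ring), `S` (short chain), `L` (long chain), with
#'   optional suffix letters `b` (branched), `c` (carboxyl), `h` (hydroxyl),
#'   `n` (nitrogen);
#' * extension: an integer count of methylenecarbonyl units, with an optional
#'   extender-substrate suffix `m`, `e`, `a` or `d`;
#' * cyclization: one of `L` (lactone), `C` (Claisen), `A` (aldol),
#'   `X` (none), `n` (nitrogen-carbon), `+` (miscellaneous), with an optional
#'   `n` suffix (e.g. `Cn`).
#'
#' The wildcard `*` is accepted for any element, but only when
#' `allow_wildcard = TRUE` (grouping contexts such as `"S-*-*"`).
#'
#' @param label Character vector of reaction-type labels.
#' @param allow_wildcard Allow `*` elements (grouping labels)?
#' @return A tibble with columns `label`, `starter`, `extension`,
#'   `cyclization`.
#' @examples
#' parse_reaction_type(c("R-4-C", "R-2d-X", "Lh-4-L"))
#' @export
parse_reaction_type <- function(label, allow_wildcard = FALSE) {
  stopifnot(is.character(label), length(label) >= 1L)
  parts <- strsplit(label, "-", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("not a starter-extension-cyclization triplet: ",
                 paste(label[bad], collapse = ", ")))
  }
  starter <- vapply(parts, `[[`, "", 1L)
  extension <- vapply(parts, `[[`, "", 2L)
  cyclization <- vapply(parts, `[[`, "", 3L)

  re_starter <- "^[RSL][bchn]*$"
  re_ext <- "^[0-9]+[mead]?$"
  re_cyc <- "^([LCAXn+])n?$"
  ok <- grepl(re_starter, starter) & grepl(re_ext, extension) &
    grepl(re_cyc, cyclization)
  if (allow_wildcard) {
    ok <- ok | (grepl(paste0(re_starter, "|^\\*$"), starter) &
                  grepl(paste0(re_ext, "|^\\*$"), extension) &
                  grepl(paste0(re_cyc, "|^\\*$"), cyclization))
  }
  if (!all(ok)) {
    abort(paste0("invalid reaction-type label(s): ",
                 paste(label[!ok], collapse = ", ")))
  }
  tibble(label = label, starter = starter, extension = extension,
         cyclization = cyclization)
}

#' Map a reaction-type label to its four-way prediction group
#'
#' The classifier cascade outputs one of `R-4-A`, `R-4-C`, `R-2-X` or
#' `"other"`. Any label that is not one of the three target types belongs to
#' the `"other"` group (`R-2d-X` is folded into `R-2-X`, matching the
#' training-set convention).
#'
#' @param label Character vector of reaction-type labels.
#' @return Character vector over `c("R-4-A", "R-4-C", "R-2-X", "other")`.
#' @export
reaction_type_group <- function(label) {
  out <- ifelse(label == "R-2d-X", "R-2-X", label)
  ifelse(out %in% TARGET_TYPES, out, "other")
}

# Starter element of a (possibly wildcard) label; used to hold long-chain
# starter types out of discriminant fitting.
label_starter <- function(label) {
  sub("-.*$", "", label)
}
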