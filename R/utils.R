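# Internal constants and small helpers shared across the pipeline.

# The 20 standard amino acids, in conventional one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Gap symbol used everywhere; the correlation-model alphabet is the 20
# standard residues plus the gap (21 symbols). 'X' marks an unknown residue:
# it counts toward N but belongs to no symbol class.
GAP <- "-"
AA21 <- c(AA20, GAP)

UNCLASSIFIED <- "UNCLASSIFIED"

# Canonical target reaction types and the fixed tie-break / cascade order.
TARGET_TYPES <- c("R-4-A", "R-4-C", "R-2-X")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Feature-name suffix for a reaction type label: "R-4-A" -> "r4a".
type_suffix <- function(label) {
  tolower(gsub("[^A-Za-z0-9]+", "", label))
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only for provenance stamps on model artifacts (leakage audits compare
# the recorded training ids; the hash is a compact fingerprint).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits only (byte values < 256), keep h in double
    lo <- h %% 65536
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    a <- h %/% 65536
    c <- h %% 65536
    h <- (((a * 16777619) %% 65536) * 65536 + c * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_stamp <- function(training_ids) {
  ids <- sort(as.character(training_ids))
  list(training_ids = ids,
       n = length(ids),
       hash = fnv1a32(paste(ids, collapse = "\x1f")))
}

# Split a residue string into a character vector of single symbols.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

degap <- function(s) gsub("-", "", s, fixed = TRUE)
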