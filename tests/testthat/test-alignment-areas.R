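write_fa <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("FASTA reading parses, normalizes case and maps ambiguity codes", {
  f <- write_fa(c(">q1 some description", "MKTAY", ">q2", "mksay"))
  tb <- read_sequences(f)
  expect_equal(tb$id, c("q1", "q2"))
  expect_equal(tb$residues, c("MKTAY", "MKSAY"))
  expect_equal(tb$description[1], "some description")

  f2 <- write_fa(c(">amb", "MKBZU"))
  expect_warning(tb2 <- read_sequences(f2), "mapped to 'X'")
  expect_equal(tb2$residues, "MKXXX")
})

test_that("aligned FASTA promotes to an alignment; ragged input names the row", {
  f <- write_fa(c(">a", "MK-AY", ">b", "MKSAY"))
  aln <- read_sequences(f, "aligned-fasta")
  expect_s3_class(aln, "ppap_alignment")
  expect_equal(dim(aln), c(2L, 5L))

  f2 <- write_fa(c(">a", "MKAY", ">b", "MKSAY"))
  expect_error(read_sequences(f2, "aligned-fasta"), "ragged.*'b'")
  f3 <- write_fa(character(0))
  expect_error(read_sequences(f3), "empty")
})

test_that("reference residue ranges map to alignment columns, skipping gaps", {
  aln <- aln_fix("A-CD", "AACD", ids = c("ref", "x"))
  map <- area_map("ref", tibble::tibble(name = "Area1", start = 1, end = 2))
  expect_equal(map_reference_positions(aln, map)$Area1, c(1L, 3L))

  aln2 <- aln_fix("ACDEF", "ACDEF", ids = c("ref", "x"))
  map2 <- area_map("ref", tibble::tibble(name = "A", start = 3, end = 5))
  expect_equal(map_reference_positions(aln2, map2)$A, 3:5)

  expect_error(map_reference_positions(
    aln2, area_map("nope", tibble::tibble(name = "A", start = 1, end = 2))),
    "not a row")
  expect_error(map_reference_positions(
    aln2, area_map("ref", tibble::tibble(name = "A", start = 4, end = 9))),
    "exceeds")
})

test_that("column mapping matches a brute-force walk of a gapped reference", {
  set.seed(31)
  for (rep in 1:5) {
    aln <- random_alignment(6, 30, gap_prob = 0.2)
    ref <- aln$mat[1, ]
    n_res <- sum(ref != "-")
    if (n_res < 6) next
    map <- area_map("s1", tibble::tibble(name = c("A", "B"),
                                         start = c(2, 5),
                                         end = c(3, min(6, n_res))))
    got <- map_reference_positions(aln, map)
    # oracle: walk the row counting residues
    walk <- function(from, to) {
      count <- 0L
      cols <- integer(0)
      for (c in seq_along(ref)) {
        if (ref[c] != "-") {
          count <- count + 1L
          if (count >= from && count <= to) cols <- c(cols, c)
        }
      }
      cols
    }
    expect_equal(got$A, walk(2, 3))
    expect_equal(got$B, walk(5, min(6, n_res)))
  }
})

test_that("area extraction selects and concatenates columns in area order", {
  aln <- aln_fix("ABCDEFGHIK", "KIHGFEDCBA")
  cis <- list(Area1 = c(1L, 2L), Area4 = 10L)
  one <- extract_area_segments(aln, list(A = c(2L, 3L, 4L)), "A")
  expect_equal(dim(one), c(2L, 3L))
  expect_equal(paste(one$mat[1, ], collapse = ""), "BCD")

  both <- extract_area_segments(aln, cis, c("Area1", "Area4"))
  expect_equal(paste(both$mat[1, ], collapse = ""), "ABK")
  expect_error(extract_area_segments(aln, cis, "Area9"), "unknown area")
})

test_that("extracting a union of areas equals concatenating the parts", {
  set.seed(7)
  aln <- random_alignment(5, 40)
  cis <- list(A1 = 3:6, A2 = 11:14, A3 = 20:24, A4 = 30:33)
  all4 <- extract_area_segments(aln, cis, c("A1", "A2", "A3", "A4"))
  parts <- lapply(c("A1", "A2", "A3", "A4"), function(a) {
    extract_area_segments(aln, cis, a)$mat
  })
  expect_identical(all4$mat, do.call(cbind, parts))
})

test_that("mapping then extracting the reference row reproduces its segment", {
  set.seed(12)
  aln <- random_alignment(4, 30, gap_prob = 0.15)
  ref_res <- aln$mat[1, ][aln$mat[1, ] != "-"]
  map <- area_map("s1", tibble::tibble(name = "A", start = 4,
                                       end = min(9, length(ref_res))))
  cis <- map_reference_positions(aln, map)
  seg <- extract_area_segments(aln, cis, "A")
  expect_equal(paste(seg$mat[1, ], collapse = ""),
               paste(ref_res[4:min(9, length(ref_res))], collapse = ""))
})

test_that("gap filtering removes over-gapped columns and is idempotent", {
  clean <- aln_fix("ACDEF", "ACDEF", "ACDEF", "ACDEF", "ACDEF")
  filt <- filter_columns(clean, 0.8)
  expect_equal(filt$kept_columns, 1:5)

  rows <- c("AC-EF", "AC-EF", "AC-EF", "AC-EF", "AC-EF")
  gappy <- aln_fix(rows[1], rows[2], rows[3], rows[4], rows[5])
  filt2 <- filter_columns(gappy, 0.8)
  expect_equal(filt2$kept_columns, c(1L, 2L, 4L, 5L))

  # idempotence
  again <- filter_columns(filt2$alignment, 0.8)
  expect_identical(again$alignment$mat, filt2$alignment$mat)
  expect_equal(again$kept_columns, seq_along(filt2$kept_columns))

  all_gap <- aln_fix("--", "--")
  expect_error(filter_columns(all_gap, 0.8), "all columns removed")
})

test_that("kept columns equal a brute-force per-column gap-fraction filter", {
  set.seed(5)
  for (rep in 1:5) {
    aln <- random_alignment(8, 25, gap_prob = 0.35)
    got <- tryCatch(filter_columns(aln, 0.5, trim_terminal = FALSE),
                    error = function(e) NULL)
    keep <- vapply(seq_len(25), function(c) {
      sum(aln$mat[, c] == "-") / 8 <= 0.5
    }, TRUE)
    if (is.null(got)) {
      expect_false(any(keep))
    } else {
      expect_equal(got$kept_columns, which(keep))
    }
  }
})

test_that("terminal trimming drops leading/trailing over-gapped columns only", {
  aln <- aln_fix("--ACD-F--", "---CDEF--", "A-ACD-F-A")
  filt <- filter_columns(aln, 0.5, trim_terminal = TRUE)
  # columns 1,2 and 8,9 are over-gapped terminals; column 6 internal over-gap
  expect_equal(filt$kept_columns, c(3L, 4L, 5L, 7L))
})

test_that("adding a duplicate of an existing row reproduces that row", {
  b <- get_bench(seed = 11, n_seqs = 8)
  aln <- b$alignments[["R-4-C"]]
  q <- tibble::tibble(id = "dup",
                      residues = gsub("-", "",
                                      paste(aln$mat[2, ], collapse = "")))
  ext <- add_query_to_alignment(q, aln, method = "builtin")
  expect_equal(dim(ext)[1], dim(aln)[1] + 1L)
  expect_equal(dim(ext)[2], dim(aln)[2])
  # identical at every column where the original row has a residue
  has_res <- aln$mat[2, ] != "-"
  expect_identical(ext$mat["dup", has_res], unname(aln$mat[2, has_res]))
  # original rows untouched
  expect_identical(ext$mat[rownames(aln$mat), ], aln$mat)
})

test_that("a query with one internal deletion gains exactly one extra gap", {
  b <- get_bench(seed = 11, n_seqs = 8)
  aln <- b$alignments[["R-4-A"]]
  full <- gsub("-", "", paste(aln$mat[1, ], collapse = ""))
  # delete one internal residue far from the areas
  res <- strsplit(full, "")[[1]]
  res <- res[-5]
  ext <- add_query_to_alignment(
    tibble::tibble(id = "del1", residues = paste(res, collapse = "")),
    aln, method = "builtin")
  n_gap_q <- sum(ext$mat["del1", ] == "-")
  n_gap_orig <- sum(aln$mat[1, ] == "-")
  expect_equal(n_gap_q, n_gap_orig + 1L)
})

test_that("adding a query to an empty alignment errors", {
  empty <- structure(list(mat = matrix(character(0), nrow = 0, ncol = 0),
                          family_label = NULL), class = "ppap_alignment")
  expect_error(add_query_to_alignment(
    tibble::tibble(id = "q", residues = "MKT"), empty), "empty")
})

test_that("the mafft adapter maps an existing member back onto its columns", {
  b <- get_bench(seed = 11, n_seqs = 8)
  aln <- b$alignments[["R-4-C"]]
  q <- tibble::tibble(id = "dup",
                      residues = gsub("-", "",
                                      paste(aln$mat[3, ], collapse = "")))
  ext <- add_query_to_alignment(q, aln, method = "mafft")
  expect_equal(dim(ext)[2], dim(aln)[2])
  has_res <- aln$mat[3, ] != "-"
  expect_identical(ext$mat["dup", has_res], unname(aln$mat[3, has_res]))
})

test_that("area maps round-trip through JSON", {
  map <- synthetic_area_map()
  f <- tempfile(fileext = ".json")
  write_area_map(map, f)
  back <- read_area_map(f)
  expect_equal(back$reference_id, map$reference_id)
  expect_equal(as.data.frame(back$segments), as.data.frame(map$segments))
  # shipped reconstructed default parses
  expect_s3_class(default_area_map(), "area_map")
})

test_that("the redundancy-filter wrapper validates its external tool", {
  seqs <- tibble::tibble(id = c("a", "b"), residues = c("MKTAY", "MKTAY"))
  if (nzchar(Sys.which("cd-hit"))) {
    kept <- filter_redundant_sequences(seqs, 0.9)
    expect_lte(nrow(kept), 2L)
    expect_true(all(kept$id %in% seqs$id))
  } else {
    expect_error(filter_redundant_sequences(seqs, 0.9), "PATH")
  }
  expect_error(filter_redundant_sequences(seqs, identity = 0.2))
})
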