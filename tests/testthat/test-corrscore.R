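# Build a small correlation model directly from an alignment by selecting
# pairs at a permissive threshold (so a usable pair set always exists).
toy_model <- function(aln, threshold = 0, max_gap = 0.9) {
  filt <- filter_columns(aln, max_gap, trim_terminal = FALSE)
  ps <- compute_mip(mi_matrix(filt$alignment))
  sel <- select_correlated_pairs(ps, threshold)
  build_correlation_model(filt, sel, reaction_type = "R-4-C")
}

# model over an explicit pair list, bypassing MIp selection (for degenerate
# toy alignments whose MI is identically zero)
manual_model <- function(aln, pairs_ij) {
  filt <- filter_columns(aln, 0.9, trim_terminal = FALSE)
  sel <- tibble::tibble(i = as.integer(pairs_ij[, 1]),
                        j = as.integer(pairs_ij[, 2]),
                        mi = 0, mip = 0, z = 9)
  attr(sel, "C") <- nrow(sel)
  build_correlation_model(filt, sel, reaction_type = "R-4-C")
}

test_that("smoothing parameters follow the printed formulas", {
  sm <- smoothing_params(1)
  expect_equal(sm$alpha, 1 / 21)
  expect_equal(sm$d_s, 21L)
  expect_equal(sm$d_p, 441L)
  expect_equal(sm$beta, (1 / 441) / 3)  # = 1/1323 at N = 1
  expect_equal(sm$beta, 1 / 1323, tolerance = 1e-12)
  expect_error(smoothing_params(0), "N")

  sm10 <- smoothing_params(10)
  expect_equal(sm10$beta, (1 / 21)^2 / (10 + 2 * (1 / 21) * 21))
})

test_that("an unseen pair of unseen residues has ratio exactly 1 for all N", {
  for (N in c(1:20, 50, 100, 200)) {
    sm <- smoothing_params(N)
    p_single <- sm$alpha / (N + sm$alpha * sm$d_s)
    p_pair <- sm$beta / (N + sm$beta * sm$d_p)
    expect_equal(p_pair / (p_single * p_single), 1, tolerance = 1e-12)
  }
})

test_that("smoothed frequencies match hand-substituted values and normalize", {
  model <- manual_model(aln_fix("AC", "AD"), cbind(1, 2))

  # check the N = 1 substitutions against a single-sequence model
  one <- manual_model(aln_fix("AC"), cbind(1, 2))
  expect_equal(smoothed_frequency(one, 1, "A"), (1 + 1 / 21) / 2)  # 11/21
  expect_equal(smoothed_frequency(one, 1, "W"), (1 / 21) / 2)      # 1/42
  tot <- sum(vapply(c(AA20_T, "-"),
                    function(s) smoothed_frequency(one, 1, s), 1.0))
  expect_equal(tot, 1, tolerance = 1e-12)

  # pair distribution normalizes too
  tot2 <- 0
  for (x in AA21_T) for (y in AA21_T) {
    tot2 <- tot2 + smoothed_frequency(model, 1, x, y)
  }
  expect_equal(tot2, 1, tolerance = 1e-10)
  expect_error(smoothed_frequency(model, 1, "B"), "alphabet")
})

test_that("model counts match a manual tally and marginalize correctly", {
  aln <- aln_fix("ACDA", "ACEA", "RCDA")
  model <- toy_model(aln)
  expect_equal(model$N, 3L)
  expect_equal(unname(model$single_counts["A", 1]), 2L)
  expect_equal(unname(model$single_counts["R", 1]), 1L)
  expect_equal(unname(model$single_counts["C", 2]), 3L)
  expect_true(all(colSums(model$single_counts) == 3L))

  # marginalization: sum_Y n_ij(X, Y) == n_i(X) for every selected pair
  set.seed(6)
  aln2 <- random_alignment(9, 6, gap_prob = 0.1)
  m2 <- toy_model(aln2)
  for (k in seq_len(nrow(m2$pairs))) {
    keys <- names(m2$pair_counts)
    kk <- startsWith(keys, paste0(k, ":"))
    sub <- m2$pair_counts[kk]
    xs <- substr(names(sub), nchar(paste0(k, ":")) + 1L,
                 nchar(paste0(k, ":")) + 1L)
    marg <- tapply(sub, xs, sum)
    for (x in names(marg)) {
      expect_equal(unname(marg[x]),
                   unname(m2$single_counts[x, m2$pairs$i[k]]))
    }
    expect_equal(sum(sub), m2$N)
  }
})

test_that("a single-pair model scores a seen pair per the hand formula", {
  aln <- aln_fix("TG", "TG")  # N = 2, only (T, G) ever observed
  model <- manual_model(aln, cbind(1, 2))
  expect_equal(nrow(model$pairs), 1L)
  sm <- smoothing_params(2)
  p_ij <- (2 + sm$beta) / (2 + sm$beta * 441)
  p_t <- (2 + sm$alpha) / (2 + sm$alpha * 21)
  expected <- log(p_ij / (p_t * p_t))
  expect_equal(correlation_score(model, "TG"), expected, tolerance = 1e-12)
})

test_that("queries with only unseen residues at the pairs score exactly zero", {
  aln <- aln_fix("TGAC", "TGAC", "TGAC")
  model <- manual_model(aln, rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
  # W/Y/H/M never occur anywhere in training
  expect_equal(correlation_score(model, "WYHM"), 0, tolerance = 1e-12)
})

test_that("S_cor equals the independent brute-force recomputation", {
  set.seed(29)
  for (rep in 1:8) {
    aln <- random_alignment(8, 10, gap_prob = 0.1)
    model <- tryCatch(toy_model(aln), error = function(e) NULL)
    if (is.null(model)) next
    row <- c(sample(AA21_T, 9, replace = TRUE), "X")[sample.int(10)]
    got <- suppressMessages(correlation_score(model, row, projected = TRUE))
    filt_mat <- aln$mat[, model$kept_columns, drop = FALSE]
    expect_equal(got, scor_brute(filt_mat, model$pairs, row),
                 tolerance = 1e-12)
  }
})

test_that("pairs whose ratio is 1 only dilute S_cor through C", {
  aln <- aln_fix("TGAC", "TGAC", "TGRC")
  model <- manual_model(aln, rbind(c(1, 2), c(2, 3)))
  C <- nrow(model$pairs)
  # append a fake pair whose query residues were never observed (ratio 1)
  aug <- model
  aug$pairs <- dplyr::bind_rows(model$pairs,
                                tibble::tibble(i = 1L, j = 4L, mi = 0,
                                               mip = 0, z = 9))
  s_aug <- correlation_score(aug, "WGAY")  # W,Y unseen anywhere
  s_base <- correlation_score(model, "WGAY")
  expect_equal(s_aug * (C + 1), s_base * C, tolerance = 1e-12)
})

test_that("a serialized and reloaded model reproduces scores exactly", {
  b <- get_bench(seed = 11, n_seqs = 8)
  model <- get_small_model()
  f <- tempfile(fileext = ".json")
  write_ppap_model(model, f)
  back <- read_ppap_model(f)
  q <- b$sequences[c(1, 9, 20), c("id", "residues")]
  q$id <- paste0("q_", q$id)
  p1 <- suppressMessages(predict(model, q))
  p2 <- suppressMessages(predict(back, q))
  expect_equal(p1, p2, tolerance = 1e-12)
  # correlation models rebuild bit-identically
  cm1 <- model$types[["R-4-C"]]$corr_model
  cm2 <- back$types[["R-4-C"]]$corr_model
  expect_identical(cm1$pair_counts, cm2$pair_counts)
  expect_identical(unname(cm1$single_counts), unname(cm2$single_counts))
})

test_that("queries drawn from the pair joints outscore their permutations", {
  set.seed(55)
  spec <- family_spec("R-4-C", n_seqs = 30, seq_length = 60,
                      planted_pairs = ppap:::default_planted_pairs(
                        seq(3, 21, 2), seq(35, 53, 2), ppap:::PAIR_COMBOS),
                      indel_rate = 0, seed = 15)
  fam <- generate_family(spec)
  model <- toy_model(fam$alignment, threshold = 3)
  wins <- 0L
  n_trials <- 10L
  for (t in seq_len(n_trials)) {
    # a fresh sequence from the same generative process
    fresh <- generate_family(
      family_spec("R-4-C", n_seqs = 2, seq_length = 60,
                  planted_pairs = spec$planted_pairs, indel_rate = 0,
                  seed = 1000 + t))
    row <- fresh$alignment$mat[1, ]
    perm <- row[sample.int(length(row))]
    if (correlation_score(model, row, projected = TRUE) >
          correlation_score(model, perm, projected = TRUE)) {
      wins <- wins + 1L
    }
  }
  # sign test: >= 9 of 10 wins rejects "no signal" at p < 0.01
  expect_gte(wins, 9L)
})
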