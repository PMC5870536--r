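test_that("standardize/unstandardize round-trips the training matrix", {
  set.seed(2)
  x <- matrix(rnorm(60, mean = 3, sd = 2), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  std <- fit_standardizer(x)
  z <- standardize(std, x)
  expect_equal(colMeans(z), setNames(rep(0, 6), paste0("f", 1:6)),
               tolerance = 1e-12)
  expect_equal(unstandardize(std, z), x, tolerance = 1e-12)
  x0 <- cbind(x, fz = 1)
  expect_error(fit_standardizer(x0), "zero-variance")
})

test_that("two separated Gaussian clouds are perfectly discriminated", {
  set.seed(10)
  n <- 40
  x <- rbind(matrix(rnorm(n * 6, 0), ncol = 6),
             matrix(rnorm(n * 6, 4), ncol = 6))
  colnames(x) <- paste0("f", 1:6)
  lab <- rep(c(FALSE, TRUE), each = n)
  std <- fit_standardizer(x)
  z <- standardize(std, x)
  cls <- fit_binary_lda(z, lab, target_type = "R-4-A")
  pred <- as.vector(z %*% cls$weights + cls$intercept > 0)
  expect_equal(mean(pred == lab), 1.0)
})

test_that("LDA recovers a known discriminant direction under identity cov", {
  set.seed(20)
  n <- 500
  d <- c(1, -2, 0.5, 0, 3, -1)
  d <- d / sqrt(sum(d^2))
  x <- rbind(matrix(rnorm(n * 6), ncol = 6),
             sweep(matrix(rnorm(n * 6), ncol = 6), 2L, 2 * d, "+"))
  colnames(x) <- paste0("f", 1:6)
  lab <- rep(c(FALSE, TRUE), each = n)
  cls <- fit_binary_lda(x, lab)
  w <- cls$weights / sqrt(sum(cls$weights^2))
  expect_gt(sum(w * d), 0.99)
})

test_that("permuted labels give chance-level training accuracy", {
  set.seed(30)
  n <- 300
  x <- matrix(rnorm(n * 6), ncol = 6)
  colnames(x) <- paste0("f", 1:6)
  lab <- sample(rep(c(TRUE, FALSE), times = c(90, 210)))
  cls <- fit_binary_lda(x, lab)
  pred <- as.vector(x %*% cls$weights + cls$intercept > 0)
  acc <- mean(pred == lab)
  prior <- max(mean(lab), 1 - mean(lab))
  expect_lt(abs(acc - prior), 0.1)
})

test_that("decisions agree with the reference LDA implementation", {
  set.seed(40)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, 0), ncol = 4),
             matrix(rnorm(2 * n * 4, 2.5), ncol = 4))
  colnames(x) <- paste0("f", 1:4)
  lab <- rep(c(FALSE, TRUE), times = c(n, 2 * n))
  cls <- fit_binary_lda(x, lab)
  ours <- as.vector(x %*% cls$weights + cls$intercept > 0)
  ref <- MASS::lda(x, grouping = lab)
  theirs <- as.logical(as.character(predict(ref, as.data.frame(x))$class))
  expect_gt(mean(ours == theirs), 0.98)
})

test_that("degenerate feature matrices fall back to ridge regularization", {
  set.seed(50)
  n <- 30
  base <- matrix(rnorm(n * 2), ncol = 2)
  x <- cbind(base, base[, 1] + base[, 2])  # exactly collinear
  colnames(x) <- paste0("f", 1:3)
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  expect_warning(cls <- fit_binary_lda(x, lab), "ridge")
  expect_true(all(is.finite(cls$weights)))
})

test_that("the cascade fires in order and defaults to 'other'", {
  # hand-built classifiers keyed to single features so outcomes are forced
  mk <- function(feature, thr, types) {
    w <- setNames(rep(0, 6), ppap:::feature_names(types))
    w[feature] <- 1
    structure(list(target_type = NULL, weights = w, intercept = -thr),
              class = "lda_classifier")
  }
  types <- c("R-4-A", "R-4-C", "R-2-X")
  feats <- ppap:::feature_names(types)
  std <- structure(list(mean = setNames(rep(0, 6), feats),
                        sd = setNames(rep(1, 6), feats)),
                   class = "ppap_standardizer")
  cl <- list(mk("hmm_r4a", 1, types), mk("hmm_r4c", 1, types),
             mk("hmm_r2x", 1, types))
  names(cl) <- types
  sv <- function(a, c, x) {
    tibble::tibble(hmm_r4a = a, hmm_r4c = c, hmm_r2x = x,
                   cor_r4a = 0, cor_r4c = 0, cor_r2x = 0)
  }
  r1 <- apply_cascade(cl, sv(2, 0, 0), std)   # (yes, no, no)
  expect_equal(r1$final_label, "R-4-A")
  expect_true(r1$yes_r4a && !r1$yes_r4c && !r1$yes_r2x)
  r2 <- apply_cascade(cl, sv(0, 0, 0), std)   # (no, no, no)
  expect_equal(r2$final_label, "other")
  r3 <- apply_cascade(cl, sv(0, 2, 2), std)   # (no, yes, yes)
  expect_equal(r3$final_label, "R-4-C")
  expect_equal(r3$n_yes, 2L)

  # totality: any finite vector yields exactly one of the four labels
  set.seed(60)
  for (k in 1:25) {
    v <- sv(rnorm(1, 0, 3), rnorm(1, 0, 3), rnorm(1, 0, 3))
    out <- apply_cascade(cl, v, std)
    expect_true(out$final_label %in% c(types, "other"))
  }
})

test_that("score vectors are deterministic and reflect the true family", {
  model <- get_small_model()
  b <- get_bench(seed = 11, n_seqs = 8)
  q <- b$sequences[b$sequences$reaction_type == "R-4-C", ][1, ]
  sv1 <- assemble_score_vector(q, model)
  sv2 <- assemble_score_vector(q, model)
  expect_identical(sv1, sv2)
  hmm <- unlist(sv1[, c("hmm_r4a", "hmm_r4c", "hmm_r2x")])
  expect_equal(names(which.max(hmm)), "hmm_r4c")
  expect_true(all(hmm >= 0))
  expect_true(all(is.finite(unlist(sv1))))
})

test_that("random sequences yield valid (possibly all-zero) score vectors", {
  model <- get_small_model()
  set.seed(70)
  sv <- suppressMessages(assemble_score_vector(
    tibble::tibble(id = "rnd", residues = random_protein(120)), model))
  expect_true(all(unlist(sv[, c("hmm_r4a", "hmm_r4c", "hmm_r2x")]) >= 0))
  expect_true(all(is.finite(unlist(sv))))
})

test_that("tidy and glance summarize fitted models", {
  model <- get_small_model()
  td <- tidy(model)
  expect_equal(sort(unique(td$classifier)), sort(c("R-4-A", "R-4-C", "R-2-X")))
  expect_equal(nrow(td), 3 * 7)  # 6 weights + intercept per classifier
  gl <- glance(model)
  expect_equal(gl$n_train, 40L)
  expect_equal(gl$area_combo, "Area1+Area3+Area4")
})

test_that("prediction output keeps query order and one row per query", {
  model <- get_small_model()
  b <- get_bench(seed = 11, n_seqs = 8)
  q <- b$sequences[c(3, 1, 17), c("id", "residues")]
  q$id <- paste0("q_", q$id)
  pred <- suppressMessages(predict(model, q))
  expect_equal(pred$query_id, q$id)
  expect_true(all(pred$final_label %in%
                    c("R-4-A", "R-4-C", "R-2-X", "other")))
  expect_error(predict(model, q[0, ]), "no query")
})

test_that("very short queries are handled without a crash", {
  model <- get_small_model()
  out <- suppressMessages(predict(
    model, tibble::tibble(id = "tiny", residues = "MKTAY")))
  expect_equal(nrow(out), 1L)
  expect_true(out$final_label %in% c("R-4-A", "R-4-C", "R-2-X", "other"))
})
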