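# Cross-validation harnesses and the PCA report.
#
# Both harnesses rebuild every artifact whose training set changes in a fold
# (held-out family models, the standardizer, the discriminants). Artifacts of
# the other families are reused because the held-out sequence was never in
# their inputs — the leakage audit asserts this on every fold from the
# recorded provenance (training ids + hash).

aln_keep_rows_dropgap <- function(aln, ids) {
  out <- aln_subset(aln, rows = intersect(aln_ids(aln), ids))
  all_gap <- colSums(out$mat != GAP) == 0L
  if (any(all_gap)) out <- aln_subset(out, cols = which(!all_gap))
  out
}

new_accuracy_report <- function(mode, folds, config, seed = NULL,
                                reps = NULL, extra = list()) {
  per_type <- folds |>
    group_by(.data$true_group) |>
    summarise(n = n(), correct = sum(.data$correct), .groups = "drop") |>
    mutate(accuracy = .data$correct / .data$n)
  overall <- sum(folds$correct) / nrow(folds)
  structure(c(list(mode = mode, folds = folds, per_type = per_type,
                   overall_accuracy = overall, n = nrow(folds),
                   seed = seed, reps = reps, config = config),
              extra),
            class = "ppap_accuracy_report")
}

#' @export
print.ppap_accuracy_report <- function(x, ...) {
  cat("<ppap_accuracy_report> mode:", x$mode, "-", x$n, "predictions,",
      "overall accuracy", round(x$overall_accuracy, 4), "\n")
  print(x$per_type)
  invisible(x)
}

#' @export
tidy.ppap_accuracy_report <- function(x, ...) x$per_type

#' @export
glance.ppap_accuracy_report <- function(x, ...) {
  tibble(mode = x$mode, n = x$n, correct = sum(x$folds$correct),
         accuracy = x$overall_accuracy)
}

# Fold-local refit of standardizer + discriminants and prediction of the
# held-out score vector.
fold_classify <- function(train_scores, test_features, config) {
  feats <- feature_names(config$target_types)
  fit_rows <- train_scores |> filter(.data$in_lda)
  standardizer <- fit_standardizer(fit_rows[, feats])
  std <- standardize(standardizer, fit_rows[, feats])
  ldas <- lapply(config$target_types, function(t) {
    fit_binary_lda(std, fit_rows$group == t, target_type = t)
  })
  names(ldas) <- config$target_types
  apply_cascade(ldas, test_features, standardizer)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For each sequence, every artifact that its removal can touch — its own
#' family's alignment, profile, column filter, pair selection (Z-threshold
#' re-applied on the reduced alignment) and correlation model, plus the
#' standardizer and the three discriminants — is rebuilt without it; the
#' sequence is then aligned back in as a query and classified. Models of the
#' other families are reused unchanged (the held-out id never contributed to
#' them; asserted per fold via provenance).
#'
#' @param sequences Tibble with `id`, `residues`, `reaction_type`.
#' @param alignments Named list of target-type family alignments.
#' @param map An [area_map()].
#' @param reference Optional reference sequence tibble (see [ppap_fit()]).
#' @param config A [ppap_config()].
#' @return A `ppap_accuracy_report`; `$folds` has one row per sequence with
#'   the prediction and the fold's leakage-audit result, `$audits` the
#'   per-fold artifact provenance hashes.
#' @export
loocv <- function(sequences, alignments, map, reference = NULL,
                  config = ppap_config()) {
  if (nrow(sequences) < 2L) abort("need at least 2 sequences for LOOCV")
  for (t in config$target_types) {
    members <- intersect(aln_ids(alignments[[t]]), sequences$id)
    if (length(members) > 0L && length(aln_ids(alignments[[t]])) < 3L) {
      abort(paste0("type ", t, " would retain fewer than 2 sequences ",
                   "after exclusion"))
    }
  }
  fit0 <- ppap_fit(sequences, alignments, map, reference, config)
  feats <- feature_names(config$target_types)
  scores0 <- fit0$train_scores

  fold_results <- vector("list", nrow(sequences))
  audits <- vector("list", nrow(sequences))
  for (k in seq_len(nrow(sequences))) {
    e <- sequences$id[k]
    affected <- NULL
    for (t in config$target_types) {
      if (e %in% aln_ids(alignments[[t]])) affected <- t
    }
    fold_scores <- scores0
    e_features <- scores0[scores0$id == e, feats]
    arts <- fit0$types
    if (!is.null(affected)) {
      reduced <- aln_drop_row(alignments[[affected]], e)
      reduced$family_label <- affected
      art_e <- build_type_artifacts(reduced, affected, map, reference, config)
      arts[[affected]] <- art_e
      hc <- paste0("hmm_", type_suffix(affected))
      cc <- paste0("cor_", type_suffix(affected))
      for (m in seq_len(nrow(sequences))) {
        s <- sequences$id[m]
        if (s == e) next
        row <- aligned_row_for(s, sequences$residues[m], reduced,
                               config$align_method)
        sc <- type_scores_for_row(row, art_e)
        fold_scores[fold_scores$id == s, hc] <- unname(sc["hmm"])
        fold_scores[fold_scores$id == s, cc] <- unname(sc["cor"])
      }
      row_e <- aligned_row_for(e, sequences$residues[k], reduced,
                               config$align_method)
      sc_e <- type_scores_for_row(row_e, art_e)
      e_features[[hc]] <- unname(sc_e["hmm"])
      e_features[[cc]] <- unname(sc_e["cor"])
    }
    train <- fold_scores |> filter(.data$id != e)
    dec <- fold_classify(train, e_features, config)

    audit <- purrr::map_dfr(config$target_types, function(t) {
      tibble(fold_id = e, artifact = paste0(t, "/models"),
             hash = arts[[t]]$corr_model$provenance$hash,
             leaked = e %in% arts[[t]]$corr_model$training_ids ||
               e %in% arts[[t]]$profile$training_ids)
    }) |>
      bind_rows(tibble(fold_id = e, artifact = "lda_fit",
                       hash = fnv1a32(paste(sort(train$id[train$in_lda]),
                                            collapse = "\x1f")),
                       leaked = e %in% train$id))
    if (any(audit$leaked)) {
      abort(paste0("leakage detected in fold for '", e, "'"))
    }
    audits[[k]] <- audit
    fold_results[[k]] <- dplyr::bind_cols(
      tibble(id = e,
             true_type = sequences$reaction_type[k],
             true_group = reaction_type_group(sequences$reaction_type[k])),
      dec, e_features)
  }
  folds <- bind_rows(fold_results) |>
    mutate(correct = .data$final_label == .data$true_group)
  new_accuracy_report("loocv", folds, config,
                      extra = list(audits = bind_rows(audits)))
}

#' Repeated random sub-sampling validation
#'
#' In each repetition, for every reaction type independently,
#' `ceiling(fraction * n)` of its sequences are drawn as the training set
#' (the decimal is rounded up) and the remainder form the test set. All
#' models, the standardizer and the discriminants are rebuilt from the
#' training split; test sequences are classified and the accuracy is
#' averaged over repetitions. Fully reproducible from `seed` (one master
#' stream; per-repetition substreams drawn from it).
#'
#' @inheritParams loocv
#' @param fraction Training fraction per type (default 0.5).
#' @param reps Number of repetitions (default 10).
#' @param seed Integer seed.
#' @return A `ppap_accuracy_report`; `$folds` holds all test predictions
#'   (with a `rep` column), `$rep_accuracy` per-repetition accuracies, and
#'   `$train_sizes` the per-type training-set sizes in each repetition.
#' @export
rrsv <- function(sequences, alignments, map, reference = NULL,
                 fraction = 0.5, reps = 10, seed = 1,
                 config = ppap_config()) {
  stopifnot(fraction > 0, fraction < 1, reps >= 1)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  fold_list <- list()
  size_list <- list()
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    split <- sequences |>
      group_by(.data$reaction_type) |>
      mutate(.train = {
        n_train <- ceiling(fraction * n())
        seq_len(n()) %in% sample.int(n(), n_train)
      }) |>
      ungroup()
    sizes <- split |>
      group_by(.data$reaction_type) |>
      summarise(n = n(), n_train = sum(.data$.train), .groups = "drop") |>
      mutate(rep = r)
    if (any(sizes$n_train == sizes$n)) {
      inform(paste0("rrsv rep ", r, ": type(s) with no test sequences: ",
                    paste(sizes$reaction_type[sizes$n_train == sizes$n],
                          collapse = ", ")))
    }
    train_ids <- split$id[split$.train]
    sub_aln <- lapply(config$target_types, function(t) {
      a <- aln_keep_rows_dropgap(alignments[[t]], train_ids)
      if (nrow(a$mat) < 2L) {
        abort(paste0("type ", t, " has fewer than 2 training sequences in ",
                     "repetition ", r))
      }
      a$family_label <- t
      a
    })
    names(sub_aln) <- config$target_types
    fit <- ppap_fit(split |> filter(.data$.train) |>
                      select("id", "residues", "reaction_type"),
                    sub_aln, map, reference, config)
    test <- split |> filter(!.data$.train)
    if (nrow(test) > 0L) {
      pred <- stats::predict(fit, test)
      fold_list[[r]] <- pred |>
        left_join(test |> select(query_id = "id", "reaction_type"),
                  by = "query_id") |>
        mutate(rep = r,
               id = .data$query_id,
               true_type = .data$reaction_type,
               true_group = reaction_type_group(.data$reaction_type),
               correct = .data$final_label == .data$true_group)
    }
    size_list[[r]] <- sizes
  }
  folds <- bind_rows(fold_list)
  rep_acc <- folds |>
    group_by(.data$rep) |>
    summarise(n = n(), correct = sum(.data$correct), .groups = "drop") |>
    mutate(accuracy = .data$correct / .data$n)
  rpt <- new_accuracy_report("rrsv", folds, config, seed = seed, reps = reps,
                             extra = list(rep_accuracy = rep_acc,
                                          train_sizes = bind_rows(size_list),
                                          fraction = fraction))
  # report the mean of per-repetition accuracies (repetitions are the unit)
  rpt$overall_accuracy <- mean(rep_acc$accuracy)
  rpt
}

#' PCA report on score vectors
#'
#' Standardizes the features, drops zero-variance features with a warning,
#' and eigendecomposes the feature covariance. Component signs are fixed so
#' the largest-magnitude loading of each component is positive.
#'
#' @param score_vectors Data frame or matrix of score features (>= 3 rows).
#' @param labels Optional per-row labels carried into the scores for
#'   plotting.
#' @return A `ppap_pca`: list with `loadings`, `variance_fraction`, `sdev`,
#'   `scores` and `labels`.
#' @export
pca_report <- function(score_vectors, labels = NULL) {
  x <- as.matrix(score_vectors)
  stopifnot(nrow(x) >= 3L)
  sdev <- apply(x, 2L, stats::sd)
  if (any(sdev == 0)) {
    warn(paste0("dropping zero-variance feature(s): ",
                paste(colnames(x)[sdev == 0], collapse = ", ")))
    x <- x[, sdev > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = rot, variance_fraction = vf, sdev = pc$sdev,
                 scores = scores, labels = labels),
            class = "ppap_pca")
}

#' @export
print.ppap_pca <- function(x, ...) {
  cat("<ppap_pca>", ncol(x$loadings), "components; variance fractions:",
      paste(round(x$variance_fraction, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ppap_pca <- function(x, ...) {
  rot <- x$loadings
  tibble(component = rep(colnames(rot), each = nrow(rot)),
         term = rep(rownames(rot), times = ncol(rot)),
         loading = as.numeric(rot))
}

#' @export
glance.ppap_pca <- function(x, ...) {
  tibble(n_components = ncol(x$loadings),
         pc1_fraction = x$variance_fraction[1L],
         pc2_fraction = if (length(x$variance_fraction) > 1L)
           x$variance_fraction[2L] else NA_real_)
}
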