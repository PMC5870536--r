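# Six-feature score vectors, standardization, binary LDA classifiers and the
# cascaded four-way decision.
#
# For each of the three target reaction types a query gets one profile score
# (over the configured Area combination) and one correlation score, yielding
# a six-dimensional feature vector. Three binary discriminants (target vs
# rest) are applied in a fixed order; the first "yes" wins, and a query
# rejected by all three is called "other".

#' Pipeline configuration
#'
#' Defaults follow the published operating point of the method: profile
#' models over Area 1 + 3 + 4, pair selection at Z > 3.0, internal columns
#' kept up to 80% gaps, and the cascade order R-4-A, R-4-C, R-2-X.
#'
#' @param area_combo Areas concatenated for profile construction.
#' @param z_threshold MIp Z-score cutoff for pair selection.
#' @param gap_fraction Maximum column gap fraction kept by
#'   [filter_columns()].
#' @param target_types The three target reaction types, in cascade order.
#' @param backend Profile backend, `"pssm"` or `"hmmer"`.
#' @param align_method Query-addition method for [add_query_to_alignment()].
#' @param exclude_starters_from_lda Starter elements whose sequences are held
#'   out of discriminant fitting (long-chain starters by default) but still
#'   evaluated — they must come out as `"other"`.
#' @return A named list of class `ppap_config`.
#' @export
ppap_config <- function(area_combo = c("Area1", "Area3", "Area4"),
                        z_threshold = 3.0,
                        gap_fraction = 0.8,
                        target_types = TARGET_TYPES,
                        backend = c("pssm", "hmmer"),
                        align_method = c("builtin", "mafft", "auto"),
                        exclude_starters_from_lda = c("L", "Lh")) {
  stopifnot(length(target_types) == 3L, !anyDuplicated(target_types))
  structure(list(area_combo = area_combo,
                 z_threshold = z_threshold,
                 gap_fraction = gap_fraction,
                 target_types = target_types,
                 backend = match.arg(backend),
                 align_method = match.arg(align_method),
                 exclude_starters_from_lda = exclude_starters_from_lda),
            class = "ppap_config")
}

feature_names <- function(target_types) {
  c(paste0("hmm_", vapply(target_types, type_suffix, "")),
    paste0("cor_", vapply(target_types, type_suffix, "")))
}

# ---- standardizer --------------------------------------------------------

#' Fit a feature standardizer
#'
#' @param x Numeric matrix or data frame of features (training rows).
#' @return A `ppap_standardizer` with per-feature `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  if (any(sdev <= 0 | !is.finite(sdev))) {
    abort(paste0("zero-variance feature(s): ",
                 paste(colnames(x)[sdev <= 0 | !is.finite(sdev)],
                       collapse = ", ")))
  }
  structure(list(mean = mu, sd = sdev), class = "ppap_standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer A fitted `ppap_standardizer`.
#' @export
standardize <- function(standardizer, x) {
  x <- as.matrix(x)[, names(standardizer$mean), drop = FALSE]
  sweep(sweep(x, 2L, standardizer$mean), 2L, standardizer$sd, "/")
}

#' @rdname fit_standardizer
#' @export
unstandardize <- function(standardizer, x) {
  sweep(sweep(as.matrix(x), 2L, standardizer$sd, "*"), 2L,
        standardizer$mean, "+")
}

# ---- binary LDA ----------------------------------------------------------

#' Fit a two-class linear discriminant ("target vs rest")
#'
#' Fisher discriminant: `w` is proportional to the inverse pooled
#' within-class covariance times the difference of class means; the decision
#' boundary sits midway between the projected class means, shifted by the
#' log-ratio of the class priors (proportional to class sizes). The decision
#' is "yes" iff `w . v + b > 0` on standardized features.
#'
#' @param score_matrix Numeric matrix of standardized features.
#' @param is_target Logical vector, `TRUE` for the target class.
#' @param target_type Optional label recorded on the classifier.
#' @return An `lda_classifier` with `weights`, `intercept` and training
#'   metadata.
#' @export
fit_binary_lda <- function(score_matrix, is_target, target_type = NULL) {
  x <- as.matrix(score_matrix)
  stopifnot(nrow(x) == length(is_target))
  n1 <- sum(is_target)
  n0 <- sum(!is_target)
  if (n1 < 2L || n0 < 2L) abort("each class needs at least 2 samples")
  x1 <- x[is_target, , drop = FALSE]
  x0 <- x[!is_target, , drop = FALSE]
  m1 <- colMeans(x1)
  m0 <- colMeans(x0)
  S <- ((n1 - 1) * stats::cov(x1) + (n0 - 1) * stats::cov(x0)) / (n1 + n0 - 2)
  w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w)) {
    lambda <- 1e-6 * sum(diag(S)) / ncol(x)
    warn("singular pooled covariance; applying ridge regularization")
    w <- solve(S + diag(lambda, ncol(x)), m1 - m0)
  }
  b <- -sum(w * (m1 + m0)) / 2 + log(n1 / n0)
  structure(list(target_type = target_type,
                 weights = setNames(as.numeric(w), colnames(x)),
                 intercept = b,
                 class_means = rbind(target = m1, rest = m0),
                 priors = c(target = n1 / (n1 + n0), rest = n0 / (n1 + n0)),
                 n = c(target = n1, rest = n0)),
            class = "lda_classifier")
}

#' @export
print.lda_classifier <- function(x, ...) {
  cat("<lda_classifier>", x$target_type %||% "(unlabelled)", "vs rest;",
      "n =", x$n["target"], "/", x$n["rest"], "\n")
  invisible(x)
}

lda_decide <- function(classifier, std_vector) {
  d <- sum(classifier$weights * std_vector) + classifier$intercept
  list(yes = d > 0, discriminant = d)
}

# ---- cascade -------------------------------------------------------------

#' Apply the classifier cascade to one score vector
#'
#' The three binary classifiers are evaluated in the configured order
#' (default R-4-A, then R-4-C, then R-2-X); the first "yes" fixes the final
#' label, and if all three say "no" the query is labelled `"other"`. All
#' three binary outcomes are always recorded; when more than one classifier
#' fires, that is noted in the returned row.
#'
#' @param classifiers Named list of [fit_binary_lda()] classifiers, one per
#'   target type, in cascade order.
#' @param score_vector One-row tibble (or named numeric) of the six raw
#'   features.
#' @param standardizer The model's [fit_standardizer()] result.
#' @return One-row tibble: `final_label`, per-classifier `yes_*` and
#'   discriminant `d_*` columns, `n_yes`.
#' @export
apply_cascade <- function(classifiers, score_vector, standardizer) {
  types <- names(classifiers)
  stopifnot(length(types) == 3L)
  v <- as.numeric(as.matrix(as_tibble(as.list(score_vector))[
    , names(standardizer$mean), drop = FALSE]))
  if (any(!is.finite(v))) abort("score vector contains non-finite values")
  std <- (v - standardizer$mean) / standardizer$sd
  calls <- lapply(classifiers, lda_decide, std_vector = std)
  yes <- vapply(calls, function(c) c$yes, TRUE)
  d <- vapply(calls, function(c) c$discriminant, 1.0)
  final <- if (any(yes)) types[which(yes)[1L]] else "other"
  out <- tibble(final_label = final, n_yes = sum(yes))
  for (k in seq_along(types)) {
    out[[paste0("yes_", type_suffix(types[k]))]] <- yes[k]
    out[[paste0("d_", type_suffix(types[k]))]] <- d[k]
  }
  out
}

# ---- score assembly ------------------------------------------------------

# Align a query into one type's family alignment and return its gapped row
# over the original columns. A sequence that is already a row of the
# alignment is its own aligned row.
aligned_row_for <- function(id, residues, alignment, align_method) {
  if (id %in% aln_ids(alignment)) {
    return(alignment$mat[id, ])
  }
  ext <- add_query_to_alignment(tibble(id = id, residues = residues),
                                alignment, method = align_method)
  ext$mat[id, ]
}

# Score one aligned row against one type's artifacts. A query with no
# residues over the profile columns (e.g. a fragment that misses the Areas)
# counts as "no match" — clamped score 0 — rather than an error.
type_scores_for_row <- function(row, type_art) {
  seg_cols <- unlist(type_art$area_cols[type_art$area_combo],
                     use.names = FALSE)
  seg <- row[seg_cols]
  hmm <- if (!any(seg %in% AA20)) {
    inform("query has no residues over the profile columns; low coverage")
    clamp_hmm_score(NA_real_)
  } else {
    score_with_profile(type_art$profile, seg)
  }
  cor <- correlation_score(type_art$corr_model, row)
  c(hmm = hmm$clamped, cor = cor)
}

#' Assemble the six-feature score vector for a query
#'
#' For each target type the query is aligned into that type's family
#' alignment, its Area segment is scored against the type's profile (clamped
#' at zero), and its correlation score against the type's correlation model
#' is computed.
#'
#' @param query One-row tibble (or list) with `id` and `residues`.
#' @param model A fitted [ppap_fit()] model.
#' @return One-row tibble with the six features
#'   (`hmm_<type>`, `cor_<type>`).
#' @export
assemble_score_vector <- function(query, model) {
  qid <- as.character(query$id[[1L]])
  qres <- as.character(query$residues[[1L]])
  out <- list()
  for (t in model$config$target_types) {
    art <- model$types[[t]]
    row <- tryCatch(
      aligned_row_for(qid, qres, art$alignment, model$config$align_method),
      error = function(e) {
        abort(paste0("alignment of '", qid, "' into the ", t,
                     " family failed: ", conditionMessage(e)))
      })
    sc <- tryCatch(type_scores_for_row(row, art), error = function(e) {
      abort(paste0("scoring '", qid, "' against the ", t, " models failed: ",
                   conditionMessage(e)))
    })
    out[[paste0("hmm_", type_suffix(t))]] <- unname(sc["hmm"])
    out[[paste0("cor_", type_suffix(t))]] <- unname(sc["cor"])
  }
  as_tibble(out)
}

# ---- model fitting -------------------------------------------------------

# Build the per-type artifacts (area columns, profile, filtered columns,
# pair selection, correlation model) for one family alignment.
build_type_artifacts <- function(alignment, type, area_map_obj, reference,
                                 config) {
  aln <- alignment
  if (area_map_obj$reference_id %in% aln_ids(aln)) {
    area_cols <- map_reference_positions(aln, area_map_obj)
  } else {
    if (is.null(reference)) {
      abort(paste0("area-map reference '", area_map_obj$reference_id,
                   "' is not in the ", type, " alignment and no reference ",
                   "sequence was supplied"))
    }
    ext <- add_query_to_alignment(reference, aln,
                                  method = config$align_method)
    area_cols <- map_reference_positions(ext, area_map_obj)
  }
  seg <- extract_area_segments(aln, area_cols, config$area_combo)
  profile <- build_area_profile(seg, type, config$area_combo,
                                backend = config$backend)
  filtered <- filter_columns(aln, config$gap_fraction)
  ps <- compute_mip(mi_matrix(filtered$alignment))
  pairs <- select_correlated_pairs(ps, config$z_threshold)
  corr_model <- build_correlation_model(filtered, pairs, reaction_type = type)
  list(alignment = aln,
       area_cols = area_cols,
       area_combo = config$area_combo,
       profile = profile,
       filtered = filtered,
       corr_model = corr_model,
       provenance = provenance_stamp(aln_ids(aln)))
}

#' Fit the full reaction-type predictor
#'
#' Builds, for each target reaction type, the Area profile and the
#' correlation model from that type's family alignment; assembles the
#' six-feature score vector for every training sequence; standardizes the
#' features; and fits the three binary discriminants. Sequences whose
#' starter element is in `config$exclude_starters_from_lda` (long-chain
#' starters by default) are scored but held out of discriminant fitting.
#'
#' @param sequences Tibble with `id`, `residues`, `reaction_type` covering
#'   every training sequence (target families and "other" types).
#' @param alignments Named list of [ppap_alignment] objects, one per target
#'   type (names matching `config$target_types`); rows must be ids present
#'   in `sequences`.
#' @param map An [area_map()]. If its reference id is not a row of a family
#'   alignment, supply `reference`.
#' @param reference Optional one-row tibble (`id`, `residues`) of the
#'   area-map reference sequence.
#' @param config A [ppap_config()].
#' @return A `ppap_model`.
#' @export
ppap_fit <- function(sequences, alignments, map, reference = NULL,
                     config = ppap_config()) {
  stopifnot(all(c("id", "residues", "reaction_type") %in% names(sequences)))
  missing_types <- setdiff(config$target_types, names(alignments))
  if (length(missing_types) > 0L) {
    abort(paste0("missing family alignment(s) for: ",
                 paste(missing_types, collapse = ", ")))
  }
  types <- lapply(config$target_types, function(t) {
    aln <- alignments[[t]]
    aln$family_label <- t
    build_type_artifacts(aln, t, map, reference, config)
  })
  names(types) <- config$target_types

  model <- structure(list(config = config, area_map = map,
                          reference = reference, types = types),
                     class = "ppap_model")

  feats <- feature_names(config$target_types)
  score_tbl <- purrr::map_dfr(seq_len(nrow(sequences)), function(k) {
    assemble_score_vector(sequences[k, ], model)
  })
  train_scores <- dplyr::bind_cols(
    sequences |> select("id", "reaction_type"), score_tbl) |>
    mutate(group = reaction_type_group(.data$reaction_type),
           in_lda = !(label_starter(.data$reaction_type) %in%
                        config$exclude_starters_from_lda))

  fit_rows <- train_scores |> filter(.data$in_lda)
  standardizer <- fit_standardizer(fit_rows[, feats])
  std <- standardize(standardizer, fit_rows[, feats])
  ldas <- lapply(config$target_types, function(t) {
    fit_binary_lda(std, fit_rows$group == t, target_type = t)
  })
  names(ldas) <- config$target_types

  model$standardizer <- standardizer
  model$ldas <- ldas
  model$train_scores <- train_scores
  model$provenance <- provenance_stamp(fit_rows$id)
  model
}

#' @export
print.ppap_model <- function(x, ...) {
  cat("<ppap_model> targets:", paste(x$config$target_types, collapse = ", "),
      "\n  areas:", paste(x$config$area_combo, collapse = "+"),
      "| profile backend:", x$config$backend,
      "\n  training sequences:", nrow(x$train_scores),
      "(", sum(x$train_scores$in_lda), "in LDA )\n")
  for (t in x$config$target_types) {
    cm <- x$types[[t]]$corr_model
    cat("  ", t, ": ", cm$N, " seqs, ", nrow(cm$pairs),
        " correlated pairs\n", sep = "")
  }
  invisible(x)
}

#' Predict reaction types for query sequences
#'
#' @param object A fitted `ppap_model`.
#' @param new_data Tibble with `id` and `residues` columns.
#' @param ... Unused.
#' @return Tibble, one row per query in input order: `query_id`,
#'   `final_label`, per-classifier `yes_*`/`d_*` calls and the six raw
#'   scores.
#' @export
predict.ppap_model <- function(object, new_data, ...) {
  stopifnot(all(c("id", "residues") %in% names(new_data)))
  if (nrow(new_data) == 0L) abort("no query sequences")
  purrr::map_dfr(seq_len(nrow(new_data)), function(k) {
    sv <- assemble_score_vector(new_data[k, ], object)
    dec <- apply_cascade(object$ldas, sv, object$standardizer)
    dplyr::bind_cols(tibble(query_id = new_data$id[k]), dec, sv)
  })
}

#' @export
tidy.ppap_model <- function(x, ...) {
  purrr::map_dfr(x$ldas, function(l) {
    tibble(classifier = l$target_type,
           term = c(names(l$weights), "(intercept)"),
           estimate = c(unname(l$weights), l$intercept))
  })
}

#' @export
glance.ppap_model <- function(x, ...) {
  tibble(n_train = nrow(x$train_scores),
         n_lda = sum(x$train_scores$in_lda),
         n_pairs_total = sum(vapply(x$types,
                                    function(t) nrow(t$corr_model$pairs), 1L)),
         area_combo = paste(x$config$area_combo, collapse = "+"),
         backend = x$config$backend,
         z_threshold = x$config$z_threshold)
}
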