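# JSON serialization of the fitted model bundle. Counts are stored as
# integers and smoothing parameters are recomputed on load, so a reloaded
# correlation model reproduces scores exactly.

aln_to_list <- function(aln) {
  tb <- as_tibble(aln)
  list(ids = tb$id, rows = tb$aligned, family_label = aln$family_label)
}

aln_from_list <- function(x) {
  ppap_alignment(unlist(x$ids), unlist(x$rows),
                 family_label = x$family_label %||% NULL)
}

#' Write a fitted model bundle to JSON
#'
#' The bundle contains the configuration, area map, per-type alignments,
#' profiles, correlation models (sparse counts), the standardizer, the three
#' discriminants, training score vectors and provenance stamps.
#' [read_ppap_model()] restores a model whose predictions equal the
#' original's.
#'
#' @param model A [ppap_fit()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ppap_model <- function(model, path) {
  types <- lapply(model$types, function(art) {
    cm <- art$corr_model
    prof <- art$profile
    list(alignment = aln_to_list(art$alignment),
         area_cols = art$area_cols,
         area_combo = art$area_combo,
         profile = list(reaction_type = prof$reaction_type,
                        area_combo = prof$area_combo,
                        backend = prof$backend,
                        n_cols = prof$n_cols,
                        log_odds = if (prof$backend == "pssm")
                          prof$data$log_odds else NULL,
                        hmm_text = if (prof$backend == "hmmer")
                          prof$data$hmm_text else NULL,
                        training_ids = prof$training_ids,
                        provenance = prof$provenance),
         filtered = list(kept_columns = cm$kept_columns,
                         max_gap_fraction = art$filtered$max_gap_fraction),
         corr_model = list(reaction_type = cm$reaction_type,
                           N = cm$N,
                           kept_columns = cm$kept_columns,
                           n_filtered_cols = cm$n_filtered_cols,
                           pairs = as.data.frame(cm$pairs),
                           pair_attrs = list(
                             threshold = attr(cm$pairs, "threshold"),
                             mu = attr(cm$pairs, "mu"),
                             sd = attr(cm$pairs, "sd")),
                           single_counts = cm$single_counts,
                           pair_count_keys = names(cm$pair_counts),
                           pair_count_values = unname(cm$pair_counts),
                           training_ids = cm$training_ids,
                           provenance = cm$provenance),
         provenance = art$provenance)
  })
  bundle <- list(
    format = "ppap_model",
    version = 1L,
    config = unclass(model$config),
    area_map = list(reference_id = model$area_map$reference_id,
                    segments = as.data.frame(model$area_map$segments)),
    reference = if (is.null(model$reference)) NULL else
      as.data.frame(model$reference),
    types = types,
    standardizer = list(mean = as.list(model$standardizer$mean),
                        sd = as.list(model$standardizer$sd)),
    ldas = lapply(model$ldas, function(l) {
      list(target_type = l$target_type,
           weights = as.list(l$weights),
           intercept = l$intercept,
           n = as.list(l$n))
    }),
    train_scores = as.data.frame(model$train_scores),
    provenance = model$provenance)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model bundle from JSON
#'
#' @param path Path written by [write_ppap_model()].
#' @return A `ppap_model`.
#' @export
read_ppap_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "ppap_model")) {
    abort(paste0(path, " is not a ppap model bundle"))
  }
  cfg <- b$config
  class(cfg) <- "ppap_config"
  map <- area_map(b$area_map$reference_id, as_tibble(b$area_map$segments))
  types <- lapply(b$types, function(tt) {
    aln <- aln_from_list(tt$alignment)
    lo <- NULL
    if (identical(tt$profile$backend, "pssm")) {
      lo <- as.matrix(tt$profile$log_odds)
      dimnames(lo) <- list(AA20, NULL)
    }
    prof <- structure(list(reaction_type = tt$profile$reaction_type,
                           area_combo = tt$profile$area_combo,
                           backend = tt$profile$backend,
                           n_cols = tt$profile$n_cols,
                           data = if (is.null(lo))
                             list(hmm_text = tt$profile$hmm_text)
                           else list(log_odds = lo),
                           training_ids = tt$profile$training_ids,
                           provenance = tt$profile$provenance),
                      class = "ppap_profile")
    kept <- as.integer(tt$corr_model$kept_columns)
    filtered <- structure(
      list(alignment = aln_subset(aln, cols = kept),
           kept_columns = kept,
           max_gap_fraction = tt$filtered$max_gap_fraction),
      class = "filtered_alignment")
    pairs <- as_tibble(tt$corr_model$pairs) |>
      mutate(i = as.integer(.data$i), j = as.integer(.data$j))
    attr(pairs, "threshold") <- tt$corr_model$pair_attrs$threshold
    attr(pairs, "mu") <- tt$corr_model$pair_attrs$mu
    attr(pairs, "sd") <- tt$corr_model$pair_attrs$sd
    attr(pairs, "C") <- nrow(pairs)
    class(pairs) <- c("pair_selection", class(pairs))
    sc <- as.matrix(tt$corr_model$single_counts)
    storage.mode(sc) <- "integer"
    dimnames(sc) <- list(AA21, NULL)
    cm <- structure(list(reaction_type = tt$corr_model$reaction_type,
                         N = as.integer(tt$corr_model$N),
                         kept_columns = kept,
                         n_filtered_cols =
                           as.integer(tt$corr_model$n_filtered_cols),
                         pairs = pairs,
                         single_counts = sc,
                         pair_counts = setNames(
                           as.integer(tt$corr_model$pair_count_values),
                           tt$corr_model$pair_count_keys),
                         smoothing = smoothing_params(tt$corr_model$N),
                         training_ids = tt$corr_model$training_ids,
                         provenance = tt$corr_model$provenance),
                    class = "correlation_model")
    list(alignment = aln, area_cols = lapply(tt$area_cols, as.integer),
         area_combo = tt$area_combo, profile = prof, filtered = filtered,
         corr_model = cm, provenance = tt$provenance)
  })
  std <- structure(list(mean = unlist(b$standardizer$mean),
                        sd = unlist(b$standardizer$sd)),
                   class = "ppap_standardizer")
  ldas <- lapply(b$ldas, function(l) {
    structure(list(target_type = l$target_type,
                   weights = unlist(l$weights),
                   intercept = l$intercept,
                   n = unlist(l$n)),
              class = "lda_classifier")
  })
  structure(list(config = cfg, area_map = map,
                 reference = if (is.null(b$reference)) NULL else
                   as_tibble(b$reference),
                 types = types, standardizer = std, ldas = ldas,
                 train_scores = as_tibble(b$train_scores),
                 provenance = b$provenance),
            class = "ppap_model")
}
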