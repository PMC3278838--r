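#' End-to-end hexmer classification pipeline
#'
#' Wires the full architecture together: encode the labeled hexmers as
#' per-property means over an index collection, pre-select a candidate
#' property pool with the embedded linear SVM, optionally refine it to the
#' final 40-property subset with the memetic algorithm, build the requested
#' prediction-model configuration (the 5 autocorrelation properties are the
#' top-5 of the pre-selection ranking), train the feed-forward network on a
#' stratified 60/20/20 split, and evaluate on the held-out test partition.
#'
#' Pre-selection, normalization, and the memetic search see only the
#' training partition; the test partition is touched once, for the final
#' evaluation.
#'
#' @param hexmers Labeled hexmer tibble (`sequence`, `label`), e.g. from
#'   [synthesize_hexmers()] or [sliding_hexmers()].
#' @param indices Index tibble; needs at least `preselect_k` indices.
#' @param pm_id Which prediction model to build (default `"PM3"`).
#' @param preselect_k Pool size kept by [embedded_preselect()].
#' @param selection `"memetic"` (default) runs [run_memetic()] on the pool;
#'   `"preselect"` keeps the top properties of the embedded ranking
#'   directly.
#' @param subset_size Final number of BPC properties (default 40).
#' @param ma_generations,ma_pop_size,ma_patience Memetic-algorithm budget.
#' @param ma_sample Stratified subsample of the training partition used for
#'   the SVM fitness (keeps the search affordable; `Inf` = all).
#' @param fractions Train/validation/test fractions.
#' @param threshold Decision threshold for the final evaluation.
#' @param seed Seed driving every stochastic stage.
#' @return An `amyhex_pipeline` list: `selection` (chosen accessions and
#'   how), `preselect` (embedded ranking), `ma` (the `memetic_result` or
#'   `NULL`), `pm` (the [pm_config()]), `model` (the trained network),
#'   `evaluation` (an `amyhex_eval` on the test partition), `predictions`
#'   (test-set tibble with `score`), and `seed`.
#' @examples
#' \donttest{
#' hex <- synthesize_hexmers(n_pos = 150, n_neg = 150, seed = 1)
#' idx <- synthesize_indices(50, seed = 1)
#' fit <- amyhex_pipeline(hex, idx, preselect_k = 45,
#'                        selection = "preselect", seed = 1)
#' glance(fit$evaluation)
#' }
#' @export
amyhex_pipeline <- function(hexmers, indices, pm_id = "PM3",
                            preselect_k = 186L,
                            selection = c("memetic", "preselect"),
                            subset_size = 40L,
                            ma_generations = 100L, ma_pop_size = 10L,
                            ma_patience = 15L, ma_sample = 500L,
                            fractions = c(0.6, 0.2, 0.2),
                            threshold = 0.5, seed = 1L) {
  selection <- match.arg(selection)
  stopifnot("label" %in% names(hexmers))
  preselect_k <- min(as.integer(preselect_k), nrow(indices))
  seed <- as.integer(seed)

  # Stage 1: per-property means over every candidate index.
  all_cfg <- encoding_config(bpc = indices$accession, blocks = "BPC")
  bpc_all <- encode_hexmers(hexmers, indices, all_cfg)
  parts <- split_data(bpc_all, fractions, seed = seed)
  norm <- fit_minmax(parts$train)
  train_norm <- apply_minmax(parts$train, norm)

  # Stage 2: embedded pre-selection to the candidate pool.
  ranking <- embedded_preselect(train_norm, k = preselect_k)
  pool <- ranking$feature
  ac_accessions <- head(pool, 5L)

  # Stage 3: memetic refinement of the pool (on the training data only).
  ma <- NULL
  if (selection == "memetic") {
    ma_data <- train_norm
    if (is.finite(ma_sample) && nrow(ma_data) > ma_sample) {
      keep <- integer(0)
      with_seed(seed + 13L, {
        for (cl in unique(ma_data$label)) {
          idx_cl <- which(ma_data$label == cl)
          n_cl <- round(ma_sample * length(idx_cl) / nrow(ma_data))
          keep <- c(keep, sample(idx_cl, min(n_cl, length(idx_cl))))
        }
      })
      ma_data <- ma_data[sort(keep), , drop = FALSE]
    }
    cfg <- ma_config(pool = pool, pop_size = ma_pop_size,
                     subset_size = subset_size,
                     generations = ma_generations,
                     patience = ma_patience, seed = seed)
    ma <- run_memetic(ma_data, cfg)
    bpc_selected <- ma$best$subset
  } else {
    bpc_selected <- head(pool, subset_size)
  }

  # Stage 4: encode the chosen blocks, train, evaluate held-out.
  pm <- pm_config(pm_id, bpc = bpc_selected, ac = ac_accessions,
                  seed = seed)
  encoded <- encode_hexmers(hexmers, indices, pm$encoding)
  parts_pm <- split_data(encoded, fractions, seed = seed)
  model <- train_ann(parts_pm$train, parts_pm$validation, pm)
  predictions <- mutate(parts_pm$test,
                        score = predict_scores(model, parts_pm$test))
  predictions <- select(predictions, any_of(c("sequence", "label", "score")))
  evaluation <- evaluate_predictions(predictions, threshold = threshold)

  structure(
    list(selection = list(bpc = sort(bpc_selected), ac = ac_accessions,
                          method = selection),
         preselect = ranking, ma = ma, pm = pm, model = model,
         evaluation = evaluation, predictions = predictions,
         n = map_int(parts_pm, nrow), seed = seed),
    class = "amyhex_pipeline")
}

#' @export
print.amyhex_pipeline <- function(x, ...) {
  g <- glance(x$evaluation)
  cat(sprintf(
    paste0("<amyhex_pipeline> %s | selection: %s | split %s\n",
           "  test: Sn %.3f  Sp %.3f  BACC %.3f  MCC %.3f  AUC %.3f",
           "  (quadrant %s)\n"),
    x$pm$pm_id, x$selection$method,
    paste(x$n, collapse = "/"),
    g$sensitivity, g$specificity, g$bacc, g$mcc, g$auc, g$quadrant))
  invisible(x)
}

#' @describeIn amyhex_pipeline Held-out test metrics as a one-row tibble.
#' @param x An `amyhex_pipeline`.
#' @param ... Unused.
#' @method glance amyhex_pipeline
#' @export
glance.amyhex_pipeline <- function(x, ...) {
  bind_cols(tibble(pm_id = x$pm$pm_id, selection = x$selection$method),
            glance(x$evaluation))
}
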