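#' Predict log2 ER with any scoring model
#'
#' Dispatch helper used by the design stage so toy scoring functions can
#' stand in for trained ensembles in tests and examples: an `mlp_ensemble`
#' is used through its predict method; a bare function is called on the
#' signature vector.
#'
#' @param model An `mlp_ensemble` or a `function(signatures) -> numeric`.
#' @param signatures Character vector of signatures.
#' @return Numeric predictions.
#' @export
predict_log2_er <- function(model, signatures) {
  if (inherits(model, "mlp_ensemble")) {
    predict(model, signatures)
  } else if (is.function(model)) {
    as.numeric(model(signatures))
  } else {
    stop("`model` must be an mlp_ensemble or a function", call. = FALSE)
  }
}

keep_top_k <- function(current, signatures, predictions, k, decreasing) {
  cand <- dplyr::bind_rows(
    current,
    tibble::tibble(signature = signatures, prediction = predictions)
  )
  cand <- dplyr::distinct(cand, .data$signature, .keep_all = TRUE)
  ord <- order(if (decreasing) -cand$prediction else cand$prediction,
               cand$signature)
  cand[ord[seq_len(min(k, nrow(cand)))], ]
}

#' Top-k fully mutated variants by predicted log2 ER
#'
#' Streams the fully mutated space (every targeted position non-WT) in
#' batches, scores each batch with the model, and keeps a running top-k
#' (ties broken by ascending signature). The result does not depend on the
#' choice of batch positions. For spaces too large to enumerate on a
#' desktop (19^7 for the default scheme), `mode = "sampled"` scores `n`
#' uniform draws from the fully mutated space instead and returns the top-k
#' of the sample.
#'
#' @param model An `mlp_ensemble` or scoring function.
#' @param scheme A [reference_scheme()].
#' @param k Number of candidates (default 5).
#' @param mode `"exhaustive"` (batched scan) or `"sampled"`.
#' @param batch_positions Positions fixed per batch in exhaustive mode.
#' @param n,seed Sample size and seed for sampled mode.
#' @param decreasing If `TRUE` (default) the strongest *high* predictions
#'   win; set `FALSE` when the model's scale is inverted (e.g. a
#'   low-stringency gate model, where strong binders are depleted).
#' @return Tibble `signature`, `prediction`, `rank`.
#' @export
top_k_fully_mutated <- function(model, scheme, k = 5L,
                                mode = c("exhaustive", "sampled"),
                                batch_positions = utils::tail(scheme$positions, 2),
                                n = 1e5, seed = 1L, decreasing = TRUE) {
  mode <- match.arg(mode)
  if (mode == "exhaustive") {
    if (k > fully_mutated_count(scheme)) {
      stop("`k` exceeds the size of the fully mutated space", call. = FALSE)
    }
    idx <- fully_mutated_batches(scheme, batch_positions)
    top <- NULL
    for (b in seq_len(nrow(idx))) {
      sigs <- fully_mutated_batch(scheme, b, batch_positions)
      top <- keep_top_k(top, sigs, predict_log2_er(model, sigs), k,
                        decreasing)
    }
  } else {
    sigs <- unique(sample_fully_mutated(scheme, n, seed))
    if (k > length(sigs)) stop("`k` exceeds the sampled candidate set",
                               call. = FALSE)
    top <- keep_top_k(NULL, sigs, predict_log2_er(model, sigs), k,
                      decreasing)
  }
  dplyr::mutate(top, rank = dplyr::row_number())
}

#' Selectivity percentile of candidates against a model
#'
#' The percentage of the full variant space (`alphabet^n_positions`, WT
#' letters included) whose predicted log2 ER is strictly greater than the
#' candidate's prediction — ties count as not exceeding. A low percentile
#' against an on-target model means few variants look better; a low
#' percentile against an off-target model flags an (unwanted) strong
#' off-target binder.
#'
#' Exhaustive mode enumerates the space (reduced schemes only); sampled
#' mode evaluates `n` uniform draws and reports the Monte-Carlo standard
#' error of each estimate.
#'
#' @param candidates Character vector of candidate signatures.
#' @param model An `mlp_ensemble` or scoring function.
#' @param scheme A [reference_scheme()].
#' @param mode `"sampled"` (default) or `"exhaustive"`.
#' @param n,seed Sample size (default 1e6) and seed for sampled mode.
#' @return Tibble `signature`, `prediction`, `percentile` (0-100), and in
#'   sampled mode `se` (standard error, percentage points).
#' @export
selectivity_percentile <- function(candidates, model, scheme,
                                   mode = c("sampled", "exhaustive"),
                                   n = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "sampled") {
    if (n < 10) stop("sampled mode needs n >= 10", call. = FALSE)
    if (n < 1000) warning("fewer than 1000 samples: percentile estimates ",
                          "will be coarse")
    space <- sample_variant_space(scheme, n, seed)
  } else {
    space <- enumerate_space(scheme)
  }
  space_pred <- predict_log2_er(model, space)
  cand_pred <- predict_log2_er(model, candidates)
  m <- length(space_pred)
  pct <- vapply(cand_pred,
                function(p) 100 * sum(space_pred > p) / m, numeric(1))
  out <- tibble::tibble(signature = candidates, prediction = cand_pred,
                        percentile = pct)
  if (mode == "sampled") {
    out$se <- 100 * sqrt(pmax(pct / 100 * (1 - pct / 100), 0) / m)
  }
  out
}

#' Rank candidate variants across target and off-target models
#'
#' Builds the candidate report of the design stage: for each candidate, the
#' predicted log2 ER under the primary (design-target) model and under each
#' off-target model, plus the selectivity percentile against every
#' off-target model. Candidates are ranked by the primary prediction; the
#' final pick among top candidates is left to the scientist.
#'
#' @param candidates Character vector of candidate signatures.
#' @param primary_model Model used for ranking.
#' @param off_target_models Named list of models to profile against.
#' @param scheme A [reference_scheme()].
#' @param mode,n,seed Passed to [selectivity_percentile()].
#' @param decreasing Rank direction for the primary prediction.
#' @return Tibble with `signature`, `rank`, `pred_primary`, and per
#'   off-target model `pred_<name>` and `pct_<name>` columns.
#' @export
rank_candidates <- function(candidates, primary_model, off_target_models,
                            scheme, mode = c("sampled", "exhaustive"),
                            n = 1e6, seed = 1L, decreasing = TRUE) {
  stopifnot(length(candidates) >= 1L, length(off_target_models) >= 1L)
  if (is.null(names(off_target_models)) ||
      any(!nzchar(names(off_target_models)))) {
    stop("`off_target_models` must be a named list", call. = FALSE)
  }
  mode <- match.arg(mode)
  out <- tibble::tibble(
    signature = candidates,
    pred_primary = predict_log2_er(primary_model, candidates)
  )
  for (nm in names(off_target_models)) {
    pc <- selectivity_percentile(candidates, off_target_models[[nm]], scheme,
                                 mode = mode, n = n, seed = seed)
    out[[paste0("pred_", nm)]] <- pc$prediction
    out[[paste0("pct_", nm)]] <- pc$percentile
  }
  ord <- order(if (decreasing) -out$pred_primary else out$pred_primary,
               out$signature)
  out <- out[ord, ]
  dplyr::relocate(dplyr::mutate(out, rank = dplyr::row_number()),
                  "signature", "rank")
}
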