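#' Save / load a trained ensemble as a portable JSON container
#'
#' The container stores per-member layer matrices, the hyper-parameters,
#' member seeds, and the reference scheme — no framework-specific blobs —
#' so models round-trip across machines and sessions exactly.
#'
#' @param model An `mlp_ensemble`.
#' @param path Output `.json` path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the restored
#'   `mlp_ensemble`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_ensemble"))
  obj <- list(
    format = "dmsdesign-ensemble-v1",
    hp = unclass(model$hp),
    seeds = model$seeds,
    n_train = model$n_train,
    scheme = list(
      wt_sequence = model$scheme$wt_sequence,
      positions = model$scheme$positions,
      alphabet = model$scheme$alphabet
    ),
    members = lapply(model$members, function(m) {
      list(seed = m$seed, final_loss = m$final_loss,
           params = lapply(m$params, function(p) {
             if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
             else list(dim = NULL, values = as.numeric(p))
           }))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  stopifnot(identical(obj$format, "dmsdesign-ensemble-v1"))
  scheme <- reference_scheme(obj$scheme$wt_sequence,
                             positions = obj$scheme$positions,
                             alphabet = obj$scheme$alphabet)
  hp <- hyperparams(
    batch_size = obj$hp$batch_size, epochs = obj$hp$epochs,
    learning_rate = obj$hp$learning_rate,
    architecture = obj$hp$architecture,
    sample_weighting = obj$hp$sample_weighting,
    base_seed = obj$hp$base_seed
  )
  arch <- architecture_spec(hp$architecture)
  members <- lapply(obj$members, function(m) {
    params <- lapply(m$params, function(p) {
      v <- as.numeric(unlist(p$values))
      d <- unlist(p$dim)
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
    })
    structure(list(params = params, arch = arch, seed = m$seed,
                   final_loss = m$final_loss),
              class = "mlp_member")
  })
  structure(
    list(members = members, hp = hp, scheme = scheme,
         seeds = as.integer(unlist(obj$seeds)), n_train = obj$n_train),
    class = "mlp_ensemble"
  )
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Enrichment stage of the pipeline
#'
#' Reads one FASTA (or pre-tabulated counts TSV with columns `signature`,
#' `count`) per gate, counts signatures, computes enrichment ratios of
#' every sorted gate against the presort fraction, and — when `out_dir` is
#' given — writes per-gate counts TSVs, per-gate enrichment TSVs, a
#' rejection-stats JSON, and a mutation-number inventory TSV.
#'
#' @param manifest Tibble with columns `gate` (labels; exactly one must be
#'   `"PRESORT"`) and `path`.
#' @param scheme A [reference_scheme()].
#' @param out_dir Optional output directory.
#' @param pseudocount Passed to [enrichment_ratios()].
#' @return List with `counts` (named list of count tables), `enrichment`
#'   (named list of enrichment tibbles), `inventory`, `rejections`.
#' @export
run_enrich <- function(manifest, scheme, out_dir = NULL, pseudocount = 0) {
  stopifnot(all(c("gate", "path") %in% names(manifest)))
  if (sum(manifest$gate == "PRESORT") != 1L) {
    stop("manifest must contain exactly one PRESORT gate", call. = FALSE)
  }
  if (nrow(manifest) < 2L) {
    stop("manifest needs at least one sorted gate besides PRESORT",
         call. = FALSE)
  }
  read_gate <- function(path, gate) {
    if (grepl("\\.tsv$", path)) {
      tab <- readr::read_tsv(path, show_col_types = FALSE)
      stopifnot(all(c("signature", "count") %in% names(tab)))
      tab <- tibble::as_tibble(tab[c("signature", "count")])
      attr(tab, "gate") <- gate
      attr(tab, "total_reads") <- sum(tab$count)
      tab
    } else {
      count_reads(path, scheme, gate = gate)
    }
  }
  counts <- purrr::map2(manifest$path, manifest$gate, read_gate)
  names(counts) <- manifest$gate
  tryCatch(
    invisible(wt_frequency(variant_frequencies(counts[["PRESORT"]]), scheme)),
    error = function(e) stop("gate PRESORT: ", conditionMessage(e),
                             call. = FALSE)
  )
  sorted_gates <- setdiff(manifest$gate, "PRESORT")
  enrichment <- purrr::map(sorted_gates, function(g) {
    tryCatch(
      enrichment_ratios(counts[["PRESORT"]], counts[[g]], scheme,
                        pseudocount = pseudocount),
      error = function(e) stop("gate ", g, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  })
  names(enrichment) <- sorted_gates
  inventory <- purrr::map_dfr(manifest$gate, function(g) {
    dplyr::mutate(mutation_inventory(counts[[g]], scheme), gate = g,
                  .before = 1)
  })
  rejections <- purrr::map_dfr(manifest$gate, function(g) {
    dplyr::mutate(rejection_stats(counts[[g]]), gate = g, .before = 1)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in manifest$gate) {
      write_tsv_file(counts[[g]], file.path(out_dir,
                                            paste0("counts_", g, ".tsv")))
    }
    for (g in sorted_gates) {
      write_tsv_file(enrichment[[g]],
                     file.path(out_dir, paste0("enrichment_", g, ".tsv")))
    }
    write_tsv_file(inventory, file.path(out_dir, "inventory.tsv"))
    jsonlite::write_json(
      split(rejections[c("reason", "n")], rejections$gate),
      file.path(out_dir, "rejection_stats.json")
    )
  }
  list(counts = counts, enrichment = enrichment, inventory = inventory,
       rejections = rejections)
}

#' Training stage of the pipeline
#'
#' Runs the depth split and hyper-parameter grid search for one gate's
#' training table and optionally persists the winning model and the
#' leaderboard.
#'
#' @param training Training table (from [build_training_table()]) or path
#'   to its TSV.
#' @param scheme A [reference_scheme()].
#' @param grid Hyper-parameter grid tibble (default: a pragmatic small
#'   grid; pass [hp_grid()] for the full 720-combination search).
#' @param n_members Ensemble size (default 10).
#' @param base_seed Base seed.
#' @param out_dir Optional output directory (`model.json`,
#'   `leaderboard.tsv`).
#' @return The [grid_search()] result list.
#' @export
run_train <- function(training, scheme,
                      grid = hp_grid(batch_size = 32L, epochs = 30L,
                                     learning_rate = c(1e-3, 5e-3),
                                     architecture = c("Lib", "Ala"),
                                     sample_weighting = "with-weight"),
                      n_members = 10L, base_seed = 1L, out_dir = NULL) {
  if (is.character(training)) {
    training <- readr::read_tsv(training, show_col_types = FALSE)
  }
  res <- grid_search(training, scheme, grid = grid, n_members = n_members,
                     base_seed = base_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(res$model, file.path(out_dir, "model.json"))
    write_tsv_file(res$leaderboard, file.path(out_dir, "leaderboard.tsv"))
    jsonlite::write_json(
      list(best_hp = unclass(res$best_hp), val_pearson = res$val_pearson,
           test_pearson = res$test_pearson, base_seed = base_seed,
           n_members = n_members),
      file.path(out_dir, "training_summary.json"), auto_unbox = TRUE
    )
  }
  res
}

#' Design stage of the pipeline
#'
#' Selects the top-k fully mutated candidates under the primary model and
#' profiles them against the off-target models; optionally writes the
#' candidate report as TSV and JSON.
#'
#' @param primary_model,off_target_models Models (see
#'   [predict_log2_er()]); `off_target_models` must be a named list.
#' @param scheme A [reference_scheme()].
#' @param k Number of candidates.
#' @param mode `"sampled"` or `"exhaustive"` (space scan mode for both the
#'   candidate search and the percentiles).
#' @param n,seed Monte-Carlo size and seed for sampled mode.
#' @param decreasing Direction in which the primary prediction is "better".
#' @param out_dir Optional output directory.
#' @return Candidate report tibble from [rank_candidates()].
#' @export
run_design <- function(primary_model, off_target_models, scheme, k = 5L,
                       mode = c("sampled", "exhaustive"), n = 1e5,
                       seed = 1L, decreasing = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  top <- top_k_fully_mutated(primary_model, scheme, k = k, mode = mode,
                             n = n, seed = seed, decreasing = decreasing)
  report <- rank_candidates(top$signature, primary_model, off_target_models,
                            scheme, mode = mode, n = n, seed = seed,
                            decreasing = decreasing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_file(report, file.path(out_dir, "candidate_report.tsv"))
    jsonlite::write_json(
      list(k = k, mode = mode, n = n, seed = seed, decreasing = decreasing,
           candidates = report),
      file.path(out_dir, "candidate_report.json"), auto_unbox = TRUE,
      digits = NA
    )
  }
  report
}

#' Kinetics stage of the pipeline
#'
#' Fits Ki for each enzyme's inhibition curves at its assay constants and
#' assembles the selectivity (fold-change) profile against the reference
#' enzyme.
#'
#' @param curves Named list of tibbles (or TSV paths), one per enzyme, each
#'   with columns `inhibitor_nM`, `velocity`, optional `replicate`.
#' @param constants Tibble with columns `enzyme`, `E_nM`, `S_uM`, `Km_uM`.
#' @param reference Reference enzyme for fold changes.
#' @param out_dir Optional output directory.
#' @return List with `fits` (named list of `ki_fit`) and `profile`
#'   (fold-change tibble).
#' @export
run_kinetics <- function(curves, constants, reference, out_dir = NULL) {
  stopifnot(all(c("enzyme", "E_nM", "S_uM", "Km_uM") %in% names(constants)))
  fits <- purrr::map(names(curves), function(enz) {
    d <- curves[[enz]]
    if (is.character(d)) d <- readr::read_tsv(d, show_col_types = FALSE)
    if (!all(c("inhibitor_nM", "velocity") %in% names(d))) {
      stop("curves for ", enz,
           " need columns inhibitor_nM and velocity", call. = FALSE)
    }
    i <- match(enz, constants$enzyme)
    if (is.na(i)) stop("no assay constants for enzyme ", enz, call. = FALSE)
    fit_ki(d, E = constants$E_nM[i], S = constants$S_uM[i],
           Km = constants$Km_uM[i])
  })
  names(fits) <- names(curves)
  ki_table <- tibble::tibble(
    enzyme = names(fits),
    ki = vapply(fits, function(f) f$ki, numeric(1), USE.NAMES = FALSE),
    ki_sd = vapply(fits, function(f) f$ki_sd, numeric(1),
                   USE.NAMES = FALSE),
    kiapp = vapply(fits, function(f) f$kiapp, numeric(1),
                   USE.NAMES = FALSE)
  )
  profile <- fold_changes(ki_table, reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_file(profile, file.path(out_dir, "selectivity_profile.tsv"))
    jsonlite::write_json(
      purrr::map(fits, function(f) as.list(glance(f))),
      file.path(out_dir, "ki_fits.json"), auto_unbox = TRUE, digits = NA
    )
  }
  list(fits = fits, profile = profile)
}
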