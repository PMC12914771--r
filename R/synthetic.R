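#' Fabricated wild-type reference sequence
#'
#' A synthetic 127-residue protein with the canonical wild-type interface
#' residues S, I, N, S, V, H, T planted at positions 4, 35, 38, 68, 71, 97,
#' 99. The remaining positions simply cycle the amino-acid alphabet, so the
#' sequence is deterministic and clearly artificial — it stands in for a
#' real scaffold sequence, which is a required input for real data.
#'
#' @return A single character string of length 127.
#' @export
synthetic_wt_sequence <- function() {
  chars <- rep(AA_ALPHABET, length.out = 127L)
  plant <- c(`4` = "S", `35` = "I", `38` = "N", `68` = "S", `71` = "V",
             `97` = "H", `99` = "T")
  chars[as.integer(names(plant))] <- plant
  paste(chars, collapse = "")
}

#' The packaged default reference scheme
#'
#' [reference_scheme()] over [synthetic_wt_sequence()] with the seven
#' default interface positions; its WT signature is `SINSVHT`.
#'
#' @return A `ref_scheme`.
#' @export
default_scheme <- function() {
  scheme <- reference_scheme(synthetic_wt_sequence())
  stopifnot(scheme$wt_signature == "SINSVHT")
  scheme
}

#' Simulate an additive (optionally epistatic) binding landscape
#'
#' Ground-truth stand-in for the true binding affinity of every variant:
#' each (position, residue) pair gets an independent normal energy with the
#' WT residue fixed at 0, so the WT energy is 0 and, without epistasis, a
#' multi-mutant's energy is the sum of its single-mutant energies. With
#' `epistasis_pairs > 0`, that many random position pairs additionally get
#' dense pairwise interaction energies (scaled by `effect_sd / 2`, WT rows
#' and columns zeroed).
#'
#' @param scheme A [reference_scheme()].
#' @param seed Integer seed; the landscape is reproducible.
#' @param epistasis_pairs Number of interacting position pairs (default 0).
#' @param effect_sd SD of single-residue effects (default 1).
#' @return An object of class `landscape`.
#' @export
make_landscape <- function(scheme, seed, epistasis_pairs = 0L,
                           effect_sd = 1) {
  stopifnot(effect_sd > 0)
  set.seed(seed)
  a <- length(scheme$alphabet)
  np <- n_positions(scheme)
  wt <- strsplit(scheme$wt_signature, "", fixed = TRUE)[[1]]
  additive <- matrix(stats::rnorm(a * np, sd = effect_sd), a, np,
                     dimnames = list(scheme$alphabet, NULL))
  for (i in seq_len(np)) additive[wt[i], i] <- 0

  pairs <- list()
  if (epistasis_pairs > 0L) {
    if (np < 2L) stop("epistasis needs at least 2 positions", call. = FALSE)
    combos <- utils::combn(np, 2L)
    pick <- sample(ncol(combos), min(epistasis_pairs, ncol(combos)))
    pairs <- lapply(pick, function(ci) {
      i <- combos[1, ci]; j <- combos[2, ci]
      m <- matrix(stats::rnorm(a * a, sd = effect_sd / 2), a, a,
                  dimnames = list(scheme$alphabet, scheme$alphabet))
      m[wt[i], ] <- 0
      m[, wt[j]] <- 0
      list(i = i, j = j, energies = m)
    })
  }
  structure(list(additive = additive, pairs = pairs, scheme = scheme),
            class = "landscape")
}

#' True energy of variants under a simulated landscape
#'
#' @param landscape A [make_landscape()] object.
#' @param signatures Character vector of signatures.
#' @return Numeric energies; the WT signature scores exactly 0.
#' @export
landscape_energy <- function(landscape, signatures) {
  scheme <- landscape$scheme
  m <- sig_matrix(signatures, scheme)
  e <- numeric(length(signatures))
  for (i in seq_len(ncol(m))) {
    e <- e + landscape$additive[cbind(match(m[, i], scheme$alphabet), i)]
  }
  for (p in landscape$pairs) {
    e <- e + p$energies[cbind(match(m[, p$i], scheme$alphabet),
                              match(m[, p$j], scheme$alphabet))]
  }
  e
}

#' Simulate a presort library composition
#'
#' Draws `n_draws` variants i.i.d.: first a mutation number from
#' `mutation_weights`, then that many distinct positions uniformly, then a
#' non-WT residue per chosen position uniformly. Duplicated draws
#' accumulate. Relative abundance is the draw multiplicity times a
#' lognormal skew (`abundance_sdlog`), emulating uneven variant
#' representation; WT is always present and pinned to `wt_fraction` of the
#' total abundance, as the normalizer variant must be well covered.
#'
#' The default `mutation_weights` follow the observed composition of a
#' single-mutant-centred saturation mutagenesis library, which is dominated
#' by double and triple mutants with few quadruples and quintuples.
#'
#' @param scheme A [reference_scheme()].
#' @param n_draws Number of variant draws (default 5000).
#' @param mutation_weights Positive weights for 1..k mutations
#'   (default `c(131, 3142, 1526, 81, 1)`).
#' @param abundance_sdlog SD of the lognormal abundance skew (default 1).
#' @param wt_fraction WT share of total abundance (default 0.05).
#' @param seed Integer seed.
#' @return Tibble `signature`, `draws`, `abundance`, WT first.
#' @export
sample_library <- function(scheme, n_draws = 5000L,
                           mutation_weights = c(131, 3142, 1526, 81, 1),
                           abundance_sdlog = 1, wt_fraction = 0.05,
                           seed = 1L) {
  stopifnot(n_draws >= 1L, all(mutation_weights >= 0),
            sum(mutation_weights) > 0,
            length(mutation_weights) <= n_positions(scheme))
  set.seed(seed)
  np <- n_positions(scheme)
  wt <- strsplit(scheme$wt_signature, "", fixed = TRUE)[[1]]
  letters <- non_wt_letters(scheme)

  k <- sample.int(length(mutation_weights), n_draws, replace = TRUE,
                  prob = mutation_weights)
  sigs <- character(n_draws)
  chars <- matrix(rep(wt, each = n_draws), nrow = n_draws)
  for (r in seq_len(n_draws)) {
    pos <- sample.int(np, k[r])
    for (p in pos) chars[r, p] <- sample(letters[[p]], 1L)
  }
  sigs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))

  lib <- tibble::tibble(signature = sigs) |>
    dplyr::count(.data$signature, name = "draws")
  lib$abundance <- lib$draws *
    stats::rlnorm(nrow(lib), meanlog = 0, sdlog = abundance_sdlog)
  lib <- dplyr::filter(lib, .data$signature != scheme$wt_signature)
  wt_ab <- wt_fraction / (1 - wt_fraction) * sum(lib$abundance)
  dplyr::bind_rows(
    tibble::tibble(signature = scheme$wt_signature, draws = 0L,
                   abundance = wt_ab),
    dplyr::arrange(lib, dplyr::desc(.data$abundance))
  )
}

#' Simulate gate sorting and finite-depth sequencing
#'
#' Two-gate logistic sort: a cell displaying a variant with landscape
#' energy `E` lands in the high-stringency gate with probability
#' `plogis((E - gate_mid) / gate_steep)` and in the low-stringency gate
#' otherwise. Read counts per gate are multinomial with expected count
#' proportional to library abundance times the gate probability (presort:
#' abundance alone), at `reads_per_gate` total reads per fraction.
#' Unobserved variants are absent from the resulting tables, as in real
#' sequencing.
#'
#' @param library Tibble from [sample_library()].
#' @param landscape A [make_landscape()] over the same scheme.
#' @param reads_per_gate Sequencing depth per fraction (default 1e6).
#' @param gate_mid Gate midpoint on the energy scale (default 0: WT splits
#'   50/50, so its enrichment ratio is centred at 1).
#' @param gate_steep Gate steepness tau (default 1).
#' @param seed Integer seed.
#' @return A list of class `sort_sim`: count tables `presort`, `low`,
#'   `high` (tibbles `signature`, `count`), the per-variant `truth` table
#'   (`signature`, `energy`, `p_high`, `true_log2_er_high`,
#'   `true_log2_er_low`), and the `config`.
#' @export
simulate_sort_counts <- function(library, landscape, reads_per_gate = 1e6,
                                 gate_mid = 0, gate_steep = 1, seed = 1L) {
  stopifnot(reads_per_gate >= 1, gate_steep > 0)
  scheme <- landscape$scheme
  set.seed(seed)
  energy <- landscape_energy(landscape, library$signature)
  p_high <- stats::plogis((energy - gate_mid) / gate_steep)
  wt_i <- match(scheme$wt_signature, library$signature)
  stopifnot(!is.na(wt_i))

  draw_gate <- function(weights, gate) {
    counts <- as.integer(stats::rmultinom(1, reads_per_gate,
                                          prob = weights))
    tab <- tibble::tibble(signature = library$signature, count = counts) |>
      dplyr::filter(.data$count > 0L) |>
      dplyr::arrange(dplyr::desc(.data$count), .data$signature)
    attr(tab, "gate") <- gate
    attr(tab, "total_reads") <- sum(tab$count)
    tab
  }

  truth <- tibble::tibble(
    signature = library$signature,
    energy = energy,
    p_high = p_high,
    true_log2_er_high = log2(p_high / p_high[wt_i]),
    true_log2_er_low = log2((1 - p_high) / (1 - p_high[wt_i]))
  )
  structure(
    list(
      presort = draw_gate(library$abundance, "PRESORT"),
      low = draw_gate(library$abundance * (1 - p_high), "LOW"),
      high = draw_gate(library$abundance * p_high, "HIGH"),
      truth = truth,
      config = list(reads_per_gate = reads_per_gate, gate_mid = gate_mid,
                    gate_steep = gate_steep, seed = seed)
    ),
    class = "sort_sim"
  )
}

#' Emit full-length reads for a count table
#'
#' Expands a count table into one full-length read per counted molecule by
#' planting each signature into the scheme's WT sequence. Optional
#' corruption exercises the dataset filters: with probability
#' `off_target_rate` a read gets a substitution at a random non-targeted
#' position, and with probability `truncation_rate` it is truncated below
#' the WT length. Read names carry the gate and the true signature for test
#' introspection.
#'
#' @param table Count table (`signature`, `count`).
#' @param scheme A [reference_scheme()].
#' @param off_target_rate,truncation_rate Corruption probabilities.
#' @param seed Integer seed.
#' @param path If non-NULL, write a FASTA file there and return the path
#'   invisibly; otherwise return a named character vector of reads.
#' @export
emit_reads <- function(table, scheme, off_target_rate = 0,
                       truncation_rate = 0, seed = 1L, path = NULL) {
  stopifnot(off_target_rate >= 0, off_target_rate <= 1,
            truncation_rate >= 0, truncation_rate <= 1)
  set.seed(seed)
  sigs <- rep(table$signature, table$count)
  n <- length(sigs)
  L <- nchar(scheme$wt_sequence)
  reads <- rep(scheme$wt_sequence, n)
  for (i in seq_len(n_positions(scheme))) {
    p <- scheme$positions[i]
    substr(reads, p, p) <- substr(sigs, i, i)
  }

  if (off_target_rate > 0) {
    hit <- which(stats::runif(n) < off_target_rate)
    if (length(hit) > 0) {
      off_pos <- setdiff(seq_len(L), scheme$positions)
      pos <- sample(off_pos, length(hit), replace = TRUE)
      for (j in seq_along(hit)) {
        cur <- substr(reads[hit[j]], pos[j], pos[j])
        substr(reads[hit[j]], pos[j], pos[j]) <-
          sample(setdiff(scheme$alphabet, cur), 1L)
      }
    }
  }
  if (truncation_rate > 0) {
    cut <- which(stats::runif(n) < truncation_rate)
    if (length(cut) > 0) {
      len <- sample.int(L - 1L, length(cut), replace = TRUE)
      reads[cut] <- substr(reads[cut], 1L, len)
    }
  }

  gate <- attr(table, "gate", exact = TRUE)
  names(reads) <- paste0("r", seq_len(n),
                         if (!is.null(gate)) paste0(" gate=", gate) else "",
                         " truth=", sigs)
  if (is.null(path)) return(reads)
  writeLines(paste0(">", names(reads), "\n", reads), path)
  invisible(path)
}

#' Simulate Morrison inhibition curves with known Ki
#'
#' Forward-simulates relative velocities over an inhibitor concentration
#' grid from the Morrison tight-binding equation at the given assay
#' constants, with optional multiplicative gaussian noise and replicates.
#'
#' @param ki Intrinsic inhibition constant (nM).
#' @param E Enzyme concentration (nM, default 0.325).
#' @param S Substrate concentration (uM, default 7.5).
#' @param Km Michaelis constant (uM).
#' @param I_grid Inhibitor concentrations (nM); default: two-fold dilution
#'   series 0.325 to 16 nM plus an uninhibited point.
#' @param noise_sd SD of multiplicative noise (default 0: exact curves).
#' @param replicates Number of replicate curves.
#' @param seed Integer seed.
#' @return Tibble `replicate`, `inhibitor_nM`, `velocity`.
#' @export
simulate_inhibition_data <- function(ki, E = 0.325, S = 7.5, Km,
                                     I_grid = c(0, 0.325 * 2^(0:5), 16),
                                     noise_sd = 0, replicates = 1L,
                                     seed = 1L) {
  stopifnot(ki > 0, noise_sd >= 0, replicates >= 1L)
  set.seed(seed)
  kiapp <- ki_to_kiapp(ki, S, Km)
  v <- morrison_relative_velocity(E, I_grid, kiapp)
  purrr::map_dfr(seq_len(replicates), function(r) {
    eps <- if (noise_sd > 0) stats::rnorm(length(I_grid), 0, noise_sd) else 0
    tibble::tibble(replicate = r, inhibitor_nM = I_grid,
                   velocity = pmin(pmax(v * (1 + eps), 0), 1))
  })
}
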