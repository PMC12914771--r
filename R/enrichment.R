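#' Read amino-acid sequences from a FASTA file
#'
#' Uses Biostrings when available, otherwise a minimal plain-text FASTA
#' reader. Returns a bare character vector of sequences.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::readAAStringSet(path)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

#' Count variant signatures in one library fraction
#'
#' Applies the dataset filters of [signature_of()] to a set of full-length
#' reads from one sorting gate and tallies the accepted signatures. The
#' rejection reasons are tallied alongside, and accepted + rejected always
#' equals the number of input reads.
#'
#' @param sequences Character vector of full-length amino-acid reads, an
#'   `AAStringSet`, or the path to a FASTA file.
#' @param scheme A [reference_scheme()].
#' @param gate Optional gate label (e.g. `"MMP3_HIGH"` or `"PRESORT"`),
#'   stored as an attribute and carried into downstream outputs.
#'
#' @return A tibble with columns `signature`, `count` (descending), with
#'   attributes `gate`, `total_reads` (accepted reads) and `rejections`
#'   (named integer vector). See [rejection_stats()].
#' @export
count_reads <- function(sequences, scheme, gate = NULL) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta_sequences(sequences)
  }
  sequences <- as.character(sequences)
  sig <- signature_of(sequences, scheme)
  rejected <- sig$status != "OK"
  rejections <- c(
    OFF_TARGET_MUTATION = sum(sig$status == "OFF_TARGET_MUTATION"),
    TOO_SHORT = sum(sig$status == "TOO_SHORT"),
    INVALID_RESIDUE = sum(sig$status == "INVALID_RESIDUE")
  )
  tab <- sig |>
    dplyr::filter(!rejected) |>
    dplyr::count(.data$signature, name = "count", sort = TRUE) |>
    tibble::as_tibble()
  attr(tab, "gate") <- gate
  attr(tab, "total_reads") <- sum(tab$count)
  attr(tab, "rejections") <- rejections
  tab
}

#' Rejection tallies of a count table
#'
#' @param table A count table from [count_reads()].
#' @return Tibble with columns `reason`, `n`.
#' @export
rejection_stats <- function(table) {
  r <- attr(table, "rejections")
  if (is.null(r)) r <- c(OFF_TARGET_MUTATION = 0L, TOO_SHORT = 0L,
                         INVALID_RESIDUE = 0L)
  tibble::tibble(reason = names(r), n = as.integer(r))
}

#' Per-variant frequencies in one gate
#'
#' Frequency of variant j is its read count divided by the gate's total
#' read count, so frequencies sum to 1.
#'
#' @param table Tibble with columns `signature`, `count`.
#' @return Tibble with columns `signature`, `count`, `f`.
#' @export
variant_frequencies <- function(table) {
  total <- sum(table$count)
  if (total <= 0) stop("EMPTY_GATE: gate has no accepted reads", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(table), f = .data$count / total)
}

wt_frequency <- function(freqs, scheme) {
  i <- match(scheme$wt_signature, freqs$signature)
  if (is.na(i) || freqs$count[i] < 1) {
    stop("WT_MISSING: WT signature absent from gate; normalization undefined",
         call. = FALSE)
  }
  freqs$f[i]
}

#' WT-normalized frequencies
#'
#' Divides each variant's frequency by the WT frequency in the same gate;
#' the WT row is exactly 1.
#'
#' @param table Tibble with columns `signature`, `count`.
#' @param scheme A [reference_scheme()] (supplies the WT signature).
#' @return Tibble with columns `signature`, `count`, `f`, `nf`.
#' @export
normalized_frequencies <- function(table, scheme) {
  freqs <- variant_frequencies(table)
  fwt <- wt_frequency(freqs, scheme)
  dplyr::mutate(freqs, nf = .data$f / fwt)
}

#' Enrichment ratios between a sorted gate and the presort library
#'
#' For every variant present in both tables, the enrichment ratio (ER) is
#' its WT-normalized frequency in the sorted gate divided by its
#' WT-normalized frequency in the presort library; `log2_er` is its base-2
#' logarithm, the label used for model training. Frequencies are computed
#' on each table's full composition before the presence join, so excluded
#' variants still contribute to the totals.
#'
#' Variants observed in only one of the two tables are excluded and tallied
#' (attribute `excluded`: `NOT_IN_PRESORT`, `NOT_IN_GATE`); with
#' `pseudocount > 0` every count in the union of the two tables is shifted
#' by the pseudocount first, so no variant is excluded.
#'
#' @param presort_table,gate_table Count tables (`signature`, `count`) for
#'   the presort library and the sorted gate. WT must be present in both.
#' @param scheme A [reference_scheme()].
#' @param pseudocount Non-negative shift applied to all counts (default 0).
#'
#' @return A tibble with columns `signature`, `count_presort`, `count_gate`,
#'   `f_presort`, `f_gate`, `nf_presort`, `nf_gate`, `er`, `log2_er`,
#'   ordered by descending `log2_er`. The WT row has `er` 1 and `log2_er`
#'   exactly 0.
#' @export
enrichment_ratios <- function(presort_table, gate_table, scheme,
                              pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  pre <- tibble::as_tibble(presort_table)[c("signature", "count")]
  gat <- tibble::as_tibble(gate_table)[c("signature", "count")]
  if (pseudocount > 0) {
    all_sigs <- union(pre$signature, gat$signature)
    pre <- tibble::tibble(
      signature = all_sigs,
      count = pre$count[match(all_sigs, pre$signature)]
    ) |> tidyr::replace_na(list(count = 0L)) |>
      dplyr::mutate(count = .data$count + pseudocount)
    gat <- tibble::tibble(
      signature = all_sigs,
      count = gat$count[match(all_sigs, gat$signature)]
    ) |> tidyr::replace_na(list(count = 0L)) |>
      dplyr::mutate(count = .data$count + pseudocount)
  }
  pre <- normalized_frequencies(pre, scheme)
  gat <- normalized_frequencies(gat, scheme)

  shared <- dplyr::inner_join(
    dplyr::rename(pre, count_presort = "count", f_presort = "f",
                  nf_presort = "nf"),
    dplyr::rename(gat, count_gate = "count", f_gate = "f", nf_gate = "nf"),
    by = "signature"
  )
  out <- shared |>
    dplyr::mutate(
      er = .data$nf_gate / .data$nf_presort,
      log2_er = log2(.data$er)
    ) |>
    dplyr::arrange(dplyr::desc(.data$log2_er), .data$signature)
  attr(out, "excluded") <- c(
    NOT_IN_PRESORT = sum(!gat$signature %in% pre$signature),
    NOT_IN_GATE = sum(!pre$signature %in% gat$signature)
  )
  attr(out, "gate") <- attr(gate_table, "gate", exact = TRUE)
  out
}

#' Build the model training table from enrichment records
#'
#' One training example per enrichment record: the signature, the `log2_er`
#' label, and the raw weight `count_presort + count_gate` (the read-depth
#' proxy used for depth-based splitting and optional sample weighting).
#'
#' @param records Output of [enrichment_ratios()].
#' @return Tibble with columns `signature`, `label`, `weight_raw`,
#'   `count_presort`, `count_gate`.
#' @export
build_training_table <- function(records) {
  records |>
    dplyr::transmute(
      signature = .data$signature,
      label = .data$log2_er,
      weight_raw = .data$count_presort + .data$count_gate,
      count_presort = .data$count_presort,
      count_gate = .data$count_gate
    )
}

#' Variant inventory by mutation number
#'
#' Tallies distinct variants (and reads) by number of mutations, the shape
#' in which sorted-library compositions are usually reported.
#'
#' @param table Count table (`signature`, `count`).
#' @param scheme A [reference_scheme()].
#' @return Tibble with columns `n_mutations`, `variants`, `reads`.
#' @export
mutation_inventory <- function(table, scheme) {
  tibble::as_tibble(table) |>
    dplyr::mutate(n_mutations = n_mutations(.data$signature, scheme)) |>
    dplyr::group_by(.data$n_mutations) |>
    dplyr::summarise(variants = dplyr::n(), reads = sum(.data$count),
                     .groups = "drop") |>
    dplyr::arrange(.data$n_mutations)
}
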