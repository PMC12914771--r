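#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in the fixed order used for all one-hot
#' encodings in this package: `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Define a reference scheme for a mutagenised inhibitor scaffold
#'
#' A reference scheme fixes the wild-type (WT) protein sequence, the ordered
#' set of targeted interface positions, and the amino-acid alphabet. Variants
#' are identified by their *signature*: the residues found at the targeted
#' positions, written as a single string in ascending position order
#' (e.g. `"SINSVHT"` for a 7-position scheme).
#'
#' @param wt_sequence Wild-type amino-acid sequence (mature-protein
#'   numbering, first residue = position 1). A single string.
#' @param positions Integer vector of targeted positions, strictly
#'   increasing, all within the sequence. Default: the seven interface
#'   positions 4, 35, 38, 68, 71, 97, 99.
#' @param alphabet Ordered character vector of allowed residues.
#'
#' @return An object of class `ref_scheme`: a list with elements
#'   `wt_sequence`, `positions`, `alphabet`, `wt_signature`.
#' @seealso [default_scheme()] for the packaged synthetic reference.
#' @export
reference_scheme <- function(wt_sequence,
                             positions = c(4L, 35L, 38L, 68L, 71L, 97L, 99L),
                             alphabet = AA_ALPHABET) {
  stopifnot(is.character(wt_sequence), length(wt_sequence) == 1L,
            nchar(wt_sequence) >= 1L)
  positions <- as.integer(positions)
  if (length(positions) < 1L || anyNA(positions)) {
    stop("`positions` must be a non-empty integer vector", call. = FALSE)
  }
  if (any(diff(positions) <= 0L)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (max(positions) > nchar(wt_sequence) || min(positions) < 1L) {
    stop("every targeted position must lie within the WT sequence",
         call. = FALSE)
  }
  if (anyDuplicated(alphabet) || any(nchar(alphabet) != 1L)) {
    stop("`alphabet` must be distinct single characters", call. = FALSE)
  }
  wt_chars <- strsplit(wt_sequence, "", fixed = TRUE)[[1]]
  if (!all(wt_chars %in% alphabet)) {
    stop("WT sequence contains residues outside the alphabet", call. = FALSE)
  }
  structure(
    list(
      wt_sequence = wt_sequence,
      positions = positions,
      alphabet = alphabet,
      wt_signature = paste(wt_chars[positions], collapse = "")
    ),
    class = "ref_scheme"
  )
}

#' @export
print.ref_scheme <- function(x, ...) {
  cat("<ref_scheme>\n")
  cat("  WT length    :", nchar(x$wt_sequence), "residues\n")
  cat("  positions    :", paste(x$positions, collapse = ", "), "\n")
  cat("  WT signature :", x$wt_signature, "\n")
  cat("  alphabet     :", paste(x$alphabet, collapse = ""), "\n")
  invisible(x)
}

n_positions <- function(scheme) length(scheme$positions)

#' Extract variant signatures from full-length sequences
#'
#' Reduces full-length amino-acid reads to signatures over the scheme's
#' targeted positions, applying the dataset filters: reads shorter than the
#' WT sequence are rejected (`TOO_SHORT`), reads carrying a non-alphabet
#' character are rejected (`INVALID_RESIDUE`), and reads with a substitution
#' at any non-targeted position are rejected (`OFF_TARGET_MUTATION`).
#' Residues beyond the WT length are ignored.
#'
#' @param sequences Character vector of full-length amino-acid sequences.
#' @param scheme A [reference_scheme()].
#'
#' @return A tibble with one row per input sequence and columns
#'   `signature` (string, `NA` for rejected reads) and `status` (`"OK"` or
#'   the rejection reason).
#' @export
signature_of <- function(sequences, scheme) {
  stopifnot(inherits(scheme, "ref_scheme"))
  sequences <- as.character(sequences)
  L <- nchar(scheme$wt_sequence)
  status <- rep("OK", length(sequences))
  status[nchar(sequences) < L] <- "TOO_SHORT"

  s <- substr(sequences, 1L, L)
  live <- status == "OK"
  pat <- paste0("[^", paste(scheme$alphabet, collapse = ""), "]")
  bad <- live & grepl(pat, s)
  status[bad] <- "INVALID_RESIDUE"
  live <- status == "OK"

  # mask the targeted positions with WT letters; a clean read then equals WT
  masked <- s
  for (p in scheme$positions) {
    substr(masked, p, p) <- substr(scheme$wt_sequence, p, p)
  }
  off <- live & masked != scheme$wt_sequence
  status[off] <- "OFF_TARGET_MUTATION"
  live <- status == "OK"

  signature <- rep(NA_character_, length(sequences))
  if (any(live)) {
    signature[live] <- do.call(
      paste0,
      lapply(scheme$positions, function(p) substr(s[live], p, p))
    )
  }
  tibble::tibble(signature = signature, status = status)
}

sig_matrix <- function(signatures, scheme) {
  np <- n_positions(scheme)
  stopifnot(all(nchar(signatures) == np))
  m <- matrix(NA_character_, nrow = length(signatures), ncol = np)
  for (i in seq_len(np)) m[, i] <- substr(signatures, i, i)
  m
}

#' Number of mutations of each signature relative to WT
#'
#' @param signatures Character vector of signatures.
#' @param scheme A [reference_scheme()].
#' @return Integer vector of counts of positions differing from WT.
#' @export
n_mutations <- function(signatures, scheme) {
  m <- sig_matrix(signatures, scheme)
  wt <- strsplit(scheme$wt_signature, "", fixed = TRUE)[[1]]
  as.integer(rowSums(m != matrix(wt, nrow = nrow(m), ncol = ncol(m),
                                 byrow = TRUE)))
}

#' One-hot encode variant signatures
#'
#' Encodes each signature as a binary vector of length
#' `length(alphabet) * n_positions` (140 for the default scheme), flattened
#' position-major: the first `length(alphabet)` slots describe position 1.
#'
#' @param signatures Character vector of signatures.
#' @param scheme A [reference_scheme()].
#' @return A numeric matrix, one row per signature, with exactly one 1 per
#'   position block.
#' @export
encode_signatures <- function(signatures, scheme) {
  m <- sig_matrix(signatures, scheme)
  a <- length(scheme$alphabet)
  np <- n_positions(scheme)
  out <- matrix(0, nrow = length(signatures), ncol = a * np)
  for (i in seq_len(np)) {
    idx <- match(m[, i], scheme$alphabet)
    if (anyNA(idx)) stop("signature contains residues outside the alphabet",
                         call. = FALSE)
    out[cbind(seq_along(signatures), (i - 1L) * a + idx)] <- 1
  }
  out
}

#' Decode a one-hot matrix back into signatures
#'
#' Inverse of [encode_signatures()]: takes the argmax within each position
#' block.
#'
#' @param x Numeric matrix as produced by [encode_signatures()].
#' @param scheme A [reference_scheme()].
#' @return Character vector of signatures.
#' @export
decode_signatures <- function(x, scheme) {
  a <- length(scheme$alphabet)
  np <- n_positions(scheme)
  stopifnot(ncol(x) == a * np)
  cols <- lapply(seq_len(np), function(i) {
    block <- x[, (i - 1L) * a + seq_len(a), drop = FALSE]
    scheme$alphabet[max.col(block, ties.method = "first")]
  })
  do.call(paste0, cols)
}

#' Theoretical variant counts per mutation number
#'
#' Size of the class of variants with exactly `k` mutated positions under
#' the library-design convention in which each of the `k` chosen positions
#' may carry any of the `alphabet_size` letters:
#' `choose(n_positions, k) * alphabet_size^k`. This convention (140 singles,
#' 8.4e3 doubles, ... for 7 positions and 20 letters) double-counts
#' lower-order variants; the strict count uses `alphabet_size - 1` non-WT
#' letters per position, and the two are related by
#' `sum_k choose(n, k) * (a - 1)^k == a^n`.
#'
#' @param k Integer vector of mutation numbers, each in `0..n_positions`.
#' @param n_positions Number of targeted positions (default 7).
#' @param alphabet_size Letters available per mutated position (default 20).
#' @return Numeric vector of class sizes.
#' @export
theoretical_variant_count <- function(k, n_positions = 7L, alphabet_size = 20L) {
  k <- as.integer(k)
  if (anyNA(k) || any(k < 0L) || any(k > n_positions)) {
    stop("`k` must lie in 0..n_positions", call. = FALSE)
  }
  choose(n_positions, k) * alphabet_size^k
}

non_wt_letters <- function(scheme) {
  wt <- strsplit(scheme$wt_signature, "", fixed = TRUE)[[1]]
  lapply(seq_len(n_positions(scheme)), function(i) {
    setdiff(scheme$alphabet, wt[i])
  })
}

#' Number of fully mutated variants in a scheme
#'
#' @param scheme A [reference_scheme()].
#' @return `(alphabet_size - 1)^n_positions` (19^7 = 893,871,739 for the
#'   default scheme).
#' @export
fully_mutated_count <- function(scheme) {
  (length(scheme$alphabet) - 1)^n_positions(scheme)
}

#' Batched enumeration of the fully mutated variant space
#'
#' The fully mutated space (every targeted position carrying a non-WT
#' residue) is enumerated in batches: the residues at `batch_positions` are
#' fixed to one combination of their non-WT letters per batch, and all
#' non-WT combinations of the remaining positions are generated within the
#' batch. The union over all batches covers the space exactly once,
#' regardless of which positions are batched on.
#'
#' `fully_mutated_batches()` returns the batch index table;
#' `fully_mutated_batch()` materialises one batch as signatures.
#'
#' @param scheme A [reference_scheme()].
#' @param batch_positions Positions (from `scheme$positions`) whose residues
#'   are held fixed within a batch. Default: the last two targeted positions.
#' @return `fully_mutated_batches()`: a tibble with one row per batch
#'   (columns `batch` and one fixed-residue column per batch position).
#' @export
fully_mutated_batches <- function(scheme,
                                  batch_positions = utils::tail(scheme$positions, 2)) {
  batch_positions <- as.integer(batch_positions)
  if (!all(batch_positions %in% scheme$positions) ||
      anyDuplicated(batch_positions) ||
      length(batch_positions) < 1L ||
      length(batch_positions) >= n_positions(scheme)) {
    stop("`batch_positions` must be a proper subset of the targeted positions",
         call. = FALSE)
  }
  slots <- match(batch_positions, scheme$positions)
  letters_by_slot <- non_wt_letters(scheme)[slots]
  names(letters_by_slot) <- paste0("pos", batch_positions)
  grid <- rev(expand.grid(rev(letters_by_slot), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  tibble::as_tibble(cbind(batch = seq_len(nrow(grid)), grid))
}

#' @rdname fully_mutated_batches
#' @param batch Batch index (row of `fully_mutated_batches()`).
#' @return `fully_mutated_batch()`: character vector of the batch's
#'   signatures, each fully mutated.
#' @export
fully_mutated_batch <- function(scheme, batch,
                                batch_positions = utils::tail(scheme$positions, 2)) {
  idx <- fully_mutated_batches(scheme, batch_positions)
  stopifnot(length(batch) == 1L, batch >= 1L, batch <= nrow(idx))
  slots <- match(as.integer(batch_positions), scheme$positions)
  np <- n_positions(scheme)
  free_slots <- setdiff(seq_len(np), slots)
  letters <- non_wt_letters(scheme)
  cols <- vector("list", np)
  for (j in seq_along(slots)) {
    cols[[slots[j]]] <- idx[[j + 1L]][batch]
  }
  if (length(free_slots) > 0L) {
    grid <- rev(expand.grid(rev(letters[free_slots]),
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    for (j in seq_along(free_slots)) cols[[free_slots[j]]] <- grid[[j]]
  }
  do.call(paste0, cols)
}

#' Enumerate variant spaces of a reduced scheme exhaustively
#'
#' `enumerate_fully_mutated()` materialises the whole fully mutated space;
#' `enumerate_space()` the whole `alphabet^n_positions` space (WT letters
#' included). Both refuse spaces above `max_size` — for the default
#' 7-position scheme use the batched stream or Monte-Carlo sampling instead.
#'
#' @param scheme A [reference_scheme()].
#' @param max_size Guard against accidental huge enumerations.
#' @return Character vector of signatures.
#' @export
enumerate_fully_mutated <- function(scheme, max_size = 2e6) {
  if (fully_mutated_count(scheme) > max_size) {
    stop("fully mutated space larger than `max_size`; use batches or sampling",
         call. = FALSE)
  }
  letters <- non_wt_letters(scheme)
  grid <- rev(expand.grid(rev(letters), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  do.call(paste0, grid)
}

#' @rdname enumerate_fully_mutated
#' @export
enumerate_space <- function(scheme, max_size = 2e6) {
  a <- length(scheme$alphabet)
  if (a^n_positions(scheme) > max_size) {
    stop("variant space larger than `max_size`; use sampling", call. = FALSE)
  }
  letters <- rep(list(scheme$alphabet), n_positions(scheme))
  grid <- rev(expand.grid(rev(letters), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  do.call(paste0, grid)
}

#' Sample the variant space uniformly
#'
#' Draws signatures i.i.d. uniformly over `alphabet^n_positions`
#' (`sample_variant_space()`) or over the fully mutated space with every
#' position non-WT (`sample_fully_mutated()`). Used as the tractable
#' Monte-Carlo surrogate for exhaustive 20^7 scans.
#'
#' @param scheme A [reference_scheme()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Character vector of `n` signatures (duplicates possible).
#' @export
sample_variant_space <- function(scheme, n, seed) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)
  np <- n_positions(scheme)
  cols <- lapply(seq_len(np), function(i) {
    sample(scheme$alphabet, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

#' @rdname sample_variant_space
#' @export
sample_fully_mutated <- function(scheme, n, seed) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)
  letters <- non_wt_letters(scheme)
  cols <- lapply(letters, function(l) sample(l, n, replace = TRUE))
  do.call(paste0, cols)
}
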