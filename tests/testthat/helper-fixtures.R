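# Reduced schemes and independent oracles shared across test files.

# 3 positions, 3-letter alphabet, WT "AAA": fully mutated space {C,D}^3
scheme_acd <- function() {
  reference_scheme("AAA", positions = 1:3, alphabet = c("A", "C", "D"))
}

# variant with W available as a mutation, for the count-the-Ws toy model
scheme_acw <- function() {
  reference_scheme("AAA", positions = 1:3, alphabet = c("A", "C", "W"))
}

# 4 positions, 5 letters: fully mutated space of 4^4 = 256
scheme_wide <- function() {
  reference_scheme("AAAA", positions = 1:4,
                   alphabet = c("A", "C", "D", "E", "F"))
}

# Independent brute-force enumeration of a fully mutated space, written
# from first principles (expand.grid over non-WT letters), deliberately
# not sharing code with the package's batched generator.
brute_fully_mutated <- function(scheme) {
  wt <- strsplit(scheme$wt_signature, "")[[1]]
  letters <- lapply(seq_along(wt), function(i) setdiff(scheme$alphabet, wt[i]))
  sort(do.call(paste0, expand.grid(letters, stringsAsFactors = FALSE)))
}

# Toy scoring model: number of W residues in the signature.
count_w_model <- function(signatures) {
  vapply(strsplit(signatures, ""), function(x) sum(x == "W"), numeric(1))
}

# Deterministic linear toy model over per-position letter values.
linear_model <- function(scheme, values) {
  force(values)
  function(signatures) {
    s <- vapply(seq_along(scheme$positions), function(i) {
      values[cbind(match(substr(signatures, i, i), scheme$alphabet), i)]
    }, numeric(length(signatures)))
    rowSums(matrix(s, nrow = length(signatures)))
  }
}

# Small labelled dataset on the default scheme for model tests.
toy_training_table <- function(scheme, n = 40, seed = 66) {
  sigs <- unique(sample_variant_space(scheme, n + 20, seed))[seq_len(n)]
  set.seed(seed + 1)
  tibble::tibble(signature = sigs, label = stats::rnorm(n),
                 weight_raw = sample(4:100, n, replace = TRUE))
}
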