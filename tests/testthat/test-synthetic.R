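test_that("the fabricated reference scheme is well-formed", {
  wt <- synthetic_wt_sequence()
  expect_equal(nchar(wt), 127)
  scheme <- default_scheme()
  expect_equal(scheme$wt_signature, "SINSVHT")
  expect_equal(scheme$positions, c(4L, 35L, 38L, 68L, 71L, 97L, 99L))
})

test_that("simulated landscapes are additive with WT pinned at zero", {
  scheme <- default_scheme()
  land <- make_landscape(scheme, seed = 4)
  expect_equal(landscape_energy(land, scheme$wt_signature), 0)
  expect_identical(make_landscape(scheme, seed = 4)$additive, land$additive)

  # additivity: double mutant energy = sum of its singles
  s1 <- "RINSVHT"; s2 <- "SINSVHD"; s12 <- "RINSVHD"
  e <- landscape_energy(land, c(s1, s2, s12))
  expect_equal(e[3], e[1] + e[2], tolerance = 1e-12)

  # epistasis breaks additivity for interacting pairs
  ep <- make_landscape(scheme, seed = 4, epistasis_pairs = 21)
  ee <- landscape_energy(ep, c(s1, s2, s12))
  expect_false(isTRUE(all.equal(ee[3], ee[1] + ee[2])))
  expect_equal(landscape_energy(ep, scheme$wt_signature), 0)
})

test_that("library composition follows the configured mutation-number mix", {
  scheme <- default_scheme()
  lib <- sample_library(scheme, n_draws = 500, seed = 10)
  expect_identical(lib, sample_library(scheme, n_draws = 500, seed = 10))
  expect_equal(lib$signature[1], "SINSVHT")  # WT always present

  singles <- sample_library(scheme, n_draws = 300,
                            mutation_weights = 1, seed = 2)
  muts <- n_mutations(singles$signature[-1], scheme)
  expect_true(all(muts == 1L))

  # draw-weighted mutation histogram within 3 multinomial SEs of the target
  w <- c(1, 2, 1)
  p <- w / sum(w)
  big <- sample_library(scheme, n_draws = 20000, mutation_weights = w,
                        abundance_sdlog = 0, seed = 5)
  k <- n_mutations(big$signature, scheme)
  obs <- vapply(1:3, function(i) sum(big$draws[k == i]), numeric(1)) / 20000
  se <- sqrt(p * (1 - p) / 20000)
  expect_true(all(abs(obs - p) < 3 * se))
})

test_that("gate sorting splits variants by energy through the logistic gate", {
  scheme <- default_scheme()
  land <- make_landscape(scheme, seed = 6)
  lib <- sample_library(scheme, n_draws = 800, seed = 7)

  # near-step gate: above-threshold variants never reach the low gate
  sim <- simulate_sort_counts(lib, land, reads_per_gate = 5e4,
                              gate_steep = 1e-9, seed = 8)
  e_low <- landscape_energy(land, sim$low$signature)
  expect_true(all(e_low <= 0))
  e_high <- landscape_energy(land, sim$high$signature)
  expect_true(all(e_high >= 0))
  expect_equal(sum(sim$presort$count), 5e4)
  expect_equal(sum(sim$low$count) + sum(sim$high$count), 1e5)

  # deep-read limit: measured high-gate log2 ER tracks energy in rank
  sim2 <- simulate_sort_counts(lib, land, reads_per_gate = 1e7,
                               gate_steep = 0.5, seed = 9)
  er <- enrichment_ratios(sim2$presort, sim2$high, scheme)
  e <- landscape_energy(land, er$signature)
  expect_gt(cor(er$log2_er, e, method = "spearman"), 0.9)

  # truth table is self-consistent
  wt_row <- sim2$truth[sim2$truth$signature == scheme$wt_signature, ]
  expect_equal(wt_row$true_log2_er_high, 0)
  expect_equal(wt_row$true_log2_er_low, 0)
})

test_that("emitted reads round-trip through counting, with corruption
           exercising the filters", {
  scheme <- default_scheme()
  tab <- tibble::tibble(
    signature = c("SINSVHT", "RFDWWID", "CINSVHT"),
    count = c(50L, 30L, 20L)
  )
  attr(tab, "gate") <- "HIGH"

  reads <- emit_reads(tab, scheme, seed = 1)
  expect_length(reads, 100L)
  back <- count_reads(unname(reads), scheme)
  expect_equal(dplyr::arrange(back, signature),
               dplyr::arrange(tab, signature), ignore_attr = TRUE)
  expect_equal(sum(rejection_stats(back)$n), 0L)

  # corrupted reads land in the rejection tallies, never in the counts
  big <- tibble::tibble(signature = rep("RFDWWID", 1L), count = 4000L)
  corrupt <- emit_reads(big, scheme, off_target_rate = 0.1,
                        truncation_rate = 0.05, seed = 3)
  cc <- count_reads(unname(corrupt), scheme)
  rs <- rejection_stats(cc)
  n_short <- rs$n[rs$reason == "TOO_SHORT"]
  n_off <- rs$n[rs$reason == "OFF_TARGET_MUTATION"]
  expect_equal(sum(cc$count) + sum(rs$n), 4000L)
  expect_true(abs(n_short / 4000 - 0.05) < 3 * sqrt(0.05 * 0.95 / 4000))
  # off-target substitutions only reject reads that escaped truncation
  expect_true(abs(n_off / 4000 - 0.1 * 0.95) <
                3 * sqrt(0.1 * 0.9 / 4000) + 0.01)
  expect_true(all(cc$signature == "RFDWWID"))

  # FASTA round trip via file
  path <- withr::local_tempfile(fileext = ".fasta")
  emit_reads(tab, scheme, seed = 1, path = path)
  expect_equal(dplyr::arrange(count_reads(path, scheme), signature),
               dplyr::arrange(tab, signature), ignore_attr = TRUE)
})

test_that("simulated inhibition curves match the forward model", {
  exact <- simulate_inhibition_data(2, Km = 4.75)
  kiapp <- ki_to_kiapp(2, 7.5, 4.75)
  expect_equal(exact$velocity,
               morrison_relative_velocity(0.325, exact$inhibitor_nM, kiapp))

  noisy <- simulate_inhibition_data(2, Km = 4.75, noise_sd = 0.02,
                                    replicates = 2, seed = 4)
  r1 <- noisy$velocity[noisy$replicate == 1]
  r2 <- noisy$velocity[noisy$replicate == 2]
  expect_false(isTRUE(all.equal(r1, r2)))
  quiet <- simulate_inhibition_data(2, Km = 4.75, replicates = 2, seed = 4)
  expect_equal(quiet$velocity[quiet$replicate == 1],
               quiet$velocity[quiet$replicate == 2])
})
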