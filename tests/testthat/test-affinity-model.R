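test_that("depth split follows the floor-10% rule deterministically", {
  scheme <- default_scheme()
  n <- 4882
  sigs <- unique(sample_variant_space(scheme, n + 600, 13))[seq_len(n)]
  ex <- tibble::tibble(signature = sigs, label = 0,
                       weight_raw = rep(c(5000:10, 10), length.out = n))
  sp <- split_by_depth(ex)
  expect_equal(sum(sp$split == "test"), 488)
  expect_equal(sum(sp$split == "val"), 488)
  expect_equal(sum(sp$split == "train"), 3906)
  # the deepest examples land in test
  expect_true(min(sp$weight_raw[sp$split == "test"]) >=
                max(sp$weight_raw[sp$split == "train"]))

  ex10 <- ex[1:10, ]
  sp10 <- split_by_depth(ex10)
  expect_equal(as.vector(table(sp10$split)[c("test", "val", "train")]),
               c(1, 1, 8))
  expect_error(split_by_depth(ex[1:9, ]), "TOO_FEW_EXAMPLES")

  # ties broken by signature: permuting the input rows changes nothing
  tie <- tibble::tibble(signature = sigs[1:20], label = 0, weight_raw = 7)
  sp_a <- split_by_depth(tie)
  sp_b <- split_by_depth(tie[sample(20), ])
  expect_identical(sp_a, sp_b)
})

test_that("sample weights are log2 read depth (or flat)", {
  expect_equal(sample_weight(128, "with-weight"), 7)
  expect_equal(sample_weight(2, "with-weight"), 1)
  expect_equal(sample_weight(1, "with-weight"), 0)
  expect_equal(sample_weight(c(5, 9), "no-weight"), c(1, 1))
  expect_error(sample_weight(0), "positive")
})

test_that("architectures have the declared shapes and parameter counts", {
  lib <- architecture_spec("Lib")
  expect_equal(lib$units, c(32L, 4L))
  expect_equal(lib$dropout, c(0.20, 0.10))
  ala <- architecture_spec("Ala")
  expect_equal(ala$units, c(8L, 2L))
  expect_equal(ala$dropout, c(0.00, 0.30))

  scheme <- default_scheme()
  tiny <- tibble::tibble(signature = c("SINSVHT", "RFDWWID"),
                         label = c(0, 1), weight_raw = c(2L, 2L))
  # 140x32 + 32 + 32x4 + 4 + 4x1 + 1 and 140x8 + 8 + 8x2 + 2 + 2x1 + 1
  expect_equal(count_params(train_member(tiny, scheme,
                                         hyperparams(epochs = 1L), 1)), 4649)
  expect_equal(count_params(train_member(
    tiny, scheme, hyperparams(epochs = 1L, architecture = "Ala"), 1)), 1149)
})

test_that("a member overfits a tiny noiseless task and trains reproducibly", {
  scheme <- default_scheme()
  set.seed(42)
  sigs <- unique(sample_variant_space(scheme, 20, 7))[1:8]
  tr <- tibble::tibble(signature = sigs, label = count_w_model(sigs),
                       weight_raw = rep(4L, 8))
  hp <- hyperparams(epochs = 500L, learning_rate = 1e-2, batch_size = 8L)
  m <- train_member(tr, scheme, hp, 3)
  expect_lt(m$final_loss, 1e-2)

  ens <- structure(list(members = list(m), hp = hp, scheme = scheme,
                        seeds = 3L, n_train = 8L), class = "mlp_ensemble")
  expect_equal(predict(ens, sigs), tr$label, tolerance = 0.2)

  # determinism: same seed, bitwise-identical weights; new seed differs
  m2 <- train_member(tr, scheme, hp, 3)
  expect_identical(m$params, m2$params)
  m3 <- train_member(tr, scheme, hp, 4)
  expect_false(identical(m$params, m3$params))
})

test_that("ensembles average their members and shrink prediction variance", {
  scheme <- default_scheme()
  probe <- sample_variant_space(scheme, 5, 88)

  # degenerate data: all labels zero -> ensemble regresses to ~0
  sigs <- unique(sample_variant_space(scheme, 40, 21))[1:25]
  zero <- tibble::tibble(signature = sigs, label = 0, weight_raw = 8L)
  hp <- hyperparams(epochs = 10L, base_seed = 5L)
  ens <- train_ensemble(zero, scheme, hp, n_members = 10L)
  expect_length(ens$members, 10L)
  expect_equal(ens$seeds, 5L + 0:9)
  expect_true(all(abs(predict(ens, probe)) < 0.1))

  # mean-of-members identity
  per_member <- predict(ens, probe, members = TRUE)
  expect_equal(predict(ens, probe), rowMeans(per_member), tolerance = 1e-14)
  expect_length(predict(ens, character(0)), 0L)

  # averaging: ensemble means vary less across base seeds than single nets
  ex <- toy_training_table(scheme, n = 30, seed = 77)
  hp_at <- function(bs) hyperparams(epochs = 5L, base_seed = bs)
  ens_preds <- sapply(1:10, function(i) {
    predict(train_ensemble(ex, scheme, hp_at(i * 100), n_members = 10L),
            probe)
  })
  mem_preds <- sapply(1:10, function(i) {
    predict(train_ensemble(ex, scheme, hp_at(i * 100), n_members = 1L),
            probe)
  })
  expect_lt(mean(apply(ens_preds, 1, var)), mean(apply(mem_preds, 1, var)))
})

test_that("read-depth weighting increases an example's training influence", {
  scheme <- default_scheme()
  set.seed(5)
  sigs <- unique(sample_variant_space(scheme, 20, 55))[1:12]
  base <- tibble::tibble(signature = sigs, label = c(5, rep(0, 11)),
                         weight_raw = rep(4L, 12))
  up <- base
  up$weight_raw[1] <- 4096L
  hp <- hyperparams(epochs = 20L, learning_rate = 5e-3, batch_size = 12L,
                    base_seed = 7L)
  loss_on_first <- function(tab) {
    ens <- train_ensemble(tab, scheme, hp, n_members = 1L)
    (predict(ens, sigs[1]) - 5)^2
  }
  expect_lte(loss_on_first(up), loss_on_first(base))
})

test_that("the Pearson statistic matches hand computations and errors out on
           degenerate input", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "ZERO_VARIANCE")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("grid search reuses one split, survives divergence, and returns the
           argmax", {
  scheme <- default_scheme()
  ex <- toy_training_table(scheme, n = 40, seed = 66)
  grid <- hp_grid(batch_size = 8L, epochs = 10L,
                  learning_rate = c(1e-3, 1e10), architecture = "Lib",
                  sample_weighting = "no-weight")
  expect_equal(nrow(hp_grid()), 720)

  res <- grid_search(ex, scheme, grid, n_members = 2L, base_seed = 3L)
  lb <- res$leaderboard
  expect_equal(nrow(lb), 2L)
  # the absurd learning rate diverges; the sane combination wins
  expect_equal(res$best_hp$learning_rate, 1e-3)
  expect_true(is.na(lb$val_pearson[lb$learning_rate == 1e10]))
  expect_true(all(res$val_pearson >= lb$val_pearson, na.rm = TRUE))
  expect_true(is.finite(res$test_pearson))
})
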