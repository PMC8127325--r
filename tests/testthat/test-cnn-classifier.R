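test_that("a zero-weight model is uninformative and outputs sum to one", {
  cfg <- cnn_config(n_filters = 8L, window = 6L, fc_units = 8L, seed = 5L)
  model <- build_cnn(cfg, 50L, init = "zero")
  set.seed(401)
  codes <- encode_codes(vapply(1:5, function(i) random_dna(50), character(1)))
  probs <- IntronEss:::cnn_forward(model, codes)$probs
  expect_equal(unname(probs), matrix(0.5, 5, 2), tolerance = 1e-12)
  rand_model <- build_cnn(cfg, 50L)
  p2 <- IntronEss:::cnn_forward(rand_model, codes)$probs
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_equal(unname(rowSums(p2)), rep(1, 5))
})

test_that("parameter count matches the closed-form layer arithmetic", {
  cfg <- cnn_config(n_filters = 32L, window = 16L, fc_units = 24L)
  model <- build_cnn(cfg, 200L)
  closed_form <- (4 * 16 * 32 + 32) + (32 * 24 + 24) + (24 * 2 + 2)
  expect_equal(n_parameters(model), closed_form)
  expect_error(build_cnn(cnn_config(window = 300L), 200L), "exceeds")
})

test_that("gene-grouped splits are stratified, exhaustive, and deterministic", {
  set.seed(402)
  ids <- sprintf("g%03d", 1:100)
  labs <- rep(c("essential", "nonessential"), each = 50)
  plan <- grouped_split(ids, labs, test_fraction = 0.2, seed = 9L)
  expect_equal(sum(plan$role == "test"), 20L)
  expect_setequal(plan$gene_id, ids)
  expect_true(all(table(plan$gene_id) == 1L))  # no gene in two partitions
  plan2 <- grouped_split(ids, labs, test_fraction = 0.2, seed = 9L)
  expect_identical(plan, plan2)
  # stratification: both classes in test
  expect_equal(as.integer(table(plan$label[plan$role == "test"])),
               c(10L, 10L))
  expect_error(grouped_split(ids[1:5], c(rep("essential", 2),
                                         rep("nonessential", 3))),
               "n_folds")
})

test_that("balanced batches equalise classes per epoch and per batch", {
  labs <- c(rep("essential", 10), rep("nonessential", 90))
  batches <- balanced_batches(labs, batch = 10L, seed = 3L)
  drawn <- unlist(batches)
  expect_equal(sum(labs[drawn] == "essential"),
               sum(labs[drawn] == "nonessential"))
  full <- batches[lengths(batches) == 10L]
  for (b in full) {
    expect_lte(abs(sum(labs[b] == "essential") - 5L), 1L)
  }
  expect_identical(balanced_batches(labs, 10L, seed = 3L), batches)
  expect_false(identical(balanced_batches(labs, 10L, seed = 4L), batches))
})

test_that("the default hyperparameter grid enumerates the four axes", {
  grid <- default_cnn_grid()
  expect_equal(sort(unique(grid$dropout)), c(0, 0.2, 0.5))
  expect_equal(sort(unique(grid$window)), c(16L, 24L))
  expect_setequal(unique(grid$activation), c("relu", "elu"))
  expect_equal(sort(unique(grid$l2)), c(0, 1e-6, 1e-4))
  # the selected reference combination is present
  expect_true(any(grid$dropout == 0.2 & grid$window == 24 &
                    grid$activation == "relu" & grid$l2 == 1e-6))
})

test_that("grid search picks the dominating combination with tie-breaks", {
  grid <- default_cnn_grid()
  planted <- 17L
  evaluator <- function(params, fold) {
    if (params$dropout == grid$dropout[planted] &&
        params$window == grid$window[planted] &&
        params$activation == grid$activation[planted] &&
        params$l2 == grid$l2[planted]) 0.9 else 0.6
  }
  found <- grid_search(grid, evaluator)
  expect_equal(found$best, grid[planted, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(found$mean_auc, 0.9)
  # all-tied grid resolves toward smaller l2 then smaller dropout
  tied <- grid_search(grid, function(params, fold) 0.7)
  expect_equal(tied$best$l2, 0)
  expect_equal(tied$best$dropout, 0)
  expect_error(grid_search(grid[0, ], evaluator), "empty")
  one <- grid_search(grid[4, , drop = FALSE], evaluator)
  expect_equal(one$best, grid[4, , drop = FALSE], ignore_attr = TRUE)
})

planted_motif_set <- function(n, seed) {
  set.seed(seed)
  motif <- "TTACGTAACG"
  labs <- rep(c("essential", "nonessential"), each = n / 2)
  seqs <- vapply(seq_len(n), function(i) {
    s <- random_dna(200)
    if (labs[i] == "essential") {
      for (k in 1:2) {  # two motif copies per essential intron
        pos <- sample(5:185, 1)
        s <- paste0(substr(s, 1, pos - 1), motif, substr(s, pos + 10, 200))
      }
    }
    s
  }, character(1))
  list(codes = encode_codes(seqs), labs = labs)
}

test_that("training learns a planted motif and zero epochs is a no-op", {
  d <- planted_motif_set(400L, seed = 403L)
  codes <- d$codes; labs <- d$labs
  n <- length(labs)
  cfg <- cnn_config(n_filters = 16L, window = 10L, fc_units = 8L,
                    epochs = 10L, batch = 32L, lr = 0.01, seed = 11L)
  model0 <- build_cnn(cfg, 200L)
  frozen <- build_cnn(cnn_config(n_filters = 16L, window = 10L,
                                 fc_units = 8L, epochs = 0L, seed = 11L),
                      200L)
  same <- train_cnn(frozen, codes, labs)
  expect_identical(same$params, frozen$params)

  trained <- train_cnn(model0, codes, labs)
  train_auc <- roc_auc(score_introns(trained, codes), labs)$auc
  expect_gt(train_auc, 0.95)
  expect_equal(nrow(trained$history), 10L)
  # batch scoring equals one-by-one scoring
  s_batch <- score_introns(trained, codes, batch = 64L)
  s_single <- vapply(seq_len(n), function(i)
    score_introns(trained, codes[i, , drop = FALSE]), numeric(1))
  expect_equal(s_batch, s_single, tolerance = 1e-12)
  expect_true(all(s_batch >= 0 & s_batch <= 1))
})

test_that("label-permuted training stays near chance on the toy set", {
  d <- planted_motif_set(400L, seed = 404L)
  set.seed(405)
  perm <- sample(d$labs)
  cfg <- cnn_config(n_filters = 16L, window = 10L, fc_units = 8L,
                    epochs = 5L, batch = 32L, lr = 0.01, seed = 12L)
  # held-out half scored against the true labels
  tr <- c(1:100, 201:300)
  trained <- train_cnn(build_cnn(cfg, 200L), d$codes[tr, ], perm[tr])
  auc <- roc_auc(score_introns(trained, d$codes[-tr, ]), d$labs[-tr])$auc
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})
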