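test_that("CV1 partitions mask the right number of cells, never orphan a line", {
  rec <- grid_records(3, 182, 1, 2, counts = 2L)
  cd <- collapse_replicates(count_dataset(rec))
  plan <- make_cv1_partitions(cd, 0.1, n_partitions = 3, seed = 1)
  for (p in plan$partitions) {
    expect_equal(nrow(p), 54)     # floor(0.1 * 546)
    left <- unique(cd$cells$line[!paste(cd$cells$env, cd$cells$line) %in%
                                   paste(p$env, p$line)])
    expect_setequal(left, cd$line_ids)
  }
  # same seed -> identical plan; different partitions differ
  plan2 <- make_cv1_partitions(cd, 0.1, n_partitions = 3, seed = 1)
  expect_identical(plan, plan2)
  expect_false(identical(plan$partitions[[1]], plan$partitions[[2]]))
})

test_that("masking fails when every line appears in one environment only", {
  rec <- grid_records(1, 10, 1, 1)
  cd <- collapse_replicates(count_dataset(rec))
  expect_error(make_cv1_partitions(cd, 0.1, 1, seed = 2), "infeasible")
})

test_that("line-level masking selects lines and proper env subsets", {
  rec <- grid_records(3, 30, 1, 1)
  cd <- collapse_replicates(count_dataset(rec))
  plan <- make_cv1_partitions(cd, 0.2, 2, seed = 3, by_line = TRUE)
  for (p in plan$partitions) {
    expect_equal(length(unique(p$line)), 6)   # floor(0.2 * 30)
    per_line <- table(p$line)
    expect_true(all(per_line >= 1 & per_line <= 2))  # proper subset of 3 envs
  }
})

test_that("predictions average r * exp(eta) over retained samples", {
  # stub chain with known draws; r = 1 so the offset factor is unity
  stub <- structure(list(
    draws = list(beta_star = matrix(0, 1, 4), b1 = matrix(0, 1, 4),
                 b2 = matrix(0, 1, 8)),
    r = 1, L = 2, J = 2, I = 2,
    env_ids = c("Env1", "Env2"), line_ids = c("L001", "L002"),
    trait_ids = c("Trait1", "Trait2"), n_retained = 1),
    class = "bpmtme_fit")
  cells <- data.frame(env = "Env2", line = "L002")
  pr <- predict_masked(stub, cells)
  expect_equal(pr$pred, c(1, 1))            # exp(0) with unit offset
  expect_equal(pr$trait, c("Trait1", "Trait2"))
  # single sample with known eta = 0.5
  stub$draws$beta_star[1, ] <- 0.5
  expect_equal(predict_masked(stub, cells)$pred, rep(exp(0.5), 2),
               tolerance = 1e-12)
  # averaging over samples equals the mean of per-sample predictions
  stub$draws$beta_star <- matrix(c(0.2, 0.7), 2, 4)
  stub$draws$b1 <- matrix(0, 2, 4); stub$draws$b2 <- matrix(0, 2, 8)
  expect_equal(predict_masked(stub, cells)$pred,
               rep(mean(exp(c(0.2, 0.7))), 2), tolerance = 1e-12)
  expect_error(predict_masked(stub, data.frame(env = "Env1", line = "LX")),
               "absent")
})

test_that("spearman uses average ranks and rejects degenerate input", {
  expect_equal(spearman(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman(1:3, c(10, 100, 1000)), 1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman(x, y), cor(rank(x), rank(y)))  # rank-then-Pearson
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1, 1), "at least 2")
})

test_that("Spearman accuracy is invariant to monotone transforms", {
  set.seed(2)
  pred <- rexp(30); obs <- rpois(30, 5)
  expect_equal(spearman(obs, pred), spearman(obs, log(pred)))
  expect_equal(spearman(obs, pred), spearman(obs, rank(pred)))
})

test_that("evaluate_models lays out the accuracy table and honors stubs", {
  set.seed(6)
  rec <- grid_records(2, 20, 1, 2, counts = rpois(160, 5))
  cd <- collapse_replicates(count_dataset(rec))
  # perfect-prediction stub: one retained sample whose b2 encodes the
  # observed sums (r = 1, everything else zero), so predict_masked returns
  # exp(log(obs)) = obs through the real prediction path
  perfect_fit <- function(train, trait, grm, hyper, st) {
    traits <- if (is.null(trait)) cd$trait_ids else trait
    I <- length(cd$env_ids); J <- length(cd$line_ids); L <- length(traits)
    b2 <- matrix(0, I * J, L)
    sub <- cd$cells[cd$cells$trait %in% traits, ]
    i <- match(sub$env, cd$env_ids); j <- match(sub$line, cd$line_ids)
    l <- match(sub$trait, traits)
    b2[cbind((i - 1) * J + j, l)] <- log(pmax(sub$sum, 0.5))
    structure(list(
      draws = list(beta_star = matrix(0, 1, I * L),
                   b1 = matrix(0, 1, J * L),
                   b2 = matrix(as.vector(t(b2)), 1)),
      r = 1, L = L, J = J, I = I, env_ids = cd$env_ids,
      line_ids = cd$line_ids, trait_ids = traits, n_retained = 1),
      class = "bpmtme_fit")
  }
  tab <- evaluate_models(cd, fractions = 0.4, n_partitions = 1,
                         fit_fun = perfect_fit, seed = 3)
  expect_s3_class(tab, "accuracy_table")
  expect_equal(nrow(tab), 2 * 2 * 2)  # L * I rows per model per fraction
  expect_true(all(tab$mean_spearman == 1))
  expect_true(all(tab$sd_spearman == 0))
  gs <- accuracy_summary(tab)
  expect_equal(gs$mean_spearman, c(1, 1))
})

test_that("masked observations never reach the fitted chain", {
  set.seed(4)
  rec <- grid_records(2, 6, 1, 1, counts = rpois(12, 6))
  cd <- collapse_replicates(count_dataset(rec))
  plan <- make_cv1_partitions(cd, 0.2, 1, seed = 11)
  mask <- plan$partitions[[1]]
  st <- chain_settings(40, 20, 2, seed = 13)
  f1 <- fit_bpmtme(drop_cells(cd, mask), settings = st)
  # perturb the masked counts and refit: chain must be bit-identical
  cd2 <- cd
  hit <- paste(cd2$cells$env, cd2$cells$line) %in% paste(mask$env, mask$line)
  cd2$cells$sum[hit] <- cd2$cells$sum[hit] + 100L
  f2 <- fit_bpmtme(drop_cells(cd2, mask), settings = st)
  expect_identical(f1$draws, f2$draws)
})

test_that("grand averages equal the mean of per-combination means", {
  tab <- data.frame(trait = rep(c("T1", "T2"), each = 2),
                    env = rep(c("E1", "E2"), 2), model = "BPME",
                    test_fraction = 0.1,
                    mean_spearman = c(0.2, 0.4, 0.6, 0.8), sd_spearman = 0)
  class(tab) <- c("accuracy_table", "data.frame")
  expect_equal(accuracy_summary(tab)$mean_spearman, 0.5)
})
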