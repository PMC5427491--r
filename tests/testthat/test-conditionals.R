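# Full-conditional updates checked against hand computations, dense oracles
# and closed-form reductions.

test_that("augmented log-likelihood kernel matches hand evaluation", {
  des <- tiny_design(I = 2, J = 2, L = 2, r = 2)
  st <- random_state(des)
  st$beta_star[] <- 0; st$b1[] <- 0; st$b2[] <- 0; st$c[] <- 0
  expect_equal(log_augmented_likelihood(st, des), 0)

  # one observation: y = 1, r = 2, eta* = 0.5, omega = 1
  des1 <- tiny_design(I = 1, J = 1, L = 1, counts = 1L, r = 2)
  st1 <- list(beta_star = 0.5, b1 = matrix(0, 1, 1), b2 = matrix(0, 1, 1),
              c = matrix(0, 1, 1), omega = matrix(1, 1, 1),
              Sigma_t = diag(1), Sigma_E = diag(1), Sigma_c = diag(1),
              a_t = 1, a_E = 1, a_c = 1)
  expect_equal(log_augmented_likelihood(st1, des1), -0.375)

  # invariance to consistent relabeling of lines (sum reordering)
  set.seed(31)
  rec <- grid_records(2, 3, 1, 2, counts = rpois(12, 3))
  perm <- c(L001 = "L003", L002 = "L001", L003 = "L002")  # old -> new label
  rec2 <- rec; rec2$line <- unname(perm[rec$line])
  des <- build_design(collapse_replicates(count_dataset(rec)), r = 5)
  des2 <- build_design(collapse_replicates(count_dataset(rec2)), r = 5)
  st <- random_state(des)
  old_of_new <- match(des2$line_ids, perm)  # old line index behind new label
  st2 <- st
  st2$b1 <- st$b1[old_of_new, , drop = FALSE]
  for (i in 1:2) st2$b2[(i - 1) * 3 + (1:3), ] <-
    st$b2[(i - 1) * 3 + old_of_new, , drop = FALSE]
  key_old <- paste(des$env, perm[des$line_ids[des$line]])
  key_new <- paste(des2$env, des2$line_ids[des2$line])
  st2$c <- st$c[match(key_new, key_old), , drop = FALSE]
  st2$omega <- st$omega[match(key_new, key_old), , drop = FALSE]
  expect_equal(log_augmented_likelihood(st2, des2),
               log_augmented_likelihood(st, des), tolerance = 1e-12)
})

test_that("scalar c update reduces to the conjugate normal by hand", {
  # single unit, L = 1, omega = 2, Sigma_c = 1, residual = 1 -> N(1/3, 1/3)
  des <- tiny_design(I = 1, J = 1, L = 1, counts = 3L, r = 1)
  st <- list(beta_star = 0, b1 = matrix(0, 1, 1), b2 = matrix(0, 1, 1),
             c = matrix(0, 1, 1), omega = matrix(2, 1, 1),
             Sigma_t = diag(1), Sigma_E = diag(1), Sigma_c = diag(1),
             a_t = 1, a_E = 1, a_c = 1)
  # residual ystar - D * eta_{-c} = (3-1)/2 - 2*0 = 1
  pp <- update_location_block("c", st, des, return_params = TRUE)
  expect_equal(drop(pp$Q), 3)         # omega + 1/Sigma_c
  expect_equal(drop(pp$mean), 1 / 3)
  set.seed(2)
  draws <- replicate(2e4, update_location_block("c", st, des))
  expect_lt(abs(mean(draws) - 1 / 3), 4 * sqrt(1 / 3 / 2e4))
  expect_lt(abs(var(draws) - 1 / 3), 0.02)
})

test_that("full-conditional mean equals the dense GLS solution", {
  set.seed(13)
  des <- tiny_design(I = 2, J = 2, L = 1, counts = c(1L, 4L, 0L, 2L), r = 3)
  st <- random_state(des)
  G <- matrix(c(1, 0.3, 0.3, 1.2), 2, 2)
  h <- bpmtme_hyper(r = 3, beta_prior_scale = 2)
  ys <- as.vector(t(des$ystar))
  D <- diag(as.vector(t(st$omega)))
  dense_gls <- function(Z, P, eta_minus, m0) {
    Q <- t(Z) %*% D %*% Z + P
    rhs <- t(Z) %*% (ys - D %*% eta_minus) + P %*% m0
    list(Q = unname(Q), mean = drop(solve(Q, rhs)))
  }
  eta_full <- as.vector(des$X %*% st$beta_star +
                          des$Z1 %*% as.vector(t(st$b1)) +
                          des$Z2 %*% as.vector(t(st$b2)) + as.vector(t(st$c)))
  X <- as.matrix(des$X); Z1 <- as.matrix(des$Z1); Z2 <- as.matrix(des$Z2)
  cases <- list(
    beta_star = dense_gls(X, diag(1 / 2, 2),
                          eta_full - X %*% st$beta_star, rep(0, 2)),
    b1 = dense_gls(Z1, solve(G) %x% solve(st$Sigma_t),
                   eta_full - Z1 %*% as.vector(t(st$b1)), rep(0, 2)),
    b2 = dense_gls(Z2, solve(st$Sigma_E) %x% solve(G) %x% solve(st$Sigma_t),
                   eta_full - Z2 %*% as.vector(t(st$b2)), rep(0, 4)),
    c = dense_gls(diag(4), diag(4) %x% solve(st$Sigma_c),
                  eta_full - as.vector(t(st$c)), rep(0, 4)))
  for (blk in names(cases)) {
    pp <- update_location_block(blk, st, des, h, grm = G,
                                return_params = TRUE)
    expect_equal(unname(pp$Q), cases[[blk]]$Q, tolerance = 1e-10,
                 label = paste("Q of", blk))
    expect_equal(unname(pp$mean), cases[[blk]]$mean, tolerance = 1e-10,
                 label = paste("mean of", blk))
  }
})

test_that("location blocks fall back to their priors when D -> 0", {
  set.seed(21)
  # counts equal to r make ystar = 0 exactly; omega ~ 0 removes D
  des2 <- build_design(collapse_replicates(count_dataset(
    grid_records(2, 3, 1, 2, counts = 1L))), r = 1)
  st2 <- random_state(des2)
  st2$omega[] <- 1e-12
  h <- bpmtme_hyper(r = 1, beta_prior_scale = 0.5)
  pp <- update_location_block("beta_star", st2, des2, h, return_params = TRUE)
  expect_equal(unname(diag(pp$Q)), rep(2, 4), tolerance = 1e-6)
  expect_equal(unname(pp$mean), rep(0, 4), tolerance = 1e-6)
  draws <- replicate(1e4, update_location_block("beta_star", st2, des2, h)[1])
  expect_lt(abs(mean(draws)), 4 * sqrt(0.5 / 1e4))
  expect_lt(abs(var(draws) - 0.5), 0.03)
  # b1 prior covariance G (x) Sigma_t recovered empirically
  G <- diag(3)
  d1 <- replicate(5e3, update_location_block("b1", st2, des2, h, grm = G)[1, ])
  emp <- cov(t(d1))
  expect_lt(max(abs(emp - st2$Sigma_t)), 0.15 * max(diag(st2$Sigma_t)))
})

test_that("covariance conditionals reduce to prior inverse-Wishart forms", {
  set.seed(4)
  des <- tiny_design(I = 2, J = 3, L = 2, r = 2)
  st <- random_state(des)
  st$b1[] <- 0; st$b2[] <- 0; st$c[] <- 0
  h <- bpmtme_hyper(r = 2, nu_t = 4, nu_E = 4, nu_c = 4)
  pp <- update_sigma_t(st, des, h, return_params = TRUE)
  expect_equal(pp$kappa, 4 + 2 - 1 + 3 + 6)
  expect_equal(unname(pp$S), unname(2 * 4 * diag(1 / st$a_t)),
               tolerance = 1e-12)
  # empirical mean of IW draws: S / (kappa - L - 1)
  draws <- replicate(2e4, update_sigma_t(st, des, h)[1, 1])
  expect_lt(abs(mean(draws) / (pp$S[1, 1] / (pp$kappa - 3)) - 1), 0.05)
  expect_true(all(draws > 0))

  ppe <- update_sigma_e(st, des, h, return_params = TRUE)
  expect_equal(ppe$kappa, 4 + 2 - 1 + 3 * 2)
  de <- replicate(2e4, update_sigma_e(st, des, h)[1, 1])
  expect_lt(abs(mean(de) / (ppe$S[1, 1] / (ppe$kappa - 3)) - 1), 0.05)

  ppc <- update_sigma_c(st, des, h, return_params = TRUE)
  expect_equal(ppc$kappa, 4 + 2 - 1 + des$n_units)
  # drawn matrices symmetric positive definite
  for (k in 1:200) {
    S <- update_sigma_c(st, des, h)
    expect_true(isSymmetric(S, tol = 1e-10))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("L = 1 covariance conditional matches the inverse-gamma oracle", {
  set.seed(6)
  des <- tiny_design(I = 2, J = 2, L = 1, counts = 2L, r = 2)
  st <- random_state(des)
  st$c[] <- 2; st$Sigma_c <- matrix(1); st$a_c <- 1
  h <- bpmtme_hyper(r = 2, nu_c = 2)
  pp <- update_sigma_c(st, des, h, return_params = TRUE)
  # 1x1 inverse Wishart(kappa, s) == inverse-gamma(kappa/2, s/2)
  kappa <- 2 + 1 - 1 + des$n_units
  s <- 2 * 2 * 1 + sum(st$c^2)
  expect_equal(pp$kappa, kappa)
  expect_equal(drop(pp$S), s)
  draws <- replicate(4e4, drop(update_sigma_c(st, des, h)))
  oracle <- 1 / rgamma(4e4, kappa / 2, rate = s / 2)
  expect_lt(abs(mean(draws) / mean(oracle) - 1), 0.05)
  expect_lt(abs(median(draws) / median(oracle) - 1), 0.05)
})

test_that("auxiliary scales follow the Huang-Wand conjugate update", {
  des <- tiny_design(I = 2, J = 2, L = 2, r = 2)
  st <- random_state(des)
  st$Sigma_t <- diag(2)
  h <- bpmtme_hyper(r = 2, nu_t = 2, A_t = 1e4)
  pp <- update_aux_scales("t", st, des, h, return_params = TRUE)
  expect_equal(pp$shape, 2)                       # (nu + L)/2
  expect_equal(pp$rate, rep(2 + 1e-8, 2))         # nu * (Sigma^-1)_ll + A^-2
  set.seed(11)
  draws <- replicate(2e4, update_aux_scales("t", st, des, h)[1])
  expect_true(all(draws > 0))
  # IG(2, rate) has infinite variance; compare on the log scale against a
  # direct inverse-gamma oracle
  oracle <- 1 / rgamma(2e4, pp$shape, rate = pp$rate[1])
  expect_lt(abs(mean(log(draws)) - mean(log(oracle))), 0.03)
  expect_lt(abs(median(draws) / median(oracle) - 1), 0.05)
  # A -> Inf limit: rate -> nu * (Sigma^-1)_ll
  h2 <- bpmtme_hyper(r = 2, nu_t = 2, A_t = 1e12)
  pp2 <- update_aux_scales("t", st, des, h2, return_params = TRUE)
  expect_equal(pp2$rate, rep(2, 2), tolerance = 1e-12)
})

test_that("omega refresh draws PG(y + r, eta) at the current predictor", {
  des <- tiny_design(I = 1, J = 2, L = 1, counts = 0L, r = 1000)
  st <- random_state(des)
  st$beta_star[] <- 0; st$b1[] <- 0; st$b2[] <- 0; st$c[] <- 0
  h <- bpmtme_hyper(r = 1000)
  set.seed(3)
  om <- replicate(5e3, update_omega(st, des, h)[1, 1])
  expect_true(all(om > 0))
  expect_lt(abs(mean(om) - 250), 4 * sqrt(pg_var(1000, 0) / 5e3))  # b/4
  set.seed(10); o1 <- update_omega(st, des, h)
  set.seed(10); o2 <- update_omega(st, des, h)
  expect_identical(o1, o2)
})

test_that("Kronecker precision identity holds numerically", {
  set.seed(14)
  rnd_pd <- function(p) crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.5
  for (k in 1:5) {
    SE <- rnd_pd(3); G <- rnd_pd(3); St <- rnd_pd(2)
    lhs <- solve(SE %x% G %x% St)
    rhs <- solve(SE) %x% solve(G) %x% solve(St)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})
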