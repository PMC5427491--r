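# Programmatic fixtures and independent oracles shared across tests.

# Long-format records for a complete I x J x K x L grid with given counts
# (recycled); labels Env*, L###, Trait*.
grid_records <- function(I, J, K, L, counts = 1L) {
  rec <- expand.grid(trait = sprintf("Trait%d", seq_len(L)),
                     rep = seq_len(K),
                     line = sprintf("L%03d", seq_len(J)),
                     env = sprintf("Env%d", seq_len(I)),
                     stringsAsFactors = FALSE)
  rec$count <- rep_len(as.integer(counts), nrow(rec))
  rec[c("env", "line", "rep", "trait", "count")]
}

tiny_design <- function(I = 2, J = 3, L = 2, K = 1, counts = 1L, r = 2) {
  d <- count_dataset(grid_records(I, J, K, L, counts))
  build_design(collapse_replicates(d), r = r)
}

# A dispersed but finite state for conditional checks.
random_state <- function(design, sd = 0.3) {
  I <- design$I; J <- design$J; L <- design$L; n <- design$n_units
  list(beta_star = rnorm(I * L, 0, sd),
       b1 = matrix(rnorm(J * L, 0, sd), J, L),
       b2 = matrix(rnorm(I * J * L, 0, sd), I * J, L),
       c = matrix(rnorm(n * L, 0, sd), n, L),
       omega = matrix(rexp(n * L) + 0.2, n, L),
       Sigma_t = crossprod(matrix(rnorm(L * L), L)) / L + diag(0.2, L),
       Sigma_E = crossprod(matrix(rnorm(I * I), I)) / I + diag(0.2, I),
       Sigma_c = crossprod(matrix(rnorm(L * L), L)) / L + diag(0.2, L),
       a_t = rexp(L) + 0.3, a_E = rexp(I) + 0.3, a_c = rexp(L) + 0.3)
}

# Independent dense evaluation of the joint log posterior of Eq.-style model
# (up to constants in blocks held fixed), used by the grid-proportionality
# tests.  Deliberately built from the sparse X/Z matrices and base R linear
# algebra, not the package's index-map code paths.
ld_mvn_prec <- function(x, Q, rhs) -0.5 * drop(t(x) %*% Q %*% x) +
  drop(t(x) %*% rhs)

ld_iw <- function(S, kappa, B) {
  p <- nrow(S)
  as.numeric(-(kappa + p + 1) / 2 * determinant(S)$modulus -
               0.5 * sum(diag(B %*% solve(S))) +
               kappa / 2 * determinant(B)$modulus)
}

ld_ig <- function(a, shape, rate) -(shape + 1) * log(a) - rate / a

log_joint_dense <- function(state, design, hyper, G) {
  v0 <- hyper$beta_prior_scale
  eta <- as.vector(design$X %*% state$beta_star +
                     design$Z1 %*% as.vector(t(state$b1)) +
                     design$Z2 %*% as.vector(t(state$b2)) +
                     as.vector(t(state$c)))
  ys <- as.vector(t(design$ystar))
  om <- as.vector(t(state$omega))
  ll <- sum(ys * eta - 0.5 * om * eta^2)
  K1 <- kronecker(G, state$Sigma_t)
  K2 <- kronecker(state$Sigma_E, K1)
  b1v <- as.vector(t(state$b1)); b2v <- as.vector(t(state$b2))
  p1 <- -0.5 * as.numeric(determinant(K1)$modulus) -
    0.5 * drop(t(b1v) %*% solve(K1) %*% b1v)
  p2 <- -0.5 * as.numeric(determinant(K2)$modulus) -
    0.5 * drop(t(b2v) %*% solve(K2) %*% b2v)
  pc <- sum(apply(state$c, 1, function(cu)
    -0.5 * as.numeric(determinant(state$Sigma_c)$modulus) -
      0.5 * drop(t(cu) %*% solve(state$Sigma_c) %*% cu)))
  pb <- sum(dnorm(state$beta_star, 0, sqrt(v0), log = TRUE))
  L <- design$L; I <- design$I
  pst <- ld_iw(state$Sigma_t, hyper$nu_t + L - 1,
               2 * hyper$nu_t * diag(1 / state$a_t, L)) +
    ld_iw(state$Sigma_E, hyper$nu_E + I - 1,
          2 * hyper$nu_E * diag(1 / state$a_E, I)) +
    ld_iw(state$Sigma_c, hyper$nu_c + L - 1,
          2 * hyper$nu_c * diag(1 / state$a_c, L))
  pa <- sum(ld_ig(state$a_t, 0.5, 1 / hyper$A_t^2)) +
    sum(ld_ig(state$a_E, 0.5, 1 / hyper$A_E^2)) +
    sum(ld_ig(state$a_c, 0.5, 1 / hyper$A_c^2))
  ll + pb + p1 + p2 + pc + pst + pa
}

# Forward draw from the prior hierarchy (independent implementation used by
# the successive-conditional sampler check).
forward_state <- function(design, hyper, G) {
  I <- design$I; J <- design$J; L <- design$L; n <- design$n_units
  rIG <- function(m, shape, rate) 1 / rgamma(m, shape, rate = rate)
  riw <- function(kappa, B) solve(stats::rWishart(1, kappa, solve(B))[, , 1])
  rmn <- function(A, B) t(chol(A)) %*%
    matrix(rnorm(nrow(A) * nrow(B)), nrow(A)) %*% chol(B)
  at <- rIG(L, 0.5, 1 / hyper$A_t^2)
  aE <- rIG(I, 0.5, 1 / hyper$A_E^2)
  ac <- rIG(L, 0.5, 1 / hyper$A_c^2)
  St <- riw(hyper$nu_t + L - 1, 2 * hyper$nu_t * diag(1 / at, L))
  SE <- riw(hyper$nu_E + I - 1, 2 * hyper$nu_E * diag(1 / aE, I))
  Sc <- riw(hyper$nu_c + L - 1, 2 * hyper$nu_c * diag(1 / ac, L))
  b1 <- rmn(G, St)
  LE <- chol(SE)
  Zi <- lapply(seq_len(I), function(i) rmn(G, St))
  b2 <- matrix(0, I * J, L)
  for (i in seq_len(I)) {
    acc <- matrix(0, J, L)
    for (i2 in seq_len(I)) acc <- acc + LE[i2, i] * Zi[[i2]]
    b2[(i - 1) * J + seq_len(J), ] <- acc
  }
  cc <- matrix(rnorm(n * L), n) %*% chol(Sc)
  list(beta_star = rnorm(I * L, 0, sqrt(hyper$beta_prior_scale)),
       b1 = b1, b2 = b2, c = cc, omega = matrix(1, n, L),
       Sigma_t = St, Sigma_E = SE, Sigma_c = Sc,
       a_t = at, a_E = aE, a_c = ac)
}

# Data refresh for the successive-conditional scheme: Y from the size-r
# negative binomial given the state, then omega jointly from PG(y + r, eta)
# (Y's conditional given omega is not the marginal NB, so the pair must be
# refreshed together).
refresh_data <- function(state, design, hyper) {
  L <- design$L
  eta <- matrix(linear_predictor(state, design), design$n_units, L,
                byrow = TRUE)
  Y <- matrix(rnbinom(length(eta), size = design$r,
                      prob = 1 / (1 + exp(eta))), design$n_units, L)
  design$Y <- Y
  state$omega <- update_omega(state, design, hyper)
  list(design = design, state = state)
}

# Effective-sample-size-adjusted variance of an autocorrelated chain mean.
ess_var <- function(x) {
  n <- length(x)
  a <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  cut <- which(a < 0.02)[1]
  if (is.na(cut)) cut <- length(a)
  tau <- 1 + 2 * sum(a[seq_len(cut)])
  stats::var(x) * max(tau, 1) / n
}
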