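#' Generating parameters of the simulation scenarios
#'
#' Returns the constants of the two study scenarios: 3 environments, 2 traits,
#' 200 genotypes, 5 replications, identity genomic relationship, Poisson-scale
#' intercepts \eqn{\beta = (0.20, 0.25, 0.15, 0.20, 0.30, 0.32)} (environment
#' outer, trait inner), and the stated trait / environment / observation-level
#' covariance matrices.  S1 carries high generating correlations (about 0.8
#' between traits); S2 carries low ones (about 0.3).
#'
#' @param name `"S1"` or `"S2"`.
#' @param J number of genotypes (default 200); covariances and \eqn{\beta} are
#'   unchanged, the relationship matrix stays the identity of order `J`.
#' @return A list of class `sim_params` with elements `I`, `J`, `K`, `L`,
#'   `beta` (I x L matrix), `Sigma_t`, `Sigma_E`, `Sigma_c`, `G`.
#' @export
scenario_params <- function(name = c("S1", "S2"), J = 200) {
  name <- match.arg(name)
  if (name == "S1") {
    St <- matrix(c(0.005, 0.0031, 0.0031, 0.003), 2, 2)
    SE <- matrix(c(0.003, 0.0022, 0.0024,
                   0.0022, 0.0022, 0.0012,
                   0.0024, 0.0012, 0.0030), 3, 3)
    Sc <- matrix(c(0.0003, 0.0003, 0.0003, 0.0004), 2, 2)
  } else {
    St <- matrix(c(0.005, 0.0012, 0.0012, 0.003), 2, 2)
    SE <- matrix(c(0.003, 0.0007, 0.0009,
                   0.0007, 0.0022, 0.0007,
                   0.0009, 0.0007, 0.0030), 3, 3)
    Sc <- matrix(c(0.0003, 0.0001, 0.0001, 0.0004), 2, 2)
  }
  sim_params(I = 3, J = J, K = 5, L = 2,
             beta = matrix(c(0.20, 0.25, 0.15, 0.20, 0.30, 0.32), 3, 2,
                           byrow = TRUE),
             Sigma_t = St, Sigma_E = SE, Sigma_c = Sc)
}

#' Simulation parameter container
#'
#' @param I,J,K,L numbers of environments, genotypes, replications, traits.
#' @param beta I x L matrix (or length I*L vector, environment outer, trait
#'   inner) of Poisson-scale intercepts.
#' @param Sigma_t,Sigma_E,Sigma_c generating covariance matrices (L x L,
#'   I x I, L x L), symmetric positive definite.
#' @param G J x J relationship matrix (identity if `NULL`).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(I, J, K, L, beta, Sigma_t, Sigma_E, Sigma_c,
                       G = NULL) {
  beta <- matrix(beta, I, L, byrow = is.null(dim(beta)))
  if (!all(is.finite(beta))) stop("beta must be finite")
  for (nm in c("Sigma_t", "Sigma_E", "Sigma_c")) {
    S <- get(nm)
    if (max(abs(S - t(S))) > 1e-12 || any(eigen(S, symmetric = TRUE,
                                                only.values = TRUE)$values <= 0))
      stop(nm, " must be symmetric positive definite")
  }
  if (is.null(G)) G <- diag(J)
  if (!all(dim(G) == c(J, J))) stop("G must be J x J")
  structure(list(I = I, J = J, K = K, L = L, beta = beta, Sigma_t = Sigma_t,
                 Sigma_E = Sigma_E, Sigma_c = Sigma_c, G = G),
            class = "sim_params")
}

# Draw N(0, A (x) B) as vec-compatible matrix: rows indexed by A, cols by B.
rmatnorm_kron <- function(A, B) {
  # Z (a x b) iid N(0,1); chol(A)' Z chol(B) has covariance A (x) B over
  # row-outer, col-inner vectorization.
  La <- chol(A); Lb <- chol(B)
  Z <- matrix(stats::rnorm(nrow(A) * nrow(B)), nrow(A), nrow(B))
  t(La) %*% Z %*% Lb
}

#' Simulate a multi-trait multi-environment count dataset
#'
#' Draws from the generative model: line effects \eqn{b_1 \sim N(0, G \otimes
#' \Sigma_t)}, interaction effects \eqn{b_2 \sim N(0, \Sigma_E \otimes G
#' \otimes \Sigma_t)}, an independent lognormal disturbance \eqn{c_{ijk} \sim
#' N(0, \Sigma_c)} per replicate unit, then counts
#' \eqn{Y_{ijk}(l) \sim Poisson(\exp(\beta_i(l) + b_j(l) + b_{ij}(l) +
#' c_{ijk}(l)))}.  Replicate-level simulation mirrors the study pipeline:
#' data are generated per replicate and summed for analysis.
#'
#' @param params a [sim_params()] or [scenario_params()] list.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param truth if `TRUE`, attach the generating effects as attribute
#'   `"truth"`.
#' @return A [count_dataset()] with labels `Env1..I`, `L001..J` (zero-padded),
#'   `Trait1..L`.
#' @export
simulate_dataset <- function(params, seed = NULL, truth = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  I <- params$I; J <- params$J; K <- params$K; L <- params$L
  B1 <- rmatnorm_kron(params$G, params$Sigma_t)              # J x L
  B2 <- matrix(0, I * J, L)                                  # row i*J + j
  # b2 ~ N(0, SE (x) G (x) St): mix I independent G (x) St matrix normals
  # through the Cholesky factor of SE (environment-outer convention).
  LE <- chol(params$Sigma_E)
  Zi <- lapply(seq_len(I), function(i) rmatnorm_kron(params$G, params$Sigma_t))
  for (i in seq_len(I)) {
    acc <- matrix(0, J, L)
    for (i2 in seq_len(I)) acc <- acc + LE[i2, i] * Zi[[i2]]
    B2[(i - 1) * J + seq_len(J), ] <- acc
  }
  Lc <- chol(params$Sigma_c)
  env_id <- sprintf("Env%d", seq_len(I))
  line_id <- sprintf("L%03d", seq_len(J))
  trait_id <- sprintf("Trait%d", seq_len(L))
  # replicate units ordered env-major, line, replicate; traits innermost
  ui <- rep(seq_len(I), each = J * K)
  uj <- rep(rep(seq_len(J), each = K), I)
  uk <- rep(seq_len(K), I * J)
  n_rep_units <- I * J * K
  Cmat <- matrix(stats::rnorm(n_rep_units * L), n_rep_units, L) %*% Lc
  eta <- params$beta[ui, , drop = FALSE] + B1[uj, , drop = FALSE] +
    B2[(ui - 1) * J + uj, , drop = FALSE] + Cmat
  counts <- matrix(stats::rpois(n_rep_units * L, exp(t(eta))),
                   nrow = L)  # column per unit, traits innermost
  rec <- data.frame(env = env_id[rep(ui, each = L)],
                    line = line_id[rep(uj, each = L)],
                    rep = rep(uk, each = L),
                    trait = trait_id[rep(seq_len(L), n_rep_units)],
                    count = as.vector(counts))
  out <- count_dataset(rec, env_ids = env_id, line_ids = line_id,
                       trait_ids = trait_id)
  if (truth)
    attr(out, "truth") <- list(beta = params$beta, b1 = B1, b2 = B2,
                               Sigma_t = params$Sigma_t,
                               Sigma_E = params$Sigma_E,
                               Sigma_c = params$Sigma_c)
  out
}

#' Covariance to correlation
#'
#' Entrywise \eqn{\sigma_{ij} / \sqrt{\sigma_{ii}\sigma_{jj}}}; unit diagonal.
#'
#' @param m symmetric positive-definite covariance matrix.
#' @return The correlation matrix.
#' @examples
#' cov_to_corr(matrix(c(0.005, 0.0031, 0.0031, 0.003), 2, 2))  # 0.8 off-diag
#' @export
cov_to_corr <- function(m) {
  m <- as.matrix(m)
  if (any(diag(m) <= 0)) stop("covariance diagonal must be positive")
  s <- sqrt(diag(m))
  out <- m / tcrossprod(s)
  diag(out) <- 1
  out
}

#' Write a phenotype table in the long CSV schema
#'
#' @param data a [count_dataset()].
#' @param path output CSV path.
#' @export
write_phenotypes <- function(data, path) {
  stopifnot(inherits(data, "count_dataset"))
  utils::write.csv(data$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
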