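#' Build the stacked design for the augmented likelihood
#'
#' Arranges the collapsed counts into the stacked form used by the Gibbs
#' sampler.  The stacking order is the package-wide law: environment-major,
#' then line, then unit, with trait innermost, matching the Kronecker column
#' conventions \eqn{G \otimes \Sigma_t} (line outer, trait inner) for b1 and
#' \eqn{\Sigma_E \otimes G \otimes \Sigma_t} (environment outer, line middle,
#' trait inner) for b2.  After replicate collapsing each observational unit is
#' one (environment, line) cell.
#'
#' @param data a [collapse_replicates()] result.
#' @param r negative-binomial approximation size (default 1000); the stacked
#'   working response is `ystar = (y - r) / 2`.
#' @return An object of class `bpmtme_design` with elements:
#'   \describe{
#'     \item{Y, ystar}{n_units x L matrices of collapsed counts and the
#'       working response.}
#'     \item{env, line}{integer unit indices (1-based) into `env_ids`,
#'       `line_ids`.}
#'     \item{X, Z1, Z2}{sparse incidence matrices of the stacked rows onto the
#'       I*L intercepts, J*L line-trait effects and I*J*L interaction
#'       effects.}
#'     \item{unit_index}{data.frame mapping each stacked row to its
#'       (env, line, unit, trait).}
#'     \item{n_units, I, J, L, r, K}{dimensions, approximation size and
#'       replicate counts.}
#'   }
#' @export
build_design <- function(data, r = 1000) {
  stopifnot(inherits(data, "collapsed_counts"))
  if (r <= 0) stop("r must be positive")
  I <- length(data$env_ids); J <- length(data$line_ids)
  L <- length(data$trait_ids)
  cells <- data$cells
  ei <- match(cells$env, data$env_ids)
  ji <- match(cells$line, data$line_ids)
  li <- match(cells$trait, data$trait_ids)
  ord <- order(ei, ji, li)
  cells <- cells[ord, , drop = FALSE]; ei <- ei[ord]; ji <- ji[ord]; li <- li[ord]
  ucell <- !duplicated(paste(ei, ji))
  n_units <- sum(ucell)
  unit_of <- cumsum(ucell)
  ntr <- tapply(li, unit_of, function(x) length(unique(x)))
  if (any(ntr != L)) {
    b <- which(ntr != L)[1]
    stop("cell (env = ", cells$env[ucell][b], ", line = ",
         cells$line[ucell][b], ") lacks full trait coverage")
  }
  Y <- matrix(0L, n_units, L, dimnames = list(NULL, data$trait_ids))
  Y[cbind(unit_of, li)] <- cells$sum
  K <- cells$K[ucell]
  env_u <- ei[ucell]; line_u <- ji[ucell]
  nrow_stack <- n_units * L
  row_env <- rep(env_u, each = L)
  row_line <- rep(line_u, each = L)
  row_unit <- rep(seq_len(n_units), each = L)
  row_trait <- rep(seq_len(L), n_units)
  X <- Matrix::sparseMatrix(i = seq_len(nrow_stack),
                            j = (row_env - 1L) * L + row_trait,
                            x = 1, dims = c(nrow_stack, I * L))
  Z1 <- Matrix::sparseMatrix(i = seq_len(nrow_stack),
                             j = (row_line - 1L) * L + row_trait,
                             x = 1, dims = c(nrow_stack, J * L))
  Z2 <- Matrix::sparseMatrix(i = seq_len(nrow_stack),
                             j = (row_env - 1L) * J * L +
                               (row_line - 1L) * L + row_trait,
                             x = 1, dims = c(nrow_stack, I * J * L))
  structure(
    list(Y = Y, ystar = (Y - r) / 2, env = env_u, line = line_u, K = K,
         X = X, Z1 = Z1, Z2 = Z2,
         unit_index = data.frame(row = seq_len(nrow_stack),
                                 env = data$env_ids[row_env],
                                 line = data$line_ids[row_line],
                                 unit = row_unit,
                                 trait = data$trait_ids[row_trait]),
         n_units = n_units, I = I, J = J, L = L, r = r,
         env_ids = data$env_ids, line_ids = data$line_ids,
         trait_ids = data$trait_ids),
    class = "bpmtme_design")
}

#' @export
print.bpmtme_design <- function(x, ...) {
  cat("bpmtme_design:", x$n_units, "units x", x$L, "traits (",
      x$n_units * x$L, "stacked observations ), r =", x$r, "\n")
  invisible(x)
}

# Internal: design slot of the list handed to the C++ core.
design_to_cpp <- function(design, G) {
  list(Y = unname(design$Y), env = design$env, line = design$line,
       I = design$I, J = design$J, L = design$L, r = design$r,
       G = unname(G))
}

#' Stacked linear predictor of a model state
#'
#' Computes \eqn{\eta^* = X \beta^* + Z_1 b_1 + Z_2 b_2 + c} through the unit
#' index maps (no dense matrix products), returned in stacking order.
#'
#' @param state a model state as produced by [init_state()] or
#'   [gibbs_step()].
#' @param design a [build_design()] result.
#' @return Numeric vector of length `n_units * L`.
#' @export
linear_predictor <- function(state, design) {
  L <- design$L; J <- design$J
  eta <- matrix(0, design$n_units, L)
  for (l in seq_len(L)) {
    eta[, l] <- state$beta_star[(design$env - 1L) * L + l] +
      state$b1[cbind(design$line, l)] +
      state$b2[cbind((design$env - 1L) * J + design$line, l)] +
      state$c[, l]
  }
  as.vector(t(eta))
}

#' Log augmented likelihood
#'
#' The Polya-Gamma-augmented log-likelihood kernel
#' \eqn{y^{*T} \eta^* - \frac{1}{2} \eta^{*T} D \eta^*} with
#' \eqn{D = diag(\omega)}, up to the state-independent constant.
#'
#' @inheritParams linear_predictor
#' @return Scalar log-likelihood kernel value.
#' @export
log_augmented_likelihood <- function(state, design) {
  check_state_dims(state, design)
  cpp_log_aug_lik(design_to_cpp(design, diag(design$J)),
                  state_to_cpp(state))
}

check_state_dims <- function(state, design) {
  I <- design$I; J <- design$J; L <- design$L
  if (length(state$beta_star) != I * L ||
      !all(dim(state$b1) == c(J, L)) ||
      !all(dim(state$b2) == c(I * J, L)) ||
      !all(dim(state$c) == c(design$n_units, L)) ||
      !all(dim(state$omega) == c(design$n_units, L)))
    stop("state dimensions do not match the design")
  invisible(TRUE)
}
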