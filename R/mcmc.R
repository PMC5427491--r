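#' Hyperparameters of the BPMTME prior hierarchy
#'
#' Defaults follow the weakly informative specification used throughout:
#' flat-ish normal intercept prior, Huang-Wand inverse-Wishart /
#' inverse-gamma hierarchy with \eqn{\nu = 2} and auxiliary scale bound
#' \eqn{A = 10^4} for all three covariance matrices, and negative-binomial
#' approximation size \eqn{r = 1000}.
#'
#' @param r negative-binomial approximation size; fixed, never estimated.
#' @param beta_prior_mean prior mean of the offset intercepts \eqn{\beta^*}
#'   (scalar recycled, default 0).
#' @param beta_prior_scale scalar `s` with prior covariance `s * I` for
#'   \eqn{\beta^*}; default `1e4`.
#' @param literal_sigma_v if `TRUE`, interpret the scale literally as a prior
#'   precision of `1e4` (prior covariance `1e-4 * I`), i.e. a tight prior.
#'   Default `FALSE`, the weakly informative reading.
#' @param nu_t,nu_E,nu_c hierarchy degrees of freedom (default 2).
#' @param A_t,A_E,A_c auxiliary scale bounds (default `1e4`).
#' @param pg_trunc maximum Polya-Gamma series truncation depth.
#' @return A list of class `bpmtme_hyper`.
#' @export
bpmtme_hyper <- function(r = 1000, beta_prior_mean = 0,
                         beta_prior_scale = 1e4, literal_sigma_v = FALSE,
                         nu_t = 2, nu_E = 2, nu_c = 2,
                         A_t = 1e4, A_E = 1e4, A_c = 1e4,
                         pg_trunc = 200L) {
  stopifnot(r > 0, beta_prior_scale > 0, nu_t >= 2, nu_E >= 2, nu_c >= 2,
            A_t > 0, A_E > 0, A_c > 0)
  structure(list(r = r, beta_prior_mean = beta_prior_mean,
                 beta_prior_scale = beta_prior_scale,
                 literal_sigma_v = literal_sigma_v,
                 nu_t = nu_t, nu_E = nu_E, nu_c = nu_c,
                 A_t = A_t, A_E = A_E, A_c = A_c,
                 pg_trunc = as.integer(pg_trunc)),
            class = "bpmtme_hyper")
}

#' Chain settings
#'
#' Defaults are the full-length analysis chain: 40,000 iterations, the first
#' 20,000 discarded as burn-in, thinning of 5 (4000 retained samples).
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before retention; must be `< n_iter`.
#' @param thin retain every `thin`-th post-burn-in state.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param verbose print progress.
#' @return A list of class `chain_settings`.
#' @export
chain_settings <- function(n_iter = 40000, burn_in = 20000, thin = 5,
                           seed = NULL, verbose = FALSE) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, verbose = verbose),
            class = "chain_settings")
}

hyper_to_cpp <- function(hyper, design) {
  p <- design$I * design$L
  v0 <- if (isTRUE(hyper$literal_sigma_v)) 1 / hyper$beta_prior_scale
        else hyper$beta_prior_scale
  list(beta_prior_mean = rep_len(hyper$beta_prior_mean, p),
       beta_prior_var = v0,
       nu_t = hyper$nu_t, nu_E = hyper$nu_E, nu_c = hyper$nu_c,
       A_t = hyper$A_t, A_E = hyper$A_E, A_c = hyper$A_c,
       pg_trunc = hyper$pg_trunc)
}

state_to_cpp <- function(state) {
  list(beta_star = state$beta_star, b1 = state$b1, b2 = state$b2,
       c = state$c, omega = state$omega, Sigma_t = state$Sigma_t,
       Sigma_E = state$Sigma_E, Sigma_c = state$Sigma_c,
       a_t = state$a_t, a_E = state$a_E, a_c = state$a_c)
}

#' Initialize a model state
#'
#' Intercepts start at `log(mean count per env-trait) - log(r)` (floored away
#' from zero means), random effects at zero, covariance matrices at `0.1 * I`,
#' auxiliaries at one, and omega from one Polya-Gamma refresh at the initial
#' predictor — an overdispersion-safe, feasible starting point.
#'
#' @param design a [build_design()] result.
#' @param hyper a [bpmtme_hyper()] list.
#' @param grm optional J x J relationship matrix (identity if `NULL`).
#' @return A named list holding one Gibbs iteration's parameter values.
#' @export
init_state <- function(design, hyper = bpmtme_hyper(), grm = NULL) {
  I <- design$I; J <- design$J; L <- design$L
  mu <- matrix(0, I, L)
  for (i in seq_len(I))
    mu[i, ] <- colMeans(design$Y[design$env == i, , drop = FALSE])
  if (any(mu == 0))
    warning("all-zero counts for some env-trait cell; ",
            "initialization floored (model assumes Poisson-lognormal counts)")
  beta_star <- as.vector(t(log(pmax(mu, 1e-3)) - log(design$r)))
  state <- list(beta_star = beta_star,
                b1 = matrix(0, J, L), b2 = matrix(0, I * J, L),
                c = matrix(0, design$n_units, L),
                omega = matrix(1, design$n_units, L),
                Sigma_t = diag(0.1, L), Sigma_E = diag(0.1, I),
                Sigma_c = diag(0.1, L),
                a_t = rep(1, L), a_E = rep(1, I), a_c = rep(1, L))
  state$omega <- update_omega(state, design, hyper)
  state
}

#' One Gibbs sweep
#'
#' Applies the full-conditional updates in the published order — \eqn{\beta^*},
#' b1, b2, c, \eqn{\Sigma_t}, a_t, \eqn{\Sigma_E}, a_E, \eqn{\omega},
#' \eqn{\Sigma_c}, a_c — and returns the refreshed state.  Randomness flows
#' through R's RNG.
#'
#' @inheritParams init_state
#' @param state current model state.
#' @return The updated state list.
#' @export
gibbs_step <- function(state, design, hyper = bpmtme_hyper(), grm = NULL) {
  check_state_dims(state, design)
  G <- align_grm(grm, design$line_ids)
  out <- cpp_gibbs_sweep(design_to_cpp(design, G), state_to_cpp(state),
                         hyper_to_cpp(hyper, design))
  out
}

#' Single full-conditional updates
#'
#' Each function draws one parameter block from its full conditional given the
#' rest of the state, or, with `return_params = TRUE`, returns the
#' conditional's defining parameters instead of a draw: precision matrix `Q`,
#' right-hand side and mean for the Gaussian location blocks; degrees of
#' freedom `kappa` and scale matrix `S` for the inverse-Wishart covariance
#' blocks; `shape` and `rate` for the inverse-gamma auxiliary scales.
#'
#' @param block one of `"beta_star"`, `"b1"`, `"b2"`, `"c"`.
#' @inheritParams gibbs_step
#' @param return_params return the conditional parameters instead of drawing.
#' @return The drawn block (vector or matrix), or a parameter list.
#' @export
update_location_block <- function(block = c("beta_star", "b1", "b2", "c"),
                                  state, design, hyper = bpmtme_hyper(),
                                  grm = NULL, return_params = FALSE) {
  block <- match.arg(block)
  check_state_dims(state, design)
  G <- align_grm(grm, design$line_ids)
  out <- cpp_update_block(design_to_cpp(design, G), state_to_cpp(state),
                          hyper_to_cpp(hyper, design), block, return_params)
  if (return_params) out else out$value
}

#' @rdname update_location_block
#' @export
update_sigma_t <- function(state, design, hyper = bpmtme_hyper(), grm = NULL,
                           return_params = FALSE) {
  G <- align_grm(grm, design$line_ids)
  out <- cpp_update_block(design_to_cpp(design, G), state_to_cpp(state),
                          hyper_to_cpp(hyper, design), "sigma_t",
                          return_params)
  if (return_params) out else out$value
}

#' @rdname update_location_block
#' @export
update_sigma_e <- function(state, design, hyper = bpmtme_hyper(), grm = NULL,
                           return_params = FALSE) {
  G <- align_grm(grm, design$line_ids)
  out <- cpp_update_block(design_to_cpp(design, G), state_to_cpp(state),
                          hyper_to_cpp(hyper, design), "sigma_e",
                          return_params)
  if (return_params) out else out$value
}

#' @rdname update_location_block
#' @export
update_sigma_c <- function(state, design, hyper = bpmtme_hyper(),
                           return_params = FALSE) {
  out <- cpp_update_block(design_to_cpp(design, diag(design$J)),
                          state_to_cpp(state), hyper_to_cpp(hyper, design),
                          "sigma_c", return_params)
  if (return_params) out else out$value
}

#' @rdname update_location_block
#' @param which hierarchy whose auxiliary scales to draw: `"t"`, `"E"` or
#'   `"c"`.
#' @export
update_aux_scales <- function(which = c("t", "E", "c"), state, design,
                              hyper = bpmtme_hyper(), return_params = FALSE) {
  which <- match.arg(which)
  out <- cpp_update_block(design_to_cpp(design, diag(design$J)),
                          state_to_cpp(state), hyper_to_cpp(hyper, design),
                          paste0("a_", ifelse(which == "E", "E", which)),
                          return_params)
  if (return_params) out else as.vector(out$value)
}

#' @rdname update_location_block
#' @export
update_omega <- function(state, design, hyper = bpmtme_hyper()) {
  out <- cpp_update_block(design_to_cpp(design, diag(design$J)),
                          state_to_cpp(state), hyper_to_cpp(hyper, design),
                          "omega", FALSE)
  out$value
}

#' Run the Gibbs sampler
#'
#' Runs `n_iter` sweeps, discards `burn_in`, retains every `thin`-th state and
#' summarizes each scalar parameter by its posterior mean and SD.  The
#' Poisson-scale intercepts \eqn{\beta = \beta^* + \log r} are reported
#' alongside the offset intercepts.
#'
#' @inheritParams gibbs_step
#' @param settings a [chain_settings()] list.
#' @param model label stored on the fit (`"BPMTME"` or `"BPME"`).
#' @return An object of class `bpmtme_fit`: list with `draws` (matrices of
#'   retained samples, one row per sample), `summary` (data.frame of posterior
#'   means and SDs), `omega_mean`, the design dimensions and labels, and the
#'   settings used.
#' @export
run_chain <- function(design, grm = NULL, hyper = bpmtme_hyper(),
                      settings = chain_settings(),
                      model = if (design$L == 1) "BPME" else "BPMTME") {
  stopifnot(inherits(design, "bpmtme_design"))
  G <- align_grm(grm, design$line_ids)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  state <- init_state(design, hyper)
  res <- tryCatch(
    cpp_run_chain(design_to_cpp(design, G), state_to_cpp(state),
                  hyper_to_cpp(hyper, design), settings$n_iter,
                  settings$burn_in, settings$thin,
                  isTRUE(settings$verbose)),
    error = function(e) stop("Gibbs chain failed: ", conditionMessage(e),
                             call. = FALSE))
  I <- design$I; J <- design$J; L <- design$L
  tr <- design$trait_ids; ev <- design$env_ids
  colnames(res$beta_star) <- paste0("beta_star[", rep(ev, each = L), ",",
                                    rep(tr, I), "]")
  colnames(res$b1) <- paste0("b1[", rep(design$line_ids, each = L), ",",
                             rep(tr, J), "]")
  colnames(res$Sigma_t) <- paste0("Sigma_t[", rep(tr, L), ",",
                                  rep(tr, each = L), "]")
  colnames(res$Sigma_E) <- paste0("Sigma_E[", rep(ev, I), ",",
                                  rep(ev, each = I), "]")
  colnames(res$Sigma_c) <- paste0("Sigma_c[", rep(tr, L), ",",
                                  rep(tr, each = L), "]")
  draws <- res[c("beta_star", "b1", "b2", "c", "Sigma_t", "Sigma_E",
                 "Sigma_c", "a_t", "a_E", "a_c", "log_aug_lik")]
  sum_of <- function(m, name) {
    data.frame(parameter = if (!is.null(colnames(m))) colnames(m)
               else paste0(name, "[", seq_len(ncol(m)), "]"),
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               row.names = NULL)
  }
  beta <- res$beta_star + log(design$r)
  colnames(beta) <- sub("beta_star", "beta", colnames(res$beta_star))
  summ <- rbind(sum_of(res$beta_star, "beta_star"),
                sum_of(beta, "beta"),
                sum_of(res$Sigma_t, "Sigma_t"),
                sum_of(res$Sigma_c, "Sigma_c"),
                sum_of(res$Sigma_E, "Sigma_E"))
  structure(
    list(draws = draws, summary = summ, omega_mean = res$omega_mean,
         n_retained = nrow(res$beta_star), model = model,
         I = I, J = J, L = L, r = design$r, n_units = design$n_units,
         env_ids = ev, line_ids = design$line_ids, trait_ids = tr,
         settings = settings, hyper = hyper),
    class = "bpmtme_fit")
}

#' @export
print.bpmtme_fit <- function(x, ...) {
  cat(x$model, "fit:", x$I, "environments x", x$J, "lines x", x$L,
      ifelse(x$L == 1, "trait |", "traits |"), x$n_retained,
      "retained samples\n")
  keep <- !grepl("^(b1|beta_star)\\[", x$summary$parameter)
  print(utils::head(x$summary[keep, ], 20), row.names = FALSE)
  invisible(x)
}

#' Fit the multi-trait multi-environment count model
#'
#' Convenience wrapper: collapses replicates if needed, builds the stacked
#' design with the hyperparameters' `r`, aligns the relationship matrix and
#' runs the Gibbs sampler.
#'
#' @param data a [count_dataset()] or [collapse_replicates()] result.
#' @param grm optional line relationship matrix (identity if `NULL`).
#' @inheritParams run_chain
#' @return A `bpmtme_fit` object.
#' @export
fit_bpmtme <- function(data, grm = NULL, hyper = bpmtme_hyper(),
                       settings = chain_settings()) {
  if (inherits(data, "count_dataset")) data <- collapse_replicates(data)
  design <- build_design(data, r = hyper$r)
  run_chain(design, grm = grm, hyper = hyper, settings = settings,
            model = if (design$L == 1) "BPME" else "BPMTME")
}

#' Fit the univariate multi-environment special case
#'
#' Restricts the dataset to one trait and runs the identical machinery with
#' L = 1, so \eqn{\Sigma_t} and \eqn{\Sigma_c} degenerate to scalar variances.
#'
#' @inheritParams fit_bpmtme
#' @param trait trait label to fit; may be omitted for a single-trait dataset.
#' @return A `bpmtme_fit` with `model = "BPME"`.
#' @export
fit_bpme <- function(data, trait = NULL, grm = NULL, hyper = bpmtme_hyper(),
                     settings = chain_settings()) {
  if (inherits(data, "count_dataset")) data <- collapse_replicates(data)
  if (is.null(trait)) {
    if (length(data$trait_ids) != 1)
      stop("specify `trait` for a multi-trait dataset")
    trait <- data$trait_ids
  }
  fit_bpmtme(subset_traits(data, trait), grm = grm, hyper = hyper,
             settings = settings)
}

#' Write a posterior summary table
#'
#' Writes the parameter, posterior-mean and SD columns as CSV.
#'
#' @param fit a `bpmtme_fit`.
#' @param path output file.
#' @export
write_summary <- function(fit, path) {
  utils::write.csv(fit$summary, path, row.names = FALSE)
  invisible(path)
}
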