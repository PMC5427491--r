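#' CV1 training/testing partitions
#'
#' Builds `n_partitions` random masks of (environment, line) cells for
#' cross-validation scheme CV1: a masked line stays observed, for all traits,
#' in at least one other environment.  Each partition masks
#' `floor(fraction * n_cells)` cells (all traits of a cell jointly).  With
#' `by_line = TRUE`, `floor(fraction * J)` lines are selected instead and each
#' is masked in a random nonempty, proper subset of its environments.
#'
#' @param data a [collapse_replicates()] result.
#' @param fraction fraction of observed env-line cells (or of lines) to mask;
#'   in (0, 1).
#' @param n_partitions number of random partitions (default 10).
#' @param seed integer seed for the partition stream.
#' @param by_line mask by line rather than by cell (see Details).
#' @return An object of class `cv1_plan`: list of partitions, each a
#'   data.frame of masked `env`, `line` labels, plus the settings.
#' @export
make_cv1_partitions <- function(data, fraction, n_partitions = 10,
                                seed = NULL, by_line = FALSE) {
  stopifnot(inherits(data, "collapsed_counts"),
            fraction > 0, fraction < 1, n_partitions >= 1)
  cells <- unique(data$cells[c("env", "line")])
  rownames(cells) <- NULL
  n_cells <- nrow(cells)
  cells_per_line <- table(cells$line)
  if (!is.null(seed)) set.seed(seed)
  parts <- vector("list", n_partitions)
  for (p in seq_len(n_partitions)) {
    if (by_line) {
      n_lines <- floor(fraction * length(data$line_ids))
      if (n_lines < 1) stop("fraction too small: no line selected")
      sel <- sample(data$line_ids, n_lines)
      rows <- integer(0)
      for (ln in sel) {
        idx <- which(cells$line == ln)
        if (length(idx) < 2)
          stop("CV1 masking infeasible: line ", ln,
               " is observed in a single environment")
        take <- sample(length(idx), sample(length(idx) - 1, 1))
        rows <- c(rows, idx[take])
      }
    } else {
      target <- floor(fraction * n_cells)
      if (target < 1) stop("fraction too small: no cell masked")
      left <- as.list(cells_per_line)
      rows <- integer(0)
      for (i in sample.int(n_cells)) {
        if (length(rows) >= target) break
        ln <- cells$line[i]
        if (left[[ln]] > 1) {
          rows <- c(rows, i)
          left[[ln]] <- left[[ln]] - 1
        }
      }
      if (length(rows) < target)
        stop("CV1 masking infeasible: cannot mask ", target,
             " cells while keeping every line observed somewhere")
    }
    parts[[p]] <- cells[sort(rows), , drop = FALSE]
  }
  structure(list(partitions = parts, fraction = fraction,
                 n_partitions = n_partitions, by_line = by_line, seed = seed),
            class = "cv1_plan")
}

#' @export
print.cv1_plan <- function(x, ...) {
  cat("cv1_plan:", x$n_partitions, "partitions,",
      if (x$by_line) "line-level" else "cell-level", "masking, fraction",
      x$fraction, "(", nrow(x$partitions[[1]]), "cells per partition )\n")
  invisible(x)
}

#' Predict masked cells from a fitted chain
#'
#' For each retained sample s the predictor of a masked (environment, line,
#' trait) is \eqn{\hat\eta^* = \beta^{*(s)} + b_1^{(s)} + b_2^{(s)}} with the
#' observation-level effect c at its conditional prior mean (zero), and the
#' prediction is the average over samples of \eqn{r \exp(\hat\eta^*)} — the
#' count-scale posterior-mean, since the \eqn{-\log r} intercept offset is
#' undone by the factor r.
#'
#' @param fit a `bpmtme_fit` from [run_chain()], trained without the masked
#'   cells.
#' @param cells data.frame with columns `env`, `line` (labels) naming the
#'   cells to predict.
#' @return data.frame with columns `env`, `line`, `trait`, `pred`.
#' @export
predict_masked <- function(fit, cells) {
  stopifnot(inherits(fit, "bpmtme_fit"))
  ei <- match(cells$env, fit$env_ids)
  ji <- match(cells$line, fit$line_ids)
  if (anyNA(ei)) stop("unknown environment in cells")
  if (anyNA(ji)) stop("masked line absent from the fit: ",
                      cells$line[which(is.na(ji))[1]])
  L <- fit$L; J <- fit$J
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    i <- ei[k]; j <- ji[k]
    eta <- fit$draws$beta_star[, (i - 1) * L + seq_len(L), drop = FALSE] +
      fit$draws$b1[, (j - 1) * L + seq_len(L), drop = FALSE] +
      fit$draws$b2[, ((i - 1) * J + j - 1) * L + seq_len(L), drop = FALSE]
    out[[k]] <- data.frame(env = cells$env[k], line = cells$line[k],
                           trait = fit$trait_ids,
                           pred = colMeans(fit$r * exp(eta)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling, used as the
#' prediction-accuracy measure because count phenotypes are not normally
#' distributed.
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return Correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 values")
  stats::cor(x, y, method = "spearman")
}

#' CV1 accuracy evaluation of the BPMTME and BPME models
#'
#' For every model, testing fraction and random partition: fits the model on
#' the unmasked cells only, predicts the masked cells, and computes the
#' Spearman correlation between predicted and observed collapsed counts per
#' (trait, environment) combination; accuracies are then averaged over
#' partitions.  The BPME model is fit to each trait separately.
#'
#' @param data a [count_dataset()] or [collapse_replicates()] result.
#' @param grm optional relationship matrix (identity if `NULL`).
#' @param fractions testing fractions, e.g. `c(0.1, 0.2)`.
#' @param n_partitions random partitions per fraction (default 10).
#' @param models subset of `c("BPMTME", "BPME")`.
#' @param hyper a [bpmtme_hyper()] list.
#' @param settings a [chain_settings()] list; its seed is ignored (per-fit
#'   seeds are derived from `seed`).
#' @param seed master seed; partition and fit seeds are derived from it by
#'   named substreams, so adding partitions or models does not perturb the
#'   other draws.
#' @param by_line propagate to [make_cv1_partitions()].
#' @param fit_fun optionally override the fitting routine (used for stub
#'   models in tests); signature `(collapsed, trait_or_NULL, grm, hyper,
#'   settings)`, must return an object accepted by [predict_masked()].
#' @param verbose print one line per fit.
#' @return An `accuracy_table`: data.frame with columns `scenario`-free
#'   `trait`, `env`, `model`, `test_fraction`, `mean_spearman`, `sd_spearman`,
#'   with the per-partition correlations in `attr(x, "per_partition")`.
#' @export
evaluate_models <- function(data, grm = NULL, fractions = 0.1,
                            n_partitions = 10,
                            models = c("BPMTME", "BPME"),
                            hyper = bpmtme_hyper(),
                            settings = chain_settings(),
                            seed = NULL, by_line = FALSE, fit_fun = NULL,
                            verbose = FALSE) {
  if (inherits(data, "count_dataset")) data <- collapse_replicates(data)
  models <- match.arg(models, several.ok = TRUE)
  L <- length(data$trait_ids)
  obs <- data$cells
  obs_key <- paste(obs$env, obs$line, obs$trait, sep = "\r")
  rows <- list(); per_part <- list()
  for (frac in fractions) {
    plan <- make_cv1_partitions(data, frac, n_partitions,
                                seed = derive_seed(seed, "partition", frac),
                                by_line = by_line)
    for (model in models) {
      acc <- array(NA_real_, c(n_partitions, L, length(data$env_ids)),
                   dimnames = list(NULL, data$trait_ids, data$env_ids))
      for (p in seq_len(n_partitions)) {
        mask <- plan$partitions[[p]]
        train <- drop_cells(data, mask)
        preds <- NULL
        if (model == "BPMTME") {
          st <- settings
          st$seed <- derive_seed(seed, "fit", model, frac, p)
          fit <- if (is.null(fit_fun))
            fit_bpmtme(train, grm = grm, hyper = hyper, settings = st)
          else fit_fun(train, NULL, grm, hyper, st)
          preds <- predict_masked(fit, mask)
        } else {
          for (tr in data$trait_ids) {
            st <- settings
            st$seed <- derive_seed(seed, "fit", model, tr, frac, p)
            fit <- if (is.null(fit_fun))
              fit_bpme(train, trait = tr, grm = grm, hyper = hyper,
                       settings = st)
            else fit_fun(train, tr, grm, hyper, st)
            preds <- rbind(preds, predict_masked(fit, mask))
          }
        }
        preds$obs <- obs$sum[match(paste(preds$env, preds$line, preds$trait,
                                         sep = "\r"), obs_key)]
        for (tr in data$trait_ids) for (ev in data$env_ids) {
          sub <- preds[preds$trait == tr & preds$env == ev, ]
          if (nrow(sub) >= 2)
            acc[p, tr, ev] <- spearman(sub$obs, sub$pred)
        }
        if (verbose)
          message(model, " fraction ", frac, " partition ", p, " done")
      }
      for (tr in data$trait_ids) for (ev in data$env_ids) {
        v <- acc[, tr, ev]
        v <- v[!is.na(v)]
        rows[[length(rows) + 1L]] <-
          data.frame(trait = tr, env = ev, model = model,
                     test_fraction = frac,
                     mean_spearman = mean(v),
                     sd_spearman = if (length(v) < 2) 0 else stats::sd(v))
      }
      per_part[[paste(model, frac)]] <- acc
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_table", "data.frame")
  attr(out, "per_partition") <- per_part
  out
}

#' Grand-average accuracy
#'
#' The "Average" row construction: per model and testing fraction, the mean of
#' the per-(trait, environment) mean Spearman correlations.
#'
#' @param table an `accuracy_table` from [evaluate_models()].
#' @return data.frame with columns `model`, `test_fraction`, `mean_spearman`.
#' @export
accuracy_summary <- function(table) {
  agg <- stats::aggregate(mean_spearman ~ model + test_fraction,
                          data = as.data.frame(table), FUN = mean)
  agg[order(agg$model, agg$test_fraction), , drop = FALSE]
}

#' Write an accuracy table as CSV
#'
#' @param table an `accuracy_table`.
#' @param path output file.
#' @export
write_accuracy_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
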