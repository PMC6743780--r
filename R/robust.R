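# Robust linear regression by iteratively reweighted least squares with
# Tukey's bisquare psi, and the per-predictor variance partition built on
# it. The IWLS machinery is implemented here because the variance partition
# and the downstream odds ratio both need its internals (final weights,
# robust scale); MASS::rlm serves as an independent cross-check in the test
# suite only.

#' Robust linear fit by IWLS with Tukey's bisquare
#'
#' Iteratively reweighted least squares: residuals are scaled by the
#' median absolute deviation rescaled for consistency at the normal
#' (`median(|e|) / 0.6745`), observations are weighted by the bisquare
#' weight `(1 - u^2)^2` for `|u| = |e| / (k * s) < 1` (0 beyond), and the
#' weighted least-squares step is iterated until the largest coefficient
#' change falls below `tol` (relative to coefficient magnitude) or
#' `max_iter` is reached. An exact fit (robust scale numerically 0) stops
#' with unit weights.
#'
#' @param formula model formula.
#' @param data data frame with at least 6 complete observations.
#' @param k bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency).
#' @param tol convergence tolerance on coefficient change (default 1e-8).
#' @param max_iter maximum IWLS iterations (default 50).
#' @param weights optional fixed case weights; if supplied, a single
#'   weighted least-squares solve is returned (no reweighting), so unit
#'   weights reproduce ordinary least squares exactly.
#' @return object of class `robust_fit`: `coefficients`, `scale`,
#'   `weights`, `iterations`, `converged`, `fitted`, `residuals`, plus the
#'   response `y`, model matrix `x` and `terms`.
#' @export
fit_rlm <- function(formula, data, k = 4.685, tol = 1e-8, max_iter = 50,
                    weights = NULL) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  x <- model.matrix(attr(mf, "terms"), mf)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 6L) stop("need at least 6 observations")
  qr_x <- qr(x)
  if (qr_x$rank < p) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("design is collinear; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == n, all(weights >= 0))
    fit <- lm.wfit(x, y, w = weights)
    return(new_robust_fit(fit$coefficients, x, y,
                          scale = mad_scale(y - x %*% fit$coefficients),
                          w = weights, iterations = 0L, converged = TRUE,
                          terms = attr(mf, "terms")))
  }
  beta <- qr.coef(qr_x, y)
  w <- rep(1, n)
  s <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    e <- as.numeric(y - x %*% beta)
    s <- mad_scale(e)
    if (s < 1e-10 * max(1, mad_scale(y - mean(y)))) {
      w <- rep(1, n)   # exact fit
      converged <- TRUE
      break
    }
    u <- e / (k * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < p) stop("too many observations down-weighted to zero")
    fit <- lm.wfit(x, y, w = w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol * max(1, max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  new_robust_fit(beta, x, y, scale = s, w = w, iterations = iter,
                 converged = converged, terms = attr(mf, "terms"))
}

# MAD about zero, rescaled for consistency at the normal.
mad_scale <- function(e) median(abs(e)) / 0.6745

new_robust_fit <- function(beta, x, y, scale, w, iterations, converged,
                           terms) {
  fitted <- as.numeric(x %*% beta)
  structure(list(coefficients = beta, scale = scale, weights = w,
                 iterations = iterations, converged = converged,
                 fitted = fitted, residuals = as.numeric(y) - fitted,
                 y = as.numeric(y), x = x, terms = terms),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("Robust linear fit (IWLS, bisquare)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("scale %.4g, %d iteration(s)%s\n", x$scale, x$iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

# Weighted R-squared of a coefficient vector on (x, y) under weights w.
weighted_r2 <- function(x, y, beta, w) {
  e <- y - as.numeric(x %*% beta)
  ybar <- sum(w * y) / sum(w)
  sst <- sum(w * (y - ybar)^2)
  if (sst <= 0) return(0)
  1 - sum(w * e^2) / sst
}

# Columns of the model matrix belonging to one term.
term_columns <- function(fit, predictor) {
  labs <- attr(fit$terms, "term.labels")
  if (!predictor %in% labs)
    stop("unknown predictor '", predictor, "'; model terms: ",
         paste(labs, collapse = ", "))
  which(attr(fit$x, "assign") == match(predictor, labs))
}

#' Percent variance uniquely explained by one predictor
#'
#' The leave-one-predictor-out difference in robust R-squared:
#' `100 * (R2_full - R2_without)`, both computed on robust-weighted data
#' using the final full-model IWLS weights (the reduced model is refitted
#' by weighted least squares under those frozen weights). Clipped at 0.
#'
#' @param fit a [fit_rlm()] result.
#' @param predictor name of a model term (e.g. `"tonality"`).
#' @return percentage in \[0, 100\].
#' @export
percent_variance <- function(fit, predictor) {
  stopifnot(inherits(fit, "robust_fit"))
  w <- fit$weights
  r2_full <- weighted_r2(fit$x, fit$y, fit$coefficients, w)
  drop <- term_columns(fit, predictor)
  x_red <- fit$x[, -drop, drop = FALSE]
  fit_red <- lm.wfit(x_red, fit$y, w = w)
  r2_red <- weighted_r2(x_red, fit$y, fit_red$coefficients, w)
  min(100, max(0, 100 * (r2_full - r2_red)))
}

#' Variance partition across all predictors of a robust fit
#'
#' One row per model term with its unique percent variance, the partial F
#' for dropping the term (on robust-weighted data, with the full model's
#' frozen weights) and its p-value. The degrees-of-freedom columns report
#' the full-model pair (number of estimated parameters, n - parameters),
#' the labeling convention used in published variance-partition tables for
#' this design; the partial F itself has (terms dropped, n - parameters)
#' degrees of freedom.
#'
#' @param fit a [fit_rlm()] result.
#' @return [tibble::tibble()] with columns `predictor`,
#'   `percent_variance`, `F`, `df1`, `df2`, `p`; the full-model robust
#'   R-squared and model F are attached as attributes `r2` and `model_F`.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "robust_fit"))
  labs <- attr(fit$terms, "term.labels")
  w <- fit$weights
  n <- length(fit$y)
  p <- ncol(fit$x)
  sse_full <- sum(w * fit$residuals^2)
  r2_full <- weighted_r2(fit$x, fit$y, fit$coefficients, w)
  rows <- lapply(labs, function(term) {
    drop <- term_columns(fit, term)
    x_red <- fit$x[, -drop, drop = FALSE]
    fit_red <- lm.wfit(x_red, fit$y, w = w)
    sse_red <- sum(w * (fit$y - as.numeric(x_red %*% fit_red$coefficients))^2)
    df_num <- length(drop)
    f_part <- if (sse_full > 0)
      ((sse_red - sse_full) / df_num) / (sse_full / (n - p)) else Inf
    tibble::tibble(
      predictor = term,
      percent_variance = percent_variance(fit, term),
      F = f_part, df1 = p, df2 = n - p,
      p = pf(f_part, df_num, n - p, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  model_f <- if (r2_full < 1)
    (r2_full / (p - 1)) / ((1 - r2_full) / (n - p)) else Inf
  attr(out, "r2") <- r2_full
  attr(out, "model_F") <- model_f
  out
}

#' Permutation importance of each predictor under the robust fit
#'
#' For each model term, the term's column(s) in the design are permuted
#' `n_perm` times, predictions are recomputed with the fitted
#' coefficients, and the increase in the robust residual criterion
#' (weighted mean squared residual under the final IWLS weights) over the
#' unpermuted baseline is averaged. A model-agnostic cross-check on the
#' variance partition; deterministic per seed.
#'
#' @param fit a [fit_rlm()] result.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed.
#' @return [tibble::tibble()] with columns `predictor`, `importance`.
#' @export
permutation_importance <- function(fit, n_perm = 200, seed = 1) {
  stopifnot(inherits(fit, "robust_fit"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  labs <- attr(fit$terms, "term.labels")
  w <- fit$weights
  sw <- sum(w)
  n <- length(fit$y)
  base <- sum(w * fit$residuals^2) / sw
  with_seed(seed, {
    imp <- vapply(labs, function(term) {
      cols <- term_columns(fit, term)
      mean(vapply(seq_len(n_perm), function(i) {
        xp <- fit$x
        xp[, cols] <- xp[sample.int(n), cols]
        e <- fit$y - as.numeric(xp %*% fit$coefficients)
        sum(w * e^2) / sw - base
      }, numeric(1)))
    }, numeric(1))
    tibble::tibble(predictor = labs, importance = unname(imp))
  })
}

#' Build the 24-row regression design for one emotion and group
#'
#' Response: the group's mean rating of each excerpt for the emotion.
#' Predictors: the excerpt's tonality ratio, rhythm as the binary
#' presentation mode (0 = alaap, 1 = gat), and the mean familiarity of the
#' excerpt's raters in that group (familiarity varies across excerpts
#' because raters could opt out part-way).
#'
#' @param ratings a rating table.
#' @param features per-excerpt feature table with `raga`, `mode`,
#'   `tonality_ratio`.
#' @param group `"E"` or `"NE"`.
#' @param emotion one of the canonical labels.
#' @return data frame with columns `raga`, `mode`, `rating`, `tonality`,
#'   `rhythm`, `familiarity` (one row per excerpt).
#' @export
build_regression_design <- function(ratings, features, group, emotion) {
  validate_rating_table(ratings)
  group <- match.arg(group, GROUPS)
  emotion <- match.arg(emotion, EMOTIONS)
  d <- ratings[ratings$group == group & ratings$emotion == emotion, ,
               drop = FALSE]
  if (nrow(d) == 0L) stop("no ratings for group ", group)
  agg <- aggregate(cbind(rating, familiarity) ~ raga + mode, data = d,
                   FUN = mean)
  out <- merge(agg, features[c("raga", "mode", "tonality_ratio")],
               by = c("raga", "mode"))
  if (anyNA(out$tonality_ratio))
    stop("missing tonality for some excerpts")
  out <- out[order(out$raga, out$mode), , drop = FALSE]
  data.frame(raga = out$raga, mode = out$mode, rating = out$rating,
             tonality = out$tonality_ratio,
             rhythm = as.integer(out$mode == "gat"),
             familiarity = out$familiarity)
}

#' Fit all 16 robust regressions and collect the variance partition
#'
#' One robust regression per emotion x group of mean excerpt ratings on
#' tonality + rhythm + familiarity, with the per-predictor percent
#' variance, partial F and p-value of each.
#'
#' @param ratings a rating table.
#' @param features per-excerpt feature table (see
#'   [build_regression_design()]).
#' @param ... passed to [fit_rlm()].
#' @return [tibble::tibble()] with columns `emotion`, `group`,
#'   `predictor`, `percent_variance`, `F`, `df1`, `df2`, `p`.
#' @export
fit_all_regressions <- function(ratings, features, ...) {
  rows <- list()
  for (g in GROUPS) for (emo in EMOTIONS) {
    design <- build_regression_design(ratings, features, g, emo)
    fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, design, ...)
    part <- variance_partition(fit)
    part$emotion <- emo
    part$group <- g
    rows[[length(rows) + 1L]] <- part[c("emotion", "group", "predictor",
                                        "percent_variance", "F", "df1",
                                        "df2", "p")]
  }
  dplyr::bind_rows(rows)
}
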