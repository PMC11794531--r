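# ---- partial least squares (SIMPLS) --------------------------------------

#' Fit a partial-least-squares regression
#'
#' SIMPLS (de Jong 1993).  Predictor and response columns are standardized
#' (zero mean, unit variance; constant columns are centered only) before
#' fitting, and predictions are returned on the original response scale.
#' If `n_components` exceeds the rank of the predictor cross-product the
#' component count is reduced automatically with a warning.
#'
#' @param predictors numeric matrix, observations x p.
#' @param responses numeric matrix (or vector), observations x q.
#' @param n_components number of latent components (<= p).
#' @return An object of class `pls_fit` usable with `predict()`.
#' @export
pls_fit <- function(predictors, responses, n_components) {
  X <- as.matrix(predictors)
  Y <- as.matrix(responses)
  stopifnot(nrow(X) == nrow(Y), n_components >= 1)
  if (n_components > ncol(X)) {
    stop("n_components must not exceed the number of predictor columns",
         call. = FALSE)
  }
  mx <- colMeans(X); my <- colMeans(Y)
  sx <- apply(X, 2, sd); sy <- apply(Y, 2, sd)
  sx[sx == 0 | !is.finite(sx)] <- 1
  sy[sy == 0 | !is.finite(sy)] <- 1
  X0 <- sweep(sweep(X, 2, mx), 2, sx, "/")
  Y0 <- sweep(sweep(Y, 2, my), 2, sy, "/")
  p <- ncol(X0); q <- ncol(Y0)
  S <- crossprod(X0, Y0)
  R <- matrix(0, p, n_components)   # X weights
  Q <- matrix(0, q, n_components)   # Y loadings
  V <- matrix(0, p, n_components)   # orthonormal basis of X loadings
  a_used <- 0L
  for (a in seq_len(n_components)) {
    sv <- svd(S, nu = 1, nv = 1)
    if (sv$d[1] < 1e-12) {
      warning("component count reduced to ", a_used,
              " (predictor cross-product exhausted)", call. = FALSE)
      break
    }
    r <- sv$u[, 1]
    t_ <- X0 %*% r
    normt <- sqrt(sum(t_^2))
    if (normt < 1e-12) break
    t_ <- t_ / normt; r <- r / normt
    pl <- crossprod(X0, t_)
    ql <- crossprod(Y0, t_)
    v <- pl
    if (a_used > 0L) {
      Vp <- V[, seq_len(a_used), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    a_used <- a_used + 1L
    R[, a_used] <- r; Q[, a_used] <- ql; V[, a_used] <- v
  }
  if (a_used == 0L) stop("PLS fit failed: no usable components", call. = FALSE)
  coef <- R[, seq_len(a_used), drop = FALSE] %*%
    t(Q[, seq_len(a_used), drop = FALSE])
  structure(list(coef = coef, mx = mx, sx = sx, my = my, sy = sy,
                 n_components = a_used, p = p, q = q),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$p, " predictors -> ", x$q, " responses, ",
      x$n_components, " components\n", sep = "")
  invisible(x)
}

#' Predict from a PLS fit
#'
#' @param object a `pls_fit`.
#' @param newdata numeric matrix (or vector) of new predictor rows.
#' @param ... unused.
#' @return Matrix of predicted responses on the original scale.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != object$p) Xn <- matrix(as.numeric(Xn), ncol = object$p)
  X0 <- sweep(sweep(Xn, 2, object$mx), 2, object$sx, "/")
  Y0 <- X0 %*% object$coef
  sweep(sweep(Y0, 2, object$sy, "*"), 2, object$my, "+")
}

# ---- predictor matrices ----------------------------------------------------

#' Build a predictor matrix for the PLS protocols
#'
#' Predictors are either network parameters or mean processing-node
#' activities, restricted to the full set, the top-`l` KS-ranked subset
#' (ranking from [compare_populations()], shared by all leave-one-out
#' fits), or a random size-`l` subset.
#'
#' @param pop the aversion-resistant `population`.
#' @param batch the shared test batch (for activities).
#' @param type `"params"` or `"activities"`.
#' @param subset `"all"`, `"ks"` or `"random"`.
#' @param l subset size (1..6) when `subset != "all"`.
#' @param comparison a `population_comparison` (required for `subset =
#'   "ks"`).
#' @param seed seed for random subsets.
#' @return Numeric matrix, networks x p, with attribute `"columns"` naming
#'   the selected predictors.
#' @export
predictor_matrix <- function(pop, batch, type = c("params", "activities"),
                             subset = c("all", "ks", "random"), l = NULL,
                             comparison = NULL, seed = 1L) {
  type <- match.arg(type)
  subset <- match.arg(subset)
  full <- if (type == "params") {
    m <- t(vapply(pop$networks, flatten_params, numeric(31)))
    colnames(m) <- param_names()
    m
  } else {
    m <- activity_matrix(pop, batch)
    colnames(m) <- activity_names()
    m
  }
  cols <- switch(subset,
    all = seq_len(ncol(full)),
    ks = {
      if (is.null(comparison)) {
        stop("subset = 'ks' requires a population_comparison", call. = FALSE)
      }
      rk <- if (type == "params") comparison$param_ranking else
        comparison$activity_ranking
      rk[seq_len(l)]
    },
    random = withr::with_seed(seed, sample(ncol(full), l))
  )
  out <- full[, cols, drop = FALSE]
  attr(out, "columns") <- colnames(full)[cols]
  out
}

# ---- leave-one-out treatment prediction -----------------------------------

COR3_INDEX <- 12L

# Achieved metrics after imposing values at idx on network m, on that
# network's fresh evaluation batch.
impose_and_evaluate <- function(params, idx, values, n_eval, noise_sd,
                                seed) {
  treated <- set_params(params, idx, values)
  eval_batch <- generate_trials(n_eval, rule = "aversion_sensitive",
                                seed = seed, noise_sd = noise_sd)
  evaluate_network(treated, eval_batch)
}

#' Predict CoR3 treatments by leave-one-out PLS
#'
#' For every network `m` in the aversion-resistant population, fits a PLS
#' model on all *other* networks mapping their predictors to the CoR3 value
#' each one's single-parameter search found (the parameter-12 record of
#' [search_all_params()]), predicts a new CoR3 value for network `m`,
#' imposes it (parameter 12 only) and evaluates the treated network on a
#' fresh batch.
#'
#' @param pop the aversion-resistant `population`.
#' @param search_results list of [search_all_params()] results, one per
#'   network, in population order.
#' @param predictors predictor matrix from [predictor_matrix()] (rows in
#'   population order).
#' @param n_components latent components; default `min(p, 5)`.
#' @param n_eval fresh evaluation batch size (default 1000).
#' @param noise_sd input noise for the evaluation batches.
#' @param seed master seed for the evaluation batches.
#' @return A data frame: `network_id`, `predicted_cor3`, `ar_drink_rate`,
#'   `side_effect_rate`, `total_error`.
#' @export
predict_cor3_treatment <- function(pop, search_results, predictors,
                                   n_components = NULL, n_eval = 1000L,
                                   noise_sd = 0.2, seed = 1L) {
  N <- length(pop$networks)
  if (length(search_results) != N) {
    stop("search results required for every network", call. = FALSE)
  }
  X <- as.matrix(predictors)
  y <- vapply(search_results, function(sr) {
    sr$records[[COR3_INDEX]]$new_values[1]
  }, numeric(1))
  ncomp <- if (is.null(n_components)) min(ncol(X), 5L) else n_components
  rows <- lapply(seq_len(N), function(m) {
    fit <- pls_fit(X[-m, , drop = FALSE], y[-m], ncomp)
    pred <- drop(predict(fit, X[m, , drop = FALSE]))
    met <- impose_and_evaluate(pop$networks[[m]], COR3_INDEX, pred,
                               n_eval, noise_sd,
                               derive_seed(seed, "pls-eval", m))
    data.frame(network_id = pop$networks[[m]]$network_id,
               predicted_cor3 = pred,
               ar_drink_rate = met$ar_drink_rate,
               side_effect_rate = met$side_effect_rate,
               total_error = met$total_error)
  })
  do.call(rbind, rows)
}

#' Predict the best treatment by leave-one-out PLS
#'
#' For every network `m`, fits a leave-one-out PLS model whose responses
#' are the 62 columns (the 31 searched parameter values and their 31
#' achieved total-error rates), predicts all 62 for network `m`, tests the
#' 8 candidate parameter changes with the lowest *predicted* error by
#' imposing each predicted value on `m`, and selects the tested candidate
#' with the lowest realized total error.
#'
#' @inheritParams predict_cor3_treatment
#' @param n_test number of lowest-predicted-error candidates to test
#'   (default 8).
#' @return A data frame: `network_id`, `chosen_param`, `chosen_value`,
#'   `ar_drink_rate`, `side_effect_rate`, `total_error`.
#' @export
predict_best_treatment <- function(pop, search_results, predictors,
                                   n_components = NULL, n_test = 8L,
                                   n_eval = 1000L, noise_sd = 0.2,
                                   seed = 1L) {
  N <- length(pop$networks)
  if (length(search_results) != N) {
    stop("search results required for every network", call. = FALSE)
  }
  X <- as.matrix(predictors)
  Bstar <- t(vapply(search_results, function(sr) {
    vapply(sr$records, function(r) r$new_values[1], numeric(1))
  }, numeric(31)))
  Cstar <- t(vapply(search_results, function(sr) {
    vapply(sr$records, function(r) r$achieved$total_error, numeric(1))
  }, numeric(31)))
  Y <- cbind(Bstar, Cstar)
  ncomp <- if (is.null(n_components)) min(ncol(X), 5L) else n_components
  rows <- lapply(seq_len(N), function(m) {
    fit <- pls_fit(X[-m, , drop = FALSE], Y[-m, , drop = FALSE], ncomp)
    pred <- drop(predict(fit, X[m, , drop = FALSE]))
    test_predicted_candidates(pop$networks[[m]], pred[1:31], pred[32:62],
                              n_test = n_test, n_eval = n_eval,
                              noise_sd = noise_sd,
                              seed = derive_seed(seed, "pls-best-eval", m))
  })
  do.call(rbind, rows)
}

# Test the n_test candidate parameter changes with the lowest predicted
# error on the actual network; keep the one with the lowest realized total
# error.  Split out of predict_best_treatment so the selection step can be
# exercised with injected (oracle) predictions.
test_predicted_candidates <- function(params, pred_vals, pred_err,
                                      n_test = 8L, n_eval = 1000L,
                                      noise_sd = 0.2, seed = 1L) {
  cand <- order(pred_err)[seq_len(n_test)]
  tested <- lapply(cand, function(j) {
    impose_and_evaluate(params, j, pred_vals[j], n_eval, noise_sd,
                        derive_seed(seed, "candidate", j))
  })
  tot <- vapply(tested, `[[`, numeric(1), "total_error")
  b <- which.min(tot)
  met <- tested[[b]]
  data.frame(network_id = params$network_id,
             chosen_param = cand[b],
             chosen_value = pred_vals[cand[b]],
             ar_drink_rate = met$ar_drink_rate,
             side_effect_rate = met$side_effect_rate,
             total_error = met$total_error)
}
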