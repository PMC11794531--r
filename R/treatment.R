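# ---- fast candidate evaluation -------------------------------------------
#
# A change to one or two of the 31 parameters perturbs the output logit
# matrix Z = H %*% t(w2) + b2 by at most two rank-one terms: w1/b1 changes
# alter a single hidden node's activity column, w2/b2 changes alter a single
# logit column.  The search evaluates 100+ candidate values per iteration,
# so candidates are scored in bulk on this structure instead of re-running
# the full forward pass.  An invariant test checks this path against the
# naive forward pass.

# Precompute per-(network, batch) state reused across all candidate
# evaluations during a search.
net_precompute <- function(params, batch) {
  X <- batch$noisy_inputs
  n <- nrow(X)
  P0 <- X %*% t(params$w1) + rep(params$b1, each = n)
  H0 <- tanh(P0)
  Z0 <- H0 %*% t(params$w2) + rep(params$b2, each = n)
  is_ar <- batch$trial_type == AR_TRIAL_TYPE
  list(X = X, n = n, w1 = params$w1, w2 = params$w2,
       b1 = params$b1, b2 = params$b2,
       P0 = P0, H0 = H0, Z0 = Z0,
       is_ar = is_ar, non_ar = !is_ar,
       targets_non_ar = batch$targets[!is_ar])
}

# Decode a flat parameter index into its structural location.
decode_param <- function(j) {
  if (j <= 12L) {
    list(kind = "w1", node = (j - 1L) %/% 4L + 1L, col = (j - 1L) %% 4L + 1L)
  } else if (j <= 24L) {
    list(kind = "w2", out = (j - 13L) %/% 3L + 1L, node = (j - 13L) %% 3L + 1L)
  } else if (j <= 27L) {
    list(kind = "b1", node = j - 24L)
  } else {
    list(kind = "b2", out = j - 27L)
  }
}

# Actions (n x K integer matrix) for K joint candidate values V (K x d) of
# the flat parameters idx (d = 1 or 2).
candidate_actions <- function(pre, idx, V) {
  V <- as.matrix(V)
  K <- nrow(V); n <- pre$n
  locs <- lapply(idx, decode_param)

  # accumulate per-hidden-node preactivation perturbations (n x K each)
  padd <- vector("list", 3L)
  w2_changes <- list()           # list of (out, node, delta[K])
  b2_add <- matrix(0, K, 4L)
  for (m in seq_along(idx)) {
    loc <- locs[[m]]; v <- V[, m]
    if (loc$kind == "w1") {
      d <- pre$X[, loc$col] %o% (v - pre$w1[loc$node, loc$col])
      padd[[loc$node]] <- if (is.null(padd[[loc$node]])) d else padd[[loc$node]] + d
    } else if (loc$kind == "b1") {
      d <- matrix(v - pre$b1[loc$node], n, K, byrow = TRUE)
      padd[[loc$node]] <- if (is.null(padd[[loc$node]])) d else padd[[loc$node]] + d
    } else if (loc$kind == "w2") {
      w2_changes[[length(w2_changes) + 1L]] <-
        list(out = loc$out, node = loc$node,
             delta = v - pre$w2[loc$out, loc$node])
    } else {
      b2_add[, loc$out] <- b2_add[, loc$out] + (v - pre$b2[loc$out])
    }
  }
  hidden_affected <- which(!vapply(padd, is.null, logical(1)))
  Hmat <- lapply(hidden_affected, function(k) tanh(pre$P0[, k] + padd[[k]]))
  names(Hmat) <- as.character(hidden_affected)

  act <- matrix(1L, n, K)
  best <- NULL
  for (i in 1:4) {
    Ti <- matrix(pre$Z0[, i], n, K)
    for (k in hidden_affected) {
      # per-candidate w2[i, k] if that entry is also being changed
      coef <- rep(pre$w2[i, k], K)
      for (ch in w2_changes) {
        if (ch$out == i && ch$node == k) coef <- coef + ch$delta
      }
      Ti <- Ti - pre$H0[, k] * pre$w2[i, k] +
        Hmat[[as.character(k)]] * matrix(coef, n, K, byrow = TRUE)
    }
    for (ch in w2_changes) {
      if (ch$out == i && !(ch$node %in% hidden_affected)) {
        Ti <- Ti + pre$H0[, ch$node] %o% ch$delta
      }
    }
    if (any(b2_add[, i] != 0)) {
      Ti <- Ti + matrix(b2_add[, i], n, K, byrow = TRUE)
    }
    if (i == 1L) {
      best <- Ti
    } else {
      gt <- Ti > best
      act[gt] <- i
      best[gt] <- Ti[gt]
    }
  }
  act
}

# Objective values for K candidates; objective "total_error" or "ar_only".
candidate_objective <- function(pre, idx, V, objective) {
  act <- candidate_actions(pre, idx, V)
  ar <- colMeans(act[pre$is_ar, , drop = FALSE] == 3L)
  if (objective == "ar_only") return(ar)
  se <- colMeans(act[pre$non_ar, , drop = FALSE] != pre$targets_non_ar)
  ar + se
}

# ---- iterative Gaussian random search ------------------------------------

#' Derivative-free iterative Gaussian random search
#'
#' On each iteration, 100 candidate values are drawn from a Gaussian
#' centered on the current value (initial standard deviation 10; thereafter
#' `min(sd_cap, |previous value - new value|)` per coordinate), the
#' objective is evaluated on all candidates plus the current value, and the
#' best is kept.  The search stops when the relative improvement falls below
#' `stop_rel` (1%), or immediately when the objective reaches zero.  If no
#' proposal is accepted, the standard deviation drops to `sd_floor` for one
#' extra iteration before the stopping rule fires.  Because the current
#' value is always among the candidates, the objective never increases.
#'
#' @param f objective: a function taking a K x d matrix of candidate values
#'   and returning K objective values (lower is better).
#' @param v0 numeric starting value(s) (length 1 or 2).
#' @param seed integer seed; the search is fully reproducible.
#' @param n_proposals Gaussian proposals per iteration (default 100).
#' @param init_sd first-iteration proposal sd (default 10).
#' @param sd_cap ceiling on later-iteration sd (default 0.5).
#' @param stop_rel relative-improvement stopping threshold (default 0.01).
#' @param sd_floor sd used for the single extra iteration after a
#'   no-move iteration (default 0.01).
#' @param max_iter hard iteration cap.
#' @return List with `value` (best value(s) found), `objective` (its
#'   objective), and `iterations`.
#' @export
random_search <- function(f, v0, seed = 1L, n_proposals = 100L, init_sd = 10,
                          sd_cap = 0.5, stop_rel = 0.01, sd_floor = 0.01,
                          max_iter = 200L) {
  d <- length(v0)
  v_cur <- as.numeric(v0)
  e_cur <- f(matrix(v_cur, 1L, d))
  if (e_cur <= 0) {
    return(list(value = v_cur, objective = e_cur, iterations = 0L))
  }
  prop_sd <- rep(init_sd, d)
  extra_used <- FALSE
  iters <- 0L
  withr::with_seed(seed, {
    while (iters < max_iter) {
      iters <- iters + 1L
      props <- matrix(rnorm(n_proposals * d,
                            mean = rep(v_cur, each = n_proposals),
                            sd = rep(prop_sd, each = n_proposals)),
                      n_proposals, d)
      cand <- rbind(props, v_cur)
      vals <- f(cand)
      b <- which.min(vals)
      v_new <- cand[b, ]
      e_new <- vals[b]
      moved <- any(v_new != v_cur)
      rel <- (e_cur - e_new) / e_cur
      sd_next <- pmin(sd_cap, abs(v_cur - v_new))
      v_cur <- v_new
      e_cur <- e_new
      if (e_cur <= 0) break
      if (rel < stop_rel) {
        if (!moved && !extra_used) {
          extra_used <- TRUE
          prop_sd <- rep(sd_floor, d)
          next
        }
        break
      }
      sd_next[sd_next == 0] <- sd_floor
      prop_sd <- sd_next
    }
  })
  list(value = v_cur, objective = e_cur, iterations = iters)
}

# ---- network treatment searches ------------------------------------------

new_treatment_record <- function(network_id, idx, values, objective,
                                 objective_value, iterations, achieved) {
  structure(list(network_id = network_id,
                 param_indices = as.integer(idx),
                 new_values = as.numeric(values),
                 objective = objective,
                 objective_value = objective_value,
                 iterations = iterations,
                 achieved = achieved),
            class = "treatment_record")
}

#' @export
print.treatment_record <- function(x, ...) {
  cat("<treatment_record> ", x$network_id, ": param(s) ",
      paste(x$param_indices, collapse = ","), " -> ",
      paste(format(x$new_values, digits = 4), collapse = ","),
      " | achieved AR drinking ",
      format(x$achieved$ar_drink_rate, digits = 3), "\n", sep = "")
  invisible(x)
}

# Shared implementation for single- and two-parameter network searches.
search_params_impl <- function(params, idx, batch, objective, seed,
                               eval_batch, ...) {
  objective <- match.arg(objective, c("total_error", "ar_only"))
  batch <- retarget_batch(batch, "aversion_sensitive")
  pre <- net_precompute(params, batch)
  f <- function(V) candidate_objective(pre, idx, V, objective)
  flat <- flatten_params(params)
  rs <- random_search(f, v0 = flat[idx], seed = seed, ...)
  treated <- set_params(params, idx, rs$value)
  if (is.null(eval_batch)) {
    eval_batch <- generate_trials(batch$n, rule = "aversion_sensitive",
                                  seed = derive_seed(seed, "treat-eval"),
                                  noise_sd = batch$noise_sd)
  }
  achieved <- evaluate_network(treated, eval_batch)
  new_treatment_record(params$network_id, idx, rs$value, objective,
                       rs$objective, rs$iterations, achieved)
}

#' Search a single parameter for the best treatment value
#'
#' Runs the iterative Gaussian random search ([random_search()]) over
#' parameter `j` of an aversion-resistant network, minimizing either the
#' total error (aversion-resistant drinking rate plus side-effect rate,
#' under aversion-sensitive targets) or the drinking rate alone.  The
#' objective is evaluated on the fixed `batch` (so the search is
#' deterministic given `seed`); the achieved metrics in the returned record
#' are measured on an independent fresh batch.
#'
#' @param params the network under treatment.
#' @param j flat parameter index in 1..31 (12 is CoR3).
#' @param batch the fixed search batch; its targets are recomputed under the
#'   aversion-sensitive rule.
#' @param objective `"total_error"` or `"ar_only"`.
#' @param seed integer seed for the proposal draws.
#' @param eval_batch optional fresh batch for the achieved metrics (derived
#'   from `seed` when absent).
#' @param ... further tuning arguments for [random_search()].
#' @return A `treatment_record`: `param_indices`, `new_values`, the
#'   search-batch `objective_value`, `iterations`, and `achieved`
#'   ([evaluate_network()] metrics on the fresh batch).
#' @export
search_single <- function(params, j, batch,
                          objective = c("total_error", "ar_only"),
                          seed = 1L, eval_batch = NULL, ...) {
  j <- as.integer(j)
  stopifnot(length(j) == 1L, j >= 1L, j <= 31L)
  search_params_impl(params, j, batch, objective, seed, eval_batch, ...)
}

#' Search a pair of parameters jointly
#'
#' As [search_single()], but each iteration draws 100 candidate value
#' *pairs* (independent Gaussians per coordinate, the same sd schedule
#' applied coordinate-wise).
#'
#' @inheritParams search_single
#' @param j,k distinct flat parameter indices in 1..31.
#' @return A `treatment_record` with two `param_indices`.
#' @export
search_pair <- function(params, j, k, batch,
                        objective = c("total_error", "ar_only"),
                        seed = 1L, eval_batch = NULL, ...) {
  j <- as.integer(j); k <- as.integer(k)
  stopifnot(j >= 1L, j <= 31L, k >= 1L, k <= 31L)
  if (j == k) stop("pair search requires two distinct parameters",
                   call. = FALSE)
  search_params_impl(params, c(j, k), batch, objective, seed, eval_batch, ...)
}

#' Exhaustive single-parameter search over all 31 parameters
#'
#' Runs [search_single()] for every parameter and identifies the best
#' record (lowest search objective, ties broken toward the lower parameter
#' index).
#'
#' @inheritParams search_single
#' @return List with `records` (31 `treatment_record`s), `best` (the winning
#'   record) and `best_param` (its index).
#' @export
search_all_params <- function(params, batch,
                              objective = c("total_error", "ar_only"),
                              seed = 1L, eval_batch = NULL, ...) {
  objective <- match.arg(objective)
  if (is.null(eval_batch)) {
    eval_batch <- generate_trials(batch$n, rule = "aversion_sensitive",
                                  seed = derive_seed(seed, "treat-eval"),
                                  noise_sd = batch$noise_sd)
  }
  records <- lapply(1:31, function(j) {
    search_single(params, j, batch, objective = objective,
                  seed = derive_seed(seed, "param", j),
                  eval_batch = eval_batch, ...)
  })
  obj_vals <- vapply(records, `[[`, numeric(1), "objective_value")
  best_param <- which.min(obj_vals)   # first minimum = lowest index on ties
  list(records = records, best = records[[best_param]],
       best_param = best_param)
}

#' Exhaustive pair search over all parameter pairs
#'
#' Runs [search_pair()] on all 465 unordered parameter pairs; used on
#' networks whose best single-parameter treatment failed.
#'
#' @inheritParams search_single
#' @return List with `records` (one per pair), `best`, and `best_pair`.
#' @export
search_all_pairs <- function(params, batch,
                             objective = c("total_error", "ar_only"),
                             seed = 1L, eval_batch = NULL, ...) {
  objective <- match.arg(objective)
  if (is.null(eval_batch)) {
    eval_batch <- generate_trials(batch$n, rule = "aversion_sensitive",
                                  seed = derive_seed(seed, "treat-eval"),
                                  noise_sd = batch$noise_sd)
  }
  pairs <- utils::combn(31L, 2L)
  records <- lapply(seq_len(ncol(pairs)), function(q) {
    search_pair(params, pairs[1L, q], pairs[2L, q], batch,
                objective = objective,
                seed = derive_seed(seed, "pair", pairs[1L, q], pairs[2L, q]),
                eval_batch = eval_batch, ...)
  })
  obj_vals <- vapply(records, `[[`, numeric(1), "objective_value")
  b <- which.min(obj_vals)
  list(records = records, best = records[[b]], best_pair = pairs[, b])
}

#' Impose retraining parameter changes in order of magnitude
#'
#' Given an aversion-resistant network and its fully retrained version
#' (same lineage), sorts the 31 parameter changes by absolute magnitude and
#' imposes them cumulatively from largest to smallest, evaluating the
#' network after each additional change.  Step 0 is the untreated network;
#' step 31 is the fully retrained network.
#'
#' @param ar the aversion-resistant `network_params`.
#' @param retrained its retrained version (matching `network_id`).
#' @param batch evaluation batch (targets recomputed under the
#'   aversion-sensitive rule).
#' @return A data frame with one row per step (0..31): `n_imposed`,
#'   `param_imposed` (NA at step 0), `ar_drink_rate`, `side_effect_rate`,
#'   `total_error`.
#' @export
impose_ordered_retraining <- function(ar, retrained, batch) {
  if (!identical(ar$network_id, retrained$network_id)) {
    stop("ar and retrained networks must share lineage (same network_id)",
         call. = FALSE)
  }
  batch <- retarget_batch(batch, "aversion_sensitive")
  f_ar <- flatten_params(ar)
  f_re <- flatten_params(retrained)
  ord <- order(abs(f_re - f_ar), decreasing = TRUE)
  flat <- f_ar
  rows <- vector("list", 32L)
  for (step in 0:31) {
    if (step > 0L) flat[ord[step]] <- f_re[ord[step]]
    m <- evaluate_network(unflatten_params(flat, template = ar), batch)
    rows[[step + 1L]] <- data.frame(
      n_imposed = step,
      param_imposed = if (step == 0L) NA_integer_ else ord[step],
      ar_drink_rate = m$ar_drink_rate,
      side_effect_rate = m$side_effect_rate,
      total_error = m$total_error)
  }
  do.call(rbind, rows)
}

#' Treatment failure rate
#'
#' Fraction of treated networks whose achieved aversion-resistant drinking
#' rate exceeds `threshold` (default 0.1).
#'
#' @param records list of `treatment_record`s (one best record per network),
#'   or a numeric vector of achieved drinking rates.
#' @param threshold failure threshold on the drinking rate.
#' @return A fraction in \[0, 1\].
#' @export
failure_rate <- function(records, threshold = 0.1) {
  rates <- if (is.numeric(records)) {
    records
  } else {
    if (length(records) == 0L) stop("no treatment records", call. = FALSE)
    vapply(records, function(r) r$achieved$ar_drink_rate, numeric(1))
  }
  if (length(rates) == 0L) stop("no treatment records", call. = FALSE)
  mean(rates > threshold)
}

#' Serialize treatment records to JSON
#'
#' @param records list of `treatment_record`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_treatments_json <- function(records, path) {
  obj <- lapply(records, function(r) {
    list(network_id = r$network_id, param_indices = r$param_indices,
         new_values = r$new_values, objective = r$objective,
         iterations = r$iterations,
         achieved = list(ar_drink_rate = r$achieved$ar_drink_rate,
                         side_effect_rate = r$achieved$side_effect_rate,
                         total_error = r$achieved$total_error))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
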