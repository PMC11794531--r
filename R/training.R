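#' Derive a reproducible sub-seed
#'
#' Deterministically hashes a master seed together with any number of string
#' or integer labels (stage names, network ids, attempt counters) into an
#' integer seed below 2^31.  All randomness in the package flows through
#' sub-seeds derived this way, so any stage can be re-run in isolation.
#'
#' @param master_seed integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, ...) {
  labels <- paste(c(master_seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  m <- 2147483629  # largest prime < 2^31
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Training configurations.  Trained endpoints depend noticeably on the
# optimizer, so each network draws one configuration at random (optimizer
# family, learning rate, stopping error), emulating training with one of
# several randomly selected algorithms.  This heterogeneity is part of the
# study conditions: it produces both crisp and marginal solutions.
draw_train_algo <- function(seed) {
  withr::with_seed(seed, {
    algo <- sample(c("adam", "gdm", "rprop"), 1L)
    list(algo = algo,
         lr = switch(algo,
                     adam = 10^runif(1, -2.3, -0.7),
                     gdm = 10^runif(1, -1.3, -0.3),
                     rprop = 0.01),
         stop_error = runif(1, 0.01, 0.045))
  })
}

# One full-batch fit of the 31 parameters on softmax cross-entropy with the
# given configuration.  Returns the flat parameter vector reached (the
# acceptance decision is made by the caller).
optimizer_fit <- function(flat, inputs, targets, algo = list(),
                          max_epochs = 3000L, check_every = 25L) {
  algo <- modifyList(list(algo = "adam", lr = 0.05, stop_error = 0.02),
                     algo)
  n <- nrow(inputs)
  tmat <- matrix(0, n, 4L)
  tmat[cbind(seq_len(n), targets)] <- 1
  m <- v <- numeric(31)
  step <- rep(algo$lr, 31)       # rprop per-parameter step sizes
  g_prev <- numeric(31)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  p <- unflatten_params(flat)
  w1 <- p$w1; w2 <- p$w2; b1 <- p$b1; b2 <- p$b2
  for (epoch in seq_len(max_epochs)) {
    h <- tanh(inputs %*% t(w1) + rep(b1, each = n))
    z <- h %*% t(w2) + rep(b2, each = n)
    pr <- softmax_rows(z)
    dz <- (pr - tmat) / n
    g_w2 <- t(dz) %*% h
    g_b2 <- colSums(dz)
    dh <- (dz %*% w2) * (1 - h * h)
    g_w1 <- t(dh) %*% inputs
    g_b1 <- colSums(dh)
    g <- c(as.vector(t(g_w1)), as.vector(t(g_w2)), g_b1, g_b2)
    if (algo$algo == "adam") {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      delta <- -algo$lr * (m / (1 - beta1^epoch)) /
        (sqrt(v / (1 - beta2^epoch)) + eps)
    } else if (algo$algo == "gdm") {
      m <- 0.9 * m + g
      delta <- -algo$lr * m
    } else {  # resilient backprop: sign-based adaptive steps
      same <- sign(g) == sign(g_prev) & g != 0 & g_prev != 0
      step <- pmin(pmax(ifelse(same, step * 1.2, step * 0.5), 1e-6), 1)
      delta <- -sign(g) * step
      g_prev <- g
    }
    flat <- c(as.vector(t(w1)), as.vector(t(w2)), b1, b2) + delta
    w1 <- matrix(flat[1:12], 3, 4, byrow = TRUE)
    w2 <- matrix(flat[13:24], 4, 3, byrow = TRUE)
    b1 <- flat[25:27]; b2 <- flat[28:31]
    if (epoch %% check_every == 0L) {
      acts <- max.col(z, ties.method = "first")
      if (mean(acts != targets) < algo$stop_error) break
    }
  }
  flat
}

#' Train one network to criterion
#'
#' Trains a network on 1000 noisy trials under the given rule set with a
#' full-batch Adam optimizer on softmax cross-entropy, then accepts it only
#' if its overall error rate (fraction of trials where the selected action
#' differs from the target) on a fresh held-out 1000-trial batch is below
#' `acceptance_threshold`.  Initialization is i.i.d. uniform on \[-1, 1\]
#' unless `init` is given (retraining starts from those parameters).
#'
#' @param rule rule set to train on.
#' @param seed integer seed controlling initialization and the training /
#'   held-out batches.
#' @param init optional `network_params` to start from (retraining).
#' @param n_train,n_eval training and held-out batch sizes (default 1000).
#' @param acceptance_threshold maximum held-out error rate (default 0.05).
#' @param noise_sd input noise, as at test time (default 0.2).
#' @param max_epochs optimizer budget per attempt.
#' @param algo optional list (`algo`, `lr`, `stop_error`) fixing the
#'   training configuration; by default one is drawn at random per attempt,
#'   emulating training with one of several randomly selected algorithms.
#' @param network_id identifier stored in the result.
#' @return A `network_params` on success, or `NULL` if the criterion was not
#'   reached within the budget (caller retries with a new seed).
#' @export
train_network <- function(rule = c("aversion_resistant", "aversion_sensitive"),
                          seed = 1L, init = NULL, n_train = 1000L,
                          n_eval = 1000L, acceptance_threshold = 0.05,
                          noise_sd = 0.2, max_epochs = 3000L,
                          algo = NULL, network_id = NULL) {
  rule <- match.arg(rule)
  train_batch <- generate_trials(n_train, rule = rule,
                                 seed = derive_seed(seed, "train-batch"),
                                 noise_sd = noise_sd)
  flat0 <- if (is.null(init)) {
    withr::with_seed(derive_seed(seed, "init"), runif(31, -1, 1))
  } else {
    flatten_params(init)
  }
  if (is.null(algo)) algo <- draw_train_algo(derive_seed(seed, "algo"))
  flat <- optimizer_fit(flat0, train_batch$noisy_inputs, train_batch$targets,
                        algo = algo, max_epochs = max_epochs)
  label <- if (!is.null(init)) "retrained" else rule
  if (is.null(network_id)) {
    network_id <- if (!is.null(init)) init$network_id else
      paste0(substr(rule, 10, 12), "-", seed)
  }
  net <- unflatten_params(flat)
  net$rule_label <- label
  net$network_id <- network_id
  net$seed <- as.integer(seed %% .Machine$integer.max)
  class(net) <- "network_params"
  eval_batch <- generate_trials(n_eval, rule = rule,
                                seed = derive_seed(seed, "heldout-batch"),
                                noise_sd = noise_sd)
  if (evaluate_network(net, eval_batch)$error_rate < acceptance_threshold) {
    net
  } else {
    NULL
  }
}

# Retry wrapper: keeps drawing attempt sub-seeds until a network is accepted.
train_accepted <- function(rule, master_seed, id_label, init = NULL,
                           max_attempts = 25L, ...) {
  for (attempt in seq_len(max_attempts)) {
    seed <- derive_seed(master_seed, "train", id_label, attempt)
    net <- train_network(rule = rule, seed = seed, init = init,
                         network_id = id_label, ...)
    if (!is.null(net)) {
      attr(net, "attempts") <- attempt
      return(net)
    }
  }
  stop("training budget exhausted for network ", id_label, call. = FALSE)
}

#' Construct a population object
#'
#' @param networks list of `network_params`.
#' @param rule_label population label.
#' @param acceptance_threshold the training criterion its members met.
#' @return An object of class `population`.
#' @export
population <- function(networks, rule_label,
                       acceptance_threshold = 0.05) {
  structure(list(networks = networks, rule_label = rule_label,
                 acceptance_threshold = acceptance_threshold),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", length(x$networks), " networks [", x$rule_label,
      "], trained to <", 100 * x$acceptance_threshold, "% error\n", sep = "")
  invisible(x)
}

#' @export
length.population <- function(x) length(x$networks)

#' Build matched aversion-resistant, aversion-sensitive and retrained populations
#'
#' Trains `n_per_rule` networks to criterion under each rule set, then
#' retrains each accepted aversion-resistant network on the
#' aversion-sensitive rules (starting from its trained parameters) to
#' produce the fully retrained population.  Retrained networks keep the
#' `network_id` of their aversion-resistant parent, so treatment comparisons
#' can pair the two versions of the same initialization.
#'
#' @param n_per_rule networks per population (>= 1).
#' @param master_seed master seed; identical seeds give bit-identical
#'   populations.
#' @param ... further arguments passed to [train_network()]
#'   (e.g. `acceptance_threshold`, `noise_sd`).
#' @return A list with elements `ar`, `as`, `retrained`, each a `population`.
#' @export
build_populations <- function(n_per_rule, master_seed = 1L, ...) {
  n_per_rule <- as.integer(n_per_rule)
  stopifnot(n_per_rule >= 1L)
  ids <- sprintf("%04d", seq_len(n_per_rule))
  ar <- lapply(ids, function(i) {
    train_accepted("aversion_resistant", master_seed, paste0("ar-", i), ...)
  })
  as_ <- lapply(ids, function(i) {
    train_accepted("aversion_sensitive", master_seed, paste0("as-", i), ...)
  })
  re <- lapply(seq_along(ar), function(k) {
    train_accepted("aversion_sensitive", master_seed,
                   paste0("re-", ids[k]), init = ar[[k]], ...)
  })
  # retrained networks inherit the parent's id for lineage pairing
  for (k in seq_along(re)) re[[k]]$network_id <- ar[[k]]$network_id
  list(ar = population(ar, "aversion_resistant"),
       as = population(as_, "aversion_sensitive"),
       retrained = population(re, "retrained"))
}
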