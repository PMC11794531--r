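# Shared fixtures, all built in code.

# Network with all 31 parameters zero.
zero_net <- function(id = "zero") {
  network_params(matrix(0, 3, 4), matrix(0, 4, 3), rep(0, 3), rep(0, 4),
                 network_id = id)
}

# Network from a flat 31-vector.
net_from_flat <- function(flat, id = "net", rule = "aversion_resistant") {
  p <- unflatten_params(flat)
  p$network_id <- id
  p$rule_label <- rule
  p
}

# Random network, parameters i.i.d. uniform on [-s, s].
random_net <- function(seed, s = 2, id = paste0("rnd-", seed)) {
  net_from_flat(withr::with_seed(seed, runif(31, -s, s)), id = id)
}

# A hand-crafted network that performs the aversion-sensitive rules
# perfectly on noiseless inputs.  Node roles are canonical by construction:
# node 1 detects danger (escape), node 2 safe food (eat), node 3 safe
# alcohol (drink); "wait" wins when all nodes are off.
perfect_as_net <- function(id = "perfect-as") {
  w1 <- rbind(c(20, 0, 0, 0),     # danger
              c(0, 20, 0, -20),   # food, suppressed by risk
              c(0, 0, 20, -20))   # alcohol, suppressed by risk
  b1 <- c(-10, -10, -10)
  w2 <- rbind(c(50, 0, 0),        # escape <- node 1
              c(0, 40, 0),        # eat    <- node 2
              c(0, 0, 30),        # drink  <- node 3
              c(0, 0, 0))         # wait: baseline
  b2 <- c(0, 0, 0, 20)            # wait wins when all nodes near -1
  # with all nodes at -1: z = (-50, -40, -30, 20) -> wait
  network_params(w1, w2, b1, b2, rule_label = "aversion_sensitive",
                 network_id = id)
}

# Noiseless, exactly balanced batch: m trials of each of the six types.
balanced_batch <- function(m = 50, rule = "aversion_sensitive",
                           noise_sd = 0) {
  tt <- trial_types()
  type <- rep(1:6, each = m)
  cues <- as.matrix(tt[type, c("danger", "food", "alcohol", "risk")])
  dimnames(cues) <- list(NULL, c("danger", "food", "alcohol", "risk"))
  targets <- if (rule == "aversion_resistant") tt$target_ar else tt$target_as
  structure(list(n = 6L * m, cue_matrix = cues, noisy_inputs = cues,
                 trial_type = type, targets = targets[type], rule = rule,
                 seed = NA_integer_, noise_sd = noise_sd),
            class = "trial_batch")
}

# Independent entropy computation used by the MI brute-force oracle.
oracle_entropy <- function(x) {
  tab <- table(x)
  p <- as.numeric(tab) / sum(tab)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# Independent MI route: H(X) + H(Y) - H(X, Y).
oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) -
    oracle_entropy(paste(x, y, sep = "|"))
}

# O(n^2)-style KS oracle: evaluate both ECDFs at every pooled point.
oracle_ks <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Small trained populations, computed once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

small_trained_pops <- function() {
  if (is.null(.fixture_env$pops)) {
    .fixture_env$pops <- build_populations(3, master_seed = 20260925)
  }
  .fixture_env$pops
}
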