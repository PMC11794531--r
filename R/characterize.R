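# ---- information theory ---------------------------------------------------

#' Plug-in mutual information (bits)
#'
#' Empirical-frequency (plug-in) estimate of `I(X; Y) = sum p(x,y)
#' log2(p(x,y) / (p(x) p(y)))` from two equal-length discrete sample
#' vectors.  Nonnegative and symmetric in its arguments.
#'
#' @param x,y discrete sample vectors (any type usable as factor levels).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("samples must be nonempty", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("samples must have equal length", call. = FALSE)
  }
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  ratio <- joint / outer(px, py)
  sum(joint[nz] * log2(ratio[nz]))
}

# Shannon entropy (bits) of a discrete sample.
plugin_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Discretize a continuous sample into four equal-count bins
#'
#' Rank-based quartile split: ties are assigned to the lower bin and any
#' remainder trials go to the earliest bins, so bin counts are equal to
#' within one (exactly, absent ties).
#'
#' @param x numeric vector.
#' @param n_bins number of bins (default 4).
#' @return Integer bin labels in `1..n_bins`.
#' @export
equal_count_bins <- function(x, n_bins = 4L) {
  n <- length(x)
  r <- rank(x, ties.method = "min")
  base <- n %/% n_bins
  sizes <- rep(base, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  cuts <- cumsum(sizes)
  findInterval(r, c(1, cuts[-n_bins] + 1)) # bin k iff rank <= cuts[k]
}

# Encode a cue matrix (n x 4 binary) into joint pattern symbols, optionally
# excluding one cue column.
cue_symbols <- function(cues, exclude = NULL) {
  keep <- setdiff(seq_len(ncol(cues)), exclude)
  drop(cues[, keep, drop = FALSE] %*% 2^(seq_along(keep) - 1))
}

#' Encoding profile of one processing node
#'
#' Normalized mutual-information encoding of the four cues and four actions
#' by a node's activity over test trials.  Activity is discretized into four
#' equal-count bins.  Input encoding for cue `j` is the interaction-corrected
#' `[I(X; all four cues jointly) - I(X; the other three cues jointly)] /
#' H(X)`; output encoding for action `j` is `I(X; action == j) / H(X)`,
#' using the one-hot indicator of the selected action (actions are mutually
#' exclusive).  The binary pre-noise cue states are used, never the noisy
#' inputs.
#'
#' @param node_activity numeric vector of the node's tanh activity per trial.
#' @param cues binary n x 4 cue matrix.
#' @param actions integer vector of selected actions (1..4).
#' @return List of class `encoding_profile`: `input_encoding` (length 4,
#'   may be slightly negative from plug-in bias), `output_encoding` (length
#'   4, in \[0, 1\]), `node_entropy` (bits), `degenerate` (TRUE when the
#'   activity is constant, in which case all encodings are 0).
#' @export
encode_node <- function(node_activity, cues, actions) {
  stopifnot(length(node_activity) == nrow(cues),
            length(actions) == nrow(cues))
  cue_nm <- cue_labels()
  act_nm <- action_labels()
  if (length(unique(node_activity)) == 1L) {
    zero <- stats::setNames(numeric(4), cue_nm)
    return(structure(list(input_encoding = zero,
                          output_encoding = stats::setNames(numeric(4), act_nm),
                          node_entropy = 0, degenerate = TRUE),
                     class = "encoding_profile"))
  }
  bins <- equal_count_bins(node_activity)
  hx <- plugin_entropy(bins)
  i_all <- mutual_information(bins, cue_symbols(cues))
  input_enc <- vapply(1:4, function(j) {
    (i_all - mutual_information(bins, cue_symbols(cues, exclude = j))) / hx
  }, numeric(1))
  output_enc <- vapply(1:4, function(j) {
    mutual_information(bins, as.integer(actions == j)) / hx
  }, numeric(1))
  structure(list(input_encoding = stats::setNames(input_enc, cue_nm),
                 output_encoding = stats::setNames(output_enc, act_nm),
                 node_entropy = hx, degenerate = FALSE),
            class = "encoding_profile")
}

# 8-column encoding matrix (3 rows, one per node) for one network.
network_encoding <- function(params, batch) {
  fb <- forward_batch(params, batch$noisy_inputs)
  t(vapply(1:3, function(i) {
    pr <- encode_node(fb$hidden[, i], batch$cue_matrix, fb$actions)
    c(pr$input_encoding, pr$output_encoding)
  }, numeric(8)))
}

#' Encoding table for a population
#'
#' @param pop a `population`.
#' @param batch the shared test batch.
#' @return A data frame: `network_id`, `node`, then the 8 normalized
#'   encodings (`in_danger`..`in_risk`, `out_escape`..`out_wait`).
#' @export
encoding_table <- function(pop, batch) {
  rows <- lapply(pop$networks, function(p) {
    enc <- network_encoding(p, batch)
    colnames(enc) <- c(paste0("in_", cue_labels()),
                       paste0("out_", action_labels()))
    data.frame(network_id = p$network_id, node = 1:3, enc)
  })
  do.call(rbind, rows)
}

# ---- functional node relabeling ------------------------------------------

# Apply a hidden-node permutation perm (new position l <- old node perm[l])
# to a network; the input-output function is unchanged.
permute_hidden <- function(params, perm) {
  params$w1 <- params$w1[perm, , drop = FALSE]
  params$b1 <- params$b1[perm]
  params$w2 <- params$w2[, perm, drop = FALSE]
  params
}

#' Relabel processing nodes by functional role
#'
#' Trained networks assign functional roles to hidden nodes in arbitrary
#' order, so nodes are renumbered before population comparisons.  The eight
#' encoding values of every node of every network in the population are
#' reduced to two principal-component scores; k-means (3 clusters, 10
#' restarts, seeded) clusters the scores; each network's three nodes are
#' then assigned bijectively to the three clusters by the permutation
#' minimizing summed distance to the cluster centroids in PC space.
#' Clusters are labeled by mean output encodings: highest escape encoding
#' -> node 1; of the remaining two, highest eat encoding -> node 2; the
#' remaining cluster -> node 3.  Weight rows/columns and biases are permuted
#' consistently, so no network's input-output function changes.
#'
#' @param pop a `population`.
#' @param batch the shared test batch used for the encoding profiles.
#' @param seed seed for the k-means restarts.
#' @return The relabeled `population`, with attribute `"permutations"`
#'   (list of the applied per-network permutations).
#' @export
relabel_nodes <- function(pop, batch, seed = 1L) {
  stopifnot(inherits(pop, "population"))
  encs <- lapply(pop$networks, network_encoding, batch = batch)
  all_enc <- do.call(rbind, encs)          # (3 * N) x 8
  pca <- prcomp(all_enc, center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1:2, drop = FALSE]
  km <- withr::with_seed(seed, kmeans(scores, centers = 3L, nstart = 10L))
  if (length(unique(km$cluster)) < 3L) {
    stop("k-means failed to find 3 nonempty clusters; reseed", call. = FALSE)
  }
  # label clusters from mean output encodings of their member nodes
  esc <- tapply(all_enc[, 5], km$cluster, mean)    # out_escape
  eat <- tapply(all_enc[, 6], km$cluster, mean)    # out_eat
  node1 <- as.integer(names(which.max(esc)))
  rest <- setdiff(1:3, node1)
  node2 <- rest[which.max(eat[as.character(rest)])]
  node3 <- setdiff(rest, node2)
  cluster_of_label <- c(node1, node2, node3)   # label l -> cluster id
  perms <- permutations3()
  out <- pop
  applied <- vector("list", length(pop$networks))
  for (m in seq_along(pop$networks)) {
    sc <- scores[(3 * (m - 1) + 1):(3 * m), , drop = FALSE]
    d2 <- outer(seq_len(3), seq_len(3), Vectorize(function(i, k) {
      sum((sc[i, ] - km$centers[k, ])^2)
    }))
    # choose the node->cluster bijection with minimum total distance
    costs <- apply(perms, 1L, function(pm) sum(d2[cbind(pm, 1:3)]))
    assign_ <- perms[which.min(costs), ]     # cluster k served by node assign_[k]
    perm <- assign_[cluster_of_label]        # new label l <- old node
    out$networks[[m]] <- permute_hidden(pop$networks[[m]], perm)
    applied[[m]] <- perm
  }
  attr(out, "permutations") <- applied
  out
}

# The 6 permutations of 1:3.
permutations3 <- function() {
  matrix(c(1L, 2L, 3L,  1L, 3L, 2L,  2L, 1L, 3L,
           2L, 3L, 1L,  3L, 1L, 2L,  3L, 2L, 1L),
         ncol = 3, byrow = TRUE)
}

# ---- silencing -------------------------------------------------------------

#' Silencing experiment over a population
#'
#' Evaluates every network with each processing node silenced in turn (and
#' unsilenced), reporting per-trial-type correct rates.  Run on a relabeled
#' population so node indices are functional roles.
#'
#' @param pop a `population` (relabeled).
#' @param batch evaluation batch.
#' @return A data frame: `network_id`, `silenced` (0 = none, 1..3),
#'   `type1`..`type6` correct rates, plus `ar_drink_rate` and
#'   `side_effect_rate`.
#' @export
silencing_experiment <- function(pop, batch) {
  rows <- lapply(pop$networks, function(p) {
    do.call(rbind, lapply(0:3, function(s) {
      m <- evaluate_network(p, batch, silenced = if (s == 0L) NULL else s)
      data.frame(network_id = p$network_id, silenced = s,
                 t(m$per_scenario_correct),
                 ar_drink_rate = m$ar_drink_rate,
                 side_effect_rate = m$side_effect_rate)
    }))
  })
  do.call(rbind, rows)
}

# ---- population comparison -------------------------------------------------

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute difference between the two empirical CDFs; values in
#' \[0, 1\], larger meaning more different distributions.
#'
#' @param a,b nonempty numeric samples.
#' @return The KS statistic.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("samples must be nonempty", call. = FALSE)
  }
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Mean processing-node activities per trial type
#'
#' `A[j, k]`: the average tanh activity of processing node `j` over the test
#' trials of type `k`.
#'
#' @param params a `network_params`.
#' @param batch the test batch.
#' @return A 3 x 6 numeric matrix (nodes x trial types).
#' @export
mean_activities <- function(params, batch) {
  h <- forward_batch(params, batch$noisy_inputs)$hidden
  A <- vapply(1:6, function(k) {
    idx <- batch$trial_type == k
    colMeans(h[idx, , drop = FALSE])
  }, numeric(3))
  dimnames(A) <- list(paste0("node", 1:3), paste0("type", 1:6))
  A
}

# N x 18 matrix of mean activities for a population (column order: node
# fastest within trial type).
activity_matrix <- function(pop, batch) {
  t(vapply(pop$networks, function(p) as.vector(mean_activities(p, batch)),
           numeric(18)))
}

activity_names <- function() {
  paste0("A_node", rep(1:3, 6), "_type", rep(1:6, each = 3))
}

#' Compare aversion-resistant and aversion-sensitive populations
#'
#' Computes, for each of the 31 parameters and each of the 18 (node, trial
#' type) mean activities, the KS statistic between the two populations'
#' distributions, and ranks both predictor families by descending KS.
#' Weight parameters (flat indices 1..24) are compared on absolute values,
#' collapsing excitatory and inhibitory connections; biases (25..31) are
#' compared signed.  Both populations should be relabeled first.
#'
#' @param pop_ar,pop_as the two populations.
#' @param batch the shared test batch (for the activities).
#' @param abs_params flat indices compared on absolute values
#'   (default 1..24, config-overridable).
#' @return List of class `population_comparison`: `param_ks` (named length
#'   31), `activity_ks` (3 x 6 matrix), `param_ranking` and
#'   `activity_ranking` (index vectors, descending KS), `abs_params`.
#' @export
compare_populations <- function(pop_ar, pop_as, batch, abs_params = 1:24) {
  flat_ar <- t(vapply(pop_ar$networks, flatten_params, numeric(31)))
  flat_as <- t(vapply(pop_as$networks, flatten_params, numeric(31)))
  param_ks <- vapply(1:31, function(j) {
    a <- flat_ar[, j]; b <- flat_as[, j]
    if (j %in% abs_params) ks_statistic(abs(a), abs(b)) else ks_statistic(a, b)
  }, numeric(1))
  names(param_ks) <- param_names()
  act_ar <- activity_matrix(pop_ar, batch)
  act_as <- activity_matrix(pop_as, batch)
  act_ks <- vapply(1:18, function(q) ks_statistic(act_ar[, q], act_as[, q]),
                   numeric(1))
  names(act_ks) <- activity_names()
  activity_ks <- matrix(act_ks, 3, 6,
                        dimnames = list(paste0("node", 1:3),
                                        paste0("type", 1:6)))
  structure(list(param_ks = param_ks,
                 activity_ks = activity_ks,
                 param_ranking = order(param_ks, decreasing = TRUE),
                 activity_ranking = order(act_ks, decreasing = TRUE),
                 abs_params = abs_params),
            class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  top <- x$param_ranking[1:3]
  cat("<population_comparison>\n  top parameters by KS: ",
      paste0(names(x$param_ks)[top], " (",
             format(x$param_ks[top], digits = 3), ")", collapse = ", "),
      "\n  top activity by KS: ",
      activity_names()[x$activity_ranking[1]], "\n", sep = "")
  invisible(x)
}
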