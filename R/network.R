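#' netmod: network modification treatments for model neural circuits
#'
#' Tools to build populations of small feedforward networks that perform a
#' four-cue / four-action behavioral task with either aversion-resistant or
#' aversion-sensitive alcohol-drinking rules, to characterize them with
#' standard systems-neuroscience analyses (silencing, mutual-information
#' encoding, Kolmogorov-Smirnov population comparison), and to "treat" the
#' aversion-resistant networks by parameter modification -- full retraining,
#' exhaustive single- and two-parameter random search, and leave-one-out
#' partial-least-squares prediction of effective modifications.
#'
#' @docType package
#' @name netmod-package
#' @aliases netmod
#' @importFrom stats rnorm runif prcomp kmeans ks.test sd median quantile
#' @importFrom utils write.csv read.csv modifyList
"_PACKAGE"

# Action coding used throughout: 1 = escape, 2 = eat, 3 = drink, 4 = wait.
# Ties in the output argmax are broken toward the lowest action index.

#' Action labels
#'
#' The four possible behavioral outputs, in the index order used everywhere
#' in the package (the output layer's node order).
#'
#' @return Character vector `c("escape", "eat", "drink", "wait")`.
#' @export
action_labels <- function() c("escape", "eat", "drink", "wait")

#' Cue labels
#'
#' The four binary input cues, in input-node order.
#'
#' @return Character vector `c("danger", "food", "alcohol", "risk")`.
#' @export
cue_labels <- function() c("danger", "food", "alcohol", "risk")

#' Construct a network parameter set
#'
#' A model organism is a 4-3-4 feedforward network: four binary cue inputs,
#' three nonlinear "processing" (hidden) nodes, and four softmax output nodes
#' whose argmax is the selected action.  The 31 parameters are the 12
#' input-to-hidden weights `w1`, the 12 hidden-to-output weights `w2`, the 3
#' hidden biases `b1` and the 4 output biases `b2`.
#'
#' @param w1 3x4 numeric matrix; `w1[i, j]` is the weight from input `j` to
#'   processing node `i`.
#' @param w2 4x3 numeric matrix; `w2[i, j]` is the weight from processing
#'   node `j` to output node `i`.
#' @param b1 length-3 numeric; processing-node biases.
#' @param b2 length-4 numeric; output-node biases.
#' @param rule_label one of `"aversion_resistant"`, `"aversion_sensitive"`,
#'   `"retrained"`.
#' @param network_id opaque identifier string.
#' @param seed integer seed recorded for provenance (not used here).
#' @return An object of class `network_params`.
#' @export
network_params <- function(w1, w2, b1, b2,
                           rule_label = c("aversion_resistant",
                                          "aversion_sensitive",
                                          "retrained"),
                           network_id = "net", seed = NA_integer_) {
  rule_label <- match.arg(rule_label)
  w1 <- matrix(as.numeric(w1), 3, 4)
  w2 <- matrix(as.numeric(w2), 4, 3)
  b1 <- as.numeric(b1)
  b2 <- as.numeric(b2)
  stopifnot(length(b1) == 3, length(b2) == 4)
  if (!all(is.finite(w1)) || !all(is.finite(w2)) ||
      !all(is.finite(b1)) || !all(is.finite(b2))) {
    stop("network parameters must be finite", call. = FALSE)
  }
  structure(list(w1 = w1, w2 = w2, b1 = b1, b2 = b2,
                 rule_label = rule_label,
                 network_id = as.character(network_id),
                 seed = as.integer(seed)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> ", x$network_id, " [", x$rule_label, "]\n", sep = "")
  cat("  4-3-4 feedforward network, 31 parameters\n")
  cat("  CoR3 (w1[3,4], flat index 12):", format(x$w1[3, 4], digits = 4), "\n")
  invisible(x)
}

#' Flatten network parameters to the canonical 31-vector
#'
#' The canonical flat ordering is: entries 1-12 = `w1` row-major by
#' processing node (so entry 12 is `w1[3, 4]`, the consumption-risk input to
#' processing node 3, "CoR3"); 13-24 = `w2` row-major by output node;
#' 25-27 = `b1`; 28-31 = `b2`.
#'
#' @param params a `network_params` object.
#' @return Numeric vector of length 31.
#' @seealso [unflatten_params()]
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "network_params"))
  c(as.vector(t(params$w1)), as.vector(t(params$w2)), params$b1, params$b2)
}

#' Rebuild network parameters from a flat 31-vector
#'
#' Inverse of [flatten_params()]; `unflatten_params(flatten_params(p))`
#' reproduces `p` exactly.
#'
#' @param flat numeric vector of length 31.
#' @param template optional `network_params` supplying the metadata
#'   (`rule_label`, `network_id`, `seed`) of the result.
#' @return A `network_params` object.
#' @export
unflatten_params <- function(flat, template = NULL) {
  flat <- as.numeric(flat)
  if (length(flat) != 31L) {
    stop("flat parameter vector must have exactly 31 entries", call. = FALSE)
  }
  args <- list(w1 = matrix(flat[1:12], 3, 4, byrow = TRUE),
               w2 = matrix(flat[13:24], 4, 3, byrow = TRUE),
               b1 = flat[25:27], b2 = flat[28:31])
  if (!is.null(template)) {
    args$rule_label <- template$rule_label
    args$network_id <- template$network_id
    args$seed <- template$seed
  }
  do.call(network_params, args)
}

#' Names of the 31 flat parameters
#'
#' @return Character vector: `w1_1_1` .. `w1_3_4`, `w2_1_1` .. `w2_4_3`,
#'   `b1_1` .. `b1_3`, `b2_1` .. `b2_4`.
#' @export
param_names <- function() {
  c(paste0("w1_", rep(1:3, each = 4), "_", rep(1:4, 3)),
    paste0("w2_", rep(1:4, each = 3), "_", rep(1:3, 4)),
    paste0("b1_", 1:3), paste0("b2_", 1:4))
}

#' Replace selected flat parameters
#'
#' @param params a `network_params` object.
#' @param idx integer indices in 1..31.
#' @param values replacement values, same length as `idx`.
#' @return A modified `network_params`.
#' @export
set_params <- function(params, idx, values) {
  stopifnot(all(idx >= 1), all(idx <= 31), length(idx) == length(values))
  flat <- flatten_params(params)
  flat[idx] <- values
  unflatten_params(flat, template = params)
}

# Numerically stable softmax over the rows of a matrix.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Run the forward pass for one input vector
#'
#' Processing-node activity is `tansig(w1 %*% x + b1)` (tansig is the
#' hyperbolic tangent); output activity is `softmax(w2 %*% h + b2)`; the
#' action is the output node with the highest activity, ties broken toward
#' the lowest action index.  Silencing forces a processing node's activity to
#' exactly 0 before the output layer, modeling ablation.
#'
#' @param params a `network_params` object.
#' @param x_in numeric length-4 input (binary cues plus noise).
#' @param silenced optional processing-node index in 1..3 whose activity is
#'   clamped to 0, or `NULL`.
#' @return A list of class `activity_record` with `x_in`, `x_hidden`
#'   (in (-1, 1)), `x_out` (nonnegative, sums to 1), and `action`
#'   (integer 1..4, see [action_labels()]).
#' @export
forward_pass <- function(params, x_in, silenced = NULL) {
  stopifnot(inherits(params, "network_params"))
  x_in <- as.numeric(x_in)
  if (length(x_in) != 4L || !all(is.finite(x_in))) {
    stop("x_in must be a finite numeric vector of length 4", call. = FALSE)
  }
  if (!is.null(silenced)) {
    silenced <- as.integer(silenced)
    stopifnot(length(silenced) == 1L, silenced %in% 1:3)
  }
  h <- tanh(drop(params$w1 %*% x_in) + params$b1)
  if (!is.null(silenced)) h[silenced] <- 0
  z <- drop(params$w2 %*% h) + params$b2
  out <- drop(softmax_rows(matrix(z, 1L)))
  structure(list(x_in = x_in, x_hidden = h, x_out = out,
                 action = which.max(out)),
            class = "activity_record")
}

# Vectorized forward pass over a batch: inputs n x 4.  Returns hidden
# activities (n x 3), output logits (n x 4) and actions (length n).
forward_batch <- function(params, inputs, silenced = NULL) {
  n <- nrow(inputs)
  h <- tanh(inputs %*% t(params$w1) + rep(params$b1, each = n))
  if (!is.null(silenced)) h[, silenced] <- 0
  z <- h %*% t(params$w2) + rep(params$b2, each = n)
  list(hidden = h, logits = z, actions = max.col(z, ties.method = "first"))
}

#' Serialize a list of networks to JSON
#'
#' Populations are stored as a JSON array of objects with fields
#' `network_id`, `seed`, `rule_label`, `w1` (3x4 nested arrays), `w2` (4x3),
#' `b1`, `b2`.
#'
#' @param networks a `population` or plain list of `network_params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_networks_json <- function(networks, path) {
  nets <- if (inherits(networks, "population")) networks$networks else networks
  obj <- lapply(nets, function(p) {
    list(network_id = p$network_id,
         seed = if (is.na(p$seed)) NULL else p$seed,
         rule_label = p$rule_label,
         w1 = apply(p$w1, 1L, identity, simplify = FALSE),
         w2 = apply(p$w2, 1L, identity, simplify = FALSE),
         b1 = p$b1, b2 = p$b2)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read networks from JSON
#'
#' @param path file written by [write_networks_json()].
#' @return A list of `network_params`.
#' @export
read_networks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(o) {
    network_params(w1 = do.call(rbind, lapply(o$w1, unlist)),
                   w2 = do.call(rbind, lapply(o$w2, unlist)),
                   b1 = unlist(o$b1), b2 = unlist(o$b2),
                   rule_label = o$rule_label, network_id = o$network_id,
                   seed = if (is.null(o$seed)) NA_integer_ else o$seed)
  })
}

#' Export networks as a flat-parameter CSV
#'
#' One row per network: `network_id`, `rule_label`, then the 31 flat
#' parameters as columns `p01`..`p31` (see [flatten_params()] for the
#' ordering; `p12` is CoR3).
#'
#' @inheritParams write_networks_json
#' @return `path`, invisibly.
#' @export
write_networks_csv <- function(networks, path) {
  nets <- if (inherits(networks, "population")) networks$networks else networks
  flat <- t(vapply(nets, flatten_params, numeric(31)))
  colnames(flat) <- sprintf("p%02d", 1:31)
  df <- data.frame(network_id = vapply(nets, `[[`, "", "network_id"),
                   rule_label = vapply(nets, `[[`, "", "rule_label"),
                   flat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
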