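test_that("plug-in mutual information matches hand evaluation and the entropy route", {
  # perfectly coupled fair binary variables: exactly 1 bit
  x <- rep(c(0, 1), each = 50)
  expect_equal(mutual_information(x, x), 1)

  # I(X, X) = H(X) for a uniform four-symbol sample
  x4 <- rep(1:4, 25)
  expect_equal(mutual_information(x4, x4), 2)

  # independent fair binaries: near zero at large n
  xy <- withr::with_seed(1, list(x = rbinom(1e5, 1, 0.5),
                                 y = rbinom(1e5, 1, 0.5)))
  expect_lt(mutual_information(xy$x, xy$y), 0.001)

  # random contingency tables vs the independent H(X)+H(Y)-H(X,Y) route
  for (seed in 1:15) {
    tab <- withr::with_seed(seed, matrix(rpois(12, 8) + 1, 3, 4))
    x <- rep(rep(1:3, 4), as.vector(tab))
    y <- rep(rep(1:4, each = 3), as.vector(tab))
    expect_equal(mutual_information(x, y), oracle_mi(x, y),
                 tolerance = 1e-12)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
  }
  expect_error(mutual_information(numeric(0), numeric(0)), "nonempty")
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("KS statistic matches the pairwise ECDF oracle", {
  expect_equal(ks_statistic(1:10, 1:10), 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_statistic(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  for (seed in 1:10) {
    s <- withr::with_seed(seed, list(a = rnorm(40), b = rnorm(35, 0.5)))
    expect_equal(ks_statistic(s$a, s$b), oracle_ks(s$a, s$b),
                 tolerance = 1e-12)
  }
  expect_error(ks_statistic(numeric(0), 1:3), "nonempty")
})

test_that("equal-count binning balances counts and sends ties low", {
  x <- withr::with_seed(2, rnorm(4000))
  expect_equal(unname(table(equal_count_bins(x))), rep(1000, 4),
               ignore_attr = TRUE)
  # remainder goes to the earliest bins
  x7 <- withr::with_seed(3, rnorm(7))
  expect_equal(sort(unname(table(equal_count_bins(x7)))), c(1, 2, 2, 2),
               ignore_attr = TRUE)
  # tied values share the lower bin
  bins <- equal_count_bins(c(1, 1, 1, 1, 2, 3, 4, 5))
  expect_equal(bins[1:4], rep(1L, 4))
})

test_that("input encoding recovers a danger-detector node exactly", {
  b <- balanced_batch(60)
  act_raw <- ifelse(b$cue_matrix[, "danger"] == 1, 0.9, -0.9)
  actions <- ifelse(b$cue_matrix[, "danger"] == 1, 1L, 4L)
  prof <- encode_node(act_raw, b$cue_matrix, actions)
  # closed form on the balanced design: the binned activity equals the
  # danger indicator, with P(danger) = 1/6.  Excluding danger, the other
  # three cues leave types {danger-only, all-off} (mass 1/3) ambiguous at
  # P = 1/2, so I drops by exactly 1/3 bit.
  h16 <- -(1 / 6) * log2(1 / 6) - (5 / 6) * log2(5 / 6)
  expect_equal(prof$node_entropy, h16)
  expect_equal(unname(prof$input_encoding["danger"]), (1 / 3) / h16)
  expect_equal(unname(prof$input_encoding[c("food", "alcohol", "risk")]),
               rep(0, 3))
  # actions are a deterministic function of the activity
  expect_equal(unname(prof$output_encoding[c("escape", "wait")]), c(1, 1))
  expect_equal(unname(prof$output_encoding[c("eat", "drink")]), c(0, 0))
})

test_that("noise-driven activity encodes nothing; constant activity is flagged", {
  b <- balanced_batch(500)
  act <- withr::with_seed(4, rnorm(b$n))
  actions <- rep(1:4, length.out = b$n)
  prof <- encode_node(act, b$cue_matrix, actions)
  expect_true(all(abs(prof$input_encoding) < 0.01))
  expect_true(all(prof$output_encoding < 0.01))
  expect_false(prof$degenerate)

  flat <- encode_node(rep(0.5, b$n), b$cue_matrix, actions)
  expect_true(flat$degenerate)
  expect_equal(unname(flat$input_encoding), rep(0, 4))
  expect_equal(flat$node_entropy, 0)
})

test_that("relabeling recovers known node permutations and preserves function", {
  base <- perfect_as_net()
  perms <- netmod:::permutations3()
  nets <- lapply(1:12, function(i) {
    jit <- withr::with_seed(200 + i, rnorm(31, sd = 0.3))
    net <- net_from_flat(flatten_params(base) + jit, id = sprintf("s-%02d", i),
                         rule = "aversion_sensitive")
    netmod:::permute_hidden(net, perms[(i - 1) %% 6 + 1, ])
  })
  pop <- population(nets, "aversion_sensitive")
  batch <- generate_trials(900, "aversion_sensitive", seed = 31)
  rel <- relabel_nodes(pop, batch, seed = 7)
  # every network comes back with node 1 = danger/escape, 2 = eat, 3 = drink:
  # the large diagonal w2 blocks of the generator make roles unambiguous
  for (net in rel$networks) {
    expect_gt(net$w2[1, 1], 40)   # escape driven by node 1
    expect_gt(net$w2[2, 2], 30)   # eat by node 2
    expect_gt(net$w2[3, 3], 20)   # drink by node 3
  }
  # relabeling never alters the input-output function
  X <- withr::with_seed(5, matrix(rnorm(40), 10, 4))
  for (i in seq_along(nets)) {
    for (r in 1:10) {
      expect_equal(forward_pass(rel$networks[[i]], X[r, ])$x_out,
                   forward_pass(nets[[i]], X[r, ])$x_out)
    }
  }
  # a canonical population relabels with the identity permutation
  canon <- population(lapply(rel$networks, identity), "aversion_sensitive")
  rel2 <- relabel_nodes(canon, batch, seed = 7)
  for (pm in attr(rel2, "permutations")) expect_identical(pm, 1:3)
})

test_that("silencing a disconnected node leaves behavior unchanged", {
  net <- random_net(17)
  net$w2[, 2] <- 0  # node 2 has no influence on the outputs
  b <- generate_trials(400, "aversion_sensitive", seed = 12)
  expect_equal(evaluate_network(net, b, silenced = 2),
               evaluate_network(net, b))
})

test_that("comparing a population with itself gives all-zero KS", {
  pop <- population(lapply(1:6, random_net), "aversion_resistant")
  b <- generate_trials(300, "aversion_sensitive", seed = 9)
  cmp <- compare_populations(pop, pop, b)
  expect_equal(unname(cmp$param_ks), rep(0, 31))
  expect_equal(as.vector(cmp$activity_ks), rep(0, 18))
})

test_that("weights are compared on absolute values, biases signed", {
  flip <- function(net, i) { net$w1[1, 1] <- i * 1.5; net$b1[1] <- i * 1.5; net }
  pop_pos <- population(lapply(1:8, function(i) flip(random_net(i), +1)), "a")
  pop_neg <- population(lapply(1:8, function(i) flip(random_net(i), -1)), "b")
  b <- generate_trials(200, "aversion_sensitive", seed = 14)
  cmp <- compare_populations(pop_pos, pop_neg, b)
  expect_equal(unname(cmp$param_ks[1]), 0)   # weight: |1.5| vs |-1.5|
  expect_equal(unname(cmp$param_ks[25]), 1)  # bias: 1.5 vs -1.5, signed
})
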