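test_that("forward pass reproduces hand-computed activity values", {
  # all parameters zero: hidden all zero, softmax uniform, escape by tie-break
  rec <- forward_pass(zero_net(), c(0.3, -0.1, 0.7, 0))
  expect_equal(rec$x_hidden, rep(0, 3))
  expect_equal(rec$x_out, rep(0.25, 4))
  expect_identical(rec$action, 1L)

  # single active path: alcohol -> node 3 -> drink
  net <- zero_net()
  net$w1[3, 3] <- 5
  net$w2[3, 3] <- 5
  rec <- forward_pass(net, c(0, 0, 1, 0))
  expect_equal(rec$x_hidden, c(0, 0, tanh(5)))
  expect_equal(rec$x_out, exp(c(0, 0, 5 * tanh(5), 0)) /
                 sum(exp(c(0, 0, 5 * tanh(5), 0))))
  expect_identical(rec$action, 3L)  # drink strictly largest

  # silencing the only active node removes the path entirely
  rec <- forward_pass(net, c(0, 0, 1, 0), silenced = 3)
  expect_equal(rec$x_hidden, rep(0, 3))
  expect_equal(rec$x_out, rep(0.25, 4))
})

test_that("forward pass rejects invalid parameters and inputs", {
  net <- zero_net()
  expect_error(forward_pass(net, c(1, 2, 3)), "length 4")
  expect_error(forward_pass(net, c(1, 2, 3, NA)), "finite")
  bad <- net
  expect_error({bad$w1[1, 1] <- Inf; network_params(bad$w1, bad$w2, bad$b1,
                                                    bad$b2)}, "finite")
})

test_that("softmax outputs are normalized and positive for every input", {
  for (seed in 1:20) {
    net <- random_net(seed, s = 8)
    x <- withr::with_seed(seed + 100, rnorm(4, sd = 2))
    rec <- forward_pass(net, x)
    expect_equal(sum(rec$x_out), 1, tolerance = 1e-12)
    expect_true(all(rec$x_out >= 0))
    expect_true(all(abs(rec$x_hidden) <= 1))  # tanh saturates numerically
  }
})

test_that("flat parameter indexing follows the canonical 31-entry layout", {
  net <- zero_net()
  net$w1[3, 4] <- 7.5
  flat <- flatten_params(net)
  expect_equal(flat[12], 7.5)
  expect_equal(sum(flat != 0), 1)

  p <- unflatten_params(1:31)
  expect_equal(p$w1[1, 1], 1)
  expect_equal(p$w1[3, 4], 12)  # CoR3
  expect_equal(p$w2[1, 1], 13)
  expect_equal(p$b1[1], 25)
  expect_equal(p$b2[4], 31)

  expect_error(unflatten_params(1:30), "31")
})

test_that("flatten/unflatten round-trip is the identity", {
  for (seed in 1:10) {
    net <- random_net(seed)
    back <- unflatten_params(flatten_params(net), template = net)
    expect_identical(flatten_params(back), flatten_params(net))
    expect_identical(back$w1, net$w1)
    expect_identical(back$rule_label, net$rule_label)
  }
})

test_that("silencing an already-silent node changes nothing", {
  net <- random_net(4)
  net$w1[2, ] <- 0   # node 2 activity is tanh(b1[2])
  net$b1[2] <- 0     # ... which is exactly 0
  x <- c(1, 0, 1, 0.4)
  expect_identical(forward_pass(net, x, silenced = 2)$x_out,
                   forward_pass(net, x)$x_out)
})

test_that("hidden activity is monotone in the risk weight when risk is on", {
  net <- random_net(9)
  vals <- seq(-3, 3, length.out = 13)
  h3 <- vapply(vals, function(v) {
    forward_pass(set_params(net, 12, v), c(0, 0, 1, 1))$x_hidden[3]
  }, numeric(1))
  expect_true(all(diff(h3) > 0))  # risk input is +1, so increasing
})

test_that("bulk candidate evaluation agrees exactly with the naive forward pass", {
  batch <- generate_trials(300, "aversion_sensitive", seed = 5)
  for (seed in 1:12) {
    net <- random_net(seed, s = 3)
    pre <- netmod:::net_precompute(net, batch)
    d <- 1 + seed %% 2
    idx <- withr::with_seed(seed, sample(31, d))
    V <- withr::with_seed(seed + 50, matrix(rnorm(4 * d, sd = 6), 4, d))
    fast <- netmod:::candidate_actions(pre, idx, V)
    for (k in 1:4) {
      treated <- set_params(net, idx, V[k, ])
      naive <- netmod:::forward_batch(treated, batch$noisy_inputs)$actions
      expect_identical(fast[, k], naive)
    }
  }
})

test_that("network JSON serialization round-trips", {
  nets <- lapply(1:3, random_net)
  path <- withr::local_tempfile(fileext = ".json")
  write_networks_json(nets, path)
  back <- read_networks_json(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(flatten_params(back[[i]]), flatten_params(nets[[i]]))
    expect_identical(back[[i]]$network_id, nets[[i]]$network_id)
  }
})

test_that("flat CSV export uses the p01..p31 layout", {
  net <- zero_net()
  net$w1[3, 4] <- -2.25
  path <- withr::local_tempfile(fileext = ".csv")
  write_networks_csv(list(net), path)
  df <- read.csv(path, check.names = FALSE)
  expect_identical(colnames(df)[3:33], sprintf("p%02d", 1:31))
  expect_equal(df$p12, -2.25)
})
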