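test_that("remaining-count convention floors toward the sparser side", {
  expect_equal(remaining_count(100, 0), 100L)
  expect_equal(remaining_count(10, 0.33), 6L)
  expect_equal(remaining_count(0, 0.5), 0L)
  expect_error(remaining_count(100, 1), "\\[0, 1\\)")
  expect_error(remaining_count(100, -0.1), "\\[0, 1\\)")
  expect_error(remaining_count(-1, 0.5), "non-negative")
})

test_that("magnitude selection zeroes the smallest weights with
           deterministic ties", {
  # one relevant layer: weights [0.1, -0.05, 0.3, 0.0, -0.2], s = 0.4
  # keeps floor(0.6 * 5) = 3, zeroing 0.0 and -0.05
  w1 <- matrix(c(0.1, -0.05, 0.3, 0.0, -0.2), nrow = 1)
  net <- hand_net(c(5, 1, 1), list(w1, matrix(10)))
  m <- select_mask(net, 0.4, scope = "per_layer")
  expect_equal(as.vector(m[[1]]), c(1, 0, 1, 0, 1))
  # size-1 second layer: floor(0.6 * 1) = 0 weights remain per convention
  expect_equal(as.vector(m[[2]]), 0)
  # s = 0 keeps everything
  m0 <- select_mask(net, 0)
  expect_true(all(unlist(m0) == 1))
  # exact tie: equal magnitudes pruned in (layer, row, col) order
  wt <- matrix(c(0.2, 0.2, 0.2, 0.2), nrow = 2)
  nt <- hand_net(c(2, 2, 1), list(wt, matrix(c(1, 1), nrow = 1)))
  mt <- select_mask(nt, 0.5, scope = "global")  # zero 3 of 6
  expect_equal(sum(unlist(mt)), 3)
  expect_equal(as.vector(mt[[1]]), c(0, 0, 0, 1))  # column-major display
  expect_equal(as.vector(mt[[2]]), c(1, 1))
})

test_that("global selection matches a brute-force magnitude sort", {
  net <- init_params(moth_arch(c(6, 5, 4, 3)), 91)
  N <- count_kernel_weights(net$arch)
  for (s in c(0.2, 0.5, 0.77)) {
    m <- select_mask(net, s, scope = "global")
    n_zero <- N - remaining_count(N, s)
    allw <- abs(unlist(net$weights))
    cutoff <- sort(allw)[n_zero]
    zeroed <- abs(unlist(lapply(seq_along(m), function(l)
      net$weights[[l]][m[[l]] == 0])))
    expect_equal(length(zeroed), n_zero)
    expect_true(all(zeroed <= cutoff))
    expect_equal(sum(unlist(m)), remaining_count(N, s))
  }
})

test_that("per-layer selection applies the remaining convention within
           each layer", {
  net <- init_params(moth_arch(c(6, 5, 4, 3)), 92)
  m <- select_mask(net, 0.6, scope = "per_layer")
  sizes <- vapply(net$weights, length, 0)
  expect_equal(vapply(m, sum, 0),
               as.numeric(remaining_count(sizes, 0.6)))
})

test_that("masks are nested along an increasing schedule", {
  net <- init_params(moth_arch(c(8, 6, 4)), 93)
  m1 <- select_mask(net, 0.5)
  # perturb weights as retraining would, then re-select at higher sparsity
  net2 <- net
  net2$weights <- lapply(apply_masks(net, m1)$weights,
                         function(w) w + 0.01 * sign(w))
  m2 <- select_mask(net2, 0.7, current = m1)
  for (l in seq_along(m1))
    expect_true(all(m2[[l]][m1[[l]] == 0] == 0))
  expect_error(select_mask(net2, 0.3, current = m1), "below")
})

test_that("achieved sparsity counts mask zeros", {
  m <- list(matrix(1, 10, 10))
  expect_equal(achieved_sparsity(m), 0)
  expect_equal(achieved_sparsity(list(matrix(0, 5, 5))), 1)
  m2 <- matrix(0, 10, 10); m2[1:7] <- 1
  expect_equal(achieved_sparsity(list(m2)), 0.93)
})

test_that("masked forward zeroes exactly the masked connections", {
  net <- hand_net(c(1, 1, 1), list(matrix(2), matrix(3)))
  masks <- list(matrix(0), matrix(1))
  expect_equal(masked_forward(net, masks, 5)[1, 1], 0)
  ones <- list(matrix(1), matrix(1))
  expect_equal(masked_forward(net, ones, 5), forward(net, 5))
  zeros <- list(matrix(0), matrix(0))
  expect_equal(masked_forward(net, zeros, 5)[1, 1], 0)
  expect_error(masked_forward(net, list(matrix(1)), 5), "mask count")
  expect_error(masked_forward(net, list(matrix(1, 2, 2), matrix(1)), 5),
               "congruent")
})

test_that("masked training keeps pruned weights bit-exact zero while
           honouring counts", {
  prep <- make_scaled(300, seed = 51)
  net0 <- init_params(moth_arch(c(10, 8, 8, 7)), 4)
  cfg <- train_config(max_epochs = 3, eval_every = 10, seed = 61)
  res0 <- train(net0, prep$data, cfg)
  run <- masked_prune_run(res0$net, prep$data, c(0.3, 0.5, 0.8), cfg)
  N <- count_kernel_weights(net0$arch)
  # exact cardinality at the final level
  expect_equal(sum(unlist(run$masks)), remaining_count(N, 0.8))
  for (l in seq_along(run$masks))
    expect_true(all(run$net$weights[[l]][run$masks[[l]] == 0] == 0))
  # achieved sparsities are non-decreasing and match the convention
  expect_equal(run$records$achieved,
               1 - remaining_count(N, c(0.3, 0.5, 0.8)) / N)
  # nesting across stored levels
  for (i in 1:2)
    for (l in seq_along(run$masks))
      expect_true(all(run$masks_by_level[[i + 1]][[l]][
        run$masks_by_level[[i]][[l]] == 0] == 0))
  # a schedule of [0] behaves as plain training
  plain <- masked_prune_run(res0$net, prep$data, 0, cfg)
  expect_true(all(unlist(plain$masks) == 1))
  direct <- train(res0$net, prep$data, cfg)
  expect_identical(plain$net$weights, direct$net$weights)
})

test_that("manual pruning zeroes n weights each epoch but lets them regrow
           between zeroings", {
  prep <- make_scaled(200, seed = 52)
  net0 <- init_params(moth_arch(c(10, 8, 7)), 5)
  N <- count_kernel_weights(net0$arch)
  cfg <- train_config(max_epochs = 2, eval_every = 5, seed = 62)
  run <- manual_prune_run(net0, prep$data, c(0.4), cfg)
  # immediately after the final zeroing, exactly n entries are zero
  n_zero <- N - remaining_count(N, 0.4)
  expect_equal(sum(unlist(run$net$weights) == 0), n_zero)
  expect_equal(run$records$achieved, n_zero / N, tolerance = 1e-12)

  # regrowth: zero the smallest weights manually, take one gradient epoch,
  # and observe previously zeroed entries move off zero
  m <- select_mask(net0, 0.4)
  zeroed_net <- apply_masks(net0, m)
  step <- train(zeroed_net, prep$data,
                train_config(max_epochs = 1, eval_every = 1000, seed = 63))
  regrown <- unlist(lapply(seq_along(m), function(l)
    step$net$weights[[l]][m[[l]] == 0]))
  expect_true(any(regrown != 0))
})

test_that("manual and masked paradigms select identical zero-sets from
           identical weights", {
  prep <- make_scaled(100, seed = 53)
  net <- init_params(moth_arch(c(10, 6, 7)), 6)
  N <- count_kernel_weights(net$arch)
  s <- 0.5
  m <- select_mask(net, s)
  # lr = 0 manual run: the only effect is the per-epoch re-zeroing
  res <- train(net, prep$data,
               train_config(lr = 0, max_epochs = 1, eval_every = 1000),
               rezero_n = N - remaining_count(N, s))
  for (l in seq_along(m))
    expect_equal(res$net$weights[[l]] == 0, m[[l]] == 0)
})

test_that("schedules must be strictly increasing fractions below one", {
  net <- init_params(moth_arch(c(4, 3, 2)), 7)
  d <- list(inputs = matrix(rnorm(20), 5, 4),
            targets = matrix(rnorm(10), 5, 2))
  cfg <- train_config(max_epochs = 1)
  expect_error(masked_prune_run(net, d, c(0.5, 0.5), cfg), "increasing")
  expect_error(masked_prune_run(net, d, c(0.5, 1.0), cfg), "\\[0, 1\\)")
})
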