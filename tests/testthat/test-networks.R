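test_that("local connection rule joins every in-radius pair at p = 1", {
  coords <- as.matrix(expand.grid(x = seq(100, 500, 100),
                                  y = seq(100, 500, 100)))
  set.seed(1)
  edges <- random_local_connect(coords, radius = 200 * sqrt(2), p = 1)
  d <- as.matrix(dist(coords))
  n_pairs <- sum(d[upper.tri(d)] <= 200 * sqrt(2) + 1e-9)
  expect_equal(nrow(edges), n_pairs)          # one direction per pair
  expect_true(all(edges$pre != edges$post))
  # every edge within the radius, inclusive comparison
  dd <- sqrt(rowSums((coords[edges$pre, ] - coords[edges$post, ])^2))
  expect_true(all(dd <= 200 * sqrt(2) + 1e-9))
})

test_that("interior lattice node has 24 candidate neighbours within 200*sqrt(2)", {
  xs <- seq(100, 1100, 100)
  coords <- as.matrix(expand.grid(x = xs, y = xs))
  centre <- which(coords[, 1] == 600 & coords[, 2] == 600)
  d <- sqrt(rowSums((coords - rep(coords[centre, ], each = nrow(coords)))^2))
  expect_equal(sum(d <= 200 * sqrt(2) + 1e-9) - 1, 24) # 5x5 block minus self
})

test_that("interior degree matches the binomial expectation at p = 0.5", {
  xs <- seq(100, 1100, 100)
  coords <- as.matrix(expand.grid(x = xs, y = xs))
  centre <- which(coords[, 1] == 600 & coords[, 2] == 600)
  set.seed(10)
  degs <- replicate(30, {
    edges <- random_local_connect(coords, radius = 200 * sqrt(2), p = 0.5)
    sum(edges$pre == centre) + sum(edges$post == centre)
  })
  # Binomial(24, 0.5): mean 12, sd 2.45; the mean of 30 draws is within 4 sd
  expect_gt(mean(degs), 12 - 4 * 2.45 / sqrt(30))
  expect_lt(mean(degs), 12 + 4 * 2.45 / sqrt(30))
})

test_that("task 1 network has the documented geometry and orientation", {
  cfg <- pw_config(task = 1)
  set.seed(2)
  net <- build_task1(cfg)
  expect_equal(net$n, 121)
  s_id <- net$stim_patterns[[1]]
  t_id <- net$pattern_targets[[1]]
  f_id <- net$pattern_false[[1]]
  expect_equal(net$coords[s_id, ], c(x = 600, y = 600))
  expect_equal(net$coords[t_id, ], c(x = 600, y = 100))
  expect_setequal(net$coords[f_id, 1] + 1i * net$coords[f_id, 2],
                  c(100 + 600i, 1100 + 600i, 600 + 1100i))
  expect_equal(sum(net$edges$post == s_id), 0)  # S outward only
  expect_equal(sum(net$edges$pre == t_id), 0)   # T inward only
  expect_true(all(net$edges$weight == cfg$task1_weight_init))
  # directed reachability from S to T is enforced by construction
  expect_true(polywave:::reachable(net$edges, s_id, net$n)[t_id])
  # no isolated neurons
  deg <- tabulate(c(net$edges$pre, net$edges$post), nbins = net$n)
  expect_true(all(deg > 0))
})

test_that("task 2 network carries a 3x detour and the quoted roles", {
  cfg <- pw_config(task = 2)
  set.seed(3)
  net <- build_task2(cfg)
  s_id <- net$stim_patterns[[1]]
  t_id <- net$pattern_targets[[1]]
  expect_equal(net$coords[s_id, ], c(x = 100, y = 500))
  expect_equal(net$coords[t_id, ], c(x = 100, y = 100))
  expect_equal(sum(net$edges$post == s_id), 0)
  expect_equal(sum(net$edges$pre == t_id), 0)
  w <- net$edges$weight
  expect_setequal(unique(w), c(cfg$task2_base_weight,
                               3 * cfg$task2_base_weight))
  expect_equal(w[net$detour_edges], rep(3 * cfg$task2_base_weight, 12))
  # detour forms a directed path from S to T
  dt <- net$edges[net$detour_edges, ]
  expect_equal(dt$pre[1], s_id)
  expect_equal(dt$post[12], t_id)
  expect_equal(dt$pre[-1], dt$post[-12])
  # the connection radius admits offsets up to (200, 100) um
  dd <- sqrt(rowSums((net$coords[net$edges$pre, ] -
                        net$coords[net$edges$post, ])^2))
  expect_true(all(dd <= 100 * sqrt(5) + 1e-9))
})

test_that("task 3 network implements the XOR wiring rules", {
  set.seed(4)
  net <- build_task3()
  expect_equal(net$n, 126)
  mids <- which(net$roles == "middle")
  expect_length(mids, 120)
  e <- net$edges
  for (m in mids) {
    expect_equal(sum(e$post == m), 2)  # strong + weak input
    expect_equal(sum(e$pre == m), 1)   # one output projection
    w_in <- sort(e$weight[e$post == m])
    expect_equal(w_in, c(0.1, 0.2))
    expect_equal(e$weight[e$pre == m], 0.2)
    # the strong input comes from the nearest stimulated neuron
    strong_pre <- e$pre[e$post == m & e$weight == 0.2]
    d_in <- abs(net$coords[1:4, 1] - net$coords[m, 1])
    expect_equal(strong_pre, which.min(d_in))
  }
  # stimulus patterns map to rewarded outputs F, T, T, F
  t_id <- which(net$roles == "target")
  f_id <- which(net$roles == "false_target")
  expect_equal(unlist(net$pattern_targets), c(f_id, t_id, t_id, f_id))
  # inputs project only out, outputs only in
  expect_equal(sum(e$post %in% 1:4), 0)
  expect_equal(sum(e$pre %in% c(t_id, f_id)), 0)
})

test_that("orientation and isolation invariants hold across seeds", {
  cfg1 <- pw_config(task = 1)
  cfg2 <- pw_config(task = 2)
  for (s in 1:5) {
    set.seed(s)
    for (net in list(build_task1(cfg1), build_task2(cfg2))) {
      stim <- which(net$roles == "stimulated")
      tf <- which(net$roles %in% c("target", "false_target"))
      expect_equal(sum(net$edges$post %in% stim), 0)
      expect_equal(sum(net$edges$pre %in% tf), 0)
      deg <- tabulate(c(net$edges$pre, net$edges$post), nbins = net$n)
      expect_true(all(deg > 0))
    }
  }
})
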