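test_that("Pearson connectivity reproduces hand-computed cases", {
  tax <- c(0, 0.4, 0.8)
  m <- rbind(A = c(1, 2, 3), B = c(1, 2, 4))
  conn <- pearson_connectivity(m, time_axis = tax)
  expect_equal(conn["A", "B"], 9 / sqrt(84), tolerance = 1e-12)

  m2 <- rbind(A = c(1, 2, 3), B = c(1, 2, 3))
  expect_equal(pearson_connectivity(m2, time_axis = tax)["A", "B"], 1)

  m3 <- rbind(A = c(1, 2, 3), B = -c(1, 2, 3))
  expect_equal(pearson_connectivity(m3, time_axis = tax)["A", "B"], -1)
})

test_that("connectivity matrices are symmetric with unit diagonal", {
  sim <- small_sim()
  blocks <- make_trial_blocks(
    bandpass(select_trials(sim$recording, tasks = c("left", "right")), 3, 30),
    20
  )
  for (w in c("task", "rest")) {
    conn <- pearson_connectivity(blocks[1, ], w)
    expect_equal(unclass(conn), t(unclass(conn)), ignore_attr = TRUE)
    expect_equal(unname(diag(conn)), rep(1, 19))
    expect_true(all(abs(conn) <= 1 + 1e-12))
    expect_identical(attr(conn, "window_role"), w)
  }
})

test_that("zero-variance channels get zero edges and a warning, not NaN", {
  tax <- seq(0, 0.95, by = 0.05)
  m <- rbind(A = sin(1:20), B = rep(2, 20), C = cos(1:20))
  expect_warning(conn <- pearson_connectivity(m, time_axis = tax), "B")
  expect_equal(conn["B", "A"], 0)
  expect_equal(conn["B", "C"], 0)
  expect_false(anyNA(conn))
})

test_that("node degree matches the brute-force double loop exactly", {
  m3 <- matrix(c(1, 0.2, 0.5,
                 0.2, 1, 0.1,
                 0.5, 0.1, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(node_degree(m3, "a"), c(a = 0.7))

  zero <- diag(3)
  dimnames(zero) <- dimnames(m3)
  expect_equal(unname(node_degree(zero)), rep(0, 3))

  set.seed(21)
  m <- random_symmetric(19)
  deg <- node_degree(m)
  for (i in 1:19) {
    expect_equal(unname(deg[i]), brute_node_degree(m, i))
  }
  expect_error(node_degree(m, "Xz"), "unknown node")
})

test_that("regional and cross-hemisphere degrees follow the edge sums", {
  labs <- c("a", "b", "c")
  m <- matrix(c(1, 0.1, 0.2,
                0.1, 1, 0.3,
                0.2, 0.3, 1), 3, 3, dimnames = list(labs, labs))
  expect_equal(region_degree(m, labs), 0.6)
  expect_error(region_degree(m, "a"), "at least 2")

  montage <- mi_montage()
  z <- diag(19)
  dimnames(z) <- list(montage$channels, montage$channels)
  z["C3", "C4"] <- z["C4", "C3"] <- 0.8
  expect_equal(ex_degree(z, montage), 0.8)
  expect_equal(region_degree(z, montage$left_set), 0)
  expect_equal(region_degree(z, montage$right_set), 0)
})

test_that("partition identity: LnL + LnR + EX + medial pairs = total", {
  montage <- mi_montage()
  set.seed(33)
  for (rep in 1:5) {
    m <- random_symmetric(19)
    lnl <- region_degree(m, montage$left_set)
    lnr <- region_degree(m, montage$right_set)
    ex <- ex_degree(m, montage)
    medial_pairs <- sum(m[montage$medial_set, ]) -
      sum(diag(m[montage$medial_set, montage$medial_set, drop = FALSE])) -
      region_degree(m, montage$medial_set)
    total <- (sum(m) - sum(diag(m))) / 2
    expect_equal(lnl + lnr + ex + medial_pairs, total, tolerance = 1e-12)
  }
})

test_that("binarization keeps >= threshold edges with signed comparison", {
  labs <- c("a", "b", "c")
  m <- matrix(c(1, 0.59, 0.60,
                0.59, 1, 0.61,
                0.60, 0.61, 1), 3, 3, dimnames = list(labs, labs))
  g <- binarize(m, 0.6)
  expect_equal(g["a", "b"], 0) # 0.59 < 0.6
  expect_equal(g["a", "c"], 1) # 0.60 >= 0.6 (boundary included)
  expect_equal(g["b", "c"], 1)
  expect_equal(unname(diag(g)), rep(0, 3))

  neg <- m
  neg["a", "b"] <- neg["b", "a"] <- -0.9
  expect_equal(binarize(neg, 0.6)["a", "b"], 0) # strong negatives: no edge
  expect_equal(binarize(neg, 0.6, absolute = TRUE)["a", "b"], 1)

  ones <- matrix(1, 19, 19)
  k19 <- binarize(ones, 0.6)
  expect_equal(sum(k19) / 2, choose(19, 2)) # complete graph

  expect_error(binarize(m, 1.5), "threshold")
})

test_that("transitivity matches triangles over connected triples", {
  tri <- matrix(c(0, 1, 1,
                  1, 0, 1,
                  1, 1, 0), 3, 3)
  expect_equal(transitivity_coef(tri), 1)

  path <- matrix(c(0, 1, 0,
                   1, 0, 1,
                   0, 1, 0), 3, 3)
  expect_equal(transitivity_coef(path), 0)

  k4e <- matrix(1, 4, 4) - diag(4)
  k4e[1, 2] <- k4e[2, 1] <- 0 # K4 minus one edge: 2 triangles, 2 open
  expect_equal(transitivity_coef(k4e), 0.75)

  empty <- matrix(0, 5, 5)
  expect_equal(transitivity_coef(empty), 0) # no connected triple -> 0
  expect_error(transitivity_coef(tri[1:2, 1:2]), "3 nodes")
})

test_that("graph metrics agree with enumeration and igraph on random graphs", {
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    adj <- matrix(stats::rbinom(n * n, 1, stats::runif(1, 0.2, 0.8)), n, n)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- 0
    ours <- transitivity_coef(adj)
    expect_identical(ours, brute_transitivity(adj))
    ig <- igraph::transitivity(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"),
      type = "global"
    )
    expect_equal(ours, ifelse(is.nan(ig), 0, ig), tolerance = 1e-12)

    m <- matrix(stats::runif(n * n, -1, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
    i <- sample(n, 1)
    expect_equal(unname(node_degree(m)[i]), brute_node_degree(m, i),
                 tolerance = 1e-12)
    idx <- sample(n, 3)
    expect_equal(region_degree(m, rownames(m)[idx]),
                 brute_region_degree(m, idx), tolerance = 1e-12)
  }
})

test_that("lowering the threshold never removes triangles", {
  set.seed(13)
  m <- random_symmetric(12, labels = paste0("n", 1:12))
  tri_count <- function(th) {
    a <- unclass(binarize(m, th))
    sum(diag(a %*% a %*% a)) / 6
  }
  counts <- vapply(seq(0.8, -0.8, by = -0.2), tri_count, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("network_metrics assembles all indicators for both windows", {
  sim <- small_sim()
  blocks <- make_trial_blocks(
    bandpass(select_trials(sim$recording, tasks = c("left", "right")), 3, 30),
    20
  )
  nm <- network_metrics(blocks[1, ])
  expect_setequal(unique(nm$window_role), c("task", "rest"))
  expect_equal(sum(nm$scale == "node"), 2 * 19)
  expect_setequal(nm$indicator[nm$scale == "region"], c("LnL", "LnR", "EX"))
  expect_setequal(nm$indicator[nm$scale == "clustering"],
                  c("all", "left", "right"))
  cl <- nm$value[nm$scale == "clustering"]
  expect_true(all(cl >= 0 & cl <= 1))
})

test_that("a flat zero block yields zero degrees and zero clustering", {
  tax <- seq(-200, 200) / 200
  blk <- tibble::tibble(block = 1L, day = 1L, session = 1L, task = "left",
                        n_trials = 20L, data = list(matrix(0, 19, 401)))
  blk <- structure(blk, class = c("trial_blocks", class(blk)),
                   sampling_rate = 200, time_axis = tax,
                   channels = mi_montage()$channels)
  suppressWarnings(nm <- network_metrics(blk[1, ]))
  expect_true(all(nm$value[nm$scale != "clustering"] == 0))
  expect_true(all(nm$value[nm$scale == "clustering"] == 0))
})

test_that("metrics are invariant under simultaneous channel relabeling", {
  sim <- small_sim()
  blocks <- make_trial_blocks(
    bandpass(select_trials(sim$recording, tasks = c("left", "right")), 3, 30),
    20
  )
  conn <- pearson_connectivity(blocks[1, ], "task")
  perm <- sample(19)
  permuted <- conn[perm, perm]
  expect_equal(sort(unname(node_degree(permuted))),
               sort(unname(node_degree(conn))), tolerance = 1e-12)
  montage <- mi_montage()
  expect_equal(region_degree(permuted, montage$left_set),
               region_degree(conn, montage$left_set), tolerance = 1e-12)
  expect_equal(transitivity_coef(binarize(permuted, 0.6)),
               transitivity_coef(binarize(conn, 0.6)), tolerance = 1e-12)
})

test_that("single-band scan equals running the pipeline stages once", {
  sim <- small_sim()
  rec <- select_trials(sim$recording, tasks = c("left", "right"))
  scan <- band_scan_degree(rec, band_definition(3, 30))
  blocks <- make_trial_blocks(bandpass(rec, 3, 30), 20)
  target <- c("C3", "C4", "O1", "O2", "Fp1", "Fp2")
  manual <- vapply(seq_len(nrow(blocks)), function(i) {
    mean(node_degree(pearson_connectivity(blocks[i, ], "task"), target))
  }, numeric(1))
  expect_equal(scan$mean, mean(manual), tolerance = 1e-12)
  expect_equal(scan$sd, stats::sd(manual), tolerance = 1e-12)
  expect_equal(scan$n_blocks, length(manual))
})
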