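test_that("exact 1-D k-means reproduces hand-checkable partitions", {
  ch <- array(0, c(2, 4, 1))
  ch[1:8] <- c(1, 2, 10, 11, 20, 21, 30, 31)
  cl <- cluster_channel(ch, k = 4)
  expect_equal(cl$means, c(1.5, 10.5, 20.5, 30.5))
  expect_equal(cl$sse, 2.0)
  expect_equal(cl$breaks, c(2, 11, 21, 31))

  cl2 <- cluster_channel(c(5, 5, 100, 0), k = 2)
  expect_equal(cl2$means, c(5, 100))
  expect_equal(cl2$sizes, c(2, 1))

  # fewer distinct values than k: k reduces
  cl3 <- cluster_channel(array(c(0, 7, 7, 7), c(4, 1, 1)), k = 4)
  expect_equal(cl3$k, 1L)
  expect_equal(cl3$means, 7)
})

test_that("dynamic program attains the exhaustive-search optimum", {
  set.seed(42)
  for (i in 1:40) {
    d <- sample(2:12, 1)
    vals <- sort(sample(1:500, d))
    reps <- sample(1:5, d, replace = TRUE)
    x <- rep(vals, reps)
    k <- sample(2:min(5, d), 1)
    cl <- cluster_channel(x, k = k)
    expect_equal(cl$sse, brute_kmeans1d_sse(x, k), tolerance = 1e-9)
  }
})

test_that("background removal keeps exactly the non-background clusters", {
  ch <- array(0, c(2, 4, 1))
  ch[1:8] <- c(1, 2, 10, 11, 20, 21, 30, 31)
  cl <- cluster_channel(ch, k = 4)
  mask <- remove_background(ch, cl)
  expect_equal(sum(mask), 6)
  expect_gt(min(ch[mask]), max(ch[!mask & ch > 0]))

  # single-cluster channel: all non-zero voxels are kept
  ch1 <- array(c(0, 7, 7, 7), c(4, 1, 1))
  m1 <- remove_background(ch1, cluster_channel(ch1, 4))
  expect_equal(sum(m1), 3)

  # all-zero channel signals empty, yields an empty mask
  ch0 <- array(0, c(3, 3, 3))
  cl0 <- cluster_channel(ch0, 4)
  expect_true(cl0$empty)
  expect_false(any(remove_background(ch0, cl0)))
})

test_that("threshold property holds on random channels", {
  set.seed(7)
  for (i in 1:20) {
    x <- c(rpois(200, 3), rpois(50, 60))
    ch <- array(x, c(10, 5, 5))
    cl <- cluster_channel(ch, 4)
    if (cl$k < 2) next
    mask <- remove_background(ch, cl)
    expect_gt(min(ch[mask]), max(ch[!mask & ch > 0]))
  }
})

test_that("lloyd mode solves the same objective on well-separated data", {
  x <- c(rep(10, 20), rep(100, 20), rep(500, 20), rep(900, 20))
  dp <- cluster_channel(x, 4, method = "dp")
  ll <- cluster_channel(x, 4, method = "lloyd")
  expect_equal(ll$means, dp$means)
  expect_equal(ll$sse, dp$sse)
})

test_that("exclusions clear both channels and are monotone", {
  sim <- generate_stack_pair(quiet_stack_params(seed = 5))
  masks <- segment_stack_pair(sim$pair)
  # identity
  none <- apply_exclusions(masks, array(FALSE, dim(sim$pair$live)))
  expect_identical(none$live, masks$live)
  expect_identical(none$dead, masks$dead)
  # annihilation
  all_ex <- apply_exclusions(masks, array(TRUE, dim(sim$pair$live)))
  expect_false(any(all_ex$live))
  expect_false(any(all_ex$dead))
  # set arithmetic against the simulator's ground truth
  excl <- sim$truth$labels == 1L
  cut <- apply_exclusions(masks, excl)
  expect_equal(sum(cut$live), sum(masks$live) - sum(masks$live & excl))
  expect_equal(sum(cut$dead), sum(masks$dead) - sum(masks$dead & excl))
  # growing the exclusion never increases foreground
  for (i in 1:5) {
    grown <- excl | (array(runif(length(excl)), dim(excl)) < 0.1)
    g <- apply_exclusions(masks, grown)
    expect_lte(sum(g$live), sum(cut$live))
    expect_lte(sum(g$dead), sum(cut$dead))
  }
})

test_that("large-component filter removes yeast and is idempotent", {
  # moderate noise so the background cluster is noise, not a dim yeast blob
  p <- stack_sim_params(n_live = 40L, n_dead = 10L, n_double = 0L,
                        n_chains = 0L, n_yeast = 2L, seed = 9)
  sim <- generate_stack_pair(p)
  masks <- segment_stack_pair(sim$pair)
  # a coccus at radius 2 covers 15 voxels; threshold = 4x max cell volume
  res <- auto_exclude_large_components(masks, min_volume = 60L)
  yeast <- sim$truth$labels == 4L
  recall <- sum(res$exclusion & yeast) / sum(yeast)
  expect_gte(recall, 0.95)
  # idempotent
  res2 <- auto_exclude_large_components(res$masks, min_volume = 60L)
  expect_identical(res2$masks$live, res$masks$live)
  expect_identical(res2$masks$dead, res$masks$dead)
  # no component reaches the threshold: unchanged
  small <- auto_exclude_large_components(masks, min_volume = 10000L)
  expect_identical(small$masks$live, masks$live)
  expect_false(any(small$exclusion))
})

test_that("segmentation is deterministic", {
  sim <- generate_stack_pair(stack_sim_params(seed = 3))
  m1 <- segment_stack_pair(sim$pair)
  m2 <- segment_stack_pair(sim$pair)
  expect_identical(m1$live, m2$live)
  expect_identical(m1$dead, m2$dead)
})
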