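planted_matrix <- function(n_per = 20, k = 5, sep = 0.5, sd = 0.01, seed = 1) {
  set.seed(seed)
  centers <- matrix(seq(0, by = sep, length.out = k * 14), k, 14)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * 14, 0, sd), ncol = 14), 2, centers[i, ], `+`)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

test_that("stratified sampling hits the schemes' quotas deterministically", {
  sch <- sampling_scheme("healthy")
  expect_equal(sum(sch), 100)
  expect_equal(unname(sch), c(48L, 13L, 13L, 13L, 13L))
  expect_equal(unname(sampling_scheme("doc")), c(50L, 50L))
  set.seed(1)
  f <- matrix(rnorm(300 * 14), 300)
  strata <- sample(rep(STAGE_LEVELS, each = 60))
  s1 <- sample_epochs(f, strata, sch, seed = 4)
  s2 <- sample_epochs(f, strata, sch, seed = 4)
  expect_identical(s1$indices, s2$indices)
  expect_equal(nrow(s1$features), 100)
  expect_equal(table(factor(s1$strata, names(sch)))[["W"]], 48)
  expect_false(anyDuplicated(s1$indices) > 0)   # without replacement
  # within-stratum indices are time-ordered
  wi <- s1$indices[s1$strata == "W"]
  expect_false(is.unsorted(wi))
  # a DOC subject with exactly the quota gets every epoch
  fd <- matrix(rnorm(100 * 14), 100)
  sd_ <- sample_epochs(fd, rep(c("day", "night"), each = 50),
                       sampling_scheme("doc"), seed = 1)
  expect_equal(sort(sd_$indices), 1:100)
  # short stratum: strict errors naming it, default warns and resamples
  short <- rep(c("day", "night"), c(95, 5))
  expect_error(sample_epochs(fd, short, sampling_scheme("doc"), strict = TRUE),
               "stratum night")
  expect_warning(sw <- sample_epochs(fd, short, sampling_scheme("doc"), seed = 2),
                 "replacement")
  expect_equal(nrow(sw$features), 100)
})

test_that("group averaging is position-wise within stratum", {
  sch <- c(day = 2L, night = 2L)
  mk <- function(m) list(features = m, strata = rep(c("day", "night"), each = 2),
                         indices = 1:4)
  A <- matrix(1, 4, 3); B <- matrix(3, 4, 3)
  g <- group_average(list(mk(A), mk(B)), "g")
  expect_equal(unclass(g), (A + B) / 2, ignore_attr = TRUE)
  expect_identical(attr(g, "strata"), rep(c("day", "night"), each = 2))
  # single-subject group is the subject's sample
  expect_equal(unclass(group_average(list(mk(A)))), A, ignore_attr = TRUE)
  bad <- mk(B); bad$strata <- rev(bad$strata)
  expect_error(group_average(list(mk(A), bad)), "mixed schemes")
  # planted per-stratum means are recovered
  set.seed(5)
  subs <- lapply(1:30, function(i) {
    m <- rbind(matrix(rnorm(2 * 3, 0.88, 0.02), 2),
               matrix(rnorm(2 * 3, 0.83, 0.02), 2))
    mk(m)
  })
  gm <- group_average(subs)
  expect_equal(mean(gm[1:2, ]), 0.88, tolerance = 0.005)
  expect_equal(mean(gm[3:4, ]), 0.83, tolerance = 0.005)
})

test_that("average-linkage trees match exhaustive hand agglomeration", {
  # 4 hand-picked points in 2-D
  X <- rbind(c(0, 0), c(0, 1), c(4, 0), c(6, 0))
  tr <- hcluster(X)
  expect_equal(tr$heights, hand_average_linkage(X), tolerance = 1e-12)
  expect_true(tr$monotone)
  # 12 random points, several seeds
  for (s in 1:4) {
    set.seed(s)
    Y <- matrix(rnorm(24), 12, 2)
    expect_equal(sort(hcluster(Y)$heights), sort(hand_average_linkage(Y)),
                 tolerance = 1e-12)
  }
  # identical rows merge at height zero
  Z <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(min(hcluster(Z)$heights), 0)
  expect_error(hcluster(rbind(c(1, NA), c(0, 0))), "missing")
  # root height equals the mean pairwise distance between the two final clusters
  set.seed(9)
  W <- matrix(rnorm(40), 20, 2)
  trw <- hcluster(W)
  two <- cut_tree(trw, select_cutoff(trw, 2))
  D <- as.matrix(dist(W))
  expect_equal(max(trw$heights), mean(D[two == 1, two == 2]), tolerance = 1e-12)
})

test_that("cut-off selection yields exactly k clusters and recovers planted structure", {
  pl <- planted_matrix()
  tr <- hcluster(pl$x)
  for (k in c(1, 2, 5, 10)) {
    co <- select_cutoff(tr, k)
    expect_equal(length(unique(cut_tree(tr, co))), k)
  }
  asg <- cut_tree(tr, select_cutoff(tr, 5))
  expect_equal(mclust::adjustedRandIndex(asg, pl$labels), 1)
  # extremes
  expect_equal(length(unique(cut_tree(tr, 0))), nrow(pl$x))        # distinct rows
  expect_equal(length(unique(cut_tree(tr, max(tr$heights) * 1.1))), 1)
  expect_error(select_cutoff(tr, nrow(pl$x) + 1), "between")
})

test_that("row permutation changes leaf ids but not heights or the partition", {
  pl <- planted_matrix(n_per = 8, seed = 3)
  set.seed(4)
  perm <- sample(nrow(pl$x))
  t1 <- hcluster(pl$x)
  t2 <- hcluster(pl$x[perm, ])
  expect_equal(sort(t1$heights), sort(t2$heights), tolerance = 1e-12)
  a1 <- cut_tree(t1, select_cutoff(t1, 5))
  a2 <- cut_tree(t2, select_cutoff(t2, 5))
  expect_equal(mclust::adjustedRandIndex(a1[perm], a2), 1)
})

test_that("cluster summaries report sizes, means and composition", {
  m <- rbind(matrix(0.88, 3, 4), matrix(0.83, 2, 4))
  asg <- c(1, 1, 1, 2, 2)
  sm <- summarize_clusters(asg, m, strata = c("W", "W", "R", "N2", "N2"),
                           root_height = 0.07)
  expect_equal(sm$n_clusters, 2)
  expect_equal(sm$clusters[[1]]$size, 3)
  expect_equal(sm$clusters[[1]]$mean_pe, 0.88)
  expect_equal(sm$clusters[[1]]$sd_pooled, 0)
  expect_equal(sm$clusters[[1]]$composition$W, 2 / 3)
  expect_equal(sm$root_height, 0.07)
  expect_equal(sum(vapply(sm$clusters, `[[`, numeric(1), "size")), 5)
  # planted means recovered under noise
  set.seed(6)
  mm <- rbind(matrix(rnorm(50 * 5, 0.88, 0.003), 50),
              matrix(rnorm(50 * 5, 0.83, 0.003), 50))
  sm2 <- summarize_clusters(rep(1:2, each = 50), mm)
  expect_equal(sm2$clusters[[1]]$mean_pe, 0.88, tolerance = 0.002)
  expect_equal(sm2$clusters[[2]]$mean_pe, 0.83, tolerance = 0.002)
  expect_error(summarize_clusters(c(1, 2), mm), "cover")
})

test_that("trees export as merge tables and Newick", {
  pl <- planted_matrix(n_per = 3, k = 3, seed = 2)
  tr <- hcluster(pl$x)
  f <- tempfile(fileext = ".csv")
  write_merge_table(tr, f)
  mt <- read.csv(f)
  expect_equal(nrow(mt), nrow(pl$x) - 1)
  expect_equal(mt$height, tr$heights)
  nwk <- tree_to_newick(tr)
  expect_match(nwk, "^\\(.*\\);$")
})
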