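test_that("jaccard weight matches set enumeration", {
  expect_equal(jaccard_weight(c("x", "y", "z"), c("x", "y", "z")), 1)
  expect_equal(jaccard_weight(c("x", "y"), c("u", "v")), 0)
  expect_equal(jaccard_weight(c("1", "2", "3"), c("2", "3", "4")), 0.5)
  expect_equal(jaccard_weight("a", c("a", "b")), jaccard_weight(c("a", "b"), "a"))
  expect_error(jaccard_weight(character(0), character(0)), "empty")
})

test_that("bipartite map holds exactly the positive-Jaccard pairs", {
  p <- tiny_pair()
  m <- build_bipartite_map(p$s1, p$s2)
  e <- m$edges
  expect_equal(nrow(e), 3L)
  expect_equal(e$weight[e$source == "A" & e$target == "X"], 0.75)
  expect_equal(e$weight[e$source == "A" & e$target == "Y"], 1 / 6)
  expect_equal(e$weight[e$source == "B" & e$target == "Y"], 2 / 3)
  expect_false(any(e$source == "B" & e$target == "X"))

  # identical partitions: identity map of unit weights
  s <- snapshot_partition(1, list(A = c("1", "2"), B = "3"))
  s2 <- snapshot_partition(2, list(A = c("1", "2"), B = "3"))
  mi <- build_bipartite_map(s, s2)
  expect_true(all(mi$edges$weight == 1))
  expect_equal(mi$edges$source, mi$edges$target)

  # disjoint node sets: no edges
  s3 <- snapshot_partition(2, list(Q = c("8", "9")))
  expect_equal(nrow(build_bipartite_map(s, s3)$edges), 0L)

  expect_error(build_bipartite_map(p$s1, snapshot_partition(3, list(A = "1"))),
               "consecutive")
})

test_that("threshold is the minimum of the per-cluster maximum weights", {
  p <- tiny_pair()
  m <- compute_threshold(build_bipartite_map(p$s1, p$s2))
  expect_setequal(round(unname(m$L), 10), round(c(0.75, 2 / 3, 0.75, 2 / 3), 10))
  expect_equal(m$theta, 2 / 3)

  # singleton edge
  s1 <- snapshot_partition(1, list(A = c("1", "2", "3", "4", "5")))
  s2 <- snapshot_partition(2, list(X = c("1", "2", "3", "4")))
  expect_equal(compute_threshold(build_bipartite_map(s1, s2))$theta, 0.8)

  # identity partitions give theta = 1
  s <- snapshot_partition(1, list(A = "1", B = "2"))
  sb <- snapshot_partition(2, list(A = "1", B = "2"))
  expect_equal(compute_threshold(build_bipartite_map(s, sb))$theta, 1)
})

test_that("pruning keeps boundary edges and drops sub-threshold ones", {
  p <- tiny_pair()
  m <- prune_map(compute_threshold(build_bipartite_map(p$s1, p$s2)))
  kept <- m$edges[m$retained, ]
  expect_setequal(paste(kept$source, kept$target), c("A X", "B Y"))

  # all weights equal: nothing removed
  s1 <- snapshot_partition(1, list(A = c("1", "2"), B = c("3", "4")))
  s2 <- snapshot_partition(2, list(X = c("1", "2", "3", "4")))
  m2 <- prune_map(compute_threshold(build_bipartite_map(s1, s2)))
  expect_true(all(m2$retained))

  # user-overridden threshold may empty the map
  m3 <- prune_map(compute_threshold(build_bipartite_map(p$s1, p$s2)),
                  theta = 0.9)
  expect_false(any(m3$retained))
  m3 <- attach_pseudo_clusters(m3, p$s1, p$s2)
  expect_setequal(m3$pseudo$source[m3$pseudo$kind == "dump"], c("A", "B"))
  expect_setequal(m3$pseudo$target[m3$pseudo$kind == "birth"], c("X", "Y"))
})

test_that("dump sink and birth sources attach to disconnected communities", {
  s1 <- snapshot_partition(1, list(A = c("1", "2", "3"), B = c("4", "5")))
  s2 <- snapshot_partition(2, list(X = c("1", "2", "3"), Z = c("7", "8")))
  m <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(s1, s2))), s1, s2)
  ps <- m$pseudo
  expect_equal(ps$target[ps$source == "B"], "Dump")
  expect_equal(ps$source[ps$target == "Z"], "C0")
  expect_equal(ps$unseen_frac[ps$target == "Z"], 1)

  # two births: C0 goes to the larger newborn, C-1 to the smaller
  s2b <- snapshot_partition(2, list(X = c("1", "2", "3"),
                                    Z = c("7", "8", "9"),
                                    Q = paste0("q", 1:5)))
  m2 <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(s1, s2b))), s1, s2b)
  ps2 <- m2$pseudo[m2$pseudo$kind == "birth", ]
  expect_equal(ps2$target[ps2$source == "C0"], "Q")
  expect_equal(ps2$target[ps2$source == "C-1"], "Z")

  # no deaths or births: no pseudo attachments
  p <- tiny_pair()
  m3 <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(p$s1, p$s2))),
    p$s1, p$s2)
  expect_equal(nrow(m3$pseudo), 0L)
})

test_that("user threshold override follows the tolerance rule", {
  res <- apply_user_threshold(c(0.40, 0.44), rho = 0.4, nu = 0.1)
  expect_equal(res$mu_theta, 0.42)
  expect_true(res$overridden)
  expect_equal(res$applied, c(0.4, 0.4))

  res2 <- apply_user_threshold(c(0.40, 0.44), rho = 0.9, nu = 0.1)
  expect_false(res2$overridden)
  expect_equal(res2$applied, c(0.40, 0.44))

  # boundary: |rho - mu| = 0 with nu = 0 still overrides
  res3 <- apply_user_threshold(c(0.3, 0.5), rho = 0.4, nu = 0)
  expect_true(res3$overridden)
  expect_equal(res3$applied, c(0.4, 0.4))

  expect_error(apply_user_threshold(c(0.4), rho = 1.5), "rho")
  expect_error(apply_user_threshold(numeric(0), rho = 0.4), "non-empty")
})

test_that("event classification covers merge, split, continuation, size changes", {
  # merge: A + B -> X, both weights 0.5 = theta
  s1 <- snapshot_partition(1, list(A = c("1", "2"), B = c("3", "4")))
  s2 <- snapshot_partition(2, list(X = c("1", "2", "3", "4")))
  m <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(s1, s2))), s1, s2)
  ev <- classify_events(m)
  expect_equal(ev$type, "merge")
  expect_equal(ev$sources, "A+B")
  expect_equal(ev$targets, "X")

  # split: mirror case
  m2 <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(
      snapshot_partition(1, list(A = c("1", "2", "3", "4"))),
      snapshot_partition(2, list(X = c("1", "2"), Y = c("3", "4")))))),
    snapshot_partition(1, list(A = c("1", "2", "3", "4"))),
    snapshot_partition(2, list(X = c("1", "2"), Y = c("3", "4"))))
  ev2 <- classify_events(m2)
  expect_equal(ev2$type, "split")
  expect_equal(ev2$targets, "X+Y")

  # continuation with 25% shrinkage
  s1c <- snapshot_partition(1, list(A = c("1", "2", "3", "4")))
  s2c <- snapshot_partition(2, list(X = c("1", "2", "3")))
  m3 <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(s1c, s2c))), s1c, s2c)
  ev3 <- classify_events(m3, growth_frac = 0.2)
  expect_setequal(ev3$type, c("continuation", "shrinkage"))
  # with a 30% fraction the same pair is a plain continuation
  ev4 <- classify_events(m3, growth_frac = 0.3)
  expect_equal(ev4$type, "continuation")
})

test_that("every community carries exactly one primary event", {
  for (seed in 1:25) {
    p <- random_snapshot_pair(seed)
    m <- attach_pseudo_clusters(
      prune_map(compute_threshold(build_bipartite_map(p$s1, p$s2))),
      p$s1, p$s2)
    ev <- classify_events(m)
    src_of <- function(types) unique(unlist(strsplit(
      ev$sources[ev$type %in% types], "+", fixed = TRUE)))
    tgt_of <- function(types) unique(unlist(strsplit(
      ev$targets[ev$type %in% types], "+", fixed = TRUE)))
    # each t-community is covered, and death/continuation are exclusive of
    # any merge/split participation
    final_src <- src_of(c("death", "continuation"))
    busy_src <- src_of(c("split", "merge"))
    expect_length(intersect(final_src, busy_src), 0L)
    expect_setequal(c(final_src, busy_src), m$sources)
    # symmetric cover at t+1 with birth/continuation exclusive
    final_tgt <- tgt_of(c("birth", "continuation"))
    busy_tgt <- tgt_of(c("split", "merge"))
    expect_length(intersect(final_tgt, busy_tgt), 0L)
    expect_setequal(c(final_tgt, busy_tgt), m$targets)
  }
})

test_that("threshold agrees with the brute-force oracle on random fixtures", {
  for (seed in 1:50) {
    p <- random_snapshot_pair(seed + 100)
    m <- compute_threshold(build_bipartite_map(p$s1, p$s2))
    orc <- oracle_threshold(p$s1, p$s2)
    expect_equal(m$theta, orc$theta)
    expect_equal(sort(unname(m$L)), sort(orc$L))
    # weights match the oracle matrix
    for (i in seq_len(nrow(m$edges)))
      expect_equal(m$edges$weight[i],
                   orc$W[m$edges$source[i], m$edges$target[i]])
    # adaptive pruning never disconnects a community that had an edge
    mp <- attach_pseudo_clusters(prune_map(m), p$s1, p$s2)
    kept <- mp$edges[mp$retained, ]
    expect_setequal(unique(mp$edges$source), unique(kept$source))
    expect_setequal(unique(mp$edges$target), unique(kept$target))
  }
})

test_that("track_all chains intervals and handles degenerate maps", {
  # identity partition over two snapshots: all continuations, theta = 1
  dp <- as.dynamic_partition(data.frame(
    node = rep(c("a", "b", "c", "d"), 2),
    time = rep(1:2, each = 4),
    cluster = rep(c("X", "X", "Y", "Y"), 2)))
  tr <- track_all(dp)
  expect_equal(tr$thetas, 1)
  expect_setequal(tr$events$type, "continuation")

  # completely disjoint snapshots: theta undefined, all deaths + births
  dp2 <- as.dynamic_partition(data.frame(
    node = c("a", "b", "p", "q"), time = c(1, 1, 2, 2),
    cluster = c("X", "Y", "U", "V")))
  tr2 <- track_all(dp2)
  expect_true(is.na(tr2$thetas))
  expect_setequal(tr2$events$type, c("death", "birth"))
  expect_equal(sum(tr2$events$type == "death"), 2L)
  expect_equal(sum(tr2$events$type == "birth"), 2L)

  # one death per interval for the hide-style schedule
  sim <- generate_dynamic_partition(schedule_hide(9))
  tr3 <- track_all(sim$partition)
  deaths <- tr3$events[tr3$events$type == "death", ]
  expect_equal(deaths$time, 1:4)
})

test_that("tracking a single snapshot is rejected", {
  dp1 <- as.dynamic_partition(data.frame(node = "a", time = 1, cluster = "X"))
  expect_error(track_all(dp1), "at least 2")
})
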