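test_that("a single continuing community lays out flat at slot zero", {
  db <- build_query_database(
    lapply(1:3, function(t) commtrace:::pair_table("A", "A", t)))
  g <- assign_tracks(extract_threads(db))
  expect_equal(nrow(g$circles), 4L)
  expect_true(all(g$circles$y == 1))
  expect_true(all(g$segments$y0 == g$segments$y1))
  expect_equal(count_crossovers(g), 0L)
})

test_that("split children follow the slot inheritance rule", {
  db <- commtrace:::new_query_database(
    data.frame(T1 = c("A", "A"), T2 = c("B", "C"), T3 = c("B", "C"),
               stringsAsFactors = FALSE))
  g <- assign_tracks(extract_threads(db))
  cc <- g$circles
  # smallest label (B) inherits the parent slot; C is appended below
  expect_equal(cc$slot[cc$label == "B" & cc$time == 2], 0L)
  expect_equal(cc$slot[cc$label == "C" & cc$time == 2], 1L)
  expect_true(all(abs(cc$y - cc$track) <= 0.4 + 1e-12))
  # two diverging segments from one circle at the split
  iv1 <- g$segments[g$segments$interval == 1, ]
  expect_equal(nrow(iv1), 2L)
  expect_equal(length(unique(iv1$c0)), 1L)
})

test_that("crossing counts follow the strict segment-crossing rule", {
  geom <- function(y0, y1, c0 = paste0("a", seq_along(y0)),
                   c1 = paste0("b", seq_along(y0))) {
    structure(list(circles = data.frame(id = c(c0, c1)),
                   segments = data.frame(interval = 1L, y0 = y0, y1 = y1,
                                         c0 = c0, c1 = c1, kind = "timeline",
                                         origin0 = "o", origin1 = "o",
                                         stringsAsFactors = FALSE),
                   ordering = "o", T = 2L),
              class = "timeline_geometry")
  }
  expect_equal(count_crossovers(geom(c(1, 2), c(1, 2))), 0L)  # parallel
  expect_equal(count_crossovers(geom(c(1, 2), c(2, 1))), 1L)  # X shape
  # touching at a shared endpoint circle does not count
  g <- geom(c(1, 2), c(2, 2), c0 = c("a1", "a2"), c1 = c("b", "b"))
  expect_equal(count_crossovers(g), 0L)
})

test_that("crossing counts are invariant under increasing y transforms", {
  for (seed in 1:20) {
    g <- random_geometry(seed)
    n0 <- count_crossovers(g)
    g2 <- g
    g2$segments$y0 <- exp(0.3 * g2$segments$y0) + 5
    g2$segments$y1 <- exp(0.3 * g2$segments$y1) + 5
    expect_equal(count_crossovers(g2), n0)
  }
})

test_that("crossing counts agree with the geometric oracle", {
  for (seed in 1:60)  {
    g <- random_geometry(seed)
    expect_equal(count_crossovers(g), oracle_crossings(g))
  }
})

test_that("published lineage layout reproduces the banded merge geometry", {
  db <- read_lineage_table(published_lineage_path())
  th <- extract_threads(db)
  pol <- c("2:C8" = "C6")
  res <- resolve_merges(th, paste0("C", 1:7), survivor_policy = pol)
  # two cross-track merges: C5 absorbed at T2, the C6-hosted line at T4
  expect_equal(res$merges$absorbed_origin, c("C5", "C6"))
  expect_equal(res$merges$survivor_origin, c("C6", "C1"))
  g <- assign_tracks(th, paste0("C", 1:7), resolution = res)
  s <- g$segments
  # band contents at the T3->T4 interval: 2 (C2), 4 (C3), 2 (C4) segments
  iv3 <- s[s$interval == 3 & s$kind != "merge-dash", ]
  expect_equal(sum(iv3$origin0 == "C2"), 2L)
  expect_equal(sum(iv3$origin0 == "C3"), 4L)
  expect_equal(sum(iv3$origin0 == "C4"), 2L)
  # C5's line terminated at T2: its band is empty afterwards
  expect_equal(sum(s$origin0 == "C5" & s$interval >= 2), 0L)
  # the survivor policy must name an arriving origin
  expect_error(resolve_merges(th, survivor_policy = c("2:C8" = "C3")),
               "policy")
})

test_that("an unknown origin in the ordering is rejected", {
  db <- read_lineage_table(published_lineage_path())
  th <- extract_threads(db)
  expect_error(assign_tracks(th, c(paste0("C", 1:6), "Z")), "permutation")
})

test_that("greedy reordering pulls merging tracks together", {
  # three tracks, one merge between tracks 1 and 3, a straight line on 2
  db <- commtrace:::new_query_database(
    data.frame(T1 = c("A", "B", "Z"), T2 = c("M", "B", "M"),
               stringsAsFactors = FALSE))
  th <- extract_threads(db)
  init <- c("A", "B", "Z")
  g0 <- assign_tracks(th, init)
  expect_gte(count_crossovers(g0), 1L)
  better <- greedy_reorder(th, init)
  g1 <- assign_tracks(th, better,
                      resolution = resolve_merges(th, init))
  expect_equal(count_crossovers(g1), 0L)
  # brute force agrees that 0 is the minimum
  bf <- brute_force_order(th, init)
  expect_equal(bf$crossings, 0L)

  # single origin: identity, zero crossings
  db1 <- commtrace:::new_query_database(
    data.frame(T1 = "A", T2 = "A", stringsAsFactors = FALSE))
  th1 <- extract_threads(db1)
  expect_equal(greedy_reorder(th1), "A")
  expect_equal(brute_force_order(th1)$ordering, "A")

  # the exhaustive search refuses oversized instances
  dbn <- commtrace:::new_query_database(
    data.frame(T1 = paste0("O", 1:9), T2 = paste0("O", 1:9),
               stringsAsFactors = FALSE))
  expect_error(brute_force_order(extract_threads(dbn)), "greedy")
})

test_that("reordering contracts hold on random thread sets", {
  for (seed in c(3, 7, 12, 19, 28, 39, 52, 67, 84, 103)) {
    ts <- random_thread_set(seed)
    init <- ts$threads$origins
    res <- resolve_merges(ts$threads, init, maps = ts$maps)
    n_init <- count_crossovers(
      assign_tracks(ts$threads, init, resolution = res))
    better <- greedy_reorder(ts$threads, init, maps = ts$maps)
    n_greedy <- count_crossovers(
      assign_tracks(ts$threads, better, resolution = res))
    expect_lte(n_greedy, n_init)
    if (length(init) <= 7L) {
      bf <- brute_force_order(ts$threads, init, maps = ts$maps)
      expect_lte(bf$crossings, n_greedy)
      n_bf <- count_crossovers(
        assign_tracks(ts$threads, bf$ordering, resolution = res))
      expect_equal(n_bf, bf$crossings)
    }
  }
})

test_that("only merge-dash crossings vary with the track ordering", {
  ts <- random_thread_set(41)
  init <- ts$threads$origins
  res <- resolve_merges(ts$threads, init, maps = ts$maps)
  within_count <- function(ordering) {
    g <- assign_tracks(ts$threads, ordering, resolution = res)
    s <- g$segments[g$segments$kind != "merge-dash", , drop = FALSE]
    g$segments <- s
    count_crossovers(g)
  }
  base <- within_count(init)
  set.seed(99)
  for (i in 1:10)
    expect_equal(within_count(sample(init)), base)
})

test_that("circle radii follow the square-root area rule", {
  dp <- as.dynamic_partition(data.frame(
    node = c(paste0("a", 1:100), paste0("b", 1:400),
             paste0("a", 1:100), paste0("b", 1:400)),
    time = rep(1:2, each = 500),
    cluster = rep(c(rep("A", 100), rep("B", 400)), 2)))
  fit <- commtrace(dp)
  cc <- fit$geometry$circles
  rA <- cc$radius[cc$label == "A"][1]
  rB <- cc$radius[cc$label == "B"][1]
  expect_equal(rB / rA, 2)
  expect_equal(max(cc$radius), 0.35)
})
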