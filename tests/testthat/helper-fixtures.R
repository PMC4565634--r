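# Shared fixtures and independent oracles for the test suite.

published_lineage_path <- function() {
  system.file("extdata", "mergesplit_lineage.tsv", package = "commtrace",
              mustWork = TRUE)
}

# canonical event keys for set comparison (labels are sorted inside records)
event_keys <- function(ev) {
  paste(ev$type, ev$time, ev$sources, ev$targets, sep = "|")
}

expect_same_events <- function(got, want) {
  expect_setequal(event_keys(got), event_keys(want))
}

# a tiny two-snapshot partition used across tracking tests:
# t1: A = {1,2,3,4}, B = {5,6};  t2: X = {1,2,3}, Y = {4,5,6}
tiny_pair <- function() {
  list(s1 = snapshot_partition(1, list(A = c("1", "2", "3", "4"),
                                       B = c("5", "6"))),
       s2 = snapshot_partition(2, list(X = c("1", "2", "3"),
                                       Y = c("4", "5", "6"))))
}

# random consecutive snapshot pair: n nodes relabelled into random clusters
# on both sides, with some node turnover
random_snapshot_pair <- function(seed, n = 24L, k_max = 4L) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n))
  mk <- function(t, pool) {
    k <- sample(2:k_max, 1L)
    lab <- paste0("g", seq_len(k))
    memb <- sample(lab, length(pool), replace = TRUE)
    memb[seq_len(k)] <- lab  # ensure non-empty clusters
    snapshot_partition(t, split(pool, memb))
  }
  keep <- sample(nodes, max(4L, rbinom(1L, n, 0.85)))
  extra <- paste0("w", seq_len(max(0L, rbinom(1L, 6L, 0.5))))
  list(s1 = mk(1L, nodes), s2 = mk(2L, c(keep, extra)))
}

# --- independent threshold oracle: explicit pairwise Jaccards + min-of-max
oracle_threshold <- function(s1, s2) {
  labs1 <- names(s1$clusters); labs2 <- names(s2$clusters)
  W <- matrix(0, length(labs1), length(labs2),
              dimnames = list(labs1, labs2))
  for (a in labs1) for (b in labs2) {
    A <- s1$clusters[[a]]; B <- s2$clusters[[b]]
    W[a, b] <- length(intersect(A, B)) / length(union(A, B))
  }
  L <- c(apply(W, 1L, max)[apply(W, 1L, max) > 0],
         apply(W, 2L, max)[apply(W, 2L, max) > 0])
  list(W = W, L = unname(L),
       theta = if (length(L)) min(L) else NA_real_)
}

# --- independent crossing oracle: orientation tests on the actual segment
# coordinates (x = interval endpoints), strict interior intersection only
oracle_crossings <- function(geom) {
  s <- geom$segments
  n <- 0L
  ccw <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  m <- nrow(s)
  if (m < 2L) return(0L)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (s$interval[i] != s$interval[j]) next
    if (s$c0[i] == s$c0[j] || s$c0[i] == s$c1[j] ||
        s$c1[i] == s$c0[j] || s$c1[i] == s$c1[j]) next
    x0 <- s$interval[i]; x1 <- x0 + 1L
    d1 <- ccw(x0, s$y0[i], x1, s$y1[i], x0, s$y0[j])
    d2 <- ccw(x0, s$y0[i], x1, s$y1[i], x1, s$y1[j])
    d3 <- ccw(x0, s$y0[j], x1, s$y1[j], x0, s$y0[i])
    d4 <- ccw(x0, s$y0[j], x1, s$y1[j], x1, s$y1[i])
    if (d1 * d2 < 0 && d3 * d4 < 0) n <- n + 1L
  }
  n
}

# random synthetic geometry (not derived from threads): circles on a grid of
# times, segments connecting random circles of consecutive times
random_geometry <- function(seed, Tn = 4L) {
  set.seed(seed)
  circles <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    k <- sample(3:7, 1L)
    data.frame(id = paste0("t", t, "_", seq_len(k)), time = t,
               y = sort(runif(k, 0, 10)), stringsAsFactors = FALSE)
  }))
  segs <- do.call(rbind, lapply(seq_len(Tn - 1L), function(t) {
    a <- circles[circles$time == t, ]
    b <- circles[circles$time == t + 1L, ]
    m <- sample(4:10, 1L)
    i <- sample(nrow(a), m, replace = TRUE)
    j <- sample(nrow(b), m, replace = TRUE)
    data.frame(interval = t, y0 = a$y[i], y1 = b$y[j],
               c0 = a$id[i], c1 = b$id[j], kind = "timeline",
               origin0 = "o", origin1 = "o", stringsAsFactors = FALSE)
  }))
  segs <- unique(segs)
  structure(list(circles = circles, segments = segs,
                 ordering = "o", T = Tn),
            class = "timeline_geometry")
}

# random tracked thread set (via a small planted schedule)
random_thread_set <- function(seed, n_nodes = 150L, max_clusters = 6L) {
  sim <- generate_dynamic_partition(
    random_schedule(seed, n_nodes = n_nodes, max_clusters = max_clusters))
  tr <- track_all(sim$partition)
  db <- build_query_database(lapply(tr$maps, make_pair_table))
  list(threads = thread_sizes(extract_threads(db), sim$partition),
       maps = tr$maps, db = db)
}
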