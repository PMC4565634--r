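test_that("pair tables list retained and pseudo correspondences", {
  p <- tiny_pair()
  m <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(p$s1, p$s2))),
    p$s1, p$s2)
  pt <- make_pair_table(m)
  expect_equal(as.data.frame(pt),
               data.frame(source = c("A", "B"), target = c("X", "Y"),
                          stringsAsFactors = FALSE), ignore_attr = TRUE)

  # death contributes a Dump row; births contribute C0/C-1 rows
  s1 <- snapshot_partition(1, list(A = c("1", "2", "3"), B = c("4", "5")))
  s2 <- snapshot_partition(2, list(X = c("1", "2", "3"),
                                   Z = c("7", "8", "9"),
                                   Q = paste0("q", 1:5)))
  m2 <- attach_pseudo_clusters(
    prune_map(compute_threshold(build_bipartite_map(s1, s2))), s1, s2)
  pt2 <- make_pair_table(m2)
  expect_true(any(pt2$source == "B" & pt2$target == "Dump"))
  expect_true(any(pt2$source == "C0" & pt2$target == "Q"))
  expect_true(any(pt2$source == "C-1" & pt2$target == "Z"))
})

test_that("outer join steps cross-multiply, pad deaths and seed births", {
  db <- commtrace:::new_query_database(
    data.frame(T1 = c("A", "B"), T2 = c("X", "X"), stringsAsFactors = FALSE))
  p <- commtrace:::pair_table(c("X", "X"), c("Q", "R"), t = 2)
  db2 <- outer_join_step(db, p)
  rows <- apply(as.data.frame(db2)[, 1:3], 1, paste, collapse = ",")
  expect_setequal(rows, c("A,X,Q", "A,X,R", "B,X,Q", "B,X,R"))

  # dead thread extends with DEAD
  dbd <- commtrace:::new_query_database(
    data.frame(T1 = "B", T2 = "DUMP", stringsAsFactors = FALSE))
  db3 <- outer_join_step(dbd, commtrace:::pair_table("Z", "Z2", t = 2))
  expect_equal(unname(unlist(as.data.frame(db3)[1, 1:3])),
               c("B", "DUMP", "DEAD"))

  # a birth row starts a new thread padded with empty cells
  db4 <- outer_join_step(dbd, commtrace:::pair_table("C0", "Z", t = 2))
  born <- as.data.frame(db4)
  born <- born[born$T3 == "Z", ]
  expect_equal(unname(unlist(born[1, 1:3])), c("", "", "Z"))
  expect_match(born$origin, "^NewC")

  # interval mismatch is an error
  expect_error(outer_join_step(db, commtrace:::pair_table("X", "Q", t = 5)),
               "interval")
})

test_that("the published lineage database is reproduced by the join chain", {
  db <- read_lineage_table(published_lineage_path())
  pts <- database_pair_tables(db)
  expect_length(pts, 4L)
  rebuilt <- build_query_database(pts)
  expect_equal(as.data.frame(rebuilt), as.data.frame(db),
               ignore_attr = TRUE)

  # single pair table: database equals the table
  db1 <- build_query_database(pts[1])
  expect_equal(nrow(db1), nrow(pts[[1]]))

  # chain of pure continuations collapses to one thread
  chain <- lapply(1:3, function(t) commtrace:::pair_table("A", "A", t))
  dbc <- build_query_database(chain)
  expect_equal(nrow(dbc), 1L)
  expect_equal(unname(unlist(as.data.frame(dbc)[1, 1:4])), rep("A", 4))
})

test_that("pair tables and the database stay mutually consistent", {
  for (seed in c(2, 5, 8, 13, 21, 34, 55, 89)) {
    sim <- generate_dynamic_partition(random_schedule(seed, n_nodes = 200L,
                                                      max_clusters = 7L))
    tr <- track_all(sim$partition)
    pts <- lapply(tr$maps, make_pair_table)
    db <- build_query_database(pts)
    d <- as.data.frame(db)
    for (t in seq_along(pts)) {
      a <- d[[t]]; b <- d[[t + 1L]]
      live <- !(a %in% c("", "DEAD", "DUMP"))
      got <- unique(paste(a[live], ifelse(b[live] == "DUMP", "Dump", b[live])))
      pt <- pts[[t]]
      real <- !commtrace:::is_birth_label(pt$source)
      want <- unique(paste(pt$source[real], pt$target[real]))
      expect_setequal(got, want)
      # births: targets seeded from empty padding match the pair table
      born_db <- unique(b[a == "" & !(b %in% c("", "DEAD", "DUMP"))])
      born_pt <- pt$target[!real]
      expect_setequal(born_db, born_pt)
    }
    # thread count >= T1 clusters + births
    n_births <- sum(tr$events$type == "birth")
    expect_gte(nrow(db), sim$partition$snapshots[[1]]$n + n_births)
    # rebuild from adjacent columns and re-join: idempotent
    again <- build_query_database(database_pair_tables(db))
    expect_equal(as.data.frame(again)[, 1:attr(db, "T")],
                 d[, 1:attr(db, "T")], ignore_attr = TRUE)
  }
})

test_that("threads branch at splits and never re-collapse", {
  db <- read_lineage_table(published_lineage_path())
  th <- extract_threads(db)
  expect_setequal(th$origins, paste0("C", 1:7))
  nd <- th$nodes

  # origin C3: root splits in 2 at T2, one branch splits again at T3,
  # another at T4
  c3 <- nd[nd$origin == "C3", ]
  kids <- function(sub, id) sub$id[!is.na(sub$parent) & sub$parent == id]
  root <- c3$id[is.na(c3$parent)]
  expect_length(kids(c3, root), 2L)
  t2 <- kids(c3, root)
  n_grandkids <- vapply(t2, function(i) length(kids(c3, i)), integer(1))
  expect_setequal(n_grandkids, c(1L, 2L))
  # branch nodes per time in the C3 band: 1, 2, 3, 4, 5 at T1..T5
  # (the C1 branch splits once more at T5 into C7 and C8)
  expect_equal(as.integer(table(c3$time)), c(1L, 2L, 3L, 4L, 5L))

  # origin C2 splits at T2 into two branches that stay parallel through
  # T3..T5 despite sharing labels C5, C7, C5
  c2 <- nd[nd$origin == "C2", ]
  expect_equal(as.integer(table(c2$time)), c(1L, 2L, 2L, 2L, 2L))
  expect_equal(sort(c2$label[c2$time == 3]), c("C5", "C5"))

  # a one-row thread is a simple path
  one <- commtrace:::new_query_database(
    data.frame(T1 = "A", T2 = "B", stringsAsFactors = FALSE))
  th1 <- extract_threads(one)
  expect_equal(nrow(th1$nodes), 2L)
  expect_equal(sum(is.na(th1$nodes$parent)), 1L)
})
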