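test_that("the merge rule requires same type, same chromosome, overlap > threshold", {
  a <- make_calls("1", 1000, 1500, "DEL")
  expect_true(sv_mergeable(a, make_calls("1", 1400, 1900, "DEL")))    # overlap 100
  expect_false(sv_mergeable(a, make_calls("1", 1000, 1500, "DUP")))   # type differs
  expect_false(sv_mergeable(a, make_calls("2", 1000, 1500, "DEL")))   # chrom differs
  # overlap of exactly 25 bp fails the strict > 25 rule
  expect_false(sv_mergeable(make_calls("1", 1000, 1030, "DEL"),
    make_calls("1", 1005, 1035, "DEL")))
  expect_true(sv_mergeable(make_calls("1", 1000, 1031, "DEL"),
    make_calls("1", 1005, 1036, "DEL")))
  # insertions: breakpoint distance window
  expect_true(sv_mergeable(make_calls("1", 1000, 1000, "INS"),
    make_calls("1", 1025, 1025, "INS")))
  expect_false(sv_mergeable(make_calls("1", 1000, 1000, "INS"),
    make_calls("1", 1026, 1026, "INS")))
})

test_that("dual-caller consensus keeps doubly-called, well-supported SVs", {
  a <- make_calls("1", c(1000, 5000), c(1400, 5400), "DEL",
    support = c(5, 8), caller_id = "A")
  b <- make_calls("1", 1000, 1400, "DEL", support = 7, caller_id = "B")
  cons <- dual_caller_consensus(a, b)
  expect_equal(nrow(cons), 1)            # the 5000-5400 DEL is A-only
  expect_equal(cons$support, 7)          # max of the matched pair
  expect_equal(cons$start, 1000)
  # representative comes from the higher-support member
  b2 <- make_calls("1", 1010, 1410, "DEL", support = 9, caller_id = "B")
  expect_equal(dual_caller_consensus(a, b2)$start, 1010)
  # support ties favour caller A's record
  b3 <- make_calls("1", 1010, 1410, "DEL", support = 5, caller_id = "B")
  expect_equal(dual_caller_consensus(a, b3)$start, 1000)
  # support filter is applied per caller record before matching
  weak <- make_calls("1", 1000, 1400, "DEL", support = 2, caller_id = "B")
  expect_equal(nrow(dual_caller_consensus(a, weak)), 0)
  expect_equal(nrow(dual_caller_consensus(a, weak, min_support = 2)), 1)
  # mixed samples are rejected
  expect_error(
    dual_caller_consensus(a, make_calls("1", 1000, 1400, "DEL", sample_id = "s2")),
    "single sample")
})

test_that("greedy consensus matching equals exhaustive best assignment under jitter", {
  # 4 true SVs observed by both callers with +-10 bp jitter
  truth_start <- c(1000, 2000, 3000, 4000)
  set.seed(42)
  mk <- function(caller) {
    s <- truth_start + sample(-10:10, 4, replace = TRUE)
    make_calls("1", s, s + 300, "DEL", support = sample(3:9, 4),
      caller_id = caller)
  }
  a <- mk("A"); b <- mk("B")
  cons <- dual_caller_consensus(a, b)
  expect_equal(nrow(cons), 4)
  # brute force over all 4! one-to-one assignments, maximizing total overlap
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
    c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3),
    c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2),
    c(3,4,2,1), c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2),
    c(4,3,2,1))
  score <- apply(perms, 1, function(p) {
    sum(pmin(a$end, b$end[p]) - pmax(a$start, b$start[p])) })
  best <- perms[which.max(score), ]
  # each consensus pair must be a pair of the maximum-overlap assignment
  expect_setequal(paste(cons$a_start, cons$b_start),
    paste(a$start, b$start[best]))
})

test_that("cross-individual merging is transitive, order-invariant and idempotent", {
  # identical DEL from three samples collapses to one record with 3 carriers
  calls <- make_calls("1", 1000, 1400, "DEL", support = c(5, 6, 7),
    sample_id = c("s1", "s2", "s3"))
  merged <- merge_cohort(calls)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_carriers, 3)
  expect_equal(merged$carriers, "s1,s2,s3")
  expect_equal(merged$support, 7)   # highest-support representative

  # DEL and INV at identical coordinates never cluster
  mixed <- rbind(make_calls("1", 1000, 1400, "DEL"),
    make_calls("1", 1000, 1400, "INV", sample_id = "s2"))
  expect_equal(nrow(merge_cohort(mixed)), 2)

  # two transitive chains -> 2 clusters even though ends never meet directly
  chain <- make_calls("1",
    c(1000, 1200, 1400, 5000, 5200, 5400),
    c(1300, 1500, 1700, 5300, 5500, 5700), "DEL",
    support = 4:9, sample_id = paste0("s", 1:6))
  m <- merge_cohort(chain)
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$n_carriers), c(3, 3))

  # order invariance
  set.seed(1)
  for (rep in 1:5) {
    shuffled <- chain[sample(nrow(chain)), ]
    expect_equal(merge_cohort(shuffled), m)
  }

  # idempotence: merging the representatives reproduces the same records
  reps <- m
  reps$sample_id <- "rep"
  again <- merge_cohort(reps[, c("sample_id", "chrom", "start", "end",
    "svtype", "length", "support")])
  expect_equal(again[, c("chrom", "start", "end", "svtype")],
    m[, c("chrom", "start", "end", "svtype")])
})

test_that("clustering equals the brute-force union-find oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(sample(5:50, 1), seed = seed)
    inst$uid <- paste0("u", seq_len(nrow(inst)))
    merged <- merge_cohort(inst)
    members <- attr(merged, "members")
    got <- partition_of(members$uid, members$cluster)
    want <- partition_of(inst$uid, oracle_clusters(inst))
    expect_equal(got, want)
  }
})

test_that("raising the overlap threshold never reduces the cluster count", {
  for (seed in 1:5) {
    inst <- random_instance(40, seed = 100 + seed)
    sizes <- vapply(c(10, 25, 50, 100, 200), function(mo) {
      nrow(merge_cohort(inst, min_overlap = mo))
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("cohort filters drop singletons and the Y chromosome, with bookkeeping", {
  svs <- data.frame(
    id = sprintf("sv_%05d", 1:3),
    chrom = c("18", "Y", "1"), start = c(100L, 200L, 300L),
    end = c(400L, 500L, 600L), svtype = "DEL", length = 300L,
    support = 5L, n_carriers = c(2L, 5L, 1L),
    carriers = c("a,b", "a,b,c,d,e", "a"), stringsAsFactors = FALSE)
  expect_message(kept <- apply_cohort_filters(svs), "1 removed on Y")
  expect_equal(kept$chrom, "18")
  log <- attr(kept, "filter_log")
  expect_equal(unname(log[["records_in"]]),
    unname(log[["records_kept"]] + log[["removed_chrom"]] +
      log[["removed_min_individuals"]]))
})

test_that("type counts always sum to their total", {
  svs <- data.frame(svtype = rep(c("DEL", "DUP", "INS", "INV"), c(7, 2, 3, 1)))
  tc <- type_counts(svs)
  expect_equal(unname(tc[["total"]]), 13)
  expect_equal(unname(tc[["DEL"]]), 7)
  empty <- type_counts(character(0))
  expect_equal(unname(empty[["total"]]), 0)
})
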