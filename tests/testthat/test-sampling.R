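test_that("systematic PPS allocation is exact when the interval divides the spans", {
  frame <- make_frame(c(300, 100, 100), ids = c("A", "B", "C"))
  # interval = 100 divides every span: allocation identical for every start
  for (u in seq(0.5, 99.5, by = 4.5)) {
    alloc <- pps_systematic_sample(frame, 5, start = u)
    got <- setNames(alloc$clusters_assigned, alloc$school_id)
    expect_equal(got[c("A", "B", "C")], c(A = 3L, B = 1L, C = 1L))
  }
  # k equal schools, k clusters: each exactly once
  eq <- make_frame(rep(250, 7))
  alloc <- pps_systematic_sample(eq, 7, seed = 3)
  expect_equal(alloc$clusters_assigned, rep(1L, 7))
  # single school
  one <- pps_systematic_sample(make_frame(40), 1, seed = 1)
  expect_equal(one$clusters_assigned, 1L)
})

test_that("allocations always conserve the requested cluster count", {
  set.seed(11)
  for (rep in 1:20) {
    frame <- make_frame(sample(20:2000, sample(3:25, 1)))
    k <- sample(1:15, 1)
    alloc <- pps_systematic_sample(frame, k, seed = rep)
    expect_equal(sum(alloc$clusters_assigned), k)
    expect_equal(alloc$shortfall,
                 pmax(0L, alloc$clusters_assigned * 100L - alloc$enrollment))
  }
  expect_error(pps_systematic_sample(make_frame(5), 10), "exceeds total")
})

test_that("expected cluster counts match enrollment shares (Monte Carlo)", {
  enr <- c(120, 250, 400, 800, 1500, 300, 650, 900, 2000, 80)
  frame <- make_frame(enr)
  k <- 4
  reps <- 10000
  counts <- matrix(0, reps, length(enr))
  seeds <- seq_len(reps)
  for (r in seq_len(reps)) {
    alloc <- pps_systematic_sample(frame, k, seed = seeds[r])
    idx <- match(alloc$school_id, frame$school_id)
    counts[r, idx] <- alloc$clusters_assigned
  }
  expected <- k * enr / sum(enr)
  got <- colMeans(counts)
  se <- apply(counts, 2, sd) / sqrt(reps)
  expect_true(all(abs(got - expected) <= 3 * se + 1e-9))
})

test_that("sampling is reproducible under a fixed seed", {
  frame <- make_frame(c(500, 700, 900, 1100))
  a1 <- pps_systematic_sample(frame, 3, seed = 99)
  a2 <- pps_systematic_sample(frame, 3, seed = 99)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  sch <- data.frame(school_id = "X", enrollment = 800)
  expect_identical(second_stage_sample(sch, 100, seed = 5),
                   second_stage_sample(sch, 100, seed = 5))
})

test_that("year-group quotas use equal largest-remainder apportionment with capping", {
  sch <- data.frame(school_id = "S1", enrollment = 450,
                    yg_1 = 75, yg_2 = 75, yg_3 = 75,
                    yg_4 = 75, yg_5 = 75, yg_6 = 75)
  sel <- second_stage_sample(sch, cluster_size = 100, seed = 7)
  expect_equal(attr(sel, "yg_allocation"), c(17L, 17L, 17L, 17L, 16L, 16L))
  expect_equal(length(sel), 100L)
  expect_equal(anyDuplicated(sel), 0L)
  # a tiny year group is capped at its size, excess spread over the rest
  sch2 <- data.frame(school_id = "S2", enrollment = 410,
                     yg_1 = 10, yg_2 = 200, yg_3 = 200)
  sel2 <- second_stage_sample(sch2, cluster_size = 100, seed = 7)
  expect_equal(attr(sel2, "yg_allocation"), c(10L, 45L, 45L))
  # indices stay within their year group's roster block
  expect_true(all(sel2[1:10] <= 10))
})

test_that("undersized schools are enumerated completely with the shortfall recorded", {
  sch <- data.frame(school_id = "T", enrollment = 80)
  sel <- second_stage_sample(sch, cluster_size = 100)
  expect_equal(sort(sel), 1:80)
  expect_equal(attr(sel, "shortfall"), 20L)
  expect_error(second_stage_sample(data.frame(enrollment = 0), 100), ">= 1")
  # plain roster: exact quota of distinct indices
  big <- second_stage_sample(data.frame(enrollment = 1000), 100, seed = 2)
  expect_equal(length(big), 100L)
  expect_equal(anyDuplicated(big), 0L)
  expect_equal(attr(big, "shortfall"), 0L)
})

test_that("the two-stage design is self-weighting in expectation", {
  frame <- make_frame(c(150, 200, 300, 400, 500, 450))
  k <- 4; m <- 100
  p_tab <- inclusion_probability(frame, k, m)
  expect_equal(p_tab$p_child, rep(k * m / 2000, 6))
  expect_false(any(p_tab$undersized | p_tab$certainty))
  expect_equal(inclusion_probability(frame, k, m, school_id = "S03"), 0.2)
  # linearity in the number of clusters (2 -> 4 keeps every school
  # below the sampling interval)
  expect_equal(inclusion_probability(frame, 4, m)$p_child,
               2 * inclusion_probability(frame, 2, m)$p_child)

  # Monte Carlo: empirical frequency of a fixed child per school
  reps <- 3000
  hit <- matrix(0L, reps, nrow(frame))
  target <- c(75L, 10L, 250L, 399L, 1L, 225L)  # arbitrary fixed pupil per school
  for (r in seq_len(reps)) {
    alloc <- pps_systematic_sample(frame, k, cluster_size = m, seed = r)
    for (i in seq_len(nrow(alloc))) {
      row <- match(alloc$school_id[i], frame$school_id)
      sel <- second_stage_sample(frame[row, , drop = FALSE], m,
                                 clusters_assigned = alloc$clusters_assigned[i],
                                 seed = r * 31L + row)
      if (target[row] %in% sel) hit[r, row] <- 1L
    }
  }
  freq <- colMeans(hit)
  se <- sqrt(0.2 * 0.8 / reps)
  expect_true(all(abs(freq - 0.2) <= 3 * se))
})

test_that("inclusion probability flags the irregular school sizes", {
  frame <- make_frame(c(60, 3000, 400, 500))  # interval at k=2 is 1980
  tab <- inclusion_probability(frame, 2, 100)
  expect_true(tab$undersized[1])
  expect_true(tab$certainty[2])
  expect_true(is.na(tab$p_child[2]))
  # undersized: census at stage two, probability k*e/N
  expect_equal(tab$p_child[1], 2 * 60 / 3960)
  expect_error(inclusion_probability(frame, 2, 100, school_id = "S02"),
               "certainty")
  expect_error(inclusion_probability(frame, 2, 100, school_id = "ZZ"),
               "not in frame")
})
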