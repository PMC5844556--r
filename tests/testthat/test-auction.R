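ptable <- function(id, pvals, len, x_max)
  structure(list(contig_id = id, pvals = pvals, contig_len_px = len,
                 x_max = x_max), class = "cb_pvaltable")

test_that("bids use -2 ln p strictly below the threshold", {
  x_max <- 10L
  pv <- rep(0.5, 20)
  pv[3] <- exp(-1)          # score exactly 2
  pv[7] <- 0.01             # at threshold: no bid
  pv[15] <- 0.001           # flipped orientation, start 5
  bids <- build_bids(list(ptable("c1", pv, 4L, x_max)), p_thresh = 0.5)
  expect_equal(nrow(bids), 3L)  # p = 0.5 entries are not < 0.5
  b3 <- bids[bids$x_start == 3 & bids$orientation == "forward", ]
  expect_equal(b3$score, 2)
  expect_equal(b3$x_end, 6L)

  strict <- build_bids(list(ptable("c1", pv, 4L, x_max)), p_thresh = 0.01)
  expect_equal(nrow(strict), 1L)   # only p = 0.001 survives
  expect_equal(strict$orientation, "flipped")
  expect_equal(strict$x_start, 5L)

  none <- build_bids(list(ptable("c1", rep(0.9, 20), 4L, x_max)),
                     p_thresh = 0.01)
  expect_equal(nrow(none), 0L)
})

test_that("wrapped intervals are flagged and pixelized correctly", {
  pv <- rep(0.5, 16)
  pv[7] <- 1e-4             # start 7, length 4 on an 8-px circle: wraps
  bids <- build_bids(list(ptable("c1", pv, 4L, 8L)), p_thresh = 0.01)
  expect_true(bids$wrapped)
  expect_equal(bids$x_end, 2L)
  expect_equal(cbscaffold:::bid_pixels(7L, 2L, 8L), c(7L, 8L, 1L, 2L))
})

test_that("single bids and at-most-once bidders resolve trivially", {
  one <- data.frame(bidder = "a", x_start = 3L, x_end = 7L,
                    length_px = 5L, orientation = "forward",
                    p_value = 0.001, score = 5, wrapped = FALSE)
  sol <- solve_auction_exact(one, 20L, circular = FALSE)
  expect_equal(sol$total_score, 5)
  expect_equal(nrow(sol$placements), 1L)
  expect_equal(filling_fraction(sol), 5 / 20)

  two <- rbind(one, data.frame(bidder = "a", x_start = 12L, x_end = 16L,
                               length_px = 5L, orientation = "forward",
                               p_value = 1e-4, score = 9, wrapped = FALSE))
  sol2 <- solve_auction_exact(two, 20L, circular = FALSE)
  expect_equal(sol2$total_score, 9)   # disjoint, but one bid per bidder
  expect_equal(sol2$placements$x_start, 12L)

  empty <- build_bids(list(), p_thresh = 0.01)
  sol0 <- brute_force_auction(empty, 10L)
  expect_equal(sol0$total_score, 0)
  expect_equal(nrow(sol0$placements), 0L)
})

test_that("exact solver equals brute force on seeded random instances", {
  for (seed in 1:120) {
    inst <- random_auction_instance(seed)
    got <- solve_auction_exact(inst$bids, inst$x_max, inst$circular)
    want <- brute_force_auction(inst$bids, inst$x_max, inst$circular)
    expect_equal(got$total_score, want$total_score, tolerance = 1e-9)
    # identical placement sets under the shared tie rule
    expect_equal(got$placements[order(got$placements$bidder), ],
                 want$placements[order(want$placements$bidder), ],
                 ignore_attr = TRUE)
    # feasibility: solver already asserts occupancy/bidder internally
    expect_true(all(table(got$placements$bidder) <= 1))
  }
})

test_that("solutions dominate a greedy baseline", {
  for (seed in 201:230) {
    inst <- random_auction_instance(seed)
    sol <- solve_auction_exact(inst$bids, inst$x_max, inst$circular)
    # greedy: take bids in decreasing score order when feasible
    occ <- logical(inst$x_max)
    used <- character(0)
    g <- 0
    for (i in order(-inst$bids$score)) {
      px <- cbscaffold:::bid_pixels(inst$bids$x_start[i],
                                    inst$bids$x_end[i], inst$x_max)
      if (!any(occ[px]) && !(inst$bids$bidder[i] %in% used)) {
        occ[px] <- TRUE
        used <- c(used, inst$bids$bidder[i])
        g <- g + inst$bids$score[i]
      }
    }
    expect_gte(sol$total_score, g - 1e-9)
  }
})

test_that("instances split at bid-free gaps solve to the same total", {
  set.seed(301)
  mk <- function(offset, tag) {
    do.call(rbind, lapply(1:3, function(b) data.frame(
      bidder = sprintf("%s%d", tag, b),
      x_start = offset + sample(0:6, 1), x_end = 0L, length_px = 0L,
      orientation = "forward", p_value = NA_real_,
      score = round(runif(1, 1, 5), 2), wrapped = FALSE)))
  }
  left <- mk(1L, "L"); right <- mk(30L, "R")
  both <- rbind(left, right)
  both$length_px <- sample(3:5, nrow(both), replace = TRUE)
  both$x_end <- both$x_start + both$length_px - 1L
  whole <- solve_auction_exact(both, 60L, circular = FALSE)
  parts <- solve_auction_exact(both[1:3, ], 60L, circular = FALSE)$total_score +
    solve_auction_exact(both[4:6, ], 60L, circular = FALSE)$total_score
  expect_equal(whole$total_score, parts)
})

test_that("adding a non-overlapping positive bid never lowers the optimum", {
  for (seed in 401:420) {
    inst <- random_auction_instance(seed, circular = FALSE)
    base <- solve_auction_exact(inst$bids, inst$x_max, FALSE)
    cov <- logical(inst$x_max)
    for (i in seq_len(nrow(inst$bids)))
      cov[cbscaffold:::bid_pixels(inst$bids$x_start[i], inst$bids$x_end[i],
                                  inst$x_max)] <- TRUE
    free <- which(!cov)
    if (!length(free)) next
    s <- free[1]
    extra <- data.frame(bidder = "zz_new", x_start = s, x_end = s,
                        length_px = 1L, orientation = "forward",
                        p_value = NA_real_, score = 0.7, wrapped = FALSE)
    more <- solve_auction_exact(rbind(inst$bids, extra), inst$x_max, FALSE)
    expect_gte(more$total_score, base$total_score - 1e-9)
  }
})

test_that("complexity estimates match the instance structure", {
  expect_equal(estimate_complexity(build_bids(list()), 10L),
               c(A = 0, B = 0, C = 0))

  one <- data.frame(bidder = "a", x_start = c(1L, 6L), x_end = c(3L, 9L),
                    length_px = c(3L, 4L), orientation = "forward",
                    p_value = NA, score = 1, wrapped = FALSE)
  expect_lte(estimate_complexity(one, 20L)[["C"]], 1)
  expect_equal(estimate_complexity(one, 20L)[["A"]], 1)
  expect_equal(estimate_complexity(one, 20L)[["B"]], 7)  # 1:3 and 6:9

  # two independent clusters of 3 bidders each, separated by a gap
  cl <- function(off, tag) do.call(rbind, lapply(1:3, function(b)
    data.frame(bidder = paste0(tag, b), x_start = off + b,
               x_end = off + b + 2L, length_px = 3L,
               orientation = "forward", p_value = NA, score = 1,
               wrapped = FALSE)))
  inst <- rbind(cl(0L, "p"), cl(30L, "q"))
  expect_lte(estimate_complexity(inst, 60L)[["C"]], 3)
})

test_that("over-entangled instances fail loudly instead of silently", {
  inst <- random_auction_instance(7, circular = FALSE, max_bidders = 8L)
  expect_error(solve_auction_exact(inst$bids, inst$x_max, FALSE,
                                   max_mask_bits = 1L), "entangled")
})
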