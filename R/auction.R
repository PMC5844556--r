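#' Build placement bids from p-value tables
#'
#' A contig bids for the interval of reference pixels it would occupy at
#' every position/orientation whose p-value clears the threshold
#' (strictly `p < p_thresh`); the bid score is the Fisher-style transform
#' `-2 * log(p)` (natural log), which is positive by construction.
#' Positions at or above the threshold produce no bid.
#'
#' @param pvalue_tables list of per-contig p-value tables as produced by the
#'   pipeline: each a list with `contig_id`, `pvals` (length `2 * x_max`),
#'   `contig_len_px`, `x_max`.
#' @param lengths_px optional named vector of contig lengths in pixels,
#'   overriding the per-table `contig_len_px`.
#' @param p_thresh significance threshold in (0, 1), default 0.01.
#' @return data.frame of bids: `bidder`, `x_start`, `x_end`, `length_px`,
#'   `orientation`, `p_value`, `score`, `wrapped`. `x_end` is the last pixel
#'   of the interval on the circular reference; `wrapped` flags intervals
#'   crossing the origin.
#' @export
build_bids <- function(pvalue_tables, lengths_px = NULL, p_thresh = 0.01) {
  stopifnot(p_thresh > 0, p_thresh < 1)
  out <- list()
  for (tb in pvalue_tables) {
    x_max <- tb$x_max
    len <- if (!is.null(lengths_px)) lengths_px[[tb$contig_id]] else
      tb$contig_len_px
    hit <- which(tb$pvals < p_thresh)
    if (!length(hit)) next
    start <- mod1(hit, x_max)
    p <- tb$pvals[hit]
    out[[length(out) + 1L]] <- data.frame(
      bidder = tb$contig_id,
      x_start = start,
      x_end = mod1(start + len - 1L, x_max),
      length_px = len,
      orientation = ifelse(hit <= x_max, "forward", "flipped"),
      p_value = p,
      score = -2 * log(p),
      wrapped = start + len - 1L > x_max,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(bidder = character(0), x_start = integer(0),
                      x_end = integer(0), length_px = integer(0),
                      orientation = character(0), p_value = numeric(0),
                      score = numeric(0), wrapped = logical(0)))
  do.call(rbind, out)
}

bid_pixels <- function(s, e, x_max) {
  if (s <= e) s:e else c(s:x_max, 1:e)
}

# Deterministic tie-break signature of a placement set: the lexicographically
# smallest (bidder, x_end, forward-first) set wins among equal scores.
placement_sig <- function(bids, rows) {
  if (!length(rows)) return("")
  paste(sort(sprintf("%s|%09d|%d", bids$bidder[rows], bids$x_end[rows],
                     ifelse(bids$orientation[rows] == "forward", 0L, 1L))),
        collapse = ";")
}

translate_mask <- function(mask, from, to) {
  if (mask == 0L || !length(from)) return(0L)
  out <- 0L
  for (b in seq_along(from)) {
    if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
      j <- match(from[b], to)
      if (!is.na(j)) out <- bitwOr(out, bitwShiftL(1L, j - 1L))
    }
  }
  out
}

# Exact DP for the linear (non-wrapping) interval-bidding auction.
#
# Sweep distinct bid end-positions in increasing order (positions without
# ending bids cost nothing). The state is the subset of already-served
# bidders among the currently "relevant" ones: a bidder is relevant from its
# first bid end until its last bid end; outside that span its service bit
# carries no information and is dropped (states merging by max), which keeps
# the bitmask narrow when bids cluster. Choosing a bid [s, e] continues from
# the best states at position s - 1.
solve_linear_auction <- function(bids, rows, max_mask_bits) {
  bd <- data.frame(idx = rows, bidder = bids$bidder[rows],
                   s = bids$x_start[rows], e = bids$x_end[rows],
                   score = bids$score[rows], stringsAsFactors = FALSE)
  if (nrow(bd) == 0L) return(list(score = 0, rows = integer(0)))
  ord <- order(bd$e, bd$bidder, bd$s,
               bids$orientation[bd$idx] != "forward")
  bd <- bd[ord, , drop = FALSE]
  sig <- function(r) placement_sig(bids, r)

  ends <- sort(unique(bd$e))
  fe <- tapply(bd$e, bd$bidder, min)
  le <- tapply(bd$e, bd$bidder, max)
  all_bidders <- names(fe)
  layouts <- vector("list", length(ends))
  dicts <- vector("list", length(ends))

  better <- function(v, r, old_v, old_r) {
    if (is.null(old_v) || v > old_v) return(TRUE)
    v == old_v && sig(r) < sig(old_r)
  }

  for (t in seq_along(ends)) {
    pos <- ends[t]
    lay <- sort(all_bidders[fe <= pos & le >= pos])
    if (length(lay) > max_mask_bits)
      stop("instance too entangled: ", length(lay), " simultaneously ",
           "relevant bidders exceed the ", max_mask_bits,
           "-bit working-set bound; raise max_mask_bits if feasible")
    layouts[[t]] <- lay

    sc <- numeric(0)
    rw <- list()
    put <- function(mask, v, r) {
      k <- as.character(mask)
      if (better(v, r, if (k %in% names(sc)) sc[[k]] else NULL, rw[[k]])) {
        sc[[k]] <<- v
        rw[[k]] <<- r
      }
    }
    if (t == 1L) {
      put(0L, 0, integer(0))
    } else {
      prev <- dicts[[t - 1L]]
      playout <- layouts[[t - 1L]]
      for (key in names(prev$score))
        put(translate_mask(as.integer(key), playout, lay),
            prev$score[[key]], prev$rows[[key]])
    }

    for (bi in which(bd$e == pos)) {
      s <- bd$s[bi]
      n <- bd$bidder[bi]
      w <- bd$score[bi]
      tp <- findInterval(s - 1L, ends)
      if (tp == 0L) {
        pl <- character(0)
        psc <- setNames(0, "0")
        prw <- list(`0` = integer(0))
      } else {
        pl <- layouts[[tp]]
        psc <- dicts[[tp]]$score
        prw <- dicts[[tp]]$rows
      }
      nbit_prev <- match(n, pl)
      nbit_now <- match(n, lay)
      for (key in names(psc)) {
        mask <- as.integer(key)
        if (!is.na(nbit_prev) &&
            bitwAnd(mask, bitwShiftL(1L, nbit_prev - 1L)) != 0L) next
        newmask <- bitwOr(translate_mask(mask, pl, lay),
                          bitwShiftL(1L, nbit_now - 1L))
        put(newmask, psc[[key]] + w, c(prw[[key]], bd$idx[bi]))
      }
    }
    dicts[[t]] <- list(score = sc, rows = rw)
  }

  fin <- dicts[[length(ends)]]
  best_v <- max(fin$score)
  cand <- names(fin$score)[fin$score == best_v]
  best_r <- fin$rows[[cand[1L]]]
  for (k in cand[-1L])
    if (sig(fin$rows[[k]]) < sig(best_r)) best_r <- fin$rows[[k]]
  list(score = best_v, rows = best_r)
}

make_placement <- function(bids, rows, x_max) {
  occupied <- logical(x_max)
  if (length(rows)) {
    ord <- order(bids$bidder[rows], bids$x_end[rows],
                 bids$orientation[rows] != "forward")
    rows <- rows[ord]
    for (r in rows) {
      px <- bid_pixels(bids$x_start[r], bids$x_end[r], x_max)
      if (any(occupied[px])) stop("internal error: pixel collision")
      occupied[px] <- TRUE
    }
    if (anyDuplicated(bids$bidder[rows]))
      stop("internal error: bidder placed twice")
  }
  placements <- bids[rows, c("bidder", "x_start", "x_end", "length_px",
                             "orientation", "p_value", "score", "wrapped")]
  rownames(placements) <- NULL
  structure(list(placements = placements,
                 total_score = if (length(rows)) sum(bids$score[rows]) else 0,
                 occupied = occupied, x_max = x_max),
            class = "cb_placement")
}

#' @export
print.cb_placement <- function(x, ...) {
  cat(sprintf("<cb_placement> %d contig(s) placed, total score %.3f, filling fraction %.3f\n",
              nrow(x$placements), x$total_score, mean(x$occupied)))
  if (nrow(x$placements)) print(x$placements)
  invisible(x)
}

#' Solve the non-overlapping placement problem exactly
#'
#' Maximizes the summed placement score over all assignments in which each
#' pixel of the reference is covered at most once and each contig (bidder)
#' wins at most one interval, by an exact interval-bidding
#' combinatorial-auction dynamic program. Two structural speedups keep it
#' fast: positions without ending bids are skipped, and the bitmask state
#' only spans the currently relevant bidders. A circular reference is
#' handled exactly by conditioning on the content of the cut between the
#' last and first pixel: either no interval crosses it (one linear solve) or
#' a specific wrapping bid does (one linear solve per wrapping bid).
#'
#' Equal-score optima are resolved to the lexicographically smallest
#' (bidder, x_end, forward-first) placement set, so results are
#' reproducible.
#'
#' @param bids a bid data.frame from [build_bids()] (all scores > 0).
#' @param x_max number of pixels of the reference.
#' @param circular is the reference circular?
#' @param max_mask_bits guard on the relevant-bidder working set; instances
#'   needing a wider bitmask raise an "instance too entangled" error rather
#'   than returning a heuristic answer.
#' @return object of class `cb_placement`: `placements` (data.frame),
#'   `total_score`, `occupied` (logical pixel map), `x_max`.
#' @export
empty_bids <- function()
  data.frame(bidder = character(0), x_start = integer(0),
             x_end = integer(0), length_px = integer(0),
             orientation = character(0), p_value = numeric(0),
             score = numeric(0), wrapped = logical(0))

solve_auction_exact <- function(bids, x_max, circular = TRUE,
                                max_mask_bits = 20L) {
  stopifnot(x_max >= 1)
  if (is.null(bids) || !nrow(bids)) bids <- empty_bids()
  if (nrow(bids)) {
    stopifnot(all(bids$score > 0), all(bids$x_end >= 1),
              all(bids$x_end <= x_max), all(bids$length_px <= x_max))
    if (!circular && any(bids$wrapped))
      stop("wrapped bids are impossible on a linear reference")
  }
  rows_all <- seq_len(nrow(bids))
  straight <- rows_all[!bids$wrapped[rows_all]]
  best <- solve_linear_auction(bids, straight, max_mask_bits)

  if (circular) {
    wrapped <- rows_all[bids$wrapped[rows_all]]
    for (k in wrapped) {
      kpix <- bid_pixels(bids$x_start[k], bids$x_end[k], x_max)
      # remaining bids: other bidders, not wrapped, inside the free arc
      ok <- straight[bids$bidder[straight] != bids$bidder[k] &
                       bids$x_start[straight] > bids$x_end[k] &
                       bids$x_end[straight] < bids$x_start[k]]
      sub <- solve_linear_auction(bids, ok, max_mask_bits)
      v <- sub$score + bids$score[k]
      r <- c(sub$rows, k)
      if (v > best$score ||
          (v == best$score &&
             placement_sig(bids, r) < placement_sig(bids, best$rows)))
        best <- list(score = v, rows = r)
    }
  }
  make_placement(bids, best$rows, x_max)
}

#' Exhaustive reference solver for small auction instances
#'
#' Enumerates, with pruning, every feasible assignment (each bidder takes
#' one of its bids or none) and returns the optimum under the same tie rule
#' as [solve_auction_exact()]. Exists as an independent correctness oracle;
#' guarded against large instances.
#'
#' @inheritParams solve_auction_exact
#' @param max_bidders,max_px size guards.
#' @return a `cb_placement`.
#' @export
brute_force_auction <- function(bids, x_max, circular = TRUE,
                                max_bidders = 12L, max_px = 80L) {
  if (is.null(bids) || !nrow(bids)) bids <- empty_bids()
  if (!circular && nrow(bids) && any(bids$wrapped))
    stop("wrapped bids are impossible on a linear reference")
  bidders <- unique(bids$bidder)
  if (length(bidders) > max_bidders || x_max > max_px)
    stop("instance too large for the brute-force oracle")
  bybidder <- lapply(bidders, function(b) which(bids$bidder == b))
  pix <- lapply(seq_len(nrow(bids)), function(r)
    bid_pixels(bids$x_start[r], bids$x_end[r], x_max))

  best_v <- 0
  best_r <- integer(0)
  best_s <- ""
  recurse <- function(i, occ, rows, v) {
    if (i > length(bybidder)) {
      s <- placement_sig(bids, rows)
      if (v > best_v || (v == best_v && s < best_s)) {
        best_v <<- v; best_r <<- rows; best_s <<- s
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, occ, rows, v)
    for (r in bybidder[[i]]) {
      if (!any(occ[pix[[r]]])) {
        occ2 <- occ
        occ2[pix[[r]]] <- TRUE
        recurse(i + 1L, occ2, c(rows, r), v + bids$score[r])
      }
    }
  }
  recurse(1L, logical(x_max), integer(0), 0)
  make_placement(bids, best_r, x_max)
}

#' Effective size of an auction instance
#'
#' Reports the quantities governing the DP cost (which scales as
#' `A * B^2 * 2^C`): `A` = number of bidders with at least one bid, `B` =
#' number of reference pixels carrying at least one bid (gaps excluded), and
#' `C` = the maximum number of simultaneously relevant bidders across the
#' sweep (an upper bound on the bitmask width actually used).
#'
#' @inheritParams solve_auction_exact
#' @return named numeric vector `c(A = , B = , C = )`.
#' @export
estimate_complexity <- function(bids, x_max) {
  if (is.null(bids) || !nrow(bids)) return(c(A = 0, B = 0, C = 0))
  A <- length(unique(bids$bidder))
  cov <- logical(x_max)
  for (r in seq_len(nrow(bids)))
    cov[bid_pixels(bids$x_start[r], bids$x_end[r], x_max)] <- TRUE
  B <- sum(cov)
  fe <- tapply(bids$x_end, bids$bidder, min)
  le <- tapply(bids$x_end, bids$bidder, max)
  C <- max(vapply(sort(unique(bids$x_end)),
                  function(e) sum(fe <= e & le >= e), 0L))
  c(A = A, B = B, C = C)
}
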