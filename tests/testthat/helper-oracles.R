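# Independent oracles and small fixture builders used across the suite.

# Brute-force configuration enumeration for the two-ligand lattice model:
# every subset of non-overlapping placements, weight = product of per-ligand
# weights. Species 1 is the fluorophore (coverage reported). Feasible for
# L <= ~16.
brute_lattice <- function(L, foot, w, circular) {
  placements <- list()
  for (s in seq_along(foot)) {
    maxstart <- if (circular) L else L - foot[s] + 1L
    if (foot[s] > L) maxstart <- 0L
    for (j in seq_len(max(0L, maxstart))) {
      if (w[[s]][j] <= 0) next
      pix <- ((j - 1L + seq_len(foot[s]) - 1L) %% L) + 1L
      placements[[length(placements) + 1L]] <-
        list(species = s, pix = pix, w = w[[s]][j])
    }
  }
  Z <- 0
  covY <- numeric(L)
  rec <- function(i, occ, weight, ypix) {
    if (i > length(placements)) {
      Z <<- Z + weight
      if (length(ypix)) covY[ypix] <<- covY[ypix] + weight
      return(invisible(NULL))
    }
    rec(i + 1L, occ, weight, ypix)
    p <- placements[[i]]
    if (!any(occ[p$pix])) {
      occ2 <- occ
      occ2[p$pix] <- TRUE
      rec(i + 1L, occ2, weight * p$w,
          if (p$species == 1L) c(ypix, p$pix) else ypix)
    }
  }
  rec(1L, logical(L), 1, integer(0))
  list(logZ = log(Z), p_yoyo = covY / Z)
}

# Per-bp YOYO coverage from the installed transfer matrix, on raw weights
# (bypasses the sequence layer so arbitrary random constants can be tested).
tm_coverage <- function(L, foot, w, circular) {
  wx <- w
  if (!circular) {
    for (s in seq_along(foot))
      if (foot[s] > 1L && foot[s] <= L)
        wx[[s]][(L - foot[s] + 2L):L] <- 0
  }
  res <- cbscaffold:::lattice_occupancy_cpp(L, foot, wx, circular)
  list(logZ = res$logZ,
       p_yoyo = cbscaffold:::coverage_from_starts(res$pstart[[1L]],
                                                  foot[1L], circular))
}

random_lattice_case <- function(seed) {
  set.seed(seed)
  L <- sample(6:16, 1L)
  foot <- sample(2:4, 2L, replace = TRUE)
  circular <- runif(1) < 0.5
  w <- list(runif(L, 0, 4), runif(L, 0, 4))
  list(L = L, foot = foot, circular = circular, w = w)
}

# Random auction instance with wrapped bids allowed on circular references.
random_auction_instance <- function(seed, circular = NULL,
                                    max_bidders = 8L) {
  set.seed(seed)
  x_max <- sample(20:60, 1L)
  if (is.null(circular)) circular <- runif(1) < 0.5
  nb <- sample(2:max_bidders, 1L)
  rows <- list()
  for (b in seq_len(nb)) {
    for (k in seq_len(sample(1:3, 1L))) {
      len <- sample(3:min(25L, x_max), 1L)
      s <- sample.int(x_max, 1L)
      e_raw <- s + len - 1L
      wrapped <- e_raw > x_max
      if (wrapped && !circular) next
      rows[[length(rows) + 1L]] <- data.frame(
        bidder = sprintf("b%02d", b), x_start = s,
        x_end = ((e_raw - 1L) %% x_max) + 1L, length_px = len,
        orientation = sample(c("forward", "flipped"), 1L),
        p_value = NA_real_, score = round(runif(1, 0.5, 10), 3),
        wrapped = wrapped, stringsAsFactors = FALSE)
    }
  }
  bids <- do.call(rbind, rows)
  if (is.null(bids)) bids <- cbscaffold:::empty_bids()
  list(bids = bids, x_max = x_max, circular = circular)
}

# Small deterministic reference barcode (circular) built from a seeded
# random genome; cached per session to keep tests fast.
local({
  env <- new.env(parent = emptyenv())
  assign("ref_cache", env, envir = topenv())
})

tiny_reference <- function(len_bp = 60000, seed = 701, noise_sd = 0) {
  key <- sprintf("%d_%d_%g", len_bp, seed, noise_sd)
  if (is.null(ref_cache[[key]])) {
    g <- random_genome(len_bp, seed = seed, id = sprintf("g%d", seed))
    ref_cache[[key]] <- list(
      genome = g,
      ref = pseudo_experimental_barcode(g, noise_sd = noise_sd,
                                        seed = seed + 1L))
  }
  ref_cache[[key]]
}
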