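params_for <- function(KY = 26, cY = 0.5, cN = 6, cdna = 0.4,
                       tab = default_binding_constants())
  ligand_params(netropsin_constants = tab, K_yoyo = KY,
                conc_yoyo_total = cY, conc_netropsin_total = cN,
                conc_dna = cdna)

test_that("free concentrations reduce to totals without DNA or binding", {
  sq <- dna_sequence("ACGTACGTACGT")
  p0 <- params_for(cdna = 0)
  expect_equal(unname(free_concentrations(p0, sq)), c(0.5, 6))
  tab0 <- setNames(rep(0, 256), names(default_binding_constants()))
  pK0 <- params_for(KY = 0, tab = tab0)
  expect_equal(unname(free_concentrations(pK0, sq)), c(0.5, 6))
})

test_that("free concentrations match a scalar Langmuir oracle on a single-footprint lattice", {
  # one ligand (YOYO only), sequence length = footprint: exactly one
  # placement, occupancy theta = w / (1 + w), bound conc = theta / L * c_dna
  tab0 <- setNames(rep(0, 256), names(default_binding_constants()))
  p <- params_for(KY = 8, cY = 0.3, cN = 0, cdna = 2, tab = tab0)
  sq <- dna_sequence("ACGT")
  got <- free_concentrations(p, sq)

  f <- function(cf) {
    th <- 8 * cf / (1 + 8 * cf)
    0.3 - cf - th / 4 * 2
  }
  lo <- 0; hi <- 0.3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(unname(got[["yoyo"]]), lo, tolerance = 1e-7)
  expect_equal(unname(got[["netropsin"]]), 0)
})

test_that("mass balance holds at the solution", {
  sq <- random_genome(3000, seed = 31, circular = FALSE, id = "mb")
  p <- params_for()
  cf <- free_concentrations(p, sq)
  st <- cbscaffold:::lattice_stats(sq, p, cf[["yoyo"]], cf[["netropsin"]])
  bound <- c(sum(st$pstart_yoyo), sum(st$pstart_netropsin)) / st$L * 0.4
  expect_equal(unname(cf + bound), c(0.5, 6), tolerance = 1e-7)
})

test_that("transfer matrix equals brute-force enumeration on random lattices", {
  for (seed in 1:40) {
    cs <- random_lattice_case(seed)
    got <- tm_coverage(cs$L, cs$foot, cs$w, cs$circular)
    want <- brute_lattice(cs$L, cs$foot,
                          local({
                            w <- cs$w
                            if (!cs$circular)
                              for (s in 1:2)
                                if (cs$foot[s] > 1L)
                                  w[[s]][(cs$L - cs$foot[s] + 2L):cs$L] <- 0
                            w
                          }), cs$circular)
    expect_equal(got$logZ, want$logZ, tolerance = 1e-10)
    expect_equal(got$p_yoyo, want$p_yoyo, tolerance = 1e-10)
  }
})

test_that("binding probabilities stay in [0, 1] under parameter sweeps", {
  set.seed(11)
  for (i in 1:10) {
    sq <- random_genome(sample(50:300, 1), gc_content = runif(1, 0.2, 0.8),
                        circular = runif(1) < 0.5, seed = 100 + i, id = "s")
    p <- params_for(KY = runif(1, 0, 60), cY = runif(1, 0, 3),
                    cN = runif(1, 0, 20), cdna = runif(1, 0, 2))
    cf <- free_concentrations(p, sq)
    pb <- yoyo_binding_profile(sq, p, cf[["yoyo"]], cf[["netropsin"]])
    expect_true(all(pb >= 0 & pb <= 1))
  }
})

test_that("occupancy is monotone in the competing free concentrations", {
  sq <- random_genome(200, seed = 5, circular = FALSE, id = "m")
  p <- params_for()
  base <- yoyo_binding_profile(sq, p, 0.4, 5)
  up_y <- yoyo_binding_profile(sq, p, 0.8, 5)
  up_n <- yoyo_binding_profile(sq, p, 0.4, 10)
  expect_true(all(up_y >= base - 1e-12))
  expect_true(all(up_n <= base + 1e-12))
})

test_that("netropsin outcompetes YOYO on AT-rich sequence at high concentration", {
  sq <- dna_sequence(strrep("AT", 30))
  p <- params_for()
  pb <- yoyo_binding_profile(sq, p, 0.5, 1e5)
  expect_true(all(pb < 1e-3))
})

test_that("palindromic sequences give mirror-symmetric profiles", {
  half <- "ACGGTCA"
  sq <- dna_sequence(paste0(half, revcomp <- cbscaffold:::revcomp_bases(half)))
  p <- params_for()
  pb <- yoyo_binding_profile(sq, p, 0.5, 6)
  expect_equal(pb, rev(pb), tolerance = 1e-12)
})

test_that("PSF blur: identity at sigma 0, mean-conserving, impulse response", {
  x <- c(1, 0, 0, 2, 5, 0, 0, 1)
  expect_identical(apply_psf(x, 0, circular = TRUE), x)
  const <- rep(3.5, 100)
  expect_equal(apply_psf(const, 7, circular = FALSE), const,
               tolerance = 1e-12)
  # circular mean conservation is exact
  set.seed(2)
  y <- runif(200)
  expect_equal(mean(apply_psf(y, 12, circular = TRUE)), mean(y),
               tolerance = 1e-12)
  # unit impulse on a circle -> the sampled (radius-4-sigma) kernel,
  # centered at the impulse, sum preserved
  imp <- numeric(101); imp[51] <- 1
  sm <- apply_psf(imp, 3, circular = TRUE)
  r <- ceiling(4 * 3)
  k <- dnorm(-r:r, sd = 3); k <- k / sum(k)
  offset <- ((seq_len(101) - 51 + 50) %% 101) - 50  # circular offset to peak
  want <- numeric(101)
  want[abs(offset) <= r] <- k[offset[abs(offset) <= r] + r + 1]
  expect_lt(max(abs(sm - want)), 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("pixel downsampling: identity, constants, and ramp block means", {
  x <- rnorm(50)
  expect_equal(to_pixel_resolution(x, 1)$values, x)
  cst <- rep(2, 100)
  bc <- to_pixel_resolution(cst, 10)
  expect_equal(bc$n_px, 10L)
  expect_equal(bc$values, rep(2, 10))
  ramp <- seq_len(100)
  blocks <- to_pixel_resolution(ramp, 10, method = "block")$values
  oracle <- vapply(1:10, function(j) mean(ramp[(10 * j - 9):(10 * j)]), 0)
  expect_equal(blocks, oracle)
  interp <- to_pixel_resolution(ramp, 10, method = "interp")$values
  expect_equal(interp, oracle)  # linear signal: interpolation = block mean
  expect_error(to_pixel_resolution(c(1, 2), 10), "shorter")
})

test_that("circular and linear barcodes agree away from the ends", {
  g <- random_genome(30000, seed = 77, circular = TRUE, id = "cl")
  glin <- g; glin$circular <- FALSE
  p <- params_for()
  bc_c <- sequence_to_barcode(g, p)
  bc_l <- sequence_to_barcode(glin, p)
  mid <- 15:45  # interior pixels, several PSF widths from either end
  expect_equal(bc_c$values[mid], bc_l$values[mid], tolerance = 1e-4)
})

test_that("rotating a circular sequence rotates its barcode", {
  g <- random_genome(20000, seed = 78, circular = TRUE, id = "rot")
  shift_bp <- 5000   # 10 pixels at 500 bp/px
  g2 <- g
  g2$bases <- paste0(substr(g$bases, shift_bp + 1, 20000),
                     substr(g$bases, 1, shift_bp))
  p <- params_for()
  b1 <- sequence_to_barcode(g, p)$values
  b2 <- sequence_to_barcode(g2, p)$values
  expect_equal(b2, c(b1[11:40], b1[1:10]), tolerance = 1e-9)
})

test_that("GC-rich homopolymer barcodes are brighter than AT-rich ones", {
  p <- params_for()
  at <- sequence_to_barcode(dna_sequence(strrep("AT", 10000)), p)
  gc <- sequence_to_barcode(dna_sequence(strrep("GC", 10000)), p)
  expect_gt(mean(gc$values), mean(at$values))
})

test_that("input validation: short linear sequences and bad alphabets error", {
  expect_error(yoyo_binding_profile(dna_sequence("ACG"), params_for(),
                                    0.5, 6), "footprint")
  expect_error(dna_sequence("ACGN"), "ACGT")
})

test_that("barcode TSV round-trips values and metadata", {
  bc <- barcode(c(0.1, 0.5, 0.2), bp_per_px = 500, psf_sigma_bp = 1000,
                circular = TRUE, id = "x")
  f <- tempfile(fileext = ".tsv")
  write_barcode(bc, f)
  back <- read_barcode(f)
  expect_equal(back$values, bc$values)
  expect_equal(back$bp_per_px, 500)
  expect_true(back$circular)
  expect_equal(back$id, "x")
})

test_that("binding constant tables are strand-symmetrized and validated", {
  tab <- default_binding_constants()
  expect_length(tab, 256)
  p <- ligand_params(netropsin_constants = tab)
  sym <- p$netropsin_constants
  expect_equal(unname(sym["AATT"]),
               unname(sym[cbscaffold:::revcomp_bases("AATT")]))
  expect_error(ligand_params(netropsin_constants = c(AAAA = 1)),
               "cover")
})
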