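test_that("genome map defaults to 22 autosomes of ~3500 cM", {
  gm <- genome_map()
  expect_length(gm$chrom, 22L)
  expect_equal(sum(gm$length_cM), 3500, tolerance = 0.02)
  expect_error(genome_map(c(100, -5)))
})

test_that("founder mosaics are single intervals; drops are seed-deterministic", {
  ped <- first_cousin_ped()
  gm <- genome_map(c(100, 80))
  d <- gene_drop(ped, gm, seed = 1, targets = c(1, 7))
  f <- d$mosaics[["1"]]
  for (c in 1:2) {
    expect_equal(f$h1[[c]]$end, gm$length_cM[c])
    expect_length(f$h1[[c]]$lab, 1L)
  }
  d2 <- gene_drop(ped, gm, seed = 1, targets = c(1, 7))
  expect_identical(d$mosaics, d2$mosaics)
  d3 <- gene_drop(ped, gm, seed = 2, targets = c(1, 7))
  expect_false(identical(d$mosaics, d3$mosaics))
})

test_that("mosaics tile chromosomes exactly after every drop", {
  ped <- double_first_cousin_ped()
  gm <- genome_map(c(150, 90, 60))
  for (s in 1:25) {
    d <- gene_drop(ped, gm, seed = s, targets = c(9, 10))
    for (m in d$mosaics) for (h in m) for (c in seq_along(gm$chrom)) {
      ends <- h[[c]]$end
      expect_equal(ends[length(ends)], gm$length_cM[c])
      expect_true(all(diff(ends) > 0))
      # adjacent segments never share a label (maximal intervals)
      labs <- h[[c]]$lab
      if (length(labs) > 1) expect_true(all(diff(labs) != 0))
    }
  }
})

test_that("crossover count matches the Poisson rate of 1 per 100 cM", {
  # child haplotype on a 100 cM chromosome: E[crossovers] = 1, and the
  # mosaic has E[segments] <= E[crossovers] + 1 with equality minus label
  # merges; count segment interior breakpoints over many transmissions
  ped <- pedigree(data.frame(id = 1:3, father = c(0, 0, 1),
                             mother = c(0, 0, 2), sex = c("M", "F", "M")))
  gm <- genome_map(100)
  set.seed(99)
  nseg <- replicate(4000, {
    d <- gene_drop(ped, gm, targets = 3)
    length(d$mosaics[["3"]]$h1[[1]]$lab)
  })
  # founder parent: the two source haplotypes carry distinct labels, so every
  # crossover starts a new interval and E[intervals] = E[crossovers] + 1 = 2
  expect_lt(abs(mean(nseg) - 2), 3 * sd(nseg) / sqrt(length(nseg)))
})

test_that("parent-child union IBD covers the full genome; disjoint founders share nothing", {
  ped <- first_cousin_ped()
  gm <- genome_map(c(120, 90))
  d <- gene_drop(ped, gm, seed = 4, targets = c(1, 3, 5, 6))
  seg <- extract_ibd(d, 1, 3, min_cM = 0)
  expect_equal(sum(seg$length_cM), sum(gm$length_cM))
  expect_equal(nrow(extract_ibd(d, 5, 6, min_cM = 0)), 0L)
})

test_that("expected pairing IBD total equals 4 x kinship x map length", {
  gm <- genome_map()
  L <- sum(gm$length_cM)
  cases <- list(
    list(ped = first_cousin_ped(), pair = c(1, 3), phi = 1 / 4),   # parent-child
    list(ped = half_sib_ped(), pair = c(4, 5), phi = 1 / 8))
  set.seed(515)
  for (cs in cases) {
    tot <- replicate(250, {
      d <- gene_drop(cs$ped, gm, targets = cs$pair)
      ibd_total_pairings(d, cs$pair[1], cs$pair[2])
    })
    # parent-child sharing is deterministic (sd 0), hence the epsilon
    expect_lt(abs(mean(tot) - 4 * cs$phi * L),
              3 * sd(tot) / sqrt(length(tot)) + 1e-9)
  }
})

test_that("one-parent individuals get unique phantom founders (no spurious IBD)", {
  ped <- pedigree(data.frame(id = 1:4, father = c(0, 0, 1, 1),
                             mother = c(0, 0, 2, 0), sex = c("M", "F", "M", "M")))
  gm <- genome_map(c(200, 100))
  d <- gene_drop(ped, gm, seed = 12, targets = c(3, 4))
  expect_true(4 %in% d$phantom)
  # 3 and 4 share only through father 1: expected phi = 1/8 (half sibs);
  # phantom maternal side of 4 must never match anything
  seg <- extract_ibd(d, 3, 4, min_cM = 0, merge = "pairings")
  expect_true(all(seg$pairing %in% 1:4))
  set.seed(88)
  tot <- replicate(300, {
    dd <- gene_drop(ped, gm, targets = c(3, 4))
    ibd_total_pairings(dd, 3, 4)
  })
  expect_lt(abs(mean(tot) - 4 * (1 / 8) * 300), 3 * sd(tot) / sqrt(300))
})

test_that("segment binning uses [2,5), [5,10), ... and per-pair means", {
  segs <- data.frame(group = c("A", "A", "A", "B"),
                     length_cM = c(12.3, 3.1, 1.5, 40))
  b <- bin_sharing(segs, n_pairs = c(A = 2, B = 1))
  expect_equal(b$mean_segments_per_pair[b$group == "A" & b$bin == "[10,15)"], 0.5)
  expect_equal(b$mean_segments_per_pair[b$group == "A" & b$bin == "[2,5)"], 0.5)
  expect_equal(sum(b$mean_segments_per_pair[b$group == "A"]), 1)  # 1.5 filtered
  expect_equal(b$mean_segments_per_pair[b$group == "B" & b$bin_start == 40], 1)
  empty <- bin_sharing(segs[0, ], n_pairs = c(A = 3))
  expect_true(all(empty$mean_segments_per_pair == 0))
})
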