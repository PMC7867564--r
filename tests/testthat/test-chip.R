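# Small deterministic tracks are built inline; the planted-fixture recovery
# runs on a scaled-down generator spec to stay fast.

small_spec <- function(seed = 4) {
  synth_spec(seed = seed, chip = list(genome = c(chr1 = 2e5), depth = 4e4,
                                      n_regions = 4L, region_width = 4000L,
                                      narrow_width = 1400L))
}

track_from_pos <- function(pos, strand, L = 10000L, id = "t",
                           role = "ChIP") {
  tag_track(data.frame(chrom = "chr1", pos = pos, strand = strand),
            chrom_sizes = c(chr1 = L), id = id, role = role)
}

test_that("tag track validation", {
  expect_error(track_from_pos(10001, "+"), "outside declared")
  expect_error(track_from_pos(-1, "+"), "outside declared")
  tr <- track_from_pos(c(0, 9999), c("+", "-"))
  expect_identical(tr$total_tags, 2L)
})

test_that("BED round trip preserves 5' positions and strand", {
  tr <- track_from_pos(c(100, 200, 300), c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(tr, path)
  back <- read_tags_bed(path, chrom_sizes = c(chr1 = 10000L))
  expect_identical(back$tags$pos, tr$tags$pos)
  expect_identical(back$tags$strand, tr$tags$strand)
})

test_that("fragment length: zero for mirrored strands, truth within 20 bp, warns on noise", {
  # identical plus/minus profiles: best shift is 0
  pos <- c(1000, 2000, 3000, 4000)
  tr0 <- track_from_pos(c(pos, pos), rep(c("+", "-"), each = 4))
  expect_equal(suppressWarnings(estimate_fragment_length(tr0)), 0)

  expect_error(estimate_fragment_length(track_from_pos(pos, rep("+", 4))),
               "both strands")

  # planted fragments of length 180, piling on 40 point sources with jitter
  set.seed(1)
  sites <- sample.int(9000, 40) + 500
  ctr <- round(sample(sites, 3000, replace = TRUE) + rnorm(3000, 0, 15))
  strand <- sample(c("+", "-"), 3000, replace = TRUE)
  p5 <- ifelse(strand == "+", ctr - 90, ctr + 90)
  tr <- track_from_pos(p5, strand)
  expect_lte(abs(estimate_fragment_length(tr) - 180), 20)

  # uniform random tags: unreliable, warning
  set.seed(2)
  trU <- track_from_pos(sample.int(10000, 4000) - 1,
                        sample(c("+", "-"), 4000, replace = TRUE))
  expect_warning(estimate_fragment_length(trU), "unreliable")
})

test_that("binning: empty track, single tag, count conservation, phases", {
  L <- 10000L
  empty <- tag_track(data.frame(chrom = character(0), pos = integer(0),
                                strand = character(0)),
                     chrom_sizes = c(chr1 = L))
  empty$total_tags <- 1L  # avoid 0/0 in scaling of a degenerate empty track
  bt <- bin_and_scale(empty, bin_size = 500L)
  expect_identical(nrow(bt$bins), 20L)
  expect_true(all(bt$counts == 0))
  expect_equal(bt$scaled, rep(log2(30), 20))

  one <- track_from_pos(750, "+", L = L)
  b0 <- bin_and_scale(one, bin_size = 500L, offset = 0L)
  expect_identical(sum(b0$counts), 1L)
  expect_identical(b0$bins$start[b0$counts == 1], 500)
  b250 <- bin_and_scale(one, bin_size = 500L, offset = 250L)
  expect_identical(sum(b250$counts), 1L)
  expect_identical(b250$bins$start[b250$counts == 1], 750)

  # fragment shift moves the tag toward the centre
  bsh <- bin_and_scale(one, bin_size = 500L, offset = 0L,
                       fragment_length = 500L)
  expect_identical(bsh$bins$start[bsh$counts == 1], 1000)

  set.seed(3)
  n <- 5000L
  rand <- track_from_pos(sample.int(L, n, replace = TRUE) - 1L,
                         sample(c("+", "-"), n, replace = TRUE), L = L)
  for (off in c(0L, 250L)) {
    bt <- bin_and_scale(rand, bin_size = 500L, offset = off,
                        fragment_length = 100L)
    expect_identical(sum(bt$counts), n)
    expect_true(all(diff(bt$bins$start) > 0))
  }
})

test_that("significant bins: none when ChIP equals INPUT; planted bins found; grids must match", {
  set.seed(4)
  L <- 1e5L
  n <- 2e4L
  mk <- function(extra_pos = integer(0)) {
    pos <- c(sample.int(L, n, replace = TRUE) - 1L, extra_pos)
    track_from_pos(pos, sample(c("+", "-"), length(pos), replace = TRUE),
                   L = L)
  }
  inp <- mk()
  same <- bin_and_scale(inp, 500L)
  expect_identical(sum(significant_bins(same, same)$significant), 0L)

  # 20-fold enrichment in bins 40-43 (0-based 20000..22000)
  extra <- sample(2000L, 19 * 400, replace = TRUE) + 20000L
  chip <- bin_and_scale(mk(extra), 500L)
  inpb <- bin_and_scale(mk(), 500L)
  sig <- significant_bins(chip, inpb)
  planted <- which(inpb$bins$start >= 20000 & inpb$bins$start < 22000)
  expect_true(all(sig$significant[planted]))
  expect_lte(sum(sig$significant[-planted]), 2L)

  off <- bin_and_scale(inp, 500L, offset = 250L)
  expect_error(significant_bins(same, off), "grids differ")
})

test_that("BH adjustment matches an independent step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(50:500, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
  # and through the bin test itself
  L <- 5e4L
  n <- 5e3L
  t1 <- track_from_pos(sample.int(L, n, TRUE) - 1L,
                       sample(c("+", "-"), n, TRUE), L = L)
  t2 <- track_from_pos(sample.int(L, n, TRUE) - 1L,
                       sample(c("+", "-"), n, TRUE), L = L)
  sig <- significant_bins(bin_and_scale(t1, 500L), bin_and_scale(t2, 500L))
  expect_equal(sig$padj, bh_oracle(sig$pval))
})

test_that("consensus and merging: replicate intersection, gap rule, brute-force oracle", {
  gr <- function(starts, width = 500) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(start = starts + 1L,
                                                    width = width))
  }
  # significant in one replicate only: dropped
  res <- consensus_and_merge(list(r1 = gr(1000), r2 = gr(5000)),
                             c(r1 = "c1", r2 = "c1"))
  expect_length(res, 0)
  # 400-nt gap (< 500) merges into one region
  res2 <- consensus_and_merge(list(r1 = gr(c(1000, 1900)),
                                   r2 = gr(c(1000, 1900))),
                              c(r1 = "c1", r2 = "c1"))
  expect_length(res2, 1)
  expect_identical(BiocGenerics::start(res2), 1001L)
  expect_identical(BiocGenerics::end(res2), 2400L)
  # exactly 500-nt gap stays two regions
  res3 <- consensus_and_merge(list(r1 = gr(c(1000, 2000)),
                                   r2 = gr(c(1000, 2000))),
                              c(r1 = "c1", r2 = "c1"))
  expect_length(res3, 2)
  # union across conditions
  res4 <- consensus_and_merge(list(r1 = gr(1000), r2 = gr(1000),
                                   s1 = gr(9000), s2 = gr(9000)),
                              c(r1 = "c1", r2 = "c1", s1 = "c2", s2 = "c2"))
  expect_length(res4, 2)

  # brute-force interval merge oracle on random bin sets
  set.seed(7)
  for (rep in 1:10) {
    starts <- sort(sample(seq(0, 2e4, by = 500), 15))
    shared <- gr(starts)
    got <- consensus_and_merge(list(a = shared, b = shared),
                               c(a = "c1", b = "c1"))
    # oracle: scan sorted intervals, merge when gap < 500
    merged <- list()
    cur <- c(starts[1], starts[1] + 500)
    for (s in starts[-1]) {
      if (s - cur[2] < 500) cur[2] <- s + 500
      else { merged[[length(merged) + 1]] <- cur; cur <- c(s, s + 500) }
    }
    merged[[length(merged) + 1]] <- cur
    expect_identical(length(got), length(merged))
    expect_identical(BiocGenerics::start(got),
                     vapply(merged, function(m) as.integer(m[1] + 1), 1L))
    expect_identical(BiocGenerics::end(got),
                     vapply(merged, function(m) as.integer(m[2]), 1L))
  }
})

test_that("region density: empty regions, depth invariance, naive oracle", {
  L <- 10000L
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(start = c(1001, 5001),
                                                     end = c(2000, 5500)))
  tr <- track_from_pos(c(1100, 1200, 1999, 5100, 9000),
                       c("+", "-", "+", "+", "-"), L = L)
  d <- region_density(regions, tr, scale = 1)
  naive <- c(3 / 1000 / 5, 1 / 500 / 5)
  expect_equal(d, naive)
  # doubling every tag leaves densities unchanged
  tr2 <- track_from_pos(rep(tr$tags$pos, 2), rep(tr$tags$strand, 2), L = L)
  expect_equal(region_density(regions, tr2, scale = 1), naive)
  expect_length(region_density(GenomicRanges::GRanges(), tr), 0)
})

test_that("end-to-end recovery of planted regions, including the bin-boundary straddler", {
  sp <- small_spec()
  cx <- make_chip(sp)
  res <- suppressWarnings(
    call_chip_regions(cx$chip, cx$input, cx$condition_of))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(res$regions,
                                                             cx$truth)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(res$regions,
                                                       cx$truth)))
  expect_gte(inter / uni, 0.8)
  expect_lte(max(abs(res$fragment_length - cx$fragment_length)), 20)
  # the narrow region straddling a phase-0 bin boundary is recovered
  narrow <- cx$truth[GenomicRanges::width(cx$truth) < 2000]
  expect_length(narrow, 1)
  bnd <- 500 * round(BiocGenerics::start(narrow) / 500)
  expect_true(BiocGenerics::start(narrow) < bnd && BiocGenerics::end(narrow) > bnd)
  cov <- sum(GenomicRanges::width(GenomicRanges::intersect(res$regions, narrow)))
  expect_gte(cov / GenomicRanges::width(narrow), 0.8)
  # densities are higher inside regions for ChIP than INPUT
  dens_chip <- region_density(res$regions, cx$chip[[1]],
                              fragment_length = res$fragment_length[1])
  dens_input <- region_density(res$regions, cx$input[[1]])
  expect_true(all(dens_chip > dens_input))
  # output invariant under chromosome/sample order
  res_r <- suppressWarnings(
    call_chip_regions(rev(cx$chip), rev(cx$input),
                      cx$condition_of[rev(names(cx$chip))]))
  expect_identical(as.character(res$regions), as.character(res_r$regions))
})

test_that("ChIP identical to INPUT yields an empty region set", {
  sp <- small_spec(seed = 9)
  cx <- make_chip(sp)
  res <- suppressWarnings(
    call_chip_regions(cx$input, cx$input, cx$condition_of, fdr = 0.5))
  expect_length(res$regions, 0)
})
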