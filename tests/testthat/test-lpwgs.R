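make_reads <- function(contig, pos, cigar, flag = 0L, mapq = 60L) {
  tibble::tibble(qname = sprintf("r%03d", seq_along(contig)),
                 flag = as.integer(flag), contig = contig,
                 pos = as.integer(pos), mapq = as.integer(mapq),
                 cigar = cigar)
}

test_that("contig classification recognizes reference dialects", {
  cls <- classify_contigs(c(chrM = 16569, chr17 = 83257441, chrX = 1e6,
                            chrUn_KI270442v1 = 392061, chr1 = 2e8))
  expect_equal(cls$class[cls$contig == "chrM"], "mitochondrial")
  expect_equal(cls$class[cls$contig == "chr17"], "autosome")
  expect_equal(cls$class[cls$contig == "chrX"], "sex")
  expect_equal(cls$class[cls$contig == "chrUn_KI270442v1"], "other")

  cls2 <- classify_contigs(c(MT = 16569, `17` = 83257441, Y = 1e6))
  expect_equal(cls2$class, c("mitochondrial", "autosome", "sex"))

  expect_error(classify_contigs(c(chr1 = 1e6)), "mitochondrial")
  expect_error(classify_contigs(c(chrM = 16569, MT = 16569)),
               "mitochondrial")
  # overrides win, e.g. reclassifying a NUMT-bearing decoy
  cls3 <- classify_contigs(c(chrM = 16569, weird = 5e5, chr1 = 1e6),
                           c(weird = "autosome"))
  expect_equal(cls3$class[cls3$contig == "weird"], "autosome")
})

test_that("aligned bases count CIGAR M/=/X only", {
  cls <- classify_contigs(tibble::tibble(name = c("chr1", "chrM"),
                                         length = c(1000, 1000)))
  cov <- mean_depth(make_reads("chr1", 1, "100M"), cls)
  expect_equal(cov$per_contig$mean_depth[cov$per_contig$contig == "chr1"],
               0.1)
  cov2 <- mean_depth(make_reads("chr1", 1, "50M50S"), cls)
  expect_equal(cov2$per_contig$aligned_bases[1], 50)
  expect_equal(cov2$per_contig$mean_depth[1], 0.05)
  # deletions advance the reference but are not counted as covered bases
  cov3 <- mean_depth(make_reads("chr1", 1, "40M10D40M"), cls)
  expect_equal(cov3$per_contig$aligned_bases[1], 80)
})

test_that("filter policy drops flagged reads with accounted reasons", {
  cls <- classify_contigs(tibble::tibble(name = c("chr1", "chrM"),
                                         length = c(1000, 1000)))
  reads <- make_reads(rep("chr1", 5), rep(1, 5), rep("100M", 5),
                      flag = c(0L, 4L, 256L, 1024L, 0L),
                      mapq = c(60L, 60L, 60L, 60L, 0L))
  cov <- mean_depth(reads, cls)
  expect_equal(cov$reads_kept, 1)
  expect_equal(unname(cov$reads_filtered[c("unmapped", "secondary",
                                           "duplicate", "low_mapq")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(cov$reads_kept + sum(cov$reads_filtered), nrow(reads))

  lax <- mean_depth(reads, cls,
                    read_filter_policy(min_mapq = 0,
                                       drop_duplicates = FALSE,
                                       drop_secondary = FALSE,
                                       drop_supplementary = FALSE,
                                       drop_unmapped = FALSE))
  expect_equal(lax$reads_kept, 5)
})

test_that("raising min_mapq never increases reads kept", {
  set.seed(11)
  reads <- make_reads(rep("chr1", 200), sample(1:900, 200, TRUE),
                      rep("100M", 200),
                      mapq = sample(0:60, 200, TRUE))
  cls <- classify_contigs(tibble::tibble(name = c("chr1", "chrM"),
                                         length = c(1000, 1000)))
  kept <- vapply(c(0, 1, 10, 30, 60, 61), function(q) {
    mean_depth(reads, cls, read_filter_policy(min_mapq = q))$reads_kept
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("records on contigs absent from the classification are an error", {
  cls <- classify_contigs(tibble::tibble(name = c("chr1", "chrM"),
                                         length = c(1000, 1000)))
  expect_error(mean_depth(make_reads("chr9", 1, "100M"), cls), "chr9")
})

test_that("streaming depth equals the per-base pileup oracle exactly", {
  genome <- small_genome()
  for (seed in c(7, 21)) {
    reads <- simulate_lpwgs_reads(150, genome, seed = seed)
    a <- mean_depth(reads)
    b <- pileup_depth_oracle(reads)
    expect_identical(tidy(a), tidy(b))
    expect_identical(a$reads_kept, b$reads_kept)
    expect_identical(a$reads_filtered, b$reads_filtered)
    expect_equal(a$autosomal_mean_depth, b$autosomal_mean_depth)
    expect_equal(a$mito_mean_depth, b$mito_mean_depth)
    expect_equal(a$mito_read_count, b$mito_read_count)
  }
  # and with CIGARs containing clips and deletions
  cls <- classify_contigs(tibble::tibble(name = c("chr1", "chrM"),
                                         length = c(500, 300)))
  reads <- make_reads(c("chr1", "chr1", "chrM"), c(1, 450, 10),
                      c("20M5D30M10S", "10S40M", "25M2D25M"))
  expect_identical(tidy(mean_depth(reads, cls)),
                   tidy(pileup_depth_oracle(reads, cls)))
})

test_that("the coverage formula doubles the depth ratio", {
  expect_equal(mtdnacn_from_coverage(expected_depth_profile(200))$mtdnacn,
               200)
  expect_equal(mtdnacn_from_coverage(expected_depth_profile(2))$mtdnacn, 2)
  half <- toy_genome_spec(target_autosomal_depth = 0.5)
  r <- mtdnacn_from_coverage(expected_depth_profile(2000, half))
  expect_equal(r$mtdnacn, 2000)
  expect_equal(r$mito_mean_depth, 500)
  expect_equal(r$autosomal_mean_depth, 0.5)
})

test_that("degenerate depths are handled explicitly", {
  cls <- classify_contigs(tibble::tibble(name = c("chr1", "chrM"),
                                         length = c(1000, 1000)))
  no_auto <- mean_depth(make_reads("chrM", 1, "100M"), cls)
  expect_error(mtdnacn_from_coverage(no_auto), "Autosomal")
  no_mito <- mean_depth(make_reads("chr1", 1, "100M"), cls)
  r <- mtdnacn_from_coverage(no_mito)
  expect_equal(r$mtdnacn, 0)
  expect_equal(r$qc_flags, "LOW_MITO_COVERAGE")
})

test_that("SAM files round-trip through Rsamtools unchanged", {
  genome <- small_genome()
  reads <- simulate_lpwgs_reads(100, genome, seed = 3)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, genome_contigs <- attr(reads, "header_contigs"), sam)
  from_file <- mean_depth(sam)
  in_memory <- mean_depth(reads)
  expect_equal(tidy(from_file)[order(tidy(from_file)$contig), ],
               tidy(in_memory)[order(tidy(in_memory)$contig), ])
  expect_equal(from_file$reads_kept, in_memory$reads_kept)
  # empty alignment set: valid header, all depths zero
  empty <- reads[0, ]
  attr(empty, "header_contigs") <- attr(reads, "header_contigs")
  sam0 <- tempfile(fileext = ".sam")
  write_sam(empty, attr(reads, "header_contigs"), sam0)
  cov0 <- mean_depth(sam0)
  expect_true(all(cov0$per_contig$mean_depth == 0))
})

test_that("random read thinning preserves the expected estimate", {
  genome <- toy_genome_spec(target_autosomal_depth = 2)
  reads <- simulate_lpwgs_reads(300, genome, seed = 5)
  full <- mtdnacn_from_coverage(mean_depth(reads))$mtdnacn
  set.seed(99)
  thin <- reads[runif(nrow(reads)) < 0.5, ]
  attr(thin, "header_contigs") <- attr(reads, "header_contigs")
  thinned <- mtdnacn_from_coverage(mean_depth(thin))$mtdnacn
  expect_equal(thinned, full, tolerance = 0.1)
})
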