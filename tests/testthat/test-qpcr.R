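test_that("Ct table parsing maps fields, sentinels and gene aliases", {
  csv <- c(
    "sample_id,gene,replicate,ct,is_ntc",
    "S1,ND1,1,17.20,false",
    "S1,MT-ND6,1,18.00,false",
    "S1,NEB1,1,25.30,false",
    "S2,nd1,1,Undetermined,false",
    "NTC,ND1,1,,true"
  )
  tbl <- read_ct_table(csv)
  expect_equal(nrow(tbl), 5)
  expect_equal(tbl$ct[1], 17.20)
  expect_equal(tbl$gene[2], "ND6")
  expect_equal(tbl$gene[3], "NEB")
  expect_equal(tbl$gene[4], "ND1")
  expect_true(is.na(tbl$ct[4]))
  expect_true(tbl$is_ntc[5] && is.na(tbl$ct[5]))
})

test_that("Ct table parsing rejects bad rows and missing columns", {
  expect_error(
    read_ct_table(c("sample_id,gene,replicate,is_ntc", "S1,ND1,1,false")),
    "ct"
  )
  expect_warning(
    tbl <- read_ct_table(c("sample_id,gene,replicate,ct,is_ntc",
                           "S1,ACTB,1,20,false",
                           "S1,ND1,1,20,false")),
    "unknown gene"
  )
  expect_equal(nrow(tbl), 1)
  expect_warning(
    tbl2 <- read_ct_table(c("sample_id,gene,replicate,ct,is_ntc",
                            "S1,ND1,1,45,false",
                            "S1,ND1,2,20,false")),
    "outside"
  )
  expect_equal(nrow(tbl2), 1)
  expect_error(
    read_ct_table(c("sample_id,gene,replicate,ct,is_ntc",
                    "S1,ND1,1,20,false",
                    "S1,ND1,1,21,false")),
    "Duplicate replicate"
  )
})

test_that("replicate aggregation computes moments and QC flags", {
  m <- make_measurements(list(
    clean = list(ND1 = c(20.0, 20.2, 20.4)),
    undet = list(ND1 = c(20.0, NA, 20.4)),
    noisy = list(ND1 = c(20.0, 21.5, 20.1))
  ))
  s <- summarize_replicates(m)
  clean <- s[s$sample_id == "clean", ]
  expect_equal(clean$mean_ct, 20.2)
  expect_equal(clean$sd_ct, 0.2)
  expect_equal(clean$flags, "")

  undet <- s[s$sample_id == "undet", ]
  expect_equal(undet$n_used, 2L)
  expect_equal(undet$mean_ct, 20.2)
  expect_equal(undet$flags, "HAS_UNDETERMINED")

  noisy <- s[s$sample_id == "noisy", ]
  expect_equal(noisy$sd_ct, 0.8386497, tolerance = 1e-6)
  expect_match(noisy$flags, "HIGH_CT_SD")
})

test_that("all-undetermined wells yield no summary but a recorded failure", {
  m <- make_measurements(list(bad = list(ND1 = c(NA_real_, NA_real_)),
                              ok = list(ND1 = c(20, 20))))
  expect_warning(s <- summarize_replicates(m), "bad/ND1")
  expect_equal(s$sample_id, "ok")
  expect_equal(attr(s, "qc_failures")$sample_id, "bad")
})

test_that("NTC verdicts pass late/absent amplification and fail early wells", {
  ntc <- tibble::tibble(
    sample_id = "NTC", gene = rep(c("ND1", "ND6"), each = 2),
    replicate = rep(1:2, 2), ct = c(NA, NA, 28, 36),
    plate_id = "p1", run_date = as.Date("2024-01-01"),
    is_ntc = TRUE, input_mass_ng = 0
  )
  v <- check_ntc(ntc, max_allowed_ct = 35)
  expect_equal(v$verdict[v$gene == "ND1"], "PASS")
  expect_equal(v$verdict[v$gene == "ND6"], "FAIL")
  expect_match(v$offending_wells[v$gene == "ND6"], "ct=28")
  # a 36-cycle NTC is above the 35-cycle threshold: pass
  ntc36 <- ntc[ntc$ct %in% 36 | FALSE, ]
  expect_equal(check_ntc(ntc36)$verdict, "PASS")
  expect_warning(w <- check_ntc(ntc[0, ]), "No NTC")
  expect_equal(w$verdict, "WARN")
})

test_that("paired delta-Ct subtracts mito from nuclear mean Cts", {
  s <- make_summaries(list(
    S1 = list(ND1 = 17.0, ND6 = 22.0, BECN1 = 25.0, NEB = 22.0),
    S2 = list(ND1 = 16.9, ND6 = 18.0, BECN1 = 24.3, NEB = 25.0)
  ))
  d <- delta_ct(s)
  expect_equal(d$delta_ct_1[d$sample_id == "S1"], 8.0)
  expect_equal(d$delta_ct_2[d$sample_id == "S1"], 0.0)
  expect_equal(d$delta_ct_1[d$sample_id == "S2"], 7.4)
  s_missing <- s[s$gene != "NEB" | s$sample_id != "S2", ]
  expect_error(delta_ct(s_missing), "NEB.*S2")
})

test_that("copy-number conversion is exactly 2^deltaCt and monotone", {
  expect_identical(relative_copy_number(c(-2, 0, 8)), c(0.25, 1, 256))
  expect_identical(relative_copy_number(-1), 0.5)
  grid <- seq(-5, 12, by = 0.25)
  expect_true(all(diff(relative_copy_number(grid)) > 0))
  expect_error(relative_copy_number(Inf), "finite")
  expect_error(relative_copy_number(NA_real_), "finite")
})

test_that("the two pair estimates combine by arithmetic mean", {
  expect_equal(mtdnacn_paired(256, 200), 228)
  expect_equal(mtdnacn_paired(123.4, 123.4), 123.4)
  expect_equal(mtdnacn_paired(2^7.4, 2^7), 148.4485, tolerance = 1e-4)
  expect_error(mtdnacn_paired(-1, 5), "positive")
})

test_that("geomean method averages nuclear Cts before conversion", {
  s1 <- make_summaries(list(S1 = list(ND1 = 17, ND6 = 17,
                                      BECN1 = 25, NEB = 25)))
  expect_equal(mtdnacn_geomean(s1)$mtdnacn, 256)
  # asymmetric nuclear Cts with the same mean give the same answer
  s2 <- make_summaries(list(S1 = list(ND1 = 17, ND6 = 17,
                                      BECN1 = 24, NEB = 26)))
  expect_equal(mtdnacn_geomean(s2)$mtdnacn, 256)
})

test_that("geomean equals paired exactly when the nuclear Cts coincide", {
  set.seed(42)
  for (i in 1:25) {
    nuc <- runif(1, 22, 28)
    s <- make_summaries(list(S = list(ND1 = runif(1, 14, 20),
                                      ND6 = runif(1, 14, 20),
                                      BECN1 = nuc, NEB = nuc)))
    expect_identical(mtdnacn_geomean(s)$mtdnacn,
                     qpcr_mtdnacn(s, method = "paired")$mtdnacn)
  }
})

test_that("mtDNAcn decreases strictly in each mito gene's mean Ct", {
  base <- list(ND1 = 17, ND6 = 18, BECN1 = 25, NEB = 24)
  for (g in c("ND1", "ND6")) {
    cts <- seq(15, 22, by = 0.5)
    est <- vapply(cts, function(ct) {
      genes <- base
      genes[[g]] <- ct
      qpcr_mtdnacn(make_summaries(list(S = genes)))$mtdnacn
    }, numeric(1))
    expect_true(all(diff(est) < 0))
  }
})

test_that("doubling template input shifts Cts one cycle and leaves mtDNAcn fixed", {
  truth <- simulate_cohort(3, 0, seed = 7)
  p2 <- simulate_ct_plate(truth, ct_sd = 0, input_mass_ng = 2, seed = 7)
  p4 <- simulate_ct_plate(truth, ct_sd = 0, input_mass_ng = 4, seed = 7)
  expect_equal(p4$ct[!p4$is_ntc], p2$ct[!p2$is_ntc] - 1)
  expect_equal(qpcr_mtdnacn(p4)$mtdnacn, qpcr_mtdnacn(p2)$mtdnacn)
})

test_that("reference drift is judged against the across-plate mean", {
  ref_results <- function(vals) {
    tibble::tibble(sample_id = "NA12878",
                   plate_id = paste0("p", seq_along(vals)), mtdnacn = vals)
  }
  q1 <- reference_sample_qc(ref_results(c(100, 100, 100)))
  expect_equal(q1$cv_pct, 0)
  expect_false(any(q1$per_plate$flagged))
  expect_equal(q1$verdict, "OK")
  # 130 deviates 18.2% from the mean of 110: under the 20% threshold
  q2 <- reference_sample_qc(ref_results(c(100, 100, 130)))
  expect_false(any(q2$per_plate$flagged))
  expect_equal(max(q2$per_plate$deviation_pct), 18.18182, tolerance = 1e-5)
  # 100 and 160 both sit ~23% from their mean of 130: both flagged
  q3 <- reference_sample_qc(ref_results(c(100, 160)))
  expect_true(all(q3$per_plate$flagged))
  expect_equal(q3$verdict, "DRIFT")
  expect_warning(q4 <- reference_sample_qc(ref_results(numeric(0))), "absent")
  expect_equal(q4$verdict, "WARN")
})

test_that("inter/intra-day CVs follow the validation design", {
  res <- tibble::tibble(
    sample_id = c("a1", "a1", "a2", "a2", "a3"),
    mtdnacn = c(200, 200, 190, 210, 150),
    run_date = as.Date(c("2024-01-01", "2024-01-02",
                         "2024-01-01", "2024-01-01",
                         "2024-01-01")),
    plate_id = c("p1", "p2", "p1", "p1", "p1")
  )
  v <- replicate_variability(res)
  expect_equal(v$inter_day_cv_pct[v$sample_id == "a1"], 0)
  expect_equal(v$intra_day_cv_pct[v$sample_id == "a2"], 7.071068,
               tolerance = 1e-6)
  expect_true(is.na(v$inter_day_cv_pct[v$sample_id == "a3"]))
  expect_true(is.na(v$intra_day_cv_pct[v$sample_id == "a3"]))
})

test_that("the packaged primer panel is complete and well-formed", {
  panel <- primer_panel()
  expect_equal(nrow(panel), 8)
  expect_setequal(unique(panel$gene), c("ND1", "ND6", "BECN1", "NEB"))
  expect_true(all(table(panel$gene) == 2))
  expect_true(all(grepl("^[ACGT]+$", panel$sequence)))
  expect_true(all(panel$reported_tm > 50 & panel$reported_tm < 70))
})
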