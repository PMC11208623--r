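# Build a measurement tibble from per-(sample, gene) Ct vectors.
# cts: named list like list(S1 = list(ND1 = c(...), BECN1 = c(...), ...))
make_measurements <- function(cts, plate_id = "p1",
                              run_date = as.Date("2024-01-01")) {
  rows <- list()
  for (s in names(cts)) {
    for (g in names(cts[[s]])) {
      v <- cts[[s]][[g]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = s, gene = g, replicate = seq_along(v), ct = v,
        plate_id = plate_id, run_date = run_date, is_ntc = FALSE,
        input_mass_ng = 2
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Summary tibble holding one mean Ct per gene for each sample.
make_summaries <- function(mean_cts) {
  purrr::imap_dfr(mean_cts, function(genes, s) {
    tibble::tibble(sample_id = s, gene = names(genes),
                   n_used = 3L, mean_ct = unname(unlist(genes)),
                   sd_ct = 0, cv_pct = 0, flags = "")
  })
}

# Small genome spec for oracle comparisons (keeps pileup loops cheap).
small_genome <- function(depth = 1) {
  toy_genome_spec(
    autosomes = tibble::tibble(name = c("chr1", "chr2"),
                               length = c(10000, 8000)),
    mito_length = 2000, read_length = 100,
    target_autosomal_depth = depth
  )
}

# Run paired-qPCR, geomean-qPCR and lpWGS (analytic or sampled) on one
# simulated cohort; returns a long tibble for method_concordance().
estimate_three_ways <- function(truth, ct_sd = 0, sampled = FALSE,
                                genome = toy_genome_spec(), seed = NULL) {
  plate <- simulate_ct_plate(truth, ct_sd = ct_sd, seed = seed)
  paired <- qpcr_mtdnacn(plate, method = "paired")
  geo <- qpcr_mtdnacn(plate, method = "geomean")
  lp <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    cov <- if (sampled) {
      mean_depth(simulate_lpwgs_reads(
        truth$true_mtdnacn[i], genome,
        seed = if (is.null(seed)) NULL else seed + i))
    } else {
      expected_depth_profile(truth$true_mtdnacn[i], genome)
    }
    mtdnacn_from_coverage(cov, sample_id = truth$sample_id[i])
  })
  cols <- c("sample_id", "method", "mtdnacn")
  dplyr::bind_rows(paired[cols], geo[cols], lp[cols])
}
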