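#' Read a qPCR Ct plate table
#'
#' Parses a CSV of per-well threshold-cycle (Ct) observations into the tidy
#' measurement table used by the qPCR estimators. Each row is one well:
#' a sample, a gene, a replicate index and a Ct value. The instrument
#' sentinel `"Undetermined"` (any case) and empty cells are mapped to `NA`,
#' which downstream aggregation treats as an undetermined well, never as a
#' numeric Ct.
#'
#' Gene names are normalized case-insensitively: a leading `MT-`/`MT_`
#' prefix is stripped (so `MT-ND1` becomes `ND1`) and the alias `NEB1` is
#' mapped to `NEB`. Rows with a gene outside the assay panel
#' (ND1, ND6, BECN1, NEB) are dropped with a warning; a missing required
#' column is a hard error naming the column.
#'
#' @param file Path to a CSV file, or a literal character vector of CSV
#'   lines.
#' @param col_map Optional named character vector remapping the canonical
#'   column names (`sample_id`, `gene`, `replicate`, `ct`, `is_ntc`, and
#'   optionally `plate_id`, `run_date`, `input_mass_ng`) to the names used
#'   in the file, e.g. `c(ct = "CT_value")`.
#' @param max_cycles Number of cycles the instrument ran; numeric Ct values
#'   outside `[0, max_cycles]` are rejected with a warning. Default 40.
#'
#' @return A tibble with columns `sample_id`, `gene`, `replicate`, `ct`
#'   (numeric; `NA` = undetermined), `plate_id`, `run_date`, `is_ntc`,
#'   `input_mass_ng`.
#' @examples
#' csv <- c(
#'   "sample_id,gene,replicate,ct,is_ntc",
#'   "S1,MT-ND1,1,17.20,FALSE",
#'   "S1,BECN1,1,25.1,FALSE",
#'   "NTC,ND1,1,Undetermined,TRUE"
#' )
#' read_ct_table(csv)
#' @export
read_ct_table <- function(file, col_map = NULL, max_cycles = 40) {
  raw <- readr::read_csv(
    if (length(file) > 1 || grepl("\n", file[1])) I(paste(file, collapse = "\n")) else file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  canonical <- c("sample_id", "gene", "replicate", "ct", "is_ntc",
                 "plate_id", "run_date", "input_mass_ng")
  map <- setNames(canonical, canonical)
  if (!is.null(col_map)) map[names(col_map)] <- unname(col_map)
  required <- c("sample_id", "gene", "replicate", "ct", "is_ntc")
  missing <- required[!map[required] %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("Ct table is missing required column(s): ",
                 paste(map[missing], collapse = ", ")))
  }
  get_col <- function(nm, default = NA_character_) {
    if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else rep(default, nrow(raw))
  }

  ct_chr <- trimws(get_col("ct"))
  undet <- is.na(ct_chr) | ct_chr == "" | tolower(ct_chr) == "undetermined"
  ct <- suppressWarnings(as.numeric(ct_chr))
  unparseable <- !undet & is.na(ct)
  ct[undet] <- NA_real_

  out <- tibble(
    sample_id = get_col("sample_id"),
    gene = normalize_gene(get_col("gene")),
    gene_raw = get_col("gene"),
    replicate = as.integer(get_col("replicate")),
    ct = ct,
    plate_id = get_col("plate_id", "plate1"),
    run_date = as.Date(get_col("run_date")),
    is_ntc = tolower(get_col("is_ntc", "false")) %in% c("true", "t", "1", "yes"),
    input_mass_ng = as.numeric(get_col("input_mass_ng", "2"))
  )
  out$plate_id[is.na(out$plate_id)] <- "plate1"
  out$input_mass_ng[is.na(out$input_mass_ng)] <- 2

  bad_gene <- is.na(out$gene)
  if (any(bad_gene)) {
    warn(paste0("Dropping ", sum(bad_gene), " row(s) with unknown gene name(s): ",
                paste(unique(out$gene_raw[bad_gene]), collapse = ", ")))
  }
  out_of_range <- !is.na(out$ct) & (out$ct < 0 | out$ct > max_cycles)
  if (any(out_of_range)) {
    warn(paste0("Dropping ", sum(out_of_range), " row(s) with Ct outside [0, ",
                max_cycles, "]"))
  }
  if (any(unparseable)) {
    warn(paste0("Dropping ", sum(unparseable), " row(s) with unparseable Ct values"))
  }
  out <- out[!bad_gene & !out_of_range & !unparseable, , drop = FALSE]
  out$gene_raw <- NULL

  dup <- out |>
    filter(!.data$is_ntc) |>
    dplyr::count(.data$sample_id, .data$gene, .data$plate_id, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate replicate index within (sample, gene, plate): ",
                 paste(utils::head(paste(dup$sample_id, dup$gene, dup$replicate,
                                         sep = "/"), 5), collapse = "; ")))
  }
  out
}

#' Normalize assay gene names
#'
#' Case-insensitive; strips a leading `MT-`/`MT_` prefix and maps the alias
#' `NEB1` to `NEB`. Names outside the panel return `NA`.
#'
#' @param gene Character vector of gene labels.
#' @return Character vector over `ND1`, `ND6`, `BECN1`, `NEB`, or `NA`.
#' @export
normalize_gene <- function(gene) {
  g <- toupper(trimws(as.character(gene)))
  g <- sub("^MT[-_]", "", g)
  g[g == "NEB1"] <- "NEB"
  g[!g %in% ALL_GENES] <- NA_character_
  g
}

#' Aggregate replicate Ct wells per sample and gene
#'
#' Computes the mean, SD and CV of replicate Cts for each (sample, gene),
#' excluding undetermined wells from the statistics while flagging their
#' presence. QC flags: `HAS_UNDETERMINED` when any replicate was
#' undetermined, `TOO_FEW_REPLICATES` when fewer than two determinate wells
#' remain, and `HIGH_CT_SD` when the replicate SD exceeds `sd_max` cycles.
#'
#' A (sample, gene) whose wells are all undetermined yields no summary row;
#' such failures are recorded in the `qc_failures` attribute and a warning.
#'
#' @param measurements Measurement tibble from [read_ct_table()] or
#'   [simulate_ct_plate()]; NTC wells are ignored.
#' @param sd_max Replicate-SD flag threshold in cycles (default 0.5).
#' @return Tibble with columns `sample_id`, `gene`, `n_used`, `mean_ct`,
#'   `sd_ct`, `cv_pct`, `flags`; attribute `qc_failures` lists all-undetermined
#'   (sample, gene) pairs.
#' @export
summarize_replicates <- function(measurements, sd_max = 0.5) {
  stopifnot(is.data.frame(measurements), nrow(measurements) > 0)
  meas <- filter(measurements, !.data$is_ntc)
  if (nrow(meas) == 0) abort("No non-NTC measurements to summarize")

  out <- meas |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(
      n_total = dplyr::n(),
      n_used = sum(!is.na(.data$ct)),
      mean_ct = mean(.data$ct[!is.na(.data$ct)]),
      sd_ct = sd(.data$ct[!is.na(.data$ct)]),
      .groups = "drop"
    ) |>
    mutate(
      cv_pct = 100 * .data$sd_ct / .data$mean_ct,
      flags = purrr::pmap_chr(
        list(.data$n_total, .data$n_used, .data$sd_ct),
        function(n_total, n_used, sd_ct) {
          f <- character(0)
          if (n_used < n_total) f <- c(f, "HAS_UNDETERMINED")
          if (n_used < 2) f <- c(f, "TOO_FEW_REPLICATES")
          if (!is.na(sd_ct) && sd_ct > sd_max) f <- c(f, "HIGH_CT_SD")
          join_flags(f)
        }
      )
    )

  failed <- filter(out, .data$n_used == 0)
  if (nrow(failed) > 0) {
    warn(paste0("All replicates undetermined for: ",
                paste(paste(failed$sample_id, failed$gene, sep = "/"),
                      collapse = ", ")))
    out <- filter(out, .data$n_used > 0)
  }
  out <- select(out, -"n_total")
  attr(out, "qc_failures") <- select(failed, "sample_id", "gene")
  out
}

#' No-template-control verdict per gene
#'
#' An NTC well containing nuclease-free water must not amplify: the plate
#' passes for a gene when every NTC well is undetermined or crosses
#' threshold later than `max_allowed_ct` cycles. Amplification at or below
#' the threshold indicates contamination and fails the gene, listing the
#' offending wells. Absent NTC wells give a `WARN` verdict, never a silent
#' pass.
#'
#' @param measurements Measurement tibble; only rows with `is_ntc = TRUE`
#'   are considered.
#' @param max_allowed_ct Latest acceptable Ct for an amplifying NTC well
#'   (default 35).
#' @return Tibble `gene`, `n_wells`, `verdict` (PASS/FAIL/WARN),
#'   `offending_wells`.
#' @export
check_ntc <- function(measurements, max_allowed_ct = 35) {
  ntc <- filter(measurements, .data$is_ntc)
  if (nrow(ntc) == 0) {
    warn("No NTC wells present; contamination cannot be assessed")
    return(tibble(gene = NA_character_, n_wells = 0L,
                  verdict = "WARN", offending_wells = ""))
  }
  ntc |>
    group_by(.data$gene) |>
    summarise(
      n_wells = dplyr::n(),
      offending_wells = paste(
        sprintf("%s/rep%d(ct=%.2f)",
                .data$sample_id[!is.na(.data$ct) & .data$ct <= max_allowed_ct],
                .data$replicate[!is.na(.data$ct) & .data$ct <= max_allowed_ct],
                .data$ct[!is.na(.data$ct) & .data$ct <= max_allowed_ct]),
        collapse = ";"),
      .groups = "drop"
    ) |>
    mutate(verdict = ifelse(nzchar(.data$offending_wells), "FAIL", "PASS")) |>
    select("gene", "n_wells", "verdict", "offending_wells")
}

#' Default mitochondrial/nuclear gene pairing
#'
#' The paired delta-Ct method references each mitochondrial target against
#' a fixed nuclear gene: ND1 against BECN1 and ND6 against NEB.
#'
#' @return Tibble with columns `mito_gene`, `nuclear_gene` (two rows).
#' @export
default_gene_pairing <- function() {
  tibble(mito_gene = c("ND1", "ND6"), nuclear_gene = c("BECN1", "NEB"))
}

validate_pairing <- function(pairing) {
  stopifnot(is.data.frame(pairing), nrow(pairing) == 2,
            all(c("mito_gene", "nuclear_gene") %in% names(pairing)))
  genes <- c(pairing$mito_gene, pairing$nuclear_gene)
  if (anyDuplicated(genes)) abort("Each gene may appear at most once in the pairing")
  if (!all(pairing$mito_gene %in% MITO_GENES)) abort("Mito genes must be ND1/ND6")
  if (!all(pairing$nuclear_gene %in% NUCLEAR_GENES)) abort("Nuclear genes must be BECN1/NEB")
  pairing
}

# Wide per-sample mean-Ct table; errors when a sample lacks one of the four
# genes, naming the sample and gene.
ct_wide <- function(summaries, sample_id = NULL) {
  if (!is.null(sample_id)) {
    summaries <- filter(summaries, .data$sample_id %in% !!sample_id)
  }
  wide <- summaries |>
    select("sample_id", "gene", "mean_ct") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mean_ct")
  for (g in ALL_GENES) {
    if (!g %in% names(wide)) wide[[g]] <- NA_real_
    bad <- is.na(wide[[g]])
    if (any(bad)) {
      abort(paste0("Missing Ct summary for gene ", g, " in sample(s): ",
                   paste(wide$sample_id[bad], collapse = ", ")))
    }
  }
  wide
}

#' Paired delta-Ct values per sample
#'
#' For each sample, the mitochondrial mean Ct is subtracted from its paired
#' nuclear gene's mean Ct: with the default pairing,
#' deltaCt1 = Ct(BECN1) - Ct(ND1) and deltaCt2 = Ct(NEB) - Ct(ND6).
#' Because the mitochondrial genome is present in many copies per cell its
#' Ct is lower, so delta-Ct is typically large and positive.
#'
#' @param summaries Replicate summaries from [summarize_replicates()].
#' @param pairing Gene pairing tibble; see [default_gene_pairing()].
#' @param sample_id Optional sample subset.
#' @return Tibble `sample_id`, `delta_ct_1`, `delta_ct_2`.
#' @export
delta_ct <- function(summaries, pairing = default_gene_pairing(), sample_id = NULL) {
  pairing <- validate_pairing(pairing)
  wide <- ct_wide(summaries, sample_id)
  tibble(
    sample_id = wide$sample_id,
    delta_ct_1 = wide[[pairing$nuclear_gene[1]]] - wide[[pairing$mito_gene[1]]],
    delta_ct_2 = wide[[pairing$nuclear_gene[2]]] - wide[[pairing$mito_gene[2]]]
  )
}

#' Relative copy number from a delta-Ct
#'
#' `N = 2^deltaCt`, assuming ideal per-cycle amplification efficiency of 2.
#' Strictly positive and monotone increasing in delta-Ct.
#'
#' @param delta_ct Numeric vector of delta-Ct values (cycles); must be finite.
#' @return `2^delta_ct`.
#' @examples
#' relative_copy_number(c(-1, 0, 8)) # 0.5 1 256
#' @export
relative_copy_number <- function(delta_ct) {
  if (!is.numeric(delta_ct) || any(!is.finite(delta_ct))) {
    abort("delta_ct must be finite numeric")
  }
  2^delta_ct
}

#' Combine the two per-pair copy numbers
#'
#' The final relative mtDNAcn of a sample is the arithmetic mean of the two
#' paired-gene copy-number estimates.
#'
#' @param n_1,n_2 Strictly positive relative copy numbers from the two gene
#'   pairs.
#' @return `(n_1 + n_2) / 2`.
#' @export
mtdnacn_paired <- function(n_1, n_2) {
  if (any(!is.finite(n_1)) || any(!is.finite(n_2)) ||
      any(n_1 <= 0) || any(n_2 <= 0)) {
    abort("Copy numbers must be finite and strictly positive")
  }
  (n_1 + n_2) / 2
}

#' Commercial-style geometric-mean mtDNAcn
#'
#' Normalizes each mitochondrial gene against the geometric mean of the two
#' nuclear reference signals. In Ct space the geometric mean of copy signals
#' is the arithmetic mean of Cts, so the nuclear reference Ct is
#' `(Ct(BECN1) + Ct(NEB)) / 2`; each mitochondrial gene then yields
#' `N_g = 2^(refCt - Ct_g)` and the final value is the mean of the two.
#' When the two nuclear Cts are equal this coincides exactly with the
#' paired method.
#'
#' @param summaries Replicate summaries from [summarize_replicates()].
#' @param sample_id Optional sample subset.
#' @return Result tibble in the same shape as [qpcr_mtdnacn()], with
#'   `method = "geomean"`; `delta_ct_1`/`delta_ct_2` hold the per-mito-gene
#'   differences against the nuclear reference Ct.
#' @export
mtdnacn_geomean <- function(summaries, sample_id = NULL) {
  wide <- ct_wide(summaries, sample_id)
  ref_ct <- (wide$BECN1 + wide$NEB) / 2
  d1 <- ref_ct - wide$ND1
  d2 <- ref_ct - wide$ND6
  n1 <- relative_copy_number(d1)
  n2 <- relative_copy_number(d2)
  tibble(
    sample_id = wide$sample_id,
    method = "geomean",
    delta_ct_1 = d1, delta_ct_2 = d2,
    n_1 = n1, n_2 = n2,
    mtdnacn = mtdnacn_paired(n1, n2)
  )
}

#' Relative mtDNAcn from a Ct plate table
#'
#' End-to-end qPCR estimator: aggregates replicates, computes per-pair
#' delta-Ct values, converts to copy numbers (`N = 2^deltaCt`) and averages
#' the two pairs. `method = "paired"` references each mitochondrial gene
#' against its own nuclear partner; `method = "geomean"` references both
#' against the combined nuclear signal as the commercial assay does.
#'
#' Per-sample `qc_flags` are the union of the replicate-level flags of the
#' four contributing gene summaries.
#'
#' @param measurements Measurement tibble ([read_ct_table()] /
#'   [simulate_ct_plate()]), or a pre-computed summary tibble from
#'   [summarize_replicates()].
#' @param method `"paired"` (default) or `"geomean"`.
#' @param pairing Gene pairing for the paired method.
#' @param sd_max Replicate-SD QC threshold passed to
#'   [summarize_replicates()].
#' @return Tibble `sample_id`, `method`, `delta_ct_1`, `delta_ct_2`, `n_1`,
#'   `n_2`, `mtdnacn`, `qc_flags`, one row per sample, sorted by sample.
#' @examples
#' plate <- simulate_ct_plate(simulate_cohort(2, 2, seed = 1), ct_sd = 0, seed = 1)
#' qpcr_mtdnacn(plate)
#' @export
qpcr_mtdnacn <- function(measurements, method = c("paired", "geomean"),
                         pairing = default_gene_pairing(), sd_max = 0.5) {
  method <- match.arg(method)
  summaries <- if ("mean_ct" %in% names(measurements)) {
    measurements
  } else {
    summarize_replicates(measurements, sd_max = sd_max)
  }

  res <- if (method == "paired") {
    d <- delta_ct(summaries, pairing)
    n1 <- relative_copy_number(d$delta_ct_1)
    n2 <- relative_copy_number(d$delta_ct_2)
    tibble(
      sample_id = d$sample_id, method = "paired",
      delta_ct_1 = d$delta_ct_1, delta_ct_2 = d$delta_ct_2,
      n_1 = n1, n_2 = n2, mtdnacn = mtdnacn_paired(n1, n2)
    )
  } else {
    mtdnacn_geomean(summaries)
  }

  flags <- summaries |>
    group_by(.data$sample_id) |>
    summarise(qc_flags = join_flags(unlist(strsplit(.data$flags, ","))),
              .groups = "drop")
  res |>
    left_join(flags, by = "sample_id") |>
    mutate(qc_flags = dplyr::coalesce(.data$qc_flags, "")) |>
    arrange(.data$sample_id)
}

#' Cross-plate drift of the reference control sample
#'
#' A reference DNA sample (by convention NA12878) run on every plate tracks
#' assay drift. This reports the per-plate reference mtDNAcn, the
#' across-plate mean, SD and CV, and flags plates whose reference value
#' deviates from the across-plate mean by more than `max_drift_pct`
#' percent. The report is informational: sample values are never
#' renormalized against the reference.
#'
#' @param results Result tibble (from [qpcr_mtdnacn()]) that includes a
#'   `plate_id` column, covering all plates.
#' @param reference_id Sample identifier of the reference control
#'   (default `"NA12878"`).
#' @param max_drift_pct Percent deviation from the across-plate mean that
#'   flags a plate (default 20).
#' @return An object of class `mtcn_ref_qc`: list with `per_plate` tibble
#'   (`plate_id`, `mtdnacn`, `deviation_pct`, `flagged`), `mean`, `sd`,
#'   `cv_pct`, and `verdict` (`"OK"`, `"DRIFT"` or `"WARN"` when the
#'   reference is absent).
#' @export
reference_sample_qc <- function(results, reference_id = "NA12878",
                                max_drift_pct = 20) {
  stopifnot(is.data.frame(results), "plate_id" %in% names(results))
  ref <- filter(results, .data$sample_id == reference_id)
  if (nrow(ref) == 0) {
    warn(paste0("Reference sample ", reference_id, " absent from results"))
    out <- list(per_plate = tibble(plate_id = character(), mtdnacn = numeric(),
                                   deviation_pct = numeric(), flagged = logical()),
                mean = NA_real_, sd = NA_real_, cv_pct = NA_real_,
                verdict = "WARN", reference_id = reference_id)
    return(structure(out, class = "mtcn_ref_qc"))
  }
  per_plate <- ref |>
    group_by(.data$plate_id) |>
    summarise(mtdnacn = mean(.data$mtdnacn), .groups = "drop")
  m <- mean(per_plate$mtdnacn)
  s <- if (nrow(per_plate) > 1) sd(per_plate$mtdnacn) else NA_real_
  per_plate <- per_plate |>
    mutate(deviation_pct = 100 * abs(.data$mtdnacn - m) / m,
           flagged = .data$deviation_pct > max_drift_pct)
  structure(list(
    per_plate = per_plate,
    mean = m, sd = s,
    cv_pct = if (is.na(s)) NA_real_ else 100 * s / m,
    verdict = if (any(per_plate$flagged)) "DRIFT" else "OK",
    reference_id = reference_id
  ), class = "mtcn_ref_qc")
}

#' @export
print.mtcn_ref_qc <- function(x, ...) {
  cat("Reference-sample QC (", x$reference_id, "): ", x$verdict, "\n", sep = "")
  cat(sprintf("  across-plate mean %.4g, SD %.4g, CV %.2f%%\n",
              x$mean, x$sd, x$cv_pct))
  print(x$per_plate)
  invisible(x)
}

#' Inter- and intra-day variability of mtDNAcn results
#'
#' Mirrors the standard validation design: the same samples assayed in
#' triplicate on consecutive days (inter-day) and a second time on the same
#' plate (intra-day). Per sample, the inter-day CV is the CV of per-day
#' mean mtDNAcn across distinct run dates, and the intra-day CV is the mean
#' CV across plates holding two or more results. An axis with a single
#' observation is reported `NA` (not assessable).
#'
#' @param results Result tibble with `sample_id`, `mtdnacn`, `run_date`,
#'   `plate_id` columns (one row per assay result).
#' @return Tibble `sample_id`, `n_days`, `inter_day_cv_pct`,
#'   `intra_day_cv_pct`.
#' @export
replicate_variability <- function(results) {
  stopifnot(all(c("sample_id", "mtdnacn", "run_date", "plate_id") %in%
                  names(results)))
  cv <- function(x) 100 * sd(x) / mean(x)
  inter <- results |>
    group_by(.data$sample_id, .data$run_date) |>
    summarise(day_mean = mean(.data$mtdnacn), .groups = "drop_last") |>
    summarise(n_days = dplyr::n(),
              inter_day_cv_pct = if (dplyr::n() >= 2) cv(.data$day_mean) else NA_real_,
              .groups = "drop")
  intra <- results |>
    group_by(.data$sample_id, .data$plate_id) |>
    summarise(n_on_plate = dplyr::n(),
              plate_cv = if (dplyr::n() >= 2) cv(.data$mtdnacn) else NA_real_,
              .groups = "drop_last") |>
    summarise(intra_day_cv_pct = if (all(is.na(.data$plate_cv))) NA_real_
              else mean(.data$plate_cv, na.rm = TRUE),
              .groups = "drop")
  left_join(inter, intra, by = "sample_id")
}

#' Packaged primer panel for the dual-gene assay
#'
#' The eight primers (forward and reverse for ND1, ND6, BECN1 and NEB) with
#' their reported melting temperatures, carried as assay metadata only — no
#' Tm or in-silico PCR computation is performed.
#'
#' @return Tibble `name`, `gene`, `orientation`, `sequence`, `reported_tm`.
#' @export
primer_panel <- function() {
  path <- system.file("extdata", "primer_panel.tsv", package = "mtcn",
                      mustWork = TRUE)
  panel <- readr::read_tsv(path, col_types = "ccccd", progress = FALSE)
  stopifnot(nrow(panel) == 8,
            all(panel$gene %in% ALL_GENES),
            all(grepl("^[ACGT]+$", panel$sequence)),
            !anyDuplicated(panel[c("gene", "orientation")]))
  panel
}
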