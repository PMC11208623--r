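#' Simulate a ground-truth mtDNAcn cohort
#'
#' Draws per-sample true relative mtDNAcn from a lognormal distribution
#' with moments matched to the requested group mean and SD (lognormal
#' rather than truncated normal so positivity needs no truncation). The
#' group defaults are the buccal-swab cohort summaries the simulator
#' emulates: infants 229.2 +/- 66.4 and mothers 136.7 +/- 41.8 relative
#' copies.
#'
#' @param n_infants,n_mothers Group sizes (either may be 0).
#' @param infant_mean,infant_sd,mother_mean,mother_sd Target moments of
#'   the true mtDNAcn distribution per group.
#' @param seed Optional RNG seed; fixed seed gives a bit-identical table.
#' @return Tibble `sample_id`, `group` (`"infant"`/`"mother"`),
#'   `true_mtdnacn`; generation parameters are stored in the `provenance`
#'   attribute.
#' @examples
#' simulate_cohort(3, 3, seed = 1)
#' @export
simulate_cohort <- function(n_infants = 0, n_mothers = 0,
                            infant_mean = 229.2, infant_sd = 66.4,
                            mother_mean = 136.7, mother_sd = 41.8,
                            seed = NULL) {
  stopifnot(n_infants >= 0, n_mothers >= 0,
            infant_mean > 0, infant_sd > 0, mother_mean > 0, mother_sd > 0)
  draw <- function(n, m, s) {
    # lognormal moment match: mean m, sd s
    sigma2 <- log(1 + (s / m)^2)
    rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
  }
  with_seed(seed, {
    infants <- draw(n_infants, infant_mean, infant_sd)
    mothers <- draw(n_mothers, mother_mean, mother_sd)
    out <- tibble(
      sample_id = c(sprintf("I%03d", seq_len(n_infants)),
                    sprintf("M%03d", seq_len(n_mothers))),
      group = rep(c("infant", "mother"), c(n_infants, n_mothers)),
      true_mtdnacn = c(infants, mothers)
    )
    attr(out, "provenance") <- list(
      n_infants = n_infants, n_mothers = n_mothers,
      infant_mean = infant_mean, infant_sd = infant_sd,
      mother_mean = mother_mean, mother_sd = mother_sd, seed = seed
    )
    out
  })
}

#' Simulate a qPCR Ct plate for a ground-truth cohort
#'
#' Emits the triplicate dual-gene plate design: for each sample, nuclear
#' Cts are the baseline plus Gaussian replicate noise, and mitochondrial
#' Cts sit `log(true mtDNAcn) / log(efficiency)` cycles earlier, so that
#' with zero noise and efficiency 2 the downstream paired estimator
#' recovers the true value exactly. One undetermined NTC well per gene is
#' appended. The baseline is defined at 2 ng template input; a different
#' `input_mass_ng` shifts every Ct by `-log(mass/2)/log(efficiency)`
#' cycles, leaving mtDNAcn unchanged.
#'
#' Replicate noise is homoscedastic Gaussian across genes — a simplifying
#' model of instrument and pipetting variability; efficiency exists here
#' for robustness testing only, the estimators always assume the ideal
#' value 2.
#'
#' @param truth Cohort tibble from [simulate_cohort()] (columns
#'   `sample_id`, `true_mtdnacn`).
#' @param ct_sd Replicate Ct noise SD in cycles (default 0.15).
#' @param nuclear_baseline_ct Mean nuclear Ct at 2 ng input (default 25).
#' @param efficiency Per-cycle amplification factor in (1, 2] (default 2).
#' @param replicates Wells per sample per gene (default 3).
#' @param input_mass_ng Template mass per well (default 2).
#' @param plate_id,run_date Plate metadata stamped on every row.
#' @param include_ntc Append one undetermined NTC well per gene.
#' @param seed Optional RNG seed.
#' @return Measurement tibble in the [read_ct_table()] schema.
#' @export
simulate_ct_plate <- function(truth, ct_sd = 0.15, nuclear_baseline_ct = 25,
                              efficiency = 2, replicates = 3,
                              input_mass_ng = 2, plate_id = "plate1",
                              run_date = as.Date("2024-01-01"),
                              include_ntc = TRUE, seed = NULL) {
  stopifnot(all(c("sample_id", "true_mtdnacn") %in% names(truth)),
            all(truth$true_mtdnacn > 0),
            ct_sd >= 0, efficiency > 1, efficiency <= 2, replicates >= 1,
            input_mass_ng > 0)
  base_ct <- nuclear_baseline_ct - log(input_mass_ng / 2) / log(efficiency)
  mito_base <- base_ct - log(truth$true_mtdnacn) / log(efficiency)
  if (any(mito_base < 0)) {
    abort(paste0("Simulated mitochondrial Ct would be negative; ",
                 "increase nuclear_baseline_ct"))
  }
  grid <- tidyr::expand_grid(
    sample_id = truth$sample_id,
    gene = ALL_GENES,
    replicate = seq_len(replicates)
  )
  base_for <- setNames(mito_base, truth$sample_id)
  grid$true_base <- ifelse(grid$gene %in% MITO_GENES,
                           base_for[grid$sample_id], base_ct)
  with_seed(seed, {
    grid$ct <- grid$true_base + rnorm(nrow(grid), sd = ct_sd)
    out <- grid |>
      mutate(plate_id = plate_id, run_date = run_date, is_ntc = FALSE,
             input_mass_ng = input_mass_ng) |>
      select("sample_id", "gene", "replicate", "ct", "plate_id",
             "run_date", "is_ntc", "input_mass_ng")
    if (include_ntc) {
      out <- bind_rows(out, tibble(
        sample_id = "NTC", gene = ALL_GENES, replicate = 1L,
        ct = NA_real_, plate_id = plate_id, run_date = run_date,
        is_ntc = TRUE, input_mass_ng = 0
      ))
    }
    out
  })
}

#' Toy genome specification for the lpWGS simulator
#'
#' A deliberately small reference (two 200 kb autosomes plus the 16,569 bp
#' mitochondrial contig) that keeps simulated alignments cheap while
#' preserving the quantity under test, the mitochondrial-to-autosomal
#' depth ratio.
#'
#' @param autosomes Tibble `name`, `length`.
#' @param mito_name,mito_length Mitochondrial contig.
#' @param read_length Read length in bp (default 100).
#' @param target_autosomal_depth Mean autosomal depth in X (default 1).
#' @return A `mtcn_genome_spec` list.
#' @export
toy_genome_spec <- function(autosomes = tibble(name = c("chr1", "chr2"),
                                               length = c(200000, 200000)),
                            mito_name = "chrM", mito_length = 16569,
                            read_length = 100,
                            target_autosomal_depth = 1) {
  stopifnot(all(autosomes$length >= read_length),
            mito_length >= read_length, target_autosomal_depth >= 0)
  structure(list(
    autosomes = autosomes,
    mito = tibble(name = mito_name, length = mito_length),
    read_length = as.integer(read_length),
    target_autosomal_depth = target_autosomal_depth
  ), class = "mtcn_genome_spec")
}

genome_contigs <- function(genome) {
  bind_rows(genome$autosomes, genome$mito)
}

#' Simulate aligned lpWGS reads for one sample
#'
#' Per contig, the read count is Poisson with mean
#' `length * depth / read_length`, where the mitochondrial depth is
#' `target_autosomal_depth * true_mtdnacn / 2` (inverting the coverage
#' formula). Start positions are uniform; every read is a perfect primary
#' alignment (full-match CIGAR, MAPQ 60), since the estimator, not the
#' aligner, is under test.
#'
#' @param true_mtdnacn True relative copy number of the sample.
#' @param genome A [toy_genome_spec()].
#' @param seed Optional RNG seed.
#' @return Read tibble (`qname`, `flag`, `contig`, `pos`, `mapq`, `cigar`)
#'   with the `header_contigs` attribute; feed to [mean_depth()] or
#'   [write_sam()].
#' @export
simulate_lpwgs_reads <- function(true_mtdnacn, genome = toy_genome_spec(),
                                 seed = NULL) {
  stopifnot(inherits(genome, "mtcn_genome_spec"), true_mtdnacn > 0)
  contigs <- genome_contigs(genome)
  depth <- c(rep(genome$target_autosomal_depth, nrow(genome$autosomes)),
             genome$target_autosomal_depth * true_mtdnacn / 2)
  rl <- genome$read_length
  with_seed(seed, {
    n_reads <- rpois(nrow(contigs), contigs$length * depth / rl)
    reads <- tibble(
      contig = rep(contigs$name, n_reads),
      pos = unlist(purrr::map2(contigs$length, n_reads, function(L, n) {
        if (n == 0) integer(0) else sample.int(L - rl + 1L, n, replace = TRUE)
      })),
      flag = 0L,
      mapq = 60L,
      cigar = sprintf("%dM", rl)
    )
    reads$qname <- sprintf("r%07d", seq_len(nrow(reads)))
    reads <- select(reads, "qname", "flag", "contig", "pos", "mapq", "cigar")
    attr(reads, "header_contigs") <- contigs
    reads
  })
}

#' Simulate lpWGS alignment files for a cohort
#'
#' Writes one SAM per sample plus a toy-genome FASTA (random sequence; the
#' reads carry no bases, so the FASTA documents contig names and lengths)
#' and a provenance JSON recording all parameters and the seed.
#'
#' @param truth Cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param genome A [toy_genome_spec()].
#' @param seed Optional RNG seed covering genome sequence and all samples.
#' @return Tibble `sample_id`, `true_mtdnacn`, `sam` (file path).
#' @export
simulate_lpwgs_alignments <- function(truth, dir,
                                      genome = toy_genome_spec(),
                                      seed = NULL) {
  stopifnot(all(c("sample_id", "true_mtdnacn") %in% names(truth)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contigs <- genome_contigs(genome)
  with_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(contigs$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- contigs$name
    fasta <- file.path(dir, "toy_genome.fa")
    Biostrings::writeXStringSet(seqs, fasta)
    paths <- vapply(seq_len(nrow(truth)), function(i) {
      reads <- simulate_lpwgs_reads(truth$true_mtdnacn[i], genome,
                                    seed = NULL)
      write_sam(reads, contigs,
                file.path(dir, paste0(truth$sample_id[i], ".sam")))
    }, character(1))
    jsonlite::write_json(
      list(genome = list(contigs = contigs,
                         read_length = genome$read_length,
                         target_autosomal_depth = genome$target_autosomal_depth),
           n_samples = nrow(truth), seed = seed),
      file.path(dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA)
    tibble(sample_id = truth$sample_id,
           true_mtdnacn = truth$true_mtdnacn, sam = paths)
  })
}

#' Analytic (noiseless) coverage summary for a true mtDNAcn
#'
#' The sampling-free limit of [simulate_lpwgs_reads()]: every autosome at
#' exactly the target depth and the mitochondrial contig at
#' `target_autosomal_depth * true_mtdnacn / 2`, so
#' [mtdnacn_from_coverage()] returns the true value exactly. Used for
#' noiseless identity checks.
#'
#' @inheritParams simulate_lpwgs_reads
#' @return An `mtcn_coverage` object.
#' @export
expected_depth_profile <- function(true_mtdnacn, genome = toy_genome_spec()) {
  stopifnot(inherits(genome, "mtcn_genome_spec"), true_mtdnacn > 0)
  contigs <- genome_contigs(genome)
  cls <- classify_contigs(contigs)
  depth <- c(rep(genome$target_autosomal_depth, nrow(genome$autosomes)),
             genome$target_autosomal_depth * true_mtdnacn / 2)
  per_contig <- cls |>
    mutate(mean_depth = depth, aligned_bases = depth * .data$length) |>
    select("contig", "length", "class", "aligned_bases", "mean_depth")
  mito_depth <- depth[length(depth)]
  expected_reads <- round(genome$mito$length * mito_depth /
                            genome$read_length)
  new_coverage_summary(per_contig,
                       mito_read_count = expected_reads,
                       reads_kept = NA_integer_,
                       reads_filtered = c(unmapped = 0L, secondary = 0L,
                                          supplementary = 0L, duplicate = 0L,
                                          low_mapq = 0L),
                       n_records = NA_integer_)
}

#' Synthetic haplogroup panel sequences
#'
#' Generates a random ancestral mitochondrial-length sequence and derives
#' one synthetic "haplogroup" per label by planting a label-specific set
#' of substitutions. These are test fixtures with the combinatorial
#' structure of haplogroup consensus sequences (shared backbone, private
#' variants) and no biological content; they are clearly not PhyloTree
#' references.
#'
#' @param haplogroups Labels (default six spanning the packaged region
#'   map).
#' @param length Sequence length (default 16,569 bp).
#' @param n_variants Substitutions planted per haplogroup (default 25).
#' @param seed RNG seed (default 101, fixed so the packaged fixture panel
#'   is stable).
#' @return Named character vector of sequences.
#' @export
simulate_haplogroup_sequences <- function(haplogroups = c("A2", "B2", "C1",
                                                          "D1", "H1", "L3"),
                                          length = 16569, n_variants = 25,
                                          seed = 101) {
  stopifnot(length >= 100, n_variants >= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ancestral <- sample(bases, length, replace = TRUE)
    out <- vapply(haplogroups, function(h) {
      s <- ancestral
      at <- sample.int(length, n_variants)
      s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1),
                      character(1))
      paste(s, collapse = "")
    }, character(1))
    setNames(out, haplogroups)
  })
}

#' Plant m random substitutions in a sequence
#'
#' Test helper for mutation-robustness checks: substitutes `m` distinct
#' positions with a different base each.
#'
#' @param sequence DNA string.
#' @param m Number of substitutions.
#' @param seed Optional RNG seed.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, m, seed = NULL) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(m <= length(s))
  with_seed(seed, {
    at <- sample.int(length(s), m)
    s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1),
                    character(1))
    paste(s, collapse = "")
  })
}
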