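#' Classify alignment contigs as autosome, sex, mitochondrial or other
#'
#' Recognizes the common human reference dialects case-insensitively:
#' `chrM`, `chrMT`, `MT`, `M` and `NC_012920.1` are mitochondrial,
#' `chr1`..`chr22` / `1`..`22` are autosomes, `chrX`/`chrY`/`X`/`Y` are sex
#' chromosomes, and everything else (decoys, unplaced scaffolds, EBV) is
#' `other`. Explicit overrides win. Estimation requires exactly one
#' mitochondrial contig.
#'
#' @param contigs Tibble/data frame with columns `name` and `length`, or a
#'   named numeric vector of contig lengths.
#' @param overrides Optional named character vector `c(contig = class)` or
#'   data frame with columns `contig`, `class`.
#' @return Tibble `contig`, `length`, `class`.
#' @examples
#' classify_contigs(c(chr1 = 2e5, chrM = 16569))
#' @export
classify_contigs <- function(contigs, overrides = NULL) {
  if (!is.data.frame(contigs)) {
    contigs <- tibble(name = names(contigs), length = unname(as.numeric(contigs)))
  }
  stopifnot(all(c("name", "length") %in% names(contigs)))
  if (anyDuplicated(contigs$name)) abort("Contig names must be unique")

  low <- tolower(contigs$name)
  cls <- rep("other", nrow(contigs))
  cls[low %in% c("chrm", "chrmt", "mt", "m", "nc_012920.1")] <- "mitochondrial"
  cls[low %in% c(paste0("chr", 1:22), as.character(1:22))] <- "autosome"
  cls[low %in% c("chrx", "chry", "x", "y")] <- "sex"

  if (!is.null(overrides)) {
    if (is.data.frame(overrides)) {
      overrides <- setNames(overrides$class, overrides$contig)
    }
    bad <- !overrides %in% c("autosome", "sex", "mitochondrial", "other")
    if (any(bad)) abort(paste0("Unknown contig class: ",
                               paste(unique(overrides[bad]), collapse = ", ")))
    hit <- contigs$name %in% names(overrides)
    cls[hit] <- unname(overrides[contigs$name[hit]])
  }

  n_mito <- sum(cls == "mitochondrial")
  if (n_mito != 1) {
    abort(paste0("Exactly one mitochondrial contig is required; found ",
                 n_mito))
  }
  tibble(contig = contigs$name, length = as.numeric(contigs$length), class = cls)
}

#' Read-filtering policy for depth computation
#'
#' At 0.5-1X genome depth, duplicate reads inflate coverage and MAPQ-0
#' reads include NUMT cross-mapping between the mitochondrial genome and
#' its nuclear-embedded copies, so both are excluded by default. Set every
#' drop to `FALSE` and `min_mapq = 0` to reproduce unfiltered coverage.
#'
#' @param min_mapq Minimum mapping quality kept (default 1).
#' @param drop_duplicates,drop_secondary,drop_supplementary,drop_unmapped
#'   Flag-based exclusions (all default `TRUE`).
#' @return A `mtcn_filter_policy` list.
#' @export
read_filter_policy <- function(min_mapq = 1L, drop_duplicates = TRUE,
                               drop_secondary = TRUE,
                               drop_supplementary = TRUE,
                               drop_unmapped = TRUE) {
  stopifnot(min_mapq >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_secondary = isTRUE(drop_secondary),
                 drop_supplementary = isTRUE(drop_supplementary),
                 drop_unmapped = isTRUE(drop_unmapped)),
            class = "mtcn_filter_policy")
}

#' Load an alignment file into a read table
#'
#' Reads a SAM or BAM file via Rsamtools (SAM input is converted to BAM in
#' a temporary location first) and returns one row per record with the
#' fields needed for depth computation. Header contigs are attached as the
#' `header_contigs` attribute.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @return Tibble `qname`, `flag`, `contig`, `pos`, `mapq`, `cigar`;
#'   attribute `header_contigs` is a tibble `name`, `length`.
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  reads <- tibble(
    qname = b$qname,
    flag = as.integer(b$flag),
    contig = as.character(b$rname),
    pos = as.integer(b$pos),
    mapq = as.integer(b$mapq),
    cigar = b$cigar
  )
  attr(reads, "header_contigs") <- tibble(name = names(targets),
                                          length = unname(as.numeric(targets)))
  reads
}

#' Write a read table as a SAM file
#'
#' Minimal SAM emitter for simulated alignments: a `@HD`/`@SQ` header from
#' the contig table and one line per read with `*` sequence and quality.
#'
#' @param reads Tibble with `flag`, `contig`, `pos`, `mapq`, `cigar` and
#'   optionally `qname`.
#' @param contigs Tibble `name`, `length` describing the reference.
#' @param path Output path (conventionally `.sam`).
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, contigs, path) {
  stopifnot(all(c("flag", "contig", "pos", "mapq", "cigar") %in% names(reads)))
  qname <- if ("qname" %in% names(reads)) reads$qname
           else sprintf("r%06d", seq_len(nrow(reads)))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name,
                      as.integer(contigs$length)))
  body <- if (nrow(reads) > 0) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            qname, reads$flag, reads$contig, reads$pos, reads$mapq,
            reads$cigar)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

# Applies the filter policy, tagging each excluded record with the first
# matching reason (unmapped > secondary > supplementary > duplicate >
# low_mapq). Returns list(kept = tibble, filtered = named integer counts).
filter_reads <- function(reads, policy) {
  stopifnot(inherits(policy, "mtcn_filter_policy"))
  reason <- rep(NA_character_, nrow(reads))
  f <- reads$flag
  mark <- function(cond, label) {
    reason[is.na(reason) & cond] <<- label
  }
  if (policy$drop_unmapped) mark(bitwAnd(f, 4L) > 0L, "unmapped")
  if (policy$drop_secondary) mark(bitwAnd(f, 256L) > 0L, "secondary")
  if (policy$drop_supplementary) mark(bitwAnd(f, 2048L) > 0L, "supplementary")
  if (policy$drop_duplicates) mark(bitwAnd(f, 1024L) > 0L, "duplicate")
  mark(!is.na(reads$mapq) & reads$mapq < policy$min_mapq, "low_mapq")
  counts <- c(unmapped = 0L, secondary = 0L, supplementary = 0L,
              duplicate = 0L, low_mapq = 0L)
  tab <- table(reason)
  counts[names(tab)] <- as.integer(tab)
  list(kept = reads[is.na(reason), , drop = FALSE], filtered = counts)
}

# Reference-consuming aligned length per record: CIGAR M/=/X bases only
# (deletions and skips advance the reference but are not sequenced bases;
# clips and insertions consume no reference).
aligned_ref_bases <- function(cigar) {
  out <- numeric(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    tab <- GenomicAlignments::cigarOpTable(cigar[ok])
    out[ok] <- rowSums(tab[, c("M", "=", "X"), drop = FALSE])
  }
  out
}

resolve_alignments <- function(alignments, classification) {
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_alignments(alignments)
  }
  stopifnot(is.data.frame(alignments))
  if (is.null(classification)) {
    hdr <- attr(alignments, "header_contigs")
    if (is.null(hdr)) {
      abort("classification is required when alignments carry no header contigs")
    }
    classification <- classify_contigs(hdr)
  }
  list(reads = alignments, classification = classification)
}

new_coverage_summary <- function(per_contig, mito_read_count, reads_kept,
                                 reads_filtered, n_records) {
  auto <- per_contig[per_contig$class == "autosome", , drop = FALSE]
  mito <- per_contig[per_contig$class == "mitochondrial", , drop = FALSE]
  structure(list(
    per_contig = per_contig,
    autosomal_mean_depth = sum(auto$aligned_bases) / sum(auto$length),
    mito_mean_depth = mito$aligned_bases / mito$length,
    mito_read_count = mito_read_count,
    reads_kept = reads_kept,
    reads_filtered = reads_filtered,
    n_records = n_records
  ), class = "mtcn_coverage")
}

#' Per-contig mean depth from aligned reads (streaming)
#'
#' Single pass over the records: each read passing the filter policy adds
#' its reference-consuming aligned length (CIGAR `M`/`=`/`X` bases) to its
#' contig's base count; mean depth per contig is aligned bases over contig
#' length. The aggregate autosomal mean is length-weighted over autosomes
#' only — sex chromosomes and unplaced contigs are excluded so the ratio is
#' not biased by the donor's sex. Record order is irrelevant.
#'
#' @param alignments A SAM/BAM path, or a read tibble from
#'   [read_alignments()] / [simulate_lpwgs_reads()].
#' @param classification Contig classification from [classify_contigs()];
#'   defaults to classifying the alignment header.
#' @param policy Filter policy from [read_filter_policy()].
#' @return An `mtcn_coverage` object: `per_contig` tibble (`contig`,
#'   `class`, `length`, `aligned_bases`, `mean_depth`),
#'   `autosomal_mean_depth`, `mito_mean_depth`, `mito_read_count`,
#'   `reads_kept`, `reads_filtered` (named counts), `n_records`.
#' @export
mean_depth <- function(alignments, classification = NULL,
                       policy = read_filter_policy()) {
  inp <- resolve_alignments(alignments, classification)
  classification <- inp$classification
  flt <- filter_reads(inp$reads, policy)
  kept <- flt$kept

  unknown <- setdiff(unique(kept$contig), classification$contig)
  if (length(unknown) > 0) {
    abort(paste0("Records reference contig(s) absent from the header/",
                 "classification: ", paste(unknown, collapse = ", ")))
  }

  kept$aligned <- aligned_ref_bases(kept$cigar)
  by_contig <- kept |>
    group_by(.data$contig) |>
    summarise(aligned_bases = sum(.data$aligned), n_reads = dplyr::n(),
              .groups = "drop")
  per_contig <- classification |>
    left_join(by_contig, by = "contig") |>
    mutate(aligned_bases = dplyr::coalesce(.data$aligned_bases, 0),
           n_reads = dplyr::coalesce(.data$n_reads, 0L),
           mean_depth = .data$aligned_bases / .data$length)
  mito_reads <- per_contig$n_reads[per_contig$class == "mitochondrial"]
  new_coverage_summary(select(per_contig, -"n_reads"),
                       mito_read_count = mito_reads,
                       reads_kept = nrow(kept),
                       reads_filtered = flt$filtered,
                       n_records = nrow(inp$reads))
}

#' Brute-force per-base pileup depth (test oracle)
#'
#' Computes depth at every reference position by explicit counting — for
#' each kept read, walking its CIGAR and incrementing a per-base counter
#' over `M`/`=`/`X` spans (deletions/skips advance without counting) — then
#' averages per contig. Intended for toy-scale genomes as an independent
#' check of [mean_depth()]; under identical filters the two must agree
#' field-by-field.
#'
#' @inheritParams mean_depth
#' @return An `mtcn_coverage` object (same shape as [mean_depth()]).
#' @export
pileup_depth_oracle <- function(alignments, classification = NULL,
                                policy = read_filter_policy()) {
  inp <- resolve_alignments(alignments, classification)
  classification <- inp$classification
  if (sum(classification$length) > 1e7) {
    abort("pileup_depth_oracle is restricted to toy genomes (< 10 Mb)")
  }
  flt <- filter_reads(inp$reads, policy)
  kept <- flt$kept
  unknown <- setdiff(unique(kept$contig), classification$contig)
  if (length(unknown) > 0) {
    abort(paste0("Records reference contig(s) absent from the header/",
                 "classification: ", paste(unknown, collapse = ", ")))
  }

  depth <- lapply(setNames(classification$length, classification$contig),
                  function(L) integer(L))
  if (nrow(kept) > 0) {
    ok <- !is.na(kept$cigar) & kept$cigar != "*"
    ops <- GenomicAlignments::explodeCigarOps(kept$cigar[ok])
    lens <- GenomicAlignments::explodeCigarOpLengths(kept$cigar[ok])
    contig_ok <- kept$contig[ok]
    pos_ok <- kept$pos[ok]
    for (i in seq_along(ops)) {
      at <- pos_ok[i]
      v <- depth[[contig_ok[i]]]
      for (j in seq_along(ops[[i]])) {
        op <- ops[[i]][j]
        w <- lens[[i]][j]
        if (op %in% c("M", "=", "X")) {
          if (at + w - 1 > length(v)) abort("Read extends beyond contig end")
          v[at:(at + w - 1)] <- v[at:(at + w - 1)] + 1L
          at <- at + w
        } else if (op %in% c("D", "N")) {
          at <- at + w
        }
      }
      depth[[contig_ok[i]]] <- v
    }
  }

  per_contig <- classification |>
    mutate(aligned_bases = unname(vapply(depth[.data$contig],
                                         function(v) sum(as.numeric(v)),
                                         numeric(1))),
           mean_depth = .data$aligned_bases / .data$length)
  mito_contig <- classification$contig[classification$class == "mitochondrial"]
  mito_reads <- sum(kept$contig == mito_contig)
  new_coverage_summary(per_contig,
                       mito_read_count = mito_reads,
                       reads_kept = nrow(kept),
                       reads_filtered = flt$filtered,
                       n_records = nrow(inp$reads))
}

#' mtDNAcn from a coverage summary
#'
#' Each cell carries two copies of every autosome, so the mitochondrial
#' copy number per cell is twice the mitochondrial-to-autosomal mean-depth
#' ratio: `mtDNAcn = (mito depth / autosomal depth) * 2`. Equal depths
#' therefore return exactly 2 (the diploid identity).
#'
#' @param summary `mtcn_coverage` object from [mean_depth()],
#'   [pileup_depth_oracle()] or [expected_depth_profile()].
#' @param sample_id Sample label for the result row.
#' @return Tibble `sample_id`, `method` (`"lpwgs"`), `mtdnacn`,
#'   `mito_mean_depth`, `autosomal_mean_depth`, `mito_read_count`,
#'   `qc_flags` (`LOW_MITO_COVERAGE` when the mitochondrial depth is zero).
#' @export
mtdnacn_from_coverage <- function(summary, sample_id = "sample") {
  stopifnot(inherits(summary, "mtcn_coverage"))
  if (!is.finite(summary$autosomal_mean_depth) ||
      summary$autosomal_mean_depth <= 0) {
    abort("Autosomal mean depth is zero; mtDNAcn is undefined")
  }
  cn <- (summary$mito_mean_depth / summary$autosomal_mean_depth) * 2
  tibble(
    sample_id = sample_id,
    method = "lpwgs",
    mtdnacn = cn,
    mito_mean_depth = summary$mito_mean_depth,
    autosomal_mean_depth = summary$autosomal_mean_depth,
    mito_read_count = as.integer(summary$mito_read_count),
    qc_flags = if (summary$mito_mean_depth == 0) "LOW_MITO_COVERAGE" else ""
  )
}

#' @export
print.mtcn_coverage <- function(x, ...) {
  cat("Coverage summary:", x$reads_kept, "reads kept of", x$n_records,
      "records\n")
  cat(sprintf("  autosomal mean depth %.4gX, mitochondrial %.4gX\n",
              x$autosomal_mean_depth, x$mito_mean_depth))
  print(x$per_contig)
  invisible(x)
}
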