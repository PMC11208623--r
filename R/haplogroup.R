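#' Distinct k-mers of a (possibly circular) DNA sequence
#'
#' Slides a window of width `k` across the sequence; in circular mode the
#' mitochondrial origin is crossed by appending the first `k - 1` bases, so
#' every rotation of the genome yields the same k-mer set. K-mers
#' containing ambiguity codes are dropped with a warning.
#'
#' @param sequence A single DNA string (A/C/G/T, case-insensitive).
#' @param k Word size.
#' @param circular Wrap around the origin (default `TRUE`, matching the
#'   circular mitochondrial genome).
#' @return Character vector of distinct k-mers.
#' @examples
#' sequence_kmers("ACGTACGT", k = 4, circular = FALSE)
#' @export
sequence_kmers <- function(sequence, k, circular = TRUE) {
  stopifnot(length(sequence) == 1, k >= 1)
  s <- toupper(as.character(sequence))
  if (nchar(s) < k) {
    abort(paste0("Sequence (", nchar(s), " bp) is shorter than k = ", k))
  }
  ext <- if (circular) paste0(s, substr(s, 1, k - 1)) else s
  n <- nchar(ext) - k + 1
  kmers <- substring(ext, seq_len(n), seq_len(n) + k - 1)
  bad <- grepl("[^ACGT]", kmers)
  if (any(bad)) {
    warn(paste0("Dropping ", sum(bad), " k-mer(s) containing ambiguity codes"))
    kmers <- kmers[!bad]
  }
  unique(kmers)
}

#' Default macrohaplogroup-to-region map
#'
#' Editable fixture mapping haplogroup name prefixes to broad geographic
#' regions (e.g. macrohaplogroups A-D to "Americas"). Lookup uses
#' longest-prefix match, so a more specific prefix can override a
#' macrohaplogroup assignment.
#'
#' @param path Optional TSV with columns `prefix`, `region`; default the
#'   packaged map.
#' @return Tibble `prefix`, `region`.
#' @export
default_region_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "haplogroup_regions.tsv",
                                package = "mtcn", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Build a haplogroup k-mer panel from labeled sequences
#'
#' For each labeled mitochondrial sequence, records its set of distinct
#' k-mers. This is a deliberately simplified k-mer haplogroup library in
#' the spirit of Phy-mer-style classifiers: it does not reproduce any
#' published tool's library, weighting or PhyloTree versioning, and the
#' packaged fixtures are synthetic sequences, not real haplogroup
#' references (building a panel from real consensus sequences is a user
#' path).
#'
#' @param sequences Named character vector of DNA sequences (names are
#'   haplogroup labels), a named `Biostrings::DNAStringSet`, or a FASTA
#'   path whose record names are haplogroup labels.
#' @param k Word size (default 12; `4^12` vastly exceeds the 16.6 kb
#'   mitochondrial genome, so chance k-mer collisions are rare while a few
#'   private variants still leave most k-mers intact).
#' @param circular Treat sequences as circular (default `TRUE`).
#' @param region_map Tibble `prefix`, `region`; default
#'   [default_region_map()].
#' @return An `mtcn_kmer_panel` object: `k`, `entries` (named list of
#'   k-mer character vectors), `region_map`.
#' @export
build_kmer_panel <- function(sequences, k = 12, circular = TRUE,
                             region_map = default_region_map()) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences),
                          sub("\\s.*$", "", names(sequences)))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(nzchar(names(sequences))))
  entries <- lapply(sequences, sequence_kmers, k = k, circular = circular)
  structure(list(k = as.integer(k), circular = circular,
                 entries = entries, region_map = region_map),
            class = "mtcn_kmer_panel")
}

#' @export
print.mtcn_kmer_panel <- function(x, ...) {
  cat("k-mer haplogroup panel: k =", x$k, ",", length(x$entries),
      "haplogroups\n")
  for (h in names(x$entries)) {
    cat(sprintf("  %s: %d k-mers\n", h, length(x$entries[[h]])))
  }
  invisible(x)
}

#' Serialize / load a k-mer panel
#'
#' TSV with columns `haplogroup`, `kmer`; the word size is implied by the
#' k-mers themselves.
#'
#' @param panel An `mtcn_kmer_panel`.
#' @param path TSV path.
#' @param region_map Region map attached on load.
#' @return `write_kmer_panel` the path invisibly; `read_kmer_panel` the
#'   panel.
#' @export
write_kmer_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mtcn_kmer_panel"))
  df <- tibble(
    haplogroup = rep(names(panel$entries),
                     lengths(panel$entries)),
    kmer = unlist(panel$entries, use.names = FALSE)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_kmer_panel
#' @export
read_kmer_panel <- function(path, region_map = default_region_map()) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  k <- unique(nchar(df$kmer))
  stopifnot(length(k) == 1)
  entries <- split(df$kmer, df$haplogroup)
  entries <- lapply(entries, unique)
  structure(list(k = as.integer(k), circular = TRUE, entries = entries,
                 region_map = region_map),
            class = "mtcn_kmer_panel")
}

region_for_haplogroup <- function(haplogroup, region_map) {
  if (is.na(haplogroup)) return(NA_character_)
  prefixes <- region_map$prefix[order(-nchar(region_map$prefix))]
  for (p in prefixes) {
    if (startsWith(haplogroup, p)) {
      return(region_map$region[region_map$prefix == p][1])
    }
  }
  NA_character_
}

#' Call the haplogroup of a mitochondrial query sequence
#'
#' Scores every panel haplogroup by the fraction of its k-mers found in
#' the query (asymmetric on purpose: extra query content, such as reads
#' beyond the consensus, costs nothing). The best-scoring haplogroup is
#' the call; exact score ties are broken lexicographically and flagged
#' `TIED`. A query whose best score falls below `min_score` is
#' `"unclassified"`: chance k-mer collisions between an unrelated query
#' and a 16.6 kb panel entry give an expected shared fraction of roughly
#' `query length / 4^k` (a fraction of a percent at k = 12), so the
#' default floor of 0.01 separates noise from even heavily mutated true
#' matches, which retain scores near 1. The region is attached by
#' longest-prefix match in the panel's region map.
#'
#' @param query A single consensus sequence (string or FASTA path with one
#'   record), or a character vector of reads.
#' @param panel An `mtcn_kmer_panel`.
#' @param sample_id Label carried into the call.
#' @param circular Whether a single-sequence query is circular (reads are
#'   always treated as linear).
#' @param min_score Scores below this are reported as `"unclassified"`
#'   (default 0.01).
#' @return An `mtcn_haplogroup_call`: `sample_id`, `best`, `score`,
#'   `region`, `flags`, and the full `ranked` tibble
#'   (`haplogroup`, `score`, non-increasing).
#' @export
call_haplogroup <- function(query, panel, sample_id = "query",
                            circular = TRUE, min_score = 0.01) {
  stopifnot(inherits(panel, "mtcn_kmer_panel"))
  if (is.character(query) && length(query) == 1 && file.exists(query)) {
    query <- as.character(Biostrings::readDNAStringSet(query))
  }
  qk <- if (length(query) == 1) {
    sequence_kmers(query, panel$k, circular = circular)
  } else {
    unique(unlist(lapply(query, sequence_kmers, k = panel$k,
                         circular = FALSE)))
  }
  if (length(qk) == 0) abort("Query yields no valid k-mers")

  scores <- vapply(panel$entries,
                   function(e) sum(e %in% qk) / length(e), numeric(1))
  ranked <- tibble(haplogroup = names(scores), score = unname(scores)) |>
    arrange(dplyr::desc(.data$score), .data$haplogroup)

  flags <- character(0)
  if (ranked$score[1] < min_score) {
    best <- "unclassified"
    score <- ranked$score[1]
    region <- NA_character_
  } else {
    best <- ranked$haplogroup[1]
    score <- ranked$score[1]
    if (nrow(ranked) > 1 && ranked$score[2] == ranked$score[1]) {
      flags <- c(flags, "TIED")
    }
    region <- region_for_haplogroup(best, panel$region_map)
  }
  structure(list(sample_id = sample_id, best = best, score = score,
                 region = region, flags = join_flags(flags),
                 ranked = ranked),
            class = "mtcn_haplogroup_call")
}

#' @export
print.mtcn_haplogroup_call <- function(x, ...) {
  cat(sprintf("%s: %s (score %.4f, region %s)%s\n", x$sample_id, x$best,
              x$score, x$region %||% "NA",
              if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' @rdname call_haplogroup
#' @param x An `mtcn_haplogroup_call`.
#' @param ... Unused.
#' @export
tidy.mtcn_haplogroup_call <- function(x, ...) x$ranked

#' @export
as_tibble.mtcn_haplogroup_call <- function(x, ...) {
  tibble(sample_id = x$sample_id, best = x$best, score = x$score,
         region = x$region, flags = x$flags)
}

#' Tally haplogroup calls by region
#'
#' @param calls A list of `mtcn_haplogroup_call` objects, or a data frame
#'   with a `region` column.
#' @return Tibble `region`, `n`, ordered by decreasing count then region
#'   name; unclassified calls count under `"unclassified"`. Empty input
#'   gives an empty tally.
#' @export
region_tally <- function(calls) {
  regions <- if (is.data.frame(calls)) {
    calls$region
  } else {
    vapply(calls, function(x) {
      stopifnot(inherits(x, "mtcn_haplogroup_call"))
      x$region %||% NA_character_
    }, character(1))
  }
  if (length(regions) == 0) {
    return(tibble(region = character(), n = integer()))
  }
  regions[is.na(regions)] <- "unclassified"
  tibble(region = regions) |>
    dplyr::count(.data$region, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$region)
}
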