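#' Pearson product-moment correlation with strict input checks
#'
#' Thin validation wrapper around [stats::cor()]: requires equal-length
#' finite vectors of at least three observations and nonzero variance in
#' both (a degenerate input raises an error rather than propagating `NaN`).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("Pearson r requires at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson r is undefined for a zero-variance input")
  }
  cor(x, y, method = "pearson")
}

#' Cohort summary (n, mean, sample SD)
#'
#' @param data Data frame of per-sample values.
#' @param value Column holding the values (default `mtdnacn`).
#' @param group Optional grouping column (e.g. infant vs mother); when
#'   omitted, a single overall row is returned.
#' @return Tibble `group` (if grouped), `n`, `mean`, `sd`. The SD uses the
#'   n-1 denominator and is `NA` (not assessable) for groups of one.
#' @examples
#' truth <- simulate_cohort(5, 5, seed = 1)
#' group_summary(truth, true_mtdnacn, group)
#' @export
group_summary <- function(data, value = mtdnacn, group = NULL) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  if (!rlang::quo_is_null(group)) data <- group_by(data, !!group)
  data |>
    summarise(n = dplyr::n(),
              mean = mean(!!value),
              sd = if (dplyr::n() >= 2) sd(!!value) else NA_real_,
              .groups = "drop")
}

#' Pairwise concordance between mtDNAcn methods
#'
#' Validates agreement between estimators (e.g. paired qPCR, geomean qPCR,
#' lpWGS) run on the same samples: for every method pair, the Pearson r
#' over samples with both estimates present. Concordance is computed on the
#' raw mtDNAcn scale by default; `log_scale = TRUE` correlates
#' log-transformed values instead.
#'
#' @param data Long tibble with columns `sample_id`, `method`, `mtdnacn`
#'   (e.g. stacked outputs of [qpcr_mtdnacn()] and
#'   [mtdnacn_from_coverage()]).
#' @param methods Optional subset/ordering of methods; default all present.
#' @param log_scale Correlate `log(mtdnacn)` instead of raw values.
#' @return An `mtcn_concordance` object; see [tidy.mtcn_concordance()] for
#'   the per-pair table and [autoplot.mtcn_concordance()] for scatter
#'   plots.
#' @examples
#' truth <- simulate_cohort(4, 4, seed = 1)
#' plate <- simulate_ct_plate(truth, ct_sd = 0, seed = 1)
#' ests <- rbind(
#'   qpcr_mtdnacn(plate)[c("sample_id", "method", "mtdnacn")],
#'   qpcr_mtdnacn(plate, method = "geomean")[c("sample_id", "method", "mtdnacn")]
#' )
#' method_concordance(ests)
#' @export
method_concordance <- function(data, methods = NULL, log_scale = FALSE) {
  stopifnot(all(c("sample_id", "method", "mtdnacn") %in% names(data)))
  if (any(data$mtdnacn <= 0)) abort("mtDNAcn values must be strictly positive")
  methods <- methods %||% sort(unique(data$method))
  if (length(methods) < 2) abort("Concordance requires at least two methods")
  wide <- data |>
    filter(.data$method %in% methods) |>
    select("sample_id", "method", "mtdnacn") |>
    tidyr::pivot_wider(names_from = "method", values_from = "mtdnacn")

  pair_idx <- utils::combn(methods, 2, simplify = FALSE)
  pairs <- purrr::map_dfr(pair_idx, function(p) {
    ok <- complete.cases(wide[p])
    n <- sum(ok)
    if (n < 3) {
      abort(paste0("Fewer than 3 samples shared between methods ",
                   p[1], " and ", p[2]))
    }
    x <- wide[[p[1]]][ok]
    y <- wide[[p[2]]][ok]
    if (log_scale) { x <- log(x); y <- log(y) }
    tibble(method_a = p[1], method_b = p[2], n = n,
           pearson_r = pearson_r(x, y))
  })
  structure(list(pairs = pairs, wide = wide, methods = methods,
                 log_scale = log_scale),
            class = "mtcn_concordance")
}

#' @export
print.mtcn_concordance <- function(x, ...) {
  cat("Method concordance (", if (x$log_scale) "log" else "raw",
      " mtDNAcn scale), ", length(x$methods), " methods:\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' @rdname method_concordance
#' @param x An `mtcn_concordance` object.
#' @param ... Unused.
#' @export
tidy.mtcn_concordance <- function(x, ...) x$pairs

#' @rdname method_concordance
#' @export
glance.mtcn_concordance <- function(x, ...) {
  tibble(n_methods = length(x$methods),
         n_pairs = nrow(x$pairs),
         min_r = min(x$pairs$pearson_r),
         max_r = max(x$pairs$pearson_r))
}

#' @rdname reference_sample_qc
#' @param x An `mtcn_ref_qc` object.
#' @param ... Unused.
#' @export
tidy.mtcn_ref_qc <- function(x, ...) x$per_plate

#' @rdname reference_sample_qc
#' @export
glance.mtcn_ref_qc <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, cv_pct = x$cv_pct,
         n_plates = nrow(x$per_plate), verdict = x$verdict)
}

#' @rdname mean_depth
#' @param x An `mtcn_coverage` object.
#' @param ... Unused.
#' @export
tidy.mtcn_coverage <- function(x, ...) x$per_contig

#' @rdname mean_depth
#' @export
glance.mtcn_coverage <- function(x, ...) {
  tibble(autosomal_mean_depth = x$autosomal_mean_depth,
         mito_mean_depth = x$mito_mean_depth,
         mito_read_count = as.integer(x$mito_read_count),
         reads_kept = x$reads_kept,
         reads_filtered = sum(x$reads_filtered),
         n_records = x$n_records)
}
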