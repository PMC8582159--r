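#' Score-to-scan matching windows
#'
#' @param mmse_days maximum days between MMSE and scan (default 183,
#'   i.e. six calendar months).
#' @param cdr_days maximum days between CDR and scan (default 92, three
#'   months).
#' @return A `match_windows` list.
#' @export
match_windows <- function(mmse_days = 183L, cdr_days = 92L) {
  if (mmse_days <= 0 || cdr_days <= 0) stop("matching windows must be positive")
  structure(list(mmse_days = as.integer(mmse_days),
                 cdr_days = as.integer(cdr_days)),
            class = "match_windows")
}

parse_dates <- function(x, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & x != "" & is.na(d)
  if (any(bad))
    stop("malformed ", what, " date(s): ", paste(unique(x[bad]), collapse = ", "))
  d
}

#' Match clinical scores to scans by date window
#'
#' A subject's MMSE (CDR) is retained iff its date lies within the window
#' of the scan date; scores outside the window are set to `NA`. With
#' several qualifying scores per subject the nearest-dated wins (ties:
#' earlier date).
#'
#' @param manifest cohort manifest with `scan_date` and optional dated
#'   `mmse`/`cdr` columns (possibly several rows per subject-score in
#'   long-format extensions; one score per row is expected here).
#' @param windows a [match_windows()].
#' @return The manifest with out-of-window scores replaced by `NA` and
#'   integer day-offset columns `mmse_offset`, `cdr_offset`.
#' @export
match_scores <- function(manifest, windows = match_windows()) {
  stopifnot(inherits(windows, "match_windows"))
  out <- manifest
  scan_d <- parse_dates(manifest$scan_date, "scan")
  for (score in c("mmse", "cdr")) {
    datecol <- paste0(score, "_date")
    offcol <- paste0(score, "_offset")
    if (!score %in% names(out)) {
      out[[score]] <- NA_real_
      out[[offcol]] <- NA_integer_
      next
    }
    sd <- parse_dates(out[[datecol]], score)
    off <- as.integer(sd - scan_d)
    win <- windows[[paste0(score, "_days")]]
    drop <- is.na(off) | abs(off) > win
    out[[score]][drop] <- NA
    off[drop] <- NA_integer_
    out[[offcol]] <- off
  }
  out
}

#' Sample skewness g1
#'
#' Third standardised central moment m3 / m2^(3/2) with moments
#' mk = sum((x - mean)^k) / n (the population-moment form, as tabulated in
#' classical descriptive summaries). Undefined (NA) for n < 3 or zero
#' variance.
#'
#' @param x numeric vector.
#' @return g1, or `NA` when undefined.
#' @export
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 1)
}

#' Per-group distribution summary of cluster-positive voxel counts
#'
#' For each cluster (1-4) and diagnostic group: n, median, interquartile
#' range (Q3 - Q1, linear-interpolation quantiles) and skewness g1 of the
#' per-subject positive-voxel counts.
#'
#' @param features feature table from [build_feature_table()].
#' @return Data frame with columns `cluster`, `group`, `n`, `median`,
#'   `iqr`, `skewness_g1`.
#' @export
group_distribution_summary <- function(features) {
  groups <- intersect(c("CN", "EMCI", "LMCI", "AD"), unique(features$group))
  if (length(groups) == 0L) stop("no recognised diagnostic groups in feature table")
  rows <- list()
  for (cl in 1:4) {
    col <- sprintf("cluster%d_pos", cl)
    for (g in groups) {
      x <- features[[col]][features$group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, group = g, n = length(x),
        median = stats::median(x),
        iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
        skewness_g1 = skewness_g1(x),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the p-value from the t transform
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (pairs with any `NA`
#'   dropped).
#' @return List `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlations of cluster counts with clinical scores
#'
#' Pearson correlations of each cluster's positive-voxel count with MMSE
#' and CDR over the subjects whose scores fall in the matching windows.
#'
#' @param features feature table (with `subject_id`).
#' @param manifest cohort manifest carrying the dated scores.
#' @param windows a [match_windows()].
#' @return Data frame per cluster: `r_mmse`, `p_mmse`, `n_mmse`, `r_cdr`,
#'   `p_cdr`, `n_cdr`.
#' @export
clinical_correlations <- function(features, manifest,
                                  windows = match_windows()) {
  matched <- match_scores(manifest, windows)
  m <- merge(features, matched[, c("subject_id", "mmse", "cdr")],
             by = "subject_id", sort = TRUE)
  rows <- lapply(1:4, function(cl) {
    x <- m[[sprintf("cluster%d_pos", cl)]]
    cm <- pearson_correlation(x, m$mmse)
    cc <- pearson_correlation(x, m$cdr)
    data.frame(cluster = cl, r_mmse = cm$r, p_mmse = cm$p, n_mmse = cm$n,
               r_cdr = cc$r, p_cdr = cc$p, n_cdr = cc$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
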