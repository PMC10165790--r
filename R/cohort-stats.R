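#' Initial in-brace correction (IBC)
#'
#' Percentage reduction of the Cobb angle in the first in-brace radiograph
#' relative to the pre-brace angle: `100 * (pre - inBrace) / pre`. Negative
#' values (in-brace worsening) are allowed.
#'
#' @param preCA pre-brace Cobb angle in degrees (> 0).
#' @param inBraceCA in-brace Cobb angle in degrees.
#' @return IBC in percent; vectorised.
#' @examples
#' computeIBC(40, 30)  # 25
#' @export
computeIBC <- function(preCA, inBraceCA) {
  if (any(preCA <= 0)) stop("computeIBC: preCA must be > 0")
  100 * (preCA - inBraceCA) / preCA
}

#' Spearman rank correlation
#'
#' Average-rank tie handling; equals the Pearson correlation of the rank
#' vectors, and for tie-free data the classical
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))`. A constant input yields `NA` with the
#' attribute `undefined = TRUE` (flagged, not an error).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return Spearman's rho.
#' @examples
#' spearmanRho(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("spearmanRho: lengths differ")
  if (length(x) < 3L) stop("spearmanRho: need n >= 3")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearmanRho: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(x, y, method = "spearman")
}

#' Correlation strength category
#'
#' The conventional bins on |rho|: 0.90-1.00 very strong, 0.70-0.89 strong,
#' 0.50-0.69 moderate, 0.26-0.49 weak, and <= 0.25 little if any. Bin edges
#' between the printed ranges are half-open, assigned to the lower category's
#' printed upper edge. The sign is reported separately via the `sign`
#' attribute-free return of [spearmanRho()]; this function classifies
#' magnitude only.
#'
#' @param rho correlation in \[-1, 1\] (NA allowed, returns NA).
#' @return factor level among `"very strong"`, `"strong"`, `"moderate"`,
#'   `"weak"`, `"little if any"`; vectorised.
#' @examples
#' classifyStrength(-0.85)  # strong
#' classifyStrength(0.64)   # moderate
#' @export
classifyStrength <- function(rho) {
  lv <- c("very strong", "strong", "moderate", "weak", "little if any")
  out <- rep(NA_character_, length(rho))
  a <- abs(rho)
  if (any(a > 1 + 1e-12, na.rm = TRUE))
    stop("classifyStrength: |rho| > 1")
  out[!is.na(a) & a >= 0.90] <- "very strong"
  out[!is.na(a) & a >= 0.70 & a < 0.90] <- "strong"
  out[!is.na(a) & a >= 0.50 & a < 0.70] <- "moderate"
  out[!is.na(a) & a > 0.25 & a < 0.50] <- "weak"
  out[!is.na(a) & a <= 0.25] <- "little if any"
  factor(out, levels = lv)
}

#' Names of the 24 segment-peak features
#'
#' `peakPositive_ALU ... peakPositive_PRL`, then `peakNegative_ALU ...
#' peakNegative_PRL`, matching the row order of the reporting tables.
#'
#' @return character vector of 24 names.
#' @export
segmentFeatureNames <- function() {
  c(paste0("peakPositive_", segmentCodes()),
    paste0("peakNegative_", segmentCodes()))
}

#' Correlation table for one Lenke group and outcome
#'
#' One row per feature: Spearman's rho of the feature against the chosen
#' in-brace-correction outcome, with its strength category and the group
#' size. Default features are the 24 segment peaks
#' ([segmentFeatureNames()]); any named numeric columns of `records` can be
#' supplied instead (for example `"asymmetryTorso"`). Row order is
#' deterministic and matches the feature order given.
#'
#' Peak-negative features enter the correlation as magnitudes (depth of the
#' expansion zone in mm): a negative rho for a `peakNegative_*` row means a
#' larger expansion zone goes with less in-brace correction, which is the
#' reporting convention of clinical brace studies.
#'
#' @param records data.frame of patient records (one row per patient) with
#'   columns `lenkeType`, the outcome column, and the feature columns.
#' @param lenkeType 1 or 5.
#' @param outcome `"ibcAP"` or `"ibcLat"`.
#' @param features character vector of feature column names.
#' @return data.frame with columns `feature`, `rho`, `category`, `n`.
#' @export
correlationTable <- function(records, lenkeType,
                             outcome = c("ibcAP", "ibcLat"),
                             features = segmentFeatureNames()) {
  outcome <- match.arg(outcome)
  stopifnot(lenkeType %in% c(1, 5))
  g <- records[records$lenkeType == lenkeType, , drop = FALSE]
  if (nrow(g) < 3L)
    stop("correlationTable: only ", nrow(g), " records of Lenke type ",
         lenkeType, " (need >= 3)")
  missingCols <- setdiff(c(outcome, features), names(g))
  if (length(missingCols))
    stop("correlationTable: missing columns: ",
         paste(missingCols, collapse = ", "))
  y <- g[[outcome]]
  rho <- vapply(features, function(f) {
    x <- g[[f]]
    if (startsWith(f, "peakNegative_")) x <- abs(x)
    as.numeric(spearmanRho(x, y))
  }, 0)
  data.frame(feature = features, rho = unname(rho),
             category = classifyStrength(unname(rho)),
             n = nrow(g), stringsAsFactors = FALSE)
}

#' Per-Lenke-group mean and SD summary
#'
#' Sample mean and sample standard deviation (n-1 denominator) of the chosen
#' numeric variables, per Lenke group. Groups of size 1 get `NA` SD with a
#' flag column.
#'
#' @param records data.frame with a `lenkeType` column.
#' @param variables character vector of numeric column names to summarise;
#'   defaults to the Cobb-angle, IBC and asymmetry columns present.
#' @return data.frame with columns `lenkeType`, `variable`, `mean`, `sd`,
#'   `n`, `sdUndefined`.
#' @export
summarizeCohort <- function(records, variables = NULL) {
  if (nrow(records) == 0L) stop("summarizeCohort: no records")
  if (is.null(variables)) {
    candidates <- c("preCaAP", "inBraceCaAP", "preCaLat", "inBraceCaLat",
                    "ibcAP", "ibcLat", "asymmetryTorso", "asymmetryBrace")
    variables <- intersect(candidates, names(records))
  }
  groups <- sort(unique(records$lenkeType))
  rows <- list()
  for (lt in groups) {
    g <- records[records$lenkeType == lt, , drop = FALSE]
    for (v in variables) {
      x <- g[[v]]
      x <- x[is.finite(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        lenkeType = lt, variable = v,
        mean = mean(x),
        sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
        n = length(x),
        sdUndefined = length(x) <= 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
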