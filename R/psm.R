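# Percolator-style PSM tables: reading/writing, deltaCn re-scoring, and
# FDR filtering.
#
# deltaCn is always recomputed here from the xcorr columns, replacing any
# deltaCn the search engine exported. The alternate definition
# deltaCn_i = 1 - (xcorr_1 - xcorr_i)/xcorr_1 keeps near-tied candidates
# (e.g. trimethyl vs acetyl on low-mass-accuracy ion-trap spectra, which
# produce identical xcorr) at deltaCn ~ 1 instead of collapsing to 0.

PSM_REQUIRED <- c(psm_id = "PSMId", spectrum_id = "SpectrumId",
                  rt = "RT", charge = "Charge", peptide = "Peptide",
                  xcorr = "XCorr", rank = "Rank",
                  pep = "posterior_error_prob", q_value = "q-value")

#' Read a Percolator-style PSM table
#'
#' Tab-separated with a header row. The default dialect expects columns
#' `PSMId`, `SpectrumId`, `RT` (minutes), `Charge`, `Peptide` (serialized,
#' see [parse_peptide()]), `XCorr`, `Rank`, `posterior_error_prob`,
#' `q-value`; an optional `Sample` column carries the sample label.
#' Extra columns are preserved.
#'
#' @param path Path to the table (or a connection).
#' @param dialect Named character vector remapping internal field names
#'   (names of [PSM_REQUIRED]-style keys: `psm_id`, `spectrum_id`, `rt`,
#'   `charge`, `peptide`, `xcorr`, `rank`, `pep`, `q_value`, `sample`) to
#'   the file's column names. Defaults cover Percolator extended output.
#' @param scheme Derivatization scheme used to validate peptide strings.
#' @return Data frame of class `psm_table` with the internal column names;
#'   row order preserved from the file.
#' @export
read_psm_table <- function(path, dialect = NULL,
                           scheme = c("propionylated", "underivatized")) {
  scheme <- match.arg(scheme)
  cols <- PSM_REQUIRED
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing) > 0) {
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- stats::setNames(raw[, unname(cols), drop = FALSE], names(cols))
  if ("Sample" %in% names(raw) && !"sample" %in% names(df)) {
    df$sample <- raw$Sample
  }
  for (num in c("rt", "xcorr", "pep", "q_value")) {
    v <- suppressWarnings(as.numeric(df[[num]]))
    if (anyNA(v) & !all(is.na(df[[num]]) == is.na(v))) {
      bad <- which(is.na(v) & !is.na(df[[num]]))[1]
      stop("unparseable numeric value in column '", num, "' at data row ",
           bad, " (file line ", bad + 1, ")")
    }
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("missing numeric value in column '", num, "' at data row ", bad)
    }
    df[[num]] <- v
  }
  for (int in c("charge", "rank")) {
    v <- suppressWarnings(as.integer(df[[int]]))
    if (anyNA(v)) stop("unparseable integer in column '", int, "'")
    df[[int]] <- v
  }
  if (anyDuplicated(df$psm_id)) {
    stop("duplicate psm_id: ", df$psm_id[duplicated(df$psm_id)][1])
  }
  if (any(df$rt < 0)) stop("negative retention time")
  if (any(df$pep < 0 | df$pep > 1) || any(df$q_value < 0 | df$q_value > 1)) {
    stop("PEP and q-value must lie in [0, 1]")
  }
  # validate peptide strings (raises on malformed cells), canonicalize
  df$peptide <- vapply(df$peptide, function(s) {
    format_peptide(parse_peptide(s, scheme))
  }, "", USE.NAMES = FALSE)
  check_ranks(df)
  attr(df, "scheme") <- scheme
  class(df) <- c("psm_table", "data.frame")
  df
}

# within each spectrum, ranks must be 1..k and xcorr non-increasing in rank
check_ranks <- function(df) {
  for (sp in split(df, df$spectrum_id)) {
    r <- sort(sp$rank)
    if (!identical(r, seq_along(r))) {
      stop("spectrum '", sp$spectrum_id[1],
           "' has gapped or duplicated ranks: ",
           paste(sp$rank, collapse = ","))
    }
    x <- sp$xcorr[order(sp$rank)]
    if (is.unsorted(rev(x))) {
      stop("spectrum '", sp$spectrum_id[1],
           "' has xcorr increasing with rank")
    }
  }
  invisible(TRUE)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()] for the default dialect.
#'
#' @param df A `psm_table` data frame.
#' @param path Output path.
#' @export
write_psm_table <- function(df, path) {
  out <- df
  back <- c(PSM_REQUIRED, sample = "Sample",
            deltacn = "deltaCn", accepted = "Accepted", flag = "Flag")
  keep <- intersect(names(out), names(back))
  out <- stats::setNames(out[, keep, drop = FALSE], unname(back[keep]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recompute deltaCn for one spectrum's xcorr ladder
#'
#' Applies `deltaCn_i = 1 - (xcorr_1 - xcorr_i) / xcorr_1` to the
#' rank-ordered xcorr values of a single spectrum. The top rank always gets
#' exactly 1; algebraically the result equals `xcorr_i / xcorr_1`.
#'
#' @param xcorrs Numeric vector ordered by rank (rank 1 first),
#'   non-increasing, with `xcorrs[1] > 0`.
#' @return Numeric vector of deltaCn values, same length.
#' @export
#' @examples
#' recompute_deltacn(c(2.0, 1.5, 0.5))  # 1.00 0.75 0.25
recompute_deltacn <- function(xcorrs) {
  if (length(xcorrs) == 0) stop("empty xcorr list")
  if (!all(is.finite(xcorrs))) stop("non-finite xcorr")
  if (xcorrs[1] <= 0) stop("xcorr of rank-1 PSM must be > 0")
  if (is.unsorted(rev(xcorrs))) stop("xcorr must be non-increasing with rank")
  out <- 1 - (xcorrs[1] - xcorrs) / xcorrs[1]
  out[1] <- 1.0
  out
}

#' Recompute deltaCn across a PSM table
#'
#' Groups rows by `spectrum_id`, applies [recompute_deltacn()] per spectrum
#' in rank order, and writes/overwrites the `deltacn` column.
#'
#' @param df A `psm_table`.
#' @return The table with a `deltacn` column; input row order preserved.
#' @export
rescore_deltacn <- function(df) {
  check_ranks(df)
  df$deltacn <- NA_real_
  for (sp in unique(df$spectrum_id)) {
    idx <- which(df$spectrum_id == sp)
    ord <- idx[order(df$rank[idx])]
    df$deltacn[ord] <- recompute_deltacn(df$xcorr[ord])
  }
  df
}

#' Filter PSMs at an FDR (q-value) threshold
#'
#' Retains rows with `q_value <= q_threshold` (inclusive boundary), stable
#' order.
#'
#' @param df A `psm_table` (or any data frame with a `q_value` column).
#' @param q_threshold FDR threshold, default 0.05.
#' @return The retained rows.
#' @export
fdr_filter <- function(df, q_threshold = 0.05) {
  if (!"q_value" %in% names(df)) stop("no q_value column")
  if (anyNA(df$q_value)) stop("missing q_value")
  df[df$q_value <= q_threshold, , drop = FALSE]
}
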