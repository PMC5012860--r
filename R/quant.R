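# Extracted-ion-chromatogram quantification: trapezoidal areas, charge-state
# summation, HeDNA/UnDNA ratios with free-ubiquitin normalization,
# enrichment filtering, and spectral-count summaries.

#' Construct an XIC trace
#'
#' @param time Strictly increasing time points, minutes.
#' @param intensity Non-negative intensities, same length (arbitrary units).
#' @param peptide,charge,sample Optional identifiers.
#' @return Object of class `xic_trace`.
#' @export
xic_trace <- function(time, intensity, peptide = NA_character_,
                      charge = NA_integer_, sample = NA_character_) {
  time <- as.numeric(time); intensity <- as.numeric(intensity)
  if (length(time) < 2) stop("XIC trace needs at least 2 points")
  if (length(time) != length(intensity)) stop("time/intensity length mismatch")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  if (any(intensity < 0)) stop("negative intensity")
  structure(list(time = time, intensity = intensity, peptide = peptide,
                 charge = charge, sample = sample), class = "xic_trace")
}

#' Trapezoidal area under an XIC trace
#'
#' Integrates the full trace against a zero baseline; no smoothing or peak
#' detection (traces are assumed pre-extracted).
#'
#' @param trace An [xic_trace()], or anything accepted by its constructor
#'   when passed as `xic_auc(time, intensity)`.
#' @param intensity Optional; when given, `trace` is taken as the time
#'   vector.
#' @return Area in intensity x minutes.
#' @export
#' @examples
#' xic_auc(c(0, 1, 2), c(0, 2, 0))  # 2
xic_auc <- function(trace, intensity = NULL) {
  if (!is.null(intensity)) trace <- xic_trace(trace, intensity)
  if (!inherits(trace, "xic_trace")) stop("not an xic_trace")
  t <- trace$time; y <- trace$intensity
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sum XIC areas over charge states
#'
#' @param areas Named (by charge) or unnamed numeric vector of per-charge
#'   areas for one peptide/sample.
#' @return Arithmetic sum.
#' @export
sum_charge_states <- function(areas) {
  areas <- unlist(areas)
  if (length(areas) == 0) stop("no charge states to sum")
  if (anyNA(areas)) stop("NA area")
  sum(areas)
}

#' Read long-format XIC CSV
#'
#' Columns: `peptide`, `charge`, `sample`, `time_min`, `intensity`.
#'
#' @param path CSV path.
#' @return List of [xic_trace()] objects, one per
#'   (peptide, charge, sample).
#' @export
read_xic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide", "charge", "sample", "time_min", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("XIC CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  key <- interaction(df$peptide, df$charge, df$sample, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    xic_trace(g$time_min, g$intensity, g$peptide[1],
              as.integer(g$charge[1]), g$sample[1])
  })
}

#' Charge-summed per-peptide areas from XIC traces
#'
#' @param traces List of [xic_trace()] objects.
#' @return Data frame with columns `peptide`, `sample`, `auc` (summed over
#'   charge states).
#' @export
peptide_areas <- function(traces) {
  auc <- vapply(traces, xic_auc, 0)
  pep <- vapply(traces, `[[`, "", "peptide")
  smp <- vapply(traces, `[[`, "", "sample")
  agg <- stats::aggregate(auc, list(peptide = pep, sample = smp), sum)
  names(agg)[3] <- "auc"
  agg
}

#' HeDNA/UnDNA ratios with free-ubiquitin normalization
#'
#' Raw ratio is the charge-summed area in the numerator sample divided by
#' that in the denominator sample. The normalizer is the arithmetic mean of
#' the free-ubiquitin peptides' raw ratios (`mode = "mean_of_ratios"`,
#' default) or the ratio of their summed areas (`"ratio_of_sums"`).
#' Peptides with a zero denominator area are flagged undefined and excluded
#' from the normalizer.
#'
#' @param areas Data frame from [peptide_areas()] (columns `peptide`,
#'   `sample`, `auc`).
#' @param free_ub Character vector of free-ubiquitin peptide identifiers
#'   (must be non-empty and present with finite ratios).
#' @param numerator,denominator Sample labels, default `"HeDNA"`/`"UnDNA"`.
#' @param mode Normalizer mode, see above.
#' @return Data frame with `peptide`, `auc_num`, `auc_den`, `ratio`,
#'   `normalized_ratio`, `is_free_ub`, `flag`; attribute `normalizer`.
#' @export
normalized_ratios <- function(areas, free_ub,
                              numerator = "HeDNA", denominator = "UnDNA",
                              mode = c("mean_of_ratios", "ratio_of_sums")) {
  mode <- match.arg(mode)
  if (length(free_ub) == 0) stop("free-ubiquitin peptide set is empty")
  num <- areas[areas$sample == numerator, c("peptide", "auc")]
  den <- areas[areas$sample == denominator, c("peptide", "auc")]
  merged <- merge(num, den, by = "peptide", all = TRUE,
                  suffixes = c("_num", "_den"))
  merged$auc_num[is.na(merged$auc_num)] <- 0
  merged$auc_den[is.na(merged$auc_den)] <- 0
  merged$ratio <- ifelse(merged$auc_den > 0,
                         merged$auc_num / merged$auc_den, NA_real_)
  merged$is_free_ub <- merged$peptide %in% free_ub
  merged$flag <- ifelse(is.na(merged$ratio), "undefined_ratio", "")
  fu <- merged[merged$is_free_ub & !is.na(merged$ratio), , drop = FALSE]
  if (nrow(fu) == 0) {
    stop("no free-ubiquitin peptide with a finite raw ratio")
  }
  normalizer <- if (mode == "mean_of_ratios") {
    mean(fu$ratio)
  } else {
    sum(fu$auc_num) / sum(fu$auc_den)
  }
  if (!is.finite(normalizer) || normalizer <= 0) {
    stop("free-ubiquitin normalizer is not positive and finite")
  }
  merged$normalized_ratio <- merged$ratio / normalizer
  attr(merged, "normalizer") <- normalizer
  merged
}

#' Retain peptides enriched more than `fold`-fold
#'
#' Strict inequality: a normalized ratio exactly equal to `fold` is not
#' retained.
#'
#' @param quants Data frame with a `normalized_ratio` column.
#' @param fold Enrichment cutoff, default 10.
#' @return The retained rows.
#' @export
enrichment_filter <- function(quants, fold = 10) {
  keep <- !is.na(quants$normalized_ratio) & quants$normalized_ratio > fold
  quants[keep, , drop = FALSE]
}

#' Spectral counts of ubiquitylation sites
#'
#' Counts accepted PSMs per ubiquitylated site and summarizes the top site
#' against the runner-up.
#'
#' @param df PSM table (rows already FDR/RT-filtered) with canonical
#'   peptide strings; sites are taken from `ub` modifications.
#' @param protein Optional protein label recorded in the output.
#' @param site_offset Integer added to within-peptide positions to report
#'   protein coordinates (e.g. the peptide's start position minus one).
#'   Either a single value or a named vector keyed by peptide string.
#' @return List with `counts` (data frame `site`, `n`) and `summary`
#'   (list `top_site`, `top_n`, `fold_over_second`; fold is `Inf` with a
#'   single site, and the summary is `NULL` with no ubiquitylated PSMs).
#' @export
spectral_counts <- function(df, protein = NA_character_, site_offset = 0L) {
  sites <- character()
  for (i in seq_len(nrow(df))) {
    p <- parse_peptide(df$peptide[i],
                       attr(df, "scheme") %||% "propionylated")
    ubpos <- as.integer(names(p$mods)[p$mods == "ub"])
    if (length(ubpos) == 0) next
    off <- if (length(site_offset) == 1) site_offset else
      site_offset[[df$peptide[i]]]
    sites <- c(sites, paste0("K", ubpos + off))
  }
  if (length(sites) == 0) {
    return(list(counts = data.frame(site = character(), n = integer()),
                summary = NULL))
  }
  tab <- sort(table(sites), decreasing = TRUE)
  counts <- data.frame(site = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  fold <- if (nrow(counts) >= 2) counts$n[1] / counts$n[2] else Inf
  list(counts = counts,
       summary = list(protein = protein, top_site = counts$site[1],
                      top_n = counts$n[1], fold_over_second = fold))
}
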