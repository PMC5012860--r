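# Pipeline orchestration: rescore -> FDR filter -> RT filter -> quantify,
# under one JSON configuration, with a machine-readable run report.

#' Build a run configuration
#'
#' @param psms Path to the input PSM table (required).
#' @param xics Optional path to a long-format XIC CSV (see
#'   [read_xic_csv()]); when present the quantification stage runs.
#' @param free_ub Character vector of free-ubiquitin peptide identifiers
#'   (required when `xics` is given).
#' @param out_dir Output directory (created if absent).
#' @param q_threshold FDR threshold (default 0.05).
#' @param tolerance RT coelution tolerance, minutes (default 2).
#' @param fold Enrichment cutoff (default 10).
#' @param overrides Optional path to a whitelist file (one serialized
#'   peptide per line) or a character vector of peptides.
#' @param scheme Derivatization scheme.
#' @param seed Integer seed echoed into the report.
#' @return Object of class `run_config`.
#' @export
run_config <- function(psms, xics = NULL, free_ub = character(),
                       out_dir = tempfile("histoneub_run"),
                       q_threshold = 0.05, tolerance = 2.0, fold = 10,
                       overrides = character(),
                       scheme = c("propionylated", "underivatized"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  if (!file.exists(psms)) stop("PSM table not found: ", psms)
  if (!is.null(xics) && !file.exists(xics)) stop("XIC file not found: ", xics)
  if (length(overrides) == 1 && file.exists(overrides)) {
    overrides <- readLines(overrides)
    overrides <- overrides[nzchar(trimws(overrides))]
  }
  structure(list(psms = psms, xics = xics, free_ub = free_ub,
                 out_dir = out_dir, q_threshold = q_threshold,
                 tolerance = tolerance, fold = fold,
                 overrides = as.character(overrides), scheme = scheme,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full post-processing pipeline
#'
#' Stages: read PSM table, recompute deltaCn, FDR-filter at the configured
#' q threshold, group by unmodified sequence and apply the greedy
#' RT-consistency filter (whitelisted peptides re-injected and flagged),
#' then, when XICs are supplied, quantify the surviving peptides with
#' free-ubiquitin-normalized HeDNA/UnDNA ratios. Stage outputs and a JSON
#' run report are written under `cfg$out_dir`; identical configuration and
#' inputs reproduce identical outputs.
#'
#' @param cfg A [run_config()].
#' @return The run report (list), invisibly also written to
#'   `report.json`: per-stage row counts in/out/rejected, parameter echo,
#'   package version, input checksums.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package = "histoneub",
    version = as.character(utils::packageVersion("histoneub")),
    parameters = cfg[c("q_threshold", "tolerance", "fold", "scheme",
                       "seed")],
    overrides = cfg$overrides,
    inputs = list(psms = unname(tools::md5sum(cfg$psms)),
                  xics = if (!is.null(cfg$xics))
                    unname(tools::md5sum(cfg$xics)) else NULL),
    stages = list()
  )
  stage <- function(name, n_in, n_out, detail = NULL) {
    stopifnot(n_in == n_out + (n_in - n_out))
    report$stages[[name]] <<- c(list(rows_in = n_in, rows_out = n_out,
                                     rows_rejected = n_in - n_out), detail)
  }

  psms <- read_psm_table(cfg$psms, scheme = cfg$scheme)
  stage("read", nrow(psms), nrow(psms))

  psms <- rescore_deltacn(psms)
  stage("rescore", nrow(psms), nrow(psms))
  write_psm_table(psms, file.path(cfg$out_dir, "psms_rescored.tsv"))

  kept <- fdr_filter(psms, cfg$q_threshold)
  # whitelisted peptides bypass the FDR gate (manual-inspection overrides)
  if (length(cfg$overrides) > 0) {
    extra <- psms[psms$q_value > cfg$q_threshold &
                    psms$peptide %in% cfg$overrides, , drop = FALSE]
    kept <- rbind(kept, extra)
  }
  stage("fdr_filter", nrow(psms), nrow(kept),
        list(q_threshold = cfg$q_threshold))
  write_psm_table(kept, file.path(cfg$out_dir, "psms_fdr.tsv"))

  rtcfg <- rt_filter_config(tolerance = cfg$tolerance,
                            whitelist = cfg$overrides)
  groups <- group_peptides(kept, cfg$scheme)
  decisions <- lapply(groups, rt_accept, cfg = rtcfg)
  bind_decisions <- function(which) {
    parts <- lapply(decisions, `[[`, which)
    parts <- parts[vapply(parts, nrow, 0L) > 0]
    if (length(parts) == 0) return(NULL)
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  accepted <- bind_decisions("accepted")
  rejected <- bind_decisions("rejected")
  n_pept <- sum(vapply(groups, function(g) length(g$members), 0L))
  stage("rt_filter", n_pept,
        if (is.null(accepted)) 0L else nrow(accepted),
        list(tolerance = cfg$tolerance,
             rejected_peptides = if (is.null(rejected)) character()
             else rejected$peptide))
  decision_rows <- function(d, decision, detail) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    data.frame(d[, c("peptide", "pep", "q_value")], decision = decision,
               detail = detail, stringsAsFactors = FALSE)
  }
  rtab <- rbind(
    decision_rows(accepted, "accept",
                  if (is.null(accepted)) character() else accepted$flag),
    decision_rows(rejected, "reject",
                  if (is.null(rejected)) character() else
                    rejected$reason))
  if (is.null(rtab)) {
    rtab <- data.frame(peptide = character(), pep = numeric(),
                       q_value = numeric(), decision = character(),
                       detail = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(rtab, file.path(cfg$out_dir, "rt_decisions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  accepted_peptides <- if (is.null(accepted)) character() else
    accepted$peptide
  final <- kept[kept$peptide %in% accepted_peptides, , drop = FALSE]
  write_psm_table(final, file.path(cfg$out_dir, "psms_final.tsv"))

  if (!is.null(cfg$xics)) {
    traces <- read_xic_csv(cfg$xics)
    areas <- peptide_areas(traces)
    quants <- normalized_ratios(areas, cfg$free_ub)
    quants <- quants[quants$peptide %in% c(accepted_peptides, cfg$free_ub), ,
                     drop = FALSE]
    enriched <- enrichment_filter(quants, cfg$fold)
    stage("quantify", nrow(quants), nrow(enriched),
          list(fold = cfg$fold,
               normalizer = attr(quants, "normalizer")))
    utils::write.table(quants, file.path(cfg$out_dir, "quant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enriched, file.path(cfg$out_dir, "enriched.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' Load a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path JSON config path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(j), known)
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "))
  do.call(run_config, j)
}
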