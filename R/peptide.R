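# Modified peptides: construction, string serialization, mass, candidate
# validation, and in silico digestion.

#' Construct a modified peptide
#'
#' @param sequence Uppercase amino-acid string (one-letter codes).
#' @param mods Named list/vector mapping 1-based positions to modification
#'   names from [mod_table()], e.g. `c("9" = "ub")`, or a list of
#'   `list(pos =, mod =)` pairs. At most one modification per position.
#' @param scheme Derivatization scheme: `"propionylated"` samples carry a
#'   static propionyl on every otherwise-unmodified (or mono-methylated)
#'   lysine and on the peptide N-terminus; `"underivatized"` samples do not.
#' @return Object of class `modified_peptide` with fields `sequence`,
#'   `mods` (named character, names are positions), `scheme`.
#' @export
#' @examples
#' modified_peptide("KQLATKAAR", c("1" = "ub"))
modified_peptide <- function(sequence, mods = character(),
                             scheme = c("propionylated", "underivatized")) {
  scheme <- match.arg(scheme)
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  if (sequence != toupper(sequence) || grepl("[^A-Z]", sequence)) {
    stop("sequence must be an uppercase amino-acid string, got '",
         sequence, "'")
  }
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(residue_masses()))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  }
  if (is.list(mods) && length(mods) > 0 && !is.null(mods[[1]]$pos)) {
    mods <- stats::setNames(vapply(mods, function(m) m$mod, ""),
                            vapply(mods, function(m) as.character(m$pos), ""))
  }
  mods <- unlist(mods)
  if (length(mods) > 0) {
    pos <- as.integer(names(mods))
    if (anyNA(pos) || any(pos < 1) || any(pos > nchar(sequence))) {
      stop("modification position out of sequence bounds")
    }
    if (anyDuplicated(pos)) stop("more than one modification at a position")
    tab <- mod_table()
    bad <- setdiff(mods, names(tab))
    if (length(bad) > 0) stop("unknown modification name(s): ",
                              paste(bad, collapse = ", "))
    for (i in seq_along(mods)) {
      targ <- tab[[mods[i]]]$targets
      if (!res[pos[i]] %in% targ) {
        stop("modification '", mods[i], "' cannot occupy residue ",
             res[pos[i]], pos[i])
      }
    }
    mods <- mods[order(pos)]
    names(mods) <- as.character(sort(pos))
  } else {
    mods <- stats::setNames(character(), character())
  }
  structure(list(sequence = sequence, mods = mods, scheme = scheme),
            class = "modified_peptide")
}

#' Serialize a modified peptide to its canonical string form
#'
#' Canonical form places the modification name in square brackets after the
#' modified residue, e.g. `"KQLATK[ub]AAR"`.
#'
#' @param p A [modified_peptide()].
#' @return Character scalar.
#' @export
format_peptide <- function(p) {
  res <- strsplit(p$sequence, "")[[1]]
  if (length(p$mods) > 0) {
    pos <- as.integer(names(p$mods))
    res[pos] <- paste0(res[pos], "[", p$mods, "]")
  }
  paste0(res, collapse = "")
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(format_peptide(x), " (", x$scheme, ")\n", sep = "")
  invisible(x)
}

#' Parse a serialized peptide string
#'
#' Accepts the canonical named form (`K[ub]`) and bracketed signed delta
#' masses at up to 4 decimals (`K[+58.0167]`), which are resolved against
#' the scheme-adjusted deltas of [mod_table()] within 0.01 Da.
#'
#' @param text Serialized peptide.
#' @inheritParams modified_peptide
#' @return A [modified_peptide()].
#' @export
#' @examples
#' parse_peptide("KQLATK[ub]AAR")
#' parse_peptide("KQLATK[+58.0167]AAR")
parse_peptide <- function(text, scheme = c("propionylated", "underivatized")) {
  scheme <- match.arg(scheme)
  stopifnot(is.character(text), length(text) == 1)
  if (grepl("[[:space:]]", text)) {
    stop("peptide string contains whitespace: '", text, "'")
  }
  toks <- regmatches(text, gregexpr("[A-Z](\\[[^]\\[]+\\])?", text))[[1]]
  if (paste0(toks, collapse = "") != text) {
    stop("cannot parse peptide string '", text, "'")
  }
  res <- substr(toks, 1, 1)
  tags <- ifelse(nchar(toks) > 1, substr(toks, 3, nchar(toks) - 1), NA)
  mods <- character()
  tab <- mod_table()
  vtab <- tab[setdiff(names(tab), "prop")]
  for (i in seq_along(tags)) {
    if (is.na(tags[i])) next
    tag <- tags[i]
    if (tag %in% names(vtab)) {
      mods[as.character(i)] <- tag
    } else if (grepl("^[+-]?[0-9.]+$", tag)) {
      delta <- as.numeric(tag)
      adj <- vapply(vtab, adjusted_mod_mass, 0, scheme = scheme)
      hit <- which(abs(adj - delta) < 0.01)
      if (length(hit) == 0) {
        stop("no modification within 0.01 Da of delta ", tag,
             " under scheme '", scheme, "'")
      }
      mods[as.character(i)] <- names(vtab)[hit[1]]
    } else {
      stop("unrecognized modification tag '[", tag, "]' in '", text, "'")
    }
  }
  modified_peptide(paste0(res, collapse = ""), mods, scheme)
}

#' Monoisotopic peptide mass
#'
#' Residue masses plus one water, plus variable-modification deltas. Under
#' the propionylated scheme one static propionyl is added for every lysine
#' (the scheme-adjusted variable deltas make this strictly additive) and,
#' when `nterm_prop` is `TRUE` (default), one on the peptide N-terminus.
#'
#' @param p A [modified_peptide()].
#' @param table Mass table, default [atomic_masses()].
#' @param nterm_prop Apply static N-terminal propionyl under the
#'   propionylated scheme.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass(modified_peptide("G", scheme = "underivatized"))  # 75.03203
peptide_mass <- function(p, table = atomic_masses(), nterm_prop = TRUE) {
  stopifnot(inherits(p, "modified_peptide"))
  res <- strsplit(p$sequence, "")[[1]]
  rm <- residue_masses()
  mass <- sum(rm[res]) + WATER_MONO
  tab <- mod_table()
  if (length(p$mods) > 0) {
    mass <- mass + sum(vapply(tab[p$mods], adjusted_mod_mass, 0,
                              scheme = p$scheme))
  }
  if (p$scheme == "propionylated") {
    mass <- mass + sum(res == "K") * propionyl_mass()
    if (nterm_prop) mass <- mass + propionyl_mass()
  }
  mass
}

#' Search parameter set
#'
#' Length bounds, precursor tolerance, enzyme, missed-cleavage allowance,
#' per-modification caps (from [mod_table()]), total variable-modification
#' cap, and derivatization scheme. Defaults mirror a propionylated Arg-C
#' histone search; underivatized defaults are trypsin with 3 missed
#' cleavages.
#'
#' @param min_length,max_length Peptide length bounds (residues).
#' @param precursor_tol Precursor mass tolerance, amu.
#' @param enzyme `"ArgC"` or `"trypsin"`.
#' @param max_missed Maximum missed cleavages.
#' @param max_total_mods Cap on total variable modifications per peptide.
#' @param scheme Derivatization scheme.
#' @return Object of class `search_params`.
#' @export
search_params <- function(min_length = 6L, max_length = 25L,
                          precursor_tol = 0.5,
                          enzyme = c("ArgC", "trypsin"),
                          max_missed = NULL,
                          max_total_mods = 4L,
                          scheme = c("propionylated", "underivatized")) {
  enzyme <- match.arg(enzyme)
  scheme <- match.arg(scheme)
  if (is.null(max_missed)) max_missed <- if (enzyme == "ArgC") 0L else 3L
  stopifnot(min_length > 0, max_length >= min_length, precursor_tol > 0,
            max_missed >= 0, max_total_mods >= 0)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 precursor_tol = precursor_tol, enzyme = enzyme,
                 max_missed = as.integer(max_missed),
                 max_total_mods = as.integer(max_total_mods),
                 scheme = scheme),
            class = "search_params")
}

#' Validate a candidate peptide against search parameters
#'
#' Checks length bounds, per-modification caps, and the total
#' variable-modification cap.
#'
#' @param p A [modified_peptide()].
#' @param params A [search_params()].
#' @return List with `accept` (logical) and `reason` (`NA` when accepted;
#'   otherwise one of `"length"`, `"cap"`, `"total"` with detail).
#' @export
validate_candidate <- function(p, params = search_params()) {
  n <- nchar(p$sequence)
  if (n < params$min_length || n > params$max_length) {
    return(list(accept = FALSE,
                reason = sprintf("length: %d outside [%d, %d]", n,
                                 params$min_length, params$max_length)))
  }
  tab <- mod_table()
  if (length(p$mods) > 0) {
    counts <- table(p$mods)
    for (m in names(counts)) {
      if (counts[[m]] > tab[[m]]$max_count) {
        return(list(accept = FALSE,
                    reason = sprintf("cap: %d x %s exceeds max %d",
                                     counts[[m]], m, tab[[m]]$max_count)))
      }
    }
    if (length(p$mods) > params$max_total_mods) {
      return(list(accept = FALSE,
                  reason = sprintf("total: %d variable mods exceeds max %d",
                                   length(p$mods), params$max_total_mods)))
    }
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Fully enzymatic in silico digestion
#'
#' Arg-C cleaves after R; trypsin cleaves after K or R except when the next
#' residue is P. Cleavage at modified/propionylated lysine is not
#' suppressed. Returns all fully enzymatic peptides with 0..`max_missed`
#' missed cleavages.
#'
#' @param sequence Uppercase protein sequence.
#' @param enzyme `"ArgC"` or `"trypsin"`.
#' @param max_missed Maximum missed cleavages (>= 0).
#' @return Data frame with columns `peptide`, `start`, `end`, `missed`.
#' @export
#' @examples
#' digest("ARGR", "ArgC", 0)$peptide     # "AR", "GR"
#' digest("AKPR", "trypsin", 0)$peptide  # "AKPR"
digest <- function(sequence, enzyme = c("ArgC", "trypsin"), max_missed = 0L) {
  enzyme <- match.arg(enzyme)
  stopifnot(is.character(sequence), length(sequence) == 1,
            nchar(sequence) > 0)
  if (sequence != toupper(sequence)) stop("sequence must be uppercase")
  if (max_missed < 0) stop("max_missed must be >= 0")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- if (enzyme == "ArgC") {
    which(res == "R")
  } else {
    which(res %in% c("K", "R"))
  }
  if (enzyme == "trypsin") {
    cut_after <- cut_after[!(cut_after < n & res[cut_after + 1] == "P")]
  }
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment end positions
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nseg <- length(starts)
  out <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:min(max_missed, nseg - i)) {
      out[[length(out) + 1]] <- data.frame(
        peptide = substr(sequence, starts[i], ends[i + m]),
        start = starts[i], end = ends[i + m], missed = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`; description lines are
#' preserved as names.
#'
#' @param path Path to a plain (multi-record) FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   full description lines.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(toupper(as.character(aa)), names(aa))
}
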