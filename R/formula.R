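# Elemental formulas and mass arithmetic.

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of non-negative element
#' counts over the supported element vocabulary (C, H, N, O, S, P). Signed
#' composition deltas (used for modification mass differences) are held as a
#' pair of formulas instead; see [mod_table()].
#'
#' @param counts Named numeric vector or list of element counts. Names must
#'   be element symbols present in [atomic_masses()]; counts must be
#'   non-negative integers. An empty vector yields the empty formula.
#' @return An object of class `elemental_formula`.
#' @export
#' @examples
#' elemental_formula(c(C = 3, H = 4, O = 1))
elemental_formula <- function(counts = numeric()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    out <- structure(integer(), names = character(), class = "elemental_formula")
    return(out)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("elemental formula counts must be named by element symbol")
  }
  known <- atomic_masses()$element
  bad <- setdiff(names(counts), known)
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  structure(as.integer(counts), names = names(counts),
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  if (length(x) == 0) {
    cat("<empty formula>\n")
  } else {
    cat(paste0(names(x), ifelse(x == 1, "", x), collapse = ""), "\n")
  }
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  elemental_formula(out)
}

#' Parse a Hill-style formula string
#'
#' Accepts formulas written as repeated element/count groups, e.g.
#' `"C3H4O"`. Underscores and Unicode subscript digits used as count
#' separators are normalized away before parsing, so
#' `"C_622_H_1040_N_196_O_172_S_3"` parses identically to
#' `"C622H1040N196O172S3"`. An element with no trailing digits has count 1.
#'
#' @param text Formula string.
#' @return An [elemental_formula()].
#' @export
#' @examples
#' parse_formula("C3H4O")
#' parse_formula("C_622_H_1040_N_196_O_172_S_3")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- text
  # normalize separators: underscores, whitespace, unicode subscripts
  subs <- c("₀", "₁", "₂", "₃", "₄",
            "₅", "₆", "₇", "₈", "₉")
  for (i in seq_along(subs)) text <- gsub(subs[i], as.character(i - 1), text)
  text <- gsub("[_[:space:]]", "", text)
  if (text == "") return(elemental_formula())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    # find the first character not consumed by a valid token
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) {
      if (m[i] > 0) {
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
      }
    }
    bad_at <- which(!covered)[1]
    stop("cannot parse formula '", raw, "': unexpected token near '",
         substr(text, bad_at, min(nchar(text), bad_at + 2)), "'")
  }
  el <- sub("[0-9]*$", "", toks)
  nstr <- sub("^[A-Za-z]+", "", toks)
  if (any(grepl("^0", nstr))) {
    stop("cannot parse formula '", raw, "': zero or zero-prefixed count")
  }
  n <- ifelse(nstr == "", 1L, suppressWarnings(as.integer(nstr)))
  known <- atomic_masses()$element
  bad <- setdiff(el, known)
  if (length(bad) > 0) {
    stop("cannot parse formula '", raw, "': unknown element symbol '",
         bad[1], "'")
  }
  counts <- tapply(n, el, sum)
  elemental_formula(counts[unique(el)])
}

mass_of <- function(f, table, kind) {
  if (!inherits(f, "elemental_formula")) f <- elemental_formula(f)
  if (length(f) == 0) return(0.0)
  idx <- match(names(f), table$element)
  if (anyNA(idx)) {
    stop("element(s) missing from mass table: ",
         paste(names(f)[is.na(idx)], collapse = ", "))
  }
  sum(unclass(f) * table[[kind]][idx])
}

#' Average (conventional atomic weight) mass of a formula
#'
#' @param f An [elemental_formula()] (or named count vector).
#' @param table Mass table, default [atomic_masses()].
#' @return Mass in Da. Rounding to two decimals is a reporting-layer choice,
#'   not applied here.
#' @export
#' @examples
#' average_mass(parse_formula("H2O"))
average_mass <- function(f, table = atomic_masses()) {
  mass_of(f, table, "average")
}

#' Monoisotopic mass of a formula
#'
#' @inheritParams average_mass
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("C3H4O"))  # propionyl, 56.026215
monoisotopic_mass <- function(f, table = atomic_masses()) {
  mass_of(f, table, "monoisotopic")
}
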