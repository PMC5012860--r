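# Variable/static modification definitions and the propionylation
# adjustment applied to lysine modification masses in derivatized samples.
#
# Chemistry behind the adjustment: the search applies a static propionyl
# (+C3H4O) to every lysine. A variable modification occupying the lysine
# epsilon-amine displaces that propionyl, so its effective search delta is
# (modification - propionyl). Mono-methylated lysine keeps a propionylatable
# N-H and is therefore exempt; di-/tri-methylation and acetylation/GlyGly
# block the amine and are adjusted.

#' Define a modification
#'
#' @param name Short name used in serialized peptide strings (e.g. "ub").
#' @param targets Character vector of one-letter residue codes the
#'   modification may occupy, or "protein-nterm".
#' @param composition [elemental_formula()] (or parseable string) of the
#'   added atoms. Compositions here are gains; losses are not needed for the
#'   supported set.
#' @param max_count Maximum copies per peptide (1 or 2).
#' @param methylation_class Logical; `TRUE` exempts the modification from
#'   propionyl subtraction (only mono-methylation, which leaves a free
#'   propionylatable N-H on the lysine).
#' @return An object of class `modification_def`.
#' @export
modification_def <- function(name, targets, composition, max_count = 2L,
                             methylation_class = FALSE) {
  if (is.character(composition)) composition <- parse_formula(composition)
  stopifnot(inherits(composition, "elemental_formula"))
  if (!max_count %in% c(1L, 2L)) {
    stop("max_count must be 1 or 2 for modification '", name, "'")
  }
  structure(
    list(name = name, targets = targets, composition = composition,
         max_count = as.integer(max_count),
         methylation_class = isTRUE(methylation_class)),
    class = "modification_def"
  )
}

#' Built-in modification table
#'
#' The standard (Unimod-composition) variable modifications plus the static
#' propionyl, with per-peptide caps as used for histone searches: up to 2
#' each of GlyGly (ubiquitylation remnant), methyl, dimethyl, trimethyl and
#' acetyl on lysine, 1 methionine oxidation, 1 STY phosphorylation.
#'
#' @return Named list of [modification_def()] objects, keyed by name:
#'   `ub`, `me`, `me2`, `me3`, `ac`, `ox`, `ph`, `prop`.
#' @export
#' @examples
#' names(mod_table())
#' monoisotopic_mass(mod_table()$ub$composition)  # 114.0429, GlyGly remnant
mod_table <- function() {
  list(
    ub  = modification_def("ub",  "K", "C4H6N2O2", 2L, FALSE),
    me  = modification_def("me",  "K", "CH2",      2L, TRUE),
    me2 = modification_def("me2", "K", "C2H4",     2L, FALSE),
    me3 = modification_def("me3", "K", "C3H6",     2L, FALSE),
    ac  = modification_def("ac",  "K", "C2H2O",    2L, FALSE),
    ox  = modification_def("ox",  "M", "O",        1L, FALSE),
    ph  = modification_def("ph",  c("S", "T", "Y"), "HPO3", 1L, FALSE),
    prop = modification_def("prop", c("K", "protein-nterm"), "C3H4O",
                            2L, FALSE)
  )
}

#' Read a modification table from a plain-text file
#'
#' Tab-separated with columns `name`, `targets` (comma-separated residue
#' codes / `protein-nterm`), `composition` (Hill formula), `max_count`,
#' `methylation_class`. The package ships its built-in set at
#' `system.file("extdata", "modifications.tsv", package = "histoneub")`;
#' users may extend or replace it.
#'
#' @param path Path to the table; defaults to the shipped file.
#' @return Named list of [modification_def()] objects.
#' @export
#' @examples
#' identical(names(read_mod_table()), names(mod_table()))
read_mod_table <- function(path = system.file("extdata",
                                              "modifications.tsv",
                                              package = "histoneub")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "targets", "composition", "max_count",
            "methylation_class")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("modification table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$name)) stop("duplicate modification name")
  mods <- lapply(seq_len(nrow(df)), function(i) {
    modification_def(df$name[i],
                     strsplit(df$targets[i], ",")[[1]],
                     df$composition[i],
                     as.integer(df$max_count[i]),
                     as.logical(df$methylation_class[i]))
  })
  stats::setNames(mods, df$name)
}

#' Monoisotopic mass of the propionyl group
#' @return 56.026215 Da (C3H4O).
#' @keywords internal
propionyl_mass <- function() monoisotopic_mass(parse_formula("C3H4O"))

#' Scheme-adjusted modification delta mass
#'
#' Under the `"underivatized"` scheme the delta is the plain monoisotopic
#' composition mass. Under the `"propionylated"` scheme, lysine-targeted
#' modifications that are not methylation-class have the propionyl mass
#' subtracted, because they displace the static propionyl already applied
#' to every lysine. Methylation-class and non-lysine modifications are
#' unchanged.
#'
#' @param m A [modification_def()].
#' @param scheme `"propionylated"` or `"underivatized"`.
#' @return Delta mass in Da (may be negative under adjustment).
#' @export
#' @examples
#' adjusted_mod_mass(mod_table()$ub, "propionylated")   #  58.0167
#' adjusted_mod_mass(mod_table()$me2, "propionylated")  # -27.9949
#' adjusted_mod_mass(mod_table()$me, "propionylated")   #  14.0157 (exempt)
adjusted_mod_mass <- function(m, scheme = c("propionylated", "underivatized")) {
  scheme <- match.arg(scheme)
  delta <- monoisotopic_mass(m$composition)
  if (scheme == "underivatized") return(delta)
  if ("K" %in% m$targets && !m$methylation_class && m$name != "prop") {
    delta <- delta - propionyl_mass()
  }
  delta
}
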