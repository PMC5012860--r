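# Retention-time consistency filtering of modified histone peptides.
#
# Under reversed-phase chromatography the lysine modification state shifts
# peptide hydrophobicity in a predictable direction, giving an elution
# partial order over site states:
#
#   ubiquitin < dimethyl <= trimethyl < acetyl < propionyl_only < methyl
#   methyl < unmodified;  oxidation < unmodified;  phospho <= unmodified
#
# ('<' = strictly earlier, '<=' = earlier or coeluting). Identifications
# whose retention times violate the order relative to better-scoring forms
# of the same unmodified sequence are rejected by a greedy pass in
# ascending posterior-error-probability order.

SITE_STATES <- c("ubiquitin", "dimethyl", "trimethyl", "acetyl",
                 "propionyl_only", "methyl", "unmodified",
                 "oxidation", "phospho")

RT_RELATIONS <- c("STRICT_BEFORE", "BEFORE_OR_COELUTE", "COELUTE",
                  "STRICT_AFTER", "AFTER_OR_COELUTE", "UNDEFINED")

# transitive closure of the elution order with strictness propagation:
# 0 = no path, 1 = non-strict path, 2 = strict path (strict if any link
# strict along the path)
site_order_closure <- function() {
  n <- length(SITE_STATES)
  M <- matrix(0L, n, n, dimnames = list(SITE_STATES, SITE_STATES))
  edge <- function(a, b, strict) {
    M[a, b] <<- max(M[a, b], if (strict) 2L else 1L)
  }
  edge("ubiquitin", "dimethyl", TRUE)
  edge("dimethyl", "trimethyl", FALSE)
  edge("trimethyl", "acetyl", TRUE)
  edge("acetyl", "propionyl_only", TRUE)
  edge("propionyl_only", "methyl", TRUE)
  edge("methyl", "unmodified", TRUE)
  edge("oxidation", "unmodified", TRUE)
  edge("phospho", "unmodified", FALSE)
  repeat {
    changed <- FALSE
    for (k in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
      if (M[a, k] > 0 && M[k, b] > 0) {
        v <- if (M[a, k] == 2L || M[k, b] == 2L) 2L else 1L
        if (v > M[a, b]) { M[a, b] <- v; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  M
}

.site_closure_cache <- new.env(parent = emptyenv())

site_closure <- function() {
  if (is.null(.site_closure_cache$M)) {
    .site_closure_cache$M <- site_order_closure()
  }
  .site_closure_cache$M
}

#' Expected elution relation between two site states
#'
#' @param a,b Site states (see `SITE_STATES`): `"ubiquitin"`, `"dimethyl"`,
#'   `"trimethyl"`, `"acetyl"`, `"propionyl_only"`, `"methyl"`,
#'   `"unmodified"`, `"oxidation"`, `"phospho"`.
#' @return One of `"STRICT_BEFORE"`, `"BEFORE_OR_COELUTE"`, `"COELUTE"`,
#'   `"STRICT_AFTER"`, `"AFTER_OR_COELUTE"`, `"UNDEFINED"`, giving the
#'   expected elution of `a` relative to `b`.
#' @export
#' @examples
#' site_relation("ubiquitin", "acetyl")    # STRICT_BEFORE
#' site_relation("dimethyl", "trimethyl")  # BEFORE_OR_COELUTE
site_relation <- function(a, b) {
  a <- match.arg(a, SITE_STATES)
  b <- match.arg(b, SITE_STATES)
  if (a == b) return("COELUTE")
  M <- site_closure()
  if (M[a, b] == 2L) return("STRICT_BEFORE")
  if (M[a, b] == 1L) return("BEFORE_OR_COELUTE")
  if (M[b, a] == 2L) return("STRICT_AFTER")
  if (M[b, a] == 1L) return("AFTER_OR_COELUTE")
  "UNDEFINED"
}

#' Per-site modification states of a peptide
#'
#' Maps a [modified_peptide()] to one site state per residue position. An
#' unmodified lysine is `"propionyl_only"` under the propionylated scheme
#' and `"unmodified"` otherwise; all other unmodified residues are
#' `"unmodified"`.
#'
#' @param p A [modified_peptide()] or serialized string.
#' @inheritParams modified_peptide
#' @return Character vector of site states, length `nchar(sequence)`.
#' @export
site_states <- function(p, scheme = "propionylated") {
  if (is.character(p)) p <- parse_peptide(p, scheme)
  res <- strsplit(p$sequence, "")[[1]]
  states <- ifelse(res == "K" & p$scheme == "propionylated",
                   "propionyl_only", "unmodified")
  statemap <- c(ub = "ubiquitin", me = "methyl", me2 = "dimethyl",
                me3 = "trimethyl", ac = "acetyl", ox = "oxidation",
                ph = "phospho")
  if (length(p$mods) > 0) {
    states[as.integer(names(p$mods))] <- statemap[p$mods]
  }
  states
}

#' Expected elution relation between two peptides of one group
#'
#' Both peptides must share the unmodified sequence. Sites with identical
#' states are ignored; the remaining per-site relations are combined:
#' all agreeing in direction gives that direction (strict if any site is
#' strict, `_OR_COELUTE` otherwise); no differing sites gives `COELUTE`;
#' any `UNDEFINED` site or conflicting directions gives `UNDEFINED`
#' (no constraint -- ambiguous evidence never rejects).
#'
#' @param pa,pb [modified_peptide()] objects or serialized strings.
#' @inheritParams modified_peptide
#' @return An RT relation string, as [site_relation()].
#' @export
peptide_relation <- function(pa, pb, scheme = "propionylated") {
  if (is.character(pa)) pa <- parse_peptide(pa, scheme)
  if (is.character(pb)) pb <- parse_peptide(pb, scheme)
  if (pa$sequence != pb$sequence) {
    stop("peptides have different unmodified sequences: ",
         pa$sequence, " vs ", pb$sequence)
  }
  sa <- site_states(pa)
  sb <- site_states(pb)
  combine_site_relations(mapply(site_relation, sa[sa != sb], sb[sa != sb]))
}

# combine per-site relations into a peptide-level relation
combine_site_relations <- function(rels) {
  rels <- rels[rels != "COELUTE"]
  if (length(rels) == 0) return("COELUTE")
  if (any(rels == "UNDEFINED")) return("UNDEFINED")
  before <- rels %in% c("STRICT_BEFORE", "BEFORE_OR_COELUTE")
  if (all(before)) {
    if (any(rels == "STRICT_BEFORE")) "STRICT_BEFORE" else "BEFORE_OR_COELUTE"
  } else if (all(!before)) {
    if (any(rels == "STRICT_AFTER")) "STRICT_AFTER" else "AFTER_OR_COELUTE"
  } else {
    "UNDEFINED"
  }
}

#' RT-filter configuration
#'
#' @param tolerance Coelution window in minutes (default 2.0): peptides
#'   expected to coelute may differ by at most this much; it also pads the
#'   non-strict (`_OR_COELUTE`) bounds. Strict bounds carry zero slack.
#' @param whitelist Character vector of serialized peptides accepted
#'   unconditionally (manual-inspection overrides); they are flagged and do
#'   not constrain other candidates.
#' @param representative `"satisfying"` (default): an accepted peptide's
#'   representative RT is the scan that satisfied its check;
#'   `"best_scan"`: always the first (lowest-PEP) scan.
#' @return Object of class `rt_filter_config`.
#' @export
rt_filter_config <- function(tolerance = 2.0, whitelist = character(),
                             representative = c("satisfying", "best_scan")) {
  stopifnot(tolerance >= 0)
  structure(list(tolerance = tolerance, whitelist = whitelist,
                 representative = match.arg(representative)),
            class = "rt_filter_config")
}

#' Construct a peptide group
#'
#' @param members List of members, each a list with `peptide` (serialized
#'   string or [modified_peptide()]), `pep`, `q_value`, `rts` (numeric
#'   vector of scan retention times, minutes, ordered best PSM first).
#' @inheritParams modified_peptide
#' @return Object of class `peptide_group` with the shared unmodified
#'   `sequence` and normalized members.
#' @export
peptide_group <- function(members, scheme = "propionylated") {
  stopifnot(length(members) > 0)
  members <- lapply(members, function(m) {
    p <- if (is.character(m$peptide)) parse_peptide(m$peptide, scheme) else m$peptide
    if (length(m$rts) == 0) {
      stop("group member '", format_peptide(p), "' has no scan RTs")
    }
    list(peptide = p, key = format_peptide(p), pep = m$pep,
         q_value = if (is.null(m$q_value)) NA_real_ else m$q_value,
         rts = as.numeric(m$rts))
  })
  seqs <- unique(vapply(members, function(m) m$peptide$sequence, ""))
  if (length(seqs) != 1) {
    stop("group members do not share one unmodified sequence: ",
         paste(seqs, collapse = ", "))
  }
  structure(list(sequence = seqs, members = members),
            class = "peptide_group")
}

# does scan RT s satisfy relation rel against an accepted peptide at rt_y?
rt_consistent <- function(s, rel, rt_y, tol) {
  switch(rel,
         STRICT_BEFORE     = s <= rt_y,
         BEFORE_OR_COELUTE = s <= rt_y + tol,
         COELUTE           = abs(s - rt_y) <= tol,
         STRICT_AFTER      = s >= rt_y,
         AFTER_OR_COELUTE  = s >= rt_y - tol,
         UNDEFINED         = TRUE)
}

#' Greedy RT-consistency acceptance over one peptide group
#'
#' Members are sorted by ascending PEP (ties: ascending q-value, then
#' lexicographic serialized peptide). The first member is accepted with its
#' first scan's RT as representative. Each subsequent member is accepted iff
#' at least one of its scan RTs is consistent with the expected elution
#' relation against every already-accepted member (whitelisted members are
#' accepted unconditionally, flagged, and impose no constraints).
#'
#' @param group A [peptide_group()].
#' @param cfg An [rt_filter_config()].
#' @return List with data frames `accepted` (columns `peptide`, `pep`,
#'   `q_value`, `rep_rt`, `flag`) and `rejected` (columns `peptide`, `pep`,
#'   `q_value`, `reason`).
#' @export
rt_accept <- function(group, cfg = rt_filter_config()) {
  stopifnot(inherits(group, "peptide_group"))
  m <- group$members
  ord <- order(vapply(m, `[[`, 0, "pep"),
               vapply(m, `[[`, 0, "q_value"),
               vapply(m, `[[`, "", "key"))
  m <- m[ord]
  accepted <- list()
  rejected <- list()
  for (cand in m) {
    if (cand$key %in% cfg$whitelist) {
      accepted[[length(accepted) + 1]] <-
        c(cand, list(rep_rt = cand$rts[1], flag = "whitelist",
                     constrains = FALSE))
      next
    }
    constraining <- Filter(function(a) a$constrains, accepted)
    rels <- vapply(constraining, function(a) {
      peptide_relation(cand$peptide, a$peptide)
    }, "")
    live <- which(rels != "UNDEFINED")
    rep_rt <- NA_real_
    failure <- NULL
    for (s in cand$rts) {
      ok <- TRUE
      for (j in live) {
        if (!rt_consistent(s, rels[j], constraining[[j]]$rep_rt,
                           cfg$tolerance)) {
          if (is.null(failure)) {
            failure <- sprintf("scan %.4g min violates %s vs %s @ %.4g min",
                               s, rels[j], constraining[[j]]$key,
                               constraining[[j]]$rep_rt)
          }
          ok <- FALSE
          break
        }
      }
      if (ok) { rep_rt <- s; break }
    }
    if (!is.na(rep_rt)) {
      if (cfg$representative == "best_scan") rep_rt <- cand$rts[1]
      accepted[[length(accepted) + 1]] <-
        c(cand, list(rep_rt = rep_rt, flag = "", constrains = TRUE))
    } else {
      rejected[[length(rejected) + 1]] <-
        c(cand, list(reason = failure %||% "no consistent scan"))
    }
  }
  list(
    accepted = data.frame(
      peptide = vapply(accepted, `[[`, "", "key"),
      pep = vapply(accepted, `[[`, 0, "pep"),
      q_value = vapply(accepted, `[[`, 0, "q_value"),
      rep_rt = vapply(accepted, `[[`, 0, "rep_rt"),
      flag = vapply(accepted, `[[`, "", "flag"),
      stringsAsFactors = FALSE),
    rejected = data.frame(
      peptide = vapply(rejected, `[[`, "", "key"),
      pep = vapply(rejected, `[[`, 0, "pep"),
      q_value = vapply(rejected, `[[`, 0, "q_value"),
      reason = vapply(rejected, `[[`, "", "reason"),
      stringsAsFactors = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build peptide groups from a PSM table
#'
#' Collapses PSM rows to unique canonical peptides (member PEP and q-value
#' are the minima over the peptide's PSMs; scan RTs are ordered by
#' ascending PSM PEP) and groups them by unmodified sequence.
#'
#' @param df A `psm_table` (see [read_psm_table()]).
#' @inheritParams modified_peptide
#' @return Named list of [peptide_group()] objects keyed by unmodified
#'   sequence.
#' @export
group_peptides <- function(df, scheme = c("propionylated", "underivatized")) {
  scheme <- match.arg(scheme)
  if (nrow(df) == 0) return(list())
  base <- vapply(df$peptide, function(s) parse_peptide(s, scheme)$sequence,
                 "", USE.NAMES = FALSE)
  groups <- split(df, base)
  lapply(groups, function(g) {
    members <- lapply(split(g, g$peptide), function(rows) {
      rows <- rows[order(rows$pep, rows$rt), , drop = FALSE]
      list(peptide = rows$peptide[1], pep = min(rows$pep),
           q_value = min(rows$q_value), rts = rows$rt)
    })
    peptide_group(unname(members), scheme)
  })
}
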