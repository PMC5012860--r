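# Independent brute-force reference for the RT-consistency filter.
#
# Deliberately implemented from scratch: the elution order is a literal
# edge list closed by path enumeration (not the package's matrix closure),
# site states are derived directly from the abstract member description
# (not via site_states/parse_peptide), and acceptance re-checks every scan
# against the whole accepted prefix.

oracle_edges <- data.frame(
  from = c("ubiquitin", "dimethyl", "trimethyl", "acetyl",
           "propionyl_only", "methyl", "oxidation", "phospho"),
  to = c("dimethyl", "trimethyl", "acetyl", "propionyl_only",
         "methyl", "unmodified", "unmodified", "unmodified"),
  strict = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

# all paths a -> b; returns NA (no path), "strict", or "nonstrict"
oracle_path <- function(a, b) {
  found <- character()
  walk <- function(node, any_strict) {
    if (node == b) {
      found <<- c(found, if (any_strict) "strict" else "nonstrict")
      return()
    }
    nxt <- oracle_edges[oracle_edges$from == node, , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      walk(nxt$to[i], any_strict || nxt$strict[i])
    }
  }
  walk(a, FALSE)
  if (length(found) == 0) NA_character_
  else if (any(found == "strict")) "strict" else "nonstrict"
}

oracle_site_rel <- function(a, b) {
  if (a == b) return("COELUTE")
  fwd <- oracle_path(a, b)
  if (!is.na(fwd)) {
    return(if (fwd == "strict") "STRICT_BEFORE" else "BEFORE_OR_COELUTE")
  }
  bwd <- oracle_path(b, a)
  if (!is.na(bwd)) {
    return(if (bwd == "strict") "STRICT_AFTER" else "AFTER_OR_COELUTE")
  }
  "UNDEFINED"
}

oracle_pep_rel <- function(states_a, states_b) {
  rels <- character()
  for (i in seq_along(states_a)) {
    if (states_a[i] != states_b[i]) {
      rels <- c(rels, oracle_site_rel(states_a[i], states_b[i]))
    }
  }
  if (length(rels) == 0) return("COELUTE")
  if (any(rels == "UNDEFINED")) return("UNDEFINED")
  fwd <- rels %in% c("STRICT_BEFORE", "BEFORE_OR_COELUTE")
  if (all(fwd)) {
    if (any(rels == "STRICT_BEFORE")) "STRICT_BEFORE"
    else "BEFORE_OR_COELUTE"
  } else if (all(!fwd)) {
    if (any(rels == "STRICT_AFTER")) "STRICT_AFTER"
    else "AFTER_OR_COELUTE"
  } else "UNDEFINED"
}

oracle_ok <- function(s, rel, rt_y, tol) {
  if (rel == "STRICT_BEFORE") s <= rt_y
  else if (rel == "BEFORE_OR_COELUTE") s <= rt_y + tol
  else if (rel == "COELUTE") abs(s - rt_y) <= tol
  else if (rel == "STRICT_AFTER") s >= rt_y
  else if (rel == "AFTER_OR_COELUTE") s >= rt_y - tol
  else TRUE
}

# members: list of list(key, states, pep, q, rts); returns accepted keys
oracle_accept <- function(members, tol) {
  ord <- order(vapply(members, `[[`, 0, "pep"),
               vapply(members, `[[`, 0, "q"),
               vapply(members, `[[`, "", "key"))
  members <- members[ord]
  acc <- list()
  for (cand in members) {
    rep_rt <- NA
    for (s in cand$rts) {
      all_ok <- TRUE
      for (a in acc) {
        rel <- oracle_pep_rel(cand$states, a$states)
        if (!oracle_ok(s, rel, a$rep_rt, tol)) { all_ok <- FALSE; break }
      }
      if (all_ok) { rep_rt <- s; break }
    }
    if (!is.na(rep_rt)) acc[[length(acc) + 1]] <- c(cand,
                                                    list(rep_rt = rep_rt))
  }
  sort(vapply(acc, `[[`, "", "key"))
}

# --- random-group machinery shared by the oracle tests -------------------

# abstract state tuples over sequence "MKSAGGKAR": position 1 (M), 2 (K),
# 3 (S); K7 always bare
ORACLE_SEQ <- "MKSAGGKAR"
K_STATES <- c("propionyl_only", "ubiquitin", "methyl", "dimethyl",
              "trimethyl", "acetyl")
M_STATES <- c("unmodified", "oxidation")
S_STATES <- c("unmodified", "phospho")

state_tuple_to_mods <- function(kst, mst, sst) {
  modmap <- c(ubiquitin = "ub", methyl = "me", dimethyl = "me2",
              trimethyl = "me3", acetyl = "ac", oxidation = "ox",
              phospho = "ph")
  mods <- character()
  if (kst != "propionyl_only") mods["2"] <- modmap[[kst]]
  if (mst != "unmodified") mods["1"] <- modmap[[mst]]
  if (sst != "unmodified") mods["3"] <- modmap[[sst]]
  mods
}

full_states <- function(kst, mst, sst) {
  # per-position site states of ORACLE_SEQ under the propionylated scheme
  st <- rep("unmodified", nchar(ORACLE_SEQ))
  st[c(2, 7)] <- "propionyl_only"
  st[2] <- kst; st[1] <- mst; st[3] <- sst
  st
}

random_group <- function(n_members, n_scans_max = 3) {
  tuples <- expand.grid(k = K_STATES, m = M_STATES, s = S_STATES,
                        stringsAsFactors = FALSE)
  pick <- tuples[sample(nrow(tuples), n_members), , drop = FALSE]
  members_pkg <- list(); members_orc <- list()
  for (i in seq_len(n_members)) {
    mods <- state_tuple_to_mods(pick$k[i], pick$m[i], pick$s[i])
    p <- modified_peptide(ORACLE_SEQ, mods)
    pep <- stats::runif(1)
    q <- stats::runif(1)
    rts <- round(stats::runif(sample(n_scans_max, 1), 0, 60), 2)
    members_pkg[[i]] <- list(peptide = p, pep = pep, q_value = q,
                             rts = rts)
    members_orc[[i]] <- list(key = format_peptide(p),
                             states = full_states(pick$k[i], pick$m[i],
                                                  pick$s[i]),
                             pep = pep, q = q, rts = rts)
  }
  list(pkg = members_pkg, orc = members_orc)
}
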