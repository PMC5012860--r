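# Elution partial order, peptide relations, greedy RT acceptance.

test_that("site_relation implements the stated chain and its closure", {
  expect_identical(site_relation("ubiquitin", "dimethyl"), "STRICT_BEFORE")
  expect_identical(site_relation("dimethyl", "trimethyl"),
                   "BEFORE_OR_COELUTE")
  expect_identical(site_relation("trimethyl", "acetyl"), "STRICT_BEFORE")
  expect_identical(site_relation("acetyl", "propionyl_only"),
                   "STRICT_BEFORE")
  expect_identical(site_relation("propionyl_only", "methyl"),
                   "STRICT_BEFORE")
  expect_identical(site_relation("methyl", "unmodified"), "STRICT_BEFORE")
  expect_identical(site_relation("oxidation", "unmodified"),
                   "STRICT_BEFORE")
  expect_identical(site_relation("phospho", "unmodified"),
                   "BEFORE_OR_COELUTE")
  # closure: strictness propagates along any strict link
  expect_identical(site_relation("ubiquitin", "acetyl"), "STRICT_BEFORE")
  expect_identical(site_relation("dimethyl", "acetyl"), "STRICT_BEFORE")
  expect_identical(site_relation("ubiquitin", "unmodified"),
                   "STRICT_BEFORE")
  # inverses
  expect_identical(site_relation("acetyl", "ubiquitin"), "STRICT_AFTER")
  expect_identical(site_relation("trimethyl", "dimethyl"),
                   "AFTER_OR_COELUTE")
  # unrelated pairs
  expect_identical(site_relation("oxidation", "ubiquitin"), "UNDEFINED")
  expect_identical(site_relation("phospho", "methyl"), "UNDEFINED")
})

test_that("site_relation is its own inverse and reflexive to COELUTE", {
  inverse <- c(STRICT_BEFORE = "STRICT_AFTER",
               BEFORE_OR_COELUTE = "AFTER_OR_COELUTE",
               COELUTE = "COELUTE",
               STRICT_AFTER = "STRICT_BEFORE",
               AFTER_OR_COELUTE = "BEFORE_OR_COELUTE",
               UNDEFINED = "UNDEFINED")
  states <- c("ubiquitin", "dimethyl", "trimethyl", "acetyl",
              "propionyl_only", "methyl", "unmodified", "oxidation",
              "phospho")
  for (a in states) {
    expect_identical(site_relation(a, a), "COELUTE")
    for (b in states) {
      expect_identical(site_relation(b, a),
                       unname(inverse[site_relation(a, b)]))
    }
  }
})

test_that("site_relation agrees with the path-enumeration oracle", {
  states <- c("ubiquitin", "dimethyl", "trimethyl", "acetyl",
              "propionyl_only", "methyl", "unmodified", "oxidation",
              "phospho")
  for (a in states) for (b in states) {
    expect_identical(site_relation(a, b), oracle_site_rel(a, b),
                     label = paste(a, "vs", b))
  }
})

test_that("peptide_relation combines per-site relations", {
  # single differing site reduces to site_relation
  expect_identical(peptide_relation("KQLATK[ub]AAR", "KQLATKAAR"),
                   "STRICT_BEFORE")
  # identical modification states coelute
  expect_identical(peptide_relation("KQLATK[ub]AAR", "KQLATK[ub]AAR"),
                   "COELUTE")
  # conflicting directions give no constraint
  expect_identical(peptide_relation("K[ub]QLATK[ac]AAR",
                                    "K[ac]QLATK[ub]AAR"), "UNDEFINED")
  # agreeing directions promote strictness
  expect_identical(peptide_relation("K[ub]QLATK[me2]AAR",
                                    "K[me2]QLATK[me3]AAR"),
                   "STRICT_BEFORE")
  # conflicting directions across different sites give no constraint
  expect_identical(peptide_relation("M[ox]KSAGGK[ub]AR",
                                    "MK[ub]SAGGK[ub]AR"), "UNDEFINED")
  expect_error(peptide_relation("KQLATKAAR", "TKQTAR"),
               "different unmodified sequences")
})

test_that("rt_accept handles the hand-worked single-constraint cases", {
  cfg <- rt_filter_config(tolerance = 2)
  mk <- function(pep, pepval, rts) {
    list(peptide = pep, pep = pepval, q_value = pepval, rts = rts)
  }
  # singleton group accepted
  g1 <- peptide_group(list(mk("KQLATK[ub]AAR", 0.001, 40.0)))
  r1 <- rt_accept(g1, cfg)
  expect_identical(r1$accepted$peptide, "KQLATK[ub]AAR")
  expect_identical(nrow(r1$rejected), 0L)

  # accepted ubiquitin form at 40; propionyl-only candidate must elute
  # at or after it (strict, zero slack)
  g_bad <- peptide_group(list(mk("KQLATK[ub]AAR", 0.001, 40.0),
                              mk("KQLATKAAR", 0.01, 38.0)))
  r_bad <- rt_accept(g_bad, cfg)
  expect_identical(r_bad$rejected$peptide, "KQLATKAAR")
  expect_match(r_bad$rejected$reason, "STRICT_AFTER")

  g_ok <- peptide_group(list(mk("KQLATK[ub]AAR", 0.001, 40.0),
                             mk("KQLATKAAR", 0.01, 41.0)))
  expect_identical(nrow(rt_accept(g_ok, cfg)$rejected), 0L)

  # one consistent scan among several suffices
  g_multi <- peptide_group(list(mk("KQLATK[ub]AAR", 0.001, 40.0),
                                mk("KQLATKAAR", 0.01, c(38.0, 41.5))))
  r_multi <- rt_accept(g_multi, cfg)
  expect_identical(nrow(r_multi$rejected), 0L)
  expect_equal(r_multi$accepted$rep_rt[r_multi$accepted$peptide ==
                                         "KQLATKAAR"], 41.5)
})

test_that("whitelisted peptides are accepted, flagged, non-constraining", {
  cfg <- rt_filter_config(tolerance = 2, whitelist = "KQLATKAAR")
  g <- peptide_group(list(
    list(peptide = "KQLATK[ub]AAR", pep = 0.001, q_value = 0.001,
         rts = 40.0),
    # would fail the strict-after check without the override
    list(peptide = "KQLATKAAR", pep = 0.01, q_value = 0.01, rts = 30.0),
    list(peptide = "KQLATK[me2]AAR", pep = 0.02, q_value = 0.02,
         rts = 41.0)))
  r <- rt_accept(g, cfg)
  expect_identical(nrow(r$rejected), 0L)
  wl <- r$accepted[r$accepted$peptide == "KQLATKAAR", ]
  expect_identical(wl$flag, "whitelist")
  # the me2 form is checked against the ub form only (30.0 would conflict)
  expect_identical(r$accepted$flag[r$accepted$peptide ==
                                     "KQLATK[me2]AAR"], "")
})

test_that("rt_accept errors on a member with zero scans", {
  expect_error(peptide_group(list(list(peptide = "KQLATKAAR", pep = 0.1,
                                       q_value = 0.1,
                                       rts = numeric()))),
               "no scan RTs")
})

test_that("rt_accept matches the brute-force oracle on random groups", {
  set.seed(42)
  cfgs <- c(0, 1, 2)
  for (i in 1:300) {
    grp <- random_group(sample(2:6, 1))
    tol <- sample(cfgs, 1)
    pkg <- rt_accept(peptide_group(grp$pkg),
                     rt_filter_config(tolerance = tol))
    expect_identical(sort(pkg$accepted$peptide),
                     oracle_accept(grp$orc, tol),
                     label = paste("group", i))
  }
})

test_that("rt_accept is invariant to input member order", {
  set.seed(99)
  for (i in 1:40) {
    grp <- random_group(sample(3:6, 1))
    cfg <- rt_filter_config(tolerance = 2)
    ref <- rt_accept(peptide_group(grp$pkg), cfg)
    perm <- sample(length(grp$pkg))
    out <- rt_accept(peptide_group(grp$pkg[perm]), cfg)
    expect_equal(out$accepted[order(out$accepted$peptide), ],
                 ref$accepted[order(ref$accepted$peptide), ],
                 ignore_attr = TRUE)
  }
})

test_that("enlarging the tolerance never rejects a previously accepted
           member (best-scan representative)", {
  set.seed(17)
  for (i in 1:60) {
    grp <- random_group(sample(2:6, 1))
    g <- peptide_group(grp$pkg)
    prev <- rt_accept(g, rt_filter_config(tolerance = 0,
                                          representative = "best_scan"))
    for (tol in c(0.5, 2, 10)) {
      cur <- rt_accept(g, rt_filter_config(tolerance = tol,
                                           representative = "best_scan"))
      expect_true(all(prev$accepted$peptide %in% cur$accepted$peptide))
      prev <- cur
    }
  }
})

test_that("group_peptides collapses PSMs and groups by unmodified
           sequence", {
  df <- read_psm_table(write_psm_fixture())
  groups <- group_peptides(df)
  expect_setequal(names(groups), c("KQLATKAAR", "TKQTAR"))
  g <- groups[["KQLATKAAR"]]
  expect_identical(length(g$members), 3L)
  keys <- vapply(g$members, `[[`, "", "key")
  expect_setequal(keys, c("KQLATK[ub]AAR", "KQLATK[ac]AAR", "KQLATKAAR"))
})
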