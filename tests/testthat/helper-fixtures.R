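# In-code fixtures: a small well-formed Percolator-style PSM table.

psm_fixture_df <- function() {
  data.frame(
    PSMId = c("p1", "p2", "p3", "p4"),
    SpectrumId = c("s1", "s1", "s2", "s3"),
    RT = c(30.1, 30.1, 41.5, 12.0),
    Charge = c(2L, 2L, 3L, 2L),
    Peptide = c("KQLATK[ub]AAR", "KQLATK[ac]AAR", "KQLATKAAR",
                "TK[me3]QTAR"),
    XCorr = c(3.2, 2.4, 2.8, 1.9),
    Rank = c(1L, 2L, 1L, 1L),
    `posterior_error_prob` = c(0.001, 0.30, 0.004, 0.02),
    `q-value` = c(0.002, 0.21, 0.004, 0.03),
    Sample = "HeDNA",
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

write_psm_fixture <- function(df = psm_fixture_df(),
                              path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
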