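# Small in-code fixtures shared across tests.

toy_counts <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    s1 = c(10, 0, 7),
    s2 = c(20, 5, 7)
  )
}

write_toy_maf <- function(path = tempfile(fileext = ".maf"),
                          comment_first = FALSE) {
  lines <- c(
    if (comment_first) "#version 2.4",
    "Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode",
    "TP53\tMissense_Mutation\tS1",
    "TP53\tMissense_Mutation\tS1",
    "KRAS\tSilent\tS1",
    "EGFR\tNonsense_Mutation\tS2"
  )
  writeLines(lines, path)
  path
}

write_toy_gmt <- function(path = tempfile(fileext = ".gmt"),
                          lines = c("A\tdesc\tg1\tg2", "B\tdesc\tg2\tg3")) {
  writeLines(lines, path)
  path
}

toy_clinical_lines <- function() {
  c(
    "sample_id\tos_time\tos_event\tsex\trace\tstage\tgrade\tage",
    "S1\t24.3\t1\tF\twhite\tStage II\thigh\t61",
    "S2\t10.0\t0\tM\tasian\t3\tlow\t54",
    "S3\tNA\tNA\tF\twhite\tStage IVa\t\t70"
  )
}

# A deterministic small survival dataset exercising censoring and both
# group labels.
toy_survival <- function() {
  tibble::tibble(
    group = c("low", "low", "low", "high", "high", "high"),
    time = c(2, 4, 6, 1, 3, 5),
    event = c(1, 1, 0, 1, 1, 1)
  )
}
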