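# Independent direct-arithmetic oracles for the five disproportionality
# statistics. Deliberately coded without logs and without reuse of any
# package internals, so they can stand against the implementation.

oracle_ror <- function(a, b, c, d) (a / c) / (b / d)

oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))

oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

oracle_ebgm <- function(a, b, c, d) {
  a * (a + b + c + d) / ((a + b) * (a + c))
}

oracle_ic <- function(a, b, c, d) log2(oracle_ebgm(a, b, c, d))

# every 2x2 table with all cells drawn from `cells`
all_tables <- function(cells) {
  expand.grid(a = cells, b = cells, c = cells, d = cells)
}

# write a tiny hand-rolled quarter into dir; returns dir
write_mini_quarter <- function(dir, quarter = "24Q1",
                               demo, drug, reac, outc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(lines, stem) {
    writeLines(lines, file.path(dir, sprintf("%s%s.txt", stem, quarter)))
  }
  w(demo, "DEMO")
  w(drug, "DRUG")
  w(reac, "REAC")
  if (!is.null(outc)) w(outc, "OUTC")
  dir
}

# minimal vocabulary files; returns a loaded vocabulary_map
write_mini_vocab <- function(dir,
                             syn = c("synonym\tingredient",
                                     "aldactone\tspironolactone",
                                     "spironolactone\tspironolactone"),
                             pts = c("pt\tsoc",
                                     "hyperkalaemia\tmetabolism and nutrition disorders",
                                     "nipple pain\treproductive system and breast disorders")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  drug_file <- file.path(dir, "syn.tsv")
  pt_file <- file.path(dir, "ptsoc.tsv")
  writeLines(syn, drug_file)
  writeLines(pts, pt_file)
  load_vocabulary(drug_file, pt_file)
}
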