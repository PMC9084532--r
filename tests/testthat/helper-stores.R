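# Build a store from a named list of genotype literals, e.g.
# quick_store(rs1800546 = "G/G", `chr1:16949` = "T/T", rs12 = "--")
quick_store <- function(...) {
  calls <- list(...)
  rows <- lapply(seq_along(calls), function(i) {
    key <- names(calls)[i]
    if (grepl(":", key, fixed = TRUE)) {
      bits <- strsplit(key, ":", fixed = TRUE)[[1]]
      data.frame(rsid = ".", chrom = sub("^chr", "", bits[1]),
                 pos = as.integer(bits[2]), genotype = calls[[i]])
    } else {
      data.frame(rsid = key, chrom = "1", pos = 1000L + i * 10L,
                 genotype = calls[[i]])
    }
  })
  genotype_store(do.call(rbind, rows), sample_id = "test")
}

# The bundled worked-example files.
demo_script_path <- function() {
  system.file("extdata", "demo_risk.lua", package = "genorules")
}
fructose_path <- function() {
  system.file("extdata", "fructose.txt", package = "genorules")
}
demo_script_text <- function() {
  paste(readLines(demo_script_path()), collapse = "\n")
}

# The four stores exercised against the demo script: high-risk,
# medium-risk and no-match genotype configurations.
demo_store_high <- function() quick_store(
  rs568149713 = "A/G", rs557514207 = "G/G",
  `chr1:16949` = "T/T", rs553090414 = "C/T")
demo_store_medium <- function() quick_store(
  rs568149713 = "G/G", rs557514207 = "A/G",
  `chr1:16949` = "T/T", rs553090414 = "C/C")
demo_store_none <- function() quick_store(
  rs568149713 = "T/T", rs557514207 = "T/T",
  `chr1:16949` = "T/T", rs553090414 = "T/T")

# Fixture spec over the three fructose-screen variants with chosen GTs
# (REF/ALT arranged so 0=reference, 1=the rule's risk allele).
fructose_fixture_spec <- function(gt1800546 = "0/0", gt76917243 = "0/0",
                                  gt78340951 = "0/0") {
  fixture_spec(
    data.frame(chrom = "9",
               pos = c(101421528, 101425426, 101428946),
               rsid = c("rs1800546", "rs76917243", "rs78340951"),
               ref = c("C", "G", "G"),
               alt = c("G", "T", "C")),
    genotypes = c(gt1800546, gt76917243, gt78340951))
}
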