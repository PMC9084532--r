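# Synthetic fixtures: deterministic VCF/TSV writers plus random generators
# for rule sets, scripts and stores, so the whole pipeline is testable
# without external data.

#' Describe a synthetic single-sample fixture
#'
#' @param variants data.frame with columns `chrom`, `pos`, `rsid` (`""` or
#'   `"."` for none), `ref` and `alt` (comma-joined alternate alleles).
#' @param genotypes character vector of VCF GT strings (`"0/1"`, `"1|1"`,
#'   `"./."`, ...), one per variant row; recycled if length 1.
#' @param sample_id sample column name for the VCF.
#' @param seed integer recorded with the spec (generation from a spec is
#'   fully deterministic; the seed documents how a randomly drawn spec was
#'   produced).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(variants, genotypes = "0/0", sample_id = "SAMPLE1",
                         seed = 0L) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "rsid", "ref", "alt") %in% names(variants)))
  genotypes <- rep_len(as.character(genotypes), nrow(variants))
  v <- data.table::as.data.table(variants)
  v[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
           rsid = as.character(rsid), ref = toupper(as.character(ref)),
           alt = toupper(as.character(alt)), gt = genotypes)]
  data.table::setorder(v, chrom, pos)
  dup <- v[, any(duplicated(pos)), by = chrom]$V1
  if (any(dup)) {
    stop("fixture positions must be strictly increasing within a chromosome")
  }
  structure(list(variants = v, sample_id = sample_id, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Write a fixture as a matched VCF/TSV pair
#'
#' Emits a single-sample VCF 4.2 file (sorted records, GT-only FORMAT) and
#' the equivalent four-column genotype table. Output is byte-deterministic
#' given the spec; reading either file back yields stores that agree on every
#' non-missing call.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param basename stem for the two file names.
#' @return list with elements `vcf` and `tsv` (the written paths).
#' @export
generate_fixture <- function(spec, dir = tempdir(), basename = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- spec$variants
  vcf_path <- file.path(dir, paste0(basename, ".vcf"))
  tsv_path <- file.path(dir, paste0(basename, ".tsv"))

  id <- ifelse(is.na(v$rsid) | !nzchar(v$rsid), ".", v$rsid)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genorules-fixture",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", spec$sample_id), collapse = "\t"))
  body <- if (nrow(v) > 0L) {
    paste(v$chrom, v$pos, id, v$ref, v$alt, ".", ".", ".", "GT", v$gt,
          sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), vcf_path)

  geno <- vapply(seq_len(nrow(v)), function(i) {
    call <- tryCatch(
      normalize_genotype(v$gt[i], v$ref[i],
                         strsplit(v$alt[i], ",", fixed = TRUE)[[1]]),
      error = function(e) genotype_call(character(0), raw = v$gt[i]))
    if (call$missing) "--" else paste(call$alleles, collapse = "/")
  }, character(1))
  writeLines(c("# rsid\tchrom\tpos\tgenotype",
               paste(id, v$chrom, v$pos, geno, sep = "\t")), tsv_path)

  list(vcf = vcf_path, tsv = tsv_path)
}

# --- random generators (driven by the caller's RNG state) ------------------

ALLELE_POOL <- c("A", "C", "G", "T")

random_literal_text <- function(indel_prob = 0.1) {
  if (stats::runif(1) < indel_prob) {
    long <- paste(sample(ALLELE_POOL, sample(2:4, 1), replace = TRUE),
                  collapse = "")
    paste0(sample(ALLELE_POOL, 1), "/", long)
  } else {
    paste(sample(ALLELE_POOL, 2, replace = TRUE), collapse = "/")
  }
}

#' Draw a random rule set
#'
#' Generator for property tests: 1--3 blocks of mixed Any/All mode with 1--3
#' conditions each, keys drawn from a small pool of rsIDs and positional
#' keys, genotype literals over A/C/G/T with occasional indels, trait labels
#' containing spaces, and (with the stated probabilities) nonzero risk values
#' and an else label. Uses the caller's RNG state; seed it for
#' reproducibility.
#'
#' @param key_pool candidate variant keys.
#' @param p_else probability of an else label.
#' @param p_risk probability that a block carries a nonzero risk value.
#' @return a [rule_set()].
#' @export
random_ruleset <- function(key_pool = default_key_pool(),
                           p_else = 0.7, p_risk = 0.3) {
  n_blocks <- sample(1:3, 1)
  traits <- c("High Risk", "Moderate Risk", "Carrier", "Protective",
              "Variant Carrier", "Intolerant")
  blocks <- lapply(seq_len(n_blocks), function(b) {
    n_cond <- sample(1:3, 1)
    keys <- sample(key_pool, n_cond)
    lits <- replicate(n_cond, random_literal_text(), simplify = FALSE)
    risk <- if (stats::runif(1) < p_risk) round(stats::runif(1), 2) else 0
    rule_block(sample(c("any", "all"), 1), keys, lits,
               paste(sample(traits, 1), b), risk)
  })
  else_trait <- if (stats::runif(1) < p_else) "No Match" else NULL
  rule_set(blocks, else_trait)
}

#' @rdname random_ruleset
#' @export
default_key_pool <- function() {
  c(paste0("rs", 1001:1008), "chr1:16949", "chr2:500100", "chrX:99001")
}

#' Draw a random genotype store over a key pool
#'
#' Each key is present with probability `p_present`; present calls are
#' missing with probability `p_missing`, otherwise a random unphased diploid
#' genotype over A/C/G/T (occasionally an indel allele). Uses the caller's
#' RNG state.
#'
#' @param key_pool variant keys to consider.
#' @param p_present inclusion probability per key.
#' @param p_missing probability a present call is missing.
#' @return a `genotype_store`.
#' @export
random_genotype_store <- function(key_pool = default_key_pool(),
                                  p_present = 0.75, p_missing = 0.1) {
  rows <- list()
  auto_pos <- 10000L
  for (key in key_pool) {
    if (stats::runif(1) >= p_present) next
    if (grepl(":", key, fixed = TRUE)) {
      bits <- strsplit(key, ":", fixed = TRUE)[[1]]
      chrom <- norm_chrom(bits[1]); pos <- as.integer(bits[2]); rsid <- "."
    } else {
      chrom <- "1"; pos <- auto_pos; auto_pos <- auto_pos + 100L; rsid <- key
    }
    g <- if (stats::runif(1) < p_missing) "--" else random_literal_text(0.05)
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = rsid, chrom = chrom, pos = pos, genotype = g)
  }
  if (length(rows) == 0L) {
    rows <- list(data.frame(rsid = "rs999999", chrom = "1", pos = 1L,
                            genotype = "--"))
  }
  genotype_store(do.call(rbind, rows), sample_id = "random")
}

#' Draw a random rule-script program text
#'
#' Emits 1--3 if-blocks whose conditions are and/or combinations (depth up to
#' 2, occasionally parenthesized) of genotype equality tests over the key
#' pool, with bodies assigning `comment`/`risk` and optionally returning
#' early, plus optional trailing default assignments. The output always
#' parses under [parse_script()]. Uses the caller's RNG state.
#'
#' @param key_pool candidate variant keys (colon-form keys are emitted
#'   verbatim and sanitized by the parser).
#' @return a single string of script text.
#' @export
random_script <- function(key_pool = default_key_pool()) {
  atom <- function() {
    paste0(sample(key_pool, 1), " == \"", random_literal_text(0.05), "\"")
  }
  expr <- function(depth = 0) {
    if (depth >= 2 || stats::runif(1) < 0.4) return(atom())
    op <- sample(c("and", "or"), 1)
    left <- expr(depth + 1)
    right <- expr(depth + 1)
    txt <- paste(left, op, right)
    if (stats::runif(1) < 0.2) paste0("(", txt, ")") else txt
  }
  n_blocks <- sample(1:3, 1)
  out <- character(0)
  for (b in seq_len(n_blocks)) {
    body <- c(paste0("  comment = \"label ", b, "\""),
              paste0("  risk = ", round(stats::runif(1), 2)))
    if (stats::runif(1) < 0.4) body <- c(body, "  return risk, comment")
    out <- c(out, paste0("if ", expr(), " then"), body, "end")
  }
  if (stats::runif(1) < 0.3) out <- c(out, "comment = \"fallthrough\"")
  paste(out, collapse = "\n")
}
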