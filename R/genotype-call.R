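# Genotype calls: the value every rule condition tests.

MISSING_TOKENS <- c(".", "-", "0")          # single-allele missing markers
MISSING_GENOTYPES <- c("--", "..", "00")    # whole-genotype missing markers (TSV)

#' Construct a genotype call
#'
#' A genotype call is an ordered pair (or degenerate single/empty set) of
#' allele strings for one sample at one site, with phase and missingness
#' flags. Alleles are uppercased nucleotide sequences (`[ACGTN]+`); a single
#' allele arises from hemizygous calls, an empty set from fully missing ones.
#'
#' @param alleles character vector of 0--2 allele strings; the missing token
#'   `"."` is allowed and marks the call missing.
#' @param phased logical; only meaningful (and only permitted `TRUE`) for
#'   two-allele calls.
#' @param raw the genotype string as read from the source, kept for reporting.
#' @return an object of class `genotype_call` with fields `alleles`, `phased`,
#'   `missing` and `raw`.
#' @examples
#' genotype_call(c("A", "G"))
#' genotype_call(character(0))$missing
#' @export
genotype_call <- function(alleles = character(0), phased = FALSE, raw = NULL) {
  alleles <- toupper(as.character(alleles))
  if (length(alleles) > 2) {
    stop("a genotype call carries at most two alleles, got ", length(alleles))
  }
  missing <- length(alleles) == 0L || any(alleles %in% MISSING_TOKENS)
  bad <- alleles[!(alleles %in% MISSING_TOKENS) & !grepl("^[ACGTN]+$", alleles)]
  if (length(bad)) {
    stop("invalid allele string(s): ", paste(sQuote(bad), collapse = ", "),
         " (alleles must match [ACGTN]+)")
  }
  if (phased && length(alleles) != 2L) {
    stop("phased may only be TRUE for a two-allele call")
  }
  if (is.null(raw)) raw <- paste(alleles, collapse = if (phased) "|" else "/")
  structure(
    list(alleles = alleles, phased = isTRUE(phased), missing = missing,
         raw = as.character(raw)),
    class = "genotype_call"
  )
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$missing) {
    cat("<genotype_call: missing (raw '", x$raw, "')>\n", sep = "")
  } else {
    sep <- if (x$phased) "|" else "/"
    cat("<genotype_call: ", paste(x$alleles, collapse = sep), ">\n", sep = "")
  }
  invisible(x)
}

#' @export
format.genotype_call <- function(x, ...) {
  if (x$missing) return("./.")
  paste(x$alleles, collapse = if (x$phased) "|" else "/")
}

#' Parse a genotype literal as written in rule files
#'
#' Accepted forms are a two-character shorthand like `GG` and a slash form
#' like `C/G`, either optionally wrapped in single or double quotes (straight
#' or typographic). The slash form is mandatory for sites whose alleles are
#' longer than one base (indels, e.g. `'T/TGAT'`): without a slash the text
#' must be exactly two single-character alleles.
#'
#' @param text the literal text.
#' @return a non-missing [genotype_call()].
#' @examples
#' parse_genotype_literal("'GG'")
#' parse_genotype_literal("C/G")
#' parse_genotype_literal("'T/TGAT'")
#' @export
parse_genotype_literal <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- strip_quotes(trimws(text))
  if (!nzchar(stripped)) stop("empty genotype literal")
  if (grepl("/", stripped, fixed = TRUE)) {
    alleles <- strsplit(stripped, "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2L || any(!nzchar(alleles))) {
      stop("genotype literal ", sQuote(text),
           " must have exactly two non-empty alleles around '/'")
    }
  } else {
    if (nchar(stripped) != 2L) {
      stop("genotype literal ", sQuote(text), " without '/' must be exactly ",
           "two single-character alleles; multi-base alleles (indels) ",
           "require the slash form, e.g. 'T/TGAT'")
    }
    alleles <- strsplit(stripped, "")[[1]]
  }
  call <- genotype_call(alleles, phased = FALSE, raw = stripped)
  if (call$missing) stop("genotype literal ", sQuote(text), " is missing-valued")
  call
}

# Strip one layer of matching straight or typographic quotes.
strip_quotes <- function(x) {
  pairs <- list(c("'", "'"), c('"', '"'),
                c("‘", "’"), c("“", "”"))
  for (p in pairs) {
    if (nchar(x) >= 2L && startsWith(x, p[1]) && endsWith(x, p[2])) {
      return(substr(x, 2L, nchar(x) - 1L))
    }
  }
  x
}

#' Resolve a VCF GT field against REF/ALT alleles
#'
#' Replaces the allele indices of a VCF `GT` entry (`a/b`, `a|b`, `a`, or
#' missing tokens) by the corresponding allele sequences. Index 0 is the
#' reference allele; index k >= 1 is the k-th alternate. `|` marks the call
#' phased, `/` unphased; allele order is preserved as given.
#'
#' @param gt_field the raw GT string.
#' @param ref reference allele string.
#' @param alts character vector of alternate allele strings.
#' @return a [genotype_call()]; missing tokens yield a missing call.
#' @examples
#' normalize_genotype("0/1", "A", "G")
#' normalize_genotype("1|1", "C", "G")$phased
#' normalize_genotype("./.", "A", "G")$missing
#' @export
normalize_genotype <- function(gt_field, ref, alts) {
  gt_field <- trimws(as.character(gt_field))
  if (is.na(gt_field) || !nzchar(gt_field)) {
    return(genotype_call(character(0), raw = gt_field))
  }
  phased <- grepl("|", gt_field, fixed = TRUE)
  toks <- strsplit(gt_field, "[/|]")[[1]]
  if (length(toks) < 1L || length(toks) > 2L ||
      !all(grepl("^(\\.|[0-9]+)$", toks))) {
    stop("malformed GT field ", sQuote(gt_field))
  }
  pool <- c(ref, alts)
  alleles <- vapply(toks, function(tk) {
    if (tk == ".") return(".")
    i <- as.integer(tk)
    if (i > length(alts)) {
      stop("GT allele index ", i, " out of range for REF=", ref,
           " ALT=", paste(alts, collapse = ","))
    }
    pool[i + 1L]
  }, character(1), USE.NAMES = FALSE)
  genotype_call(alleles, phased = phased && length(alleles) == 2L,
                raw = gt_field)
}

#' Test whether a genotype call satisfies a rule literal
#'
#' Matching is unphased and order-insensitive: the multiset of called alleles
#' must equal the multiset of literal alleles, so a call `G/A` matches the
#' literal `A/G`. Phase separators are ignored because the rule language
#' carries no phase information. A missing call never matches.
#'
#' @param call the sample's [genotype_call()].
#' @param literal a non-missing [genotype_call()] from a rule.
#' @return `TRUE` or `FALSE`.
#' @examples
#' genotype_match(genotype_call(c("G", "A")), parse_genotype_literal("A/G"))
#' @export
genotype_match <- function(call, literal) {
  stopifnot(inherits(literal, "genotype_call"))
  if (literal$missing) stop("rule literal must be non-missing")
  if (is.null(call) || !inherits(call, "genotype_call") || call$missing) {
    return(FALSE)
  }
  if (length(call$alleles) != length(literal$alleles)) return(FALSE)
  identical(sort(call$alleles), sort(literal$alleles))
}

#' Turn a variant key into a script-dialect variable name
#'
#' rsIDs (`rs` followed by digits) are already valid identifiers and pass
#' through unchanged. Positional keys (`chr1:6658743`, or `1:6658743` without
#' the prefix) have the colon replaced by an underscore; a `chr` prefix is
#' added when absent so the result never starts with a digit.
#'
#' @param key an rsID or `chrom:pos` key.
#' @return a valid identifier string.
#' @examples
#' sanitize_identifier("chr1:16949")
#' sanitize_identifier("rs553090414")
#' @export
sanitize_identifier <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  key <- trimws(key)
  if (grepl("^rs[0-9]+$", key)) return(key)
  m <- regmatches(key, regexec("^(?i)(chr)?([A-Za-z0-9]+):([0-9]+)$", key,
                               perl = TRUE))[[1]]
  if (length(m) == 0L) {
    stop("key ", sQuote(key), " is neither an rsID (rs<digits>) nor a ",
         "positional key (chr<label>:<pos>)")
  }
  paste0("chr", m[3], "_", m[4])
}

#' Recover the store-query key from a sanitized variable name
#'
#' Inverse of [sanitize_identifier()]: rs-variables pass through; positional
#' variables (`chr<label>_<pos>`) have the final underscore restored to a
#' colon.
#'
#' @param var a variable name produced by [sanitize_identifier()].
#' @return an rsID or `chr<label>:<pos>` key string.
#' @export
unsanitize_identifier <- function(var) {
  stopifnot(is.character(var), length(var) == 1L)
  if (grepl("^rs[0-9]+$", var)) return(var)
  m <- regmatches(var, regexec("^(?i)chr([A-Za-z0-9]+)_([0-9]+)$", var,
                               perl = TRUE))[[1]]
  if (length(m) == 0L) {
    stop("variable ", sQuote(var), " is not a sanitized variant key")
  }
  paste0("chr", m[2], ":", m[3])
}

# TRUE if `key` looks like either accepted key form (used by rule parsing).
is_variant_key <- function(key) {
  grepl("^rs[0-9]+$", key) ||
    grepl("^(?i)(chr)?[A-Za-z0-9]+:[0-9]+$", key, perl = TRUE)
}
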