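# End-to-end runner: load genotypes, load rules (either dialect), evaluate,
# report. The thin command-line wrappers under inst/cli/ call into here.

#' Detect the genotype input format
#'
#' Resolution is by extension first (`.vcf`/`.vcf.gz` versus
#' `.tsv`/`.csv`/`.txt`), then by content: a file whose header carries
#' `##fileformat=VCF` or a `#CHROM` line is VCF, anything else is treated as
#' a delimited genotype table.
#'
#' @param path input file path.
#' @return `"vcf"` or `"tsv"`.
#' @export
detect_input_format <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) return("vcf")
  if (grepl("\\.(tsv|csv|txt)(\\.gz)?$", path, ignore.case = TRUE)) return("tsv")
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  head <- tryCatch(readLines(con, n = 50L, warn = FALSE),
                   finally = close(con))
  if (any(grepl("^##fileformat=VCF", head)) || any(startsWith(head, "#CHROM"))) {
    "vcf"
  } else {
    "tsv"
  }
}

#' Detect the rules format
#'
#' A rules file whose first non-comment token is `if` (or a top-level
#' genotype binding followed by `if`) is script dialect; one opening with
#' `Any`, `All` or `else` is structured rule text. Anything else is an error
#' asking for an explicit format.
#'
#' @param text rules file content (string or lines).
#' @return `"script"` or `"text"`.
#' @export
detect_rules_format <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- tolower(sub("^([A-Za-z]+).*$", "\\1", ln))
    if (tok == "if" || grepl("^rs[0-9]+\\s*=[^=]", ln) ||
        grepl("^(?i)chr[A-Za-z0-9]+[_:][0-9]+\\s*=[^=]", ln, perl = TRUE)) {
      return("script")
    }
    if (tok %in% c("any", "all", "else")) return("text")
    stop("cannot determine rules format from leading token ", sQuote(tok),
         "; pass rules_format = \"script\" or \"text\" explicitly")
  }
  stop("rules file is empty")
}

#' Screen a genotype file against a rule file
#'
#' Loads a single-sample genotype store from a VCF or delimited table,
#' parses the rules (structured rule text is evaluated through the rule-set
#' evaluator; script text through the script engine — the two agree by the
#' transpilation-equivalence property), evaluates, and prints one result
#' line `risk=<float>\tcomment=<string>` to standard output (or a JSON
#' object with `--json`). Warnings about variants the rules reference but
#' the store lacks go to standard error.
#'
#' @param input path to the VCF or genotype table.
#' @param rules path to the rules file.
#' @param input_format `"auto"` (default), `"vcf"` or `"tsv"`.
#' @param rules_format `"auto"` (default), `"script"` or `"text"`.
#' @param sample sample name for multi-sample VCFs.
#' @param json emit a JSON object instead of the plain result line.
#' @param quiet suppress the stdout line (the result is still returned).
#' @return the [trait_result()], invisibly.
#' @export
run_screen <- function(input, rules,
                       input_format = c("auto", "vcf", "tsv"),
                       rules_format = c("auto", "script", "text"),
                       sample = NULL, json = FALSE, quiet = FALSE) {
  input_format <- match.arg(input_format)
  rules_format <- match.arg(rules_format)
  if (!file.exists(input)) stop("input file not found: ", input)
  if (!file.exists(rules)) stop("rules file not found: ", rules)

  if (input_format == "auto") input_format <- detect_input_format(input)
  store <- if (input_format == "vcf") read_vcf(input, sample = sample)
           else read_tsv(input)

  rule_text <- readLines(rules, warn = FALSE)
  if (rules_format == "auto") rules_format <- detect_rules_format(rule_text)
  result <- if (rules_format == "text") {
    evaluate_ruleset(parse_rule_text(rule_text), store)
  } else {
    evaluate_script(parse_script(paste(rule_text, collapse = "\n")), store)
  }

  if (!quiet) {
    if (json) {
      cat(jsonlite::toJSON(list(risk = result$risk, comment = result$comment),
                           auto_unbox = TRUE), "\n", sep = "")
    } else {
      cat(format_trait_result(result), "\n", sep = "")
    }
  }
  invisible(result)
}

#' Convert a structured rule-text file to script dialect
#'
#' File-level wrapper around [parse_rule_text()] + [ruleset_to_script()],
#' mirroring the text-to-script converter executable.
#'
#' @param input path to the rule-text file.
#' @return the script text, invisibly (it is also printed unless `quiet`).
#' @param quiet suppress printing to standard output.
#' @export
rules_to_script <- function(input, quiet = FALSE) {
  if (!file.exists(input)) stop("rules file not found: ", input)
  txt <- readLines(input, warn = FALSE)
  if (!nzchar(trimws(paste(txt, collapse = "\n")))) {
    stop("rules file is empty: ", input)
  }
  script <- ruleset_to_script(parse_rule_text(txt))
  if (!quiet) cat(script, "\n", sep = "")
  invisible(script)
}
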