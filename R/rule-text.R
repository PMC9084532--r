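# Structured-text rule language: ordered Any/All blocks of genotype
# conditions with trait labels, plus an optional else label. Rule sets are
# evaluated directly or transpiled to the script dialect; both routes give
# identical results.

#' Construct a rule block
#'
#' @param mode `"any"` (block fires when any condition matches) or `"all"`
#'   (all conditions must match).
#' @param keys character vector of variant keys (rsIDs or `chrom:pos`).
#' @param literals list of genotype literals, one per key — strings accepted
#'   by [parse_genotype_literal()] or `genotype_call` objects.
#' @param trait trait label returned when the block fires.
#' @param risk risk value returned when the block fires (default 0, as the
#'   plain text dialect carries no risk values).
#' @return an object of class `rule_block`.
#' @export
rule_block <- function(mode, keys, literals, trait, risk = 0) {
  mode <- tolower(mode)
  stopifnot(mode %in% c("any", "all"), length(keys) >= 1L,
            length(keys) == length(literals), is.character(trait))
  for (k in keys) sanitize_identifier(k)   # validates the key pattern
  literals <- lapply(literals, function(l) {
    if (inherits(l, "genotype_call")) l else parse_genotype_literal(l)
  })
  structure(list(mode = mode, keys = as.character(keys), literals = literals,
                 trait = trait, risk = as.numeric(risk)),
            class = "rule_block")
}

#' Construct a rule set
#'
#' @param blocks list of [rule_block()]s, tested in order (first match wins).
#' @param else_trait optional label returned when no block fires; required if
#'   `blocks` is empty.
#' @return an object of class `rule_set`.
#' @export
rule_set <- function(blocks = list(), else_trait = NULL) {
  stopifnot(is.list(blocks),
            all(vapply(blocks, inherits, logical(1), "rule_block")))
  if (length(blocks) == 0L && is.null(else_trait)) {
    stop("a rule set with no blocks must set else_trait")
  }
  structure(list(blocks = blocks, else_trait = else_trait),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set: ", length(x$blocks), " block(s)",
      if (!is.null(x$else_trait)) paste0(", else ", sQuote(x$else_trait)),
      ">\n", sep = "")
  invisible(x)
}

#' Parse structured rule text into a rule set
#'
#' The grammar is line-oriented. A block opens with a line `Any` or `All`
#' (case-insensitive, optional colon, attached or space-separated). Each
#' following line `KEY LITERAL` adds one condition, where `KEY` is an rsID or
#' positional key and `LITERAL` a genotype in [parse_genotype_literal()]
#' syntax. A line `== "Trait label"` closes the block; an optional trailing
#' `risk <number>` attaches a risk value (an extension — plain rule files
#' leave risk at 0). A line `else "Label"` names the no-match result. Blank
#' lines and `#` comments are ignored; straight and typographic double quotes
#' are both accepted around labels.
#'
#' @param text the rule text (single string or vector of lines).
#' @return a [rule_set()].
#' @export
parse_rule_text <- function(text) {
  stopifnot(is.character(text))
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  blocks <- list()
  else_trait <- NULL
  cur_mode <- NULL
  cur_keys <- character(0)
  cur_literals <- list()

  close_block <- function(trait, risk, lineno) {
    if (length(cur_keys) == 0L) {
      stop("rule text line ", lineno, ": block has no conditions")
    }
    blk <- rule_block(cur_mode, cur_keys, cur_literals, trait, risk)
    blocks[[length(blocks) + 1L]] <<- blk
    cur_mode <<- NULL
    cur_keys <<- character(0)
    cur_literals <<- list()
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next

    kw <- tolower(sub("^([A-Za-z]+)\\s*:?.*$", "\\1", ln))
    rest <- trimws(sub("^[A-Za-z]+\\s*:?", "", ln))

    if (kw %in% c("any", "all") && !nzchar(rest)) {
      if (!is.null(cur_mode)) {
        stop("rule text line ", i, ": block starting before line ", i,
             " was not closed with a `==` trait line")
      }
      cur_mode <- kw
      next
    }

    if (kw == "else") {
      if (!startsWith(rest, "\"") && !startsWith(rest, "“")) {
        stop("rule text line ", i, ": else label must be double-quoted")
      }
      if (!is.null(cur_mode)) {
        stop("rule text line ", i,
             ": `else` inside an unclosed block; close it with `==` first")
      }
      if (!is.null(else_trait)) stop("rule text line ", i, ": duplicate else")
      else_trait <- parse_quoted_label(rest, i)$label
      next
    }

    if (startsWith(ln, "==")) {
      if (is.null(cur_mode)) {
        stop("rule text line ", i, ": trait line outside a block")
      }
      lab <- parse_quoted_label(trimws(sub("^==", "", ln)), i)
      close_block(lab$label, lab$risk, i)
      next
    }

    # condition line: KEY LITERAL
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != 2L) {
      stop("rule text line ", i, ": expected `KEY LITERAL`, got ", sQuote(ln))
    }
    if (is.null(cur_mode)) {
      stop("rule text line ", i, ": condition outside an Any/All block")
    }
    if (!is_variant_key(fields[1])) {
      stop("rule text line ", i, ": ", sQuote(fields[1]),
           " is not an rsID or chrom:pos key")
    }
    lit <- tryCatch(parse_genotype_literal(fields[2]), error = function(e) {
      stop("rule text line ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    if (paste(fields, collapse = " ") %in%
        paste(cur_keys, vapply(cur_literals, format, character(1)))) {
      warning("rule text line ", i, ": duplicate condition in block",
              call. = FALSE)
    }
    cur_keys <- c(cur_keys, fields[1])
    cur_literals <- c(cur_literals, list(lit))
  }

  if (!is.null(cur_mode)) {
    stop("rule text ended with an unclosed block; a `==` trait line is required")
  }
  rule_set(blocks, else_trait)
}

# Parses `"Label"` with optional trailing `risk <number>`; typographic quotes
# accepted.
parse_quoted_label <- function(s, lineno) {
  m <- regmatches(s, regexec(
    "^(\"([^\"]*)\"|“([^”]*)”)\\s*(risk\\s+(-?[0-9]+(\\.[0-9]+)?))?\\s*$", s))[[1]]
  if (length(m) == 0L) {
    stop("rule text line ", lineno,
         ": expected a double-quoted label, got ", sQuote(s))
  }
  label <- if (nzchar(m[3]) || grepl("^\"", m[2])) m[3] else m[4]
  risk <- if (nzchar(m[6])) as.numeric(m[6]) else 0
  list(label = label, risk = risk)
}

#' Evaluate a rule set against a genotype store
#'
#' Blocks are tested in order; an Any block fires if any of its conditions
#' matches the stored genotype, an All block if every condition does. The
#' first firing block determines the result (its trait label and risk);
#' if no block fires the result is the else label (or `"none"`) with risk 0.
#' Absent or missing variants make their conditions false with a classed
#' warning, exactly as in [evaluate_script()].
#'
#' @param rules a [rule_set()].
#' @param store a `genotype_store`.
#' @return a [trait_result()].
#' @export
evaluate_ruleset <- function(rules, store) {
  stopifnot(inherits(rules, "rule_set"), inherits(store, "genotype_store"))
  warned <- character(0)
  test_cond <- function(key, literal) {
    call <- store_lookup(store, key)
    if (is.null(call) || call$missing) {
      if (!key %in% warned) {
        warned <<- c(warned, key)
        warning(warningCondition(
          paste0("variant ", key, " is ",
                 if (is.null(call)) "absent from the store" else "a missing call",
                 "; its condition evaluates FALSE"),
          class = "genorules_absent_variant"))
      }
      return(FALSE)
    }
    genotype_match(call, literal)
  }
  for (blk in rules$blocks) {
    hits <- mapply(test_cond, blk$keys, blk$literals)
    fired <- if (blk$mode == "any") any(hits) else all(hits)
    if (fired) return(trait_result(blk$risk, blk$trait))
  }
  trait_result(0, if (is.null(rules$else_trait)) "none" else rules$else_trait)
}

#' Transpile a rule set to script-dialect text
#'
#' Any blocks emit one `if <condition> then ... return risk, comment end`
#' unit per condition, in condition order; All blocks emit a single unit
#' whose condition chains every test with `and`. Each unit assigns the
#' block's trait label to `comment` (and its risk to `risk` when nonzero)
#' before returning, so the first matching unit determines the result. After
#' all blocks, the else label (if any) is assigned as the fall-through
#' comment. The emitted text is exactly the dialect [parse_script()] accepts,
#' and evaluating it is equivalent to [evaluate_ruleset()].
#'
#' @param rules a [rule_set()].
#' @return a single string of script text.
#' @export
ruleset_to_script <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  cond_text <- function(key, literal) {
    paste0(sanitize_identifier(key), " == \"",
           paste(literal$alleles, collapse = "/"), "\"")
  }
  unit <- function(cond, trait, risk) {
    body <- c(if (risk != 0) paste0("    risk = ", format(risk, scientific = FALSE)),
              paste0("    comment = \"", trait, "\""),
              "    return risk, comment")
    c(paste0("if ", cond, " then"), body, "end", "")
  }
  out <- character(0)
  for (blk in rules$blocks) {
    conds <- mapply(cond_text, blk$keys, blk$literals)
    if (blk$mode == "any") {
      for (cd in conds) out <- c(out, unit(cd, blk$trait, blk$risk))
    } else {
      out <- c(out, unit(paste(conds, collapse = " and "), blk$trait, blk$risk))
    }
  }
  if (!is.null(rules$else_trait)) {
    out <- c(out, paste0("comment = \"", rules$else_trait, "\""))
  }
  paste(out, collapse = "\n")
}

#' Render a rule set back to canonical rule text
#'
#' Deterministic inverse of [parse_rule_text()]: parsing the rendered text
#' reproduces the rule set.
#'
#' @param rules a [rule_set()].
#' @return a single string of rule text.
#' @export
render_ruleset <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  out <- character(0)
  for (blk in rules$blocks) {
    out <- c(out, paste0(if (blk$mode == "any") "Any:" else "All:"))
    for (i in seq_along(blk$keys)) {
      out <- c(out, paste0(blk$keys[i], " '",
                           paste(blk$literals[[i]]$alleles, collapse = "/"), "'"))
    }
    out <- c(out, paste0("== \"", blk$trait, "\"",
                         if (blk$risk != 0)
                           paste0(" risk ", format(blk$risk, scientific = FALSE))))
  }
  if (!is.null(rules$else_trait)) {
    out <- c(out, paste0("else \"", rules$else_trait, "\""))
  }
  paste(out, collapse = "\n")
}
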