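# Independent reference interpreter for the script dialect: the script text
# is mechanically rewritten into R source (if/then/end -> if (...) {...},
# and/or -> &&/||, genotype equality -> a multiset-match infix operator) and
# executed by R's own parser and evaluator. This shares no code with the
# package's tokenizer/AST interpreter, so agreement between the two routes is
# evidence about the dialect semantics, not about one implementation.
ref_eval_script <- function(text, store, key_pool) {
  t <- gsub("\\b(chr[A-Za-z0-9]+):([0-9]+)\\b", "\\1_\\2", text, perl = TRUE)
  t <- gsub("\\bif\\b", "if (", t)
  t <- gsub("\\bthen\\b", ") {", t)
  t <- gsub("\\bend\\b", "}", t)
  t <- gsub("\\band\\b", "&&", t)
  t <- gsub("\\bor\\b", "||", t)
  t <- gsub("==", "%gm%", t, fixed = TRUE)
  t <- gsub("return risk, comment",
            "return(list(risk = risk, comment = comment))", t, fixed = TRUE)

  env <- new.env(parent = globalenv())
  env$`%gm%` <- function(call, lit) {
    genotype_match(call, parse_genotype_literal(lit))
  }
  for (key in key_pool) {
    var <- if (grepl(":", key, fixed = TRUE)) sanitize_identifier(key) else key
    assign(var, store_lookup(store, key), envir = env)
  }
  src <- paste0("function() {\nrisk <- 0\ncomment <- \"none\"\n", t,
                "\nlist(risk = risk, comment = comment)\n}")
  fn <- eval(parse(text = src), envir = env)
  res <- fn()
  list(risk = as.numeric(res$risk), comment = as.character(res$comment))
}

# --- enumerated small-program grammar for the truth-table oracle -----------
# Variables v1..v3 are rs201/rs202/rs203 with fixed literals. Condition
# shapes cover single tests and every and/or combination the dialect's
# precedence can disambiguate over <=3 variables.
oracle_vars <- c("rs201", "rs202", "rs203")
oracle_literals <- c("A/A", "C/C", "G/G")

# Each shape: text builder over variables and a boolean formula over the
# per-variable match bits, written directly (not via the package AST).
oracle_shapes <- list(
  list(text = function(v) sprintf('%s == "%s"', v[1], oracle_literals[1]),
       truth = function(b) b[1]),
  list(text = function(v) sprintf('%s == "%s" and %s == "%s"',
                                  v[1], oracle_literals[1], v[2], oracle_literals[2]),
       truth = function(b) b[1] && b[2]),
  list(text = function(v) sprintf('%s == "%s" or %s == "%s"',
                                  v[1], oracle_literals[1], v[2], oracle_literals[2]),
       truth = function(b) b[1] || b[2]),
  list(text = function(v) sprintf('%s == "%s" and %s == "%s" or %s == "%s"',
                                  v[1], oracle_literals[1], v[2], oracle_literals[2],
                                  v[3], oracle_literals[3]),
       truth = function(b) (b[1] && b[2]) || b[3]),
  list(text = function(v) sprintf('%s == "%s" or %s == "%s" and %s == "%s"',
                                  v[1], oracle_literals[1], v[2], oracle_literals[2],
                                  v[3], oracle_literals[3]),
       truth = function(b) b[1] || (b[2] && b[3]))
)

# Store in which variable i matches its literal iff bits[i] is TRUE.
oracle_store <- function(bits) {
  g <- ifelse(bits, oracle_literals, "T/T")
  quick_store(rs201 = g[1], rs202 = g[2], rs203 = g[3])
}

oracle_block_text <- function(shape_id, label, risk, with_return) {
  body <- c(sprintf('  comment = "%s"', label),
            sprintf("  risk = %s", format(risk)),
            if (with_return) "  return risk, comment")
  paste(c(paste0("if ", oracle_shapes[[shape_id]]$text(oracle_vars), " then"),
          body, "end"), collapse = "\n")
}

# Expected result computed from the generating parameters alone: sequential
# blocks, a firing block overwrites risk/comment, a return halts.
oracle_expected <- function(blocks, bits) {
  risk <- 0; comment <- "none"
  for (blk in blocks) {
    if (oracle_shapes[[blk$shape]]$truth(bits)) {
      risk <- blk$risk; comment <- blk$label
      if (blk$with_return) break
    }
  }
  list(risk = risk, comment = comment)
}
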