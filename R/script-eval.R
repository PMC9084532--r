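# Evaluation of parsed rule programs against a genotype store.

#' Construct a trait evaluation result
#'
#' @param risk numeric risk score (unitless).
#' @param comment text label for the matched trait.
#' @return an object of class `trait_result`.
#' @export
trait_result <- function(risk = 0, comment = "none") {
  structure(list(risk = as.numeric(risk), comment = as.character(comment)),
            class = "trait_result")
}

#' @export
print.trait_result <- function(x, ...) {
  cat(format_trait_result(x), "\n", sep = "")
  invisible(x)
}

format_trait_result <- function(x) {
  paste0("risk=", format(x$risk, scientific = FALSE), "\tcomment=", x$comment)
}

# Translate a condition variable to its store-query key.
var_to_key <- function(var) {
  if (grepl("^(?i)chr[A-Za-z0-9]+_[0-9]+$", var, perl = TRUE)) {
    unsanitize_identifier(var)
  } else {
    var
  }
}

#' Evaluate a rule program against a genotype store
#'
#' Execution starts from the defaults `risk = 0`, `comment = "none"` and
#' proceeds statement by statement: an `if` block runs its body when its
#' condition holds, `return risk, comment` halts execution, and later
#' assignments overwrite earlier ones when no return intervenes. Condition
#' variables resolve through the store (rsID map for rs-variables, positional
#' map for chr-variables); a variant that is absent from the store, or
#' present with a missing call, makes its condition false and raises one
#' classed warning (`genorules_absent_variant`) per distinct key — evaluation
#' never aborts.
#'
#' @param program a [parse_script()] result (or script text, parsed on the
#'   fly).
#' @param store a `genotype_store`.
#' @return a [trait_result()].
#' @export
evaluate_script <- function(program, store) {
  if (is.character(program)) program <- parse_script(program)
  stopifnot(inherits(program, "rule_program"),
            inherits(store, "genotype_store"))
  state <- new.env(parent = emptyenv())
  state$risk <- 0
  state$comment <- "none"
  state$returned <- FALSE
  state$warned <- character(0)

  eval_expr <- function(e) {
    switch(e$type,
      eq = {
        key <- var_to_key(e$var)
        call <- store_lookup(store, key)
        if (is.null(call) || call$missing) {
          if (!key %in% state$warned) {
            state$warned <- c(state$warned, key)
            warning(warningCondition(
              paste0("variant ", key, " is ",
                     if (is.null(call)) "absent from the store"
                     else "a missing call",
                     "; its condition evaluates FALSE"),
              class = "genorules_absent_variant"))
          }
          FALSE
        } else {
          genotype_match(call, e$literal)
        }
      },
      and = eval_expr(e$left) && eval_expr(e$right),
      or  = eval_expr(e$left) || eval_expr(e$right),
      stop("unknown expression node ", e$type)
    )
  }

  eval_stmts <- function(stmts) {
    for (s in stmts) {
      if (state$returned) break
      switch(s$type,
        assign_risk = state$risk <- s$value,
        assign_comment = state$comment <- s$value,
        "if" = if (eval_expr(s$cond)) eval_stmts(s$body),
        "return" = state$returned <- TRUE,
        stop("unknown statement node ", s$type)
      )
    }
  }

  eval_stmts(program$statements)
  trait_result(state$risk, state$comment)
}

#' List the variant keys a program references
#'
#' Returns the condition variables translated back to store-query keys
#' (positional variables regain their colon form). Useful for targeted
#' scanning and for warning about variants missing from an input file before
#' evaluation.
#'
#' @param program a `rule_program`.
#' @return character vector of distinct keys, in first-appearance order.
#' @examples
#' p <- parse_script('if rs1 == "A/G" and chr1:16949 == "C/C" then risk = 1 end')
#' extract_variables(p)
#' @export
extract_variables <- function(program) {
  stopifnot(inherits(program, "rule_program"))
  vapply(program$referenced_vars, var_to_key, character(1), USE.NAMES = FALSE)
}
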