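---
title: "Rule-based screening of single-sample genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based screening of single-sample genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genorules)
```

## Scope and model

`genorules` evaluates *deterministic* trait rules over one individual's
genotypes. The underlying model is intentionally minimal: a trait is a
function of exact genotype matches at a small number of loci, combined with
boolean logic and first-match precedence. There is no statistics, no
weighting, no aggregation — traits that need those (polygenic scores) are
explicitly out of scope, as is phase-aware interpretation of *cis*/*trans*
configurations.

Three layers make up the package:

1. **Genotype layer.** A `genotype_store` holds one sample's calls, indexed
   both by rsID and by normalized chromosome + position. Sources are VCF 4.x
   (through `vcfR`) and four-column delimited genotype tables of the kind
   consumer platforms export.
2. **Script dialect.** A tiny imperative language — sequential statements,
   `if <condition> then ... end` blocks, `and`/`or`, assignments to the two
   result variables `risk` (numeric) and `comment` (text), and an optional
   early `return risk, comment`. The package parses it with a hand-written
   tokenizer and recursive-descent parser and evaluates the AST natively;
   the dialect is not Turing-complete (no loops, arithmetic or function
   definitions), so evaluation always terminates.
3. **Structured text.** The `Any`/`All`/`else` rule language for
   non-programmers, represented as a `rule_set` and either evaluated
   directly or transpiled to the script dialect. The transpilation is the
   bridge that keeps the two user-facing languages semantically identical.

## Genotype semantics

**Normalization.** VCF `GT` indices are resolved against REF/ALT into
allele strings, uppercased on ingest. `|` marks a phased call, `/`
unphased; the raw string is retained for reporting. Multi-base alleles
(indels) are ordinary allele strings: `0/1` with REF `T`, ALT `TGAT` gives
the call `T/TGAT`.

**Literals.** Rule files write genotypes either as a two-character
shorthand (`GG`) or a slash form (`C/G`), optionally quoted; the slash form
is mandatory when any allele is longer than one base, because `TGAT` as a
shorthand would be ambiguous. Straight and typographic quotes are both
accepted, since rule files are often written in word processors.

**Matching.** A condition is true iff the multiset of called alleles
equals the multiset of literal alleles. This is a deliberate design choice:
rule authors cannot know the arbitrary order in which a caller wrote the
two alleles of an unphased genotype, so `A/G` must match a call stored as
`G/A`. Phase separators are ignored for the same reason — the rule language
has no syntax for phase, and silently treating `|` as meaningful would make
results depend on an invisible property of the input file. A missing call
(`./.`, `--`, or a half-call like `0/.`) never matches anything.

**Absent variants.** A condition over a variant that the store lacks (or
holds only as a missing call) evaluates to false, with one classed warning
(`genorules_absent_variant`) per distinct key per evaluation; evaluation
never aborts. The alternative — erroring — would make every ruleset fragile
against the routine situation that a genotyping chip simply did not assay
one of the rule's sites.

**Hemizygous calls.** A single-allele `GT` (e.g. `1` on chrX) produces a
one-allele call rather than a fabricated diploid one. The literal grammar
cannot express one-allele genotypes, so such calls never match two-allele
literals; programmatic one-allele literals built with `genotype_call()` do
match. This is the conservative reading: inventing a second allele would
silently turn hemizygous males into homozygotes.

**Keys and identifiers.** Positional keys follow `chr1:16949`; the `chr`
prefix is optional and chromosome labels are compared after stripping it,
so rules written against `chr1:...` work with VCFs whose CHROM column says
`1`. In the script dialect a positional key becomes the identifier
`chr1_16949` (colon to underscore; a `chr` prefix is added when absent so
the identifier never starts with a digit).

## Script dialect decisions

* **Native interpreter.** The dialect is evaluated by the package's own
  AST walker rather than by embedding a general-purpose scripting engine.
  The grammar covers exactly the constructs the rule languages need (plus
  parentheses), which keeps the attack/complexity surface at zero — there
  is nothing a rule file can do except test genotypes and set the two
  result variables.
* **Precedence.** `and` binds tighter than `or`, both left-associative,
  matching the conventions of the scripting languages rule authors know.
  The test suite verifies this against R's own parser on every truth
  assignment of mixed expressions.
* **Defaults and overwriting.** Evaluation initializes `risk = 0`,
  `comment = "none"`. Without an intervening `return`, later blocks
  overwrite earlier ones — so in a two-block script where both conditions
  hold, the *second* block's values win. First-match behavior is obtained
  with explicit returns, which is exactly what the transpiler emits.
* **Ignored bindings.** Top-level statements of the form
  `rs123 = "A/G"` are accepted and ignored with a warning. Tools that
  complete a snippet into a standalone function emit such bindings as
  machine-generated scaffolding; honoring them would let a stale binding
  shadow the actual input file.
* **Returns.** `return risk, comment` is the only return form, and only as
  the last statement of a block or program; a bare `return` is a syntax
  error, as it has no defined meaning in the dialect.
* **Numbers.** Risk literals accept integer and decimal forms and are
  stored as doubles; no arithmetic exists in the dialect, so no further
  numeric tower is needed.

## Structured-text decisions

* Keywords (`Any`, `All`, `else`) are case-insensitive with an optional
  colon, attached or spaced, to tolerate hand-written files.
* Trait labels are preserved verbatim, including internal spaces
  (`"Fructose Intolerant"`). Collapsing whitespace would conflate
  user-visible labels that differ only in spacing.
* The plain dialect carries no risk values, so blocks evaluate with risk 0;
  an extension `== "Trait" risk 0.8` is parsed when present but is not part
  of the core language.
* An Any block transpiles to one `if`-unit per condition, each ending in an
  immediate return; an All block to a single unit with an `and` chain; the
  `else` label becomes a trailing default `comment` assignment. With this
  shape, transpiled evaluation is observationally identical to direct
  rule-set evaluation — the package's central invariant, enforced by a
  500-draw property test over random rule sets and stores.
* A rule set with no `else` reports `"none"` on no-match, the same default
  the script dialect initializes.
* Duplicate conditions inside a block are kept (they are harmless under
  any/all semantics) but warned about at parse time.

## Synthetic data: what it emulates and what it does not

The fixture generator (`fixture_spec()`/`generate_fixture()`) writes
matched single-sample VCF/TSV pairs — sorted records, GT-only FORMAT,
byte-deterministic output — and the random generators (`random_ruleset()`,
`random_script()`, `random_genotype_store()`) draw rule sets, scripts and
stores for property tests: 1–3 blocks or if-units, 1–3 conditions each,
diploid genotypes over A/C/G/T with ~10% indel literals, ~75% variant
presence and ~10% missing calls. These proportions were chosen as a
plausible stress mix for the matching and control-flow logic, not as a
model of any population; nothing in the evaluator is sensitive to allele
frequencies.

Passing tests on this synthetic corpus demonstrate parser/evaluator
correctness and the transpilation equivalence. They do **not** demonstrate
robustness to the full wildness of real-world VCFs — structural variants,
symbolic ALT alleles (`<DEL>`), multi-allelic records beyond two ALTs with
exotic GT ploidy — beyond the defined behavior that any unresolvable GT
becomes a missing call counted in a summary warning.

## Numerical and scale choices

Risk values pass through unchanged (no rounding); result comparison in
tests is exact on comments and to machine precision on risks. The
truth-table oracle enumerates every 1- and 2-block program over five
condition shapes (110 programs × 8 genotype assignments), small enough to
be exhaustive yet covering every precedence and control-flow combination
the dialect allows over three variables. The throughput smoke test parses a
synthetic million-record VCF — a size chosen so a full run of the suite
stays comfortable on a laptop while still exercising the vectorized bulk
GT-resolution path — and completes in well under five minutes on one CPU.

## Known limitations

* Single-sample only: multi-sample VCFs require an explicit `sample`
  argument, and there is no batch mode.
* No phasing, no genotype dosages or likelihoods, no liftover between
  genome builds; positions are 1-based VCF coordinates throughout.
* The TSV layout (rsID, chromosome, position, genotype) is an assumption
  modeled on consumer-genotype exports; files with other column orders need
  reshaping first.
* No curated library of variant–trait associations ships with the package;
  rules are entirely user-authored.
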