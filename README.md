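# genorules

Rule-based screening of single-sample genotypes for deterministic traits.

## The problem

Many phenotypes are polygenic and need aggregate statistical scoring, but a
useful subset of traits is **mono- or oligogenic**: predictable from the
presence or absence of specific genotypes at a handful of loci. Classic
examples are lactase persistence (a few *MCM6* SNPs), hereditary fructose
intolerance (homozygous *ALDOB* mutations), *APOE* risk haplotypes, and
carrier screening for recessive disease alleles in livestock sires. For
these, what a researcher actually wants is not a statistical pipeline but a
way to write down deterministic rules — *"if this site is homozygous for the
risk allele, report X"* — and run them against an individual's variant file.

`genorules` does exactly that. It loads one sample's genotypes from a VCF
(4.x, plain or bgzipped) or a delimited genotype table, evaluates
user-written trait rules against them, and reports a numeric risk score and
a text comment. It is aimed at researchers screening genomes for known
variant–trait associations and at anyone building carrier-status or
trait-prediction checks on top of consumer-style genotype exports. It is
*not* a polygenic-risk-score tool and deliberately ignores phasing.

## The two rule dialects

**Script dialect** — sequential `if` blocks over genotype equality tests,
combined with `and`/`or` (with `and` binding tighter), assigning the two
result variables and optionally returning early:

```
if rs568149713 == "A/G" and rs557514207 == "G/G" then
   comment = "highrisk"
   risk = 0.8
end
if chr1:16949 == "A/C" or rs553090414 == "C/C" then
   comment = "mediumrisk"
   risk = 0.5
end
```

Evaluation starts from `risk = 0`, `comment = "none"`; sites are referenced
by rsID or by chromosomal position (`chr1:16949`). A genotype test compares
allele multisets, so `A/G` matches a call recorded as `G/A`, and a variant
that is absent or uncalled simply makes its condition false (with a
warning).

**Structured text** — an even simpler line-oriented language using `Any`,
`All` and `else`, with first-match-wins semantics:

```
Any
rs1800546 'GG'
rs76917243 'TT'
rs78340951 'CC'
== "Fructose Intolerant"

Any:
rs1800546 'C/G'
rs76917243 'G/T'
rs78340951 C/G
== "Variant Carrier"

else "Tolerant to Fructose"
```

Structured text is transpiled to the script dialect (`ruleset_to_script()`);
direct rule-set evaluation and evaluation of the transpiled script are
verified property-tested equivalents.

## Worked example

Build a tiny single-sample VCF in which rs1800546 is a heterozygous C/G
carrier genotype, then screen it with the bundled fructose rules:

```r
library(genorules)
rules <- system.file("extdata", "fructose.txt", package = "genorules")
spec <- fixture_spec(
  data.frame(chrom = "9",
             pos   = c(101421528, 101425426, 101428946),
             rsid  = c("rs1800546", "rs76917243", "rs78340951"),
             ref   = c("C", "G", "G"), alt = c("G", "T", "C")),
  genotypes = c("0/1", "0/0", "0/0"))
fx <- generate_fixture(spec, tempdir(), "demo")
run_screen(fx$vcf, rules)
```

which prints:

```
risk=0	comment=Variant Carrier
```

`risk` is 0 because plain-text rules carry no risk values (an extension
syntax `== "Trait" risk 0.8` is available); the `comment` is the label of
the first Any block whose conditions matched — here the heterozygous-carrier
block, since the sample is C/G at rs1800546 and homozygous reference at the
other two sites. Swapping the first genotype to `1/1` (G/G) reports
`Fructose Intolerant`; all-reference genotypes fall through to
`Tolerant to Fructose`.

The same files can be run from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/genorules.R", package="genorules"))') \
    -i demo.vcf --rules fructose.txt
Rscript $(Rscript -e 'cat(system.file("cli/rules2script.R", package="genorules"))') \
    -i fructose.txt > fructose.rules
```

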