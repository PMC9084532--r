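# GenotypeStore: one sample's calls, addressable by rsID and by chrom:pos.

# Chromosome labels are compared after stripping a case-insensitive leading
# "chr", so a rule key `chr1:16949` matches CHROM values "1" and "chr1".
norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

new_genotype_store <- function(calls, sample_id = "") {
  stopifnot(data.table::is.data.table(calls))
  needed <- c("rsid", "chrom", "chrom_norm", "pos", "a1", "a2",
              "phased", "missing", "raw")
  stopifnot(all(needed %in% names(calls)))
  data.table::setindexv(calls, "rsid")
  data.table::setindexv(calls, c("chrom_norm", "pos"))
  structure(list(calls = calls, sample_id = as.character(sample_id)),
            class = "genotype_store")
}

#' Build a genotype store from a table of calls
#'
#' Convenience constructor used by tests, fixtures and scripted analyses.
#'
#' @param variants a data.frame with columns `rsid` (use `"."` or `""` for
#'   variants without an identifier), `chrom`, `pos` and `genotype`, where
#'   `genotype` is a literal accepted by [parse_genotype_literal()] or one of
#'   the missing markers `--`, `..`, `00`, `./.`, `.`.
#' @param sample_id optional sample label.
#' @return a `genotype_store`.
#' @examples
#' genotype_store(data.frame(
#'   rsid = c("rs1800546", "rs76917243"), chrom = "9",
#'   pos = c(104189856, 104198062), genotype = c("G/G", "G/T")))
#' @export
genotype_store <- function(variants, sample_id = "sample") {
  stopifnot(is.data.frame(variants),
            all(c("rsid", "chrom", "pos", "genotype") %in% names(variants)))
  n <- nrow(variants)
  a1 <- a2 <- rep(NA_character_, n)
  phased <- logical(n)
  missing <- logical(n)
  raw <- as.character(variants$genotype)
  for (i in seq_len(n)) {
    g <- trimws(raw[i])
    if (g %in% c(MISSING_GENOTYPES, "./.", ".|.", ".")) {
      missing[i] <- TRUE
    } else {
      call <- parse_genotype_literal(g)
      a1[i] <- call$alleles[1]
      a2[i] <- call$alleles[2]
      missing[i] <- call$missing
    }
  }
  rsid <- as.character(variants$rsid)
  rsid[is.na(rsid) | rsid == "."] <- ""
  calls <- data.table::data.table(
    rsid = rsid, chrom = as.character(variants$chrom),
    chrom_norm = norm_chrom(variants$chrom), pos = as.integer(variants$pos),
    a1 = a1, a2 = a2, phased = phased, missing = missing, raw = raw)
  new_genotype_store(calls, sample_id)
}

#' @export
print.genotype_store <- function(x, ...) {
  cat("<genotype_store: ", nrow(x$calls), " variant(s), sample ",
      sQuote(x$sample_id), ">\n", sep = "")
  invisible(x)
}

row_to_call <- function(row) {
  alleles <- c(row$a1, row$a2)
  alleles <- alleles[!is.na(alleles)]
  genotype_call(alleles, phased = isTRUE(row$phased), raw = row$raw)
}

#' Look up one variant's call in a store
#'
#' Accepts an rsID (`rs553090414`) or a positional key (`chr1:16949`;
#' the `chr` prefix is optional and stripped on both sides of the
#' comparison). An absent key returns `NULL`, never an error.
#'
#' @param store a `genotype_store`.
#' @param key rsID or `chrom:pos` key.
#' @return a [genotype_call()], or `NULL` if the variant is absent.
#' @export
store_lookup <- function(store, key) {
  stopifnot(inherits(store, "genotype_store"))
  key <- trimws(key)
  calls <- store$calls
  if (grepl(":", key, fixed = TRUE)) {
    if (!grepl("^(?i)(chr)?[A-Za-z0-9]+:[0-9]+$", key, perl = TRUE)) {
      stop("malformed positional key ", sQuote(key),
           " (expected chr<label>:<pos>)")
    }
    bits <- strsplit(key, ":", fixed = TRUE)[[1]]
    hit <- calls[list(norm_chrom(bits[1]), as.integer(bits[2])),
                 on = c("chrom_norm", "pos"), nomatch = NULL]
  } else {
    hit <- calls[list(key), on = "rsid", nomatch = NULL]
  }
  if (nrow(hit) == 0L) return(NULL)
  row_to_call(hit[1L])
}

#' Number of variants held in a store
#' @param store a `genotype_store`.
#' @return integer count of stored variant records.
#' @export
store_size <- function(store) nrow(store$calls)

#' Read a single-sample VCF into a genotype store
#'
#' Parses a VCF 4.x file (plain or bgzipped) and extracts the GT field of one
#' sample. Every record with a parseable GT becomes one store entry,
#' addressable by position and — when the ID column carries an identifier —
#' by rsID. Records whose GT cannot be resolved (malformed entries, allele
#' indices beyond the ALT list, symbolic alleles) are stored as missing calls
#' and reported in a single summary warning.
#'
#' @param path path to the VCF file.
#' @param sample sample name to extract; may be omitted only for
#'   single-sample files. Multi-sample files without an explicit `sample`
#'   raise an error naming the available samples.
#' @return a `genotype_store`.
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  head <- vcf_sniff(path)
  if (!head$has_data) {
    # header-only file: a legitimate (empty) store
    samples <- head$samples
    if (length(samples) == 0L) stop("VCF ", path, " contains no sample columns")
    if (is.null(sample)) {
      if (length(samples) > 1L) {
        stop("VCF ", path, " has ", length(samples), " samples (",
             paste(samples, collapse = ", "), "); pass `sample` to choose one")
      }
      sample <- samples[1L]
    } else if (!sample %in% samples) {
      stop("sample ", sQuote(sample), " not in VCF ", path,
           " (available: ", paste(samples, collapse = ", "), ")")
    }
    calls <- data.table::data.table(
      rsid = character(0), chrom = character(0), chrom_norm = character(0),
      pos = integer(0), a1 = character(0), a2 = character(0),
      phased = logical(0), missing = logical(0), raw = character(0))
    return(new_genotype_store(calls, sample))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)
  samples <- samples[samples != "FORMAT"]
  if (length(samples) == 0L) stop("VCF ", path, " contains no sample columns")
  if (is.null(sample)) {
    if (length(samples) > 1L) {
      stop("VCF ", path, " has ", length(samples), " samples (",
           paste(samples, collapse = ", "),
           "); pass `sample` to choose one")
    }
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    stop("sample ", sQuote(sample), " not in VCF ", path,
         " (available: ", paste(samples, collapse = ", "), ")")
  }

  fix <- vcf@fix
  n <- nrow(fix)
  if (n == 0L) {
    calls <- data.table::data.table(
      rsid = character(0), chrom = character(0), chrom_norm = character(0),
      pos = integer(0), a1 = character(0), a2 = character(0),
      phased = logical(0), missing = logical(0), raw = character(0))
    return(new_genotype_store(calls, sample))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  parsed <- bulk_normalize_gt(gt, fix[, "REF"], fix[, "ALT"])
  if (parsed$n_bad > 0L) {
    warning(parsed$n_bad, " of ", n, " GT entries in ", path,
            " could not be parsed and were stored as missing calls",
            call. = FALSE)
  }
  rsid <- fix[, "ID"]
  rsid[is.na(rsid) | rsid == "."] <- ""
  calls <- data.table::data.table(
    rsid = rsid, chrom = fix[, "CHROM"], chrom_norm = norm_chrom(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    a1 = parsed$a1, a2 = parsed$a2, phased = parsed$phased,
    missing = parsed$missing, raw = parsed$raw)
  new_genotype_store(calls, sample)
}

# Reads just enough of a VCF to learn the sample names and whether any data
# line exists (vcfR cannot load a header-only file).
vcf_sniff <- function(path) {
  con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  samples <- character(0)
  repeat {
    chunk <- readLines(con, n = 1000L, warn = FALSE)
    if (length(chunk) == 0L) return(list(has_data = FALSE, samples = samples))
    header <- startsWith(chunk, "#")
    chrom_line <- chunk[startsWith(chunk, "#CHROM")]
    if (length(chrom_line)) {
      cols <- strsplit(chrom_line[1], "\t", fixed = TRUE)[[1]]
      if (length(cols) > 9L) samples <- cols[-(1:9)]
    }
    if (any(!header)) return(list(has_data = TRUE, samples = samples))
  }
}

# Vectorized GT resolution for whole files. Semantics match
# normalize_genotype() except that irrecoverable entries (bad tokens,
# out-of-range indices, non-nucleotide alleles) become missing calls counted
# in n_bad instead of errors, so one corrupt line never aborts a scan.
bulk_normalize_gt <- function(gt, ref, alt) {
  n <- length(gt)
  raw <- gt
  gt <- as.character(gt)
  gt[is.na(gt) | !nzchar(gt)] <- "."
  raw[is.na(raw)] <- "."
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- data.table::tstrsplit(gt, "[/|]")
  t1 <- parts[[1]]
  t2 <- if (length(parts) >= 2L) parts[[2]] else rep(NA_character_, n)
  extra <- if (length(parts) >= 3L) !is.na(parts[[3]]) else rep(FALSE, n)

  tok_ok <- function(tk) is.na(tk) | grepl("^(\\.|[0-9]+)$", tk)
  bad <- extra | !tok_ok(t1) | !tok_ok(t2) | is.na(t1)

  alt[is.na(alt)] <- ""
  alt_parts <- data.table::tstrsplit(alt, ",", fixed = TRUE)
  amat <- cbind(toupper(ref), do.call(cbind, lapply(alt_parts, toupper)))
  nalt <- lengths(strsplit(alt, ",", fixed = TRUE))

  resolve <- function(tok) {
    out <- rep(NA_character_, n)
    dot <- !is.na(tok) & tok == "."
    out[dot] <- "."
    num <- !is.na(tok) & !dot & !bad
    idx <- suppressWarnings(as.integer(tok[num]))
    rows <- which(num)
    oor <- idx > nalt[rows]
    if (any(oor)) {
      bad[rows[oor]] <<- TRUE
      num[rows[oor]] <- FALSE
      rows <- rows[!oor]; idx <- idx[!oor]
    }
    out[rows] <- amat[cbind(rows, idx + 1L)]
    out
  }
  a1 <- resolve(t1)
  a2 <- resolve(t2)

  bad_allele <- function(a) !is.na(a) & a != "." & !grepl("^[ACGTN]+$", a)
  bad <- bad | bad_allele(a1) | bad_allele(a2)
  a1[bad] <- NA_character_
  a2[bad] <- NA_character_
  missing <- bad | is.na(a1) | a1 == "." | (!is.na(a2) & a2 == ".")
  phased <- phased & !missing & !is.na(a2)
  list(a1 = a1, a2 = a2, phased = phased, missing = missing,
       raw = as.character(raw), n_bad = sum(bad))
}

#' Read a delimited genotype table into a genotype store
#'
#' Expects one row per variant with at least four whitespace- or
#' comma-delimited fields: rsID, chromosome, position and genotype (the
#' layout common to consumer genotype exports). Lines starting with `#` are
#' comments. Genotypes use the literal syntax of [parse_genotype_literal()];
#' the tokens `--`, `..` and `00` mark missing calls. Malformed rows are
#' skipped with a warning naming the row; a file with no valid rows is an
#' error.
#'
#' @param path path to the table.
#' @param sample_id optional sample label for the store.
#' @return a `genotype_store`.
#' @export
read_tsv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt|csv)(\\.gz)?$", "", basename(path))
  }
  rows <- list()
  bad_rows <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "[ \t,]+")[[1]]
    ok <- length(fields) >= 4L && grepl("^[0-9]+$", fields[3])
    if (ok) {
      g <- fields[4]
      if (g %in% c(MISSING_GENOTYPES, "./.", ".|.", ".")) {
        rows[[length(rows) + 1L]] <- list(
          rsid = fields[1], chrom = fields[2], pos = as.integer(fields[3]),
          a1 = NA_character_, a2 = NA_character_, missing = TRUE, raw = g)
      } else {
        call <- tryCatch(parse_genotype_literal(g), error = function(e) NULL)
        if (is.null(call)) {
          ok <- FALSE
        } else {
          rows[[length(rows) + 1L]] <- list(
            rsid = fields[1], chrom = fields[2], pos = as.integer(fields[3]),
            a1 = call$alleles[1], a2 = call$alleles[2],
            missing = FALSE, raw = g)
        }
      }
    }
    if (!ok) bad_rows <- c(bad_rows, i)
  }
  if (length(bad_rows)) {
    warning("skipped ", length(bad_rows), " malformed row(s) in ", path,
            " (line ", paste(bad_rows, collapse = ", "), ")", call. = FALSE)
  }
  if (length(rows) == 0L) stop("no valid genotype rows in ", path)
  dt <- data.table::rbindlist(rows)
  dt[, `:=`(rsid = ifelse(is.na(rsid) | rsid == ".", "", rsid),
            chrom_norm = norm_chrom(chrom), phased = FALSE)]
  data.table::setcolorder(dt, c("rsid", "chrom", "chrom_norm", "pos",
                                "a1", "a2", "phased", "missing", "raw"))
  new_genotype_store(dt, sample_id)
}

#' Write a genotype store as a delimited genotype table
#'
#' Emits the four-column layout read by [read_tsv()] (rsID, chromosome,
#' position, genotype), tab-delimited, with missing calls written as `--`.
#'
#' @param store a `genotype_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(store, path) {
  stopifnot(inherits(store, "genotype_store"))
  calls <- store$calls
  geno <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i]
    geno[i] <- if (row$missing) "--" else {
      paste(c(row$a1, row$a2)[!is.na(c(row$a1, row$a2))], collapse = "/")
    }
  }
  id <- ifelse(nzchar(calls$rsid), calls$rsid, ".")
  writeLines(c("# rsid\tchrom\tpos\tgenotype",
               paste(id, calls$chrom, calls$pos, geno, sep = "\t")), path)
  invisible(path)
}
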