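VAR_CLASSES <- c("missense", "nonsense", "splice", "synonymous", "intronic",
                 "intergenic", "frameshift", "coding-indel")
PREDICTIONS <- c("benign", "possibly_damaging", "probably_damaging",
                 "unknown", "not_predicted")

#' Variant identity key
#'
#' Variants are matched across samples on (chrom, pos, ref, alt); zygosity
#' is deliberately not part of the identity.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

call_columns <- function() {
  c("chrom", "pos", "ref", "alt", "zygosity", "depth", "qual", "var_class",
    "db", "db_freq", "prediction", "gene")
}

#' Per-sample exome container
#'
#' Bundles the variant calls of one individual with its identity and
#' disease status. Calls live in a data frame with the columns returned by
#' the internal schema (chrom, pos, ref, alt, zygosity, depth, qual,
#' var_class, db, db_freq, prediction, gene); missing optional columns are
#' filled with NA. Invariants checked: `pos >= 1`, `depth >= 0`,
#' `qual >= 0`, `db_freq` in [0, 1], and uniqueness of the
#' (chrom, pos, ref, alt) identity key within the sample.
#'
#' @param sample_id Sample identifier (unique within a cohort).
#' @param status `"affected"` or `"unaffected"`.
#' @param calls Data frame of calls; mandatory columns `chrom`, `pos`,
#'   `ref`, `alt`, `zygosity`.
#' @param build Genome build label, carried as opaque metadata.
#' @return Object of class `sample_exome` with an attached (initially
#'   empty) filter trace.
#' @export
sample_exome <- function(sample_id, status = c("affected", "unaffected"),
                         calls, build = "hg18") {
  status <- match.arg(status)
  stopifnot(is.data.frame(calls))
  mandatory <- c("chrom", "pos", "ref", "alt", "zygosity")
  miss <- setdiff(mandatory, names(calls))
  if (length(miss))
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (col in setdiff(call_columns(), names(calls)))
    calls[[col]] <- rep(NA, nrow(calls))
  calls <- calls[, call_columns()]
  calls$pos <- as.numeric(calls$pos)
  if (nrow(calls)) {
    if (any(calls$pos < 1, na.rm = TRUE)) stop("pos must be >= 1")
    if (any(calls$depth < 0, na.rm = TRUE)) stop("depth must be >= 0")
    if (any(calls$qual < 0, na.rm = TRUE)) stop("qual must be >= 0")
    if (any(calls$db_freq < 0 | calls$db_freq > 1, na.rm = TRUE))
      stop("db_freq must be in [0, 1]")
    bad_zyg <- !calls$zygosity %in% c("het", "hom")
    if (any(bad_zyg))
      stop("record-level error: unknown zygosity code in row(s) ",
           paste(which(bad_zyg), collapse = ", "))
    keys <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    if (anyDuplicated(keys))
      stop("duplicate variant identity key within sample: ",
           keys[duplicated(keys)][1])
  }
  structure(list(sample_id = sample_id, status = status, calls = calls,
                 build = build,
                 trace = data.frame(stage = character(0),
                                    count = integer(0))),
            class = "sample_exome")
}

#' @export
print.sample_exome <- function(x, ...) {
  cat("<sample_exome> ", x$sample_id, " (", x$status, ", ", x$build, "): ",
      nrow(x$calls), " calls\n", sep = "")
  if (nrow(x$trace)) {
    cat("  trace:\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

exome_keys <- function(exome) {
  with(exome$calls, variant_key(chrom, pos, ref, alt))
}

#' Read a variant table
#'
#' Two dialects are supported. `"tsv"`: a header line naming at least
#' `chrom`, `pos`, `ref`, `alt`, `zygosity` plus any of the optional call
#' columns; comment lines starting with `#` are ignored; malformed rows
#' (non-numeric position, unknown zygosity code) are reported with their
#' file line numbers. `"vcf_subset"`: a minimal single-sample VCF reading
#' only CHROM/POS/REF/ALT/QUAL and FORMAT fields GT (zygosity) and DP
#' (depth); all other fields are ignored.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf_subset"`.
#' @param sample_id,status,build Passed to [sample_exome()]; `sample_id`
#'   defaults to the file name (or the VCF sample column name).
#' @return A [sample_exome()].
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_subset"),
                               sample_id = NULL,
                               status = "affected", build = "hg18") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_variant_tsv(path, sample_id, status, build)
  else read_variant_vcf(path, sample_id, status, build)
}

read_variant_tsv <- function(path, sample_id, status, build) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("format error: no header line in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  mandatory <- c("chrom", "pos", "ref", "alt", "zygosity")
  miss <- setdiff(mandatory, header)
  if (length(miss))
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (length(lines) == 1L) {
    calls <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(header)), header))
    calls$pos <- numeric(0)
    return(sample_exome(sample_id %||% basename(path), status, calls,
                        build))
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad_shape <- nf != length(header)
  pos_raw <- vapply(fields, function(f)
    if (length(f) >= match("pos", header)) f[match("pos", header)]
    else NA_character_, character(1))
  bad_pos <- is.na(suppressWarnings(as.numeric(pos_raw)))
  zyg_raw <- vapply(fields, function(f)
    if (length(f) >= match("zygosity", header)) f[match("zygosity", header)]
    else NA_character_, character(1))
  bad_zyg <- !zyg_raw %in% c("het", "hom")
  bad <- bad_shape | bad_pos | bad_zyg
  if (any(bad))
    stop("malformed row(s) at line ",
         paste(line_no[-1][bad], collapse = ", "), " of ", path)
  calls <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(calls) <- header
  calls[calls == "NA"] <- NA
  calls$pos <- as.numeric(calls$pos)
  for (col in intersect(c("depth", "qual", "db_freq", "gerp"),
                        names(calls)))
    calls[[col]] <- suppressWarnings(as.numeric(calls[[col]]))
  if ("db" %in% names(calls)) calls$db <- as.logical(calls$db)
  sample_exome(sample_id %||% basename(path), status, calls, build)
}

read_variant_vcf <- function(path, sample_id, status, build) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1L)
    stop("format error: no #CHROM header line in ", path)
  header <- strsplit(sub("^#", "", lines[hdr_i]), "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L)
    stop("format error: vcf_subset requires a FORMAT and one sample column")
  body <- lines[-seq_len(hdr_i)]
  body <- body[!grepl("^#", body)]
  parse_row <- function(line, ln) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) stop("malformed row at line ", ln, " of ", path)
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    gt <- smp[match("GT", fmt)]
    dp <- suppressWarnings(as.numeric(smp[match("DP", fmt)]))
    alleles <- strsplit(gt, "[/|]")[[1]]
    zyg <- if (all(alleles == "1")) "hom"
           else if ("1" %in% alleles) "het"
           else NA_character_
    if (is.na(zyg))
      stop("record-level error: unsupported genotype '", gt,
           "' at line ", ln)
    data.frame(chrom = f[1], pos = as.numeric(f[2]), ref = f[4],
               alt = f[5], zygosity = zyg, depth = dp,
               qual = suppressWarnings(as.numeric(f[6])),
               stringsAsFactors = FALSE)
  }
  calls <- if (length(body))
    do.call(rbind, Map(parse_row, body, hdr_i + seq_along(body)))
  else data.frame(chrom = character(0), pos = numeric(0),
                  ref = character(0), alt = character(0),
                  zygosity = character(0))
  sid <- sample_id %||% header[10]
  sample_exome(sid, status, calls, build)
}

#' Write a variant table (TSV)
#'
#' Writes the call set of a [sample_exome()] in the TSV dialect read back
#' by [read_variant_table()]; the round trip reproduces the call set.
#'
#' @param exome A `sample_exome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(exome, path) {
  stopifnot(inherits(exome, "sample_exome"))
  utils::write.table(exome$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Bundled attrition counts of the discovery family
#'
#' The per-sample stage counts of the published filtering cascade (three
#' exomes: two affected relatives and an unaffected sibling control).
#' Joint-stage counts (shared, unique to cases, after panel subtraction)
#' appear on the first row only.
#'
#' @return Data frame of counts.
#' @export
ancl_attrition_counts <- function() {
  path <- system.file("extdata", "table1_attrition.tsv",
                      package = "anclxome", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Bundled candidate-variant table
#'
#' The 22 variants (19 single-nucleotide substitutions, 3 indels) that
#' survived the published cascade, with gene, protein change, functional
#' class, pathogenicity prediction and extended-family segregation flag.
#'
#' @return Data frame with one row per candidate, including a logical
#'   `segregation_flag` and the `key` identity column.
#' @export
ancl_candidates <- function() {
  path <- system.file("extdata", "table2_candidates.tsv",
                      package = "anclxome", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$segregation_flag <- tab$segregates == "yes"
  tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  tab
}

#' Bundled population-control screen counts
#'
#' Heterozygous-carrier counts among 1,600 ethnically matched controls for
#' the three perfectly segregating candidates.
#'
#' @return Data frame with `gene`, `n_controls`, `het_carriers`,
#'   `hom_carriers`.
#' @export
ancl_control_screen <- function() {
  path <- system.file("extdata", "control_screen_counts.tsv",
                      package = "anclxome", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
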