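GENO_CODES <- c("0/0", "0/1", "1/1")

#' Genotype panel
#'
#' Long-format genotypes of pedigree members at candidate variants:
#' one row per (sample, variant) with genotype `"0/0"`, `"0/1"`, `"1/1"`
#' or `NA` (missing).
#'
#' @param df Data frame with columns `sample_id`, `key`, `genotype`.
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("sample_id", "key", "genotype") %in% names(df)))
  bad <- !is.na(df$genotype) & !df$genotype %in% GENO_CODES
  if (any(bad))
    stop("unknown genotype code(s): ",
         paste(unique(df$genotype[bad]), collapse = ", "))
  structure(list(genotypes = df[, c("sample_id", "key", "genotype")]),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  g <- x$genotypes
  cat("<genotype_panel> ", length(unique(g$key)), " variants x ",
      length(unique(g$sample_id)), " samples\n", sep = "")
  invisible(x)
}

#' Perfect-segregation test
#'
#' A variant segregates perfectly under a fully penetrant dominant model
#' iff every typed affected member carries at least one alternate allele
#' and no typed unaffected member carries any. The outcome is three-valued:
#' `"no"` as soon as a typed genotype contradicts the model (an unaffected
#' carrier or an affected non-carrier), `"unknown"` when no contradiction
#' exists but a typed member's genotype is missing, otherwise `"yes"`.
#' Members with unknown disease status are ignored.
#'
#' @param variant Variant identity key.
#' @param panel A [genotype_panel()].
#' @param ped A [pedigree()] supplying member statuses.
#' @return `"yes"`, `"no"` or `"unknown"`.
#' @export
segregates <- function(variant, panel, ped) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(ped, "pedigree"))
  g <- panel$genotypes[panel$genotypes$key == variant, ]
  if (!nrow(g)) stop("variant not present in genotype panel: ", variant)
  status <- ped$members$status[match(g$sample_id, ped$members$id)]
  if (anyNA(status))
    stop("genotyped sample(s) absent from pedigree: ",
         paste(g$sample_id[is.na(status)], collapse = ", "))
  typed <- status != "unknown"
  g <- g[typed, ]; status <- status[typed]
  carrier <- g$genotype %in% c("0/1", "1/1")
  noncarrier <- g$genotype %in% "0/0"
  if (any(status == "unaffected" & carrier)) return("no")
  if (any(status == "affected" & noncarrier)) return("no")
  if (anyNA(g$genotype)) return("unknown")
  if (all(carrier[status == "affected"]) &&
      any(status == "affected")) "yes" else "unknown"
}

#' Population-control screen of one variant
#'
#' Counts carriers among population controls and computes the carrier
#' frequency (carriers / individuals) and the allele frequency
#' ((het + 2 x hom) / (2 x individuals)). Supply either a genotype vector
#' or carrier counts.
#'
#' @param variant Variant identity key (annotation only).
#' @param genotypes Optional character vector of control genotypes
#'   (`"0/0"`, `"0/1"`, `"1/1"`; `NA` dropped).
#' @param n_het,n_hom Carrier counts, used when `genotypes` is `NULL`.
#' @param n_controls Number of control individuals; defaults to
#'   `length(genotypes)`.
#' @return Data frame row: `key`, `n_controls`, `carrier_count`,
#'   `carrier_frequency`, `allele_frequency`.
#' @examples
#' control_screen("x", n_het = 16, n_controls = 1600)
#' # carrier frequency 0.01, allele frequency 0.005
#' @export
control_screen <- function(variant = NA_character_, genotypes = NULL,
                           n_het = NULL, n_hom = 0L, n_controls = NULL) {
  if (!is.null(genotypes)) {
    genotypes <- genotypes[!is.na(genotypes)]
    bad <- !genotypes %in% GENO_CODES
    if (any(bad)) stop("unknown genotype code(s): ",
                       paste(unique(genotypes[bad]), collapse = ", "))
    n_controls <- n_controls %||% length(genotypes)
    n_het <- sum(genotypes == "0/1")
    n_hom <- sum(genotypes == "1/1")
  } else {
    if (is.null(n_het) || is.null(n_controls))
      stop("supply either genotypes or n_het and n_controls")
  }
  carriers <- n_het + n_hom
  stopifnot(carriers <= n_controls)
  data.frame(key = variant, n_controls = n_controls,
             carrier_count = carriers,
             carrier_frequency = carriers / n_controls,
             allele_frequency = (n_het + 2 * n_hom) / (2 * n_controls),
             stringsAsFactors = FALSE)
}

chrom_order <- function(chrom) {
  m <- suppressWarnings(as.numeric(chrom))
  m[chrom == "X"] <- 23
  m[chrom == "Y"] <- 24
  m[chrom %in% c("MT", "M")] <- 25
  m
}

#' Shortlist surviving candidates
#'
#' Keeps candidates that segregate perfectly and, when a control-screen
#' result is available, are absent from population controls (any carrier
#' excludes a fully penetrant dominant candidate; unscreened candidates
#' are retained). Survivors are ranked by damaging prediction
#' (probably > possibly > unknown > benign), then GERP descending (missing
#' last), with a deterministic (chrom, pos) tie-break.
#'
#' @param candidates Data frame with columns `chrom`, `pos`, `gene` and a
#'   segregation call: either `segregates` (`"yes"`/`"no"`/`"unknown"`) or
#'   logical `segregation_flag`. Optional `prediction` and `gerp`.
#' @param screen Optional data frame of [control_screen()] rows, joined by
#'   `key` if both sides carry it, else by `gene`.
#' @return The ranked data frame of surviving candidates (zero rows if
#'   none survive), with a `carrier_count` column when screened.
#' @export
shortlist <- function(candidates, screen = NULL) {
  stopifnot(is.data.frame(candidates))
  seg <- if ("segregates" %in% names(candidates)) {
    candidates$segregates == "yes"
  } else if ("segregation_flag" %in% names(candidates)) {
    candidates$segregation_flag
  } else stop("candidates need a 'segregates' or 'segregation_flag' column")
  out <- candidates[which(seg), , drop = FALSE]
  if (!is.null(screen) && nrow(out)) {
    by <- if ("gene" %in% names(screen) && "gene" %in% names(out)) "gene"
          else "key"
    cc <- screen$carrier_count[match(out[[by]], screen[[by]])]
    out$carrier_count <- cc
    out <- out[is.na(cc) | cc == 0L, , drop = FALSE]
  }
  if (!nrow(out)) { rownames(out) <- NULL; return(out) }
  sev <- c(benign = 0, not_predicted = 1, unknown = 1,
           possibly_damaging = 2, probably_damaging = 3)
  pr <- if ("prediction" %in% names(out))
    unname(sev[out$prediction]) else rep(0, nrow(out))
  pr[is.na(pr)] <- 0
  ge <- if ("gerp" %in% names(out)) out$gerp else rep(NA_real_, nrow(out))
  ge_filled <- ifelse(is.na(ge), -Inf, ge)
  ord <- order(-pr, -ge_filled, chrom_order(out$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
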