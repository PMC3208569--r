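#' Cascade configuration
#'
#' Thresholds of the filtering cascade. Defaults follow the published
#' pipeline: known variants are discarded when their database population
#' frequency exceeds 5% for heterozygous calls or 30% for homozygous
#' calls (strictly greater than; equality keeps), calls need sequencing
#' depth >= 5 and quality >= 30, and only functionally significant classes
#' are retained.
#'
#' @param het_freq_max Removal threshold for heterozygous calls.
#' @param hom_freq_max Removal threshold for homozygous calls.
#' @param min_depth Minimum read depth.
#' @param min_qual Minimum call quality.
#' @param functional_classes Variant classes kept by [filter_functional()].
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(het_freq_max = 0.05, hom_freq_max = 0.30,
                           min_depth = 5L, min_qual = 30,
                           functional_classes = c("missense", "nonsense",
                                                  "splice", "coding-indel",
                                                  "frameshift")) {
  stopifnot(het_freq_max >= 0, het_freq_max <= hom_freq_max,
            hom_freq_max <= 1, min_depth >= 1)
  structure(list(het_freq_max = het_freq_max, hom_freq_max = hom_freq_max,
                 min_depth = min_depth, min_qual = min_qual,
                 functional_classes = functional_classes),
            class = "cascade_config")
}

trace_append <- function(exome, stage, count) {
  prev <- exome$trace$count
  if (length(prev) && count > prev[length(prev)])
    stop("filter trace must be non-increasing (stage '", stage, "')")
  exome$trace <- rbind(exome$trace,
                       data.frame(stage = stage, count = as.integer(count)))
  exome
}

subset_calls <- function(exome, keep, stage) {
  exome$calls <- exome$calls[keep, , drop = FALSE]
  rownames(exome$calls) <- NULL
  trace_append(exome, stage, nrow(exome$calls))
}

#' Depth and quality filter
#'
#' Retains calls with `depth >= min_depth` and `qual >= min_qual`. Calls
#' with missing depth or quality are kept (the metrics cannot be assessed)
#' and a warning is emitted.
#'
#' @param exome A [sample_exome()].
#' @param cfg A [cascade_config()].
#' @return The filtered `sample_exome`, with a `quality` stage appended to
#'   its trace.
#' @export
filter_quality <- function(exome, cfg = cascade_config()) {
  stopifnot(inherits(exome, "sample_exome"))
  d <- exome$calls$depth
  q <- exome$calls$qual
  if (anyNA(d) || anyNA(q))
    warning("calls with missing depth/qual kept (sample ",
            exome$sample_id, ")")
  keep <- (is.na(d) | d >= cfg$min_depth) & (is.na(q) | q >= cfg$min_qual)
  subset_calls(exome, keep, "quality")
}

#' Remove known common variants
#'
#' Discards calls present in the population database at a frequency
#' strictly greater than the zygosity-specific threshold (5% het / 30%
#' hom by default). Calls absent from the database always survive.
#'
#' @param exome A [sample_exome()].
#' @param db Optional data frame with columns `key` and `freq` mapping
#'   variant identity keys to population frequencies. When `NULL`, the
#'   per-call `db`/`db_freq` columns are used instead.
#' @param cfg A [cascade_config()].
#' @return The filtered `sample_exome` (`known_common` trace stage).
#' @export
filter_known_common <- function(exome, db = NULL, cfg = cascade_config()) {
  stopifnot(inherits(exome, "sample_exome"))
  calls <- exome$calls
  if (!is.null(db)) {
    stopifnot(all(c("key", "freq") %in% names(db)))
    freq <- db$freq[match(exome_keys(exome), db$key)]
  } else {
    in_db <- !is.na(calls$db) & calls$db
    freq <- ifelse(in_db, calls$db_freq, NA_real_)
    if (any(in_db & is.na(calls$db_freq)))
      message("db-flagged call(s) without frequency treated as novel")
  }
  thr <- ifelse(calls$zygosity == "hom", cfg$hom_freq_max,
                cfg$het_freq_max)
  remove <- !is.na(freq) & freq > thr
  subset_calls(exome, !remove, "known_common")
}

#' Keep functionally significant classes
#'
#' Retains only the configured functional classes (missense, nonsense,
#' splice-site and coding indels by default); synonymous, intronic and
#' intergenic calls are removed. Calls with missing class are removed.
#'
#' @inheritParams filter_quality
#' @return The filtered `sample_exome` (`functional` trace stage).
#' @export
filter_functional <- function(exome, cfg = cascade_config()) {
  stopifnot(inherits(exome, "sample_exome"))
  keep <- !is.na(exome$calls$var_class) &
    exome$calls$var_class %in% cfg$functional_classes
  subset_calls(exome, keep, "functional")
}

#' Variant keys shared by all affected exomes
#'
#' @param exomes List of >= 2 affected [sample_exome()] objects.
#' @return Character vector: the intersection of identity keys.
#' @export
shared_in_affecteds <- function(exomes) {
  stopifnot(is.list(exomes), length(exomes) >= 2L)
  Reduce(intersect, lapply(exomes, exome_keys))
}

#' Subtract control and panel carriers
#'
#' Removes from `shared` every key carried by any of the control or panel
#' samples. Subtractions commute, so control-then-panel equals
#' panel-then-control.
#'
#' @param shared Character vector of variant keys.
#' @param controls List of [sample_exome()] objects (may be empty).
#' @return The surviving keys.
#' @export
subtract_samples <- function(shared, controls) {
  if (!length(controls)) return(shared)
  carried <- unique(unlist(lapply(controls, exome_keys)))
  setdiff(shared, carried)
}

#' Percent-remaining formatter
#'
#' Formats attrition percentages in the mixed precision used by published
#' attrition tables: values below 1% with two decimals, values from 1%
#' with one decimal, and 100 printed without decimals.
#'
#' @param p Numeric percentages.
#' @return Character vector.
#' @export
format_percent_remaining <- function(p) {
  vapply(p, function(x) {
    if (x >= 100) "100"
    else if (x >= 1) sprintf("%.1f", x)
    else sprintf("%.2f", x)
  }, character(1))
}

#' Attrition table
#'
#' Per-stage percent remaining relative to a fixed denominator (the total
#' coding substitution count). Raw fractions are exposed alongside the
#' printed-precision formatting so tests can pin the formatter while
#' downstream arithmetic keeps full precision.
#'
#' @param counts Named integer vector or a trace data frame (`stage`,
#'   `count`) of surviving counts in cascade order.
#' @param denominator Positive total used as 100%.
#' @return Data frame with `stage`, `count`, `percent_raw`,
#'   `percent_printed`.
#' @export
attrition_table <- function(counts, denominator) {
  stopifnot(denominator > 0)
  if (is.data.frame(counts)) {
    stages <- counts$stage
    counts <- counts$count
  } else {
    stages <- names(counts) %||% paste0("stage", seq_along(counts))
  }
  p <- 100 * counts / denominator
  data.frame(stage = stages, count = counts, percent_raw = p,
             percent_printed = format_percent_remaining(p),
             stringsAsFactors = FALSE)
}

#' Validation false-discovery rate
#'
#' Fraction of genotype-validated candidate calls that failed validation.
#'
#' @param n_tested Number of candidates re-genotyped (> 0).
#' @param n_failed Number failing validation.
#' @return `n_failed / n_tested`.
#' @examples
#' validation_fdr(22, 1)  # 0.045 to three decimals
#' @export
validation_fdr <- function(n_tested, n_failed) {
  stopifnot(n_tested > 0, n_failed >= 0, n_failed <= n_tested)
  n_failed / n_tested
}

#' Run the full filtering cascade on a sequenced trio (or larger cohort)
#'
#' Applies, in the published order: depth/quality filtering (the
#' "standard parameters" entering the total count), functional-class
#' restriction, known-common-variant removal, intersection across the
#' affected samples, subtraction of control samples, and optional
#' subtraction of a panel of unrelated exomes. Per-sample stages are
#' averaged across samples for the attrition table, whose denominator is
#' the mean post-quality total.
#'
#' @param affected List of affected [sample_exome()] objects (>= 2).
#' @param controls List of control `sample_exome` objects.
#' @param db Optional database data frame (see [filter_known_common()]).
#' @param cfg A [cascade_config()].
#' @param panel Optional list of panel `sample_exome` objects.
#' @return List with `final_keys` (surviving variant keys), `attrition`
#'   (data frame), `exomes` (the filtered affected exomes), and
#'   `per_sample` counts.
#' @export
run_cascade <- function(affected, controls = list(), db = NULL,
                        cfg = cascade_config(), panel = list()) {
  stopifnot(length(affected) >= 2L)
  stage_counts <- function(ex) {
    ex <- filter_quality(ex, cfg)
    total <- nrow(ex$calls)
    ex <- filter_functional(ex, cfg)
    nonsyn <- nrow(ex$calls)
    ex <- filter_known_common(ex, db, cfg)
    novel <- nrow(ex$calls)
    list(exome = ex, counts = c(total_coding = total,
                                functional = nonsyn,
                                after_filtering = novel))
  }
  aff <- lapply(affected, stage_counts)
  ctl <- lapply(controls, stage_counts)
  per_sample <- t(vapply(c(aff, ctl), function(x) x$counts, numeric(3)))
  rownames(per_sample) <- vapply(c(aff, ctl),
                                 function(x) x$exome$sample_id,
                                 character(1))
  shared <- shared_in_affecteds(lapply(aff, `[[`, "exome"))
  uniq <- subtract_samples(shared, lapply(ctl, `[[`, "exome"))
  final <- subtract_samples(uniq, panel)
  denom <- mean(per_sample[, "total_coding"])
  counts <- c(colMeans(per_sample),
              shared_in_affecteds = length(shared),
              unique_to_cases = length(uniq))
  if (length(panel)) counts <- c(counts, after_panel = length(final))
  list(final_keys = final,
       attrition = attrition_table(round(counts), denom),
       exomes = lapply(aff, `[[`, "exome"),
       per_sample = per_sample)
}
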