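# Programmatic fixtures shared across test files.

# A random call table with plausible field distributions.
random_calls <- function(n, seed = NULL, classes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(classes))
    classes <- c("missense", "nonsense", "splice", "synonymous",
                 "intronic", "intergenic")
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3, n, replace = TRUE) -
                  1L) %% 4L + 1L]
  data.frame(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    ref = ref, alt = alt,
    zygosity = sample(c("het", "hom"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    depth = sample(0:60, n, replace = TRUE),
    qual = sample(0:300, n, replace = TRUE),
    var_class = sample(classes, n, replace = TRUE),
    db = sample(c(TRUE, FALSE), n, replace = TRUE),
    db_freq = NA_real_,
    prediction = NA_character_,
    gene = sprintf("G%04d", sample.int(500, n, replace = TRUE)),
    stringsAsFactors = FALSE)
}

random_exome <- function(n, seed = NULL, sample_id = "s1",
                         status = "affected", with_freq = TRUE) {
  calls <- random_calls(n, seed)
  if (with_freq)
    calls$db_freq <- ifelse(calls$db, round(runif(n), 4), NA_real_)
  sample_exome(sample_id, status, calls)
}

# Minimal two-generation pedigrees used by sharing tests.
sibling_pedigree <- function() {
  pedigree(data.frame(
    id = c("f", "m", "s1", "s2"),
    father = c(NA, NA, "f", "f"),
    mother = c(NA, NA, "m", "m"),
    sex = c("male", "female", "male", "female"),
    status = c("unknown", "unknown", "affected", "affected"),
    stringsAsFactors = FALSE))
}

unrelated_affected_pedigree <- function() {
  pedigree(data.frame(
    id = c("x1", "x2"),
    father = NA_character_, mother = NA_character_,
    sex = c("male", "female"),
    status = c("affected", "affected"),
    stringsAsFactors = FALSE))
}

# Small, fast simulation settings for pipeline-level tests.
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_background_novel = 100L,
             novel_silent_ratio = 0.5, n_total_coding = 2000L, ...)
}
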