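test_that("depth and quality thresholds sit at the published boundaries", {
  calls <- random_calls(4, seed = 7)
  calls$depth <- c(4, 5, 100, 100)
  calls$qual <- c(100, 100, 29, 30)
  ex <- filter_quality(sample_exome("s", "affected", calls))
  expect_equal(ex$calls$depth, c(5, 100))
  expect_equal(ex$calls$qual, c(100, 30))

  deep <- random_calls(20, seed = 8)
  deep$depth <- 100; deep$qual <- 200
  ex2 <- filter_quality(sample_exome("s", "affected", deep))
  expect_equal(nrow(ex2$calls), 20L)
})

test_that("known-common removal uses strict zygosity-specific thresholds", {
  calls <- random_calls(5, seed = 9)
  calls$zygosity <- c("het", "het", "hom", "hom", "het")
  calls$db <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  calls$db_freq <- c(0.06, 0.04, 0.29, 0.31, NA)
  ex <- filter_known_common(sample_exome("s", "affected", calls))
  # removed: het @ 0.06 and hom @ 0.31; kept: het @ 0.04, hom @ 0.29, novel
  expect_equal(ex$calls$db_freq, c(0.04, 0.29, NA))

  # equality keeps ("greater than" removes)
  eq <- random_calls(2, seed = 10)
  eq$zygosity <- c("het", "hom"); eq$db <- TRUE
  eq$db_freq <- c(0.05, 0.30)
  expect_equal(nrow(filter_known_common(
    sample_exome("s", "affected", eq))$calls), 2L)

  # an explicit empty db is an identity
  ex3 <- random_exome(30, seed = 11)
  out <- filter_known_common(ex3, db = data.frame(key = character(0),
                                                  freq = numeric(0)))
  expect_equal(out$calls, ex3$calls)
})

test_that("functional filtering keeps only configured classes", {
  calls <- random_calls(3, seed = 12)
  calls$var_class <- c("missense", "intronic", "nonsense")
  ex <- filter_functional(sample_exome("s", "affected", calls))
  expect_equal(ex$calls$var_class, c("missense", "nonsense"))

  syn <- random_calls(10, seed = 13)
  syn$var_class <- "synonymous"
  expect_equal(nrow(filter_functional(
    sample_exome("s", "affected", syn))$calls), 0L)
})

test_that("each filter equals brute-force predicate filtering", {
  cfg <- cascade_config()
  for (seed in 1:5) {
    ex <- random_exome(200, seed = seed)
    calls <- ex$calls

    got <- filter_quality(ex, cfg)$calls
    want <- calls[calls$depth >= cfg$min_depth &
                    calls$qual >= cfg$min_qual, ]
    rownames(want) <- NULL
    expect_equal(got, want)

    got <- filter_functional(ex, cfg)$calls
    want <- calls[calls$var_class %in% cfg$functional_classes, ]
    rownames(want) <- NULL
    expect_equal(got, want)

    got <- filter_known_common(ex, cfg = cfg)$calls
    thr <- ifelse(calls$zygosity == "hom", cfg$hom_freq_max,
                  cfg$het_freq_max)
    drop <- calls$db & !is.na(calls$db_freq) & calls$db_freq > thr
    want <- calls[!drop, ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("set stages obey set algebra and commute", {
  set.seed(42)
  mk <- function(n, id) random_exome(n, sample_id = id)
  a <- mk(80, "a"); b <- mk(80, "b"); c3 <- mk(80, "c")

  # intersection over three sets equals fold of pairwise intersections
  keys <- lapply(list(a, b, c3), function(e)
    with(e$calls, variant_key(chrom, pos, ref, alt)))
  expect_setequal(shared_in_affecteds(list(a, b, c3)),
                  intersect(intersect(keys[[1]], keys[[2]]), keys[[3]]))

  # disjoint affected sets share nothing
  d1 <- random_exome(30, seed = 100, sample_id = "d1")
  d2 <- random_exome(30, seed = 200, sample_id = "d2")
  d2$calls$pos <- d2$calls$pos + 2e8 # force disjoint keys
  d2 <- sample_exome("d2", "affected", d2$calls)
  expect_length(shared_in_affecteds(list(d1, d2)), 0L)

  # control carrying half the keys leaves the other half
  half <- sample_exome("ctl", "unaffected", a$calls[1:40, ])
  expect_setequal(subtract_samples(keys[[1]], list(half)),
                  setdiff(keys[[1]], keys[[1]][1:40]))
  expect_equal(subtract_samples(keys[[1]], list()), keys[[1]])

  # subtraction order does not matter
  expect_setequal(
    subtract_samples(subtract_samples(keys[[1]], list(b)), list(c3)),
    subtract_samples(subtract_samples(keys[[1]], list(c3)), list(b)))
})

test_that("filter traces are non-increasing", {
  ex <- random_exome(300, seed = 3)
  ex <- filter_quality(ex)
  ex <- filter_functional(ex)
  ex <- filter_known_common(ex)
  expect_equal(ex$trace$stage, c("quality", "functional", "known_common"))
  expect_true(all(diff(ex$trace$count) <= 0))
})

test_that("attrition formatting matches the printed precision convention", {
  tab <- attrition_table(c(total = 38179, shared = 96, unique = 24),
                         denominator = 38179)
  expect_equal(tab$percent_printed, c("100", "0.25", "0.06"))
  expect_equal(format_percent_remaining(100 * 674 / 38179), "1.8")
  expect_equal(format_percent_remaining(100 * 9202 / 38179), "24.1")
  expect_equal(attrition_table(c(x = 50), 50)$percent_printed, "100")
  expect_error(attrition_table(c(x = 1), 0), "denominator")
})

test_that("validation FDR is a plain failure fraction", {
  expect_equal(round(validation_fdr(22, 1), 3), 0.045)
  expect_equal(validation_fdr(10, 0), 0)
  expect_equal(validation_fdr(7, 7), 1)
  expect_error(validation_fdr(0, 0))
  expect_error(validation_fdr(5, 6))
})
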