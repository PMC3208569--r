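test_that("config validation rejects impossible designs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1,
                          pedigree = sibling_pedigree(),
                          sequenced_affected = c("s1", "f")),
               "config error")
})

test_that("gene-dropped sharing converges to 2x kinship", {
  # siblings: 0.5
  sib <- sim_config(seed = 101, pedigree = sibling_pedigree(),
                    sequenced_affected = c("s1", "s2"),
                    sequenced_control = character(0),
                    n_background_novel = 5000L, novel_silent_ratio = 0,
                    n_total_coding = NULL, artifact_rate = 0)
  sims <- simulate_cohort(sib)
  fr <- sharing_fraction(sims, "s1", "s2")
  expect_gt(fr$n_carried, 3000)
  expect_lt(abs(fr$fraction - 0.5), 3 * fr$se)

  # first cousins (the sequenced affecteds): 0.125; sibling control: 0.5
  fc <- sim_config(seed = 102, n_background_novel = 2500L,
                   novel_silent_ratio = 0, n_total_coding = NULL,
                   artifact_rate = 0)
  simc <- simulate_cohort(fc)
  fr2 <- sharing_fraction(simc, "a1", "a2")
  expect_lt(abs(fr2$fraction - 0.125), 3 * fr2$se)
  fr3 <- sharing_fraction(simc, "a1", "u1")
  expect_lt(abs(fr3$fraction - 0.5), 3 * fr3$se)
})

test_that("unrelated affecteds share only the implanted causal variant", {
  cfg <- sim_config(seed = 103, pedigree = unrelated_affected_pedigree(),
                    sequenced_affected = c("x1", "x2"),
                    sequenced_control = character(0),
                    n_background_novel = 500L, novel_silent_ratio = 0,
                    n_total_coding = NULL, artifact_rate = 0)
  sim <- simulate_cohort(cfg)
  shared <- shared_in_affecteds(sim$exomes)
  expect_equal(shared, sim$truth$causal_key)
})

test_that("gene dropping respects Mendelian transmission", {
  cfg <- small_sim_config(seed = 104)
  sim <- simulate_cohort(cfg)
  g <- sim$panel$genotypes
  inherited <- sim$truth$origins$key[sim$truth$origins$origin ==
                                       "inherited"]
  g <- g[g$key %in% inherited, ]
  carrier <- with(g, tapply(genotype %in% c("0/1", "1/1"),
                            list(sample_id, key), any))
  m <- cfg$pedigree$members
  for (i in seq_len(nrow(m))) {
    if (is.na(m$father[i])) next
    child <- carrier[m$id[i], ]
    parents <- carrier[m$father[i], ] | carrier[m$mother[i], ]
    expect_true(all(parents[child]))
  }
})

test_that("artifacts are shared, labeled, and absent from germline truth", {
  cfg <- sim_config(seed = 105, n_background_novel = 300L,
                    novel_silent_ratio = 0, n_total_coding = NULL,
                    artifact_rate = 0.2)
  sim <- simulate_cohort(cfg)
  art <- sim$truth$origins$key[sim$truth$origins$origin == "artifact"]
  expect_gt(length(art), 0)
  # every sequenced sample observes every artifact call...
  for (ex in sim$exomes) {
    keys <- with(ex$calls, variant_key(chrom, pos, ref, alt))
    expect_true(all(art %in% keys))
  }
  # ...but nobody carries one in germline truth
  g <- sim$panel$genotypes
  expect_true(all(g$genotype[g$key %in% art] == "0/0"))
  # so the affected intersection is inflated by exactly the artifacts
  # that the control subtraction then removes
  shared <- shared_in_affecteds(sim$exomes[cfg$sequenced_affected])
  expect_true(all(art %in% shared))
  after <- subtract_samples(shared, sim$exomes[cfg$sequenced_control])
  expect_length(intersect(after, art), 0L)
})

test_that("simulation is deterministic under its seed", {
  a <- simulate_cohort(small_sim_config(seed = 106))
  b <- simulate_cohort(small_sim_config(seed = 106))
  expect_equal(a$exomes$a1$calls, b$exomes$a1$calls)
  expect_equal(a$truth, b$truth)
  c3 <- simulate_cohort(small_sim_config(seed = 107))
  expect_false(identical(a$exomes$a1$calls, c3$exomes$a1$calls))
})

test_that("attrition experiments retain the causal variant and repeat", {
  cfg <- small_sim_config(seed = 108)
  exp1 <- attrition_experiment(cfg, n_reps = 3)
  exp2 <- attrition_experiment(cfg, n_reps = 3)
  expect_equal(exp1$summary, exp2$summary)
  expect_equal(exp1$retention_rate, 1.0)
  expect_true(all(exp1$summary$stage[1:3] ==
                    c("total_coding", "functional", "after_filtering")))
  # counts decrease along the cascade
  expect_true(all(diff(exp1$summary$mean) <= 0))
})

test_that("study-scale defaults emulate the published cohort structure", {
  sim <- simulate_cohort(sim_config(seed = 109))
  a1 <- sim$exomes$a1
  # total coding calls near 38,179 and novel nonsynonymous near 674
  expect_lt(abs(nrow(a1$calls) - 38179) / 38179, 0.05)
  novel_ns <- sim$truth$origins$key[
    sim$truth$origins$origin == "inherited" &
      sim$truth$origins$var_class %in% c("missense", "nonsense", "splice")]
  keys1 <- with(a1$calls, variant_key(chrom, pos, ref, alt))
  expect_lt(abs(sum(novel_ns %in% keys1) - 674) / 674, 0.15)
})
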