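test_that("the bundled CSPalpha sequence matches its annotations", {
  wt <- cspa_sequence()
  expect_equal(length(wt), 198L)
  r <- wt$residues
  expect_equal(r[c(108, 110, 115, 116, 137, 138, 139)],
               c("A", "F", "L", "L", "K", "P", "K"))
  # the cysteine string: Cys-rich 113-136
  expect_gte(sum(r[113:136] == "C"), 13)
})

test_that("edits apply, validate references, and reverse", {
  wt <- cspa_sequence()
  m <- apply_edit(wt, "L115R")
  expect_equal(m$residues[115], "R")
  expect_equal(length(m), 198L)

  d <- apply_edit(wt, "L116del")
  expect_equal(length(d), 197L)
  # downstream numbering shifts left by one
  expect_equal(d$residues[116:150], wt$residues[117:151])

  cs <- apply_edit(wt, "C113-119S")
  expect_equal(cs$residues[c(113, 118, 119)], c("S", "S", "S"))
  expect_equal(sum(cs$residues != wt$residues), 3L)

  expect_error(apply_edit(wt, "L114R"), "position 114")

  # substitution then reverse substitution restores the original
  set.seed(21)
  for (i in 1:10) {
    pos <- sample(length(wt), 1)
    new <- sample(setdiff(c("A", "G", "W", "R", "K"),
                          wt$residues[pos]), 1)
    fwd <- apply_edit(wt, edit_substitution(pos, wt$residues[pos], new))
    back <- apply_edit(fwd, edit_substitution(pos, new,
                                              wt$residues[pos]))
    expect_equal(back$residues, wt$residues)
  }

  # deletions commute with downstream coordinate shift
  for (del in c(20, 116, 150)) {
    d2 <- apply_edit(wt, edit_deletion(del))
    after <- seq(del + 1, length(wt))
    expect_equal(d2$residues[after - 1L], wt$residues[after])
  }

  # original-coordinate segments map through deletions
  expect_equal(shifted_segment(d, 108, 139), c(108, 138))
  expect_equal(shifted_segment(d, 120, 139), c(119, 138))
  expect_equal(shifted_segment(d, 1, 50), c(1, 50))
  expect_equal(shifted_segment(m, 108, 139), c(108, 139))
  # the mapped segment carries the same residues minus the deleted one
  seg <- shifted_segment(d, 108, 139)
  expect_equal(d$residues[seg[1]:seg[2]], wt$residues[c(108:115, 117:139)])
})

test_that("CDS positions map to codons by thirds", {
  expect_equal(codon_of_cds_position(344)$codon, 115L)
  expect_equal(codon_of_cds_position(344)$offset, 2L)
  expect_equal(codon_of_cds_position(3)$codon, 1L)
  expect_equal(codon_of_cds_position(3)$offset, 3L)
  expect_equal(codon_of_cds_position(346:348)$codon, rep(116L, 3))

  ic <- inframe_check(346, 348)
  expect_equal(ic$class, "inframe_single_codon")
  expect_true(ic$codon_aligned)
  expect_equal(ic$codon_start, 116L)

  expect_equal(inframe_check(346, 347)$class, "frameshift")

  two <- inframe_check(344, 349)
  expect_equal(two$class, "inframe_multi_codon")
  expect_equal(two$n_codons_removed, 2L)
  expect_false(two$codon_aligned)
})

test_that("hydropathy profiles follow the scale and the window", {
  rr <- protein_sequence("RR", id = "rr")
  expect_equal(unname(hydropathy_profile(rr, window = 1)$values),
               c(-4.5, -4.5))

  wt <- cspa_sequence()
  kd <- hydropathy_scale("kyte_doolittle")
  expect_equal(unname(hydropathy_profile(wt, window = 1)$values),
               unname(kd[wt$residues]))
  expect_equal(max(kd), kd[["I"]])
  expect_equal(min(kd), kd[["R"]])

  # window 3 on a 5-mer equals the hand-computed truncated moving average
  p5 <- protein_sequence("AWLRG", id = "p")
  v <- unname(kd[c("A", "W", "L", "R", "G")])
  hand <- c(mean(v[1:2]), mean(v[1:3]), mean(v[2:4]), mean(v[3:5]),
            mean(v[4:5]))
  expect_equal(unname(hydropathy_profile(p5, window = 3)$values), hand)

  expect_error(hydropathy_profile(p5, window = 2), "odd")

  # replacing Leu (3.8) by Arg (-4.5) lowers every windowed mean
  # containing position 115
  m <- apply_edit(wt, "L115R")
  for (w in c(1, 5, 9)) {
    pw <- hydropathy_profile(wt, window = w)$values
    pm <- hydropathy_profile(m, window = w)$values
    touched <- max(1, 115 - (w - 1) / 2):min(198, 115 + (w - 1) / 2)
    expect_true(all(pm[touched] < pw[touched]))
    expect_equal(pm[-touched], pw[-touched])
  }
})

test_that("segment statistics agree with a two-pass oracle", {
  wt <- cspa_sequence()
  pr <- hydropathy_profile(wt, window = 9)
  st <- segment_stats(pr, 110, 120)
  v <- pr$values[110:120]
  expect_equal(st$mean, sum(v) / length(v))
  expect_equal(st$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  expect_equal(st$n, 11L)

  const <- protein_sequence(strrep("A", 10), id = "c")
  expect_equal(segment_stats(hydropathy_profile(const, window = 1),
                             2, 9)$sd, 0)
})

test_that("transfer free energies sum whole-residue scale values", {
  awl <- protein_sequence("AWL", id = "awl")
  wif <- hydropathy_scale("ww_interface")
  expect_equal(transfer_dG(awl, 1, 3, "ww_interface")$total,
               wif[["A"]] + wif[["W"]] + wif[["L"]])

  wt <- cspa_sequence()
  expect_equal(transfer_dG(wt, 10, 9, "ww_interface")$total, 0)

  # additive over segment concatenation; contributions sum to the total
  te <- transfer_dG(wt, 108, 139, "ww_interface")
  expect_equal(sum(te$contributions), te$total)
  expect_equal(transfer_dG(wt, 108, 120, "ww_interface")$total +
                 transfer_dG(wt, 121, 139, "ww_interface")$total,
               te$total)

  expect_equal(octanol_minus_interface(wt, 108, 139),
               transfer_dG(wt, 108, 139, "ww_octanol")$total - te$total)
})

test_that("splice consensus-value reductions are percentages of wild type", {
  expect_equal(round(splice_cv_reduction(69.84, 36), 2), 48.45)
  expect_equal(splice_cv_reduction(55, 55), 0)
  expect_equal(splice_cv_reduction(50, 0), 100)
  expect_error(splice_cv_reduction(0, 0))
})

test_that("Kruskal-Wallis and Dunn agree with hand rank arithmetic", {
  # identical groups: H = 0, nothing significant
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- compare_variant_profiles(g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_false(any(r$dunn$significant))

  # hand-computed H with tie correction on small groups
  hand_H <- function(groups) {
    x <- unlist(groups)
    gl <- rep(seq_along(groups), lengths(groups))
    N <- length(x)
    rk <- rank(x)
    H <- 12 / (N * (N + 1)) *
      sum(tapply(rk, gl, sum)^2 / lengths(groups)) - 3 * (N + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  set.seed(77)
  for (i in 1:10) {
    groups <- lapply(1:3, function(j) sample(1:6, sample(3:10, 1),
                                             replace = TRUE))
    got <- compare_variant_profiles(groups)$statistic
    expect_equal(got, hand_H(groups), tolerance = 1e-10)
  }
})

test_that("window calibration recovers a convention matching the targets", {
  cal <- calibrate_hydropathy_window()
  expect_equal(cal$window %% 2, 1)
  expect_lt(abs(cal$means[["wt"]] - 1.699), 0.005)
  expect_lt(abs(cal$means[["L115R"]] - 1.181), 0.005)
  expect_lt(abs(cal$means[["L116del"]] - 1.559), 0.05)
})
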