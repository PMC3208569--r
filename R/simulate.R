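#' Simulation configuration
#'
#' Defines a pedigree-structured exome cohort with known truth. Defaults
#' reproduce the statistical structure of the study design: ~674 novel
#' nonsynonymous variants per sample, ~38,179 total coding substitutions,
#' two affected first cousins plus an unaffected sibling control sequenced
#' on one flow cell (so systematic artifact calls are shared by all
#' sequenced samples), and one novel heterozygous causal missense variant
#' carried by every affected member.
#'
#' @param seed Mandatory integer seed; every stochastic draw derives from
#'   it.
#' @param pedigree A [pedigree()]; needs >= 2 affected members among the
#'   sequenced samples.
#' @param sequenced_affected,sequenced_control Ids of the sequenced
#'   samples.
#' @param n_background_novel Novel nonsynonymous variants carried
#'   per founder (which is also the expected novel nonsynonymous count per
#'   sequenced sample under gene-dropping).
#' @param novel_silent_ratio Novel synonymous/intronic variants per novel
#'   nonsynonymous one.
#' @param n_total_coding Target total coding substitutions per sample;
#'   sizes the common-variant pool. `NULL` skips the common pool (fast
#'   configurations for focused experiments).
#' @param frac_nonsyn_common Fraction of common coding variants that are
#'   nonsynonymous.
#' @param db_spectrum Population-frequency spectrum of database variants:
#'   list with `p_rare` and uniform `common_range` / `rare_range`.
#' @param artifact_rate Expected shared artifact calls as a fraction of
#'   `n_background_novel`; artifacts are novel, identical across all
#'   co-sequenced samples, and absent from everyone's germline truth.
#' @param novel_pop_freq_range True (database-unseen) population frequency
#'   range of novel founder variants, used by control screening.
#' @param causal List describing the implanted causal variant.
#' @param n_panel Number of unrelated panel exomes to simulate (novel
#'   variants only), 0 for none.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       pedigree = ancl_study_pedigree(),
                       sequenced_affected = c("a1", "a2"),
                       sequenced_control = "u1",
                       n_background_novel = 674L,
                       novel_silent_ratio = 2.47,
                       n_total_coding = 38179L,
                       frac_nonsyn_common = 0.241,
                       db_spectrum = list(p_rare = 0.05,
                                          common_range = c(0.05, 0.95),
                                          rare_range = c(1e-4, 5e-3)),
                       artifact_rate = 0.02,
                       novel_pop_freq_range = c(0, 2e-3),
                       causal = list(gene = "DNAJC5", chrom = "20",
                                     pos = 62562226, ref = "T", alt = "G",
                                     var_class = "missense"),
                       n_panel = 0L) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(inherits(pedigree, "pedigree"),
            artifact_rate >= 0, artifact_rate <= 1,
            n_background_novel > 0, novel_silent_ratio >= 0,
            frac_nonsyn_common >= 0, frac_nonsyn_common <= 1)
  m <- pedigree$members
  aff <- intersect(sequenced_affected, m$id[m$status == "affected"])
  if (length(aff) < 2L)
    stop("config error: pedigree must provide >= 2 sequenced affecteds")
  if (sum(m$status == "affected") < 2L)
    stop("config error: pedigree without >= 2 affecteds")
  structure(list(seed = as.integer(seed), pedigree = pedigree,
                 sequenced_affected = sequenced_affected,
                 sequenced_control = sequenced_control,
                 n_background_novel = as.integer(n_background_novel),
                 novel_silent_ratio = novel_silent_ratio,
                 n_total_coding = n_total_coding,
                 frac_nonsyn_common = frac_nonsyn_common,
                 db_spectrum = db_spectrum,
                 artifact_rate = artifact_rate,
                 novel_pop_freq_range = novel_pop_freq_range,
                 causal = causal, n_panel = as.integer(n_panel)),
            class = "sim_config")
}

# mean carrier probability E[1 - (1-f)^2] for f ~ U(a, b)
unif_carrier_prob <- function(r) {
  a <- r[1]; b <- r[2]
  2 * (a + b) / 2 - (a^2 + a * b + b^2) / 3
}

draw_class_nonsyn <- function(n) {
  sample(c("missense", "nonsense", "splice"), n, replace = TRUE,
         prob = c(0.97, 0.02, 0.01))
}

#' Simulate a pedigree-structured exome cohort
#'
#' Founder variants are dropped through the pedigree by Mendelian
#' gene-dropping (each parental allele transmitted with probability 1/2);
#' database-common variants get founder genotypes from Hardy-Weinberg at
#' frequencies drawn from the configured spectrum; flow-cell artifacts are
#' injected identically into every sequenced sample (and into nobody's
#' germline truth); the causal variant is implanted heterozygous in every
#' affected member and absent from all others.
#'
#' @param cfg A [sim_config()].
#' @return List with `exomes` (named list of [sample_exome()], the
#'   sequenced samples), `panel` (a [genotype_panel()] of germline-truth
#'   genotypes of all pedigree members at the tracked novel variants,
#'   artifacts and the causal variant), `truth` (causal key, per-member
#'   carrier status, per-variant origin labels and population
#'   frequencies), `db` (database frequency table for
#'   [filter_known_common()]), and `panel_exomes` (unrelated panel
#'   samples, possibly empty).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ped <- cfg$pedigree
  m <- ped$members
  founders <- m$id[is.na(m$father) & is.na(m$mother)]
  depth_ord <- order(vapply(m$id, function(i) ped_depth(ped, i),
                            numeric(1)))
  ids <- m$id[depth_ord]

  k_ns <- cfg$n_background_novel
  k_sil <- round(k_ns * cfg$novel_silent_ratio)

  ## ---- variant attribute assembly -------------------------------------
  n_common <- 0L
  common_freq <- numeric(0)
  if (!is.null(cfg$n_total_coding)) {
    sp <- cfg$db_spectrum
    cbar <- (1 - sp$p_rare) * unif_carrier_prob(sp$common_range) +
      sp$p_rare * unif_carrier_prob(sp$rare_range)
    target <- cfg$n_total_coding - k_ns * (1 + cfg$novel_silent_ratio)
    n_common <- max(0L, as.integer(round(target / cbar)))
    rare <- stats::runif(n_common) < sp$p_rare
    common_freq <- ifelse(rare,
                          stats::runif(n_common, sp$rare_range[1],
                                       sp$rare_range[2]),
                          stats::runif(n_common, sp$common_range[1],
                                       sp$common_range[2]))
  }
  n_novel <- length(founders) * (k_ns + k_sil)
  n_art <- stats::rpois(1, cfg$artifact_rate * k_ns)
  n_var <- n_common + n_novel + n_art + 1L # +1 causal

  origin <- c(rep("db-common", n_common), rep("inherited", n_novel),
              rep("artifact", n_art), "causal")
  idx_novel <- n_common + seq_len(n_novel)
  idx_art <- n_common + n_novel + seq_len(n_art)
  idx_causal <- n_var

  is_silent_novel <- rep(rep(c(FALSE, TRUE), c(k_ns, k_sil)),
                         length(founders))
  var_class <- character(n_var)
  if (n_common) {
    nonsyn <- stats::runif(n_common) < cfg$frac_nonsyn_common
    var_class[seq_len(n_common)] <- ifelse(nonsyn,
                                           draw_class_nonsyn(n_common),
                                           "synonymous")
  }
  var_class[idx_novel] <- ifelse(is_silent_novel,
                                 sample(c("synonymous", "intronic"),
                                        n_novel, replace = TRUE,
                                        prob = c(0.6, 0.4)),
                                 draw_class_nonsyn(n_novel))
  if (n_art) var_class[idx_art] <- draw_class_nonsyn(n_art)
  var_class[idx_causal] <- cfg$causal$var_class

  bases <- c("A", "C", "G", "T")
  chrom <- as.character(sample(1:22, n_var, replace = TRUE))
  pos <- sample.int(2e8, n_var) # unique positions guarantee unique keys
  ref <- sample(bases, n_var, replace = TRUE)
  alt_shift <- sample.int(3, n_var, replace = TRUE)
  alt <- bases[(match(ref, bases) + alt_shift - 1L) %% 4L + 1L]
  gene <- sprintf("GENE%05d", sample.int(20000, n_var, replace = TRUE))
  chrom[idx_causal] <- cfg$causal$chrom
  pos[idx_causal] <- cfg$causal$pos
  ref[idx_causal] <- cfg$causal$ref
  alt[idx_causal] <- cfg$causal$alt
  gene[idx_causal] <- cfg$causal$gene
  key <- variant_key(chrom, pos, ref, alt)
  dup <- duplicated(key) # only possible via the fixed causal locus
  if (any(dup)) {
    pos[dup] <- 2e8 + which(dup)
    key <- variant_key(chrom, pos, ref, alt)
  }

  pop_freq <- numeric(n_var)
  pop_freq[seq_len(n_common)] <- common_freq
  pop_freq[idx_novel] <- stats::runif(n_novel, cfg$novel_pop_freq_range[1],
                                      cfg$novel_pop_freq_range[2])
  # artifacts and the causal variant do not exist in the population
  db <- origin == "db-common"
  db_freq <- ifelse(db, pop_freq, NA_real_)

  ## ---- genotypes: founders + gene-dropping ----------------------------
  n_mendel <- n_common + n_novel
  G <- matrix(0L, nrow = nrow(m), ncol = n_mendel,
              dimnames = list(m$id, NULL))
  for (f in founders) {
    g <- integer(n_mendel)
    if (n_common) g[seq_len(n_common)] <- stats::rbinom(n_common, 2L,
                                                        common_freq)
    G[f, ] <- g
  }
  # founder-private novel variants, heterozygous in their founder
  for (i in seq_along(founders)) {
    cols <- n_common + (i - 1L) * (k_ns + k_sil) + seq_len(k_ns + k_sil)
    G[founders[i], cols] <- 1L
  }
  for (id in ids) {
    mm <- ped_member(ped, id)
    if (is.na(mm$father) && is.na(mm$mother)) next
    gf <- if (is.na(mm$father)) integer(n_mendel) else G[mm$father, ]
    gm <- if (is.na(mm$mother)) integer(n_mendel) else G[mm$mother, ]
    G[id, ] <- stats::rbinom(n_mendel, 1L, gf / 2) +
      stats::rbinom(n_mendel, 1L, gm / 2)
  }
  causal_carrier <- stats::setNames(m$status == "affected", m$id)

  ## ---- observed call sets for sequenced samples -----------------------
  sequenced <- c(cfg$sequenced_affected, cfg$sequenced_control)
  mk_exome <- function(id) {
    g <- G[id, ]
    idx <- which(g >= 1L)
    zyg <- ifelse(g[idx] == 2L, "hom", "het")
    if (n_art) { idx <- c(idx, idx_art); zyg <- c(zyg, rep("het", n_art)) }
    if (causal_carrier[[id]]) {
      idx <- c(idx, idx_causal); zyg <- c(zyg, "het")
    }
    n <- length(idx)
    calls <- data.frame(
      chrom = chrom[idx], pos = pos[idx], ref = ref[idx], alt = alt[idx],
      zygosity = zyg,
      depth = pmax(1L, stats::rnbinom(n, size = 8, mu = 120)),
      qual = round(stats::rlnorm(n, meanlog = log(228), sdlog = 0.8)),
      var_class = var_class[idx], db = db[idx], db_freq = db_freq[idx],
      prediction = NA_character_, gene = gene[idx],
      stringsAsFactors = FALSE)
    if (causal_carrier[[id]]) {
      ci <- which(idx == idx_causal)
      calls$depth[ci] <- 124L  # the causal call is high-confidence
      calls$qual[ci] <- 228
      calls$prediction[ci] <- "possibly_damaging"
    }
    status <- m$status[match(id, m$id)]
    sample_exome(id, if (status == "affected") "affected" else "unaffected",
                 calls)
  }
  exomes <- stats::setNames(lapply(sequenced, mk_exome), sequenced)

  ## ---- germline-truth genotype panel over tracked variants ------------
  tracked <- c(idx_novel[!is_silent_novel], idx_art, idx_causal)
  geno_string <- function(g) GENO_CODES[g + 1L]
  panel_df <- do.call(rbind, lapply(m$id, function(id) {
    g <- integer(length(tracked))
    mendel <- tracked <= n_mendel
    g[mendel] <- G[id, tracked[mendel]]
    g[tracked == idx_causal] <- as.integer(causal_carrier[[id]])
    data.frame(sample_id = id, key = key[tracked],
               genotype = geno_string(g), stringsAsFactors = FALSE)
  }))
  panel <- genotype_panel(panel_df)

  ## ---- unrelated panel exomes (novel variants only) -------------------
  panel_exomes <- list()
  if (cfg$n_panel > 0L) {
    # panel members carry each tracked population variant with the
    # carrier probability implied by its population frequency
    pv <- c(seq_len(n_common), idx_novel)
    pcar <- 1 - (1 - pop_freq[pv])^2
    panel_exomes <- lapply(seq_len(cfg$n_panel), function(j) {
      hit <- pv[stats::runif(length(pv)) < pcar]
      calls <- data.frame(chrom = chrom[hit], pos = pos[hit],
                          ref = ref[hit], alt = alt[hit],
                          zygosity = "het", depth = 100L, qual = 200,
                          var_class = var_class[hit], db = db[hit],
                          db_freq = db_freq[hit],
                          prediction = NA_character_, gene = gene[hit],
                          stringsAsFactors = FALSE)
      sample_exome(sprintf("panel%03d", j), "unaffected", calls)
    })
  }

  truth <- list(
    causal_key = key[idx_causal],
    carriers = causal_carrier,
    origins = data.frame(key = key, origin = origin, var_class = var_class,
                         pop_freq = pop_freq, db_freq = db_freq,
                         gene = gene, stringsAsFactors = FALSE))
  db_table <- data.frame(key = key[db], freq = pop_freq[db],
                         stringsAsFactors = FALSE)
  list(exomes = exomes, panel = panel, truth = truth, db = db_table,
       panel_exomes = panel_exomes, config = cfg)
}

#' Observed rare-variant sharing fraction between two members
#'
#' Among founder-derived ("inherited") novel variants carried by `a`, the
#' fraction also carried by `b`, read from the germline-truth genotype
#' panel. Converges to [expected_sharing()] as the founder-variant count
#' grows.
#'
#' @param sim Result of [simulate_cohort()].
#' @param a,b Member ids.
#' @return List with `fraction`, `n_carried` (denominator), `se`
#'   (binomial Monte-Carlo standard error).
#' @export
sharing_fraction <- function(sim, a, b) {
  keys <- sim$truth$origins$key[sim$truth$origins$origin == "inherited"]
  g <- sim$panel$genotypes
  g <- g[g$key %in% keys, ]
  carrier <- function(id) {
    gi <- g[g$sample_id == id, ]
    stats::setNames(gi$genotype %in% c("0/1", "1/1"), gi$key)
  }
  ca <- carrier(a); cb <- carrier(b)
  ka <- names(ca)[ca]
  ka <- ka[ka %in% names(cb)]
  if (!length(ka)) return(list(fraction = NA_real_, n_carried = 0L,
                               se = NA_real_))
  p <- mean(cb[ka])
  list(fraction = p, n_carried = length(ka),
       se = sqrt(p * (1 - p) / length(ka)))
}

#' Repeated simulation-plus-cascade attrition experiment
#'
#' Runs [simulate_cohort()] followed by [run_cascade()] `n_reps` times
#' (replicate r uses seed `cfg$seed + r - 1`) and summarizes the per-stage
#' surviving counts and the retention rate of the implanted causal
#' variant.
#'
#' @param cfg A [sim_config()].
#' @param n_reps Number of replicates.
#' @param cascade_cfg A [cascade_config()].
#' @return List with `summary` (per-stage mean and sd counts),
#'   `retention_rate`, and the raw `counts` matrix (replicates x stages).
#' @export
attrition_experiment <- function(cfg, n_reps = 10L,
                                 cascade_cfg = cascade_config()) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1L)
  rows <- vector("list", n_reps)
  retained <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    sim <- simulate_cohort(cfg_r)
    aff <- sim$exomes[cfg$sequenced_affected]
    ctl <- sim$exomes[intersect(cfg$sequenced_control,
                                names(sim$exomes))]
    res <- run_cascade(aff, ctl, db = sim$db, cfg = cascade_cfg,
                       panel = sim$panel_exomes)
    rows[[r]] <- stats::setNames(res$attrition$count,
                                 res$attrition$stage)
    retained[r] <- sim$truth$causal_key %in% res$final_keys
  }
  counts <- do.call(rbind, rows)
  summ <- data.frame(stage = colnames(counts),
                     mean = colMeans(counts),
                     sd = apply(counts, 2, stats::sd),
                     row.names = NULL)
  list(summary = summ, retention_rate = mean(retained), counts = counts)
}
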