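#' Assemble a run configuration
#'
#' A run is driven either by a simulation block (a [sim_config()] or the
#' arguments to build one) or by real input paths (variant tables and a
#' pedigree), never both. All cascade thresholds are surfaced; nothing is
#' hidden beyond the published defaults.
#'
#' @param seed Integer seed, recorded in every output header.
#' @param simulation A [sim_config()], or a list of arguments for one, or
#'   `NULL` when real inputs are given.
#' @param inputs `NULL`, or a list with `affected` (paths), `control`
#'   (paths), `ped` (path), optional `db` (path to a key/freq TSV).
#' @param cascade A [cascade_config()].
#' @param n_screen_controls Population controls used for in-silico
#'   screening of surviving candidates (simulation mode).
#' @param physchem List with `edits` (labels) and `window` (odd integer or
#'   `"calibrate"`).
#' @param out_dir Output directory for the report bundle, or `NULL` to
#'   skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed,
                       simulation = list(),
                       inputs = NULL,
                       cascade = cascade_config(),
                       n_screen_controls = 1600L,
                       physchem = list(edits = c("L115R", "L116del"),
                                       window = "calibrate"),
                       out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(simulation) && !is.null(inputs))
    stop("exactly one of simulation or real inputs must be selected")
  if (is.null(simulation) && is.null(inputs))
    stop("exactly one of simulation or real inputs must be selected")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    simulation <- do.call(sim_config, c(list(seed = seed), simulation))
  structure(list(seed = as.integer(seed), simulation = simulation,
                 inputs = inputs, cascade = cascade,
                 n_screen_controls = as.integer(n_screen_controls),
                 physchem = physchem, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Thin front end over [run_config()]: top-level keys `seed`,
#' `simulation`, `inputs`, `cascade`, `n_screen_controls`, `physchem`,
#' `out_dir`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(seed = y$seed)
  if (!is.null(y$simulation)) args$simulation <- y$simulation
  if (!is.null(y$inputs)) { args$inputs <- y$inputs; args$simulation <- NULL }
  if (!is.null(y$cascade)) args$cascade <- do.call(cascade_config, y$cascade)
  if (!is.null(y$n_screen_controls))
    args$n_screen_controls <- y$n_screen_controls
  if (!is.null(y$physchem)) args$physchem <- y$physchem
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(run_config, args)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), "out_dir")], f, version = 2,
          compress = FALSE)
  unname(tools::md5sum(f))
}

write_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", seed),
               sprintf("# config_hash: %s", hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the end-to-end prioritization pipeline
#'
#' Simulation mode: simulate the cohort, run the filtering cascade,
#' genotype the surviving candidates in the whole pedigree
#' (germline-truth panel), test perfect segregation, screen candidates
#' against in-silico population controls (carrier draws from each
#' variant's true population frequency), shortlist, and compute the
#' CSPalpha physicochemical tables for the configured edits. Real-input
#' mode runs the same cascade on variant tables read from disk (no truth,
#' so segregation requires a supplied genotype panel and is skipped
#' otherwise).
#'
#' When `out_dir` is set, writes `trace.tsv`, `candidates.tsv`,
#' `segregation.tsv`, `shortlist.tsv`, `physchem.tsv` and `summary.txt`,
#' each stamped with the seed and a config hash; re-running with the same
#' config and seed is byte-identical.
#'
#' @param cfg A [run_config()].
#' @return List with `attrition`, `candidates`, `segregation`,
#'   `shortlist`, `physchem`, `truth` (simulation mode), `hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  sim <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- simulate_cohort(cfg$simulation)
    aff <- sim$exomes[cfg$simulation$sequenced_affected]
    ctl <- sim$exomes[intersect(cfg$simulation$sequenced_control,
                                names(sim$exomes))]
    db <- sim$db
    ped <- cfg$simulation$pedigree
    panel <- sim$panel
    panel_ex <- sim$panel_exomes
  } else {
    inp <- cfg$inputs
    aff <- lapply(inp$affected, read_variant_table, dialect = "tsv",
                  status = "affected")
    ctl <- lapply(inp$control %||% character(0), read_variant_table,
                  dialect = "tsv", status = "unaffected")
    db <- if (!is.null(inp$db))
      utils::read.delim(inp$db, comment.char = "#") else NULL
    ped <- if (!is.null(inp$ped)) read_pedigree(inp$ped) else NULL
    panel <- NULL
    panel_ex <- list()
  }

  res <- run_cascade(aff, ctl, db = db, cfg = cfg$cascade,
                     panel = panel_ex)

  # candidate table in the shape of the published summary table
  first <- res$exomes[[1]]$calls
  keys1 <- variant_key(first$chrom, first$pos, first$ref, first$alt)
  cand <- first[match(res$final_keys, keys1), , drop = FALSE]
  cand$key <- res$final_keys
  rownames(cand) <- NULL

  seg_df <- NULL
  screen_df <- NULL
  short <- NULL
  if (!is.null(panel) && !is.null(ped) && nrow(cand)) {
    set.seed(cfg$seed + 1L) # screening draws, distinct from simulation
    typed <- panel$genotypes$key
    seg <- vapply(cand$key, function(k) {
      if (k %in% typed) segregates(k, panel, ped) else "unknown"
    }, character(1))
    seg_df <- data.frame(key = cand$key, gene = cand$gene,
                         segregates = unname(seg),
                         stringsAsFactors = FALSE)
    pf <- sim$truth$origins$pop_freq[match(cand$key,
                                           sim$truth$origins$key)]
    n2 <- 2L * cfg$n_screen_controls
    carriers <- stats::rbinom(nrow(cand), n2, pf) # rare: ~1 allele/carrier
    screen_df <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      control_screen(cand$key[i], n_het = carriers[i],
                     n_controls = cfg$n_screen_controls)))
    cand$segregates <- seg_df$segregates
    short <- shortlist(cand, screen_df)
  }

  phys <- NULL
  if (!is.null(cfg$physchem)) {
    wt <- cspa_sequence()
    win <- cfg$physchem$window
    seg_rng <- c(110L, 120L)
    if (identical(win, "calibrate")) {
      cal <- calibrate_hydropathy_window(wt)
      win <- cal$window
      seg_rng <- c(cal$start, cal$end)
    }
    seqs <- c(list(wt = wt),
              stats::setNames(lapply(cfg$physchem$edits, apply_edit,
                                     seq = wt), cfg$physchem$edits))
    phys <- do.call(rbind, lapply(names(seqs), function(nm) {
      s <- seqs[[nm]]
      memb <- shifted_segment(s, 108L, 139L) # A108-K139 in edited coords
      pr <- hydropathy_profile(s, window = win)
      st <- segment_stats(pr, seg_rng[1], min(seg_rng[2], length(s)))
      data.frame(variant = nm,
                 kd_mean = st$mean, kd_sd = st$sd,
                 dg_interface = transfer_dG(s, memb[1], memb[2],
                                            "ww_interface")$total,
                 dg_octanol = transfer_dG(s, memb[1], memb[2],
                                          "ww_octanol")$total,
                 ddg_oct_minus_if = octanol_minus_interface(s, memb[1],
                                                            memb[2]),
                 stringsAsFactors = FALSE)
    }))
  }

  out <- list(attrition = res$attrition, candidates = cand,
              segregation = seg_df, screen = screen_df,
              shortlist = short, physchem = phys,
              truth = if (!is.null(sim)) sim$truth else NULL,
              seed = cfg$seed, hash = hash)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) if (!is.null(df))
      write_stamped(df, file.path(cfg$out_dir, name), cfg$seed, hash)
    w(res$attrition, "trace.tsv")
    w(cand[setdiff(names(cand), "db")], "candidates.tsv")
    w(seg_df, "segregation.tsv")
    w(short, "shortlist.tsv")
    w(phys, "physchem.tsv")
    summary_lines <- c(
      sprintf("# seed: %d", cfg$seed),
      sprintf("# config_hash: %s", hash),
      sprintf("candidates surviving cascade: %d", nrow(cand)),
      if (!is.null(short))
        sprintf("shortlist: %s",
                paste(short$gene, collapse = ", ")),
      if (!is.null(sim))
        sprintf("causal variant retained: %s",
                sim$truth$causal_key %in% cand$key))
    writeLines(summary_lines, file.path(cfg$out_dir, "summary.txt"))
  }
  out
}
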