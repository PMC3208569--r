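#' Protein sequence container
#'
#' A light 1-based container for an amino-acid sequence with optional domain
#' annotations. Only the 20 canonical residues are accepted.
#'
#' @param residues Character scalar (amino-acid string) or character vector
#'   of single residues.
#' @param id Sequence identifier.
#' @param domains Optional data frame with columns `domain`, `start`, `end`
#'   (1-based inclusive).
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(residues, id = "protein", domains = NULL) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), AA_CANONICAL)
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  if (!is.null(domains)) {
    stopifnot(all(c("domain", "start", "end") %in% names(domains)))
    if (any(domains$start < 1L) || any(domains$end > length(residues)))
      stop("domain bounds outside sequence")
  }
  structure(list(id = id, residues = residues, domains = domains,
                 edits = character(0), deleted = integer(0)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", length(x$residues), " aa)\n",
      sep = "")
  if (length(x$edits))
    cat("  edits applied:", paste(x$edits, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' @export
as.character.protein_sequence <- function(x, ...)
  paste(x$residues, collapse = "")

#' Read a protein sequence from FASTA
#'
#' Reads the first (or named) record of a plain-text FASTA file.
#'
#' @param path FASTA file.
#' @param id Optional record id to select; defaults to the first record.
#' @return A [protein_sequence()].
#' @export
read_protein_fasta <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  i <- if (is.null(id)) 1L else match(id, ids)
  if (is.na(i)) stop("record '", id, "' not found in ", path)
  from <- hdr[i] + 1L
  to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
  protein_sequence(paste(lines[from:to], collapse = ""), id = ids[i])
}

#' The bundled wild-type CSPalpha sequence
#'
#' Human cysteine-string protein alpha (DNAJC5 product, UniProt Q9H3Z4,
#' 198 aa) with its conserved domains annotated: J-domain (15-83), linker
#' (84-112), cysteine-string domain (113-136), and the experimentally
#' defined membrane-binding segment A108-K139.
#'
#' @return A [protein_sequence()].
#' @export
cspa_sequence <- function() {
  path <- system.file("extdata", "cspa_q9h3z4.fasta",
                      package = "anclxome", mustWork = TRUE)
  p <- read_protein_fasta(path)
  p$id <- "CSPalpha_Q9H3Z4"
  p$domains <- data.frame(
    domain = c("J-domain", "linker", "CSD", "membrane_segment"),
    start  = c(15L, 84L, 113L, 108L),
    end    = c(83L, 112L, 136L, 139L))
  p
}

#' Protein-level edits
#'
#' Constructors for the three edit kinds used throughout: a single
#' substitution (`p.L115R`), an in-frame deletion (`p.L116del`), and a
#' multi-site substitution over a residue range (`p.C113-119S`, replacing
#' every occurrence of the reference residue within the range).
#'
#' @param pos,start,end 1-based residue positions.
#' @param ref Expected reference residue (one letter).
#' @param alt Replacement residue (one letter).
#' @return An object of class `protein_edit`.
#' @export
edit_substitution <- function(pos, ref, alt) {
  stopifnot(pos >= 1L, nchar(ref) == 1L, nchar(alt) == 1L)
  structure(list(kind = "substitution", pos = as.integer(pos),
                 ref = toupper(ref), alt = toupper(alt),
                 label = sprintf("%s%d%s", toupper(ref), pos, toupper(alt))),
            class = "protein_edit")
}

#' @rdname edit_substitution
#' @export
edit_deletion <- function(start, end = start, ref = NULL) {
  stopifnot(start >= 1L, end >= start)
  structure(list(kind = "inframe_deletion", start = as.integer(start),
                 end = as.integer(end), ref = ref,
                 label = if (start == end) sprintf("%s%ddel",
                                                   ref %||% "", start)
                         else sprintf("%s%d_%ddel", ref %||% "", start, end)),
            class = "protein_edit")
}

#' @rdname edit_substitution
#' @export
edit_multi_substitution <- function(start, end, ref, alt) {
  stopifnot(start >= 1L, end >= start, nchar(ref) == 1L, nchar(alt) == 1L)
  structure(list(kind = "multi_substitution", start = as.integer(start),
                 end = as.integer(end), ref = toupper(ref),
                 alt = toupper(alt),
                 label = sprintf("%s%d-%d%s", toupper(ref), start, end,
                                 toupper(alt))),
            class = "protein_edit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a short protein-edit label
#'
#' Understands `"L115R"` (substitution), `"L116del"` (single-residue
#' in-frame deletion) and `"C113-119S"` (all reference residues in a range
#' replaced).
#'
#' @param x Label.
#' @return A `protein_edit`.
#' @export
parse_protein_edit <- function(x) {
  x <- sub("^p\\.", "", x)
  if (grepl("^[A-Za-z]\\d+-\\d+[A-Za-z]$", x)) {
    m <- regmatches(x, regexec("^([A-Za-z])(\\d+)-(\\d+)([A-Za-z])$", x))[[1]]
    return(edit_multi_substitution(as.integer(m[3]), as.integer(m[4]),
                                   m[2], m[5]))
  }
  if (grepl("^[A-Za-z]\\d+del$", x)) {
    m <- regmatches(x, regexec("^([A-Za-z])(\\d+)del$", x))[[1]]
    return(edit_deletion(as.integer(m[3]), ref = m[2]))
  }
  if (grepl("^[A-Za-z]\\d+[A-Za-z]$", x)) {
    m <- regmatches(x, regexec("^([A-Za-z])(\\d+)([A-Za-z])$", x))[[1]]
    return(edit_substitution(as.integer(m[3]), m[2], m[4]))
  }
  stop("cannot parse protein edit: '", x, "'")
}

#' Apply a protein edit
#'
#' Substitutions replace residues in place; in-frame deletions shorten the
#' sequence, shifting downstream residue numbering left. A reference
#' residue stated in the edit must match the sequence or an error naming
#' the position and expected residue is raised. The applied-edit log is
#' carried on the returned sequence.
#'
#' @param seq A [protein_sequence()].
#' @param edit A `protein_edit` (or a label understood by
#'   [parse_protein_edit()]).
#' @return The edited `protein_sequence`.
#' @examples
#' wt <- cspa_sequence()
#' m <- apply_edit(wt, "L115R")
#' m$residues[115]  # "R"
#' @export
apply_edit <- function(seq, edit) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (is.character(edit)) edit <- parse_protein_edit(edit)
  stopifnot(inherits(edit, "protein_edit"))
  res <- seq$residues
  check_ref <- function(pos, expected) {
    if (pos > length(res))
      stop("edit position ", pos, " beyond sequence length ", length(res))
    if (!is.null(expected) && res[pos] != expected)
      stop(sprintf("reference mismatch at position %d: expected %s, found %s",
                   pos, expected, res[pos]))
  }
  out <- switch(edit$kind,
    substitution = {
      check_ref(edit$pos, edit$ref)
      res[edit$pos] <- edit$alt
      res
    },
    inframe_deletion = {
      if (edit$end > length(res))
        stop("deletion end ", edit$end, " beyond sequence length")
      if (!is.null(edit$ref)) check_ref(edit$start, edit$ref)
      res[-(edit$start:edit$end)]
    },
    multi_substitution = {
      if (edit$end > length(res))
        stop("edit range end ", edit$end, " beyond sequence length")
      idx <- edit$start:edit$end
      hit <- idx[res[idx] == edit$ref]
      if (!length(hit))
        stop("no ", edit$ref, " residues in range ", edit$start, "-",
             edit$end)
      res[hit] <- edit$alt
      res
    },
    stop("unknown edit kind"))
  new <- seq
  new$residues <- out
  new$id <- paste0(seq$id, "_", edit$label)
  new$edits <- c(seq$edits, edit$label)
  # domain annotations are positional; drop them past a deletion, but
  # remember which original positions were removed so segments defined on
  # the unedited sequence can be mapped (see shifted_segment)
  if (edit$kind == "inframe_deletion") {
    new$domains <- NULL
    new$deleted <- c(seq$deleted, edit$start:edit$end)
  }
  new
}

#' Map an original-coordinate segment onto an edited sequence
#'
#' After an in-frame deletion, downstream residues shift left; a segment
#' defined on the unedited sequence (say the membrane segment A108-K139)
#' must shrink and shift accordingly. Substitutions leave coordinates
#' untouched.
#'
#' @param seq A [protein_sequence()], possibly edited.
#' @param start,end 1-based inclusive segment in the *original*
#'   coordinates.
#' @return Integer vector `c(start, end)` in the edited coordinates.
#' @examples
#' d <- apply_edit(cspa_sequence(), "L116del")
#' shifted_segment(d, 108, 139)  # c(108, 138)
#' @export
shifted_segment <- function(seq, start, end) {
  stopifnot(inherits(seq, "protein_sequence"), end >= start)
  del <- seq$deleted
  c(start - sum(del < start), end - sum(del <= end))
}

#' Map a coding-sequence position to its codon
#'
#' 1-based CDS nucleotide index to 1-based codon index plus within-codon
#' offset (1-3). c.344 falls in codon 115 at offset 2, which is why
#' c.344T>G produces p.L115R.
#'
#' @param cds_pos 1-based coding nucleotide position(s).
#' @return A data frame with columns `cds_pos`, `codon`, `offset`.
#' @export
codon_of_cds_position <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  stopifnot(all(cds_pos >= 1L))
  data.frame(cds_pos = cds_pos,
             codon = (cds_pos - 1L) %/% 3L + 1L,
             offset = (cds_pos - 1L) %% 3L + 1L)
}

#' Classify a coding deletion by frame effect
#'
#' A deletion whose length is not a multiple of 3 shifts the reading frame.
#' In-frame deletions are classified as removing one codon or spanning
#' several; codon-boundary alignment is reported separately, since an
#' in-frame deletion need not start at offset 1.
#'
#' @param del_start,del_end 1-based CDS positions of the deleted range
#'   (inclusive).
#' @return List with `class` (one of `"frameshift"`,
#'   `"inframe_single_codon"`, `"inframe_multi_codon"`), `length`,
#'   `n_codons_removed`, `codon_start`, `codon_end`, `codon_aligned`.
#' @examples
#' inframe_check(346, 348)$class  # in-frame single codon (codon 116)
#' @export
inframe_check <- function(del_start, del_end) {
  stopifnot(del_start >= 1L, del_end >= del_start)
  len <- del_end - del_start + 1L
  cs <- codon_of_cds_position(del_start)
  ce <- codon_of_cds_position(del_end)
  aligned <- cs$offset == 1L && ce$offset == 3L
  cls <- if (len %% 3L != 0L) "frameshift"
         else if (len == 3L) "inframe_single_codon"
         else "inframe_multi_codon"
  list(class = cls, length = len, n_codons_removed = len %/% 3L,
       codon_start = cs$codon, codon_end = ce$codon,
       codon_aligned = aligned)
}

#' Windowed hydropathy profile
#'
#' Per-residue profile: the mean of scale values over a centered window of
#' odd size. At the termini the window is truncated to the residues that
#' exist (edge policy recorded on the object), so the profile has one value
#' per residue.
#'
#' @param seq A [protein_sequence()].
#' @param scale Scale name passed to [hydropathy_scale()].
#' @param window Odd window size (1 returns raw scale values).
#' @return Object of class `hydropathy_profile` with fields `scale`,
#'   `window`, `values` (named by position), `seq_id`, `edge_policy`.
#' @export
hydropathy_profile <- function(seq, scale = "kyte_doolittle", window = 9L) {
  stopifnot(inherits(seq, "protein_sequence"))
  window <- as.integer(window)
  n <- length(seq$residues)
  if (window < 1L || window %% 2L == 0L || window > n)
    stop("window must be odd, >= 1 and <= sequence length")
  sc <- hydropathy_scale(scale)
  v <- unname(sc[seq$residues])
  h <- (window - 1L) %/% 2L
  vals <- vapply(seq_len(n), function(i)
    mean(v[max(1L, i - h):min(n, i + h)]), numeric(1))
  structure(list(scale = scale, window = window,
                 values = stats::setNames(vals, seq_len(n)),
                 seq_id = seq$id, edge_policy = "truncate"),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat("<hydropathy_profile> ", x$seq_id, ": ", x$scale, ", window ",
      x$window, " (edges ", x$edge_policy, "), ", length(x$values),
      " residues\n", sep = "")
  invisible(x)
}

#' Mean and standard deviation of a profile segment
#'
#' @param profile A [hydropathy_profile()].
#' @param start,end 1-based inclusive residue range.
#' @return List with `mean`, `sd` (sample sd), `n`.
#' @export
segment_stats <- function(profile, start, end) {
  stopifnot(inherits(profile, "hydropathy_profile"),
            start >= 1L, end >= start, end <= length(profile$values))
  v <- profile$values[start:end]
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Calibrate the hydropathy windowing convention
#'
#' The windowed-profile convention behind a published segment mean is often
#' unstated (window size; exactly which profile positions were averaged).
#' This utility scans odd windows and small extensions of the averaging
#' segment's edges, scoring each convention by the total absolute deviation
#' of the wild-type, L115R and L116del segment means from the supplied
#' target values, and returns the best match.
#'
#' For the bundled CSPalpha sequence the scan selects window 9 averaged
#' over profile positions 105-120, which reproduces the wild-type mean to
#' three decimals.
#'
#' @param seq Wild-type [protein_sequence()].
#' @param targets Numeric of length 3: target means for wild type, L115R
#'   and L116del.
#' @param segment Nominal 1-based segment, default `c(110, 120)`.
#' @param windows Odd window sizes to scan.
#' @param edge_slack Maximum number of residues by which each segment edge
#'   may be extended outward during the scan.
#' @return List with `window`, `start`, `end`, `means`, `score`.
#' @export
calibrate_hydropathy_window <- function(seq = cspa_sequence(),
                                        targets = c(1.699, 1.181, 1.559),
                                        segment = c(110L, 120L),
                                        windows = seq(1L, 13L, 2L),
                                        edge_slack = 6L) {
  stopifnot(length(targets) == 3L)
  m115 <- apply_edit(seq, "L115R")
  m116 <- apply_edit(seq, "L116del")
  best <- NULL
  for (w in windows) {
    p0 <- hydropathy_profile(seq, window = w)$values
    p5 <- hydropathy_profile(m115, window = w)$values
    p6 <- hydropathy_profile(m116, window = w)$values
    for (s in (segment[1] - edge_slack):segment[1]) {
      if (s < 1L) next
      for (e in segment[2]:(segment[2] + edge_slack)) {
        if (e > length(p6)) next
        m <- c(mean(p0[s:e]), mean(p5[s:e]), mean(p6[s:e]))
        score <- sum(abs(m - targets))
        if (is.null(best) || score < best$score)
          best <- list(window = w, start = s, end = e,
                       means = stats::setNames(m, c("wt", "L115R",
                                                    "L116del")),
                       score = score)
      }
    }
  }
  best
}

#' Whole-residue membrane-transfer free energy of a segment
#'
#' Sums Wimley-White whole-residue transfer free energies over an inclusive
#' segment. Negative totals on the interface scale mean favorable transfer
#' from water to the bilayer interface. Values are scale-native kcal/mol.
#'
#' @param seq A [protein_sequence()].
#' @param start,end 1-based inclusive segment; `end < start` gives an empty
#'   segment with total 0.
#' @param scale `"ww_interface"` or `"ww_octanol"`.
#' @return Object of class `transfer_energy`: `segment`, `scale`, `total`,
#'   `contributions` (named per residue position).
#' @examples
#' wt <- cspa_sequence()
#' transfer_dG(wt, 108, 139, "ww_interface")$total  # -5.69
#' @export
transfer_dG <- function(seq, start, end,
                        scale = c("ww_interface", "ww_octanol")) {
  stopifnot(inherits(seq, "protein_sequence"))
  scale <- match.arg(scale)
  if (end < start) {
    return(structure(list(segment = c(start, end), scale = scale,
                          total = 0, contributions = numeric(0)),
                     class = "transfer_energy"))
  }
  stopifnot(start >= 1L, end <= length(seq$residues))
  sc <- hydropathy_scale(scale)
  contr <- stats::setNames(unname(sc[seq$residues[start:end]]), start:end)
  structure(list(segment = c(start, end), scale = scale,
                 total = sum(contr), contributions = contr),
            class = "transfer_energy")
}

#' @export
print.transfer_energy <- function(x, ...) {
  cat("<transfer_energy> ", x$scale, " over ", x$segment[1], "-",
      x$segment[2], ": total ", sprintf("%.2f", x$total),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Octanol-minus-interface free-energy difference
#'
#' The difference between the water-to-octanol and water-to-interface
#' transfer free energies of a segment. Larger values indicate a segment
#' that prefers water over a transbilayer-helix conformation, i.e. weaker
#' intrinsic membrane affinity.
#'
#' @inheritParams transfer_dG
#' @return Numeric scalar (kcal/mol, scale-native).
#' @export
octanol_minus_interface <- function(seq, start, end) {
  transfer_dG(seq, start, end, "ww_octanol")$total -
    transfer_dG(seq, start, end, "ww_interface")$total
}

#' Percent reduction of a splice-site consensus value
#'
#' @param wt_cv Wild-type consensus value (> 0).
#' @param mut_cv Mutant consensus value.
#' @return Percent reduction, `100 * (wt - mut) / wt`.
#' @examples
#' splice_cv_reduction(69.84, 36)  # 48.45
#' @export
splice_cv_reduction <- function(wt_cv, mut_cv) {
  stopifnot(wt_cv > 0)
  100 * (wt_cv - mut_cv) / wt_cv
}

#' Dunn's post-hoc pairwise rank tests
#'
#' Classical Dunn procedure after a Kruskal-Wallis test: pairwise z
#' statistics on mean ranks with tie correction, two-sided p values, and
#' Bonferroni adjustment over the number of pairwise comparisons.
#'
#' @param x Numeric vector of values.
#' @param g Group labels (coerced to factor).
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`, `significant`.
#' @export
dunn_test <- function(x, g, alpha = 0.05) {
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2L)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tiecorr <- sum(ties^3 - ties) / (N^3 - N)
  sig2 <- (N * (N + 1) / 12) * (1 - tiecorr)
  pairs <- utils::combn(levels(g), 2)
  k <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_)
  for (j in seq_len(k)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    z <- (rbar[[a]] - rbar[[b]]) / sqrt(sig2 * (1 / n[[a]] + 1 / n[[b]]))
    p <- 2 * stats::pnorm(-abs(z))
    res$z[j] <- z
    res$p[j] <- p
    res$p_adj[j] <- min(1, p * k)
  }
  res$significant <- res$p_adj < alpha
  res
}

#' Nonparametric comparison of labeled value groups
#'
#' Kruskal-Wallis rank test with tie correction (via
#' [stats::kruskal.test()]) followed by [dunn_test()] pairwise
#' comparisons. Used to compare windowed hydropathy values of wild-type and
#' mutant segments.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param alpha Significance level.
#' @return List with `statistic` (Kruskal-Wallis H), `df`, `p.value`,
#'   `dunn` (pairwise data frame), `alpha`.
#' @export
compare_variant_profiles <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 2L))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  kw <- stats::kruskal.test(x, factor(g))
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, dunn = dunn_test(x, g, alpha = alpha),
       alpha = alpha)
}
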