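#' Pedigree container
#'
#' A pedigree is a data frame of members with columns `id`, `father`,
#' `mother` (NA for founders), `sex` (`"male"`, `"female"`, `"unknown"`)
#' and `status` (`"affected"`, `"unaffected"`, `"unknown"`). Parent
#' references must resolve to members and no individual may be its own
#' ancestor.
#'
#' @param members Data frame as described above.
#' @return Object of class `pedigree`.
#' @export
pedigree <- function(members) {
  stopifnot(is.data.frame(members),
            all(c("id", "father", "mother", "sex", "status") %in%
                  names(members)))
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  if (anyDuplicated(members$id))
    stop("duplicate member id(s): ",
         paste(unique(members$id[duplicated(members$id)]), collapse = ", "))
  for (col in c("father", "mother")) {
    ref <- members[[col]]
    unresolved <- !is.na(ref) & !ref %in% members$id
    if (any(unresolved))
      stop("structural error: unresolved ", col, " reference(s): ",
           paste(ref[unresolved], collapse = ", "))
  }
  ped <- structure(list(members = members), class = "pedigree")
  # cycle check: generation depth must be computable
  invisible(vapply(members$id, function(i) ped_depth(ped, i), numeric(1)))
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  m <- x$members
  cat("<pedigree> ", nrow(m), " members (",
      sum(m$status == "affected"), " affected, ",
      sum(m$status == "unaffected"), " unaffected)\n", sep = "")
  invisible(x)
}

ped_member <- function(ped, id) {
  i <- match(id, ped$members$id)
  if (is.na(i)) stop("unknown pedigree member: ", id)
  ped$members[i, ]
}

ped_depth <- function(ped, id, seen = character(0)) {
  if (id %in% seen)
    stop("structural error: cyclic parentage involving ", id)
  m <- ped_member(ped, id)
  f <- m$father; mo <- m$mother
  if (is.na(f) && is.na(mo)) return(0)
  d <- 0
  if (!is.na(f)) d <- max(d, ped_depth(ped, f, c(seen, id)) + 1)
  if (!is.na(mo)) d <- max(d, ped_depth(ped, mo, c(seen, id)) + 1)
  d
}

#' Read a 6-column PED file
#'
#' Standard PED columns: family id, individual id, father id, mother id,
#' sex (1 male, 2 female, other unknown), phenotype (1 unaffected,
#' 2 affected, other unknown). `0` parent ids denote founders. Lines
#' starting with `#` are ignored.
#'
#' @param path PED file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L)
    stop("format error: PED requires 6 columns, found ", ncol(tab))
  names(tab)[1:6] <- c("fam", "id", "father", "mother", "sex", "phen")
  members <- data.frame(
    id = as.character(tab$id),
    father = ifelse(tab$father %in% c("0", 0), NA_character_,
                    as.character(tab$father)),
    mother = ifelse(tab$mother %in% c("0", 0), NA_character_,
                    as.character(tab$mother)),
    sex = c("male", "female")[match(tab$sex, 1:2)],
    status = c("unaffected", "affected")[match(tab$phen, 1:2)],
    stringsAsFactors = FALSE)
  members$sex[is.na(members$sex)] <- "unknown"
  members$status[is.na(members$status)] <- "unknown"
  pedigree(members)
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @param fam Family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, fam = "FAM1") {
  m <- ped$members
  tab <- data.frame(
    fam = fam, id = m$id,
    father = ifelse(is.na(m$father), "0", m$father),
    mother = ifelse(is.na(m$mother), "0", m$mother),
    sex = match(m$sex, c("male", "female"), nomatch = 0L),
    phen = match(m$status, c("unaffected", "affected"), nomatch = 0L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Kinship coefficient
#'
#' Probability that a random allele drawn from `a` is identical by descent
#' with one drawn from `b`, computed by the standard recursion over
#' parents: phi(i,i) = 1/2 + phi(f,m)/2 and, for i not an ancestor of j,
#' phi(i,j) = (phi(f_i,j) + phi(m_i,j))/2, with phi = 0 when a parent is
#' missing (founder).
#'
#' @param ped A [pedigree()].
#' @param a,b Member ids.
#' @return Numeric kinship coefficient. Siblings give 1/4, first cousins
#'   1/16, unrelated founders 0, self 1/2 (outbred).
#' @export
kinship <- function(ped, a, b) {
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    mi <- ped_member(ped, i); mj <- ped_member(ped, j)
    val <- if (i == j) {
      0.5 + 0.5 * phi(mi$father, mi$mother)
    } else {
      # recurse on the deeper individual: it cannot be the other's ancestor
      di <- ped_depth(ped, i); dj <- ped_depth(ped, j)
      if (di < dj) { tmp <- mi; mi <- mj; mj <- tmp }
      if (is.na(mi$father) && is.na(mi$mother)) 0
      else 0.5 * (phi(mi$father, mj$id) + phi(mi$mother, mj$id))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Relationship predicates
#'
#' `is_sibling`: the two members share both (non-missing) parents.
#' `is_first_cousin`: not siblings, and one parent of `a` is a sibling of
#' one parent of `b`.
#'
#' @param ped A [pedigree()].
#' @param a,b Member ids.
#' @return Logical scalar.
#' @export
is_sibling <- function(ped, a, b) {
  ma <- ped_member(ped, a); mb <- ped_member(ped, b)
  if (a == b) return(FALSE)
  !is.na(ma$father) && !is.na(ma$mother) &&
    identical(ma$father, mb$father) && identical(ma$mother, mb$mother)
}

#' @rdname is_sibling
#' @export
is_first_cousin <- function(ped, a, b) {
  if (a == b || is_sibling(ped, a, b)) return(FALSE)
  pa <- unlist(ped_member(ped, a)[c("father", "mother")])
  pb <- unlist(ped_member(ped, b)[c("father", "mother")])
  pa <- pa[!is.na(pa)]; pb <- pb[!is.na(pb)]
  any(outer(pa, pb, Vectorize(function(x, y) is_sibling(ped, x, y))))
}

#' Expected rare-variant sharing fraction
#'
#' For a rare variant carried (heterozygously) by `a`, the probability that
#' `b` also carries it is twice the kinship coefficient: 0.5 for siblings,
#' 0.125 for first cousins, 1 for self.
#'
#' @param ped A [pedigree()].
#' @param a,b Member ids.
#' @return Numeric fraction in [0, 1].
#' @export
expected_sharing <- function(ped, a, b) {
  min(1, 2 * kinship(ped, a, b))
}

#' The study-design pedigree
#'
#' A three-generation autosomal-dominant pedigree mirroring the sequencing
#' design: two affected first cousins (`a1`, `a2`) are the sequenced cases
#' (expected genome sharing 1/8), the elderly unaffected sibling of `a1`
#' (`u1`) is the sequenced control, and the extended family provides three
#' affected and three unaffected members for segregation genotyping.
#' Affected parents `p1`, `p2` (siblings) connect the cousins to the
#' founder generation.
#'
#' @return A [pedigree()].
#' @export
ancl_study_pedigree <- function() {
  pedigree(data.frame(
    id     = c("gp1", "gp2", "sp1", "sp2", "p1", "p2", "a1", "u1", "u3",
               "a2", "a3", "u2"),
    father = c(NA, NA, NA, NA, "gp1", "gp1", "p1", "p1", "p1", "p2", "p2",
               "p2"),
    mother = c(NA, NA, NA, NA, "gp2", "gp2", "sp1", "sp1", "sp1", "sp2",
               "sp2", "sp2"),
    sex    = c("male", "female", "female", "female", "male", "male",
               "male", "female", "female", "male", "male", "female"),
    status = c("affected", "unaffected", "unaffected", "unaffected",
               "affected", "affected", "affected", "unaffected",
               "unaffected", "affected", "affected", "unaffected"),
    stringsAsFactors = FALSE))
}
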