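# Kinship and inbreeding at maximal genealogical depth.
#
# phi(a,a)   = (1 + phi(father_a, mother_a)) / 2
# phi(a,b)   = (phi(father_u, v) + phi(mother_u, v)) / 2, recursing through
#              whichever of a,b has the larger generation index (it cannot be
#              an ancestor of the other); unknown parents contribute 0.
# F_a        = phi(father_a, mother_a)
#
# The recursion is memoized in C++ (src/kinship.cpp); no depth truncation is
# applied, so coefficients always use the full known pedigree.

#' Kinship coefficient between two individuals
#'
#' @param ped a [pedigree()]
#' @param a,b individual ids (may be equal: the self-kinship (1 + F)/2)
#' @return kinship coefficient in `[0, 1]`
#' @examples
#' ped <- pedigree(data.frame(
#'   id = 1:8,
#'   father = c(0, 0, 1, 1, 0, 0, 3, 4),
#'   mother = c(0, 0, 2, 2, 0, 0, 5, 6),
#'   sex = c("M", "F", "M", "M", "F", "F", "M", "F")))
#' kinship(ped, 7, 8)  # first cousins: 0.0625
#' @export
kinship <- function(ped, a, b) {
  ra <- .row_of(ped, a)
  rb <- .row_of(ped, b)
  .kin_pairs_cpp(ped$fa_idx, ped$mo_idx, ped$gen, ra, rb)[1]
}

#' Inbreeding coefficient
#'
#' `F_a` is the kinship coefficient of `a`'s parents; 0 when either parent is
#' unknown.
#'
#' @param ped a [pedigree()]
#' @param a individual id(s)
#' @return numeric vector of inbreeding coefficients
#' @export
inbreeding <- function(ped, a) {
  rows <- .row_of(ped, a)
  .inbreeding_cpp(ped$fa_idx, ped$mo_idx, ped$gen, rows)
}

#' Kinship matrix over a set of individuals
#'
#' @param ped a [pedigree()]
#' @param ids non-empty id vector
#' @return a `kinship_matrix`: symmetric numeric matrix with ids as
#'   dimnames; diagonal entries are `(1 + F_i) / 2`.
#' @export
kinship_matrix <- function(ped, ids) {
  if (!length(ids)) stop("ids must be non-empty")
  rows <- .row_of(ped, ids)
  m <- .kin_matrix_cpp(ped$fa_idx, ped$mo_idx, ped$gen, rows)
  dimnames(m) <- list(as.character(ids), as.character(ids))
  class(m) <- c("kinship_matrix", class(m))
  m
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", nrow(x), " individuals; mean off-diagonal phi = ",
      signif(mean(x[upper.tri(x)]), 4), "\n", sep = "")
  invisible(x)
}

#' Mean pairwise kinship over a set
#'
#' Mean of phi over all unordered pairs; when the number of pairs exceeds
#' `max_pairs` an unbiased random subset of pairs of that size is used
#' (seeded by the caller's RNG state).
#'
#' @param ped a [pedigree()]
#' @param ids id vector (>= 2)
#' @param max_pairs cap on the number of pairs evaluated
#' @return mean kinship (NA when fewer than 2 ids)
#' @export
mean_pairwise_kinship <- function(ped, ids, max_pairs = Inf) {
  if (length(ids) < 2) return(NA_real_)
  rows <- .row_of(ped, ids)
  n <- length(rows)
  npair <- n * (n - 1) / 2
  if (npair <= max_pairs) {
    return(.kin_mean_cpp(ped$fa_idx, ped$mo_idx, ped$gen, rows))
  }
  k <- sample.int(npair, max_pairs)
  # unrank unordered pairs (i < j) from linear index, column-major over j
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  i <- k - (j - 1) * (j - 2) / 2
  mean(.kin_pairs_cpp(ped$fa_idx, ped$mo_idx, ped$gen, rows[i], rows[j]))
}

#' Exact path-counting kinship oracle
#'
#' Independent of the recursive engine: enumerates every upward path from
#' each individual to each common ancestor `A` and sums
#' `(1/2)^(n + m + 1) * (1 + F_A)` over path pairs that share no individual
#' other than `A`. All terms are dyadic rationals, represented exactly in
#' doubles. Intended for small test pedigrees only.
#'
#' @param ped a [pedigree()] with at most `max_n` individuals
#' @param a,b individual ids
#' @param max_n size guard (default 25)
#' @return kinship coefficient
#' @export
kinship_oracle_paths <- function(ped, a, b, max_n = 25L) {
  if (nrow(ped$ind) > max_n) stop("oracle restricted to small pedigrees")
  ra <- .row_of(ped, a)
  rb <- .row_of(ped, b)
  if (ra == rb) {
    f <- ped$fa_idx[ra]; m <- ped$mo_idx[ra]
    Fa <- if (f > 0L && m > 0L)
      kinship_oracle_paths(ped, ped$ind$id[f], ped$ind$id[m], max_n) else 0
    return((1 + Fa) / 2)
  }
  pa <- .up_paths(ped, ra)
  pb <- .up_paths(ped, rb)
  ends_a <- vapply(pa, function(p) p[length(p)], integer(1))
  ends_b <- vapply(pb, function(p) p[length(p)], integer(1))
  common <- intersect(ends_a, ends_b)
  tot <- 0
  for (A in common) {
    f <- ped$fa_idx[A]; m <- ped$mo_idx[A]
    FA <- if (f > 0L && m > 0L)
      kinship_oracle_paths(ped, ped$ind$id[f], ped$ind$id[m], max_n) else 0
    for (p1 in pa[ends_a == A]) {
      for (p2 in pb[ends_b == A]) {
        if (length(intersect(p1[-length(p1)], p2[-length(p2)])) == 0L) {
          tot <- tot + 0.5^(length(p1) + length(p2) - 1) * (1 + FA)
        }
      }
    }
  }
  tot
}

# all upward paths (node row sequences, starting at r) to every ancestor-or-self
.up_paths <- function(ped, r) {
  out <- list()
  walk <- function(path) {
    out[[length(out) + 1L]] <<- path
    tip <- path[length(path)]
    for (p in c(ped$fa_idx[tip], ped$mo_idx[tip])) {
      if (p > 0L) walk(c(path, p))
    }
  }
  walk(r)
  out
}

#' Write a kinship matrix to CSV
#'
#' @param km a `kinship_matrix`
#' @param path output path
#' @param format `"long"` (columns id_a, id_b, phi; unordered pairs incl.
#'   diagonal) or `"square"`
#' @return `path`, invisibly
#' @export
write_kinship <- function(km, path, format = c("long", "square")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(id = rownames(km), as.data.frame(unclass(km)[, , drop = FALSE]),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(upper.tri(km, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id_a = rownames(km)[idx[, 1]],
                     id_b = colnames(km)[idx[, 2]],
                     phi = km[idx])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a kinship matrix written by [write_kinship()]
#'
#' @param path CSV path (either format; detected from the header)
#' @return a `kinship_matrix`
#' @export
read_kinship <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(names(df)[1:3], c("id_a", "id_b", "phi"))) {
    ids <- unique(c(df$id_a, df$id_b))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(df$id_a, ids), match(df$id_b, ids))] <- df$phi
    m[cbind(match(df$id_b, ids), match(df$id_a, ids))] <- df$phi
  } else {
    ids <- df$id
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(ids, ids)
  }
  class(m) <- c("kinship_matrix", class(m))
  m
}
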