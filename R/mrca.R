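# Most recent common ancestors of proband pairs.
#
# "Most recent" is defined by the descent partial order, not by meiotic
# distance: a common ancestor C of a pair is an MRCA iff no strict descendant
# of C is also a common ancestor of the pair. Because the common-ancestor set
# S is upward-closed (every ancestor of a common ancestor is one), C fails
# the test exactly when C is a parent of some member of S, so the MRCA set is
# S minus the parents of members of S.
#
# Each MRCA record carries the minimal meiotic distance (shortest upward path
# from each proband, summed) and the genetic contribution (GC) to each
# proband: the sum over distinct downward paths of (1/2)^path length.

# per-proband ancestry info: strict-ancestor rows (sorted), minimal depth and
# genetic contribution per ancestor, aligned with `anc`
.proband_anc_info <- function(ped, row) {
  anc <- .ancestor_rows(ped, row)
  nodes <- c(row, anc)
  o <- order(ped$gen[nodes], decreasing = TRUE)  # descendants first
  nodes <- nodes[o]
  pos <- integer(nrow(ped$ind))
  pos[nodes] <- seq_along(nodes)
  d <- rep.int(NA_integer_, length(nodes))
  g <- numeric(length(nodes))
  d[pos[row]] <- 0L
  g[pos[row]] <- 1
  for (i in seq_along(nodes)) {
    x <- nodes[i]
    for (p in c(ped$fa_idx[x], ped$mo_idx[x])) {
      if (p > 0L) {
        j <- pos[p]
        dj <- d[i] + 1L
        if (is.na(d[j]) || dj < d[j]) d[j] <- dj
        g[j] <- g[j] + 0.5 * g[i]
      }
    }
  }
  keep <- match(anc, nodes)
  list(anc = anc, depth = d[keep], gc = g[keep])
}

#' Common ancestors of two individuals
#'
#' Strict ancestors shared by `a` and `b`. When one of the two is itself an
#' ancestor of the other it is reported as a common ancestor as well (the
#' genealogical link passes through it).
#'
#' @param ped a [pedigree()]
#' @param a,b distinct individual ids
#' @return integer vector of ids (possibly empty)
#' @export
common_ancestors <- function(ped, a, b) {
  ra <- .row_of(ped, a); rb <- .row_of(ped, b)
  if (ra == rb) stop("a and b must differ")
  A <- .ancestor_rows(ped, ra)
  B <- .ancestor_rows(ped, rb)
  rows <- intersect(A, B)
  if (ra %in% B) rows <- union(rows, ra)
  if (rb %in% A) rows <- union(rows, rb)
  sort(ped$ind$id[rows])
}

#' MRCA set of a pair with distances and genetic contributions
#'
#' @param ped a [pedigree()]
#' @param a,b distinct individual ids
#' @return data frame with one row per MRCA: `ancestor`, `min_meioses`,
#'   `gc_to_first`, `gc_to_second`, `gc_product`. When one proband is an
#'   ancestor of the other, that proband is the sole MRCA (its GC to itself
#'   is 1). Unrelated pairs give zero rows.
#' @export
mrca_set <- function(ped, a, b) {
  ra <- .row_of(ped, a); rb <- .row_of(ped, b)
  if (ra == rb) stop("a and b must differ")
  ia <- .proband_anc_info(ped, ra)
  ib <- .proband_anc_info(ped, rb)
  .mrca_records(ped, ra, rb, ia, ib)
}

.mrca_records <- function(ped, ra, rb, ia, ib) {
  empty <- data.frame(ancestor = integer(0), min_meioses = integer(0),
                      gc_to_first = numeric(0), gc_to_second = numeric(0),
                      gc_product = numeric(0))
  if (ra %in% ib$anc || rb %in% ia$anc) {
    if (ra %in% ib$anc) {
      k <- match(ra, ib$anc)
      rec <- data.frame(ancestor = ped$ind$id[ra], min_meioses = ib$depth[k],
                        gc_to_first = 1, gc_to_second = ib$gc[k])
    } else {
      k <- match(rb, ia$anc)
      rec <- data.frame(ancestor = ped$ind$id[rb], min_meioses = ia$depth[k],
                        gc_to_first = ia$gc[k], gc_to_second = 1)
    }
    rec$gc_product <- rec$gc_to_first * rec$gc_to_second
    return(rec)
  }
  S <- intersect(ia$anc, ib$anc)
  if (!length(S)) return(empty)
  par_S <- c(ped$fa_idx[S], ped$mo_idx[S])
  M <- setdiff(S, par_S[par_S > 0L])
  ka <- match(M, ia$anc); kb <- match(M, ib$anc)
  rec <- data.frame(ancestor = ped$ind$id[M],
                    min_meioses = ia$depth[ka] + ib$depth[kb],
                    gc_to_first = ia$gc[ka],
                    gc_to_second = ib$gc[kb])
  rec$gc_product <- rec$gc_to_first * rec$gc_to_second
  rec[order(rec$min_meioses, rec$ancestor), , drop = FALSE]
}

#' Genetic contribution of an ancestor to a descendant
#'
#' Sum over all distinct downward genealogical paths of `(1/2)^path length`
#' (each parent transmits half its genome to each child).
#'
#' @param ped a [pedigree()]
#' @param ancestor,descendant individual ids
#' @param strict error (`TRUE`) or return 0 (`FALSE`, default) when
#'   `ancestor` is not an ancestor of `descendant`
#' @return expected genome fraction in `(0, 1]` (or 0, see `strict`)
#' @export
genetic_contribution <- function(ped, ancestor, descendant, strict = FALSE) {
  rA <- .row_of(ped, ancestor)
  rD <- .row_of(ped, descendant)
  info <- .proband_anc_info(ped, rD)
  k <- match(rA, info$anc)
  if (is.na(k)) {
    if (strict) stop(ancestor, " is not an ancestor of ", descendant)
    return(0)
  }
  info$gc[k]
}

#' Sum of MRCA genetic-contribution products for a pair
#'
#' @inheritParams mrca_set
#' @return sum over the pair's MRCAs of `gc_to_first * gc_to_second`
#'   (0 for unrelated pairs)
#' @export
gc_product_sum <- function(ped, a, b) {
  sum(mrca_set(ped, a, b)$gc_product)
}

#' Bootstrap-averaged MRCA curves for a proband group
#'
#' For every unordered pair of the group's probands, MRCAs are enumerated and
#' binned by minimal meiotic distance; an ancestor serving several pairs is
#' counted once per pair. Groups are resampled down to `boot_n` subjects
#' (without replacement) `boot_reps` times and the per-pair mean cumulative
#' MRCA count and per-bin (non-cumulative) GC-product sum are averaged over
#' replicates. Replicate `r` reseeds the RNG with
#' `(seed + 982451653 * r) mod (2^31 - 1)` so curves are exactly
#' reproducible.
#'
#' @param ped a [pedigree()] with proband groups
#' @param group group label
#' @param max_meioses largest meiotic distance binned (default 30)
#' @param boot_n bootstrap subsample size (default 47)
#' @param boot_reps number of replicates (default 1000)
#' @param seed master seed (default 1)
#' @return an object of class `mrca_curve`: data frame `group, meioses,
#'   cum_count_mean, cum_count_low, cum_count_high, gc_sum_mean, gc_sum_low,
#'   gc_sum_high, cum_count_sum_mean` (low/high are 2.5/97.5% bootstrap
#'   quantiles; `*_sum_mean` is the raw per-replicate sum over pairs).
#'   Attributes: `n_probands`, `boot_n`, `boot_reps`, `seed`, `subsampled`.
#' @export
group_curves <- function(ped, group, max_meioses = 30L, boot_n = 47L,
                         boot_reps = 1000L, seed = 1L) {
  pro <- as.integer(names(ped$group_of)[!is.na(ped$group_of) & ped$group_of == group])
  if (!length(pro)) stop("unknown group: ", group)
  n <- length(pro)
  subsampled <- n > boot_n
  if (!subsampled) boot_reps <- 1L
  rows <- .row_of(ped, pro)
  info <- lapply(rows, function(r) .proband_anc_info(ped, r))
  npair <- n * (n - 1L) / 2L
  cnt <- matrix(0, npair, max_meioses)   # per-pair MRCA count by meioses
  gcs <- matrix(0, npair, max_meioses)   # per-pair GC-product sum by meioses
  pi_ <- integer(npair); pj_ <- integer(npair)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      pi_[k] <- i; pj_[k] <- j
      rec <- .mrca_records(ped, rows[i], rows[j], info[[i]], info[[j]])
      if (nrow(rec)) {
        m <- pmin(rec$min_meioses, max_meioses)
        m[m < 1L] <- 1L
        cnt[k, ] <- cnt[k, ] + tabulate(m, nbins = max_meioses)
        gcs[k, ] <- gcs[k, ] + vapply(seq_len(max_meioses), function(b)
          sum(rec$gc_product[m == b]), numeric(1))
      }
    }
  }
  ccum <- t(apply(cnt, 1L, cumsum))
  if (npair == 1L) ccum <- matrix(ccum, nrow = 1L)
  reps_cc <- matrix(0, boot_reps, max_meioses)
  reps_gc <- matrix(0, boot_reps, max_meioses)
  reps_ccsum <- matrix(0, boot_reps, max_meioses)
  for (r in seq_len(boot_reps)) {
    if (subsampled) {
      set.seed((seed + 982451653 * r) %% (2^31 - 1))
      sel <- sort(sample.int(n, boot_n))
    } else sel <- seq_len(n)
    mask <- pi_ %in% sel & pj_ %in% sel
    reps_cc[r, ] <- colMeans(ccum[mask, , drop = FALSE])
    reps_gc[r, ] <- colMeans(gcs[mask, , drop = FALSE])
    reps_ccsum[r, ] <- colSums(ccum[mask, , drop = FALSE])
  }
  out <- data.frame(
    group = group, meioses = seq_len(max_meioses),
    cum_count_mean = colMeans(reps_cc),
    cum_count_low = apply(reps_cc, 2L, stats::quantile, 0.025),
    cum_count_high = apply(reps_cc, 2L, stats::quantile, 0.975),
    gc_sum_mean = colMeans(reps_gc),
    gc_sum_low = apply(reps_gc, 2L, stats::quantile, 0.025),
    gc_sum_high = apply(reps_gc, 2L, stats::quantile, 0.975),
    cum_count_sum_mean = colMeans(reps_ccsum),
    stringsAsFactors = FALSE)
  structure(out, class = c("mrca_curve", "data.frame"),
            n_probands = n, boot_n = if (subsampled) boot_n else n,
            boot_reps = boot_reps, seed = seed, subsampled = subsampled)
}

#' @export
print.mrca_curve <- function(x, ...) {
  cat("<mrca_curve> group ", x$group[1], ": ", attr(x, "n_probands"),
      " probands, bootstrap ", attr(x, "boot_n"), " x ", attr(x, "boot_reps"),
      " (seed ", attr(x, "seed"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 12))
  invisible(x)
}
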