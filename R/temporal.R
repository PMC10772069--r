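# Time-resolved structure: every individual carries the marriage year of its
# PARENTS; unknown years are imputed from dated descendants (child's year - 30,
# else grandchild's year - 60), individuals are binned into 25-year periods
# anchored at 1751, and per-period kinship structure is summarised by
# classical MDS and by per-group mean kinship/inbreeding trajectories.

#' Impute missing parents' marriage years
#'
#' An individual whose parents' marriage year is unknown receives the earliest
#' dated child's year minus 30, or failing that the earliest dated
#' grandchild's year minus 60. Imputation proceeds from the most recent
#' generations upwards in a single deterministic pass, so imputed years
#' cascade (an imputed child year can date its parent); known years are never
#' overwritten.
#'
#' @param ped a [pedigree()]
#' @return list with `years` (named integer vector over all ids, `NA` where
#'   undatable), `imputed` (ids whose year was inferred) and `unassigned`
#'   (ids with no dated descendants)
#' @export
impute_marriage_years <- function(ped) {
  n <- nrow(ped$ind)
  years <- ped$ind$marriage_year
  imputed <- logical(n)
  # children lists per row
  kids <- vector("list", n)
  for (r in seq_len(n)) {
    f <- ped$fa_idx[r]; m <- ped$mo_idx[r]
    if (f > 0L) kids[[f]] <- c(kids[[f]], r)
    if (m > 0L) kids[[m]] <- c(kids[[m]], r)
  }
  ord <- order(ped$gen, decreasing = TRUE)  # children before parents
  for (r in ord) {
    if (!is.na(years[r])) next
    ch <- kids[[r]]
    chy <- years[ch]
    if (any(!is.na(chy))) {
      years[r] <- min(chy, na.rm = TRUE) - 30L
      imputed[r] <- TRUE
      next
    }
    gch <- unlist(kids[ch], use.names = FALSE)
    gchy <- years[gch]
    if (length(gch) && any(!is.na(gchy))) {
      years[r] <- min(gchy, na.rm = TRUE) - 60L
      imputed[r] <- TRUE
    }
  }
  list(years = stats::setNames(years, ped$ind$id),
       imputed = ped$ind$id[imputed],
       unassigned = ped$ind$id[is.na(years)])
}

#' Period label for a calendar year
#'
#' Bins are 25 years long and anchored so that 1751-1775 is a bin
#' (boundaries at years congruent to 1 mod 25 relative to 1751).
#'
#' @param year integer vector
#' @param bin_length bin width in years (default 25)
#' @return character labels `"start-end"`; `NA` in gives `NA` out
#' @export
period_label <- function(year, bin_length = 25L) {
  start <- period_start(year, bin_length)
  ifelse(is.na(start), NA_character_,
         paste0(start, "-", start + bin_length - 1L))
}

#' @rdname period_label
#' @export
period_start <- function(year, bin_length = 25L) {
  as.integer(1751L + bin_length * floor((as.numeric(year) - 1751) / bin_length))
}

#' Assign individuals to 25-year periods
#'
#' @param ped a [pedigree()]
#' @param years completed years as returned by [impute_marriage_years()]
#'   (or its `$years` vector); defaults to imputing from `ped`
#' @param bin_length bin width (default 25)
#' @return data frame `id, year, period_start, period` (dated individuals
#'   only), with attributes `overlap` (fraction of dated parent-child pairs
#'   co-assigned to one bin) and `imputed` (ids with inferred years)
#' @export
assign_periods <- function(ped, years = NULL, bin_length = 25L) {
  imp_ids <- character(0)
  if (is.null(years)) {
    imp <- impute_marriage_years(ped)
    years <- imp$years
    imp_ids <- imp$imputed
  } else if (is.list(years)) {
    imp_ids <- years$imputed
    years <- years$years
  }
  y <- years[as.character(ped$ind$id)]
  keep <- !is.na(y)
  out <- data.frame(id = ped$ind$id[keep],
                    year = as.integer(y[keep]),
                    period_start = period_start(y[keep], bin_length),
                    period = period_label(y[keep], bin_length),
                    stringsAsFactors = FALSE)
  # parent-child same-bin overlap among dated pairs
  ps <- rep(NA_integer_, nrow(ped$ind))
  ps[keep] <- period_start(y[keep], bin_length)
  pairs_par <- c(ped$fa_idx, ped$mo_idx)
  pairs_ch <- rep(seq_len(nrow(ped$ind)), 2L)
  ok <- pairs_par > 0L
  pairs_par <- pairs_par[ok]; pairs_ch <- pairs_ch[ok]
  dated <- !is.na(ps[pairs_par]) & !is.na(ps[pairs_ch])
  overlap <- if (any(dated))
    mean(ps[pairs_par[dated]] == ps[pairs_ch[dated]]) else NA_real_
  attr(out, "overlap") <- overlap
  attr(out, "imputed") <- imp_ids
  out
}

#' Classical MDS of per-period kinship distances
#'
#' For the individuals assigned to one period, computes the pairwise kinship
#' matrix at maximal depth, removes individuals with no kinship ties to
#' anyone in the period (off-diagonal row all zero), and runs classical
#' (Torgerson) MDS on the distance `1 - phi`. Coordinates are defined up to
#' rotation and sign; compare inter-point distances, not raw axes.
#'
#' @param ped a [pedigree()]
#' @param assignment output of [assign_periods()]
#' @param period period label (e.g. `"1751-1775"`)
#' @param dims number of coordinates (default 2)
#' @param ids optional restriction of the period members (e.g. the ancestors
#'   of the probands); default uses every assigned individual
#' @return data frame `id, region, dim1..dimK`; attribute `removed` lists the
#'   zero-kinship individuals that were dropped
#' @export
period_mds <- function(ped, assignment, period, dims = 2L, ids = NULL) {
  members <- assignment$id[assignment$period == period]
  if (!is.null(ids)) members <- intersect(members, ids)
  if (length(members) < 3L) stop("fewer than 3 individuals in period ", period)
  km <- kinship_matrix(ped, members)
  off <- unclass(km); diag(off) <- 0
  tied <- rowSums(off != 0) > 0
  removed <- members[!tied]
  members <- members[tied]
  if (length(members) < 3L) stop("fewer than 3 individuals with kinship ties in period ", period)
  km <- km[tied, tied, drop = FALSE]
  D <- 1 - unclass(km)
  diag(D) <- 0
  xy <- stats::cmdscale(stats::as.dist(D), k = dims)
  rows <- .row_of(ped, members)
  region <- ped$ind$marriage_region[rows]
  region[is.na(region)] <- ped$ind$origin_country[rows][is.na(region)]
  out <- data.frame(id = members, region = region, xy, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("dim", seq_len(ncol(xy)))
  attr(out, "removed") <- removed
  out
}

#' Per-group mean kinship and inbreeding trajectories
#'
#' For every proband group, the ancestor set is the union of the strict
#' ancestors of that group's probands (one ancestor may belong to several
#' groups). Within each 25-year period, the trajectory reports the mean
#' pairwise kinship over the group's period members and the mean inbreeding
#' coefficient of those members.
#'
#' @param ped a [pedigree()] with proband groups
#' @param assignment output of [assign_periods()]
#' @param groups groups to include (default: all)
#' @param max_pairs cap on kinship pairs per period mean (see
#'   [mean_pairwise_kinship()]); `Inf` = exact
#' @param min_members smallest period membership reported (default 2)
#' @return data frame `group, period, period_start, mean_kinship,
#'   mean_inbreeding, n_pairs, n_individuals`
#' @export
group_trajectories <- function(ped, assignment,
                               groups = sort(unique(stats::na.omit(ped$group_of))),
                               max_pairs = Inf, min_members = 2L) {
  if (!length(groups)) stop("no proband groups")
  period_of <- stats::setNames(assignment$period_start, assignment$id)
  res <- list()
  for (g in groups) {
    pro <- as.integer(names(ped$group_of)[!is.na(ped$group_of) & ped$group_of == g])
    if (!length(pro)) stop("group with no probands: ", g)
    anc_rows <- .ancestor_rows(ped, .row_of(ped, pro))
    anc_ids <- ped$ind$id[anc_rows]
    ps <- period_of[as.character(anc_ids)]
    for (p in sort(unique(ps[!is.na(ps)]))) {
      mem <- anc_ids[!is.na(ps) & ps == p]
      if (length(mem) < min_members) next
      mk <- mean_pairwise_kinship(ped, mem, max_pairs = max_pairs)
      Fm <- mean(inbreeding(ped, mem))
      res[[length(res) + 1L]] <- data.frame(
        group = g, period = period_label(p), period_start = p,
        mean_kinship = mk, mean_inbreeding = Fm,
        n_pairs = length(mem) * (length(mem) - 1) / 2,
        n_individuals = length(mem), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
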