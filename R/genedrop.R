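# Gene-dropping IBD simulator: founder chromosomes receive unique haplotype
# labels, transmissions recombine with Haldane crossovers (Poisson, 1 per
# 100 cM, no interference), and IBD segments between probands are maximal
# intervals where founder labels match, unioned over the four haplotype
# pairings and filtered at a minimum length (default 2 cM). Coordinates are
# cM, 0-based, half-open.

#' Genetic map for gene dropping
#'
#' @param lengths_cM chromosome genetic lengths in cM; the default is a
#'   22-autosome human-like map totalling ~3500 cM
#' @param names chromosome names (default `"chr1"`...)
#' @return object of class `genome_map`
#' @export
genome_map <- function(lengths_cM = NULL, names = NULL) {
  if (is.null(lengths_cM)) {
    lengths_cM <- c(286.3, 268.8, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
                    166.4, 181.1, 158.2, 174.7, 125.9, 119.5, 141.3, 134.0,
                    128.5, 117.5, 107.3, 108.3, 62.8, 74.1)
  }
  stopifnot(all(lengths_cM > 0))
  if (is.null(names)) names <- paste0("chr", seq_along(lengths_cM))
  structure(list(chrom = names, length_cM = as.numeric(lengths_cM)),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", length(x$chrom), " chromosomes, total ",
      round(sum(x$length_cM), 1), " cM\n", sep = "")
  invisible(x)
}

#' Drop genomes through a pedigree
#'
#' Founders receive two whole-chromosome mosaics with unique labels; every
#' child haplotype is a recombinant of the corresponding parent's two
#' haplotypes. An individual with exactly one known parent gets a unique
#' phantom founder on the unknown side (phantom labels are unique per slot,
#' so they can never create spurious sharing). Deterministic given the RNG
#' state: pass `seed` or call `set.seed()` beforehand.
#'
#' @param ped a [pedigree()]
#' @param map a [genome_map()]
#' @param seed optional integer seed
#' @param targets ids whose mosaics are returned (default: the probands;
#'   ancestors are always simulated as needed)
#' @return object of class `gene_drop`: list with `mosaics` (named by target
#'   id: `h1`/`h2`, each a per-chromosome list of `end`/`lab` vectors),
#'   `map`, and `phantom` (ids that required a phantom parent)
#' @export
gene_drop <- function(ped, map = genome_map(), seed = NULL,
                      targets = ped$proband_ids) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(targets)) stop("no target individuals")
  trows <- .row_of(ped, targets, "target")
  need <- sort(unique(c(trows, .ancestor_rows(ped, trows))))
  ord <- need[order(ped$gen[need])]
  mos <- .gene_drop_cpp(ped$fa_idx, ped$mo_idx, ord, map$length_cM, trows)
  names(mos) <- as.character(targets)
  half <- xor(ped$fa_idx[need] == 0L, ped$mo_idx[need] == 0L)
  structure(list(mosaics = mos, map = map,
                 phantom = ped$ind$id[need[half]]),
            class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat("<gene_drop> ", length(x$mosaics), " individuals on ",
      length(x$map$chrom), " chromosomes (",
      round(sum(x$map$length_cM), 1), " cM)\n", sep = "")
  invisible(x)
}

#' IBD segments between two probands of a gene drop
#'
#' For each of the four haplotype pairings, maximal intervals with matching
#' founder labels are found; with `merge = "union"` (the default, mirroring
#' how pairwise IBD callers report segments) overlapping intervals from
#' different pairings are unioned per chromosome before the length filter,
#' with `merge = "pairings"` each pairing's intervals are kept separately.
#'
#' @param drop a [gene_drop()]
#' @param a,b target ids present in the drop
#' @param min_cM minimum segment length retained (default 2)
#' @param merge `"union"` or `"pairings"`
#' @return data frame `chrom, start_cM, end_cM, length_cM` (plus `pairing`
#'   1..4 when `merge = "pairings"`)
#' @export
extract_ibd <- function(drop, a, b, min_cM = 2, merge = c("union", "pairings")) {
  merge <- match.arg(merge)
  ma <- drop$mosaics[[as.character(a)]]
  mb <- drop$mosaics[[as.character(b)]]
  if (is.null(ma) || is.null(mb)) stop("mosaics missing for requested pair")
  m <- .pair_ibd_cpp(ma, mb, drop$map$length_cM, min_cM,
                     if (merge == "union") 1L else 0L)
  out <- data.frame(chrom = drop$map$chrom[m[, 1]],
                    start_cM = m[, 2], end_cM = m[, 3],
                    length_cM = m[, 3] - m[, 2],
                    stringsAsFactors = FALSE)
  if (merge == "pairings") out$pairing <- as.integer(m[, 4])
  out
}

#' Total pairwise IBD length over the four haplotype pairings
#'
#' Unfiltered sum of matching lengths across the four pairings; its
#' expectation is `4 * kinship * total map length`.
#'
#' @inheritParams extract_ibd
#' @return total length in cM
#' @export
ibd_total_pairings <- function(drop, a, b) {
  seg <- extract_ibd(drop, a, b, min_cM = 0, merge = "pairings")
  sum(seg$length_cM)
}

#' Bin IBD segments into length classes
#'
#' Bins are `[min_cM, 5), [5, 10), [10, 15), ...` cM; the table reports the
#' mean segment count per proband pair within each group.
#'
#' @param segments data frame with columns `group` and `length_cM`
#'   (one row per retained segment, pooled over within-group pairs)
#' @param n_pairs named vector: number of within-group pairs per group
#' @param bin_cM bin width (default 5)
#' @param min_cM lower edge of the first bin (default 2)
#' @param max_cM upper edge of the last bin (default 60; longer segments go
#'   in the last bin)
#' @return data frame `group, bin_start, bin_end, bin, mean_segments_per_pair`
#' @export
bin_sharing <- function(segments, n_pairs, bin_cM = 5, min_cM = 2, max_cM = 60) {
  edges <- c(min_cM, seq(bin_cM, max_cM, by = bin_cM))
  edges <- sort(unique(edges[edges >= min_cM]))
  groups <- names(n_pairs)
  out <- list()
  for (g in groups) {
    len <- segments$length_cM[segments$group == g]
    len <- len[len >= min_cM]
    len <- pmin(len, max_cM - 1e-9)
    bin <- findInterval(len, edges)
    counts <- tabulate(bin, nbins = length(edges) - 1L)
    out[[g]] <- data.frame(
      group = g,
      bin_start = edges[-length(edges)],
      bin_end = edges[-1],
      bin = paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
      mean_segments_per_pair = counts / n_pairs[[g]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-group IBD sharing from a gene drop
#'
#' Extracts union-merged IBD segments for within-group proband pairs and
#' returns the binned mean sharing per pair. With many probands the pair set
#' can be subsampled (`max_pairs`, unbiased for the per-pair mean).
#'
#' @param ped a [pedigree()] with proband groups
#' @param drop a [gene_drop()] covering the probands
#' @param groups groups to include (default: all)
#' @param min_cM segment length filter (default 2)
#' @param bin_cM bin width (default 5)
#' @param max_cM top of the last bin (default 60)
#' @param max_pairs cap on pairs per group (default `Inf`)
#' @return list with `bins` (see [bin_sharing()]) and `segments` (the pooled
#'   per-pair segments with a `group` column and pair ids)
#' @export
group_ibd_sharing <- function(ped, drop, groups = sort(unique(stats::na.omit(ped$group_of))),
                              min_cM = 2, bin_cM = 5, max_cM = 60,
                              max_pairs = Inf) {
  segs <- list()
  n_pairs <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    pro <- as.integer(names(ped$group_of)[!is.na(ped$group_of) & ped$group_of == g])
    pro <- pro[as.character(pro) %in% names(drop$mosaics)]
    n <- length(pro)
    if (n < 2L) next
    prs <- utils::combn(n, 2L)
    if (ncol(prs) > max_pairs) prs <- prs[, sample.int(ncol(prs), max_pairs), drop = FALSE]
    n_pairs[[g]] <- ncol(prs)
    for (k in seq_len(ncol(prs))) {
      s <- extract_ibd(drop, pro[prs[1, k]], pro[prs[2, k]], min_cM = min_cM)
      if (nrow(s)) {
        s$group <- g
        s$id_a <- pro[prs[1, k]]
        s$id_b <- pro[prs[2, k]]
        segs[[length(segs) + 1L]] <- s
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), start_cM = numeric(0), end_cM = numeric(0),
               length_cM = numeric(0), group = character(0),
               id_a = integer(0), id_b = integer(0))
  list(bins = bin_sharing(segments, n_pairs[n_pairs > 0], bin_cM = bin_cM,
                          min_cM = min_cM, max_cM = max_cM),
       segments = segments)
}
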