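# Pedigree container: an ascending genealogy stored as one row per individual
# with parent links, the parents' marriage metadata, and proband/group flags.
#
# Conventions used throughout the package:
#   * `marriage_year` / `marriage_region` on an individual refer to that
#     individual's PARENTS' marriage (register-style metadata); siblings share
#     them, founders usually lack them.
#   * unknown parent = 0 (or empty on file).
#   * generation numbering is relative to a proband: proband = 0, parents = 1.

#' Construct a pedigree from a data frame
#'
#' @param df data frame with columns `id`, `father`, `mother` and optionally
#'   `sex` ("M"/"F"/"U"), `marriage_year` (the individual's parents' marriage
#'   year), `marriage_region`, `origin_country`, `group`, `proband`
#'   (logical or 0/1). Unknown parents are encoded as 0 or `NA`.
#' @return An object of class `pedigree`: a list with the validated individual
#'   table (`ind`), parent row indices (`fa_idx`, `mo_idx`, 0 = unknown), the
#'   generation index `gen` (longest chain of known ancestors, founders = 0),
#'   `proband_ids` and the proband `group_of` mapping.
#' @details Validation rejects duplicate ids, references to ids not present in
#'   the table, and cycles (an individual that is its own ancestor). An
#'   individual appearing both as a father and as a mother triggers a warning,
#'   not an error, because real registers contain such inconsistencies.
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "father", "mother")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(df)
  id <- as.integer(df$id)
  if (anyNA(id) || any(id <= 0)) stop("ids must be positive integers")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate id(s): ", paste(unique(dup), collapse = ", "))
  fa <- as.integer(df$father); fa[is.na(fa)] <- 0L
  mo <- as.integer(df$mother); mo[is.na(mo)] <- 0L
  bad <- setdiff(c(fa[fa != 0L], mo[mo != 0L]), id)
  if (length(bad)) stop("dangling parent reference(s): ", paste(bad, collapse = ", "))

  fa_idx <- ifelse(fa == 0L, 0L, match(fa, id))
  mo_idx <- ifelse(mo == 0L, 0L, match(mo, id))

  gen <- .generation_index(fa_idx, mo_idx)  # errors on cycles

  sex <- if ("sex" %in% names(df)) .norm_sex(df$sex) else rep("U", n)
  as_father <- unique(fa_idx[fa_idx > 0L])
  as_mother <- unique(mo_idx[mo_idx > 0L])
  both <- intersect(as_father, as_mother)
  if (length(both)) {
    warning("individual(s) appear both as father and as mother: ",
            paste(id[both], collapse = ", "))
  }
  # fill sex from parental role when unknown
  sex[as_father[sex[as_father] == "U"]] <- "M"
  sex[as_mother[sex[as_mother] == "U"]] <- "F"
  mism <- c(as_father[sex[as_father] == "F"], as_mother[sex[as_mother] == "M"])
  if (length(mism)) {
    warning("sex inconsistent with parental role for id(s): ",
            paste(id[unique(mism)], collapse = ", "))
  }

  ind <- data.frame(
    id = id, father = fa, mother = mo, sex = sex,
    marriage_year = if ("marriage_year" %in% names(df))
      suppressWarnings(as.integer(df$marriage_year)) else rep(NA_integer_, n),
    marriage_region = if ("marriage_region" %in% names(df))
      .norm_chr(df$marriage_region) else rep(NA_character_, n),
    origin_country = if ("origin_country" %in% names(df))
      .norm_chr(df$origin_country) else rep(NA_character_, n),
    group = if ("group" %in% names(df)) .norm_chr(df$group) else rep(NA_character_, n),
    proband = if ("proband" %in% names(df))
      as.logical(as.integer(as.logical(df$proband) | df$proband %in% c(1, "1"))) else rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  ind$proband[is.na(ind$proband)] <- FALSE

  pro <- ind$id[ind$proband]
  ped <- structure(list(
    ind = ind,
    fa_idx = as.integer(fa_idx),
    mo_idx = as.integer(mo_idx),
    gen = as.integer(gen),
    proband_ids = pro,
    group_of = stats::setNames(ind$group[ind$proband], pro)
  ), class = "pedigree")
  ped
}

.norm_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("U", length(x))
  out[x %in% c("M", "MALE", "1")] <- "M"
  out[x %in% c("F", "FEMALE", "2")] <- "F"
  out
}

.norm_chr <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "0", "NA")] <- NA_character_
  x
}

# longest chain of known ancestors per row (founders = 0); detects cycles
.generation_index <- function(fa_idx, mo_idx) {
  n <- length(fa_idx)
  gen <- rep(NA_integer_, n)
  state <- integer(n)  # 0 untouched, 1 in progress, 2 done
  for (start in seq_len(n)) {
    if (state[start] == 2L) next
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]
      if (state[i] == 2L) { stack <- stack[-length(stack)]; next }
      f <- fa_idx[i]; m <- mo_idx[i]
      pend <- c(f, m)
      pend <- pend[pend > 0L & state[pend] != 2L]
      if (any(state[pend] == 1L) || i %in% pend) {
        stop("cycle detected in pedigree involving row id index ", i)
      }
      if (length(pend)) {
        state[i] <- 1L
        stack <- c(stack, pend)
      } else {
        gf <- if (f > 0L) gen[f] else -1L
        gm <- if (m > 0L) gen[m] else -1L
        gen[i] <- max(gf, gm) + 1L
        state[i] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  gen
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x$ind), " individuals, ",
      sum(x$fa_idx == 0L & x$mo_idx == 0L), " founders, ",
      length(x$proband_ids), " probands",
      if (length(x$proband_ids)) paste0(" in ",
        length(unique(stats::na.omit(x$group_of))), " group(s)") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  ped <- object
  cat("Individuals: ", nrow(ped$ind), "\n")
  cat("Founders:    ", length(founders(ped)), "\n")
  cat("Probands:    ", length(ped$proband_ids), "\n")
  gr <- table(stats::na.omit(ped$group_of))
  if (length(gr)) { cat("Groups:\n"); print(gr) }
  cat("Max generation index:", max(ped$gen), "\n")
  invisible(ped)
}

#' Founder ids (both parents unknown)
#' @param ped a `pedigree`
#' @return integer vector of ids
#' @export
founders <- function(ped) {
  ped$ind$id[ped$fa_idx == 0L & ped$mo_idx == 0L]
}

.row_of <- function(ped, id, what = "id") {
  r <- match(as.integer(id), ped$ind$id)
  if (anyNA(r)) stop("unknown ", what, ": ", paste(id[is.na(r)], collapse = ", "))
  r
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree table (comma or whitespace separated, header
#' required). Two dialects are supported: `"internal"` with columns
#' `id, father, mother, sex, marriage_year, marriage_region, origin_country,
#' group, proband`, and `"genlib_like"` with the minimal `ind, father, mother,
#' sex` layout used by ascending-genealogy tools. Unknown parents may be
#' encoded as `0` or left empty.
#'
#' @param path file path
#' @param dialect `"internal"` (default) or `"genlib_like"`
#' @return a validated [pedigree()]
#' @export
read_pedigree <- function(path, dialect = c("internal", "genlib_like")) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, blank.lines.skip = TRUE,
                          na.strings = c("NA", ""))
  if (dialect == "genlib_like") {
    names(df)[names(df) == "ind"] <- "id"
  }
  if (nrow(df) == 0L) {
    df <- data.frame(id = integer(), father = integer(), mother = integer())
  }
  if ("marriage_year" %in% names(df)) {
    df$marriage_year[!is.na(df$marriage_year) & df$marriage_year == 0] <- NA
  }
  pedigree(df)
}

#' Write a pedigree file (internal dialect)
#'
#' @param ped a `pedigree`
#' @param path output path
#' @param sep `","` (default) or `" "`
#' @return `path`, invisibly
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  out <- ped$ind
  out$proband <- as.integer(out$proband)
  # unknowns written as 0 in every column (keeps the whitespace dialect
  # parseable; 0 is mapped back to NA on read)
  out$marriage_region[is.na(out$marriage_region)] <- "0"
  out$origin_country[is.na(out$origin_country)] <- "0"
  out$group[is.na(out$group)] <- "0"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "0")
  invisible(path)
}

#' All ancestors of an individual with their meiotic depths
#'
#' Because of pedigree collapse (implex) an ancestor can occupy several
#' generational positions; every distinct path depth is reported.
#'
#' @param ped a `pedigree`
#' @param id individual id
#' @return named list mapping ancestor id to a sorted integer vector of
#'   depths (1 = parent). Founder queries return an empty list.
#' @export
ancestors_with_depths <- function(ped, id) {
  r0 <- .row_of(ped, id)
  depths <- list()
  d <- 0L
  frontier_rows <- r0
  while (length(frontier_rows)) {
    d <- d + 1L
    nxt <- c(ped$fa_idx[frontier_rows], ped$mo_idx[frontier_rows])
    nxt <- unique(nxt[nxt > 0L])
    for (r in nxt) {
      k <- as.character(ped$ind$id[r])
      depths[[k]] <- c(depths[[k]], d)
    }
    frontier_rows <- nxt
  }
  lapply(depths, function(v) sort(unique(v)))
}

# row indices of strict ancestors of a set of rows (not including the rows)
.ancestor_rows <- function(ped, rows) {
  seen <- logical(nrow(ped$ind))
  frontier <- unique(rows)
  anc <- integer(0)
  repeat {
    nxt <- c(ped$fa_idx[frontier], ped$mo_idx[frontier])
    nxt <- unique(nxt[nxt > 0L])
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(anc)
}

#' Genealogical completeness profile
#'
#' Completeness at generation g is the proportion of ancestor POSITIONS filled
#' (out of the 2^g possible) averaged over probands; an ancestor occupying k
#' positions at generation g through implex contributes k filled positions.
#'
#' @param ped a `pedigree`
#' @param probands ids over which to average (default: the pedigree probands)
#' @param max_gen deepest generation to report (g = 1 is parents)
#' @return data frame with columns `generation`, `proportion`
#' @export
completeness <- function(ped, probands = ped$proband_ids, max_gen = 10L) {
  if (!length(probands)) stop("empty proband list")
  stopifnot(max_gen >= 1L)
  rows <- .row_of(ped, probands, "proband")
  prop <- matrix(0, nrow = length(rows), ncol = max_gen)
  for (i in seq_along(rows)) {
    pos <- rows[i]  # occupied positions (rows, with multiplicity)
    for (g in seq_len(max_gen)) {
      pos <- c(ped$fa_idx[pos], ped$mo_idx[pos])
      pos <- pos[pos > 0L]
      prop[i, g] <- length(pos) / 2^g
      if (!length(pos)) break
    }
  }
  data.frame(generation = seq_len(max_gen), proportion = colMeans(prop))
}

#' Per-group completeness table
#'
#' @inheritParams completeness
#' @return data frame with columns `generation`, `proportion`, `group`
#' @export
completeness_by_group <- function(ped, max_gen = 10L) {
  groups <- sort(unique(stats::na.omit(ped$group_of)))
  if (!length(groups)) stop("pedigree has no proband groups")
  do.call(rbind, lapply(groups, function(g) {
    pro <- names(ped$group_of)[!is.na(ped$group_of) & ped$group_of == g]
    cbind(completeness(ped, as.integer(pro), max_gen), group = g)
  }))
}
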