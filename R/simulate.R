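# Synthetic colonization-scenario genealogies.
#
# The generator runs a chronological marriage market over 25-year periods:
# founder couples immigrate per region on a schedule (or are recruited
# internally from a source region, modelling daughter colonies such as a
# Saguenay-like settlement drawing on a Charlevoix-like one), couples have
# Poisson numbers of children reaching marriage, children become eligible
# about one generation (Normal(30, 5) years) after their parents' marriage,
# and mates are chosen within the region with probability `endogamy`,
# otherwise from the pool of other regions. Probands are sampled from the
# most recent generation with both parents born inside the scenario.
#
# Every random draw goes through R's RNG after set.seed(config$seed), so a
# configuration plus seed fully determines the pedigree.

#' Region specification for the scenario generator
#'
#' @param name region label (also the marriage region recorded on children)
#' @param founding_year year the first founder couples marry in the region
#' @param founder_couples number of founding couples
#' @param source where founders come from: an external origin label (e.g.
#'   `"FRANCE"`) or the name of another region (internal recruitment)
#' @param source_external `TRUE` if `source` is a country of origin outside
#'   the study area, `FALSE` if founders are recruited from another region
#' @param immigration_schedule optional data frame `year, couples` of
#'   additional external founder couples
#' @param growth_rate mean children reaching marriage per couple (Poisson)
#' @param capacity carrying capacity in couples per period: as the number of
#'   couples marrying in the region approaches it, fertility is damped
#'   linearly towards replacement (2 children per couple); `Inf` (default)
#'   disables damping
#' @param endogamy probability a marriage stays within the region
#' @param group_label optional proband group sampled from this region
#' @param proband_count probands to sample (requires `group_label`)
#' @return a `region_spec` list
#' @export
region_spec <- function(name, founding_year, founder_couples,
                        source = "EXTERNAL", source_external = TRUE,
                        immigration_schedule = NULL,
                        growth_rate = 2.5, capacity = Inf, endogamy = 0.9,
                        group_label = NULL, proband_count = 0L) {
  stopifnot(endogamy >= 0, endogamy <= 1, growth_rate > 0, founder_couples >= 0,
            capacity > 0)
  structure(list(name = name, founding_year = as.integer(founding_year),
                 founder_couples = as.integer(founder_couples),
                 source = source, source_external = isTRUE(source_external),
                 immigration_schedule = immigration_schedule,
                 growth_rate = growth_rate, capacity = capacity,
                 endogamy = endogamy,
                 group_label = group_label,
                 proband_count = as.integer(proband_count)),
            class = "region_spec")
}

#' Scenario configuration
#'
#' @param span integer vector `c(start_year, end_year)`
#' @param regions list of [region_spec()]s
#' @param seed integer seed (mandatory: scenarios are reproducible by
#'   construction)
#' @param period_length period width in years (default 25)
#' @param generation_mean,generation_sd years from a couple's marriage to a
#'   child's own marriage, Normal(30, 5) by default
#' @param proband_window parents of probands must have married within this
#'   many years of the span end (default 30)
#' @param year_jitter optional confidentiality-style jitter: recorded
#'   marriage years are shifted by a uniform integer in `[-j, j]` (default 0,
#'   off)
#' @param max_wait periods an unmatched single stays on the marriage market
#'   (default 1)
#' @return a `scenario_config` list
#' @export
scenario_config <- function(span, regions, seed, period_length = 25L,
                            generation_mean = 30, generation_sd = 5,
                            proband_window = 30L, year_jitter = 0L,
                            max_wait = 1L) {
  stopifnot(length(span) == 2L, span[1] < span[2], !missing(seed))
  nm <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate region names")
  for (r in regions) {
    if (!r$source_external && !(r$source %in% nm))
      stop("internal source region not defined: ", r$source)
    if (r$founding_year < span[1] || r$founding_year > span[2])
      stop("founding year outside span for region ", r$name)
  }
  structure(list(span = as.integer(span), regions = regions,
                 seed = as.integer(seed),
                 period_length = as.integer(period_length),
                 generation_mean = generation_mean,
                 generation_sd = generation_sd,
                 proband_window = as.integer(proband_window),
                 year_jitter = as.integer(year_jitter),
                 max_wait = as.integer(max_wait)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$span[1], "-", x$span[2], ", ",
      length(x$regions), " regions, seed ", x$seed, "\n", sep = "")
  for (r in x$regions) {
    cat(sprintf("  %-4s founded %d (%d couples from %s%s) growth %.1f endogamy %.2f%s\n",
                r$name, r$founding_year, r$founder_couples, r$source,
                if (r$source_external) "" else " [internal]",
                r$growth_rate, r$endogamy,
                if (!is.null(r$group_label))
                  paste0(" -> ", r$proband_count, " probands [", r$group_label, "]")
                else ""))
  }
  invisible(x)
}

#' Simulate a genealogy from a scenario configuration
#'
#' @param config a [scenario_config()]
#' @return a [pedigree()] with probands and group labels set
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  span <- config$span
  plen <- config$period_length
  regions <- config$regions
  rnames <- vapply(regions, `[[`, "", "name")
  growth <- stats::setNames(vapply(regions, `[[`, 0, "growth_rate"), rnames)
  capac <- stats::setNames(vapply(regions, function(r)
    if (is.null(r$capacity)) Inf else r$capacity, 0), rnames)
  endog <- stats::setNames(vapply(regions, `[[`, 0, "endogamy"), rnames)

  # individual store (grown in chunks)
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$chunks <- list()
  add_ind <- function(k, fa, mo, sex, year, region, origin) {
    ids <- st$n + seq_len(k)
    st$n <- st$n + k
    st$chunks[[length(st$chunks) + 1L]] <- data.frame(
      id = ids, father = fa, mother = mo, sex = sex,
      marriage_year = year, marriage_region = region,
      origin_country = origin, stringsAsFactors = FALSE)
    ids
  }

  # marriage pool: own readiness year per single
  pool <- data.frame(id = integer(0), sex = character(0),
                     region = character(0), ready = integer(0),
                     waited = integer(0), stringsAsFactors = FALSE)
  fallback_spouses <- 0L

  make_couples <- function(h, w, region, year) {
    data.frame(husband = h, wife = w, region = region, year = as.integer(year),
               stringsAsFactors = FALSE)
  }

  new_founder_couples <- function(k, region, year, origin) {
    if (k <= 0L) return(NULL)
    h <- add_ind(k, 0L, 0L, "M", NA_integer_, NA_character_, origin)
    w <- add_ind(k, 0L, 0L, "F", NA_integer_, NA_character_, origin)
    make_couples(h, w, region, year)
  }

  breed <- function(couples) {
    if (is.null(couples) || !nrow(couples)) return(invisible())
    # fertility damped towards replacement as the regional cohort
    # approaches carrying capacity
    ncoup <- table(couples$region)
    damp <- pmax(0, pmin(1, 1 - as.numeric(ncoup[couples$region]) /
                              capac[couples$region]))
    g_eff <- pmax(0.1, 2 + (growth[couples$region] - 2) * damp)
    nch <- stats::rpois(nrow(couples), g_eff)
    tot <- sum(nch)
    if (!tot) return(invisible())
    idx <- rep.int(seq_len(nrow(couples)), nch)
    sex <- ifelse(stats::runif(tot) < 0.5, "M", "F")
    ready <- couples$year[idx] +
      as.integer(round(stats::rnorm(tot, config$generation_mean,
                                    config$generation_sd)))
    ids <- add_ind(tot, couples$husband[idx], couples$wife[idx], sex,
                   couples$year[idx], couples$region[idx], NA_character_)
    keep <- ready <= span[2] + plen  # can still marry inside the span
    if (any(keep)) {
      pool <<- rbind(pool, data.frame(id = ids[keep], sex = sex[keep],
                                      region = couples$region[idx][keep],
                                      ready = ready[keep],
                                      waited = rep(0L, sum(keep)),
                                      stringsAsFactors = FALSE))
    }
    invisible()
  }

  period_starts <- seq(span[1], span[2], by = plen)
  for (pstart in period_starts) {
    pend <- min(pstart + plen - 1L, span[2])
    couples <- list()

    # founding + scheduled external immigration this period
    for (r in regions) {
      if (r$founding_year >= pstart && r$founding_year <= pend) {
        if (r$source_external) {
          couples[[length(couples) + 1L]] <-
            new_founder_couples(r$founder_couples, r$name, r$founding_year,
                                r$source)
        } else {
          # recruit singles from the source region and marry them directly
          # at the founding year; top up with external couples if the source
          # pool is exhausted (flagged via message)
          mcand <- which(pool$region == r$source & pool$sex == "M" &
                           pool$ready <= pend)
          fcand <- which(pool$region == r$source & pool$sex == "F" &
                           pool$ready <= pend)
          k <- min(length(mcand), length(fcand), r$founder_couples)
          if (k > 0L) {
            mi <- mcand[sample.int(length(mcand), k)]
            fi <- fcand[sample.int(length(fcand), k)]
            couples[[length(couples) + 1L]] <-
              make_couples(pool$id[mi], pool$id[fi], r$name, r$founding_year)
            pool <- pool[-c(mi, fi), , drop = FALSE]
          }
          if (k < r$founder_couples) {
            fallback_spouses <- fallback_spouses + 2L * (r$founder_couples - k)
            message("region ", r$name, ": source ", r$source, " exhausted, ",
                    r$founder_couples - k, " external founder couple(s) added")
            couples[[length(couples) + 1L]] <-
              new_founder_couples(r$founder_couples - k, r$name,
                                  r$founding_year, "EXTERNAL")
          }
        }
      }
      sch <- r$immigration_schedule
      if (!is.null(sch)) {
        here <- sch$year >= pstart & sch$year <= pend
        for (k in which(here)) {
          couples[[length(couples) + 1L]] <-
            new_founder_couples(sch$couples[k], r$name, sch$year[k],
                                if (r$source_external) r$source else "EXTERNAL")
        }
      }
    }

    # marriage market
    elig <- which(pool$ready <= pend)
    if (length(elig)) {
      taken <- logical(nrow(pool))
      males <- elig[pool$sex[elig] == "M"]
      males <- males[sample.int(length(males))]
      for (mi in males) {
        if (taken[mi]) next
        rg <- pool$region[mi]
        inr <- stats::runif(1) < endog[[rg]]
        cand_in <- elig[!taken[elig] & pool$sex[elig] == "F" &
                          pool$region[elig] == rg]
        cand_out <- elig[!taken[elig] & pool$sex[elig] == "F" &
                           pool$region[elig] != rg]
        cand <- if (inr) cand_in else cand_out
        if (!length(cand)) cand <- if (inr) cand_out else cand_in
        if (!length(cand)) next
        fi <- cand[sample.int(length(cand), 1L)]
        taken[mi] <- TRUE; taken[fi] <- TRUE
        y <- max(pool$ready[mi], pool$ready[fi])
        y <- min(max(y, pstart), pend)
        couples[[length(couples) + 1L]] <-
          make_couples(pool$id[mi], pool$id[fi], rg, y)
      }
      # retire or carry over unmatched eligibles
      left <- elig[!taken[elig]]
      pool$waited[left] <- pool$waited[left] + 1L
      drop_rows <- sort(unique(c(elig[taken[elig]],
                                 left[pool$waited[left] > config$max_wait])))
      if (length(drop_rows)) pool <- pool[-drop_rows, , drop = FALSE]
    }

    if (length(couples)) breed(do.call(rbind, couples))
  }

  ind <- do.call(rbind, st$chunks)
  rownames(ind) <- NULL

  if (config$year_jitter > 0L) {
    j <- config$year_jitter
    known <- !is.na(ind$marriage_year)
    ind$marriage_year[known] <- ind$marriage_year[known] +
      sample.int(2L * j + 1L, sum(known), replace = TRUE) - j - 1L
  }

  # proband sampling: parents married in the region recently, both parents
  # born inside the scenario (all four grandparents present)
  ind$group <- NA_character_
  ind$proband <- FALSE
  founder_of <- ind$father == 0L & ind$mother == 0L
  is_founder <- stats::setNames(founder_of, ind$id)
  for (r in regions) {
    if (is.null(r$group_label) || r$proband_count <= 0L) next
    cand <- which(ind$marriage_region == r$name &
                    !is.na(ind$marriage_year) &
                    ind$marriage_year >= span[2] - config$proband_window &
                    ind$father > 0L & ind$mother > 0L)
    cand <- cand[!is_founder[as.character(ind$father[cand])] &
                   !is_founder[as.character(ind$mother[cand])]]
    if (length(cand) < r$proband_count) {
      warning("region ", r$name, ": only ", length(cand),
              " eligible probands (requested ", r$proband_count, ")")
      take <- cand
    } else {
      take <- cand[sample.int(length(cand), r$proband_count)]
    }
    ind$group[take] <- r$group_label
    ind$proband[take] <- TRUE
  }

  pedigree(ind)
}

#' Preset scenario emulating the Quebec colonization structure
#'
#' Eight proband groups (MTL, QUE, SAG, NSH, GFC, GLO, GCI, GAC) with sample
#' sizes 138, 70, 86, 47, 97, 71, 67 and 89. The chronology follows the
#' historical narrative at desk scale: Quebec City (1608) and Montreal (1642)
#' with sustained French immigration to 1750; a small Charlevoix-like
#' community (1675) recruited internally from Quebec City; a Saguenay-like
#' daughter colony founded in 1838 from Charlevoix with a high growth rate
#' (bottleneck then rapid expansion); Gaspé groups arriving 1757-1790
#' (Acadian, French-Canadian, Loyalist, Channel-Islander) with the Acadian
#' group small and persistently endogamous; a North Shore settlement (1850)
#' recruited from Charlevoix. Population sizes are scaled down relative to a
#' real registry.
#'
#' @param seed scenario seed (default 1)
#' @return a [scenario_config()]
#' @export
quebec_preset <- function(seed = 1L) {
  sched <- function(years, couples) data.frame(year = years, couples = couples)
  regions <- list(
    region_spec("QUE", 1608, 20, source = "FRANCE",
                immigration_schedule = sched(c(1630, 1655, 1680, 1705, 1730), 10),
                growth_rate = 2.4, endogamy = 0.75,
                group_label = "QUE", proband_count = 70L),
    region_spec("MTL", 1642, 20, source = "FRANCE",
                immigration_schedule = sched(c(1660, 1685, 1710, 1735), 10),
                growth_rate = 2.4, endogamy = 0.70,
                group_label = "MTL", proband_count = 138L),
    region_spec("CHX", 1675, 18, source = "QUE", source_external = FALSE,
                growth_rate = 3.2, endogamy = 0.88),
    region_spec("GAC", 1757, 12, source = "ACADIA",
                growth_rate = 3.4, capacity = 30, endogamy = 1.0,
                group_label = "GAC", proband_count = 89L),
    region_spec("GFC", 1780, 22, source = "QUE", source_external = FALSE,
                growth_rate = 3.0, endogamy = 0.90,
                group_label = "GFC", proband_count = 97L),
    region_spec("GLO", 1784, 18, source = "LOYALIST",
                growth_rate = 3.0, capacity = 60, endogamy = 0.95,
                group_label = "GLO", proband_count = 71L),
    region_spec("GCI", 1790, 15, source = "CHANNEL_ISLANDS",
                growth_rate = 2.8, endogamy = 0.95,
                group_label = "GCI", proband_count = 67L),
    region_spec("SAG", 1838, 80, source = "CHX", source_external = FALSE,
                growth_rate = 4.6, endogamy = 0.85,
                group_label = "SAG", proband_count = 86L),
    region_spec("NSH", 1850, 20, source = "CHX", source_external = FALSE,
                growth_rate = 3.0, endogamy = 0.90,
                group_label = "NSH", proband_count = 47L)
  )
  scenario_config(span = c(1608L, 1960L), regions = regions, seed = seed,
                  proband_window = 50L, max_wait = 2L)
}

#' Write / read a scenario configuration as YAML
#'
#' @param config a [scenario_config()]
#' @param path file path
#' @return `path` invisibly (write) or a `scenario_config` (read)
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  x$regions <- lapply(x$regions, function(r) {
    r <- unclass(r)
    if (!is.null(r$immigration_schedule))
      r$immigration_schedule <- as.list(r$immigration_schedule)
    r
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  regions <- lapply(x$regions, function(r) {
    sch <- r$immigration_schedule
    if (!is.null(sch)) sch <- data.frame(year = unlist(sch$year),
                                         couples = unlist(sch$couples))
    region_spec(r$name, r$founding_year, r$founder_couples,
                source = r$source, source_external = r$source_external,
                immigration_schedule = sch, growth_rate = r$growth_rate,
                capacity = if (is.null(r$capacity)) Inf else r$capacity,
                endogamy = r$endogamy,
                group_label = r$group_label,
                proband_count = if (is.null(r$proband_count)) 0L else r$proband_count)
  })
  scenario_config(span = unlist(x$span), regions = regions, seed = x$seed,
                  period_length = x$period_length,
                  generation_mean = x$generation_mean,
                  generation_sd = x$generation_sd,
                  proband_window = x$proband_window,
                  year_jitter = x$year_jitter, max_wait = x$max_wait)
}
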