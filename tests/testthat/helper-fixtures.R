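# Pedigree fixtures built in code.

# 8 individuals: founder couple 1x2; sons 3,4 married to unrelated founders
# 5,6; one child each (7, 8) -> 7 and 8 are first cousins.
first_cousin_ped <- function() {
  pedigree(data.frame(
    id = 1:8,
    father = c(0, 0, 1, 1, 0, 0, 3, 4),
    mother = c(0, 0, 2, 2, 0, 0, 5, 6),
    sex = c("M", "F", "M", "M", "F", "F", "M", "F")))
}

# 4,5 are full sibs of founder couple 1x2
full_sib_ped <- function() {
  pedigree(data.frame(
    id = 1:4,
    father = c(0, 0, 1, 1),
    mother = c(0, 0, 2, 2),
    sex = c("M", "F", "M", "F")))
}

# shared father 1; mothers 2 and 3 -> 4,5 half sibs
half_sib_ped <- function() {
  pedigree(data.frame(
    id = 1:5,
    father = c(0, 0, 0, 1, 1),
    mother = c(0, 0, 0, 2, 3),
    sex = c("M", "F", "F", "M", "F")))
}

# two founder couples; sibs 5,6 from one and sibs 7,8 from the other;
# 5x7 and 6x8 -> children 9,10 are double first cousins
double_first_cousin_ped <- function() {
  pedigree(data.frame(
    id = 1:10,
    father = c(0, 0, 0, 0, 1, 1, 3, 3, 5, 6),
    mother = c(0, 0, 0, 0, 2, 2, 4, 4, 7, 8),
    sex = c("M", "F", "M", "F", "M", "M", "F", "F", "M", "F")))
}

# first-cousin pedigree extended one generation up: the shared grandfather 1
# is himself the child of founders 9 and 10. For the cousin pair (7, 8) the
# common ancestors are {1, 2, 9, 10} but 9 and 10 have a descendant (1) who
# is also a common ancestor, so only {1, 2} are MRCAs.
nested_mrca_ped <- function() {
  pedigree(data.frame(
    id = 1:10,
    father = c(9, 0, 1, 1, 0, 0, 3, 4, 0, 0),
    mother = c(10, 0, 2, 2, 0, 0, 5, 6, 0, 0),
    sex = c("M", "F", "M", "M", "F", "F", "M", "F", "M", "F")))
}

# random valid pedigree: parents always have smaller index (DAG by
# construction), sexes consistent; returns a pedigree of <= n individuals
random_pedigree <- function(n, p_parents = 0.6) {
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1] <- "M"; sex[2] <- "F"
  fa <- integer(n); mo <- integer(n)
  for (i in 3:n) {
    if (stats::runif(1) < p_parents) {
      males <- which(sex[seq_len(i - 1L)] == "M")
      females <- which(sex[seq_len(i - 1L)] == "F")
      if (length(males) && length(females)) {
        fa[i] <- males[sample.int(length(males), 1L)]
        mo[i] <- females[sample.int(length(females), 1L)]
      }
    }
  }
  pedigree(data.frame(id = seq_len(n), father = fa, mother = mo, sex = sex))
}

# small three-region colonization scenario for fast end-to-end tests
small_scenario <- function(seed = 1L) {
  scenario_config(
    span = c(1700L, 1900L),
    regions = list(
      region_spec("CORE", 1700, 15, source = "FRANCE",
                  growth_rate = 2.6, endogamy = 0.8,
                  group_label = "CORE", proband_count = 25L),
      region_spec("ISO", 1750, 6, source = "ELSEWHERE",
                  growth_rate = 2.8, endogamy = 1.0,
                  group_label = "ISO", proband_count = 20L),
      region_spec("EXP", 1800, 12, source = "CORE", source_external = FALSE,
                  growth_rate = 4.0, endogamy = 0.9,
                  group_label = "EXP", proband_count = 20L)),
    seed = seed, proband_window = 40L, max_wait = 2L)
}
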