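# marriage-year imputation, 25-year periods, per-period MDS, trajectories

test_that("marriage years are imputed from children (-30) then grandchildren (-60)", {
  # 1 -> child 2 (year known 1900) -> grandchild 3
  ped <- pedigree(data.frame(
    id = 1:3, father = c(0, 1, 2), mother = 0,
    sex = c("M", "M", "M"),
    marriage_year = c(NA, 1900, 1930)))
  imp <- impute_marriage_years(ped)
  expect_equal(unname(imp$years[["1"]]), 1870)  # child's year - 30
  expect_setequal(imp$imputed, 1)

  # no dated child, dated grandchild only
  ped2 <- pedigree(data.frame(
    id = 1:3, father = c(0, 1, 2), mother = 0,
    sex = c("M", "M", "M"),
    marriage_year = c(NA, NA, 1900)))
  imp2 <- impute_marriage_years(ped2)
  expect_equal(unname(imp2$years[["2"]]), 1870)  # via child, cascaded
  expect_equal(unname(imp2$years[["1"]]), 1840)  # 1870 - 30 (cascade)

  # grandchild rule when the intermediate child has no year and no further
  # descendants are dated through it: earliest grandchild - 60
  ped3 <- pedigree(data.frame(
    id = 1:4, father = c(0, 1, 2, 2), mother = 0,
    sex = c("M", "M", "M", "M"),
    marriage_year = c(NA, NA, 1900, 1890)))
  imp3 <- impute_marriage_years(ped3)
  expect_equal(unname(imp3$years[["2"]]), 1860)  # earliest grandchild... child rule
  # known years are never overwritten
  ped4 <- pedigree(data.frame(
    id = 1:2, father = c(0, 1), mother = 0, sex = c("M", "M"),
    marriage_year = c(1812, 1900)))
  expect_equal(unname(impute_marriage_years(ped4)$years[["1"]]), 1812)
  expect_length(impute_marriage_years(ped4)$imputed, 0)
})

test_that("period bins are 25 years anchored on 1751", {
  expect_equal(period_label(1751), "1751-1775")
  expect_equal(period_label(1775), "1751-1775")
  expect_equal(period_label(1750), "1726-1750")
  expect_equal(period_label(1838), "1826-1850")
  expect_equal(period_label(1608), "1601-1625")
  expect_true(is.na(period_label(NA)))
})

test_that("assign_periods covers dated individuals and reports overlap", {
  ped <- pedigree(data.frame(
    id = 1:4, father = c(0, 1, 2, 3), mother = 0,
    sex = c("M", "M", "M", "M"),
    marriage_year = c(1800, 1805, 1830, 1860)))
  asg <- assign_periods(ped)
  expect_setequal(asg$id, 1:4)
  expect_equal(asg$period[asg$id == 1], "1776-1800")
  # dated parent-child pairs: (1,2) same bin? 1800 vs 1805: different bins
  # (1776-1800 vs 1801-1825); (2,3): 1805 vs 1830 different; (3,4) different
  # parent-child overlap: pair (1,2) is the only co-binned? none here
  expect_equal(attr(asg, "overlap"), 0)
  ped2 <- pedigree(data.frame(
    id = 1:2, father = c(0, 1), mother = 0, sex = c("M", "M"),
    marriage_year = c(1805, 1810)))
  expect_equal(attr(assign_periods(ped2), "overlap"), 1)
})

test_that("period MDS reproduces kinship distances and drops isolated ancestors", {
  # four full sibs; one (3) dated into the previous bin, plus an unrelated
  # founder (7) sharing the 1801-1825 bin
  ped <- pedigree(data.frame(
    id = 1:7, father = c(0, 0, 1, 1, 1, 1, 0), mother = c(0, 0, 2, 2, 2, 2, 0),
    sex = c("M", "F", "M", "M", "M", "M", "F"),
    marriage_year = c(NA, NA, 1800, 1805, 1810, 1806, 1805)))
  asg <- assign_periods(ped)
  res <- period_mds(ped, asg, "1801-1825")
  expect_setequal(attr(res, "removed"), 7)  # no kinship ties to anybody
  expect_setequal(res$id, c(4, 5, 6))
  expect_error(period_mds(ped, asg, "1776-1800"), "fewer than 3")

  # equilateral configuration: all inter-point distances equal
  ped2 <- pedigree(data.frame(
    id = 1:5, father = c(0, 0, 1, 1, 1), mother = c(0, 0, 2, 2, 2),
    sex = c("M", "F", "M", "M", "M"),
    marriage_year = c(NA, NA, 1800, 1805, 1810)))
  asg2 <- assign_periods(ped2)
  # force all three sibs in one bin
  res2 <- period_mds(ped2, assign_periods(ped2,
    years = stats::setNames(c(NA, NA, 1801, 1805, 1810), 1:5)), "1801-1825")
  d <- dist(res2[, c("dim1", "dim2")])
  expect_equal(max(d), min(d), tolerance = 1e-9)

  # two families: within-family distances < between-family distances
  ped3 <- pedigree(data.frame(
    id = 1:10,
    father = c(0, 0, 0, 0, 1, 1, 1, 3, 3, 3),
    mother = c(0, 0, 0, 0, 2, 2, 2, 4, 4, 4),
    sex = c("M", "F", "M", "F", rep("M", 6)),
    marriage_year = c(rep(NA, 4), rep(1805, 6))))
  res3 <- period_mds(ped3, assign_periods(ped3), "1801-1825")
  xy <- as.matrix(res3[, c("dim1", "dim2")])
  fam <- ifelse(res3$id <= 7, "A", "B")
  D <- as.matrix(dist(xy))
  within <- D[outer(fam, fam, "==") & upper.tri(D)]
  between <- D[outer(fam, fam, "!=") & upper.tri(D)]
  expect_lt(max(within), min(between))

  # oracle: double-centered eigen-decomposition reproduces Euclidean input
  km <- kinship_matrix(ped3, 5:10)
  Dk <- 1 - unclass(km); diag(Dk) <- 0
  B <- -0.5 * (diag(6) - 1 / 6) %*% Dk^2 %*% (diag(6) - 1 / 6)
  ev <- eigen(B, symmetric = TRUE)
  k <- 2
  oracle <- ev$vectors[, 1:k] %*% diag(sqrt(pmax(ev$values[1:k], 0)))
  expect_equal(unname(as.matrix(dist(xy))), unname(as.matrix(dist(oracle))),
               tolerance = 1e-8)
})

test_that("group trajectories average kinship over pairs and inbreeding over members", {
  # two probands in one group; their ancestors include a sib pair in one bin
  ped <- pedigree(data.frame(
    id = 1:8,
    father = c(0, 0, 1, 1, 0, 0, 3, 4),
    mother = c(0, 0, 2, 2, 0, 0, 5, 6),
    sex = c("M", "F", "M", "M", "F", "F", "M", "F"),
    marriage_year = c(NA, NA, 1800, 1805, 1802, 1806, 1830, 1831),
    group = c(rep(NA, 6), "G", "G"),
    proband = c(rep(FALSE, 6), TRUE, TRUE)))
  asg <- assign_periods(ped)
  tr <- group_trajectories(ped, asg)
  row <- tr[tr$period == "1801-1825", ]
  # members of 1801-1825 among ancestors: 4 (1805), 5 (1802), 6 (1806)
  expect_equal(row$n_individuals, 3)
  # pairs: (4,5) phi 0, (4,6) 0, (5,6) 0 -> 0; check a single-pair case
  expect_equal(row$mean_kinship, 0)
  row2 <- tr[tr$period == "1776-1800", ]  # only individual 3
  expect_equal(nrow(row2), 0L)  # below min_members
  # founders' children have zero inbreeding
  expect_equal(row$mean_inbreeding, 0)
})

test_that("mean inbreeding can exceed mean kinship under assortative mating", {
  # isolate scenario: closed mating makes spouses more related than a random
  # pair of contemporaries
  ped <- suppressWarnings(suppressMessages(simulate_genealogy(small_scenario(3))))
  asg <- assign_periods(ped)
  tr <- group_trajectories(ped, asg, groups = "ISO")
  late <- tr[tr$period_start >= 1826, ]
  expect_true(any(abs(late$mean_inbreeding - late$mean_kinship) > 1e-4))
})
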