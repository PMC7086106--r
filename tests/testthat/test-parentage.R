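trio_tab <- function(off, mom, dad, loci) {
  genotype_table(c("o", "m", "f"), loci,
                 a1 = rbind(vapply(off, `[`, "", 1), vapply(mom, `[`, "", 1),
                            vapply(dad, `[`, "", 1)),
                 a2 = rbind(vapply(off, `[`, "", 2), vapply(mom, `[`, "", 2),
                            vapply(dad, `[`, "", 2)))
}

test_that("trio likelihood reproduces Mendelian closed forms", {
  loc <- list(locus("L1", c("A", "B"), c(0.6, 0.4)))
  # AA x BB parents force an AB offspring: transmission probability 1
  tab <- trio_tab(list(c("A", "B")), list(c("A", "A")), list(c("B", "B")), loc)
  ll <- trio_loglik(tab, "o", "m", "f", error_model(0, 0))
  expect_equal(ll, log(0.6^2 * 0.4^2 * 1), tolerance = 1e-12)

  # error-free exclusion: offspring AA with candidate father BB
  tab <- trio_tab(list(c("A", "A")), list(c("A", "A")), list(c("B", "B")), loc)
  expect_equal(trio_loglik(tab, "o", "m", "f", error_model(0, 0)), -Inf)

  # with dropout the same trio has a finite penalty
  ll <- trio_loglik(tab, "o", "m", "f", error_model(0.01, 0))
  expect_true(is.finite(ll))
})

test_that("trio likelihood equals the exhaustive true-genotype state sum", {
  set.seed(81)
  for (case in 1:20) {
    loci <- test_loci(seed = 810 + case, n_loci = 3)
    tab <- random_table(3, loci)
    err <- error_model(dropout = stats::runif(1, 0, 0.1),
                       misprint = stats::runif(1, 0, 0.1))
    ll <- trio_loglik(tab, tab$ids[1], tab$ids[2], tab$ids[3], err)
    orc <- oracle_trio_loglik(tab, tab$ids[1], tab$ids[2], tab$ids[3], err)
    expect_equal(ll, orc, tolerance = 1e-9)
  }
})

test_that("father assignment normalizes posteriors and applies the threshold", {
  loci <- test_loci(seed = 83, n_loci = 8)
  set.seed(83)
  des <- simulation_design(seed = NULL)
  b <- build_scenario(2, des)
  o <- b$truth$offspring[1]
  males <- b$roster$id[b$roster$sex == "M"]
  res <- assign_father(b$table, o, b$truth$mother[1], males,
                       error = des$error)
  expect_equal(sum(res$posteriors), 1, tolerance = 1e-9)
  expect_true(res$result$assigned == (res$result$posterior >= 0.8 &&
                                        res$result$status == "ok"))

  # single feasible consistent candidate: posterior exactly 1
  res1 <- assign_father(b$table, o, b$truth$mother[1], b$truth$father[1],
                        error = des$error)
  expect_equal(unname(res1$posteriors), 1)
  expect_true(res1$result$assigned)
})

test_that("a 3:1 likelihood ratio gives 0.75/0.25 and stays unassigned at 0.80", {
  post <- matesys:::posterior_from_loglik(log(c(3, 1)))
  expect_equal(post, c(0.75, 0.25))
  row <- matesys:::assignment_row("o", stats::setNames(post, c("f1", "f2")),
                                  0.8)
  expect_false(row$assigned)
  expect_equal(row$father, "f1")

  # exact tie between top candidates is conservatively unassigned
  row <- matesys:::assignment_row("o", c(f1 = 0.5, f2 = 0.5), 0.3)
  expect_false(row$assigned)
  expect_equal(row$status, "tie")
})

test_that("all-excluded offspring are reported, not assigned", {
  loc <- list(locus("L1", c("A", "B"), c(0.6, 0.4)))
  tab <- trio_tab(list(c("A", "A")), list(c("A", "A")), list(c("B", "B")), loc)
  res <- assign_father(tab, "o", "m", "f", error = error_model(0, 0))
  expect_equal(res$result$status, "all_excluded")
  expect_false(res$result$assigned)
})

test_that("parent-pair marginals equal brute-force joint enumeration", {
  set.seed(87)
  loci <- test_loci(seed = 870, n_loci = 5)
  des <- simulation_design(n_fathers = 4, n_mothers = 5, n_mothers_total = 5,
                           n_offspring = 8, cohort_years = 8,
                           seed = NULL)
  ped <- simulate_pedigree(des, loci)
  males <- ped$roster$id[ped$roster$sex == "M"]
  females <- ped$roster$id[ped$roster$sex == "F"]
  err <- des$error
  for (o in ped$truth$offspring) {
    res <- assign_parent_pair(ped$table, o, females, males, error = err)
    # oracle: trio likelihood for every (mother, father) pair
    L <- outer(females, males, Vectorize(function(m, f) {
      exp(trio_loglik(ped$table, o, m, f, err))
    }))
    marg <- colSums(L) / sum(L)
    expect_equal(unname(res$posteriors), marg, tolerance = 1e-9)
  }
})

test_that("the father marginal depends on mothers only through their genotypes", {
  loci <- test_loci(seed = 89, n_loci = 6)
  set.seed(89)
  tab <- random_table(6, loci)
  ids <- tab$ids
  # swap a candidate mother for a different individual with identical calls
  tab2 <- genotype_table(c(ids, "dup"), loci,
                         rbind(tab$a1, tab$a1[2, , drop = FALSE]),
                         rbind(tab$a2, tab$a2[2, , drop = FALSE]))
  r1 <- assign_parent_pair(tab2, ids[1], c(ids[2], ids[3]),
                           c(ids[4], ids[5]))
  r2 <- assign_parent_pair(tab2, ids[1], c("dup", ids[3]),
                           c(ids[4], ids[5]))
  expect_equal(unname(r1$posteriors), unname(r2$posteriors),
               tolerance = 1e-9)
})

test_that("temporal feasibility uses conception dates and half-open windows", {
  roster <- data.frame(
    id = c("early", "whole", "late"),
    start = as.Date(c("1995-01-01", "1995-01-01", "2003-01-01")),
    end = as.Date(c("1997-06-30", "2009-01-01", "2009-01-01")),
    stringsAsFactors = FALSE)
  # born Nov 1998 -> conceived Jul 1997: male dying June 1997 is excluded
  keep <- filter_candidates_by_window(as.Date("1998-11-15"), roster)
  expect_setequal(keep, c("whole"))
  # born within the early male's window + gestation: feasible
  keep <- filter_candidates_by_window(as.Date("1998-06-15"), roster)
  expect_true("early" %in% keep)
  # boundary: birth exactly at window-end + gestation is excluded
  # (12-month gestation keeps the arithmetic exact in floating point)
  roster_num <- data.frame(id = c("a", "b"), start = c(0, 0), end = c(2, 8))
  keep <- filter_candidates_by_window(3, roster_num, gestation_months = 12)
  expect_setequal(keep, "b")
  # just inside the window is kept
  keep <- filter_candidates_by_window(2.99, roster_num, gestation_months = 12)
  expect_setequal(keep, c("a", "b"))
  # missing window: retained with a warning
  roster_na <- data.frame(id = "x", start = NA_real_, end = NA_real_)
  expect_warning(keep <- filter_candidates_by_window(1, roster_na), "x")
  expect_equal(keep, "x")
})

test_that("assignments with posterior >= 0.8 are at least 80% correct", {
  des <- simulation_design(n_fathers = 13, n_mothers = 100,
                           n_mothers_total = 100, n_offspring = 500,
                           cohort_years = 8, seed = 93)
  b <- build_scenario(2, des)
  res <- assign_scenario(b, 0.8)
  expect_gte(mean(res$correct[res$assigned]), 0.8)
})

test_that("information never hurts: scenario and locus monotonicity", {
  des <- simulation_design()
  p5 <- run_scenario_power(2, simulation_design(n_loci = 5),
                           replicates = 8, seed = 95)
  p10 <- run_scenario_power(2, des, replicates = 8, seed = 95)
  expect_gte(p10$mean, p5$mean)

  # perfect-information limit: many-allele loci, no error
  des_perfect <- simulation_design(alleles_per_locus = 12, max_pic = 1,
                                   error = error_model(0, 0))
  for (s in 1:3) {
    p <- run_scenario_power(s, des_perfect, replicates = 2, seed = 97)
    expect_equal(p$mean, 100)
  }
})
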