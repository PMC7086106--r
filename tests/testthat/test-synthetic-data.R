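test_that("frequency generation is seeded, calibrated and symmetric in the limit", {
  des <- simulation_design(seed = 7)
  l1 <- generate_frequencies(des)
  l2 <- generate_frequencies(des)
  expect_identical(l1, l2)  # byte-identical under a fixed seed

  # allele numbers within 2..4 and every locus below the PIC ceiling
  ks <- vapply(l1, function(l) length(l$alleles), 0L)
  expect_true(all(ks >= 2 & ks <= 4))
  pics <- vapply(l1, function(l) matesys:::pic_from_freqs(l$freqs), 0)
  expect_true(all(pics < 0.5))

  # concentration -> infinity with k = 2 gives frequencies -> (0.5, 0.5)
  des_inf <- simulation_design(alleles_per_locus = 2, dirichlet_alpha = 1e7,
                               seed = 8)
  l <- generate_frequencies(des_inf)
  expect_true(all(abs(vapply(l, function(x) x$freqs[[1]], 0) - 0.5) < 0.01))
})

test_that("pedigrees are Mendelian-consistent before observation errors", {
  des <- simulation_design(error = error_model(0, 0), seed = 21)
  ped <- simulate_pedigree(des)
  tab <- ped$clean_table
  for (r in seq_len(nrow(ped$truth))) {
    o <- ped$truth$offspring[r]
    for (par in c(ped$truth$mother[r], ped$truth$father[r])) {
      oc <- individual_calls(tab, o)
      pc <- individual_calls(tab, par)
      share <- vapply(seq_along(tab$loci), function(l) {
        length(intersect(oc[, l], pc[, l])) > 0
      }, TRUE)
      expect_true(all(share))
    }
  }
  # with zero error rates observed and clean tables coincide
  expect_identical(ped$table$a1, ped$clean_table$a1)
})

test_that("conceptions fall inside both parents' presence windows", {
  des <- simulation_design(seed = 23)
  ped <- simulate_pedigree(des)
  ros <- ped$roster
  for (r in seq_len(nrow(ped$truth))) {
    for (par in c(ped$truth$mother[r], ped$truth$father[r])) {
      w <- ros[ros$id == par, ]
      expect_true(w$start <= ped$truth$conception[r] &&
                    ped$truth$conception[r] < w$end)
    }
    expect_equal(ped$truth$birth[r] - ped$truth$conception[r], 16 / 12)
  }
})

test_that("the father allocator reproduces the target mean sibship", {
  # Monte-Carlo check of the calibrated Dirichlet-multinomial: mean
  # sibship among sires within 5% of 5.6 over 200 replicates
  set.seed(27)
  des <- simulation_design()
  sib <- numeric(0)
  for (r in 1:200) {
    for (c in seq_along(des$n_fathers)) {
      alpha <- matesys:::calibrate_dm_alpha(des$n_fathers[c],
                                            des$n_offspring[c], 5.6)
      cnt <- matesys:::draw_counts(des$n_offspring[c], des$n_fathers[c], alpha)
      sib <- c(sib, mean(cnt[cnt > 0]))
    }
  }
  expect_lt(abs(mean(sib) - 5.6) / 5.6, 0.05)
})

test_that("founder genotypes reproduce the input allele frequencies", {
  set.seed(29)
  loc <- locus("L1", c("1", "2", "3"), c(0.5, 0.3, 0.2))
  g <- matesys:::founder_genomes(500, list(loc))
  obs <- tabulate(c(g$a1, g$a2), 3)
  gof <- stats::chisq.test(obs, p = c(0.5, 0.3, 0.2))
  expect_gt(gof$p.value, 0.01)
})

test_that("infeasible designs are rejected", {
  expect_error(
    simulation_design(n_fathers = 2, n_mothers = 2, n_mothers_total = 2,
                      n_offspring = 30, cohort_years = 8, max_litter = 3),
    "infeasible")
})

test_that("kinship-category dyads realize their IBD structure", {
  loci <- test_loci(seed = 33)
  set.seed(33)
  # PO dyads share an allele at every error-free locus
  d <- simulate_dyads("PO", 30, loci)
  for (i in seq_len(30)) {
    c1 <- individual_calls(d$table, d$pairs$id1[i])
    c2 <- individual_calls(d$table, d$pairs$id2[i])
    expect_true(all(vapply(seq_along(loci), function(l) {
      length(intersect(c1[, l], c2[, l])) > 0
    }, TRUE)))
  }

  # U dyads: per-locus genotype independence -- allele-sharing frequency
  # matches the closed-form probability from the allele frequencies
  n_u <- 400
  d <- simulate_dyads("U", n_u, loci)
  share_prob <- function(p) {
    # P(two independent HWE genotypes share at least one allele)
    k <- length(p)
    tot <- 0
    for (i in seq_len(k)) for (j in i:k) {
      g1 <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      none <- sum((if (i == j) p[-i] else p[-c(i, j)]))^2
      tot <- tot + g1 * (1 - none)
    }
    tot
  }
  exp_share <- mean(vapply(loci, function(l) share_prob(l$freqs), 0))
  obs <- mean(vapply(seq_len(n_u), function(i) {
    c1 <- individual_calls(d$table, d$pairs$id1[i])
    c2 <- individual_calls(d$table, d$pairs$id2[i])
    mean(vapply(seq_along(loci), function(l) {
      length(intersect(c1[, l], c2[, l])) > 0
    }, TRUE))
  }, 0))
  expect_lt(abs(obs - exp_share), 0.03)

  # HS dyads: mean locus-sharing above U by about the r = 0.25 IBD boost:
  # share = 0.25 * 1 + 0.75 * P(share | unrelated) per locus
  d <- simulate_dyads("HS", n_u, loci)
  obs_hs <- mean(vapply(seq_len(n_u), function(i) {
    c1 <- individual_calls(d$table, d$pairs$id1[i])
    c2 <- individual_calls(d$table, d$pairs$id2[i])
    mean(vapply(seq_along(loci), function(l) {
      length(intersect(c1[, l], c2[, l])) > 0
    }, TRUE))
  }, 0))
  exp_hs <- 0.5 * 1 + 0.5 * exp_share  # k1 = 1/2 for half sibs
  expect_lt(abs(obs_hs - exp_hs), 0.03)
})

test_that("scenario bundles expose the right information structure", {
  des <- simulation_design(seed = 37)
  b1 <- build_scenario(1, des)
  expect_null(b1$known_mothers)
  expect_length(b1$runs, 1L)
  expect_equal(length(b1$runs[[1]]$candidate_fathers), 13L)
  expect_equal(length(b1$runs[[1]]$offspring), 68L)
  expect_equal(sum(b1$roster$sex == "F"), 33L)

  b2 <- build_scenario(2, des)
  expect_equal(length(b2$known_mothers), 68L)
  expect_equal(unname(b2$known_mothers[b2$truth$offspring]), b2$truth$mother)

  b3 <- build_scenario(3, des)
  expect_length(b3$runs, 2L)
  pools <- lapply(b3$runs, `[[`, "candidate_fathers")
  expect_true(all(lengths(pools) <= 7))
  expect_length(intersect(pools[[1]], pools[[2]]), 0L)
  expect_equal(lengths(lapply(b3$runs, `[[`, "offspring")), c(36L, 32L))
  # cohort mother pools: 28 available to cohort 1, 23 to cohort 2
  expect_equal(length(unique(b3$truth$mother[b3$truth$cohort == 1])) <= 28, TRUE)
  expect_equal(length(unique(b3$truth$mother[b3$truth$cohort == 2])) <= 23, TRUE)

  expect_error(build_scenario(4, des), "unknown scenario")
})

test_that("seeded simulation is deterministic end to end", {
  des <- simulation_design(seed = 43)
  p1 <- simulate_pedigree(des)
  p2 <- simulate_pedigree(des)
  expect_identical(p1$table$a1, p2$table$a1)
  expect_identical(p1$truth, p2$truth)
})
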