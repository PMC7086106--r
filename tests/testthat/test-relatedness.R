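test_that("mode-conditional pair probabilities normalize and match the oracle", {
  set.seed(51)
  for (case in 1:6) {
    k <- sample(2:4, 1)
    p <- matesys:::rdirichlet1(rep(1, k))
    loc <- locus("L1", as.character(seq_len(k)), p)
    A <- matesys:::genotype_pair_mode_probs(loc)
    # each IBD mode is a proper distribution over genotype pairs
    expect_equal(unname(apply(A, 3, sum)), rep(1, 9), tolerance = 1e-9)
    # spot-check entries against the canonical-partition enumeration oracle
    gi <- attr(A, "gi"); gj <- attr(A, "gj")
    for (pick in 1:10) {
      g1 <- sample(length(gi), 1); g2 <- sample(length(gi), 1)
      mode <- sample(paste0("D", 1:9), 1)
      expect_equal(unname(A[g1, g2, mode]),
                   oracle_pair_prob(c(gi[g1], gj[g1]), c(gi[g2], gj[g2]),
                                    mode, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("dyad log-likelihood reduces to closed forms at pure modes", {
  loc <- locus("L1", c("A", "B"), c(0.7, 0.3))
  tab <- genotype_table(c("x", "y"), list(loc),
                        a1 = cbind(c("A", "A")), a2 = cbind(c("A", "B")))
  pA <- 0.7; pB <- 0.3
  # unrelated: product of HWE genotype probabilities
  expect_equal(dyad_loglik(tab, "x", "y", c(1, 0, 0)),
               log(pA^2 * 2 * pA * pB), tolerance = 1e-12)
  # parent-offspring: P(AA) * p_B (transmission of the non-shared allele)
  expect_equal(dyad_loglik(tab, "x", "y", c(0, 1, 0)),
               log(pA^2 * pB), tolerance = 1e-12)
  # identical-by-descent pair with different genotypes is impossible
  expect_equal(as.numeric(dyad_loglik(tab, "x", "y", c(0, 0, 1))), -Inf)
})

test_that("dyad log-likelihood equals the exhaustive mode-sum for random weights", {
  set.seed(53)
  loci <- test_loci(seed = 530, n_loci = 4)
  tab <- random_table(6, loci)
  for (case in 1:20) {
    ids <- sample(tab$ids, 2)
    w <- matesys:::rdirichlet1(rep(1, 3))
    ll <- dyad_loglik(tab, ids[1], ids[2], w)
    # oracle: per locus, sum the canonical-partition mode probabilities
    orc <- 0
    for (l in seq_along(loci)) {
      c1 <- individual_calls(tab, ids[1])[, l]
      c2 <- individual_calls(tab, ids[2])[, l]
      p <- loci[[l]]$freqs
      ix <- function(g) match(g, loci[[l]]$alleles)
      probs <- vapply(c("D9", "D8", "D7"), function(m) {
        oracle_pair_prob(ix(c1), ix(c2), m, as.numeric(p))
      }, 0)
      orc <- orc + log(sum(w * probs))
    }
    expect_equal(ll, orc, tolerance = 1e-9)
  }
})

test_that("DyadML hits boundaries and is invariant to relabeling and locus order", {
  # many informative loci, identical heterozygotes -> r near 1
  loci <- lapply(1:20, function(l) {
    locus(sprintf("L%02d", l), c("1", "2", "3", "4"), rep(0.25, 4))
  })
  tab <- genotype_table(c("x", "y"), loci,
                        matrix("1", 2, 20), matrix("2", 2, 20))
  est <- estimate_dyadml(tab, "x", "y")
  expect_gt(est$r, 0.9)
  expect_gt(est$k[["k2"]], 0.8)

  set.seed(57)
  loci <- test_loci(seed = 570, n_loci = 6)
  tab <- random_table(4, loci)
  r0 <- estimate_dyadml(tab, tab$ids[1], tab$ids[2])$r

  # permute allele labels at every locus
  perm_loci <- list(); a1 <- tab$a1; a2 <- tab$a2
  for (l in seq_along(loci)) {
    k <- length(loci[[l]]$alleles)
    prm <- sample(k)
    # relabel allele i as prm[i], keeping its frequency
    perm_loci[[l]] <- locus(loci[[l]]$name, as.character(prm),
                            as.numeric(loci[[l]]$freqs))
    map <- stats::setNames(as.character(prm), loci[[l]]$alleles)
    a1[, l] <- map[a1[, l]]; a2[, l] <- map[a2[, l]]
  }
  tab_perm <- genotype_table(tab$ids, perm_loci, a1, a2)
  expect_equal(estimate_dyadml(tab_perm, tab$ids[1], tab$ids[2])$r, r0,
               tolerance = 1e-6)

  # permute locus order
  ord <- sample(length(loci))
  tab_ord <- genotype_table(tab$ids, tab$loci[ord],
                            tab$a1[, ord, drop = FALSE],
                            tab$a2[, ord, drop = FALSE])
  expect_equal(estimate_dyadml(tab_ord, tab$ids[1], tab$ids[2])$r, r0,
               tolerance = 1e-6)
})

test_that("DyadML recovers simulated kinship at desk scale", {
  loci <- test_loci(seed = 59)
  set.seed(59)
  med <- vapply(c("PO", "U"), function(cat) {
    d <- simulate_dyads(cat, 40, loci)
    stats::median(estimate_relatedness(d$table, d$pairs)$r)
  }, 0)
  expect_lt(abs(med[["PO"]] - 0.5), 0.1)
  expect_lt(med[["U"]], 0.1)
})

test_that("moment estimators: clone identity, hand algebra and unbiasedness", {
  # Queller-Goodnight returns exactly 1 for a clonal pair
  loci <- test_loci(seed = 61, n_loci = 5)
  tab <- random_table(1, loci)
  tab2 <- genotype_table(c("c1", "c2"), loci,
                         rbind(tab$a1, tab$a1), rbind(tab$a2, tab$a2))
  expect_equal(estimate_moment(tab2, "c1", "c2", "queller_goodnight")$r, 1,
               tolerance = 1e-12)

  # hand-built two-locus case evaluated with the single-locus formulas
  l1 <- locus("L1", c("A", "B"), c(0.6, 0.4))
  l2 <- locus("L2", c("A", "B", "C"), c(0.5, 0.3, 0.2))
  tab <- genotype_table(c("u", "v"), list(l1, l2),
                        a1 = cbind(c("A", "A"), c("A", "B")),
                        a2 = cbind(c("B", "A"), c("B", "C")))
  # QG by hand: locus terms for both reference orderings
  qg_num <- function(x, y, p) {
    S <- function(a, b) as.numeric(a == b)
    0.5 * (S(x[1], y[1]) + S(x[1], y[2]) + S(x[2], y[1]) + S(x[2], y[2])) -
      p[[x[1]]] - p[[x[2]]]
  }
  qg_den <- function(x, y, p) 1 + as.numeric(x[1] == x[2]) -
    p[[x[1]]] - p[[x[2]]]
  x1 <- c("A", "B"); y1 <- c("A", "A"); x2 <- c("A", "B"); y2 <- c("B", "C")
  num <- qg_num(x1, y1, l1$freqs) + qg_num(y1, x1, l1$freqs) +
    qg_num(x2, y2, l2$freqs) + qg_num(y2, x2, l2$freqs)
  den <- qg_den(x1, y1, l1$freqs) + qg_den(y1, x1, l1$freqs) +
    qg_den(x2, y2, l2$freqs) + qg_den(y2, x2, l2$freqs)
  expect_equal(estimate_moment(tab, "u", "v", "queller_goodnight")$r,
               num / den, tolerance = 1e-12)

  # all three moment estimators are near-unbiased for unrelated dyads
  loci <- test_loci(seed = 63)
  set.seed(63)
  d <- simulate_dyads("U", 400, loci)
  for (est in c("queller_goodnight", "lynch_ritland", "wang")) {
    r <- estimate_relatedness(d$table, d$pairs, est)$r
    r <- r[is.finite(r)]
    se <- stats::sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r)), 3 * se + 0.01)
  }
})

test_that("estimator benchmark ranks by overall RMSE and shows category overlap", {
  loci <- test_loci(seed = 67)
  set.seed(67)
  sets <- lapply(c(PO = "PO", HS = "HS", U = "U"), function(cat) {
    simulate_dyads(cat, 30, loci)
  })
  bm <- benchmark_estimators(sets,
                             estimators = c("dyadml", "queller_goodnight"))
  expect_setequal(bm$ranking, c("dyadml", "queller_goodnight"))
  expect_identical(bm$ranking, names(sort(bm$overall_rmse)))
  expect_equal(nrow(bm$summary), 6L)
  # adjacent categories overlap in distribution (q3 of lower r category
  # exceeds q1 of the higher one for this weak panel)
  s <- bm$summary[bm$summary$estimator == "dyadml", ]
  expect_gt(s$q3[s$category == "U"], s$q1[s$category == "HS"])

  # an empty category is dropped with a warning
  sets$EMPTY <- list(table = sets$U$table,
                     pairs = sets$U$pairs[0, , drop = FALSE])
  expect_warning(benchmark_estimators(sets,
                                      estimators = c("dyadml",
                                                     "queller_goodnight")),
                 "EMPTY")
})

test_that("mate-relatedness comparison recovers a planted kin preference", {
  loci <- test_loci(seed = 71)
  set.seed(71)
  # males and a female pool; each male's mates are his closest relatives
  males <- sprintf("M%02d", 1:8)
  females <- sprintf("F%02d", 1:20)
  tab <- random_table(28, loci)
  tab <- genotype_table(c(males, females), tab$loci, tab$a1, tab$a2)
  r_mat <- sapply(females, function(f) {
    sapply(males, function(m) estimate_dyadml(tab, m, f)$r)
  })
  sire_offspring <- do.call(rbind, lapply(seq_along(males), function(i) {
    top <- females[order(r_mat[i, ], decreasing = TRUE)[1:4]]
    data.frame(father = males[i], mother = top, stringsAsFactors = FALSE)
  }))
  cmp <- compare_mate_relatedness(tab, sire_offspring, females)
  expect_gt(cmp$mean_mates, cmp$mean_available)
  expect_lt(cmp$p, 0.05)
  expect_equal(nrow(cmp$per_male), 8L)

  # null design: mates drawn uniformly -> no systematic difference
  sire_null <- do.call(rbind, lapply(males, function(m) {
    data.frame(father = m, mother = sample(females, 4),
               stringsAsFactors = FALSE)
  }))
  cmp0 <- compare_mate_relatedness(tab, sire_null, females)
  expect_gt(cmp0$p, 0.05)
})
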