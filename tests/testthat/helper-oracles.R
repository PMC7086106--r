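# Independent oracles used across the test files. Each re-derives the
# quantity from first principles (enumeration, direct summation) without
# touching the package's computational path.

# PIC by direct double summation over allele pairs
oracle_pic <- function(p) {
  k <- length(p)
  s <- 1 - sum(p^2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
  }
  s
}

# exact HWE p-value by enumerating every perfect matching of the
# (distinguishable) allele copies; feasible for <= ~5 individuals
oracle_hwe_p <- function(genotypes) {
  # genotypes: 2-column integer matrix of allele indices
  pool <- as.integer(t(genotypes))
  key <- function(g) {
    g <- cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
    paste(sort(paste(g[, 1], g[, 2])), collapse = ";")
  }
  counts <- new.env()
  pair_up <- function(rem) {
    if (!length(rem)) return(list(matrix(integer(0), 0, 2)))
    a <- rem[1L]
    out <- list()
    for (i in seq_along(rem)[-1L]) {
      rest <- pair_up(rem[-c(1L, i)])
      out <- c(out, lapply(rest, function(m) rbind(c(a, rem[i]), m)))
    }
    out
  }
  matchings <- pair_up(pool)
  keys <- vapply(matchings, key, "")
  tab <- table(keys)
  probs <- as.numeric(tab) / length(matchings)
  names(probs) <- names(tab)
  p_obs <- probs[[key(genotypes)]]
  sum(probs[probs <= p_obs + 1e-12])
}

# P(G1, G2 | IBD mode) by assigning one allele per IBD class of a
# canonical gene partition; genes of ind1 = (x1, x2), ind2 = (y1, y2)
oracle_pair_prob <- function(g1, g2, mode, p) {
  partitions <- list(
    D1 = list(c("x1", "x2", "y1", "y2")),
    D2 = list(c("x1", "x2"), c("y1", "y2")),
    D3 = list(c("x1", "x2", "y1"), "y2"),
    D4 = list(c("x1", "x2"), "y1", "y2"),
    D5 = list(c("y1", "y2", "x1"), "x2"),
    D6 = list(c("y1", "y2"), "x1", "x2"),
    D7 = list(c("x1", "y1"), c("x2", "y2")),
    D8 = list(c("x1", "y1"), "x2", "y2"),
    D9 = list("x1", "x2", "y1", "y2"))
  classes <- partitions[[mode]]
  k <- length(p)
  total <- 0
  grid <- expand.grid(rep(list(seq_len(k)), length(classes)))
  for (r in seq_len(nrow(grid))) {
    al <- list()
    pr <- 1
    for (c in seq_along(classes)) {
      a <- grid[r, c]
      pr <- pr * p[a]
      for (g in classes[[c]]) al[[g]] <- a
    }
    G1 <- sort(c(al$x1, al$x2)); G2 <- sort(c(al$y1, al$y2))
    if (identical(G1, sort(g1)) && identical(G2, sort(g2))) total <- total + pr
  }
  total
}

# trio log-likelihood by explicit triple sum over true genotype states,
# with its own observation-error algebra
oracle_trio_loglik <- function(table, offspring, mother, father, error) {
  loci <- table$loci
  obs_of <- function(id, l) {
    i <- match(id, table$ids)
    if (is.na(table$a1[i, l])) NULL else c(table$a1[i, l], table$a2[i, l])
  }
  p_obs_given_true <- function(obs, true, p) {
    # misprint branch
    hwe_prob <- if (obs[1] == obs[2]) p[[obs[1]]]^2 else 2 * p[[obs[1]]] * p[[obs[2]]]
    pr <- error$misprint * hwe_prob
    same <- setequal_pair(obs, true)
    if (true[1] != true[2]) {
      if (same) pr <- pr + (1 - error$misprint) * (1 - error$dropout)
      if (obs[1] == obs[2] && obs[1] %in% true) {
        pr <- pr + (1 - error$misprint) * error$dropout / 2
      }
    } else if (same) {
      pr <- pr + (1 - error$misprint)
    }
    pr
  }
  setequal_pair <- function(a, b) identical(sort(a), sort(b))
  ll <- 0
  for (l in seq_along(loci)) {
    p <- loci[[l]]$freqs
    als <- loci[[l]]$alleles
    gts <- list()
    for (i in seq_along(als)) for (j in i:length(als)) {
      gts[[length(gts) + 1L]] <- c(als[i], als[j])
    }
    hwe <- vapply(gts, function(g) {
      if (g[1] == g[2]) p[[g[1]]]^2 else 2 * p[[g[1]]] * p[[g[2]]]
    }, 0)
    mendel <- function(o, m, f) {
      pr <- 0
      for (am in m) for (af in f) {
        if (setequal_pair(c(am, af), o)) pr <- pr + 0.25
      }
      pr
    }
    oo <- obs_of(offspring, l); om <- obs_of(mother, l); of <- obs_of(father, l)
    tot <- 0
    for (tm in seq_along(gts)) for (tf in seq_along(gts)) for (to in seq_along(gts)) {
      pr <- hwe[tm] * hwe[tf] * mendel(gts[[to]], gts[[tm]], gts[[tf]])
      if (pr == 0) next
      if (!is.null(om)) pr <- pr * p_obs_given_true(om, gts[[tm]], p)
      if (!is.null(of)) pr <- pr * p_obs_given_true(of, gts[[tf]], p)
      if (!is.null(oo)) pr <- pr * p_obs_given_true(oo, gts[[to]], p)
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# two-sided Fisher p by enumerating all 2x2 tables with the observed margins
oracle_fisher_p <- function(x) {
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); n <- sum(x)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(x[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided signed-rank p by brute force over all sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% rk
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small genotype-table builder: one locus, explicit calls
toy_table <- function(calls, freqs = NULL, locus_name = "L1") {
  alleles <- sort(unique(unlist(calls)))
  loc <- locus(locus_name, alleles, freqs)
  ids <- sprintf("i%02d", seq_along(calls))
  genotype_table(ids, list(loc),
                 a1 = cbind(vapply(calls, `[`, "", 1L)),
                 a2 = cbind(vapply(calls, `[`, "", 2L)))
}

# multi-locus table from an allele-index array: list of per-locus calls
random_table <- function(n, loci) {
  g <- matesys:::founder_genomes(n, loci)
  matesys:::index_to_table(sprintf("r%03d", seq_len(n)), loci, g)
}

# a small default locus set for relatedness/parentage tests
test_loci <- function(seed = 202, n_loci = 10) {
  des <- simulation_design(n_loci = n_loci, seed = seed)
  generate_frequencies(des)
}
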