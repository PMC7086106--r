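#' Per-locus marker summary statistics
#'
#' Computes, over typed individuals at one locus: the number typed, the
#' number of distinct alleles observed, observed heterozygosity `Ho`,
#' unbiased expected heterozygosity `He = 2n/(2n-1) * (1 - sum p_i^2)`
#' (the small-sample correction used by CERVUS), and the polymorphic
#' information content `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`.
#' Frequencies are taken from the observed allele counts at the locus.
#'
#' @param table A [genotype_table()].
#' @param locus Locus name or index in `table$loci`.
#' @return A one-row data frame: `locus`, `n_typed`, `k_alleles`, `Ho`,
#'   `He`, `PIC`.
#' @examples
#' loc <- locus("L1", c("a", "b"), c(0.5, 0.5))
#' tab <- genotype_table(c("i1", "i2"), list(loc),
#'                       a1 = cbind(c("a", "a")), a2 = cbind(c("b", "b")))
#' summarize_locus(tab, "L1")
#' @export
summarize_locus <- function(table, locus) {
  l <- locus_index(table, locus)
  g1 <- table$a1[, l]; g2 <- table$a2[, l]
  ok <- !is.na(g1)
  if (!any(ok)) stop("no data at locus '", names(table$loci)[l], "'")
  n <- sum(ok)
  obs <- c(g1[ok], g2[ok])
  p <- as.numeric(table(obs)) / (2 * n)
  ho <- mean(g1[ok] != g2[ok])
  s2 <- sum(p^2)
  he <- (2 * n / (2 * n - 1)) * (1 - s2)
  if (length(p) == 1L) he <- 0
  # sum over i<j of 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
  pic <- 1 - s2 - (s2^2 - sum(p^4))
  data.frame(locus = names(table$loci)[l], n_typed = n,
             k_alleles = length(p), Ho = ho, He = he, PIC = pic,
             stringsAsFactors = FALSE)
}

#' Summaries for every locus of a table
#'
#' @inheritParams summarize_locus
#' @param hwe Also compute Hardy-Weinberg exact p-values (see
#'   [hwe_exact_test()]).
#' @param ... Passed on to [hwe_exact_test()].
#' @return Data frame with one row per locus.
#' @export
summarize_loci <- function(table, hwe = FALSE, ...) {
  out <- do.call(rbind, lapply(seq_along(table$loci),
                               function(l) summarize_locus(table, l)))
  if (hwe) {
    out$hwe_p <- vapply(seq_along(table$loci),
                        function(l) hwe_exact_test(table, l, ...), 0)
  }
  rownames(out) <- NULL
  out
}

locus_index <- function(table, locus) {
  l <- if (is.character(locus)) match(locus, names(table$loci)) else as.integer(locus)
  if (is.na(l) || l < 1L || l > length(table$loci)) {
    stop("unknown locus: ", locus)
  }
  l
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed genotype array given the allele
#' counts. The p-value is the total conditional probability of all genotype
#' arrays as likely or less likely than the observed one. For small allele
#' numbers the full array space is enumerated; otherwise (or when the
#' enumeration would exceed `max_tables`) a seed-respecting Monte-Carlo
#' permutation of the allele vector is used with `n_mc` permutations and
#' the add-one p-value correction.
#'
#' @inheritParams summarize_locus
#' @param method `"auto"` (exact when feasible), `"exact"` or `"mc"`.
#' @param n_mc Monte-Carlo permutations (default 10000).
#' @param max_tables Enumeration budget before falling back to Monte-Carlo.
#' @return The p-value, with attributes `method` ("exact", "mc" or
#'   "untestable") and `k_alleles`. A monomorphic locus returns 1 and is
#'   flagged untestable.
#' @export
hwe_exact_test <- function(table, locus, method = c("auto", "exact", "mc"),
                           n_mc = 10000, max_tables = 2e6) {
  method <- match.arg(method)
  l <- locus_index(table, locus)
  g1 <- table$a1[, l]; g2 <- table$a2[, l]
  ok <- !is.na(g1)
  if (!any(ok)) stop("no data at locus '", names(table$loci)[l], "'")
  al <- sort(unique(c(g1[ok], g2[ok])))
  k <- length(al)
  if (k == 1L) {
    return(structure(1, method = "untestable", k_alleles = 1L))
  }
  i1 <- match(g1[ok], al); i2 <- match(g2[ok], al)
  n <- sum(ok)
  counts <- matrix(0L, k, k)
  for (r in seq_len(n)) {
    a <- min(i1[r], i2[r]); b <- max(i1[r], i2[r])
    counts[a, b] <- counts[a, b] + 1L
  }
  # allele count = 2*homozygotes + all heterozygote cells touching i
  acount <- vapply(seq_len(k), function(i) {
    2L * counts[i, i] +
      sum(counts[i, seq_len(k) > i]) + sum(counts[seq_len(k) < i, i])
  }, 0L)
  logp_obs <- hwe_table_logprob(counts, acount, n)
  use_exact <- method == "exact" ||
    (method == "auto" && k <= 4L)
  if (use_exact) {
    res <- hwe_enumerate(acount, n, logp_obs, max_tables)
    if (!is.null(res)) {
      return(structure(res, method = "exact", k_alleles = k))
    }
    if (method == "exact") stop("exact HWE enumeration exceeded max_tables")
  }
  # Monte-Carlo permutation of the allele vector
  pool <- rep(seq_len(k), acount)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(pool)
    m1 <- pmin(perm[seq_len(n)], perm[n + seq_len(n)])
    m2 <- pmax(perm[seq_len(n)], perm[n + seq_len(n)])
    cnt <- matrix(0L, k, k)
    idx <- (m2 - 1L) * k + m1
    t_idx <- tabulate(idx, k * k)
    cnt[] <- t_idx
    lp <- hwe_table_logprob(cnt, acount, n)
    if (lp <= logp_obs + 1e-9) hits <- hits + 1L
  }
  structure((1 + hits) / (n_mc + 1), method = "mc", k_alleles = k)
}

# conditional probability of a genotype array given allele counts:
# P = n! 2^H prod(a_i!) / (prod n_ij! (2n)!)
hwe_table_logprob <- function(counts, acount, n) {
  het <- sum(counts) - sum(diag(counts))
  lfactorial(n) + het * log(2) + sum(lfactorial(acount)) -
    sum(lfactorial(counts[upper.tri(counts, diag = TRUE)])) -
    lfactorial(2 * n)
}

# full enumeration of genotype arrays with the given allele counts;
# returns NULL if the budget is exceeded
hwe_enumerate <- function(acount, n, logp_obs, max_tables) {
  k <- length(acount)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  psum <- 0
  ntab <- 0L
  counts <- matrix(0L, k, k)
  rec <- function(idx, rem) {
    if (ntab > max_tables) stop("budget")
    if (idx > nrow(cells)) {
      ntab <<- ntab + 1L
      lp <- hwe_table_logprob(counts, acount, n)
      if (lp <= logp_obs + 1e-9) psum <<- psum + exp(lp)
      return(invisible())
    }
    i <- cells[idx, 1]; j <- cells[idx, 2]
    last_of_row <- (j == k)
    if (i == j) {
      lo <- 0L; hi <- rem[i] %/% 2L
      if (last_of_row) lo <- hi <- if (rem[i] %% 2L == 0L) rem[i] %/% 2L else -1L
      if (lo < 0L) return(invisible())
      for (v in lo:hi) {
        counts[i, j] <<- v
        rem2 <- rem; rem2[i] <- rem2[i] - 2L * v
        if (rem2[i] >= 0L) rec(idx + 1L, rem2)
      }
    } else {
      hi <- min(rem[i], rem[j])
      lo <- 0L
      if (last_of_row) {
        if (rem[i] > rem[j]) return(invisible())
        lo <- hi <- rem[i]
      }
      for (v in lo:hi) {
        counts[i, j] <<- v
        rem2 <- rem; rem2[i] <- rem2[i] - v; rem2[j] <- rem2[j] - v
        rec(idx + 1L, rem2)
      }
    }
    counts[cells[idx, 1], cells[idx, 2]] <<- 0L
    invisible()
  }
  ok <- tryCatch({ rec(1L, acount); TRUE },
                 error = function(e) {
                   if (conditionMessage(e) == "budget") FALSE else stop(e)
                 })
  if (!ok) return(NULL)
  min(1, psum)
}

#' Flag loci deviating from Hardy-Weinberg equilibrium
#'
#' Companion filter to [hwe_exact_test()]: computes the exact p-value for
#' every locus and flags those with `p < alpha` for exclusion. The default
#' threshold 0.001 reflects the conventional exclusion criterion for
#' markers used in parentage panels.
#'
#' @inheritParams summarize_loci
#' @param alpha Exclusion threshold on the HWE p-value.
#' @param ... Passed to [hwe_exact_test()].
#' @return Data frame: `locus`, `hwe_p`, `untestable`, `excluded`.
#' @export
hwe_filter <- function(table, alpha = 0.001, ...) {
  res <- lapply(seq_along(table$loci), function(l) hwe_exact_test(table, l, ...))
  data.frame(
    locus = names(table$loci),
    hwe_p = vapply(res, as.numeric, 0),
    untestable = vapply(res, function(x) attr(x, "method") == "untestable", TRUE),
    excluded = vapply(res, as.numeric, 0) < alpha,
    stringsAsFactors = FALSE
  )
}

#' Replicate-based genotyping-error rates
#'
#' Estimates the per-locus genotyping-error rate from repeated genotyping
#' of the same individuals: for each individual and locus, the modal
#' (most common) replicate genotype is taken as the reference (ties broken
#' by first occurrence across the replicate series) and the error rate is
#' the fraction of replicate genotypes that differ from it, pooled over
#' individuals. Missing replicate calls contribute nothing.
#'
#' @param replicate_tables List of [genotype_table()] objects (one per
#'   replicate run) over the same individuals and loci.
#' @return Data frame: `locus`, `n_genotypes` (non-missing replicate
#'   genotypes), `n_discordant`, `error_rate`.
#' @export
estimate_error_rates <- function(replicate_tables) {
  stopifnot(length(replicate_tables) >= 2L)
  ref <- replicate_tables[[1L]]
  for (t in replicate_tables[-1L]) {
    if (!identical(t$ids, ref$ids) || !identical(names(t$loci), names(ref$loci))) {
      stop("replicate tables must share individuals and loci")
    }
  }
  L <- length(ref$loci)
  n_tot <- n_err <- integer(L)
  for (l in seq_len(L)) {
    for (i in seq_along(ref$ids)) {
      g <- vapply(replicate_tables, function(t) {
        if (is.na(t$a1[i, l])) NA_character_
        else paste(t$a1[i, l], t$a2[i, l], sep = "/")
      }, "")
      g <- g[!is.na(g)]
      if (!length(g)) next
      cnt <- table(factor(g, levels = unique(g)))  # first-occurrence tie-break
      modal <- names(cnt)[which.max(cnt)]
      n_tot[l] <- n_tot[l] + length(g)
      n_err[l] <- n_err[l] + sum(g != modal)
    }
  }
  data.frame(locus = names(ref$loci), n_genotypes = n_tot,
             n_discordant = n_err,
             error_rate = ifelse(n_tot > 0, n_err / n_tot, NA_real_),
             stringsAsFactors = FALSE)
}
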