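#' @name relatedness
#' @title Pairwise relatedness from codominant markers
#' @description
#' The likelihood machinery works on the nine condensed identity-by-descent
#' (IBD) modes of a dyad (Jacquard's condensed coefficients
#' \eqn{\Delta_1..\Delta_9}). Without inbreeding only three modes are
#' possible, conventionally written as the k-coefficients
#' \eqn{(k_0, k_1, k_2) = (\Delta_9, \Delta_8, \Delta_7)}: the pair shares
#' zero, one or two alleles identical by descent at a locus. Relatedness is
#' the linear functional
#' \eqn{r = 2\Delta_1 + \Delta_3 + \Delta_5 + \Delta_7 + \Delta_8/2},
#' which reduces to \eqn{k_2 + k_1/2} for non-inbred dyads.
NULL

# P(drawing one more allele v ~ freqs yields unordered {s, v} == G), for
# every genotype G (rows) and shared allele s (cols)
half_pair_prob <- function(gi, gj, p) {
  k <- length(p)
  H <- matrix(0, length(gi), k)
  for (g in seq_along(gi)) {
    i <- gi[g]; j <- gj[g]
    if (i == j) H[g, i] <- p[i]
    else { H[g, i] <- p[j]; H[g, j] <- p[i] }
  }
  H
}

# memoization for the per-locus mode-probability arrays (they only depend
# on the allele frequencies, not on the dyad)
.pair_prob_cache <- new.env(parent = emptyenv())

# array [nG, nG, 9] of P(G1, G2 | IBD mode Delta_m) for one locus
genotype_pair_mode_probs <- function(locus) {
  key <- paste(c(locus$alleles, sprintf("%.15g", locus$freqs)),
               collapse = "|")
  hit <- .pair_prob_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- as.numeric(locus$freqs)
  k <- length(p)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  gi <- idx[, 1]; gj <- idx[, 2]
  nG <- length(gi)
  hwe <- ifelse(gi == gj, p[gi]^2, 2 * p[gi] * p[gj])
  hom <- gi == gj
  H <- half_pair_prob(gi, gj, p)
  A <- array(0, c(nG, nG, 9))
  ph <- ifelse(hom, p[gi], 0)             # P(inbred individual has G) = p_a
  A1 <- matrix(0, nG, nG)
  for (g in seq_len(nG)) if (hom[g]) A1[g, g] <- p[gi[g]]
  A[, , 1] <- A1
  A[, , 2] <- outer(ph, ph)
  A3 <- matrix(0, nG, nG)
  for (g1 in seq_len(nG)) if (hom[g1]) A3[g1, ] <- p[gi[g1]] * H[, gi[g1]]
  A[, , 3] <- A3
  A[, , 4] <- outer(ph, hwe)
  A[, , 5] <- t(A3)
  A[, , 6] <- outer(hwe, ph)
  A7 <- matrix(0, nG, nG); diag(A7) <- hwe
  A[, , 7] <- A7
  A[, , 8] <- H %*% (p * t(H))
  A[, , 9] <- outer(hwe, hwe)
  dimnames(A) <- list(NULL, NULL,
                      paste0("D", 1:9))
  attr(A, "gi") <- gi; attr(A, "gj") <- gj; attr(A, "hwe") <- hwe
  if (length(.pair_prob_cache) > 500L) {
    rm(list = ls(.pair_prob_cache), envir = .pair_prob_cache)
  }
  .pair_prob_cache[[key]] <- A
  A
}

# genotype index of an individual's call at one locus (NA if missing)
call_index <- function(table, id, l) {
  i <- match(id, table$ids)
  if (is.na(i)) stop("unknown individual '", id, "'")
  a1 <- table$a1[i, l]; a2 <- table$a2[i, l]
  if (is.na(a1)) return(NA_integer_)
  loc <- table$loci[[l]]
  k <- length(loc$alleles)
  i1 <- match(a1, loc$alleles); i2 <- match(a2, loc$alleles)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  which(idx[, 1] == min(i1, i2) & idx[, 2] == max(i1, i2))
}

# per-locus matrix of mode-conditional pair probabilities (loci x modes);
# rows for loci where either individual is untyped are dropped
dyad_mode_matrix <- function(table, id1, id2,
                             modes = c("k", "jacquard")) {
  modes <- match.arg(modes)
  L <- length(table$loci)
  sel <- if (modes == "k") c(9, 8, 7) else 1:9
  out <- matrix(NA_real_, L, length(sel))
  colnames(out) <- if (modes == "k") c("k0", "k1", "k2") else paste0("D", 1:9)
  for (l in seq_len(L)) {
    g1 <- call_index(table, id1, l); g2 <- call_index(table, id2, l)
    if (is.na(g1) || is.na(g2)) next
    A <- genotype_pair_mode_probs(table$loci[[l]])
    out[l, ] <- A[g1, g2, sel]
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Dyadic log-likelihood for given IBD-mode weights
#'
#' Evaluates \eqn{\sum_l \log \sum_m w_m P(G_{1l}, G_{2l} | m)} for a dyad,
#' the mixture-over-IBD-modes likelihood underlying the maximum-likelihood
#' relatedness estimator. Loci at which either individual is untyped are
#' skipped.
#'
#' @param table A [genotype_table()] (its loci carry the reference allele
#'   frequencies).
#' @param id1,id2 Individual identifiers.
#' @param weights Mode weights on the simplex: length 3 `(k0, k1, k2)` or
#'   length 9 (Jacquard \eqn{\Delta_1..\Delta_9}).
#' @return The log-likelihood; `-Inf` (with attribute `zero_locus`) if some
#'   locus has zero probability under every weighted mode.
#' @export
dyad_loglik <- function(table, id1, id2, weights) {
  stopifnot(length(weights) %in% c(3L, 9L), all(weights >= -1e-12),
            abs(sum(weights) - 1) < 1e-9)
  P <- dyad_mode_matrix(table, id1, id2,
                        modes = if (length(weights) == 3L) "k" else "jacquard")
  lik <- as.numeric(P %*% pmax(weights, 0))
  if (any(lik == 0)) {
    return(structure(-Inf, zero_locus = which(lik == 0)))
  }
  sum(log(lik))
}

relatedness_from_weights <- function(w) {
  if (length(w) == 3L) unname(w[3L] + w[2L] / 2)
  else unname(2 * w[1L] + w[3L] + w[5L] + w[7L] + w[8L] / 2)
}

#' Maximum-likelihood dyadic relatedness (DyadML)
#'
#' Maximizes the mixture likelihood of [dyad_loglik()] over the IBD-mode
#' simplex by expectation-maximization on the per-locus latent mode
#' indicators. The likelihood is concave in the mode weights, so the EM
#' fixed point is the global maximum; optional extra random restarts are
#' provided for reassurance. Relatedness is derived from the fitted
#' weights (`r = k2 + k1/2` without inbreeding).
#'
#' @inheritParams dyad_loglik
#' @param allow_inbreeding Use the nine-mode Jacquard space instead of the
#'   three non-inbred k-coefficients.
#' @param n_restarts Total EM starts (first start is uniform, the rest are
#'   Dirichlet(1) draws consuming the current RNG state).
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations per start.
#' @return An object of class `relatedness_estimate`: list with `dyad`,
#'   `estimator`, `r`, `k` (fitted weights), `loglik`, `n_loci`,
#'   `converged`.
#' @export
estimate_dyadml <- function(table, id1, id2, allow_inbreeding = FALSE,
                            n_restarts = 1, tol = 1e-8, max_iter = 10000) {
  P <- dyad_mode_matrix(table, id1, id2,
                        modes = if (allow_inbreeding) "jacquard" else "k")
  if (nrow(P) < 1L) stop("no informative locus for dyad ", id1, "/", id2)
  M <- ncol(P)
  em_run <- function(w) {
    ll_old <- -Inf
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      lik <- as.numeric(P %*% w)
      lik[lik < 1e-300] <- 1e-300
      ll <- sum(log(lik))
      if (ll + 1e-9 < ll_old) stop("EM decreased the log-likelihood")
      if (ll - ll_old < tol) { conv <- TRUE; break }
      ll_old <- ll
      resp <- (P * rep(w, each = nrow(P))) / lik
      w <- colMeans(resp)
      w <- w / sum(w)
    }
    list(w = w, loglik = ll, converged = conv)
  }
  best <- em_run(rep(1 / M, M))
  if (n_restarts > 1L) {
    for (s in seq_len(n_restarts - 1L)) {
      cand <- em_run(rdirichlet1(rep(1, M)))
      if (cand$loglik > best$loglik) best <- cand
    }
  }
  if (!best$converged) {
    warning("EM did not converge for dyad ", id1, "/", id2,
            "; best value reported")
  }
  w <- stats::setNames(best$w, colnames(P))
  structure(list(dyad = c(id1, id2), estimator = "dyadml",
                 r = relatedness_from_weights(w), k = w,
                 loglik = best$loglik, n_loci = nrow(P),
                 converged = best$converged),
            class = "relatedness_estimate")
}

#' @export
print.relatedness_estimate <- function(x, ...) {
  cat("<relatedness_estimate> ", paste(x$dyad, collapse = " - "),
      " (", x$estimator, "): r = ", signif(x$r, 4), "\n", sep = "")
  invisible(x)
}

#' Moment estimators of pairwise relatedness
#'
#' Three classical method-of-moment estimators. `"queller_goodnight"`:
#' ratio-of-sums allele-sharing estimator, symmetrized over the two
#' reference orderings. `"lynch_ritland"`: the regression estimator with
#' its locus weights, averaged over reference orderings. `"wang"`: the
#' similarity-class moment approach of Wang (2002), implemented as a
#' least-squares fit of the per-locus phenotypic similarity-class
#' indicators on their exact mode-conditional expectations (computed from
#' the allele frequencies), with `r = k2 + k1/2`. Moment estimates are not
#' constrained to `[0, 1]`. Monomorphic loci are skipped.
#'
#' @inheritParams dyad_loglik
#' @param estimator One of `"queller_goodnight"`, `"lynch_ritland"`,
#'   `"wang"`.
#' @return A `relatedness_estimate` (with `loglik = NA`).
#' @export
estimate_moment <- function(table, id1, id2,
                            estimator = c("queller_goodnight",
                                          "lynch_ritland", "wang")) {
  estimator <- match.arg(estimator)
  L <- length(table$loci)
  r <- switch(estimator,
    queller_goodnight = {
      num <- den <- 0
      for (l in seq_len(L)) {
        al <- dyad_alleles(table, id1, id2, l)
        if (is.null(al)) next
        p <- table$loci[[l]]$freqs
        if (max(p) >= 1 - 1e-12) next
        for (ref in 1:2) {
          x <- if (ref == 1) al$x else al$y
          y <- if (ref == 1) al$y else al$x
          S <- function(u, v) as.numeric(u == v)
          num <- num + 0.5 * (S(x[1], y[1]) + S(x[1], y[2]) +
                                S(x[2], y[1]) + S(x[2], y[2])) -
            p[[x[1]]] - p[[x[2]]]
          den <- den + 1 + S(x[1], x[2]) - p[[x[1]]] - p[[x[2]]]
        }
      }
      if (den == 0) NA_real_ else num / den
    },
    lynch_ritland = {
      num <- den <- 0
      for (l in seq_len(L)) {
        al <- dyad_alleles(table, id1, id2, l)
        if (is.null(al)) next
        p <- table$loci[[l]]$freqs
        if (max(p) >= 1 - 1e-12) next
        for (ref in 1:2) {
          x <- if (ref == 1) al$x else al$y
          y <- if (ref == 1) al$y else al$x
          pa <- p[[x[1]]]; pb <- p[[x[2]]]
          S <- function(u, v) as.numeric(u == v)
          Sab <- S(x[1], x[2])
          numer <- pa * (S(x[2], y[1]) + S(x[2], y[2])) +
            pb * (S(x[1], y[1]) + S(x[1], y[2])) - 4 * pa * pb
          denom <- (1 + Sab) * (pa + pb) - 4 * pa * pb
          # locus weight w = denom / (2 pa pb); weighted mean of
          # numer/denom telescopes to sum(numer/2papb) / sum(w)
          num <- num + numer / (2 * pa * pb)
          den <- den + denom / (2 * pa * pb)
        }
      }
      if (den == 0) NA_real_ else num / den
    },
    wang = {
      Y <- NULL; X <- NULL
      for (l in seq_len(L)) {
        al <- dyad_alleles(table, id1, id2, l)
        if (is.null(al)) next
        p <- table$loci[[l]]$freqs
        if (max(p) >= 1 - 1e-12) next
        A <- genotype_pair_mode_probs(table$loci[[l]])
        cls <- similarity_class_matrix(A)
        E <- vapply(c(9, 8, 7), function(m) {
          vapply(1:3, function(cc) sum(A[, , m][cls == cc]), 0)
        }, numeric(3))  # 3 classes x (k0, k1, k2)
        obs_cls <- similarity_class(al$x, al$y)
        y <- as.numeric(1:3 == obs_cls)
        Y <- c(Y, y - E[, 1])
        X <- rbind(X, cbind(E[, 2] - E[, 1], E[, 3] - E[, 1]))
      }
      if (is.null(X) || qr(X)$rank < 2L) NA_real_
      else {
        k12 <- qr.coef(qr(X), Y)
        unname(k12[2L] + k12[1L] / 2)
      }
    })
  structure(list(dyad = c(id1, id2), estimator = estimator,
                 r = unname(r), k = NULL, loglik = NA_real_,
                 n_loci = NA_integer_, converged = NA),
            class = "relatedness_estimate")
}

# allele labels of a dyad at locus l, or NULL if either is untyped
dyad_alleles <- function(table, id1, id2, l) {
  i1 <- match(id1, table$ids); i2 <- match(id2, table$ids)
  if (is.na(i1) || is.na(i2)) stop("unknown individual")
  if (is.na(table$a1[i1, l]) || is.na(table$a1[i2, l])) return(NULL)
  list(x = c(table$a1[i1, l], table$a2[i1, l]),
       y = c(table$a1[i2, l], table$a2[i2, l]))
}

# similarity class of a genotype pair: 1 identical, 2 one homozygote
# sharing its allele with a heterozygote, 3 two heterozygotes sharing one
# allele, 4 no allele in common (incl. two distinct homozygotes)
similarity_class <- function(x, y) {
  if (identical(sort(x), sort(y))) return(1L)
  if (length(intersect(unique(x), unique(y))) == 0L) return(4L)
  if (x[1] == x[2] || y[1] == y[2]) 2L else 3L
}

# class labels for every genotype pair of a mode-probability array
similarity_class_matrix <- function(A) {
  gi <- attr(A, "gi"); gj <- attr(A, "gj")
  nG <- length(gi)
  out <- matrix(0L, nG, nG)
  for (g1 in seq_len(nG)) for (g2 in seq_len(nG)) {
    out[g1, g2] <- similarity_class(c(gi[g1], gj[g1]), c(gi[g2], gj[g2]))
  }
  out
}

#' Estimate relatedness for a set of dyads
#'
#' @inheritParams dyad_loglik
#' @param pairs Data frame with columns `id1`, `id2` (extra columns are
#'   carried through).
#' @param estimator `"dyadml"` or one of the moment estimators of
#'   [estimate_moment()].
#' @param ... Passed to [estimate_dyadml()].
#' @return `pairs` with an added numeric column `r`.
#' @export
estimate_relatedness <- function(table, pairs, estimator = "dyadml", ...) {
  pairs$r <- vapply(seq_len(nrow(pairs)), function(i) {
    if (estimator == "dyadml") {
      estimate_dyadml(table, pairs$id1[i], pairs$id2[i], ...)$r
    } else {
      estimate_moment(table, pairs$id1[i], pairs$id2[i], estimator)$r
    }
  }, 0)
  pairs
}

#' Benchmark relatedness estimators on simulated dyads
#'
#' Summarizes each estimator's sampling distribution per kinship category
#' (median and quartiles of the estimates) and ranks estimators by overall
#' root-mean-square error against the categories' true relatedness.
#'
#' @param dyad_sets Named list of [simulate_dyads()] results (one per
#'   category).
#' @param estimators Character vector of estimator labels.
#' @param ... Passed to [estimate_dyadml()].
#' @return List with `summary` (data frame: estimator, category, r_true,
#'   n, median, q1, q3, rmse) and `ranking` (estimator labels, best
#'   first, by overall RMSE).
#' @export
benchmark_estimators <- function(dyad_sets,
                                 estimators = c("dyadml",
                                                "queller_goodnight",
                                                "lynch_ritland", "wang"),
                                 ...) {
  stopifnot(length(estimators) >= 2L)
  keep <- vapply(dyad_sets, function(s) nrow(s$pairs) > 0L, TRUE)
  if (any(!keep)) {
    warning("empty dyad categories excluded: ",
            paste(names(dyad_sets)[!keep], collapse = ", "))
    dyad_sets <- dyad_sets[keep]
  }
  stopifnot(length(dyad_sets) >= 2L)
  rows <- list()
  overall <- stats::setNames(numeric(length(estimators)), estimators)
  n_all <- 0L
  for (est in estimators) {
    sq_sum <- 0; n_est <- 0L
    for (nm in names(dyad_sets)) {
      s <- dyad_sets[[nm]]
      r <- estimate_relatedness(s$table, s$pairs, est, ...)$r
      ok <- is.finite(r)
      q <- stats::quantile(r[ok], c(0.25, 0.5, 0.75), names = FALSE)
      rt <- s$pairs$r_true[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, category = nm, r_true = rt, n = sum(ok),
        median = q[2], q1 = q[1], q3 = q[3],
        rmse = sqrt(mean((r[ok] - rt)^2)), stringsAsFactors = FALSE)
      sq_sum <- sq_sum + sum((r[ok] - rt)^2); n_est <- n_est + sum(ok)
    }
    overall[est] <- sqrt(sq_sum / n_est)
  }
  list(summary = do.call(rbind, rows),
       overall_rmse = overall,
       ranking = names(sort(overall)))
}

#' Compare sires' relatedness to mates versus available females
#'
#' For every male with at least one assigned offspring, computes his mean
#' relatedness to his genetic mates and to the whole pool of available
#' females, then applies a paired two-sided Wilcoxon signed-rank test to
#' the male-level pairs. A tendency to mate with relatives shows as
#' `mean_mates > mean_available`.
#'
#' @inheritParams dyad_loglik
#' @param sire_offspring Data frame with columns `father`, `mother` (one
#'   row per assigned offspring).
#' @param females_available Character vector of female ids.
#' @param estimator Relatedness estimator label.
#' @param ... Passed to [estimate_dyadml()].
#' @return List: `per_male` (data frame `male`, `n_mates`, `r_mates`,
#'   `r_available`), `mean_mates`, `mean_available`, `W`, `p`.
#' @export
compare_mate_relatedness <- function(table, sire_offspring,
                                     females_available,
                                     estimator = "dyadml", ...) {
  males <- unique(sire_offspring$father)
  males <- males[!is.na(males)]
  if (length(males) < 2L) stop("need at least two males with assigned offspring")
  rel <- function(male, fem) {
    mean(vapply(fem, function(f) {
      if (estimator == "dyadml") estimate_dyadml(table, male, f, ...)$r
      else estimate_moment(table, male, f, estimator)$r
    }, 0))
  }
  per_male <- do.call(rbind, lapply(males, function(m) {
    mates <- unique(sire_offspring$mother[sire_offspring$father == m])
    mates <- mates[!is.na(mates)]
    if (!length(mates)) return(NULL)
    data.frame(male = m, n_mates = length(mates),
               r_mates = rel(m, mates),
               r_available = rel(m, females_available),
               stringsAsFactors = FALSE)
  }))
  ws <- wilcoxon_signed_rank(per_male$r_mates, per_male$r_available)
  list(per_male = per_male,
       mean_mates = mean(per_male$r_mates),
       mean_available = mean(per_male$r_available),
       W = ws$W, p = ws$p)
}
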