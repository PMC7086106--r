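#' Tabulate mating and reproductive success from parentage
#'
#' For every individual in the roster, mating success `mat` is the number
#' of distinct genetic partners with which at least one assigned offspring
#' was produced, and reproductive success `rep` is the total number of
#' assigned offspring. Offspring lacking an assigned parent on either
#' side contribute to nobody's `mat`; offspring with an assigned focal
#' parent always count towards that parent's `rep`.
#'
#' @param parentage Data frame with one row per offspring and columns
#'   `mother`, `father` (`NA` where unassigned).
#' @param roster Data frame with columns `id`, `sex`, and optionally
#'   `cohort`, `n_max`, plus `start`/`end` or `residence` used to fill the
#'   residence time `n_i` (years); `residence` wins, else `end - start`.
#' @return Data frame of success records: `id`, `sex`, `cohort`, `mat`,
#'   `rep`, `n_i`.
#' @export
tabulate_success <- function(parentage, roster) {
  seen <- unique(c(parentage$mother, parentage$father))
  seen <- seen[!is.na(seen)]
  missing <- setdiff(seen, roster$id)
  if (length(missing)) {
    stop("parents absent from roster: ", paste(missing, collapse = ", "))
  }
  n_i <- if ("residence" %in% names(roster)) roster$residence
         else if (all(c("start", "end") %in% names(roster))) {
           as.numeric(roster$end) - as.numeric(roster$start)
         } else rep(NA_real_, nrow(roster))
  count_for <- function(id, own, other) {
    mine <- which(!is.na(own) & own == id)
    partners <- other[mine]
    c(mat = length(unique(partners[!is.na(partners)])), rep = length(mine))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$id[i]
    cnt <- if (roster$sex[i] == "M") {
      count_for(id, parentage$father, parentage$mother)
    } else {
      count_for(id, parentage$mother, parentage$father)
    }
    data.frame(id = id, sex = roster$sex[i],
               cohort = if ("cohort" %in% names(roster)) roster$cohort[i] else NA,
               mat = unname(cnt["mat"]), rep = unname(cnt["rep"]),
               n_i = n_i[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Nonacs' binomial skew index B
#'
#' \deqn{B = \sum_i (p_i - n_i/N_t)^2 - \frac{1 - 1/\acute{N}}{K}}
#' where `p_i` is individual `i`'s share of the `K` benefits (matings or
#' offspring), `n_i` its residence time, `N_t = sum n_i`, and the weighted
#' mean group size is `N-acute = N_t / n_max` with `n_max` the maximum
#' possible residence. `B = 0` is the expectation under purely random
#' (binomial) allocation proportional to residence; positive values mean
#' more skew than chance, negative values more evenness.
#'
#' @param benefits Non-negative counts (matings or offspring) per
#'   individual.
#' @param residence Residence times `n_i` (> 0), same length.
#' @param n_max Maximum possible residence time (scalar; for pooled groups
#'   with different maxima use the global maximum).
#' @return The index value (numeric scalar).
#' @examples
#' nonacs_b(c(1, 1), c(1, 1), n_max = 1)   # -0.25
#' nonacs_b(c(2, 0), c(1, 1), n_max = 1)   #  0.25
#' @export
nonacs_b <- function(benefits, residence, n_max) {
  stopifnot(length(benefits) == length(residence), all(benefits >= 0),
            all(residence > 0), n_max > 0)
  K <- sum(benefits)
  if (K == 0) stop("K = 0: the skew index is undefined without benefits")
  Nt <- sum(residence)
  Nacute <- Nt / n_max
  sum((benefits / K - residence / Nt)^2) - (1 - 1 / Nacute) / K
}

#' Monte-Carlo test of Nonacs' B against the random-allocation null
#'
#' Simulates the null hypothesis that each of the `K` benefits falls on
#' individual `i` with probability `n_i / N_t` (multinomial allocation
#' proportional to residence), recomputes `B` for each replicate, and
#' reports the add-one-smoothed one-tailed probability
#' `p = (1 + #\{B_null >= B_obs\}) / (n_sim + 1)` (or the doubled,
#' capped version when `alternative = "two.sided"`).
#'
#' @inheritParams nonacs_b
#' @param n_sim Number of null replicates (default 100000).
#' @param alternative `"greater"` (skew exceeding the null, the usual
#'   directional question) or `"two.sided"`.
#' @param seed Optional seed set before simulation.
#' @return List of class `skew_result`: `B`, `K`, `N`, `N_t`, `N_acute`,
#'   `n_max`, `null_sample`, `p`, `alternative`.
#' @export
nonacs_b_test <- function(benefits, residence, n_max, n_sim = 100000,
                          alternative = c("greater", "two.sided"),
                          seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  B_obs <- nonacs_b(benefits, residence, n_max)
  K <- sum(benefits); Nt <- sum(residence)
  null_B <- nonacs_b_null(K, residence, n_max, n_sim)
  p_hi <- (1 + sum(null_B >= B_obs)) / (n_sim + 1)
  p <- if (alternative == "greater") p_hi else {
    p_lo <- (1 + sum(null_B <= B_obs)) / (n_sim + 1)
    min(1, 2 * min(p_hi, p_lo))
  }
  structure(list(B = B_obs, K = K, N = length(benefits), N_t = Nt,
                 N_acute = Nt / n_max, n_max = n_max,
                 null_sample = null_B, p = p, alternative = alternative),
            class = "skew_result")
}

# vectorized null sample of B values under multinomial allocation
nonacs_b_null <- function(K, residence, n_max, n_sim) {
  Nt <- sum(residence)
  share <- residence / Nt
  cnt <- stats::rmultinom(n_sim, K, share)
  colSums((cnt / K - share)^2) - (1 - n_max / Nt) / K
}

#' @export
print.skew_result <- function(x, ...) {
  cat("<skew_result> B = ", signif(x$B, 3), ", K = ", x$K, ", N = ", x$N,
      ", p (", x$alternative, ") = ", signif(x$p, 3),
      " [", length(x$null_sample), " null draws]\n", sep = "")
  invisible(x)
}

#' Bateman gradient
#'
#' Ordinary least-squares slope of relative reproductive success
#' (`rep / mean(rep)`) on relative mating success (`mat / mean(mat)`),
#' the standard measure of the fitness return on additional mates.
#'
#' @param records Data frame with columns `mat` and `rep` (see
#'   [tabulate_success()]).
#' @return List of class `bateman_result`: `beta_ss`, `n`, `fit` (the
#'   underlying `lm`), plus the relative successes used.
#' @export
bateman_gradient <- function(records) {
  stopifnot(nrow(records) >= 3L)
  if (mean(records$mat) == 0 || mean(records$rep) == 0) {
    stop("relative success undefined: mean mating or reproductive success is 0")
  }
  if (stats::var(records$mat) == 0) {
    stop("Bateman gradient undefined: no variance in mating success")
  }
  rel_mat <- records$mat / mean(records$mat)
  rel_rep <- records$rep / mean(records$rep)
  fit <- stats::lm(rel_rep ~ rel_mat)
  structure(list(beta_ss = unname(stats::coef(fit)[2L]), n = nrow(records),
                 rel_mat = rel_mat, rel_rep = rel_rep, fit = fit),
            class = "bateman_result")
}

#' @export
print.bateman_result <- function(x, ...) {
  cat("<bateman_result> beta_SS = ", signif(x$beta_ss, 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
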