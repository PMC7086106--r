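#' @name parentage
#' @title Likelihood-based paternity assignment
#' @description
#' The assignment engine scores candidate parents by the full trio (or
#' parent-pair) likelihood of the observed genotypes under an explicit
#' observation error model (allelic dropout + misprints), summing over the
#' unobserved true genotypes of all three individuals. Candidate priors
#' are flat over the temporally feasible pool, which is treated as closed
#' (every true parent is among the candidates); "confidence" of an
#' assignment is then simply the posterior probability of the best
#' candidate, and an offspring is assigned when that posterior reaches the
#' confidence threshold (default 0.80).
NULL

# per-locus model pieces: unordered genotype list, HWE prior, observation
# matrix O[obs, true] and transmission matrix T2[(father-1)*nG + mother, child]
locus_model <- function(loc, error) {
  p <- as.numeric(loc$freqs)
  k <- length(p)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  gi <- idx[, 1]; gj <- idx[, 2]
  nG <- length(gi)
  hwe <- ifelse(gi == gj, p[gi]^2, 2 * p[gi] * p[gj])
  # observation model
  O <- matrix(0, nG, nG)
  for (t in seq_len(nG)) {
    base <- numeric(nG)
    if (gi[t] == gj[t]) {
      base[t] <- 1
    } else {
      base[t] <- 1 - error$dropout
      hom_i <- which(gi == gi[t] & gj == gi[t])
      hom_j <- which(gi == gj[t] & gj == gj[t])
      base[hom_i] <- base[hom_i] + error$dropout / 2
      base[hom_j] <- base[hom_j] + error$dropout / 2
    }
    O[, t] <- error$misprint * hwe + (1 - error$misprint) * base
  }
  # Mendelian transmission
  T2 <- matrix(0, nG * nG, nG)
  gidx <- matrix(0L, k, k)
  gidx[cbind(gi, gj)] <- seq_len(nG)
  gidx[cbind(gj, gi)] <- seq_len(nG)
  for (m in seq_len(nG)) for (f in seq_len(nG)) {
    row <- (f - 1L) * nG + m
    for (am in c(gi[m], gj[m])) for (af in c(gi[f], gj[f])) {
      ch <- gidx[min(am, af), max(am, af)]
      T2[row, ch] <- T2[row, ch] + 0.25
    }
  }
  list(nG = nG, gi = gi, gj = gj, hwe = hwe, O = O, T2 = T2, gidx = gidx,
       alleles = loc$alleles)
}

# engine: precomputed locus models + integer genotype indices per individual
parentage_engine <- function(table, error = error_model()) {
  models <- lapply(table$loci, locus_model, error = error)
  L <- length(table$loci)
  G <- matrix(NA_integer_, length(table$ids), L)
  for (l in seq_len(L)) {
    m <- models[[l]]
    ok <- !is.na(table$a1[, l])
    i1 <- match(table$a1[ok, l], m$alleles)
    i2 <- match(table$a2[ok, l], m$alleles)
    G[ok, l] <- m$gidx[cbind(i1, i2)]
  }
  rownames(G) <- table$ids
  list(models = models, G = G, ids = table$ids)
}

# observation likelihood vector P(obs_i | true = .) at locus l; all-ones if
# the call is missing
obs_vec <- function(engine, id, l) {
  m <- engine$models[[l]]
  g <- engine$G[id, l]
  if (is.na(g)) rep(1, m$nG) else m$O[g, ]
}

#' Trio log-likelihood under the genotyping-error model
#'
#' \eqn{\sum_l \log \sum_{T_m,T_f,T_o} P(T_m) P(T_f)\,
#' \mathrm{Mendel}(T_o | T_m, T_f)\, P(O_m|T_m) P(O_f|T_f) P(O_o|T_o)},
#' where the sums run over all true single-locus genotypes and parental
#' priors are Hardy-Weinberg. With error rates zero, a locus at which the
#' offspring is Mendelian-inconsistent with the pair contributes `-Inf`
#' (exclusion). Missing calls are skipped (flat observation likelihood).
#'
#' @param table A [genotype_table()].
#' @param offspring,mother,father Individual identifiers.
#' @param error An [error_model()].
#' @return Log-likelihood (may be `-Inf`).
#' @export
trio_loglik <- function(table, offspring, mother, father,
                        error = error_model()) {
  eng <- parentage_engine(table, error)
  sum(vapply(seq_along(eng$models), function(l) {
    m <- eng$models[[l]]
    vo <- obs_vec(eng, offspring, l)
    Mv <- matrix(m$T2 %*% vo, m$nG, m$nG)  # [mother, father]
    wm <- m$hwe * obs_vec(eng, mother, l)
    wf <- m$hwe * obs_vec(eng, father, l)
    log(as.numeric(wm %*% Mv %*% wf))
  }, 0))
}

# log-likelihood of each candidate father for one offspring, mother known
# (or NULL for a father-offspring pair likelihood)
father_logliks <- function(engine, offspring, mother, fathers) {
  L <- length(engine$models)
  ll <- numeric(length(fathers))
  for (l in seq_len(L)) {
    m <- engine$models[[l]]
    vo <- obs_vec(engine, offspring, l)
    Mv <- matrix(m$T2 %*% vo, m$nG, m$nG)
    wm <- if (is.null(mother)) m$hwe else m$hwe * obs_vec(engine, mother, l)
    a <- as.numeric(wm %*% Mv)            # row over father genotypes
    Wf <- vapply(fathers, function(f) m$hwe * obs_vec(engine, f, l),
                 numeric(m$nG))
    ll <- ll + log(as.numeric(a %*% Wf))
  }
  stats::setNames(ll, fathers)
}

# joint log-likelihood matrix over (mother, father) pairs for one offspring
pair_logliks <- function(engine, offspring, mothers, fathers) {
  L <- length(engine$models)
  ll <- matrix(0, length(mothers), length(fathers),
               dimnames = list(mothers, fathers))
  for (l in seq_len(L)) {
    m <- engine$models[[l]]
    vo <- obs_vec(engine, offspring, l)
    Mv <- matrix(m$T2 %*% vo, m$nG, m$nG)
    Wm <- t(vapply(mothers, function(x) m$hwe * obs_vec(engine, x, l),
                   numeric(m$nG)))
    Wf <- vapply(fathers, function(f) m$hwe * obs_vec(engine, f, l),
                 numeric(m$nG))
    ll <- ll + log(Wm %*% Mv %*% Wf)
  }
  ll
}

posterior_from_loglik <- function(ll) {
  if (all(!is.finite(ll))) return(rep(0, length(ll)))
  z <- exp(ll - max(ll[is.finite(ll)]))
  z[!is.finite(z)] <- 0
  z / sum(z)
}

assignment_row <- function(offspring, post, threshold) {
  if (all(post == 0)) {
    return(data.frame(offspring = offspring, father = NA_character_,
                      posterior = NA_real_, assigned = FALSE,
                      status = "all_excluded", stringsAsFactors = FALSE))
  }
  ord <- order(post, decreasing = TRUE)
  tie <- length(post) > 1L && abs(post[ord[1L]] - post[ord[2L]]) < 1e-12
  best <- names(post)[ord[1L]]
  data.frame(offspring = offspring, father = best,
             posterior = post[ord[1L]],
             assigned = !tie && post[ord[1L]] >= threshold,
             status = if (tie) "tie" else "ok",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign a father by trio likelihood with a known mother
#'
#' Posterior over the candidate fathers under a flat prior:
#' `posterior_i = L_i / sum_j L_j` with `L_i` the exponentiated
#' [trio_loglik()]. The best candidate is assigned when its posterior
#' reaches `threshold`; an exact likelihood tie between the top candidates
#' is conservatively left unassigned.
#'
#' @inheritParams trio_loglik
#' @param candidates Character vector of candidate father ids.
#' @param threshold Posterior confidence threshold (default 0.80).
#' @param birth,roster,gestation_months Optional temporal feasibility
#'   filter applied to `candidates` via [filter_candidates_by_window()].
#' @return A list: `result` (one-row data frame: `offspring`, `father`,
#'   `posterior`, `assigned`, `status`) and `posteriors` (named vector,
#'   the per-candidate ledger).
#' @export
assign_father <- function(table, offspring, mother, candidates,
                          error = error_model(), threshold = 0.8,
                          birth = NULL, roster = NULL,
                          gestation_months = 16) {
  if (!is.null(birth) && !is.null(roster)) {
    candidates <- filter_candidates_by_window(birth, roster[
      roster$id %in% candidates, , drop = FALSE], gestation_months)
  }
  if (!length(candidates)) stop("no temporally feasible candidate father")
  eng <- parentage_engine(table, error)
  ll <- father_logliks(eng, offspring, mother, candidates)
  post <- stats::setNames(posterior_from_loglik(ll), candidates)
  list(result = assignment_row(offspring, post, threshold),
       posteriors = post, loglik = ll)
}

#' Assign a father by joint parent-pair likelihood (mothers unknown)
#'
#' When no mother-offspring links are available, the engine places a flat
#' prior over all feasible (mother, father) pairs, computes the joint
#' pair likelihood, and assigns from the father's marginal posterior.
#'
#' @inheritParams assign_father
#' @param mothers,fathers Candidate mother and father ids.
#' @return As [assign_father()], with `posteriors` the father marginal and
#'   `joint` the full pair posterior matrix.
#' @export
assign_parent_pair <- function(table, offspring, mothers, fathers,
                               error = error_model(), threshold = 0.8) {
  eng <- parentage_engine(table, error)
  ll <- pair_logliks(eng, offspring, mothers, fathers)
  post <- posterior_from_loglik(as.numeric(ll))
  joint <- matrix(post, nrow(ll), ncol(ll), dimnames = dimnames(ll))
  father_marg <- colSums(joint)
  list(result = assignment_row(offspring, father_marg, threshold),
       posteriors = father_marg, joint = joint)
}

#' Temporal feasibility filter for candidate parents
#'
#' A candidate is feasible for an offspring if the conception date (birth
#' minus the gestation time, default 16 months) falls inside the
#' candidate's presence window, using the half-open convention
#' `[start, end)`. Candidates with missing window dates are retained with
#' a warning (permissive default).
#'
#' @param birth Offspring birth date (`Date`, or numeric years).
#' @param roster Data frame with columns `id`, `start`, `end` (same type
#'   as `birth`).
#' @param gestation_months Gestation length in months.
#' @return Character vector of feasible candidate ids.
#' @export
filter_candidates_by_window <- function(birth, roster,
                                        gestation_months = 16) {
  conc <- if (inherits(birth, "Date")) {
    seq(birth, by = "-1 month", length.out = gestation_months + 1L)[
      gestation_months + 1L]
  } else {
    birth - gestation_months / 12
  }
  missing_win <- is.na(roster$start) | is.na(roster$end)
  if (any(missing_win)) {
    warning("candidates with missing presence windows retained: ",
            paste(roster$id[missing_win], collapse = ", "))
  }
  ok <- missing_win | (roster$start <= conc & conc < roster$end)
  roster$id[ok]
}

#' Assign paternity for every offspring of a scenario bundle
#'
#' Runs the information scheme encoded in the bundle: joint parent-pair
#' assignment in scenario 1, known-mother trio assignment in scenario 2,
#' and cohort-restricted known-mother assignment in scenario 3.
#'
#' @param bundle A [build_scenario()] result.
#' @param threshold Posterior confidence threshold.
#' @return Data frame with one row per offspring: `offspring`, `father`
#'   (most likely candidate), `posterior`, `assigned`, `status`,
#'   `true_father`, `correct`.
#' @export
assign_scenario <- function(bundle, threshold = 0.8) {
  eng <- parentage_engine(bundle$table, bundle$design$error)
  mothers_all <- bundle$roster$id[bundle$roster$sex == "F"]
  rows <- list()
  for (run in bundle$runs) {
    for (o in run$offspring) {
      if (is.null(bundle$known_mothers)) {
        ll <- pair_logliks(eng, o, mothers_all, run$candidate_fathers)
        post <- posterior_from_loglik(as.numeric(ll))
        post <- colSums(matrix(post, nrow(ll), ncol(ll)))
        names(post) <- run$candidate_fathers
      } else {
        ll <- father_logliks(eng, o, bundle$known_mothers[[o]],
                             run$candidate_fathers)
        post <- stats::setNames(posterior_from_loglik(ll),
                                run$candidate_fathers)
      }
      rows[[length(rows) + 1L]] <- assignment_row(o, post, threshold)
    }
  }
  out <- do.call(rbind, rows)
  out$true_father <- bundle$truth$father[match(out$offspring,
                                               bundle$truth$offspring)]
  out$correct <- !is.na(out$father) & out$father == out$true_father
  out
}

#' Power of the parentage design under each scenario
#'
#' Replicates the scenario simulation and reports, per replicate, the
#' percentage of offspring whose true father is recovered as the most
#' likely candidate with posterior at or above the confidence threshold.
#'
#' @param scenario_id 1, 2 or 3.
#' @param design A [simulation_design()] (its `seed` element is ignored
#'   here; use `seed`).
#' @param replicates Number of replicate simulations (default 10).
#' @param threshold Posterior confidence threshold.
#' @param seed Optional integer seed set once before the replicate loop.
#' @return List of class `power_summary`: `scenario`, `replicates`, `pct`
#'   (per-replicate percentages), `mean`, `sd`.
#' @export
run_scenario_power <- function(scenario_id, design = simulation_design(),
                               replicates = 10, threshold = 0.8,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design$seed <- NULL
  pct <- vapply(seq_len(replicates), function(r) {
    bundle <- build_scenario(scenario_id, design)
    res <- assign_scenario(bundle, threshold)
    100 * mean(res$assigned & res$correct)
  }, 0)
  structure(list(scenario = scenario_id, replicates = replicates,
                 pct = pct, mean = mean(pct), sd = stats::sd(pct)),
            class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat("<power_summary> scenario ", x$scenario, ": ",
      sprintf("%.1f%% +/- %.1f", x$mean, x$sd),
      " (", x$replicates, " replicates)\n", sep = "")
  invisible(x)
}
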