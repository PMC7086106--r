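#' Horn-measurement composite by PCA
#'
#' Reduces the four horn measurements (anterior and posterior horn length
#' and circumference, all in cm) to the first principal component of a
#' centered, unscaled PCA. The sign is fixed so that the first
#' measurement column (anterior horn length) loads positively, making
#' larger composite values mean larger front horns.
#'
#' @param horns Numeric matrix or data frame, one row per male, four
#'   measurement columns; rownames (or an `id` column) identify males.
#' @return List: `scores` (named vector of PC1 scores), `loadings`,
#'   `var_explained` (percent of total variance on PC1, in %),
#'   `var_explained_all` (all components).
#' @export
horn_pc1 <- function(horns) {
  if (is.data.frame(horns) && "id" %in% names(horns)) {
    ids <- horns$id
    horns <- as.matrix(horns[setdiff(names(horns), "id")])
    rownames(horns) <- ids
  } else {
    horns <- as.matrix(horns)
  }
  stopifnot(nrow(horns) >= 3L)
  const <- apply(horns, 2, function(x) stats::var(x) == 0)
  if (any(const)) {
    stop("constant measurement column(s): ",
         paste(colnames(horns)[const], collapse = ", "))
  }
  pc <- stats::prcomp(horns, center = TRUE, scale. = FALSE)
  flip <- if (pc$rotation[1L, 1L] < 0) -1 else 1
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = stats::setNames(flip * pc$x[, 1L], rownames(horns)),
       loadings = flip * pc$rotation[, 1L],
       var_explained = ve[1L], var_explained_all = ve)
}

#' Spearman rank-correlation screen with Bonferroni E-values
#'
#' Correlates every covariate with each fitness component (`mat`, `rep`)
#' by the Spearman rank correlation with midrank ties; p-values use the
#' t-approximation (`exact = FALSE`). Each p-value is multiplied by the
#' number of tests in the screen to give an uncapped Bonferroni expected
#' value `E` (values above 1 are reported as such).
#'
#' @param covariates Data frame with an `id` column and one numeric
#'   column per trait.
#' @param success Data frame with columns `id`, `mat`, `rep` (see
#'   [tabulate_success()]).
#' @param n_tests Bonferroni multiplier (default 9, the conventional
#'   screen size: two male traits, six habitat metrics, relatedness).
#' @return Data frame: `trait`, `component`, `n`, `rho`, `p`, `E`. An
#'   all-tied covariate yields `NA` rho/p with a note in `status`.
#' @export
spearman_screen <- function(covariates, success, n_tests = 9) {
  stopifnot("id" %in% names(covariates))
  traits <- setdiff(names(covariates), "id")
  merged <- merge(covariates, success, by = "id")
  rows <- list()
  for (trait in traits) {
    for (comp in c("mat", "rep")) {
      x <- merged[[trait]]; y <- merged[[comp]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 4L || length(unique(x[ok])) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, component = comp, n = n, rho = NA_real_,
          p = NA_real_, E = NA_real_,
          status = if (n < 4L) "too_few" else "all_tied",
          stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, component = comp, n = n,
        rho = unname(ct$estimate), p = ct$p.value,
        E = n_tests * ct$p.value, status = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher exact test for a 2x2 contingency table
#'
#' Two-sided exact conditional test: p is the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one, and the odds ratio is the conditional
#' maximum-likelihood estimate from the noncentral hypergeometric
#' likelihood. A zero margin returns `p = 1` with an undefined odds
#' ratio.
#'
#' @param x 2x2 matrix of non-negative integer counts.
#' @return List: `odds_ratio`, `p`.
#' @examples
#' # assignment rates in two male cohorts: 34/53 vs 39/51 offspring
#' fisher_exact_2x2(matrix(c(34, 19, 39, 12), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  stopifnot(all(dim(x) == 2L), all(x >= 0), all(x == round(x)))
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(x)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Wilcoxon signed-rank test for paired values
#'
#' Reports `W`, the sum of the ranks of the positive differences, with a
#' two-sided p-value: exact (enumeration over sign assignments) when
#' there are at most 25 non-zero differences and no tied absolute
#' differences, otherwise the normal approximation with tie correction.
#' Zero differences are dropped; if all differences are zero, `p = 1`.
#'
#' @param x,y Paired numeric vectors (or supply `x` as the differences
#'   and omit `y`).
#' @return List: `W`, `p`, `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) {
    return(list(W = 0, p = 1, n = 0L, method = "degenerate"))
  }
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value, n = length(nz),
       method = if (exact) "exact" else "normal_approx")
}

#' Assemble the per-male covariate table
#'
#' Aggregates raw field inputs into one covariate row per male: habitat
#' fractions (share of transect points per openness category, summing to
#' 1 within a territory), mean selected-food volume (mean over transect
#' points of grass cover x height), mean hormone concentration, the horn
#' PC1 composite, and mean relatedness to the reproductively active
#' females. Males whose territory has no transect points get missing
#' habitat covariates and a warning.
#'
#' @param transects Data frame: `id` (male), `habitat` (factor/character
#'   with the openness categories), and optionally `cover`, `height` of
#'   the selected food plant at the point.
#' @param hormones Optional data frame: `id`, `conc` (repeated samples
#'   allowed; the mean is used).
#' @param horns Optional horn-measurement input for [horn_pc1()] (data
#'   frame with `id` + 4 columns).
#' @param relatedness Optional data frame: `id`, `r_mean`.
#' @param habitat_levels Category order for the habitat fractions
#'   (defaults to the sorted observed categories).
#' @param males Ids to include (default: all ids seen in any input).
#' @return Data frame, one row per male: `id`, `frac_<habitat>` columns,
#'   `food_volume`, `hormone`, `horn_pc1`, `r_mean` (columns present only
#'   when the corresponding input was supplied).
#' @export
build_covariate_table <- function(transects = NULL, hormones = NULL,
                                  horns = NULL, relatedness = NULL,
                                  habitat_levels = NULL, males = NULL) {
  ids <- males
  if (is.null(ids)) {
    ids <- unique(c(if (!is.null(transects)) transects$id,
                    if (!is.null(hormones)) hormones$id,
                    if (!is.null(horns)) horns$id,
                    if (!is.null(relatedness)) relatedness$id))
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(transects)) {
    if (is.null(habitat_levels)) habitat_levels <- sort(unique(transects$habitat))
    for (h in habitat_levels) out[[paste0("frac_", h)]] <- NA_real_
    has_food <- all(c("cover", "height") %in% names(transects))
    if (has_food) out$food_volume <- NA_real_
    for (i in seq_along(ids)) {
      pts <- transects[transects$id == ids[i], , drop = FALSE]
      if (!nrow(pts)) {
        warning("male '", ids[i], "' has no transect points; habitat ",
                "covariates left missing")
        next
      }
      tab <- table(factor(pts$habitat, levels = habitat_levels))
      out[i, paste0("frac_", habitat_levels)] <- as.numeric(tab) / nrow(pts)
      if (has_food) out$food_volume[i] <- mean(pts$cover * pts$height)
    }
  }
  if (!is.null(hormones)) {
    out$hormone <- vapply(ids, function(m) {
      v <- hormones$conc[hormones$id == m]
      if (length(v)) mean(v) else NA_real_
    }, 0)
  }
  if (!is.null(horns)) {
    hp <- horn_pc1(horns)
    out$horn_pc1 <- unname(hp$scores[out$id])
  }
  if (!is.null(relatedness)) {
    out$r_mean <- relatedness$r_mean[match(out$id, relatedness$id)]
  }
  out
}
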