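#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of [run_pipeline()] with the conventional
#' defaults: assignment confidence 0.80, HWE exclusion threshold 0.001,
#' a 9-test Bonferroni multiplier for the correlate screen, and 100000
#' null replicates for the skew tests.
#'
#' @param design A [simulation_design()] describing the synthetic data.
#' @param scenario Assignment scenario (1, 2 or 3; see
#'   [build_scenario()]).
#' @param seed Integer seed governing the whole run.
#' @param confidence Posterior threshold for paternity assignment.
#' @param hwe_alpha Locus-exclusion threshold on HWE p-values.
#' @param n_tests Bonferroni multiplier of the correlate screen.
#' @param n_sim Null replicates for [nonacs_b_test()].
#' @param out_dir Output directory (`NULL`: no files written).
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(design = simulation_design(), scenario = 3,
                            seed = 1, confidence = 0.8, hwe_alpha = 0.001,
                            n_tests = 9, n_sim = 100000, out_dir = NULL) {
  stopifnot(confidence > 0, confidence <= 1, hwe_alpha > 0, hwe_alpha < 1,
            n_tests >= 1, n_sim >= 1, scenario %in% 1:3)
  structure(list(design = design, scenario = scenario, seed = seed,
                 confidence = confidence, hwe_alpha = hwe_alpha,
                 n_tests = n_tests, n_sim = n_sim, out_dir = out_dir),
            class = "run_config")
}

# demo covariates for the correlate screen: random habitat transects,
# hormone samples and horn measurements per male (no planted effects)
simulate_male_covariates <- function(males) {
  habitats <- c("grassland", "open_woodland", "close_woodland", "thickets")
  transects <- do.call(rbind, lapply(males, function(m) {
    n <- sample(25:60, 1L)
    data.frame(id = m,
               habitat = sample(habitats, n, TRUE,
                                prob = c(0.2, 0.25, 0.35, 0.2)),
               cover = stats::runif(n, 0.5, 5),
               height = stats::runif(n, 10, 80),
               stringsAsFactors = FALSE)
  }))
  hormones <- data.frame(id = rep(males, each = 4),
                         conc = stats::rlnorm(4 * length(males),
                                              log(45), 0.35))
  horns <- data.frame(id = males,
                      ant_length = stats::rnorm(length(males), 55, 8),
                      ant_circ = stats::rnorm(length(males), 60, 6),
                      post_length = stats::rnorm(length(males), 20, 4),
                      post_circ = stats::rnorm(length(males), 40, 5))
  territory <- data.frame(id = males,
                          territory_size = stats::rlnorm(length(males),
                                                         log(30), 0.5))
  list(transects = transects, hormones = hormones, horns = horns,
       territory = territory)
}

#' Run the whole mating-system pipeline on one synthetic data set
#'
#' Deterministic (given `config$seed`) end-to-end run: data simulation,
#' locus QC with HWE screening, paternity assignment under the configured
#' scenario, mating/reproductive success tabulation, Nonacs' B skew tests
#' and Bateman gradients, DyadML relatedness of males to females with the
#' mates-versus-available comparison, and the Spearman correlate screen on
#' simulated male covariates. When `config$out_dir` is set, per-stage CSV
#' tables and a machine-readable JSON summary are written there.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a report list with elements `log`, `qc`,
#'   `assignments`, `success`, `skew`, `bateman`, `relatedness`, `screen`,
#'   and `summary` (the JSON-ready digest).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  design <- config$design
  design$seed <- NULL

  bundle <- build_scenario(config$scenario, design)
  qc <- summarize_loci(bundle$table, hwe = TRUE, n_mc = 2000)
  qc$excluded <- !is.na(qc$hwe_p) & qc$hwe_p < config$hwe_alpha

  assignments <- assign_scenario(bundle, config$confidence)
  parentage <- data.frame(
    offspring = assignments$offspring,
    mother = bundle$truth$mother[match(assignments$offspring,
                                       bundle$truth$offspring)],
    father = ifelse(assignments$assigned, assignments$father, NA_character_),
    stringsAsFactors = FALSE)
  success <- tabulate_success(parentage, bundle$roster)

  males <- success[success$sex == "M", , drop = FALSE]
  females <- success[success$sex == "F", , drop = FALSE]
  n_max_male <- max(design$cohort_years)
  skew <- list(
    males_mat = nonacs_b_test(males$mat, males$n_i, n_max_male,
                              n_sim = config$n_sim),
    males_rep = nonacs_b_test(males$rep, males$n_i, n_max_male,
                              n_sim = config$n_sim),
    females_mat = nonacs_b_test(females$mat, females$n_i,
                                design$female_years, n_sim = config$n_sim),
    females_rep = nonacs_b_test(females$rep, females$n_i,
                                design$female_years, n_sim = config$n_sim))

  safe_bateman <- function(rec) {
    tryCatch(bateman_gradient(rec)$beta_ss, error = function(e) NA_real_)
  }
  bateman <- c(
    stats::setNames(
      lapply(sort(unique(males$cohort)), function(c) {
        safe_bateman(males[males$cohort == c, , drop = FALSE])
      }),
      paste0("males_c", sort(unique(males$cohort)))),
    list(females = safe_bateman(females)))

  sires <- parentage[!is.na(parentage$father), c("father", "mother")]
  rel <- compare_mate_relatedness(bundle$table, sires, females$id)
  r_mean <- vapply(males$id, function(m) {
    mean(vapply(females$id, function(f) {
      estimate_dyadml(bundle$table, m, f)$r
    }, 0))
  }, 0)

  cov_in <- simulate_male_covariates(males$id)
  covariates <- build_covariate_table(
    transects = cov_in$transects, hormones = cov_in$hormones,
    horns = cov_in$horns,
    relatedness = data.frame(id = males$id, r_mean = r_mean,
                             stringsAsFactors = FALSE))
  covariates$territory_size <- cov_in$territory$territory_size[
    match(covariates$id, cov_in$territory$id)]
  screen <- do.call(rbind, lapply(sort(unique(males$cohort)), function(c) {
    sc <- spearman_screen(covariates[covariates$id %in%
                                       males$id[males$cohort == c], ,
                                     drop = FALSE],
                          males, n_tests = config$n_tests)
    sc$cohort <- c
    sc
  }))

  summary <- list(
    seed = config$seed, scenario = config$scenario,
    confidence = config$confidence,
    n_offspring = nrow(assignments),
    n_assigned = sum(assignments$assigned),
    assignment_rate = mean(assignments$assigned),
    mean_pic = mean(qc$PIC),
    loci_excluded = sum(qc$excluded),
    skew = lapply(skew, function(s) list(B = s$B, p = s$p, K = s$K,
                                         N = s$N)),
    bateman = bateman,
    relatedness = list(mean_mates = rel$mean_mates,
                       mean_available = rel$mean_available,
                       W = rel$W, p = rel$p),
    screen_significant = sum(screen$E < 0.05, na.rm = TRUE))
  report <- list(
    log = list(seed = config$seed, scenario = config$scenario,
               n_individuals = n_individuals(bundle$table),
               n_loci = length(bundle$table$loci),
               package_version = as.character(utils::packageVersion("matesys"))),
    qc = qc, assignments = assignments, success = success, skew = skew,
    bateman = bateman, relatedness = rel, screen = screen,
    summary = summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(qc, file.path(config$out_dir, "qc_loci.csv"),
                     row.names = FALSE)
    utils::write.csv(assignments,
                     file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(success, file.path(config$out_dir, "success.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(config$out_dir, "screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
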