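#' Simulation design for synthetic mating-system data
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study system the package emulates: 10 microsatellite loci with two
#' to four alleles each and low polymorphism (per-locus PIC < 0.5), 13
#' candidate fathers split into two territorial cohorts (7 and 6 males)
#' active over consecutive tenure windows of 8 and 6 years, 33 potential
#' mothers (28 available to cohort 1, 23 to cohort 2, overlapping), 68
#' sampled offspring (36 sired under cohort 1, 32 under cohort 2), a mean
#' paternal sibship of 5.6 with skewed sibship sizes, small maternal
#' sibships, a 16-month gestation offset between conception and birth, and
#' allelic dropout at rate 0.01.
#'
#' @param n_loci Number of loci.
#' @param alleles_per_locus Integer vector of admissible allele numbers
#'   (sampled uniformly per locus).
#' @param n_fathers,n_mothers,n_offspring Roster sizes per cohort
#'   (vectors, one element per cohort). Mothers may overlap between
#'   cohorts; `n_mothers_total` fixes the distinct total.
#' @param n_mothers_total Distinct mothers across cohorts.
#' @param paternal_sibship_mean Target mean sibship size among sires; the
#'   Dirichlet-multinomial concentration of the father allocator is
#'   calibrated so the expected number of sires is
#'   `n_offspring / paternal_sibship_mean`.
#' @param maternal_sibship_mean Target mean maternal sibship. Values at or
#'   below `n_offspring/n_mothers` are not realizable; the allocator then
#'   uses an even multinomial (smallest sibships a random allocation can
#'   give).
#' @param cohort_years Tenure length (years) of each male cohort;
#'   `n_max` for males in the skew statistics.
#' @param female_years Maximum female residence (years).
#' @param dirichlet_alpha Symmetric Dirichlet parameter for allele
#'   frequencies.
#' @param max_pic Per-locus PIC ceiling enforced by resampling.
#' @param error Observation [error_model()] applied to all genotypes.
#' @param gestation_months Conception-to-birth offset.
#' @param max_litter Reject designs needing more offspring per mother.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_loci = 10,
                              alleles_per_locus = 2:4,
                              n_fathers = c(7, 6),
                              n_mothers = c(28, 23),
                              n_mothers_total = 33,
                              n_offspring = c(36, 32),
                              paternal_sibship_mean = 5.6,
                              maternal_sibship_mean = 1.6,
                              cohort_years = c(8, 6),
                              female_years = 12,
                              dirichlet_alpha = 1,
                              max_pic = 0.5,
                              error = error_model(dropout = 0.01, misprint = 0),
                              gestation_months = 16,
                              max_litter = 12,
                              seed = NULL) {
  stopifnot(n_loci >= 1, all(alleles_per_locus >= 1),
            length(n_fathers) == length(n_offspring),
            length(n_fathers) == length(n_mothers),
            all(n_fathers > 0), all(n_mothers > 0), all(n_offspring > 0),
            paternal_sibship_mean > 0, maternal_sibship_mean > 0,
            n_mothers_total <= sum(n_mothers),
            n_mothers_total >= max(n_mothers))
  if (any(n_offspring > n_mothers * max_litter)) {
    stop("infeasible design: a cohort needs more offspring than ",
         "n_mothers * max_litter allows")
  }
  structure(
    list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
         n_fathers = n_fathers, n_mothers = n_mothers,
         n_mothers_total = n_mothers_total, n_offspring = n_offspring,
         paternal_sibship_mean = paternal_sibship_mean,
         maternal_sibship_mean = maternal_sibship_mean,
         cohort_years = cohort_years, female_years = female_years,
         dirichlet_alpha = dirichlet_alpha, max_pic = max_pic,
         error = error, gestation_months = gestation_months,
         max_litter = max_litter, seed = seed),
    class = "simulation_design")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

pic_from_freqs <- function(p) {
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Generate calibrated allele-frequency tables
#'
#' Draws, for each locus, an allele number uniformly from
#' `design$alleles_per_locus` and frequencies from a symmetric Dirichlet
#' (`design$dirichlet_alpha`), resampling any locus whose PIC is at or
#' above `design$max_pic`. This reproduces the low-information marker
#' panel regime (few alleles, PIC < 0.5) in which the power analyses run.
#'
#' @param design A [simulation_design()].
#' @return A list of [locus()] objects named `L01`, `L02`, ...
#' @export
generate_frequencies <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  lapply(seq_len(design$n_loci), function(l) {
    repeat {
      k <- if (length(design$alleles_per_locus) == 1L) design$alleles_per_locus
           else sample(design$alleles_per_locus, 1L)
      p <- rdirichlet1(rep(design$dirichlet_alpha, k))
      if (pic_from_freqs(p) < design$max_pic) break
    }
    locus(sprintf("L%02d", l), as.character(seq_len(k)), p)
  })
}

# expected fraction of empty categories in a symmetric Dirichlet-multinomial
dm_p_empty <- function(alpha, k, n) {
  exp(lgamma(k * alpha) + lgamma((k - 1) * alpha + n) -
        lgamma((k - 1) * alpha) - lgamma(k * alpha + n))
}

# concentration such that the expected number of non-empty categories is
# n / target_mean (i.e. mean sibship among sires equals the target);
# Inf (plain even multinomial) when the target is not reachable
calibrate_dm_alpha <- function(k, n, target_mean) {
  want <- n / target_mean            # expected number of sires
  if (want <= 1) return(1e-3)
  f <- function(la) k * (1 - dm_p_empty(exp(la), k, n)) - want
  if (f(12) <= 0) return(Inf)        # even multinomial is as flat as it gets
  if (f(-12) >= 0) return(exp(-12))
  exp(stats::uniroot(f, c(-12, 12), tol = 1e-10)$root)
}

# draw category counts: Dirichlet-multinomial (alpha < Inf) or even multinomial
draw_counts <- function(n, k, alpha) {
  probs <- if (is.finite(alpha)) rdirichlet1(rep(alpha, k)) else rep(1 / k, k)
  as.integer(stats::rmultinom(1, n, probs))
}

# gene-dropping helpers on integer allele-index matrices (n x L)
founder_genomes <- function(n, loci) {
  L <- length(loci)
  a1 <- a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    k <- length(loci[[l]]$alleles)
    a1[, l] <- sample.int(k, n, TRUE, prob = loci[[l]]$freqs)
    a2[, l] <- sample.int(k, n, TRUE, prob = loci[[l]]$freqs)
  }
  list(a1 = a1, a2 = a2)
}

child_genomes <- function(mother, father) {
  pick <- function(g) {
    u <- matrix(stats::runif(length(g$a1)) < 0.5, nrow(g$a1))
    ifelse(u, g$a1, g$a2)
  }
  list(a1 = pick(mother), a2 = pick(father))
}

index_to_table <- function(ids, loci, g) {
  L <- length(loci)
  lab <- function(m) {
    out <- matrix(NA_character_, nrow(m), L)
    for (l in seq_len(L)) out[, l] <- loci[[l]]$alleles[m[, l]]
    out
  }
  genotype_table(ids, loci, lab(g$a1), lab(g$a2))
}

#' Simulate a two-cohort pedigree with genotypes
#'
#' Builds the founder roster (fathers per cohort, shared mother pool),
#' allocates offspring to fathers with a skewed Dirichlet-multinomial
#' (concentration calibrated to the design's mean paternal sibship) and to
#' mothers evenly (subject to `max_litter`), drops genes down the
#' pedigree under Mendelian inheritance, draws conception dates uniformly
#' inside the siring cohort's tenure window, and finally applies the
#' observation error model. Consumes the current RNG state unless
#' `design$seed` is set.
#'
#' @param design A [simulation_design()].
#' @param loci Optional pre-generated loci (default: fresh
#'   [generate_frequencies()] draw).
#' @return A list with `table` (observed [genotype_table()] of all
#'   founders and offspring), `clean_table` (before observation errors),
#'   `truth` (data frame `offspring`, `mother`, `father`, `cohort`,
#'   `conception`, `birth` in study years), `roster` (data frame `id`,
#'   `sex`, `cohort`, `start`, `end`, `n_max`), `loci`, `design`.
#' @export
simulate_pedigree <- function(design, loci = NULL) {
  if (!is.null(design$seed)) set.seed(design$seed)
  if (is.null(loci)) {
    d2 <- design; d2$seed <- NULL
    loci <- generate_frequencies(d2)
  }
  n_coh <- length(design$n_fathers)
  f_ids <- sprintf("F%02d", seq_len(sum(design$n_fathers)))
  f_cohort <- rep(seq_len(n_coh), design$n_fathers)
  m_ids <- sprintf("M%02d", seq_len(design$n_mothers_total))
  # cohort c uses the first n_mothers[1] mothers, the last n_mothers[2], ...
  m_pool <- vector("list", n_coh)
  if (n_coh == 1L) {
    m_pool[[1L]] <- seq_len(design$n_mothers[1L])
  } else {
    m_pool[[1L]] <- seq_len(design$n_mothers[1L])
    for (c in 2:n_coh) {
      m_pool[[c]] <- seq.int(design$n_mothers_total - design$n_mothers[c] + 1L,
                             design$n_mothers_total)
    }
  }
  win_start <- cumsum(c(0, design$cohort_years))[seq_len(n_coh)]
  win_end <- win_start + design$cohort_years

  off_father <- off_mother <- integer(0)
  off_cohort <- integer(0)
  conception <- numeric(0)
  litters <- integer(design$n_mothers_total)
  for (c in seq_len(n_coh)) {
    kf <- design$n_fathers[c]; n_off <- design$n_offspring[c]
    alpha <- calibrate_dm_alpha(kf, n_off, design$paternal_sibship_mean)
    cnt <- draw_counts(n_off, kf, alpha)
    fa <- rep(which(f_cohort == c), cnt)
    # mothers: even allocation, resampling any draw that would exceed the cap
    pool <- m_pool[[c]]
    mo <- integer(n_off)
    for (i in seq_len(n_off)) {
      open <- pool[litters[pool] < design$max_litter]
      mo[i] <- if (length(open) == 1L) open else sample(open, 1L)
      litters[mo[i]] <- litters[mo[i]] + 1L
    }
    off_father <- c(off_father, fa)
    off_mother <- c(off_mother, mo)
    off_cohort <- c(off_cohort, rep(c, n_off))
    conception <- c(conception, stats::runif(n_off, win_start[c], win_end[c]))
  }
  o_ids <- sprintf("O%03d", seq_along(off_father))

  fg <- founder_genomes(length(f_ids), loci)
  mg <- founder_genomes(length(m_ids), loci)
  og <- child_genomes(
    list(a1 = mg$a1[off_mother, , drop = FALSE],
         a2 = mg$a2[off_mother, , drop = FALSE]),
    list(a1 = fg$a1[off_father, , drop = FALSE],
         a2 = fg$a2[off_father, , drop = FALSE]))

  clean <- rbind_tables(index_to_table(f_ids, loci, fg),
                        index_to_table(m_ids, loci, mg),
                        index_to_table(o_ids, loci, og))
  observed <- apply_error_model(clean, design$error)

  truth <- data.frame(offspring = o_ids,
                      mother = m_ids[off_mother],
                      father = f_ids[off_father],
                      cohort = off_cohort,
                      conception = conception,
                      birth = conception + design$gestation_months / 12,
                      stringsAsFactors = FALSE)
  roster <- data.frame(
    id = c(f_ids, m_ids),
    sex = c(rep("M", length(f_ids)), rep("F", length(m_ids))),
    cohort = c(f_cohort, rep(NA_integer_, length(m_ids))),
    start = c(win_start[f_cohort], rep(0, length(m_ids))),
    end = c(win_end[f_cohort], rep(max(win_end), length(m_ids))),
    n_max = c(design$cohort_years[f_cohort],
              rep(design$female_years, length(m_ids))),
    sampled = TRUE,
    stringsAsFactors = FALSE)
  list(table = observed, clean_table = clean, truth = truth,
       roster = roster, loci = loci, design = design)
}

#' Simulate genotype dyads of known kinship
#'
#' Generates `n` pairs of multilocus genotypes for one kinship category by
#' explicit gene dropping through a minimal pedigree (e.g. first cousins
#' via shared grandparents), so each category's identity-by-descent
#' structure is exactly realized rather than approximated through
#' k-coefficient mixtures. Categories and expected relatedness: PO (0.5),
#' FS (0.5), HS (0.25), FC (0.125), SC (0.03125), U (0).
#'
#' @param category One of `"PO"`, `"FS"`, `"HS"`, `"FC"`, `"SC"`, `"U"`.
#' @param n Number of dyads.
#' @param loci List of [locus()] objects with frequencies.
#' @param error Optional [error_model()] applied to the genotypes.
#' @return A list with `table` (a [genotype_table()] of `2n` individuals),
#'   `pairs` (data frame `id1`, `id2`, `category`, `r_true`).
#' @export
simulate_dyads <- function(category = c("PO", "FS", "HS", "FC", "SC", "U"),
                           n, loci, error = NULL) {
  category <- match.arg(category)
  r_true <- c(PO = 0.5, FS = 0.5, HS = 0.25, FC = 0.125,
              SC = 0.03125, U = 0)[[category]]
  fo <- function() founder_genomes(n, loci)
  ch <- child_genomes
  g <- switch(category,
    U  = { list(a = fo(), b = fo()) },
    PO = { A <- fo(); list(a = A, b = ch(A, fo())) },
    FS = { P <- fo(); Q <- fo(); list(a = ch(P, Q), b = ch(P, Q)) },
    HS = { P <- fo(); list(a = ch(P, fo()), b = ch(P, fo())) },
    FC = {
      GP <- fo(); GM <- fo()
      s1 <- ch(GM, GP); s2 <- ch(GM, GP)
      list(a = ch(s1, fo()), b = ch(s2, fo()))
    },
    SC = {
      GP <- fo(); GM <- fo()
      s1 <- ch(GM, GP); s2 <- ch(GM, GP)
      c1 <- ch(s1, fo()); c2 <- ch(s2, fo())
      list(a = ch(c1, fo()), b = ch(c2, fo()))
    })
  id1 <- sprintf("%s%03d_a", category, seq_len(n))
  id2 <- sprintf("%s%03d_b", category, seq_len(n))
  tab <- rbind_tables(index_to_table(id1, loci, g$a),
                      index_to_table(id2, loci, g$b))
  if (!is.null(error)) tab <- apply_error_model(tab, error)
  list(table = tab,
       pairs = data.frame(id1 = id1, id2 = id2, category = category,
                          r_true = r_true, stringsAsFactors = FALSE))
}

#' Build a parentage power-analysis scenario bundle
#'
#' Packages one simulated pedigree into the information structure of the
#' three assignment scenarios: scenario 1 exposes only the pooled
#' candidate roster (no mother-offspring links, no cohort split), so the
#' engine must assign joint parent pairs; scenario 2 adds the known
#' mother-offspring links; scenario 3 additionally splits the analysis
#' into the two male cohorts, restricting each offspring's candidate
#' fathers to the males whose tenure covers its conception.
#'
#' @param scenario_id 1, 2 or 3.
#' @param design A [simulation_design()].
#' @param loci Optional pre-generated loci.
#' @return A list (`scenario_bundle`): `scenario`, all elements of
#'   [simulate_pedigree()]'s result, `known_mothers` (named character
#'   vector offspring -> mother, or `NULL` in scenario 1), and `runs` — a
#'   list of assignment runs, each with `offspring` ids and
#'   `candidate_fathers` ids.
#' @export
build_scenario <- function(scenario_id, design = simulation_design(),
                           loci = NULL) {
  if (!scenario_id %in% 1:3) stop("unknown scenario id: ", scenario_id)
  ped <- simulate_pedigree(design, loci)
  males <- ped$roster$id[ped$roster$sex == "M"]
  known <- stats::setNames(ped$truth$mother, ped$truth$offspring)
  if (scenario_id < 3) {
    runs <- list(list(offspring = ped$truth$offspring,
                      candidate_fathers = males))
  } else {
    runs <- lapply(sort(unique(ped$truth$cohort)), function(c) {
      list(offspring = ped$truth$offspring[ped$truth$cohort == c],
           candidate_fathers = ped$roster$id[
             ped$roster$sex == "M" & !is.na(ped$roster$cohort) &
               ped$roster$cohort == c])
    })
  }
  c(list(scenario = scenario_id,
         known_mothers = if (scenario_id >= 2) known else NULL,
         runs = runs),
    ped)
}
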