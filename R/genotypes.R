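#' Define a codominant locus
#'
#' A locus is a named set of allele labels with population allele
#' frequencies. Frequencies are the reference frequencies used by all
#' likelihood computations (parentage, relatedness); by convention they are
#' estimated once from the whole sampled population (parents and offspring
#' pooled) rather than per analysis.
#'
#' @param name Locus name (single string).
#' @param alleles Character vector of unique allele labels (length >= 1).
#' @param freqs Numeric vector of allele frequencies, same length as
#'   `alleles`, summing to 1 (tolerance 1e-9). Recycled to uniform if
#'   missing.
#' @return An object of class `locus`: a list with `name`, `alleles`,
#'   `freqs` (named by allele).
#' @examples
#' locus("SR54", c("140", "144", "148"), c(0.5, 0.3, 0.2))
#' @export
locus <- function(name, alleles, freqs = NULL) {
  alleles <- as.character(alleles)
  stopifnot(length(name) == 1L, length(alleles) >= 1L)
  if (anyDuplicated(alleles)) {
    stop("allele labels must be unique at locus '", name, "'")
  }
  if (is.null(freqs)) freqs <- rep(1 / length(alleles), length(alleles))
  if (length(freqs) != length(alleles)) {
    stop("freqs and alleles lengths differ at locus '", name, "'")
  }
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must be non-negative and sum to 1 at locus '", name, "'")
  }
  structure(
    list(name = as.character(name), alleles = alleles,
         freqs = stats::setNames(as.numeric(freqs), alleles)),
    class = "locus"
  )
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus>", x$name, ":", length(x$alleles), "alleles\n")
  print(round(x$freqs, 4))
  invisible(x)
}

#' Genotyping-error model
#'
#' Two error processes acting on each single-locus genotype independently:
#' allelic dropout (a true heterozygote is observed homozygous for one of
#' its alleles, each with probability `dropout/2`) and misprints (the
#' observed genotype is replaced by an independent Hardy-Weinberg draw with
#' probability `misprint`, regardless of the true genotype). Dropout is
#' invisible on true homozygotes.
#'
#' @param dropout Per-genotype dropout probability in `[0, 1)`. Default
#'   0.01, the conservative rate used for the paternity analyses.
#' @param misprint Per-genotype misprint probability in `[0, 1)`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(dropout = 0.01, misprint = 0) {
  stopifnot(dropout >= 0, dropout < 1, misprint >= 0, misprint < 1)
  structure(list(dropout = dropout, misprint = misprint),
            class = "error_model")
}

#' Assemble a genotype table
#'
#' The central container: diploid calls for `length(ids)` individuals at
#' the loci in `loci`. Calls are stored as two character matrices of allele
#' labels; a missing single-locus genotype is `NA` in both. Allele pairs
#' are unordered and stored in the allele order of the locus definition.
#'
#' @param ids Character vector of unique individual identifiers.
#' @param loci List of [locus()] objects (named list accepted; names taken
#'   from the objects).
#' @param a1,a2 Character matrices (`length(ids)` x `length(loci)`) of
#'   allele labels, `NA` for missing. A call missing one allele is treated
#'   as missing entirely.
#' @return An object of class `genotype_table` with elements `ids`, `loci`,
#'   `a1`, `a2`.
#' @export
genotype_table <- function(ids, loci, a1, a2) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual identifiers must be unique")
  loci <- as_loci(loci)
  lnames <- vapply(loci, `[[`, "", "name")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  if (!all(dim(a1) == c(length(ids), length(loci))) ||
      !all(dim(a2) == c(length(ids), length(loci)))) {
    stop("allele matrices must be n_individuals x n_loci")
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, lnames)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_; a2[miss] <- NA_character_
  # normalize order within pair and validate labels per locus
  for (l in seq_along(loci)) {
    ok <- !miss[, l]
    if (!any(ok)) next
    i1 <- match(a1[ok, l], loci[[l]]$alleles)
    i2 <- match(a2[ok, l], loci[[l]]$alleles)
    if (anyNA(i1) || anyNA(i2)) {
      bad <- which(ok)[which(is.na(i1) | is.na(i2))[1L]]
      stop("unknown allele at locus '", lnames[l], "', individual '",
           ids[bad], "'")
    }
    swap <- i1 > i2
    if (any(swap)) {
      rows <- which(ok)[swap]
      tmp <- a1[rows, l]; a1[rows, l] <- a2[rows, l]; a2[rows, l] <- tmp
    }
  }
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

as_loci <- function(loci) {
  if (inherits(loci, "locus")) loci <- list(loci)
  stopifnot(is.list(loci), all(vapply(loci, inherits, TRUE, "locus")))
  names(loci) <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(names(loci))) stop("locus names must be unique")
  loci
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$ids), " individuals x ",
      length(x$loci), " loci; ",
      sum(is.na(x$a1)), " missing single-locus genotypes\n", sep = "")
  invisible(x)
}

#' Number of individuals / locus names of a genotype table
#' @param table A [genotype_table()].
#' @return `n_individuals()`: integer count; `locus_names()`: character
#'   vector.
#' @export
n_individuals <- function(table) length(table$ids)

#' @rdname n_individuals
#' @export
locus_names <- function(table) names(table$loci)

#' Extract the calls of one individual as a 2 x n_loci matrix
#' @param table A [genotype_table()].
#' @param id Individual identifier.
#' @return Character matrix with rows `a1`, `a2` and one column per locus.
#' @export
individual_calls <- function(table, id) {
  i <- match(id, table$ids)
  if (is.na(i)) stop("unknown individual '", id, "'")
  rbind(a1 = table$a1[i, , drop = TRUE], a2 = table$a2[i, , drop = TRUE])
}

#' Estimate allele frequencies from observed calls
#'
#' Counts alleles among typed individuals at each locus and returns a new
#' list of loci carrying the observed frequencies. Alleles never observed
#' keep frequency zero unless `drop_unobserved = TRUE`.
#'
#' @param table A [genotype_table()].
#' @param drop_unobserved Drop alleles with zero observed count.
#' @return List of [locus()] objects.
#' @export
estimate_frequencies <- function(table, drop_unobserved = FALSE) {
  out <- lapply(seq_along(table$loci), function(l) {
    loc <- table$loci[[l]]
    obs <- c(table$a1[, l], table$a2[, l])
    obs <- obs[!is.na(obs)]
    if (!length(obs)) stop("no data at locus '", loc$name, "'")
    cnt <- table(factor(obs, levels = loc$alleles))
    fr <- as.numeric(cnt) / sum(cnt)
    al <- loc$alleles
    if (drop_unobserved) {
      keep <- fr > 0
      al <- al[keep]; fr <- fr[keep]
    }
    locus(loc$name, al, fr)
  })
  names(out) <- names(table$loci)
  out
}

#' Apply a genotyping-error model to a table
#'
#' Each non-missing single-locus genotype is independently perturbed:
#' first a misprint replaces it with a Hardy-Weinberg draw (using the locus
#' frequencies) with probability `model$misprint`; otherwise, if it is
#' heterozygous, one of its two alleles is dropped with probability
#' `model$dropout` (either allele equally likely), yielding an observed
#' homozygote. Uses the current RNG state.
#'
#' @param table A [genotype_table()].
#' @param model An [error_model()].
#' @return A perturbed `genotype_table`.
#' @export
apply_error_model <- function(table, model) {
  stopifnot(inherits(model, "error_model"))
  a1 <- table$a1; a2 <- table$a2
  for (l in seq_along(table$loci)) {
    loc <- table$loci[[l]]
    ok <- which(!is.na(a1[, l]))
    if (!length(ok)) next
    if (model$misprint > 0) {
      mis <- ok[stats::runif(length(ok)) < model$misprint]
      if (length(mis)) {
        g1 <- sample(loc$alleles, length(mis), TRUE, prob = loc$freqs)
        g2 <- sample(loc$alleles, length(mis), TRUE, prob = loc$freqs)
        a1[mis, l] <- g1; a2[mis, l] <- g2
      }
    }
    het <- which(!is.na(a1[, l]) & a1[, l] != a2[, l])
    if (model$dropout > 0 && length(het)) {
      drp <- het[stats::runif(length(het)) < model$dropout]
      if (length(drp)) {
        keep_first <- stats::runif(length(drp)) < 0.5
        kept <- ifelse(keep_first, a1[drp, l], a2[drp, l])
        a1[drp, l] <- kept; a2[drp, l] <- kept
      }
    }
  }
  genotype_table(table$ids, table$loci, a1, a2)
}

# internal: subset a table by individual ids (keeps locus definitions)
subset_table <- function(table, ids) {
  i <- match(ids, table$ids)
  if (anyNA(i)) stop("unknown individuals in subset")
  genotype_table(table$ids[i], table$loci,
                 table$a1[i, , drop = FALSE], table$a2[i, , drop = FALSE])
}

# internal: combine tables sharing the same loci
rbind_tables <- function(...) {
  tabs <- list(...)
  loci <- tabs[[1L]]$loci
  genotype_table(unlist(lapply(tabs, `[[`, "ids")), loci,
                 do.call(rbind, lapply(tabs, `[[`, "a1")),
                 do.call(rbind, lapply(tabs, `[[`, "a2")))
}
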