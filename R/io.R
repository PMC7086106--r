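#' Read and write genotype tables
#'
#' Two dialects are supported. `"csv"`: one row per individual, a leading
#' `id` column and two columns per locus named `<locus>_1`, `<locus>_2`;
#' missing alleles are empty cells or `"0"`. `"genepop"`: the classic
#' text format (title line, one locus name per line, `Pop`, then
#' `id ,  aaabbb ...` with 3-digit alleles and `000000` for missing).
#' Allele labels must be integers in 1..999 for the Genepop dialect.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"genepop"`.
#' @param loci Optional list of [locus()] objects fixing allele universes
#'   and frequencies; when omitted, loci are built from the observed
#'   alleles with observed frequencies.
#' @return `read_genotypes()` returns a [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "genepop"), loci = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_genotypes_csv(path, loci)
  else read_genotypes_genepop(path, loci)
}

#' @rdname read_genotypes
#' @param table A [genotype_table()] to write.
#' @param title Title line for the Genepop dialect.
#' @return `write_genotypes()` returns `path`, invisibly.
#' @export
write_genotypes <- function(table, path, dialect = c("csv", "genepop"),
                            title = "matesys export") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(id = table$ids, stringsAsFactors = FALSE)
    for (l in seq_along(table$loci)) {
      nm <- names(table$loci)[l]
      c1 <- table$a1[, l]; c2 <- table$a2[, l]
      c1[is.na(c1)] <- ""; c2[is.na(c2)] <- ""
      df[[paste0(nm, "_1")]] <- c1
      df[[paste0(nm, "_2")]] <- c2
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    code <- function(a, loc) {
      v <- suppressWarnings(as.integer(a))
      if (any(is.na(v[!is.na(a)])) || any(v < 1 | v > 999, na.rm = TRUE)) {
        stop("Genepop dialect requires integer allele labels in 1..999 (locus '",
             loc$name, "')")
      }
      v[is.na(v)] <- 0L
      sprintf("%03d", v)
    }
    lines <- c(title, names(table$loci), "Pop")
    body <- vapply(seq_along(table$ids), function(i) {
      g <- vapply(seq_along(table$loci), function(l) {
        paste0(code(table$a1[i, l], table$loci[[l]]),
               code(table$a2[i, l], table$loci[[l]]))
      }, "")
      paste0(table$ids[i], " ,  ", paste(g, collapse = " "))
    }, "")
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

read_genotypes_csv <- function(path, loci = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"id" %in% names(df)) stop("CSV genotype file must have an 'id' column")
  cols <- setdiff(names(df), "id")
  base <- sub("_[12]$", "", cols)
  lnames <- unique(base)
  for (nm in lnames) {
    need <- paste0(nm, c("_1", "_2"))
    if (!all(need %in% cols)) {
      stop("locus '", nm, "' lacks paired columns ", paste(need, collapse = "/"))
    }
  }
  n <- nrow(df)
  clean <- function(x) {
    x <- trimws(x)
    x[x == "" | x == "0" | is.na(x)] <- NA_character_
    x
  }
  a1 <- sapply(lnames, function(nm) clean(df[[paste0(nm, "_1")]]))
  a2 <- sapply(lnames, function(nm) clean(df[[paste0(nm, "_2")]]))
  a1 <- matrix(a1, nrow = n); a2 <- matrix(a2, nrow = n)
  # half-missing calls are treated as fully missing (conservative)
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_character_; a2[half] <- NA_character_
  build_table_from_calls(df$id, lnames, a1, a2, loci)
}

read_genotypes_genepop <- function(path, loci = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_at <- which(toupper(trimws(lines)) %in% c("POP"))
  if (!length(pop_at)) stop("no 'Pop' line found in Genepop file")
  header <- lines[2:(pop_at[1L] - 1L)]
  # locus names may be one per line or comma-separated on one line
  lnames <- trimws(unlist(strsplit(header, ",")))
  lnames <- lnames[nzchar(lnames)]
  body <- lines[-seq_len(pop_at[1L])]
  body <- body[!toupper(trimws(body)) %in% "POP"]
  ids <- character(0)
  a1 <- a2 <- NULL
  for (row in seq_along(body)) {
    parts <- strsplit(body[row], ",")[[1L]]
    if (length(parts) < 2L) {
      stop("Genepop row ", row, " lacks the 'id , genotypes' separator")
    }
    id <- trimws(parts[1L])
    g <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "[[:space:]]+")[[1L]]
    if (length(g) != length(lnames)) {
      stop("Genepop row ", row, " ('", id, "'): expected ", length(lnames),
           " genotypes, found ", length(g))
    }
    dig <- nchar(g) / 2L
    if (any(dig != round(dig))) {
      stop("Genepop row ", row, ": odd-width genotype string")
    }
    x1 <- as.integer(substr(g, 1L, dig))
    x2 <- as.integer(substr(g, dig + 1L, 2L * dig))
    v1 <- ifelse(x1 == 0L | x2 == 0L, NA_character_, as.character(x1))
    v2 <- ifelse(x1 == 0L | x2 == 0L, NA_character_, as.character(x2))
    ids <- c(ids, id)
    a1 <- rbind(a1, v1); a2 <- rbind(a2, v2)
  }
  build_table_from_calls(ids, lnames, a1, a2, loci)
}

build_table_from_calls <- function(ids, lnames, a1, a2, loci = NULL) {
  if (is.null(loci)) {
    loci <- lapply(seq_along(lnames), function(l) {
      obs <- c(a1[, l], a2[, l]); obs <- obs[!is.na(obs)]
      if (!length(obs)) {
        stop("locus '", lnames[l], "' has no typed individuals and no ",
             "locus definition was supplied")
      }
      al <- sort(unique(obs))
      cnt <- table(factor(obs, levels = al))
      locus(lnames[l], al, as.numeric(cnt) / sum(cnt))
    })
  } else {
    loci <- as_loci(loci)
    miss <- setdiff(lnames, names(loci))
    if (length(miss)) stop("no locus definition for: ", paste(miss, collapse = ", "))
    loci <- loci[lnames]
  }
  genotype_table(ids, loci, a1, a2)
}
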