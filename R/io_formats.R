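#' @useDynLib glacialdemog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp rpois runif rbinom rgeom rgamma quantile median mad
#'   setNames pnorm wilcox.test sd var binom.test ks.test glm coef vcov
#'   predict lm lm.wfit qnorm complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

VALID_RESIDUES <- c("A", "C", "G", "T", "-", "N")

#' Aligned sequence dataset with population labels
#'
#' Container for an alignment of haploid sequences (one row per sample) over
#' the alphabet `A,C,G,T,-,N`, each sample carrying exactly one population
#' label. This is the in-memory form of a control-region alignment.
#'
#' @param seqs character matrix (samples x sites) of single upper-case
#'   residues, or a character vector of equal-length strings.
#' @param sample_id character vector of unique sample identifiers.
#' @param population character vector of population labels, one per sample.
#' @return An object of class `seq_dataset`: a list with elements `sample_id`,
#'   `population`, `seq` (character matrix) and `L` (alignment length).
#' @export
seq_dataset <- function(seqs, sample_id = NULL, population = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- names(seqs)[which(lens != lens[1])[1]]
      stop("unequal sequence lengths (record ", if (is.null(bad)) "?" else bad,
           ")")
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  seqs <- toupper(seqs)
  n <- nrow(seqs)
  if (is.null(sample_id)) sample_id <- rownames(seqs)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  if (is.null(population)) population <- rep("all", n)
  if (length(population) != n) stop("one population label per sample required")
  bad <- setdiff(unique(as.vector(seqs)), VALID_RESIDUES)
  if (length(bad) > 0) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  rownames(seqs) <- sample_id
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 seq = seqs, L = ncol(seqs)),
            class = "seq_dataset")
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat("seq_dataset:", length(x$sample_id), "samples x", x$L, "sites;",
      "populations:", paste(sprintf("%s (%d)", names(table(x$population)),
                                    table(x$population)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Haplotype-by-population count table
#'
#' @param counts non-negative integer matrix, haplotypes in rows, populations
#'   in columns, with unique dimnames.
#' @return An integer matrix of class `hap_table`.
#' @export
hap_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("H", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("pop", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("haplotype and population labels must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) < 1))
    stop("every haplotype must have total count >= 1")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("hap_table", "matrix"))
}

#' Diploid microsatellite dataset
#'
#' Genotypes are unordered pairs of allele sizes in repeat units; missing
#' genotypes are encoded as `NA` in both allele matrices.
#'
#' @param a1,a2 integer matrices (samples x loci) of allele sizes (repeat
#'   counts); `NA` marks a missing genotype.
#' @param sample_id,population character vectors, one entry per sample.
#' @param loci character vector of locus names.
#' @return An object of class `msat_dataset`.
#' @export
msat_dataset <- function(a1, a2, sample_id = NULL, population = NULL,
                         loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(all(dim(a1) == dim(a2)))
  n <- nrow(a1); l <- ncol(a1)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  if (is.null(population)) population <- rep("all", n)
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("loc", seq_len(l))
  if (anyDuplicated(loci)) stop("duplicated locus names")
  if (length(population) != n) stop("one population label per sample required")
  ok <- function(m) all(is.na(m) | (m > 0 & m == round(m)))
  if (!ok(a1) || !ok(a2)) stop("allele sizes must be positive integers or NA")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("missing genotypes must be missing for both alleles")
  dimnames(a1) <- dimnames(a2) <- list(sample_id, loci)
  storage.mode(a1) <- storage.mode(a2) <- "integer"
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 loci = as.character(loci), a1 = a1, a2 = a2),
            class = "msat_dataset")
}

#' @export
print.msat_dataset <- function(x, ...) {
  cat("msat_dataset:", length(x$sample_id), "individuals x", length(x$loci),
      "loci;", "populations:",
      paste(sprintf("%s (%d)", names(table(x$population)),
                    table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned FASTA file into a sequence dataset
#'
#' Population labels are taken from an `id|population` header convention, or
#' from a sidecar two-column (sample, population) TSV via `pop_map`.
#'
#' @param path FASTA file path.
#' @param pop_map optional path to a TSV with columns `sample_id` and
#'   `population`, or a data.frame with those columns.
#' @return A [seq_dataset()].
#' @export
read_fasta <- function(path, pop_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no FASTA records in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1) {
    bad <- names(dna)[which(lens != lens[1])[1]]
    stop("unequal sequence lengths (record ", bad, ")")
  }
  mat <- toupper(do.call(rbind, as.character(dna)))
  ids <- names(dna)
  pop <- NULL
  if (!is.null(pop_map)) {
    pm <- if (is.data.frame(pop_map)) pop_map else
      read.delim(pop_map, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("sample_id", "population") %in% names(pm)))
      stop("pop_map needs columns sample_id, population")
    idx <- match(ids, pm$sample_id)
    if (anyNA(idx)) stop("pop_map is missing samples: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    pop <- pm$population[idx]
  } else if (all(grepl("|", ids, fixed = TRUE))) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1)
    pop <- vapply(parts, `[`, "", 2)
  }
  seq_dataset(mat, sample_id = ids, population = pop)
}

#' Write a sequence dataset to FASTA with `id|population` headers
#'
#' @param x a [seq_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_dataset"))
  mat <- tolower(x$seq)
  rownames(mat) <- paste0(x$sample_id, "|", x$population)
  ape::write.FASTA(ape::as.DNAbin(mat), path)
  invisible(path)
}

#' Read a GenePop-dialect genotype file
#'
#' Expects the classic layout: a title line, one locus name per line (or a
#' single comma-separated line), `Pop` separators, and individual rows of the
#' form `id , 0204 0507 ...` with 2- or 3-digit allele codes per allele
#' (`00`/`000` = missing). Allele codes are interpreted as repeat counts.
#'
#' @param path GenePop file path.
#' @param pop_names optional character vector naming the populations in file
#'   order; default `pop1`, `pop2`, ...
#' @return A [msat_dataset()].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("not a GenePop file: ", path)
  body <- lines[-1]
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no 'Pop' separator found")
  loc_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- unlist(strsplit(loc_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicated locus names")
  nloc <- length(loci)
  pop_of <- findInterval(seq_along(body), pop_idx)
  rows <- body[pop_of > 0 & !(seq_along(body) %in% pop_idx)]
  row_pop <- pop_of[pop_of > 0 & !(seq_along(body) %in% pop_idx)]
  if (length(rows) == 0) stop("no individual rows found")
  ids <- character(length(rows))
  a1 <- matrix(NA_integer_, length(rows), nloc)
  a2 <- matrix(NA_integer_, length(rows), nloc)
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed individual row: ", rows[i])
    ids[i] <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(codes) != nloc)
      stop("row '", ids[i], "' has ", length(codes), " genotypes, expected ",
           nloc)
    w <- nchar(codes)
    if (any(w != w[1]) || !(w[1] %in% c(4, 6)))
      stop("allele codes must be uniformly 2x2 or 2x3 digits (row '", ids[i],
           "')")
    half <- w[1] / 2
    x1 <- as.integer(substr(codes, 1, half))
    x2 <- as.integer(substr(codes, half + 1, w[1]))
    miss <- x1 == 0 | x2 == 0
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  npop <- length(pop_idx)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(npop))
  if (length(pop_names) != npop) stop("pop_names must have length ", npop)
  msat_dataset(a1, a2, sample_id = ids, population = pop_names[row_pop],
               loci = loci)
}

#' Write a microsatellite dataset as GenePop text
#'
#' @param x a [msat_dataset()].
#' @param path output file path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "glacialdemog genotypes") {
  stopifnot(inherits(x, "msat_dataset"))
  width <- if (max(c(x$a1, x$a2), na.rm = TRUE) > 99) 3L else 2L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = width, flag = "0")
  }
  g <- matrix(paste0(fmt(x$a1), fmt(x$a2)), nrow = nrow(x$a1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, x$loci), con)
  for (p in unique(x$population)) {
    writeLines("Pop", con)
    for (i in which(x$population == p)) {
      writeLines(paste(x$sample_id[i], ",",
                       paste(g[i, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a haplotype-by-population count table from TSV
#'
#' The first column holds haplotype labels and each remaining column a
#' population; blank cells count as zero. A `Total` column, if present, is
#' validated against the row sums and dropped. A trailing row of column sums
#' (labelled e.g. `Samples`) is validated and dropped likewise.
#'
#' @param path TSV path (`#` comments allowed).
#' @return A [hap_table()].
#' @export
read_haplotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "" | is.na(m)] <- "0"
  storage.mode(m) <- "integer"
  rownames(m) <- labs
  tail_tot <- grepl("^(samples|total)$", tolower(labs))
  if (any(tail_tot)) {
    sums <- m[tail_tot, , drop = FALSE][1, ]
    m <- m[!tail_tot, , drop = FALSE]
    keep <- !grepl("^total$", tolower(colnames(m)))
    if (!all(sums[keep] == colSums(m[, keep, drop = FALSE])))
      stop("stated sample sizes do not match column sums")
  }
  tot_col <- grepl("^total$", tolower(colnames(m)))
  if (any(tot_col)) {
    tot <- m[, which(tot_col)[1]]
    m <- m[, !tot_col, drop = FALSE]
    if (!all(tot == rowSums(m))) stop("Total column does not match row sums")
  }
  hap_table(m)
}

#' Write a haplotype count table as TSV (with a Total column)
#'
#' @param x a [hap_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path) {
  stopifnot(inherits(x, "hap_table"))
  df <- data.frame(Haplotypes = rownames(x), unclass(x), Total = rowSums(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sites retained under complete deletion
#'
#' @param seqmat character matrix of residues.
#' @return Integer vector of column indices free of `-` and `N` in every
#'   sequence.
#' @keywords internal
retained_sites <- function(seqmat) {
  which(colSums(seqmat == "-" | seqmat == "N") == 0)
}

#' Collapse an alignment to haplotypes
#'
#' Sites containing `-` or `N` in any sequence are excluded (complete
#' deletion); identical sequences over the retained sites share a haplotype.
#' Haplotypes and populations are ordered by first appearance and haplotypes
#' are labelled `H1..Hk`.
#'
#' @param seqs a [seq_dataset()].
#' @return A list with `table` (a [hap_table()]) and `haplotypes` (a
#'   [seq_dataset()] holding one representative full-length sequence per
#'   haplotype, sample ids = haplotype labels).
#' @export
collapse_to_haplotypes <- function(seqs) {
  stopifnot(inherits(seqs, "seq_dataset"))
  n <- length(seqs$sample_id)
  if (n == 0) stop("empty dataset")
  keep <- retained_sites(seqs$seq)
  key <- apply(seqs$seq[, keep, drop = FALSE], 1, paste, collapse = "")
  hap_of <- match(key, unique(key))
  k <- max(hap_of)
  pops <- unique(seqs$population)
  counts <- matrix(0L, k, length(pops),
                   dimnames = list(paste0("H", seq_len(k)), pops))
  for (i in seq_len(n)) {
    counts[hap_of[i], match(seqs$population[i], pops)] <-
      counts[hap_of[i], match(seqs$population[i], pops)] + 1L
  }
  rep_idx <- match(seq_len(k), hap_of)
  reps <- seq_dataset(seqs$seq[rep_idx, , drop = FALSE],
                      sample_id = paste0("H", seq_len(k)),
                      population = rep("haplotype", k))
  list(table = hap_table(counts), haplotypes = reps)
}

#' Assign north/south population labels from latitude
#'
#' Convenience rule for studies whose two management units are separated by a
#' latitudinal boundary: samples at or north of `boundary` (less negative
#' latitude) are labelled `north`, the rest `south`.
#'
#' @param latitude numeric vector of decimal latitudes (southern hemisphere
#'   negative).
#' @param boundary boundary latitude in decimal degrees (default -43).
#' @return Character vector of `"north"` / `"south"` labels.
#' @export
assign_population_by_latitude <- function(latitude, boundary = -43) {
  if (any(latitude < -90 | latitude > 0, na.rm = TRUE))
    stop("latitudes must lie in [-90, 0] for this study's range")
  ifelse(latitude >= boundary, "north", "south")
}
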