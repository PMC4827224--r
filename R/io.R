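#' Read a FASTA alignment with a population map
#'
#' Reads a plain FASTA alignment (single-line or wrapped) together with a
#' two-column tab-separated population map (\code{sequence_id TAB
#' population}).  Sequences are uppercased and length-validated.
#'
#' @param fasta_text FASTA content as a single string or character vector
#'   of lines, or a file path.
#' @param popmap_text population map content (string/lines) or a file path.
#' @return A \code{\link{sequence_dataset}}.
#' @export
read_fasta_with_popmap <- function(fasta_text, popmap_text) {
  flines <- .as_lines(fasta_text)
  plines <- .as_lines(popmap_text)

  hdr <- grep("^>", flines)
  if (length(hdr) == 0L) stop("no FASTA records found")
  ids <- sub("^>\\s*", "", flines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) stop("duplicate FASTA record IDs")
  ends <- c(hdr[-1L] - 1L, length(flines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(flines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, "")
  seqs <- gsub("\\s", "", seqs)

  pm <- strsplit(plines[nzchar(trimws(plines))], "\t", fixed = TRUE)
  if (any(lengths(pm) < 2L)) stop("population map must have two tab-separated columns")
  map <- setNames(vapply(pm, `[`, "", 2L), vapply(pm, `[`, "", 1L))
  missing_ids <- setdiff(ids, names(map))
  if (length(missing_ids) > 0L)
    stop("sequence IDs missing from population map: ",
         paste(missing_ids, collapse = ", "))

  sequence_dataset(seqs, labels = unname(map[ids]), ids = ids)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("[\n>]", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write a sequence dataset as FASTA plus population map
#'
#' @param x a \code{SequenceDataset}.
#' @return A list with elements \code{fasta} and \code{popmap}, each a
#'   single string.  \code{read_fasta_with_popmap} on the output
#'   reproduces \code{x}.
#' @export
write_fasta <- function(x) {
  stopifnot(inherits(x, "SequenceDataset"))
  fasta <- paste0(">", x$ids, "\n", x$sequences, collapse = "\n")
  popmap <- paste0(x$ids, "\t", x$labels, collapse = "\n")
  list(fasta = paste0(fasta, "\n"), popmap = paste0(popmap, "\n"))
}

#' Read GENEPOP microsatellite genotypes
#'
#' Parses the GENEPOP 4.x dialect with 3-digit alleles: a title line,
#' locus names (one per line or comma-separated on one line), \code{Pop}
#' separators, and individual lines \code{id , 004006 ...}.  The code
#' \code{000000} denotes a missing genotype.  Alleles are decoded as
#' integer repeat counts.
#'
#' @param text GENEPOP content as a string, character vector of lines, or
#'   file path.
#' @param pop_names optional population names; defaults to the id of the
#'   last individual in each block (GENEPOP convention) or \code{pop_1}...
#' @return A \code{\link{microsat_dataset}}.
#' @export
read_genepop <- function(text, pop_names = NULL) {
  lines <- .as_lines(text)
  if (length(lines) < 3L) stop("GENEPOP file too short")
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]

  body <- lines[-1L]                          # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  locus_lines <- body[seq_len(first_pop - 1L)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  if (L == 0L) stop("no locus names found")

  pop_idx <- cumsum(is_pop)
  ind_lines <- body[!is_pop & pop_idx >= 1L]
  ind_pops <- pop_idx[!is_pop & pop_idx >= 1L]
  n_pops <- max(pop_idx)

  ids <- character(0); labels <- character(0)
  geno <- matrix(NA_integer_, nrow = length(ind_lines), ncol = 2L * L)
  last_id_in_pop <- rep(NA_character_, n_pops)
  for (i in seq_along(ind_lines)) {
    parts <- strsplit(ind_lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed individual line (no comma): ", ind_lines[i])
    id <- trimws(parts[1L])
    fields <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(fields) != L)
      stop("individual ", id, ": ", length(fields),
           " genotype fields but ", L, " loci")
    for (l in seq_len(L)) {
      f <- fields[l]
      if (nchar(f) != 6L)
        stop("individual ", id, ", locus ", locus_names[l],
             ": allele field '", f, "' is not 6 digits (3-digit dialect)")
      a1 <- as.integer(substr(f, 1L, 3L)); a2 <- as.integer(substr(f, 4L, 6L))
      if (is.na(a1) || is.na(a2))
        stop("non-numeric allele field '", f, "'")
      if (a1 == 0L && a2 == 0L) next                # missing
      if (a1 == 0L || a2 == 0L)
        stop("individual ", id, ", locus ", locus_names[l],
             ": half-missing genotype '", f, "'")
      geno[i, 2L * l - 1L] <- a1; geno[i, 2L * l] <- a2
    }
    ids <- c(ids, id)
    last_id_in_pop[ind_pops[i]] <- id
    labels <- c(labels, as.character(ind_pops[i]))
  }
  if (is.null(pop_names)) pop_names <- paste0("pop_", seq_len(n_pops))
  labels <- pop_names[as.integer(labels)]

  if (length(ids) == 0L) {
    # empty blocks permitted: dataset with zero individuals
    geno <- matrix(NA_integer_, 0L, 2L * L)
    return(structure(list(genotypes = geno, labels = character(0),
                          locus_names = locus_names, ids = character(0),
                          n_pops = n_pops, pop_names = pop_names),
                     class = "MicrosatDataset"))
  }
  out <- microsat_dataset(geno, labels, locus_names, ids = ids)
  out$n_pops <- n_pops
  out$pop_names <- pop_names
  out
}

#' Write a microsatellite dataset in GENEPOP format
#'
#' @param x a \code{MicrosatDataset}.
#' @param title title line.
#' @return A single GENEPOP-format string; \code{read_genepop} on the
#'   output reproduces \code{x} (byte-stable ordering).
#' @export
write_genepop <- function(x, title = "garrapop export") {
  stopifnot(inherits(x, "MicrosatDataset"))
  if (any(x$genotypes > 999L, na.rm = TRUE))
    stop("repeat count > 999 cannot be encoded in the 3-digit dialect")
  L <- length(x$locus_names)
  pops <- unique(x$labels)
  if (length(pops) == 0L) pops <- character(0)
  out <- c(title, x$locus_names)
  for (p in pops) {
    out <- c(out, "Pop")
    rows <- which(x$labels == p)
    for (i in rows) {
      g <- x$genotypes[i, ]
      fields <- vapply(seq_len(L), function(l) {
        a1 <- g[2L * l - 1L]; a2 <- g[2L * l]
        if (is.na(a1)) "000000"
        else sprintf("%03d%03d", a1, a2)
      }, "")
      out <- c(out, paste0(x$ids[i], " , ", paste(fields, collapse = " ")))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
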