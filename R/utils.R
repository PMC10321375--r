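# IUPAC nucleotide classes used for PAM patterns and relaxed matching.
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_chars <- function() names(IUPAC)

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors as plain character vectors.
#'
#' @param x Character vector of DNA sequences (IUPAC alphabet).
#' @return Character vector of reverse complements, same length as `x`.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTA"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Translate an IUPAC pattern into a plain-ACGT regular expression.
# N deliberately maps to [ACGT]: windows containing N never match a PAM.
iupac_to_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, iupac_chars())
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC code(s) in pattern '%s': %s",
                  pattern, paste(unique(bad), collapse = ", ")))
  }
  paste0(vapply(chars, function(ch) {
    cls <- IUPAC[[ch]]
    if (length(cls) == 1) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All 1-based start positions (possibly overlapping) where `pattern`
# (IUPAC) matches in `seq`.
iupac_match_positions <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# TRUE iff `seq` (plain ACGT, same length) is in the IUPAC class of
# `pattern` at every position.
iupac_matches <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) {
    abort(sprintf("sequence length %d does not match pattern length %d",
                  nchar(seq), nchar(pattern)))
  }
  grepl(paste0("^", iupac_to_regex(pattern), "$"), seq)
}

# Number of degenerate (multi-base) positions in an IUPAC pattern; used
# to pick the most specific PAM-penalty entry when several match.
iupac_degeneracy <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sum(vapply(chars, function(ch) length(IUPAC[[ch]]) > 1, logical(1)))
}

#' Coerce sequences to the genome representation used throughout
#'
#' A genome is a named character vector of uppercase sequences over
#' `{A,C,G,T,N}`, one element per record. Accepts a named character
#' vector, a [Biostrings::DNAStringSet], or a path to a (possibly
#' gzip-compressed, multi-record) FASTA file.
#'
#' @param x Genome input as described above.
#' @return Named uppercase character vector of sequences.
#' @export
as_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x) && length(x) == 1 && !grepl("^[ACGTNacgtn]+$", x) &&
             file.exists(x)) {
    seqs <- as.character(Biostrings::readDNAStringSet(x))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(x)) {
    seqs <- x
  } else {
    abort("genome must be a named character vector, DNAStringSet, or FASTA path")
  }
  if (length(seqs) == 0) abort("genome contains no records")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("all genome records must be named")
  }
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicate genome record IDs: %s",
                  paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("record '%s' contains characters outside {A,C,G,T,N}",
                  names(seqs)[bad][1]))
  }
  seqs
}

#' Checksum of a sequence set, for index provenance
#'
#' MD5 digest of the normalised `id<TAB>sequence` dump of the genome, so
#' an index can verify it is queried against the genome it was built from.
#'
#' @param genome Genome input accepted by [as_genome()].
#' @return Length-1 character MD5 digest.
#' @export
genome_digest <- function(genome) {
  genome <- as_genome(genome)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, open = "wb")
  writeLines(paste(names(genome), genome, sep = "\t"), con, sep = "\n")
  close(con)
  unname(tools::md5sum(tf))
}

# Run code with a private RNG stream: the global .Random.seed is saved
# and restored, so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# TRUE for each row of (start, end) that overlaps any interval in
# `exclude` (tibble with record, start, end; 0-based half-open).
overlaps_excluded <- function(record, start, end, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(exclude$record == record[i] &
          exclude$start < end[i] &
          exclude$end > start[i])
  }, logical(1))
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "guidecraft")
  if (!nzchar(p)) abort(sprintf("packaged data file '%s' not found", file))
  p
}

# Fixed-format numeric printing for report files ("." for missing).
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", sprintf(paste0("%.", digits, "f"), x))
}
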