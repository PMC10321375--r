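#' Primer melting temperature (GC closed form)
#'
#' `Tm = 64.9 + 41 * (GC_count - 16.4) / length` — the simple
#' GC-fraction formula, deterministic and monotone increasing in GC
#' count at fixed length.
#'
#' @param primer Character vector of primer sequences.
#' @return Numeric Tm in degrees Celsius.
#' @export
#' @examples
#' primer_tm("GCGCGCGCGCATATATATAT")  # 10 G/C in 20 nt -> 51.78
primer_tm <- function(primer) {
  gc <- nchar(gsub("[^GC]", "", toupper(primer)))
  64.9 + 41 * (gc - 16.4) / nchar(primer)
}

# >= 4 complementary bases between the 3'-terminal 5 nt of one primer
# and the other primer (simple 3' cross-dimer screen). Patterns for a
# whole primer set are precomputed once: the reverse complements of the
# two 4-mers inside each primer's 3'-terminal 5 nt.
dimer_patterns <- function(seqs) {
  t5 <- substr(seqs, nchar(seqs) - 4, nchar(seqs))
  cbind(revcomp(substr(t5, 1, 4)), revcomp(substr(t5, 2, 5)))
}

pair_dimerizes <- function(fpat_i, rev_seq, rpat_j, fwd_seq) {
  grepl(fpat_i[1], rev_seq, fixed = TRUE) ||
    grepl(fpat_i[2], rev_seq, fixed = TRUE) ||
    grepl(rpat_j[1], fwd_seq, fixed = TRUE) ||
    grepl(rpat_j[2], fwd_seq, fixed = TRUE)
}

#' Design PCR primer pairs flanking a window
#'
#' Enumerates every candidate forward primer ending before the window
#' and reverse primer starting after it, within the length, Tm, GC and
#' pair-Tm-difference constraints, rejects pairs with 3'
#' cross-complementarity (>= 4 complementary bases against the last 5
#' nt), and sorts by `|Tm_f - Tm_r|` then product length. Tm uses the
#' GC closed form of [primer_tm()].
#'
#' @param template Template sequence.
#' @param amplicon_window Length-2 integer, 0-based half-open interval
#'   that the product must span.
#' @param primer_length Length-2 bounds (default `c(18, 25)`).
#' @param tm_bounds Length-2 Tm bounds in Celsius (default `c(55, 65)`).
#' @param gc_bounds Length-2 GC-fraction bounds (default `c(0.4, 0.6)`).
#' @param max_tm_diff Maximum pair Tm difference (default 3).
#' @param max_pairs Return at most this many pairs (default 20).
#' @return Tibble of primer pairs (possibly empty): `forward_seq`,
#'   `reverse_seq`, `forward_start`, `reverse_start` (0-based 5' start
#'   of each primer on the template / its reverse complement mapped to
#'   template coordinates), `product_length`, `tm_forward`,
#'   `tm_reverse`, `tm_diff`.
#' @export
design_primers <- function(template, amplicon_window,
                           primer_length = c(18, 25), tm_bounds = c(55, 65),
                           gc_bounds = c(0.4, 0.6), max_tm_diff = 3,
                           max_pairs = 20) {
  template <- toupper(template)
  n <- nchar(template)
  w0 <- amplicon_window[1]; w1 <- amplicon_window[2]
  if (w0 < 0 || w1 > n || w0 >= w1) {
    abort("amplicon window must lie inside the template")
  }
  lens <- seq(primer_length[1], primer_length[2])

  candidates <- function(region_start, region_end, strand) {
    rows <- list()
    for (L in lens) {
      if (region_end - L < region_start) next
      starts <- seq.int(region_start, region_end - L)
      p <- substring(template, starts + 1, starts + L)
      if (strand == "-") p <- revcomp(p)
      gc <- gc_content(p)
      tm <- primer_tm(p)
      keep <- gc >= gc_bounds[1] & gc <= gc_bounds[2] &
        tm >= tm_bounds[1] & tm <= tm_bounds[2]
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- tibble(start = as.integer(starts[keep]),
                                         length = L, seq = p[keep],
                                         tm = tm[keep])
    }
    if (length(rows) == 0) {
      tibble(start = integer(0), length = integer(0),
             seq = character(0), tm = numeric(0))
    } else bind_rows(rows)
  }

  fwd <- if (w0 >= primer_length[1]) candidates(0L, w0, "+") else
    tibble(start = integer(0), length = integer(0), seq = character(0), tm = numeric(0))
  rev <- if (n - w1 >= primer_length[1]) candidates(w1, n, "-") else
    tibble(start = integer(0), length = integer(0), seq = character(0), tm = numeric(0))
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(empty_primer_pairs())

  fi <- rep(seq_len(nrow(fwd)), each = nrow(rev))
  ri <- rep(seq_len(nrow(rev)), times = nrow(fwd))
  dtm <- abs(fwd$tm[fi] - rev$tm[ri])
  keep <- dtm <= max_tm_diff
  fi <- fi[keep]; ri <- ri[keep]; dtm <- dtm[keep]
  if (length(fi) == 0) return(empty_primer_pairs())
  fpat <- dimer_patterns(fwd$seq)
  rpat <- dimer_patterns(rev$seq)
  ok <- !vapply(seq_along(fi), function(k) {
    pair_dimerizes(fpat[fi[k], ], rev$seq[ri[k]], rpat[ri[k], ], fwd$seq[fi[k]])
  }, logical(1))
  fi <- fi[ok]; ri <- ri[ok]; dtm <- dtm[ok]
  if (length(fi) == 0) return(empty_primer_pairs())
  rev_5p <- rev$start[ri] + rev$length[ri] - 1L  # template coord of reverse 5' end
  out <- tibble(
    forward_seq = fwd$seq[fi], reverse_seq = rev$seq[ri],
    forward_start = fwd$start[fi], reverse_start = as.integer(rev_5p),
    product_length = as.integer(rev_5p - fwd$start[fi] + 1L),
    tm_forward = fwd$tm[fi], tm_reverse = rev$tm[ri],
    tm_diff = dtm
  )
  out <- arrange(out, .data$tm_diff, .data$product_length,
                 .data$forward_start, .data$reverse_start)
  head(out, max_pairs)
}

empty_primer_pairs <- function() {
  tibble(forward_seq = character(0), reverse_seq = character(0),
         forward_start = integer(0), reverse_start = integer(0),
         product_length = integer(0), tm_forward = numeric(0),
         tm_reverse = numeric(0), tm_diff = numeric(0))
}

#' Structure templates for sgRNA assembly
#'
#' Named sequence insertions (hairpin, GOLD, identity) shipped as a
#' user-editable config
#' (`system.file("extdata", "structure_templates.tsv", package =
#' "guidecraft")`). The packaged hairpin/GOLD sequences are synthetic
#' placeholders carrying a `source_tag` that says so; the mechanism —
#' templated insertion at a named position — is what the engine
#' provides. Supply your validated sequences via `path`.
#'
#' @param path Optional alternative template table (columns `name`,
#'   `insert_seq`, `insert_position`, `offset`, `source_tag`).
#' @return Tibble of templates.
#' @export
structure_templates <- function(path = NULL) {
  file <- if (is.null(path)) extdata_path("structure_templates.tsv") else path
  tab <- as_tibble(read.delim(file, stringsAsFactors = FALSE,
                              na.strings = character(0)))
  stopifnot(all(c("name", "insert_seq", "insert_position", "offset") %in% names(tab)))
  tab$insert_seq[is.na(tab$insert_seq)] <- ""
  tab
}

#' Insert a structure template into an assembled sgRNA
#'
#' Deterministically assembles `spacer + scaffold` and places the
#' template's insert at its declared position (`five_prime`,
#' `three_prime`, or `internal` at a 0-based offset into the
#' assembly). Output length is always the sum of the input lengths and
#' the insert length.
#'
#' @param spacer Spacer sequence.
#' @param scaffold Scaffold sequence (may be "").
#' @param template Template name (looked up in
#'   [structure_templates()]) or a one-row template tibble.
#' @param path Optional alternative template table for name lookup.
#' @return The assembled sequence.
#' @export
add_structure <- function(spacer, scaffold, template, path = NULL) {
  if (is.character(template) && length(template) == 1) {
    tab <- structure_templates(path)
    i <- match(template, tab$name)
    if (is.na(i)) {
      abort(sprintf("unknown structure template '%s'; available: %s",
                    template, paste(tab$name, collapse = ", ")))
    }
    template <- tab[i, ]
  }
  template <- as_tibble(template)
  body <- paste0(toupper(spacer), toupper(scaffold))
  ins <- toupper(template$insert_seq)
  if (is.na(ins)) ins <- ""
  pos <- template$insert_position
  if (pos == "five_prime") {
    paste0(ins, body)
  } else if (pos == "three_prime") {
    paste0(body, ins)
  } else if (pos == "internal") {
    k <- template$offset
    if (k < 0 || k > nchar(body)) {
      abort(sprintf("internal insert offset %d out of bounds for a %d-nt assembly",
                    k, nchar(body)))
    }
    paste0(substr(body, 1, k), ins, substr(body, k + 1, nchar(body)))
  } else {
    abort(sprintf("unknown insert position '%s'", pos))
  }
}
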