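#' Cutting-frequency-determination (CFD) penalty table
#'
#' The CFD off-target score is a product of per-position mismatch
#' penalties (position, guide base, genomic base) multiplied by a PAM
#' penalty; a perfect match with the canonical PAM scores 1.0. The
#' packaged default tables are synthetic, provenance-tagged stand-ins
#' with CFD-like structure (PAM-proximal mismatches penalised more,
#' non-canonical PAMs down-weighted); they ship as editable TSVs
#' (`cfd_mismatch_synthetic.tsv`, `cfd_pam_synthetic.tsv`) so published
#' penalty tables can be substituted verbatim via `mismatch_path` /
#' `pam_path`.
#'
#' Positions are numbered 1..spacer_length from the 5' end of the
#' spacer in guide orientation. The packaged mismatch table covers
#' 20-nt spacers; for other spacer lengths positions are mapped
#' linearly onto the 20-nt scale. The PAM table for non-NGG models is
#' derived from the model: canonical PAM 1.0, single-base departures at
#' the relaxed position down-weighted (transition 0.25, transversion
#' 0.06).
#'
#' @param model A `pam_model` or model name (default SpCas9-NGG).
#' @param mismatch_path,pam_path Optional replacement TSVs. The
#'   mismatch table needs columns `position`, `guide_base`,
#'   `genome_base`, `penalty`; the PAM table `pam_pattern`, `penalty`.
#' @return A `penalty_table` object.
#' @export
penalty_table <- function(model = "SpCas9-NGG", mismatch_path = NULL,
                          pam_path = NULL) {
  model <- pam_model(model)
  L <- model$spacer_length
  mm_file <- if (is.null(mismatch_path)) {
    extdata_path("cfd_mismatch_synthetic.tsv")
  } else mismatch_path
  mm <- read.delim(mm_file, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "guide_base", "genome_base", "penalty") %in% names(mm)))
  if (any(mm$penalty < 0 | mm$penalty > 1)) abort("mismatch penalties must lie in [0, 1]")
  table_len <- max(mm$position)
  if (L != table_len) {
    # map positions 1..L linearly onto the table's 1..table_len scale
    mapped <- round((seq_len(L) - 1) * (table_len - 1) / (L - 1)) + 1
    mm <- do.call(rbind, lapply(seq_len(L), function(p) {
      sub <- mm[mm$position == mapped[p], ]
      sub$position <- p
      sub
    }))
  }
  mismatch <- setNames(mm$penalty,
                       paste(mm$position, mm$guide_base, mm$genome_base, sep = ":"))

  if (!is.null(pam_path)) {
    pam <- read.delim(pam_path, stringsAsFactors = FALSE)
  } else if (model$pattern == "NGG") {
    pam <- read.delim(extdata_path("cfd_pam_synthetic.tsv"),
                      stringsAsFactors = FALSE)
  } else {
    pam <- derive_pam_penalties(model)
  }
  stopifnot(all(c("pam_pattern", "penalty") %in% names(pam)))
  if (any(pam$penalty < 0 | pam$penalty > 1)) abort("PAM penalties must lie in [0, 1]")
  pam$degeneracy <- vapply(pam$pam_pattern, iupac_degeneracy, integer(1))

  structure(
    list(mismatch = mismatch, pam = pam, spacer_length = L,
         model_name = model$name,
         source_tag = if (is.null(mismatch_path) && is.null(pam_path))
           "guidecraft-synthetic-v1" else "user-supplied"),
    class = "penalty_table"
  )
}

# Canonical PAM scores 1.0; each single-base departure at the relaxed
# position is down-weighted (transition 0.25, transversion 0.06).
derive_pam_penalties <- function(model) {
  chars <- strsplit(model$pattern, "")[[1]]
  fixed <- which(vapply(chars, function(ch) length(IUPAC[[ch]]) == 1, logical(1)))
  out <- data.frame(pam_pattern = model$pattern, penalty = 1.0,
                    stringsAsFactors = FALSE)
  if (length(fixed) == 0) return(out)
  i <- fixed[1]
  canon <- chars[i]
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (b in setdiff(c("A", "C", "G", "T"), canon)) {
    alt <- chars
    alt[i] <- b
    pen <- if (identical(unname(transition_of[canon]), b)) 0.25 else 0.06
    out <- rbind(out, data.frame(pam_pattern = paste(alt, collapse = ""),
                                 penalty = pen, stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.penalty_table <- function(x, ...) {
  cat(sprintf("<penalty_table> %d-nt spacers, %d mismatch entries, %d PAM entries [%s]\n",
              x$spacer_length, length(x$mismatch), nrow(x$pam), x$source_tag))
  invisible(x)
}

pam_penalty_lookup <- function(pam_seq, table) {
  hits <- which(vapply(table$pam$pam_pattern,
                       function(p) nchar(p) == nchar(pam_seq) && iupac_matches(pam_seq, p),
                       logical(1)))
  if (length(hits) == 0) {
    abort(sprintf("no PAM penalty entry matches '%s'; add a row to the PAM penalty table",
                  pam_seq))
  }
  hits <- hits[order(table$pam$degeneracy[hits])]
  table$pam$penalty[hits[1]]
}

#' CFD off-target score for one aligned site
#'
#' Product over mismatched positions of
#' `mismatch_penalty(position, guide_base, genome_base)`, multiplied by
#' the PAM penalty of the site's PAM window. A perfect match with the
#' canonical PAM scores exactly 1.0.
#'
#' @param guide_spacer,site_spacer Equal-length spacer sequences (guide
#'   orientation).
#' @param site_pam The site's PAM window.
#' @param table A [penalty_table()].
#' @return Score in `[0, 1]`.
#' @export
cfd_score <- function(guide_spacer, site_spacer, site_pam,
                      table = penalty_table()) {
  stopifnot(inherits(table, "penalty_table"))
  guide_spacer <- toupper(guide_spacer); site_spacer <- toupper(site_spacer)
  if (nchar(guide_spacer) != nchar(site_spacer)) {
    abort("guide and site spacers must have equal length")
  }
  g <- strsplit(guide_spacer, "")[[1]]
  d <- strsplit(site_spacer, "")[[1]]
  mm <- which(g != d)
  score <- pam_penalty_lookup(toupper(site_pam), table)
  if (length(mm) > 0) {
    keys <- paste(mm, g[mm], d[mm], sep = ":")
    pens <- table$mismatch[keys]
    if (anyNA(pens)) {
      bad <- keys[which(is.na(pens))[1]]
      abort(sprintf("penalty table has no entry for (position:guide>genome) = %s", bad))
    }
    score <- score * prod(pens)
  }
  unname(score)
}

#' Aggregate per-guide specificity from its off-target hits
#'
#' `1 / (1 + sum of CFD scores over all off-target hits)` — 1.0 for a
#' guide with no off-targets, strictly decreasing as any hit's CFD
#' score grows.
#'
#' @param hits A tibble with a `cfd` column (as returned by
#'   [find_offtargets()]), or a bare numeric vector of CFD scores. The
#'   on-target site must already be excluded.
#' @return Specificity in `(0, 1]`.
#' @export
specificity_score <- function(hits) {
  cfd <- if (is.data.frame(hits)) hits$cfd else hits
  if (length(cfd) == 0) return(1.0)
  1 / (1 + sum(cfd))
}

empty_hits <- function() {
  tibble(record_id = character(0), start = integer(0), end = integer(0),
         strand = character(0), site_spacer = character(0),
         site_pam = character(0), mismatch_count = integer(0),
         mismatch_detail = list(), cfd = numeric(0))
}

# Cache both strand orientations of the genome as DNAStringSets so a
# batch of guides reuses the conversion.
make_subjects <- function(genome) {
  ss <- Biostrings::DNAStringSet(genome)
  list(plus = ss, minus = Biostrings::reverseComplement(ss), n = nchar(genome))
}

#' Find genomic off-target sites of a guide within a mismatch bound
#'
#' Scans both strands of every genome record for PAM-adjacent sites
#' whose spacer Hamming distance to the guide is strictly below
#' `max_diff_exclusive` (default 5, i.e. up to 4 base differences).
#' Candidate sites must carry a PAM matching either the model's
#' canonical pattern or (default) a relaxed pattern in which the most
#' 5'-proximal fixed PAM position is widened to N; non-canonical PAMs
#' are down-weighted through the PAM penalty. Windows containing N are
#' skipped. Matching uses the C-level bounded-mismatch matcher of
#' [Biostrings::matchPattern()].
#'
#' @param guide Spacer sequence (character) or a one-row candidate
#'   tibble with a `spacer` column.
#' @param genome Genome input accepted by [as_genome()].
#' @param model A `pam_model` or model name.
#' @param max_diff_exclusive Strict upper bound on base differences
#'   (default 5; the CLI flag `--max-mismatch` is inclusive and maps to
#'   this value + 1).
#' @param exclude Optional tibble of on-target intervals to drop
#'   (columns `record`, `start`, `end`; 0-based half-open).
#' @param table A [penalty_table()]; defaults to the model's packaged
#'   table.
#' @param pam_mode `"relaxed"` (default) or `"canonical"` — whether
#'   off-target sites may carry a near-canonical PAM.
#' @return Tibble of hits sorted by `(mismatch_count, -cfd)`: columns
#'   `record_id`, `start`, `end` (0-based half-open), `strand`,
#'   `site_spacer`, `site_pam`, `mismatch_count`, `mismatch_detail`
#'   (list of per-position tibbles), `cfd`.
#' @export
find_offtargets <- function(guide, genome, model, max_diff_exclusive = 5,
                            exclude = NULL, table = NULL,
                            pam_mode = c("relaxed", "canonical")) {
  pam_mode <- match.arg(pam_mode)
  model <- pam_model(model)
  spacer <- toupper(if (is.data.frame(guide)) guide$spacer[1] else guide)
  if (nchar(spacer) != model$spacer_length) {
    abort(sprintf("guide spacer length %d does not match model spacer length %d",
                  nchar(spacer), model$spacer_length))
  }
  stopifnot(max_diff_exclusive >= 1)
  genome <- as_genome(genome)
  if (is.null(table)) table <- penalty_table(model)
  subjects <- make_subjects(genome)
  admit_pattern <- if (pam_mode == "relaxed") relaxed_pam_pattern(model) else model$pattern

  L <- model$spacer_length
  P <- model$pam_length
  rows <- list()
  for (ri in seq_along(genome)) {
    rec_id <- names(genome)[ri]
    n <- subjects$n[ri]
    for (str in c("+", "-")) {
      subj <- if (str == "+") subjects$plus[[ri]] else subjects$minus[[ri]]
      m <- Biostrings::matchPattern(spacer, subj,
                                    max.mismatch = max_diff_exclusive - 1L,
                                    with.indels = FALSE, fixed = TRUE)
      starts <- Biostrings::start(m)  # 1-based on the scanned strand
      if (length(starts) == 0) next
      subj_chr <- as.character(subj)
      for (s in starts) {
        if (model$side == "three_prime") {
          pam_s <- s + L; pam_e <- s + L + P - 1
        } else {
          pam_s <- s - P; pam_e <- s - 1
        }
        if (pam_s < 1 || pam_e > n) next
        site_spacer <- substr(subj_chr, s, s + L - 1)
        site_pam <- substr(subj_chr, pam_s, pam_e)
        if (grepl("N", site_spacer, fixed = TRUE) ||
            grepl("N", site_pam, fixed = TRUE)) next
        if (!iupac_matches(site_pam, admit_pattern)) next
        g <- strsplit(spacer, "")[[1]]
        d <- strsplit(site_spacer, "")[[1]]
        mm <- which(g != d)
        if (length(mm) >= max_diff_exclusive) next
        if (str == "+") {
          start0 <- s - 1L; end0 <- s + L - 1L
        } else {
          start0 <- n - (s + L - 1L); end0 <- n - (s - 1L)
        }
        rows[[length(rows) + 1]] <- tibble(
          record_id = rec_id, start = as.integer(start0), end = as.integer(end0),
          strand = str, site_spacer = site_spacer, site_pam = site_pam,
          mismatch_count = length(mm),
          mismatch_detail = list(tibble(position = as.integer(mm),
                                        guide_base = g[mm], genome_base = d[mm])),
          cfd = cfd_score(spacer, site_spacer, site_pam, table)
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- bind_rows(rows)
  drop <- overlaps_excluded(hits$record_id, hits$start, hits$end, exclude)
  hits <- hits[!drop, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  arrange(hits, .data$mismatch_count, desc(.data$cfd), .data$record_id,
          .data$start, .data$strand)
}
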