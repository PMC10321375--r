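#' PAM model registry
#'
#' The package ships a registry of 20 PAM recognition models (Cas9 and
#' Cas12 families), stored as a tabular config at
#' `system.file("extdata", "pam_models.tsv", package = "guidecraft")`.
#' Each model records the IUPAC PAM pattern, which side of the spacer
#' the PAM abuts (`three_prime` for Cas9-type, `five_prime` for
#' Cas12-type), the spacer length in nucleotides, and the signed cut
#' offset relative to the PAM-proximal end of the spacer. A user table
#' with the same columns can be supplied via `path` (or the CLI flag
#' `--pam-table`).
#'
#' @param path Optional path to an alternative model table.
#' @return A tibble with columns `name`, `pattern`, `side`,
#'   `spacer_length`, `cut_offset`, `description`.
#' @export
#' @examples
#' pam_models()
pam_models <- function(path = NULL) {
  key <- if (is.null(path)) "packaged" else normalizePath(path)
  if (!is.null(the_registry[[key]])) return(the_registry[[key]])
  file <- if (is.null(path)) extdata_path("pam_models.tsv") else path
  tab <- as_tibble(read.delim(file, stringsAsFactors = FALSE))
  validate_pam_table(tab)
  the_registry[[key]] <- tab
  tab
}

validate_pam_table <- function(tab) {
  needed <- c("name", "pattern", "side", "spacer_length", "cut_offset")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0) {
    abort(sprintf("PAM model table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tab$name)) {
    abort(sprintf("duplicate PAM model name(s): %s",
                  paste(unique(tab$name[duplicated(tab$name)]), collapse = ", ")))
  }
  ok_chars <- vapply(tab$pattern, function(p) {
    all(strsplit(p, "")[[1]] %in% iupac_chars())
  }, logical(1))
  if (any(!ok_chars)) {
    abort(sprintf("PAM pattern '%s' contains non-IUPAC characters",
                  tab$pattern[!ok_chars][1]))
  }
  if (!all(tab$side %in% c("three_prime", "five_prime"))) {
    abort("PAM model 'side' must be 'three_prime' or 'five_prime'")
  }
  if (!all(tab$spacer_length >= 10 & tab$spacer_length <= 30)) {
    abort("spacer_length must be between 10 and 30 nt")
  }
  invisible(tab)
}

#' Look up a PAM model by name
#'
#' @param name Registered model name, e.g. `"SpCas9-NGG"` or
#'   `"Cas12a-TTTV"`.
#' @param path Optional alternative model table (see [pam_models()]).
#' @return A `pam_model` object: a list with fields `name`, `pattern`,
#'   `side`, `spacer_length`, `cut_offset`, `pam_length`.
#' @export
#' @examples
#' pam_model("SpCas9-NGG")
pam_model <- function(name, path = NULL) {
  if (inherits(name, "pam_model")) return(name)
  tab <- pam_models(path)
  i <- match(name, tab$name)
  if (is.na(i)) {
    abort(sprintf("unknown PAM model '%s'; registered models: %s",
                  name, paste(tab$name, collapse = ", ")))
  }
  row <- tab[i, ]
  structure(
    list(name = row$name, pattern = row$pattern, side = row$side,
         spacer_length = as.integer(row$spacer_length),
         cut_offset = as.integer(row$cut_offset),
         pam_length = nchar(row$pattern)),
    class = "pam_model"
  )
}

#' @export
print.pam_model <- function(x, ...) {
  cat(sprintf("<pam_model> %s: %s PAM '%s', %d-nt spacer, cut offset %+d\n",
              x$name, ifelse(x$side == "three_prime", "3'", "5'"),
              x$pattern, x$spacer_length, x$cut_offset))
  invisible(x)
}

#' Does a window match a PAM pattern?
#'
#' @param seq Plain-ACGT window, same length as the model's pattern.
#' @param model A `pam_model` (or model name).
#' @return TRUE iff every position of `seq` is in the IUPAC class of the
#'   pattern position.
#' @export
#' @examples
#' matches_pam("AGG", pam_model("SpCas9-NGG"))
matches_pam <- function(seq, model) {
  model <- pam_model(model)
  iupac_matches(seq, model$pattern)
}

# The relaxed PAM pattern used for off-target site admission: the most
# 5'-proximal single-base position of the canonical pattern is widened
# to N. Near-PAMless patterns without a single-base position are
# returned unchanged (relaxed == canonical).
relaxed_pam_pattern <- function(model) {
  chars <- strsplit(model$pattern, "")[[1]]
  fixed <- which(vapply(chars, function(ch) length(IUPAC[[ch]]) == 1, logical(1)))
  if (length(fixed) == 0) return(model$pattern)
  chars[fixed[1]] <- "N"
  paste(chars, collapse = "")
}

#' Enumerate candidate protospacers in a sequence
#'
#' Scans a sequence (optionally both strands) for every window matching
#' the model's PAM pattern and reports the adjacent spacer of the
#' model's length. Windows containing `N` (in spacer or PAM) are
#' skipped. Coordinates are 0-based half-open on the input's forward
#' strand; minus-strand candidates report the reverse-complement spacer
#' (guide orientation) with strand `"-"`.
#'
#' @param seq A single sequence over `{A,C,G,T,N}`.
#' @param model A `pam_model` or model name.
#' @param both_strands Scan the reverse complement too? Default TRUE.
#' @return A tibble sorted by `(start, strand)` with columns `start`,
#'   `end`, `strand`, `spacer`, `pam`, `pam_start`, `pam_end`.
#' @export
#' @examples
#' enumerate_protospacers(strrep("G", 23), "SpCas9-NGG")
enumerate_protospacers <- function(seq, model, both_strands = TRUE) {
  model <- pam_model(model)
  seq <- toupper(seq)
  stopifnot(is.character(seq), length(seq) == 1)
  if (grepl("[^ACGTN]", seq)) abort("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(seq)
  plus <- scan_one_strand(seq, model)
  if (nrow(plus) > 0) plus$strand <- "+"
  out <- plus
  if (both_strands) {
    minus <- scan_one_strand(revcomp(seq), model)
    if (nrow(minus) > 0) {
      minus <- mutate(minus,
        strand = "-",
        new_start = n - .data$end, new_end = n - .data$start,
        new_pam_start = n - .data$pam_end, new_pam_end = n - .data$pam_start,
        start = .data$new_start, end = .data$new_end,
        pam_start = .data$new_pam_start, pam_end = .data$new_pam_end
      )
      minus <- select(minus, -dplyr::starts_with("new_"))
      out <- bind_rows(plus, minus)
    }
  }
  if (nrow(out) == 0) {
    return(tibble(start = integer(0), end = integer(0), strand = character(0),
                  spacer = character(0), pam = character(0),
                  pam_start = integer(0), pam_end = integer(0)))
  }
  out <- arrange(out, .data$start, .data$strand)
  select(out, "start", "end", "strand", "spacer", "pam", "pam_start", "pam_end")
}

# Forward-strand scan: coordinates 0-based half-open on the scanned
# string; caller handles strand flipping.
scan_one_strand <- function(seq, model) {
  L <- model$spacer_length
  P <- model$pam_length
  n <- nchar(seq)
  empty <- tibble(start = integer(0), end = integer(0), strand = character(0),
                  spacer = character(0), pam = character(0),
                  pam_start = integer(0), pam_end = integer(0))
  if (n < L + P) return(empty)
  pam_pos <- iupac_match_positions(seq, model$pattern)  # 1-based
  if (length(pam_pos) == 0) return(empty)
  if (model$side == "three_prime") {
    sp_start1 <- pam_pos - L
    keep <- sp_start1 >= 1
  } else {
    sp_start1 <- pam_pos + P
    keep <- sp_start1 + L - 1 <= n
  }
  sp_start1 <- sp_start1[keep]
  pam_pos <- pam_pos[keep]
  if (length(sp_start1) == 0) return(empty)
  spacer <- substring(seq, sp_start1, sp_start1 + L - 1)
  pam <- substring(seq, pam_pos, pam_pos + P - 1)
  ok <- !grepl("N", spacer, fixed = TRUE)
  tibble(
    start = as.integer(sp_start1[ok] - 1L),
    end = as.integer(sp_start1[ok] + L - 1L),
    strand = rep("+", sum(ok)),
    spacer = spacer[ok],
    pam = pam[ok],
    pam_start = as.integer(pam_pos[ok] - 1L),
    pam_end = as.integer(pam_pos[ok] + P - 1L)
  )
}
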