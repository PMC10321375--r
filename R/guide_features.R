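#' Poly-T / poly-A warning flag
#'
#' A run of four or more consecutive T's in a spacer can act as a Pol
#' III terminator and truncate sgRNA transcription; runs of four A's
#' are flagged symmetrically. Flagged guides are reported with an
#' exclamation mark in output tables, not dropped.
#'
#' @param spacer Character vector of spacers over `{A,C,G,T}`.
#' @return Logical vector: TRUE iff the spacer contains `"TTTT"` or
#'   `"AAAA"` as a substring.
#' @export
#' @examples
#' poly_ta_flag(c("GCGTTTTGCGCGCGCGCGCA", "GCGTTTGCGCGCGCGCGCAT"))
poly_ta_flag <- function(spacer) {
  grepl("TTTT", spacer, fixed = TRUE) | grepl("AAAA", spacer, fixed = TRUE)
}

#' GC fraction of a spacer
#'
#' @param spacer Non-empty character vector of sequences over `{A,C,G,T}`.
#' @return Numeric vector in `[0, 1]`: `(#G + #C) / length`.
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGT"))
gc_content <- function(spacer) {
  if (any(!nzchar(spacer))) abort("gc_content() requires non-empty sequences")
  gc <- nchar(gsub("[^GC]", "", spacer))
  gc / nchar(spacer)
}

#' Hairpin (inverted-repeat) self-complementarity flag
#'
#' Exhaustive substring scan: TRUE iff some stem of length `min_stem`
#' starting at position i has its reverse complement starting at a
#' position j far enough downstream that the intervening loop is at
#' least `min_loop` nt. Intended for the assembled spacer + scaffold
#' sequence; symmetric under reverse complementation.
#'
#' @param seq A single sequence over `{A,C,G,T}`.
#' @param min_stem Minimum stem length (>= 3), default 4.
#' @param min_loop Minimum loop length (>= 3), default 3.
#' @return Logical scalar.
#' @export
hairpin_flag <- function(seq, min_stem = 4, min_loop = 3) {
  stopifnot(min_stem >= 3, min_loop >= 3)
  seq <- toupper(seq)
  n <- nchar(seq)
  m <- as.integer(min_stem)
  if (n < 2 * m + min_loop) return(FALSE)
  subs <- substring(seq, 1:(n - m + 1), m:n)
  rcs <- revcomp(subs)
  for (i in seq_along(subs)) {
    j_min <- i + m + min_loop
    if (j_min > length(subs)) break
    if (any(subs[j_min:length(subs)] == rcs[i])) return(TRUE)
  }
  FALSE
}

#' Linear on-target activity model
#'
#' A pluggable linear scorer over a fixed-length sequence context
#' (spacer plus flanks): intercept + per-position nucleotide weights +
#' per-position dinucleotide weights + a GC-count term computed over
#' the spacer window. The packaged default weights are a synthetic,
#' provenance-tagged stand-in (see
#' `system.file("extdata", "activity_weights_synthetic.tsv", package =
#' "guidecraft")`); substitute a published weight table via `path` for
#' production scoring.
#'
#' @param path Optional path to a weight table with columns
#'   `term` (`intercept`, `positional`, `dinucleotide`, `gc_low`,
#'   `gc_high`), `position`, `token`, `weight`.
#' @param context_length Expected context length (default 30).
#' @param spacer_window 1-based inclusive `(start, end)` of the spacer
#'   within the context (default `c(5, 24)`: 4-nt 5' flank, 20-nt
#'   spacer, PAM + 3-nt 3' flank).
#' @return An `activity_model` object.
#' @export
activity_model <- function(path = NULL, context_length = 30L,
                           spacer_window = c(5L, 24L)) {
  file <- if (is.null(path)) extdata_path("activity_weights_synthetic.tsv") else path
  tab <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "position", "token", "weight") %in% names(tab)))
  pos_tab <- tab[tab$term == "positional", ]
  din_tab <- tab[tab$term == "dinucleotide", ]
  bad_pos <- c(pos_tab$position, din_tab$position)
  if (length(bad_pos) > 0 && (min(bad_pos) < 1 || max(bad_pos) > context_length)) {
    abort("activity weight positions fall outside the configured context length")
  }
  grab1 <- function(term) {
    w <- tab$weight[tab$term == term]
    if (length(w) == 0) 0 else w[1]
  }
  structure(
    list(
      intercept = grab1("intercept"),
      positional = setNames(pos_tab$weight,
                            paste(pos_tab$position, pos_tab$token, sep = ":")),
      dinucleotide = setNames(din_tab$weight,
                              paste(din_tab$position, din_tab$token, sep = ":")),
      gc_low = grab1("gc_low"),
      gc_high = grab1("gc_high"),
      gc_center = 10L,
      context_length = as.integer(context_length),
      spacer_window = as.integer(spacer_window),
      source_tag = if (is.null(path)) "guidecraft-synthetic-v1" else file
    ),
    class = "activity_model"
  )
}

#' Predicted activity of a guide context
#'
#' @param context Sequence of exactly `model$context_length` nt over
#'   `{A,C,G,T}` (spacer plus flanks).
#' @param model An [activity_model()].
#' @return Numeric score (unbounded linear predictor); deterministic.
#' @export
activity_score <- function(context, model = activity_model()) {
  stopifnot(inherits(model, "activity_model"))
  context <- toupper(context)
  if (nchar(context) != model$context_length) {
    abort(sprintf("context length %d does not match the model's configured length %d",
                  nchar(context), model$context_length))
  }
  bases <- strsplit(context, "")[[1]]
  n <- length(bases)
  pos_keys <- paste(seq_len(n), bases, sep = ":")
  din_keys <- paste(seq_len(n - 1), paste0(bases[-n], bases[-1]), sep = ":")
  pos_sum <- sum(model$positional[pos_keys], na.rm = TRUE)
  din_sum <- sum(model$dinucleotide[din_keys], na.rm = TRUE)
  sp <- substr(context, model$spacer_window[1], model$spacer_window[2])
  gc_count <- nchar(gsub("[^GC]", "", sp))
  gc_term <- if (gc_count < model$gc_center) {
    model$gc_low * (model$gc_center - gc_count)
  } else {
    model$gc_high * (gc_count - model$gc_center)
  }
  model$intercept + pos_sum + din_sum + gc_term
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> context %d nt, spacer %d-%d, %d positional + %d dinucleotide weights [%s]\n",
              x$context_length, x$spacer_window[1], x$spacer_window[2],
              length(x$positional), length(x$dinucleotide), x$source_tag))
  invisible(x)
}
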