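#' Build the genome-wide spacer uniqueness index
#'
#' Enumerates every PAM-adjacent protospacer on both strands of every
#' genome record (for the given PAM model) and tabulates occurrence
#' counts per spacer sequence, in guide orientation. This is the
#' reference-free replacement for per-species off-target databases: a
#' guide whose spacer occurs exactly once genome-wide is classified
#' unique. Occurrences are counted for the spacer sequence alone (the
#' sgRNA does not include the PAM); a spacer and its reverse complement
#' are distinct keys.
#'
#' @param genome Genome input accepted by [as_genome()].
#' @param model A `pam_model` or model name.
#' @return A `uniqueness_index` object.
#' @export
build_index <- function(genome, model) {
  genome <- as_genome(genome)
  model <- pam_model(model)
  spacers <- unlist(lapply(names(genome), function(id) {
    enumerate_protospacers(genome[[id]], model, both_strands = TRUE)$spacer
  }), use.names = FALSE)
  counts <- if (length(spacers) == 0) {
    setNames(integer(0), character(0))
  } else {
    tab <- table(spacers)
    cts <- setNames(as.integer(tab), names(tab))
    cts[order(names(cts))]
  }
  structure(
    list(counts = counts,
         model_name = model$name,
         spacer_length = model$spacer_length,
         genome_digest = genome_digest(genome),
         n_records = length(genome)),
    class = "uniqueness_index"
  )
}

#' @export
print.uniqueness_index <- function(x, ...) {
  cat(sprintf("<uniqueness_index> %d spacers (%d unique) | model %s | %d record(s) | digest %s\n",
              length(x$counts), sum(x$counts == 1L), x$model_name,
              x$n_records, substr(x$genome_digest, 1, 8)))
  invisible(x)
}

#' Genome-wide occurrence count of spacers
#'
#' @param index A `uniqueness_index`.
#' @param spacer Character vector of spacer sequences, each of the
#'   index's spacer length.
#' @return Integer vector of PAM-adjacent occurrence counts (0 for a
#'   spacer never seen in the genome).
#' @export
occurrence_count <- function(index, spacer) {
  stopifnot(inherits(index, "uniqueness_index"))
  if (any(nchar(spacer) != index$spacer_length)) {
    abort(sprintf("spacer length must be %d to query this index",
                  index$spacer_length))
  }
  out <- unname(index$counts[toupper(spacer)])
  out[is.na(out)] <- 0L
  as.integer(out)
}

INDEX_FORMAT_VERSION <- "guidecraftdb-v1"

#' Save / load a uniqueness index
#'
#' The on-disk format is a versioned plain-text table: a header with
#' format version, PAM model, spacer length, genome digest and record
#' count; one sorted `spacer<TAB>count` row per key; and a footer row
#' carrying the key count so truncated files are detected. An index can
#' be built once per genome and reused across design runs.
#'
#' @param index A `uniqueness_index`.
#' @param path File path.
#' @return `save_index()` returns `path` invisibly; `load_index()`
#'   returns the restored `uniqueness_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "uniqueness_index"))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  header <- c(
    paste0("#format\t", INDEX_FORMAT_VERSION),
    paste0("#model\t", index$model_name),
    paste0("#spacer_length\t", index$spacer_length),
    paste0("#genome_digest\t", index$genome_digest),
    paste0("#n_records\t", index$n_records)
  )
  body <- if (length(index$counts) > 0) {
    paste(names(index$counts), index$counts, sep = "\t")
  } else {
    character(0)
  }
  footer <- paste0("#end\t", length(index$counts))
  writeLines(c(header, body, footer), con, sep = "\n")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) abort(sprintf("index file '%s' does not exist", path))
  lines <- readLines(path)
  if (length(lines) < 6 || !startsWith(lines[1], "#format\t")) {
    abort(sprintf("'%s' is not a %s index file", path, INDEX_FORMAT_VERSION))
  }
  version <- sub("^#format\t", "", lines[1])
  if (version != INDEX_FORMAT_VERSION) {
    abort(sprintf("index format version '%s' not supported (expected %s)",
                  version, INDEX_FORMAT_VERSION))
  }
  get_field <- function(key) {
    pre <- paste0("#", key, "\t")
    hit <- lines[startsWith(lines, pre)]
    if (length(hit) != 1) abort(sprintf("corrupt index: missing header field '%s'", key))
    sub(pre, "", hit, fixed = TRUE)
  }
  last <- lines[length(lines)]
  if (!startsWith(last, "#end\t")) {
    abort(sprintf("corrupt or truncated index file '%s' (missing end marker; expected format %s)",
                  path, INDEX_FORMAT_VERSION))
  }
  n_expected <- as.integer(sub("^#end\t", "", last))
  body <- lines[!startsWith(lines, "#")]
  if (length(body) != n_expected) {
    abort(sprintf("corrupt index file '%s': %d rows found, %d declared",
                  path, length(body), n_expected))
  }
  counts <- integer(0)
  if (n_expected > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2)) abort(sprintf("corrupt index row in '%s'", path))
    counts <- setNames(as.integer(vapply(parts, `[`, character(1), 2)),
                       vapply(parts, `[`, character(1), 1))
    if (anyNA(counts)) abort(sprintf("corrupt count value in '%s'", path))
  }
  structure(
    list(counts = counts,
         model_name = get_field("model"),
         spacer_length = as.integer(get_field("spacer_length")),
         genome_digest = get_field("genome_digest"),
         n_records = as.integer(get_field("n_records"))),
    class = "uniqueness_index"
  )
}
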