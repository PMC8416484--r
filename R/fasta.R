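#' Parse PrLD sequences from FASTA text
#'
#' Reads one or more amino-acid records from a FASTA-formatted string.
#' Wrapped sequence lines are concatenated, residues are uppercased, and the
#' record order of the input is preserved. Only the 20 canonical one-letter
#' residue codes are accepted: non-canonical codes (X, B, Z, U, `*`, ...)
#' make every downstream feature (propensity scale, pKa table, cysteine
#' count) undefined and are rejected by default.
#'
#' @param text A single string of FASTA-formatted content (at least one
#'   `>` header line).
#' @param skip_invalid If `TRUE`, records containing non-canonical residues
#'   are dropped with a warning instead of aborting.
#' @return A tibble with columns `id`, `description` and `sequence`, one row
#'   per record.
#' @examples
#' sg_parse_fasta(">a lorem\nMKQ\nNPQ\n>b\nGGGG")
#' @export
sg_parse_fasta <- function(text, skip_invalid = FALSE) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    abort("`text` must be a non-empty string of FASTA content.",
          class = "sgpred_malformed_input")
  }
  text <- gsub("\r\n?", "\n", text)
  if (!grepl("(^|\n)>", text)) {
    abort("Malformed FASTA: no '>' header line found.",
          class = "sgpred_malformed_input")
  }
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(text, path)
  sg_read_fasta(path, skip_invalid = skip_invalid)
}

#' Read PrLD sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @inheritParams sg_parse_fasta
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @export
sg_read_fasta <- function(path, skip_invalid = FALSE) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA input: ", conditionMessage(e)),
            class = "sgpred_malformed_input", parent = e)
    }
  )
  if (length(set) == 0L) {
    abort("Malformed FASTA input: no records found.",
          class = "sgpred_malformed_input")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s*", "", headers)), "")
  if (any(!nzchar(ids))) {
    abort("Malformed FASTA input: empty record identifier.",
          class = "sgpred_malformed_input")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate record id(s): %s", paste(dup, collapse = ", ")),
          class = "sgpred_duplicate_id")
  }
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  records <- tibble(id = ids, description = desc, sequence = unname(seqs))
  validate_residues(records, skip_invalid = skip_invalid)
}

validate_residues <- function(records, skip_invalid = FALSE) {
  bad_at <- vapply(records$sequence,
                   function(s) regexpr("[^ACDEFGHIKLMNPQRSTVWY]", s)[[1]],
                   integer(1), USE.NAMES = FALSE)
  empty <- !nzchar(records$sequence)
  offending <- which(bad_at > 0L | empty)
  if (length(offending) == 0L) return(records)
  msgs <- vapply(offending, function(i) {
    if (empty[i]) sprintf("record '%s' is empty", records$id[i])
    else sprintf("record '%s' has invalid residue '%s' at position %d",
                 records$id[i],
                 substr(records$sequence[i], bad_at[i], bad_at[i]),
                 bad_at[i])
  }, character(1))
  if (skip_invalid) {
    warn(paste0("Dropping ", length(offending), " record(s): ",
                paste(msgs, collapse = "; ")))
    records[-offending, , drop = FALSE]
  } else {
    abort(paste0("Invalid residues: ", paste(msgs, collapse = "; ")),
          class = "sgpred_invalid_residue")
  }
}

#' Write sequence records to FASTA
#'
#' Inverse of [sg_parse_fasta()]: `sg_parse_fasta(sg_write_fasta(x))`
#' reproduces `x` (ids, descriptions and sequences) exactly.
#'
#' @param records A tibble with columns `id` and `sequence` (and optionally
#'   `description`).
#' @param path Optional file path; if `NULL` the FASTA text is returned as a
#'   string.
#' @param line_width Positive integer; sequence lines are wrapped at this
#'   many residues.
#' @return The FASTA text (invisibly when `path` is given).
#' @export
sg_write_fasta <- function(records, path = NULL, line_width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (!is.numeric(line_width) || line_width < 1L) {
    abort("`line_width` must be a positive integer.", class = "sgpred_parameter_error")
  }
  line_width <- as.integer(line_width)
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  chunks <- purrr::pmap_chr(
    list(records$id, desc, records$sequence),
    function(id, d, s) {
      header <- if (nzchar(d)) paste0(">", id, " ", d) else paste0(">", id)
      starts <- seq(1L, nchar(s), by = line_width)
      body <- substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))
      paste(c(header, body), collapse = "\n")
    }
  )
  out <- paste0(paste(chunks, collapse = "\n"), "\n")
  if (is.null(path)) return(out)
  cat(out, file = path)
  invisible(out)
}

#' Read a two-column id/label table
#'
#' Labels are supplied separately from the FASTA (keeping the FASTA
#' standard-compliant) as a TSV with columns `id` and `label`, where label is
#' `positive` (recruited into stress-granule foci) or `negative`.
#'
#' @param path Path to the TSV file. A header row is optional.
#' @return A tibble with columns `id`, `label`.
#' @export
sg_read_labels <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) {
    abort("Label table must have two tab-separated columns: id, label.",
          class = "sgpred_label_error")
  }
  raw <- raw[, 1:2]
  names(raw) <- c("id", "label")
  if (identical(tolower(raw$id[1]), "id")) raw <- raw[-1, , drop = FALSE]
  raw$label <- tolower(trimws(raw$label))
  assert_labels(raw$label)
  as_tibble(raw)
}

#' Attach binary recruitment labels to sequence records
#'
#' Joins a label table onto parsed records to form a labeled dataset for
#' training or evaluation. Every record must have a label; the intermediate
#' recruitment class used in focus-formation assays is not modelled, so
#' labels are strictly binary.
#'
#' @param records A tibble from [sg_parse_fasta()] / [sg_read_fasta()].
#' @param labels A tibble with columns `id`, `label` (see [sg_read_labels()]),
#'   or a named character vector of labels keyed by id.
#' @param quiet Suppress the per-class count message.
#' @return The records tibble with a `label` column appended.
#' @export
sg_label_dataset <- function(records, labels, quiet = FALSE) {
  stopifnot(is.data.frame(records))
  if (!is.data.frame(labels)) {
    labels <- tibble(id = names(labels), label = unname(labels))
  }
  assert_labels(labels$label)
  missing <- setdiff(records$id, labels$id)
  if (length(missing) > 0L) {
    abort(sprintf("No label for record(s): %s", paste(missing, collapse = ", ")),
          class = "sgpred_labeling_error")
  }
  out <- dplyr::left_join(records, labels[, c("id", "label")], by = "id")
  if (!quiet) {
    message(sprintf("Labeled dataset: %d positive, %d negative record(s).",
                    sum(out$label == "positive"), sum(out$label == "negative")))
  }
  out
}

#' Write an id/label table as TSV
#'
#' @param dataset A labeled tibble with columns `id`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sg_write_labels <- function(dataset, path) {
  stopifnot(all(c("id", "label") %in% names(dataset)))
  utils::write.table(dataset[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
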