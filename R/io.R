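#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; this wrapper
#' normalizes sequences (uppercase, non-canonical letters to `X`), rejects
#' duplicate identifiers and empty records, and reports the offending line
#' number where it can be located.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects, one per FASTA record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA (line 1): expected a '>' header in ", path,
         call. = FALSE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("failed to parse FASTA ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    line <- fasta_header_line(path, which(!nzchar(ids))[1L])
    stop("malformed FASTA header (line ", line, "): empty id", call. = FALSE)
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    bad <- which(widths == 0L)[1L]
    line <- fasta_header_line(path, bad)
    stop("empty sequence for record '", ids[bad], "' (header at line ", line,
         ")", call. = FALSE)
  }
  check_unique_ids(ids)
  seqs <- as.character(set)
  mapply(protein_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Line number of the n-th FASTA header (1-based), for error messages.
fasta_header_line <- function(path, n) {
  headers <- grep("^>", readLines(path, warn = FALSE))
  if (n <= length(headers)) headers[n] else NA_integer_
}

#' Write protein records to a FASTA file
#' @param proteins List of `protein_record`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- as_protein_list(proteins)
  check_unique_ids(protein_ids(proteins))
  seqs <- Biostrings::BStringSet(vapply(proteins, `[[`, character(1L), "sequence"))
  names(seqs) <- protein_ids(proteins)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read per-residue binding labels
#'
#' The file is tab-separated with columns `protein_id`, `position` (1-based)
#' and `label` (0/1). Positions absent from the file get `mask = 0`
#' (annotation undefined); listed positions get `mask = 1`. Every protein in
#' `proteins` receives a track, even if it has no rows.
#'
#' @param path Path to the label TSV (a header line is optional).
#' @param proteins List of `protein_record`s defining ids and lengths.
#' @return Named list of [label_track()]s keyed by protein id.
#' @export
read_labels <- function(path, proteins) {
  proteins <- as_protein_list(proteins)
  ids <- protein_ids(proteins)
  lens <- vapply(proteins, protein_length, integer(1L))
  names(lens) <- ids

  tracks <- lapply(seq_along(ids), function(i) {
    label_track(ids[i], integer(lens[i]) , mask = integer(lens[i]))
  })
  names(tracks) <- ids

  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("protein_id", "position", "label"),
                           colClasses = c("character", "character", "character"))
  if (nrow(raw) == 0L) return(tracks)
  if (identical(tolower(raw$protein_id[1L]), "protein_id")) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) return(tracks)

  pos <- suppressWarnings(as.integer(raw$position))
  lab <- suppressWarnings(as.integer(raw$label))
  if (anyNA(pos) || anyNA(lab)) {
    bad <- which(is.na(pos) | is.na(lab))[1L]
    stop("non-numeric position/label in label file row ", bad, call. = FALSE)
  }
  unknown <- setdiff(unique(raw$protein_id), ids)
  if (length(unknown)) {
    stop("label file references unknown protein id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(lab %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  oob <- pos < 1L | pos > lens[raw$protein_id]
  if (any(oob)) {
    i <- which(oob)[1L]
    stop("position ", pos[i], " out of range for protein '", raw$protein_id[i],
         "' (length ", lens[raw$protein_id[i]], ")", call. = FALSE)
  }
  for (id in unique(raw$protein_id)) {
    sel <- raw$protein_id == id
    labels <- integer(lens[id])
    mask <- integer(lens[id])
    labels[pos[sel]] <- lab[sel]
    mask[pos[sel]] <- 1L
    tracks[[id]] <- label_track(id, labels, mask)
  }
  tracks
}

#' Write label tracks to TSV
#'
#' Only masked-in positions are written, matching the [read_labels()]
#' convention that unlisted positions are unannotated.
#'
#' @param tracks Named list of `label_track`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    keep <- tr$mask == 1L
    if (!any(keep)) return(NULL)
    data.frame(protein_id = tr$protein_id, position = which(keep),
               label = tr$labels[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(protein_id = character(),
                                        position = integer(), label = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a prediction table to TSV
#' @param table A prediction table (see [prediction_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(table, path) {
  need <- c("protein_id", "position", "residue", "probability", "call")
  if (!all(need %in% names(table))) {
    stop("prediction table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(table[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path Path to the TSV.
#' @return A `data.frame` with the prediction-table columns.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$position <- as.integer(tab$position)
  tab$call <- as.integer(tab$call)
  tab$probability <- as.numeric(tab$probability)
  if (any(tab$probability < 0 | tab$probability > 1)) {
    stop("probabilities outside [0,1] in ", path, call. = FALSE)
  }
  tab
}

#' Append a timestamped line to a run log
#'
#' Minimal plain-text logging: each line carries an ISO timestamp. When the
#' message is tied to a seeded computation, pass `seed` so the line echoes it.
#'
#' @param msg Message string.
#' @param file Log file path, or `""` for standard error.
#' @param seed Optional integer seed to echo.
#' @return The formatted line, invisibly.
#' @export
log_line <- function(msg, file = "", seed = NULL) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  line <- if (is.null(seed)) sprintf("[%s] %s", stamp, msg)
          else sprintf("[%s] (seed=%d) %s", stamp, as.integer(seed), msg)
  cat(line, "\n", sep = "", file = file, append = TRUE)
  invisible(line)
}
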