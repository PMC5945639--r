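# Format plumbing: FASTA, TSV abundance tables, JSON summaries,
# flat key=value configuration files.

#' Read a 3'UTR FASTA
#'
#' Record ids are the first whitespace-delimited token of each header;
#' duplicate ids are an error. `U` is normalized to `T`; wrapped or
#' unwrapped lines and CRLF line endings are accepted.
#'
#' @param path FASTA file.
#' @return Named `DNAStringSet`.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("uU", "tT", as.character(set))
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- ids
  out
}

#' Write a UTR set as FASTA
#' @param utrs Named `DNAStringSet` or character vector.
#' @param path Output path.
#' @export
write_utr_fasta <- function(utrs, path) {
  Biostrings::writeXStringSet(as_utr_set(utrs), path)
  invisible(path)
}

#' Read a tab-delimited abundance table
#'
#' First column (`transcript_id` or first unnamed column) holds transcript
#' ids; all other columns must be numeric abundances. Ragged rows, missing
#' cells, duplicate ids and negative values are errors naming the offending
#' row.
#'
#' @param path TSV path with a header row.
#' @return Numeric matrix with transcript-id rownames.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged table ", path, ": line ", which(nf != nf[1])[1] + 0L,
         " has ", nf[nf != nf[1]][1], " fields, expected ", nf[1])
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2L) stop("table needs an id column and at least one sample column: ", path)
  ids <- as.character(x[[1]])
  vals <- x[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) | is.na(vals[[j]]))
    if (length(bad))
      stop("non-numeric or missing abundance in ", path, ", column '",
           names(vals)[j], "', row ", bad[1] + 1L)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  as_abundance(m, paste0("table ", path))
}

#' Write a summary list as deterministic JSON
#'
#' Keys are sorted; numbers are kept at full precision.
#'
#' @param x Named list of scalars/vectors.
#' @param path Output path.
#' @export
write_results_json <- function(x, path) {
  x <- x[order(names(x))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are kept
#' as strings (callers coerce).
#'
#' @param path Config file.
#' @return Named character list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) m[2], character(1))
  out
}
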