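# File formats and run plumbing: FASTA export/import of simulated
# populations, sample sheets for time-stamped alignment sets, tidy TSV
# tables, and flat key-value run configuration.

#' Export a population (or a sample of it) as FASTA
#'
#' Writes one record per genome, mapping binary alleles to residues
#' (default 0 -> "A" best-fit, 1 -> "G" less-fit). Record names are
#' deterministic: `rep<replicate>_t<time>_g<genome index>`.
#'
#' @param pop binary population matrix.
#' @param path output file path.
#' @param mapping length-2 character vector: residues for alleles 0 and 1.
#' @param time,replicate labels used in record names.
#' @param sample_n optional; write only a random sample of this many genomes
#'   (without replacement), e.g. to emulate sequencing a population sample.
#' @return the path, invisibly.
#' @export
export_population_fasta <- function(pop, path, mapping = c("A", "G"),
                                    time = 0, replicate = 1, sample_n = NULL) {
  stopifnot(length(mapping) == 2L, all(nchar(mapping) == 1L),
            mapping[1] != mapping[2])
  rows <- seq_len(nrow(pop))
  if (!is.null(sample_n)) {
    stopifnot(sample_n >= 1, sample_n <= nrow(pop))
    rows <- sample(rows, sample_n)
  }
  chars <- matrix(mapping[pop[rows, , drop = FALSE] + 1L], nrow = length(rows))
  seqs <- apply(chars, 1, paste0, collapse = "")
  names(seqs) <- sprintf("rep%d_t%g_g%d", replicate, time, rows)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read one aligned FASTA file as a character matrix
#'
#' @param path FASTA file.
#' @return character matrix, sequences x positions, rownames = record names.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("ragged alignment in ", path, ": sequence lengths ",
         paste(unique(w), collapse = ", "), call. = FALSE)
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(m) <- names(ss)
  m
}

#' Read a time-stamped alignment set from a sample sheet
#'
#' The sample sheet is a TSV with columns `file`, `time`, `replicate`
#' (paths relative to the sheet's directory unless absolute). All FASTA
#' files at one time are combined; replicate labels are carried per
#' sequence so either pooling strategy remains available downstream.
#'
#' @param sheet_path path to the TSV sample sheet.
#' @return a [timepoint_alignment()].
#' @export
read_alignment_set <- function(sheet_path) {
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("file", "time", "replicate")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$file))
    stop("duplicate file entries in sample sheet", call. = FALSE)
  base <- dirname(normalizePath(sheet_path))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", sheet$file), sheet$file,
                  file.path(base, sheet$file))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("sample sheet references missing file(s): ",
         paste(sheet$file[missing], collapse = ", "), call. = FALSE)

  mats <- lapply(paths, read_alignment_fasta)
  widths <- vapply(mats, ncol, integer(1))
  if (length(unique(widths)) != 1L) {
    bad <- sheet$file[widths != stats::median(widths)]
    stop("alignment width mismatch in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  times <- sort(unique(sheet$time))
  alignments <- vector("list", length(times))
  replicates <- vector("list", length(times))
  for (k in seq_along(times)) {
    idx <- which(sheet$time == times[k])
    alignments[[k]] <- do.call(rbind, mats[idx])
    replicates[[k]] <- rep(sheet$replicate[idx],
                           vapply(mats[idx], nrow, integer(1)))
  }
  timepoint_alignment(alignments, times, replicates)
}

#' Write a tidy table as TSV with a provenance header
#'
#' All package tables are written with a `#`-comment header recording the
#' generating parameters and seed, so any output can be traced to its run.
#' Site coordinates in user-facing tables are 1-based.
#'
#' @param df data.frame.
#' @param path output path.
#' @param header named character/numeric vector recorded as `# key: value`
#'   comment lines.
#' @return the path, invisibly.
#' @export
write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), as.character(header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_with_header()]
#'
#' @param path input path.
#' @return data.frame (header comments are skipped).
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read or write a flat key-value run configuration
#'
#' `key = value` lines, `#` comments; values are parsed as numeric where
#' possible. Round-trips losslessly for numeric and string scalars.
#'
#' @param path file path.
#' @param config named list to write.
#' @return `read_run_config` returns a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  out <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2L], as.is = TRUE)
    v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, character(1), digits = 17)),
             path)
  invisible(path)
}
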