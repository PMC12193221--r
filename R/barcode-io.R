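## Barcode record I/O.  FASTA parsing goes through Biostrings; validation and
## header dialect ("species|gene|accession") live here so errors can name the
## offending record.

.iupac_chars <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

#' Construct a species-labelled barcode record
#'
#' A `BarcodeRecord` holds one (possibly alignment-gapped) DNA barcode
#' sequence together with its species label, gene, and an optional GenBank
#' accession with 1-based inclusive coordinates (the `NC_*:start-end`
#' notation used for mitochondrial barcode regions).
#'
#' @param species_name Species label (free text, non-empty).
#' @param sequence IUPAC DNA string; alignment gaps (`-`) allowed. Stored
#'   upper-case.
#' @param gene One of `"COXI"`, `"COXII"`, `"other"`.
#' @param accession Optional accession string.
#' @param coords Optional length-2 integer vector, 1-based inclusive
#'   `c(start, end)` on the accession, `start <= end`.
#' @return An object of class `BarcodeRecord` (a named list).
#' @examples
#' barcode_record("P. misera", "TGGAACCCCTGGACGACTTA", gene = "COXII")
#' @export
barcode_record <- function(species_name, sequence, gene = "other",
                           accession = NULL, coords = NULL) {
  if (!is.character(species_name) || length(species_name) != 1L ||
      !nzchar(species_name)) {
    stop("species_name must be a non-empty string", call. = FALSE)
  }
  gene <- match.arg(gene, c("COXI", "COXII", "other"))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("sequence must be non-empty (record '", species_name, "')",
         call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1L]]),
                 .iupac_chars)
  if (length(bad)) {
    stop("alphabet error in record '", species_name, "': illegal character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.integer(coords)
    if (length(coords) != 2L || anyNA(coords) || coords[1L] > coords[2L]) {
      stop("coords must be c(start, end) with start <= end (record '",
           species_name, "')", call. = FALSE)
    }
  }
  structure(
    list(species_name = species_name, gene = gene, sequence = sequence,
         accession = accession, coords = coords),
    class = "BarcodeRecord"
  )
}

#' @export
print.BarcodeRecord <- function(x, ...) {
  loc <- if (!is.null(x$accession)) {
    paste0(" [", x$accession,
           if (!is.null(x$coords)) paste0(":", x$coords[1L], "-", x$coords[2L]),
           "]")
  } else ""
  cat(sprintf("<BarcodeRecord> %s (%s)%s, %d nt\n",
              x$species_name, x$gene, loc, nchar(x$sequence)))
  invisible(x)
}

## "NC_036107.1:3018-3708" -> list(accession, coords); plain accession ok
.parse_accession_field <- function(field) {
  if (is.na(field) || !nzchar(field)) return(list(accession = NULL, coords = NULL))
  m <- regmatches(field, regexec("^(.+):([0-9]+)-([0-9]+)$", field))[[1L]]
  if (length(m) == 4L) {
    list(accession = m[2L], coords = c(as.integer(m[3L]), as.integer(m[4L])))
  } else {
    list(accession = field, coords = NULL)
  }
}

#' Read barcode records from a FASTA file
#'
#' Headers of the form `species|gene|accession` are split on `|`; the third
#' field may carry GenBank-style coordinates (`NC_036107.1:3018-3708`,
#' 1-based inclusive).  Headers without the delimiter become the species
#' name verbatim.  Sequences are upper-cased; alignment gaps pass through.
#'
#' @param path Path to a FASTA file (may contain multiple records).
#' @return A list of [barcode_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("format error: no FASTA records in ", path, call. = FALSE)
  }
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    fields <- strsplit(header, "|", fixed = TRUE)[[1L]]
    seqs <- as.character(set[[i]])
    if (length(fields) >= 2L) {
      gene <- toupper(trimws(fields[2L]))
      gene <- if (gene %in% c("COXI", "COX1")) "COXI"
              else if (gene %in% c("COXII", "COX2")) "COXII" else "other"
      acc <- if (length(fields) >= 3L) .parse_accession_field(fields[3L])
             else list(accession = NULL, coords = NULL)
      barcode_record(trimws(fields[1L]), seqs, gene = gene,
                     accession = acc$accession, coords = acc$coords)
    } else {
      barcode_record(trimws(header), seqs)
    }
  })
}

#' Write barcode records to a FASTA file
#'
#' Inverse of [read_fasta()]: headers are rebuilt in the
#' `species|gene|accession` dialect (fields after the species are dropped
#' when absent).
#'
#' @param records List of [barcode_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- vapply(records, function(r) {
    acc <- if (!is.null(r$accession)) {
      paste0(r$accession,
             if (!is.null(r$coords)) paste0(":", r$coords[1L], "-", r$coords[2L]))
    } else NULL
    paste(c(r$species_name, r$gene, acc), collapse = "|")
  }, character(1L))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1L), "sequence"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
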