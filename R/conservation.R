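## Column-wise conservation of an aligned barcode panel, and the
## conserved-flank / variable-core region calls that drive primer placement.
## Primers cannot span indels, so any gapped column is ineligible for a
## conserved call; IUPAC ambiguity codes count as mismatches to the modal
## residue.

#' Column-wise conservation profile of an aligned panel
#'
#' For each alignment column, `identity` is the count of the modal A/C/G/T
#' residue divided by the number of non-gap residues, and `gap_frac` the gap
#' fraction.  All-gap columns get identity 0 and gap fraction 1; ambiguity
#' codes are counted in the denominator but never as the modal residue.
#'
#' @param records List of aligned [barcode_record()]s (equal lengths, >= 2
#'   records).
#' @return An object of class `ConservationProfile`: list with `length`,
#'   `identity` and `gap_frac` (each per column).
#' @export
conservation_profile <- function(records) {
  if (length(records) < 2L) stop("need >= 2 records", call. = FALSE)
  seqs <- vapply(records, `[[`, character(1L), "sequence")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ncols <- ncol(mat)
  identity <- numeric(ncols)
  gap_frac <- numeric(ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    gaps <- col == "-"
    gap_frac[j] <- mean(gaps)
    nongap <- col[!gaps]
    if (length(nongap) == 0L) {
      identity[j] <- 0
      next
    }
    counts <- tabulate(match(nongap, c("A", "C", "G", "T")), nbins = 4L)
    identity[j] <- max(counts) / length(nongap)
  }
  structure(list(length = ncols, identity = identity, gap_frac = gap_frac),
            class = "ConservationProfile")
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat(sprintf("<ConservationProfile> %d columns; mean identity %.3f, %d gapped\n",
              x$length, mean(x$identity), sum(x$gap_frac > 0)))
  invisible(x)
}

#' Call conserved and variable regions from a conservation profile
#'
#' Maximal runs of gap-free columns with identity at least `min_identity`
#' and length at least `min_conserved_len` are called conserved; all
#' remaining columns form variable regions, so the two kinds partition the
#' alignment.  Defaults reflect primer design over full-identity flanks with
#' the minimum primer length of 18 bp (20 +/- 2).
#'
#' @param profile A [conservation_profile()].
#' @param min_conserved_len Minimum conserved run length (columns).
#' @param min_identity Identity threshold in `(0, 1]`.
#' @return A data.frame with columns `kind` (`"conserved"`/`"variable"`),
#'   `start`, `end` (0-based half-open column intervals), sorted by `start`.
#' @export
find_regions <- function(profile, min_conserved_len = 18L, min_identity = 1.0) {
  stopifnot(inherits(profile, "ConservationProfile"))
  if (!(min_identity > 0 && min_identity <= 1)) {
    stop("min_identity must be in (0, 1]", call. = FALSE)
  }
  eligible <- profile$identity >= min_identity - 1e-12 & profile$gap_frac == 0
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  conserved <- r$values & r$lengths >= min_conserved_len
  cons <- data.frame(start = starts[conserved], end = ends[conserved])
  ## variable = complement of the conserved intervals
  vars <- data.frame(start = integer(0), end = integer(0))
  bounds <- c(0L, as.vector(rbind(cons$start, cons$end)), profile$length)
  for (k in seq(1L, length(bounds) - 1L, by = 2L)) {
    if (bounds[k + 1L] > bounds[k]) {
      vars <- rbind(vars, data.frame(start = bounds[k], end = bounds[k + 1L]))
    }
  }
  out <- rbind(
    if (nrow(cons)) data.frame(kind = "conserved", cons) else NULL,
    if (nrow(vars)) data.frame(kind = "variable", vars) else NULL
  )
  if (is.null(out)) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a conservation profile as CSV
#'
#' Columns: `column` (0-based), `identity`, `gap_frac`.
#'
#' @param profile A [conservation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(column = seq_len(profile$length) - 1L,
                   identity = profile$identity,
                   gap_frac = profile$gap_frac)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
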