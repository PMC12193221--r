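## Mismatch-tolerant in-silico PCR.  Primer-site search uses
## Biostrings::matchPattern; the 3'-terminal exactness requirement is
## enforced by a post-filter on each candidate site.

#' Amplicon container
#'
#' @param sequence Product sequence (forward strand, both primer footprints
#'   included).
#' @param source_species Optional label of the template's species.
#' @return Object of class `Amplicon` with fields `sequence`, `length`,
#'   `gc`, `source_species`.
#' @export
amplicon <- function(sequence, source_species = NA_character_) {
  sequence <- toupper(as.character(sequence))
  structure(
    list(sequence = sequence, length = nchar(sequence),
         gc = gc_content(sequence), source_species = source_species),
    class = "Amplicon"
  )
}

#' @export
print.Amplicon <- function(x, ...) {
  cat(sprintf("<Amplicon> %d bp, GC %.2f%s\n", x$length, x$gc,
              if (is.na(x$source_species)) "" else paste0(" (", x$source_species, ")")))
  invisible(x)
}

## sites (0-based starts) where `primer` binds `template` on the + strand
## with <= max_mismatch mismatches and the given 0-based positions exact
.binding_sites <- function(primer, template, max_mismatch, exact_positions) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch)
  starts <- Biostrings::start(hits) - 1L
  if (length(starts) == 0L || length(exact_positions) == 0L) return(starts)
  pch <- strsplit(primer, "", fixed = TRUE)[[1L]]
  tch <- strsplit(template, "", fixed = TRUE)[[1L]]
  keep <- vapply(starts, function(s) {
    all(tch[s + exact_positions + 1L] == pch[exact_positions + 1L])
  }, logical(1L))
  starts[keep]
}

#' Mismatch-tolerant in-silico PCR
#'
#' Finds every placement of the forward primer on the plus strand and of the
#' reverse primer on the minus strand with at most `max_mismatch` mismatches
#' each and an exact match over the 3'-terminal `three_prime_exact` bases
#' (polymerase extension requires a matched 3' end).  Each compatible
#' placement pair with the forward 3' end upstream of the reverse 3' end
#' yields a product spanning the forward 5' end through the reverse 5' end
#' inclusive.  All products are returned; no product gives an empty list.
#'
#' @param fwd Forward primer, 5' to 3'.
#' @param rev Reverse primer, 5' to 3' on the reverse strand.
#' @param template Ungapped template sequence (plus strand).
#' @param max_mismatch Maximum mismatches tolerated per primer.
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly.
#' @param source_species Optional species label carried onto the amplicons.
#' @return List of [amplicon()] objects, each with attributes `fwd_start`
#'   and `rev_end` (0-based half-open template coordinates of the product).
#' @export
in_silico_pcr <- function(fwd, rev, template, max_mismatch = 0L,
                          three_prime_exact = 0L,
                          source_species = NA_character_) {
  fwd <- toupper(fwd); rev <- toupper(rev); template <- toupper(template)
  if (grepl("-", template, fixed = TRUE)) {
    stop("template must be ungapped", call. = FALSE)
  }
  nf <- nchar(fwd); nr <- nchar(rev)
  te <- min(as.integer(three_prime_exact), nf, nr)
  ## forward primer: 3' end is its last base
  f_exact <- if (te > 0L) (nf - te):(nf - 1L) else integer(0)
  f_starts <- .binding_sites(fwd, template, max_mismatch, f_exact)
  ## reverse primer binds as revcomp(rev) on the + strand; its 3' end maps to
  ## the first base of that site
  r_exact <- if (te > 0L) 0:(te - 1L) else integer(0)
  r_starts <- .binding_sites(revcomp(rev), template, max_mismatch, r_exact)
  out <- list()
  for (fs in f_starts) {
    for (rs in r_starts) {
      if (fs + nf - 1L < rs) {  # fwd 3' strictly upstream of rev 3'
        prod <- substr(template, fs + 1L, rs + nr)
        amp <- amplicon(prod, source_species)
        attr(amp, "fwd_start") <- fs
        attr(amp, "rev_end") <- rs + nr
        out[[length(out) + 1L]] <- amp
      }
    }
  }
  out
}
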