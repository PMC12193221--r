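## Primer candidate screening: length and GC windows, hairpin and self-dimer
## exclusion by longest complementary run, and enumeration of primer pairs
## whose product brackets a variable core.  Screening is by run length, not
## full secondary-structure thermodynamics: the exclusions are structural
## (hairpins, self-dimers, 3'-anchored dimers) with conventional cutoffs.

.complement_map <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (IUPAC codes allowed).
#' @return The reverse complement, upper-case.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' GC content of an ungapped DNA sequence
#'
#' Fraction (G + C) / (A + C + G + T); IUPAC ambiguity codes are excluded
#' from both numerator and denominator.
#'
#' @param seq Non-empty, ungapped DNA string (case-insensitive).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("TGGAACCCCTGGACGACTTA")  # 0.55
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("value error: empty sequence", call. = FALSE)
  if (grepl("-", seq, fixed = TRUE)) {
    stop("value error: gapped sequence", call. = FALSE)
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0L) stop("value error: no unambiguous bases", call. = FALSE)
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Primer screening constraints
#'
#' Defaults: primer length 20 +/- 2 bp, GC window 40-60%, product length
#' capped at 300 bp.  Structural screens fail a primer when a
#' self-reverse-complementary stem of length > `hairpin_max_stem` can fold
#' back with a loop of >= 3 nt, when a contiguous self-complementary
#' (antiparallel) run exceeds `dimer_max_run`, or when such a run anchored
#' at the 3' terminus exceeds `dimer3_max_run`.
#'
#' @param len_min,len_max Primer length window (bp).
#' @param gc_min,gc_max GC-content window (fractions).
#' @param product_max Maximum product length (bp); must exceed `2 * len_max`.
#' @param hairpin_max_stem Longest tolerated hairpin stem (bp); a stem of
#'   `hairpin_max_stem + 1` or more fails.
#' @param hairpin_min_loop Minimum loop length for a foldback (nt).
#' @param dimer_max_run Longest tolerated self-dimer complementary run (bp).
#' @param dimer3_max_run Longest tolerated 3'-anchored complementary run (bp).
#' @return An object of class `PrimerConstraints`.
#' @export
primer_constraints <- function(len_min = 18L, len_max = 22L,
                               gc_min = 0.40, gc_max = 0.60,
                               product_max = 300L,
                               hairpin_max_stem = 3L, hairpin_min_loop = 3L,
                               dimer_max_run = 7L, dimer3_max_run = 4L) {
  if (len_min > len_max) stop("len_min must be <= len_max", call. = FALSE)
  if (!(gc_min >= 0 && gc_min <= gc_max && gc_max <= 1)) {
    stop("need 0 <= gc_min <= gc_max <= 1", call. = FALSE)
  }
  if (product_max <= 2L * len_max) {
    stop("product_max must exceed 2 * len_max", call. = FALSE)
  }
  structure(
    list(len_min = as.integer(len_min), len_max = as.integer(len_max),
         gc_min = gc_min, gc_max = gc_max,
         product_max = as.integer(product_max),
         hairpin_max_stem = as.integer(hairpin_max_stem),
         hairpin_min_loop = as.integer(hairpin_min_loop),
         dimer_max_run = as.integer(dimer_max_run),
         dimer3_max_run = as.integer(dimer3_max_run)),
    class = "PrimerConstraints"
  )
}

## longest hairpin stem: seq[i..i+k) revcomp-pairs with seq[j..j+k), loop
## j - (i+k) >= min_loop.  Brute force is fine at primer lengths.
.max_hairpin_stem <- function(ch, min_loop) {
  n <- length(ch)
  comp <- unname(.complement_map[ch])
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ## grow stem pairing (i+k, j-k) inward while the loop stays >= min_loop
      k <- 0L
      while (i + k < j - k &&
             comp[[i + k]] == ch[[j - k]] &&
             (j - k) - (i + k) - 1L >= min_loop) k <- k + 1L
      if (k > best) best <- k
    }
  }
  best
}

## longest contiguous antiparallel self-complementary run = longest common
## substring of seq and its reverse complement
.max_selfdimer_run <- function(ch) {
  rc <- rev(unname(.complement_map[ch]))
  n <- length(ch)
  best <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    cur <- integer(n)
    for (j in seq_len(n)) {
      if (ch[[i]] == rc[[j]]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

## longest 3'-anchored run: longest suffix of seq occurring in revcomp(seq)
.max_selfdimer_run_3p <- function(ch) {
  rc <- paste(rev(unname(.complement_map[ch])), collapse = "")
  n <- length(ch)
  for (k in n:1) {
    suf <- paste(ch[(n - k + 1L):n], collapse = "")
    if (grepl(suf, rc, fixed = TRUE)) return(k)
  }
  0L
}

#' Screen a single primer against design constraints
#'
#' Evaluates the length window, the GC window, hairpin foldback, self-dimer
#' runs and 3'-anchored self-dimer runs (see [primer_constraints()]).  All
#' failed checks are reported, not just the first; degenerate IUPAC bases
#' are rejected (the design pipeline emits only A/C/G/T).  The verdict is
#' invariant under letter case.
#'
#' @param seq Ungapped DNA primer (5' to 3').
#' @param constraints A [primer_constraints()].
#' @return List with `pass` (logical) and `failures` (character vector of
#'   machine-readable reason codes among `"alphabet"`, `"length"`, `"gc"`,
#'   `"hairpin"`, `"self_dimer"`, `"self_dimer_3p"`).
#' @examples
#' check_primer("TGGAACCCCTGGACGACTTA")$pass  # TRUE
#' @export
check_primer <- function(seq, constraints = primer_constraints()) {
  seq <- toupper(as.character(seq))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  failures <- character(0)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    failures <- c(failures, "alphabet")
    return(list(pass = FALSE, failures = failures))
  }
  n <- length(ch)
  if (n < constraints$len_min || n > constraints$len_max) {
    failures <- c(failures, "length")
  }
  gc <- gc_content(seq)
  if (gc < constraints$gc_min - 1e-12 || gc > constraints$gc_max + 1e-12) {
    failures <- c(failures, "gc")
  }
  if (.max_hairpin_stem(ch, constraints$hairpin_min_loop) >
      constraints$hairpin_max_stem) {
    failures <- c(failures, "hairpin")
  }
  if (.max_selfdimer_run(ch) > constraints$dimer_max_run) {
    failures <- c(failures, "self_dimer")
  }
  if (.max_selfdimer_run_3p(ch) > constraints$dimer3_max_run) {
    failures <- c(failures, "self_dimer_3p")
  }
  list(pass = length(failures) == 0L, failures = failures)
}

## consensus of an aligned panel: per-column modal A/C/G/T (ties broken
## alphabetically), "-" for all-gap columns
.consensus <- function(records) {
  seqs <- vapply(records, `[[`, character(1L), "sequence")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  apply(mat, 2L, function(col) {
    counts <- tabulate(match(col, c("A", "C", "G", "T")), nbins = 4L)
    if (max(counts) == 0L) "-" else c("A", "C", "G", "T")[which.max(counts)]
  })
}

#' Enumerate and screen primer pairs over conserved flanks
#'
#' Builds the panel consensus, slides forward-primer windows over each
#' conserved region and reverse-primer windows over every downstream
#' conserved region, and keeps pairs whose product (forward 5' through
#' reverse 5', both footprints included) spans at least one variable region,
#' passes [check_primer()] on both oligos, and respects `product_max`.
#' Pairs are sorted by ascending product length, ties broken by summed
#' distance of the two oligo GC fractions from 0.5 (closest first).
#'
#' @param records Aligned [barcode_record()]s.
#' @param regions Region calls from [find_regions()].
#' @param constraints A [primer_constraints()].
#' @return data.frame with columns `fwd`, `rev` (both 5' to 3', `rev` on the
#'   reverse strand), `fwd_start`, `rev_end` (0-based template coordinates),
#'   `product_len`, `fwd_gc`, `rev_gc`.  Empty when no conserved regions
#'   exist.
#' @export
enumerate_pairs <- function(records, regions,
                            constraints = primer_constraints()) {
  empty <- data.frame(fwd = character(0), rev = character(0),
                      fwd_start = integer(0), rev_end = integer(0),
                      product_len = integer(0), fwd_gc = numeric(0),
                      rev_gc = numeric(0))
  cons_regions <- regions[regions$kind == "conserved", , drop = FALSE]
  var_regions <- regions[regions$kind == "variable", , drop = FALSE]
  if (nrow(cons_regions) < 2L) return(empty)
  consensus <- .consensus(records)
  windows_in <- function(region) {
    out <- list()
    for (len in constraints$len_min:constraints$len_max) {
      if (region$end - region$start < len) next
      for (s in region$start:(region$end - len)) {
        out[[length(out) + 1L]] <- list(start = s, end = s + len)
      }
    }
    out
  }
  rows <- list()
  for (a in seq_len(nrow(cons_regions) - 1L)) {
    for (b in (a + 1L):nrow(cons_regions)) {
      r1 <- cons_regions[a, ]
      r2 <- cons_regions[b, ]
      for (wf in windows_in(r1)) {
        fwd_seq <- paste(consensus[(wf$start + 1L):wf$end], collapse = "")
        if (!check_primer(fwd_seq, constraints)$pass) next
        for (wr in windows_in(r2)) {
          product_len <- wr$end - wf$start
          if (product_len > constraints$product_max) next
          ## product must bracket a variable core between the footprints
          spans <- any(var_regions$start >= wf$end & var_regions$end <= wr$start)
          if (!spans) next
          rev_seq <- revcomp(paste(consensus[(wr$start + 1L):wr$end],
                                   collapse = ""))
          if (!check_primer(rev_seq, constraints)$pass) next
          rows[[length(rows) + 1L]] <- data.frame(
            fwd = fwd_seq, rev = rev_seq,
            fwd_start = wf$start, rev_end = wr$end,
            product_len = product_len,
            fwd_gc = gc_content(fwd_seq), rev_gc = gc_content(rev_seq)
          )
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  gc_dist <- abs(out$fwd_gc - 0.5) + abs(out$rev_gc - 0.5)
  out <- out[order(out$product_len, gc_dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}
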