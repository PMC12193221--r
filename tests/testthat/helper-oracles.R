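# Independent brute-force oracles, written before (and kept independent of)
# the implementations they check.

# --- nearest-neighbor dinucleotide-sum oracle -------------------------------
# Hand-coded stack table for the ten unique duplex stacks (1 M NaCl); the
# oracle walks the sequence dinucleotide-by-dinucleotide and looks each stack
# up either directly or via its reverse complement.
oracle_nn_stacks <- data.frame(
  stack = c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG"),
  dh = c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0),
  ds = c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4, -19.9),
  stringsAsFactors = FALSE
)

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_nn_thermo <- function(seq, strand_conc = 2.5e-7,
                             monovalent_salt = 0.05) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1)) {
    di <- paste0(ch[i], ch[i + 1])
    row <- match(di, oracle_nn_stacks$stack)
    if (is.na(row)) row <- match(oracle_revcomp(di), oracle_nn_stacks$stack)
    dh <- dh + oracle_nn_stacks$dh[row]
    ds <- ds + oracle_nn_stacks$ds[row]
  }
  for (end in c(ch[1], ch[n])) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else                      { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  x <- 4
  if (seq == oracle_revcomp(seq)) { ds <- ds - 1.4; x <- 1 }
  ds_salt <- ds + 0.368 * (n - 1) * log(monovalent_salt)
  tm_k <- dh * 1000 / (ds_salt + 1.987 * log(strand_conc / x))
  list(dh = dh, ds = ds, tm_celsius = tm_k - 273.15)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

# --- naive exact-match PCR oracle -------------------------------------------
# Plain string search for exact forward and reverse sites; returns product
# lengths of all placements with the fwd 3' end strictly upstream of the
# rev 3' end.
oracle_pcr_products <- function(fwd, rev, template) {
  all_starts <- function(pat, s) {
    out <- integer(0); from <- 1
    repeat {
      i <- regexpr(pat, substring(s, from), fixed = TRUE)
      if (i < 0) break
      out <- c(out, from + i - 1)
      from <- from + i
    }
    out
  }
  nf <- nchar(fwd); nr <- nchar(rev)
  fs <- all_starts(fwd, template)                 # 1-based
  rs <- all_starts(oracle_revcomp(rev), template) # 1-based
  lens <- integer(0)
  for (f in fs) for (r in rs) {
    if (f + nf - 1 < r) lens <- c(lens, (r + nr - 1) - f + 1)
  }
  sort(lens)
}

# --- analytic logistic derivative oracle ------------------------------------
# -dF/dT of a logistic mixture, evaluated exactly on a temperature grid.
oracle_logistic_deriv <- function(temps, tms, weights, width) {
  out <- numeric(length(temps))
  for (i in seq_along(tms)) {
    z <- exp((temps - tms[i]) / width)
    out <- out + weights[i] * z / (width * (1 + z)^2)
  }
  out
}

# --- max-count expectation for multinomial columns --------------------------
# E[max category count / n] for one alignment column of n species where each
# species keeps the ancestor base w.p. (1-d) and otherwise is uniform over
# the three other bases: enumerate all compositions of n into 4 categories.
oracle_expected_identity <- function(n, d) {
  p <- c(1 - d, d / 3, d / 3, d / 3)
  total <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    dd <- n - a - b - cc
    k <- c(a, b, cc, dd)
    prob <- exp(lgamma(n + 1) - sum(lgamma(k + 1)) +
                  sum(k * log(ifelse(p > 0, p, 1))))
    total <- total + prob * max(k) / n
  }
  total
}
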