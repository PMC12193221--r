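## Nearest-neighbor duplex thermodynamics: hybridization enthalpy and entropy
## summed over adjacent base-pair stacks (unified oligonucleotide parameter
## set) with initiation terms, an entropic monovalent-salt correction, and a
## two-state melting temperature.  Absolute agreement with instrument Tm
## values is not promised; the contract is rank/delta-Tm behaviour of
## amplicon variants.

## unified NN stack parameters, 1 M NaCl: dH kcal/mol, dS cal/(mol K)
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
## duplex initiation with a terminal G.C or A.T pair
.nn_init_dh <- c(GC = 0.1, AT = 2.3)
.nn_init_ds <- c(GC = -2.8, AT = 4.1)
.gas_constant <- 1.987  # cal/(mol K)

#' Heuristic delta-Tm magnitudes and instrument resolution
#'
#' Order-of-magnitude constants for how single-base changes shift a PCR
#' product's melting temperature, and the melting instrument's temperature
#' resolution: losing a whole G-C pair shifts Tm by roughly 6 degrees
#' Celsius, a G-C to A-T substitution by roughly 0.6, a hydrogen-bond
#' preserving swap (A-T to T-A, G-C to C-G) by roughly 0.15, and the
#' instrument resolves +/- 0.02 degrees Celsius.  These are documentation
#' values describing instrument-scale behaviour, not exact predictions.
#'
#' @format Named list with `gc_pair_loss`, `gc_to_at`, `isobond_swap`,
#'   `instrument_resolution` (all degrees Celsius).
#' @export
hrm_delta_tm_heuristics <- list(
  gc_pair_loss = 6.0,
  gc_to_at = 0.6,
  isobond_swap = 0.15,
  instrument_resolution = 0.02
)

#' Nearest-neighbor duplex thermodynamics and melting temperature
#'
#' Sums stack enthalpies/entropies over all adjacent dinucleotides of the
#' duplex plus the two terminal initiation contributions; applies the
#' entropic salt correction `dS + 0.368 (L - 1) ln[Na+]` and the two-state
#' melting temperature `Tm = 1000 dH / (dS_salt + R ln(Ct / x)) - 273.15`
#' with `R = 1.987 cal/(mol K)`, `x = 4` for non-self-complementary duplexes
#' and `x = 1` (plus the symmetry entropy of -1.4 cal/(mol K)) when the
#' sequence equals its own reverse complement.  A sequence and its reverse
#' complement describe the same duplex and get identical results.
#'
#' @param seq Ungapped A/C/G/T sequence, length >= 8.
#' @param strand_conc Total strand concentration Ct in mol/L.
#' @param monovalent_salt Monovalent cation concentration in mol/L.
#' @return Object of class `ThermoResult`: `dH` (kcal/mol), `dS` and
#'   `dS_salt` (cal/(mol K)), `tm_celsius`, `strand_conc`,
#'   `monovalent_salt`, `nn_table_id`.
#' @examples
#' nn_thermo("TGGAACCCCTGGACGACTTA")$tm_celsius
#' @export
nn_thermo <- function(seq, strand_conc = 2.5e-7, monovalent_salt = 0.05) {
  seq <- toupper(as.character(seq))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("alphabet error: sequence must be A/C/G/T only", call. = FALSE)
  }
  n <- length(ch)
  if (n < 8L) stop("length error: need >= 8 bases", call. = FALSE)
  if (strand_conc <= 0 || monovalent_salt <= 0) {
    stop("strand_conc and monovalent_salt must be positive", call. = FALSE)
  }
  stacks <- paste0(ch[-n], ch[-1L])
  dH <- sum(.nn_dh[stacks])
  dS <- sum(.nn_ds[stacks])
  ends <- ifelse(ch[c(1L, n)] %in% c("G", "C"), "GC", "AT")
  dH <- dH + sum(.nn_init_dh[ends])
  dS <- dS + sum(.nn_init_ds[ends])
  self_comp <- identical(seq, revcomp(seq))
  x <- 4
  if (self_comp) {
    dS <- dS - 1.4
    x <- 1
  }
  dS_salt <- dS + 0.368 * (n - 1L) * log(monovalent_salt)
  tm_k <- dH * 1000 / (dS_salt + .gas_constant * log(strand_conc / x))
  structure(
    list(dH = dH, dS = dS, dS_salt = dS_salt,
         tm_celsius = tm_k - 273.15,
         strand_conc = strand_conc, monovalent_salt = monovalent_salt,
         nn_table_id = "unified-oligo-1998"),
    class = "ThermoResult"
  )
}

#' @export
print.ThermoResult <- function(x, ...) {
  cat(sprintf(
    "<ThermoResult> dH %.1f kcal/mol, dS %.1f cal/(mol K), Tm %.2f degC\n",
    x$dH, x$dS, x$tm_celsius))
  cat(sprintf("  [%s; Ct %.3g M, Na+ %.3g M]\n",
              x$nn_table_id, x$strand_conc, x$monovalent_salt))
  invisible(x)
}

#' Predicted melting temperature of an amplicon
#'
#' Applies [nn_thermo()] to the full product sequence.  Only the relative
#' ordering and differences of predicted Tm across sequence variants are
#' meaningful; absolute instrument Tm values are not reproduced by
#' two-state nearest-neighbor prediction.
#'
#' @param amp An [amplicon()] or a plain sequence string.
#' @param strand_conc,monovalent_salt Passed to [nn_thermo()].
#' @return Predicted Tm in degrees Celsius.
#' @export
amplicon_tm <- function(amp, strand_conc = 2.5e-7, monovalent_salt = 0.05) {
  seq <- if (inherits(amp, "Amplicon")) amp$sequence else as.character(amp)
  nn_thermo(seq, strand_conc = strand_conc,
            monovalent_salt = monovalent_salt)$tm_celsius
}
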