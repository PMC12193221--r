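## Synthetic barcode panels: conserved primer flanks around a variable core,
## mimicking the structure of a short mitochondrial barcode amplicon
## (~97 bp COXII-like products: two 20 bp flanks, 57 bp core).

#' Specification for a synthetic barcode panel
#'
#' Describes a panel of aligned same-length barcodes sharing identical 5' and
#' 3' flanks (conserved primer landing sites) around a species-variable core.
#' Each species' core is derived from a common ancestor core by mutating each
#' site independently with probability `core_divergence` to a uniformly
#' chosen different base (a single-step Jukes-Cantor-like scheme, chosen for
#' its closed-form pairwise difference probability:
#' `2 d (1 - d) + (2/3) d^2` for divergence `d`).
#'
#' @param n_species Number of species (>= 1).
#' @param flank_len Flank length in bp; >= 18 so flanks can host 20 +/- 2 bp
#'   primers.
#' @param core_len Core length in bp (>= 1).
#' @param core_divergence Per-site mutation probability in `[0, 1]`.
#' @param seed Integer seed; the same spec always generates identical panels.
#' @return An object of class `SynthPanelSpec`.
#' @export
synth_panel_spec <- function(n_species, flank_len = 20L, core_len = 57L,
                             core_divergence = 0.1, seed = 1L) {
  n_species <- as.integer(n_species)
  flank_len <- as.integer(flank_len)
  core_len <- as.integer(core_len)
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (flank_len < 18L) {
    stop("flank_len must be >= 18 to host 20 +/- 2 bp primers", call. = FALSE)
  }
  if (core_len < 1L) stop("core_len must be >= 1", call. = FALSE)
  if (!is.numeric(core_divergence) || core_divergence < 0 ||
      core_divergence > 1) {
    stop("parameter error: core_divergence must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_species = n_species, flank_len = flank_len, core_len = core_len,
         core_divergence = core_divergence, seed = as.integer(seed)),
    class = "SynthPanelSpec"
  )
}

## run expr with a local RNG stream; leaves the caller's .Random.seed intact
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

.random_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## draw a flank until it could serve as a primer (GC window and structural
## screens; the length window is bypassed since flanks may exceed 22 bp) --
## conserved flanks emulate real primer landing sites
.random_flank <- function(n, as_reverse = FALSE) {
  screens <- primer_constraints(len_min = n, len_max = n,
                                product_max = 2L * n + 1L)
  repeat {
    flank <- .random_dna(n)
    oligo <- paste(flank, collapse = "")
    if (as_reverse) oligo <- revcomp(oligo)
    if (check_primer(oligo, screens)$pass) return(flank)
  }
}

#' Generate a synthetic aligned barcode panel
#'
#' All records share the same gap-free 5' and 3' flanks; core sites mutate
#' independently per species at rate `core_divergence` from a common ancestor
#' core (see [synth_panel_spec()] for the mutation scheme).  Flanks emulate
#' functional primer landing sites: they are redrawn until the full 5' flank
#' (and the reverse complement of the 3' flank) passes the GC and structural
#' screens of [check_primer()].  Output is deterministic in `spec$seed`.
#'
#' @param spec A [synth_panel_spec()].
#' @return List of [barcode_record()]s, aligned (equal length
#'   `2 * flank_len + core_len`), species named `species_01`, `species_02`,
#'   ...
#' @examples
#' recs <- synth_barcodes(synth_panel_spec(3, 20, 57, 0.1, seed = 7))
#' nchar(recs[[1]]$sequence)  # 97
#' @export
synth_barcodes <- function(spec) {
  stopifnot(inherits(spec, "SynthPanelSpec"))
  bases <- c("A", "C", "G", "T")
  .with_seed(spec$seed, {
    flank5 <- .random_flank(spec$flank_len)
    flank3 <- .random_flank(spec$flank_len, as_reverse = TRUE)
    ancestor <- .random_dna(spec$core_len)
    lapply(seq_len(spec$n_species), function(i) {
      core <- ancestor
      hit <- runif(spec$core_len) < spec$core_divergence
      if (any(hit)) {
        core[hit] <- vapply(core[hit], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1L))
      }
      barcode_record(sprintf("species_%02d", i),
                     paste(c(flank5, core, flank3), collapse = ""),
                     gene = "other")
    })
  })
}

#' Expected pairwise core difference under the synthetic mutation scheme
#'
#' Closed-form probability that two independently mutated descendants differ
#' at a core site: both copies keep the ancestor base with probability
#' `(1-d)^2`; exactly one mutates with probability `2 d (1-d)` (always a
#' difference); both mutate with probability `d^2` and then agree with
#' probability 1/3.
#'
#' @param core_divergence Per-site mutation probability `d`.
#' @return Probability that a core site differs between two species.
#' @export
expected_pairwise_diff <- function(core_divergence) {
  d <- core_divergence
  2 * d * (1 - d) + (2 / 3) * d^2
}
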