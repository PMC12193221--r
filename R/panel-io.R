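## Reference Tm panels: species -> list of melt-peak temperatures acquired in
## one run ("batch").  Serialized as TSV (species <TAB> peaks <TAB> batch) with
## semicolon-joined peak lists so a species' multi-peak signature stays atomic,
## plus a JSON mirror.  Tm storage precision is 0.01 degC, half the +/-0.02
## degC instrument resolution.

.hrm_ramp_window <- c(65, 90)

#' Construct a reference Tm panel
#'
#' A `ReferencePanel` maps species to the melt-peak temperatures (degrees
#' Celsius) observed for their barcode amplicon in one acquisition batch.
#' Peaks must lie inside the HRM ramp window (65-90 degrees Celsius); each
#' species needs at least one peak and may carry several (multi-peak melt
#' signatures occur for some species); species names are unique within a
#' panel.  Peak values are stored rounded to 0.01 degrees Celsius.
#'
#' @param panel_id Panel identifier.
#' @param primer_set Name of the primer pair the panel was acquired with.
#' @param species Character vector of species names.
#' @param peaks List of numeric vectors (one per species), peak Tm in
#'   degrees Celsius.
#' @param batch Character vector of batch identifiers (recycled).
#' @return An object of class `ReferencePanel`.
#' @examples
#' reference_panel("toy", "COX2-519/COX2-615",
#'                 species = c("A. one", "B. two"),
#'                 peaks = list(76.22, c(74.75, 77.65)))
#' @export
reference_panel <- function(panel_id, primer_set, species, peaks,
                            batch = "batch1") {
  species <- as.character(species)
  if (length(species) != length(peaks)) {
    stop("species and peaks must have the same length", call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("validation error: duplicate species in panel: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  batch <- rep_len(as.character(batch), length(species))
  peaks <- lapply(seq_along(peaks), function(i) {
    p <- round(as.numeric(peaks[[i]]), 2L)
    if (length(p) == 0L || any(!is.finite(p))) {
      stop("validation error: species '", species[i],
           "' needs >= 1 finite peak", call. = FALSE)
    }
    if (any(p < .hrm_ramp_window[1L] | p > .hrm_ramp_window[2L])) {
      stop("validation error: peak outside the 65-90 degC ramp window for '",
           species[i], "'", call. = FALSE)
    }
    p
  })
  structure(
    list(panel_id = as.character(panel_id),
         primer_set = as.character(primer_set),
         species = species, peaks = peaks, batch = batch),
    class = "ReferencePanel"
  )
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("<ReferencePanel> %s (primers %s): %d species\n",
              x$panel_id, x$primer_set, length(x$species)))
  for (i in seq_along(x$species)) {
    cat(sprintf("  %-22s %s  [%s]\n", x$species[i],
                paste(sprintf("%.2f", x$peaks[[i]]), collapse = "; "),
                x$batch[i]))
  }
  invisible(x)
}

#' @rdname reference_panel
#' @param panel A `ReferencePanel`.
#' @export
n_species <- function(panel) length(panel$species)

#' Principal peak per species
#'
#' The principal peak of a panel entry is its first listed peak (panels carry
#' no peak heights; instrument reports list the dominant transition first).
#'
#' @param panel A [reference_panel()].
#' @return Named numeric vector of principal peak Tm, one per species.
#' @export
principal_peaks <- function(panel) {
  stats::setNames(vapply(panel$peaks, `[[`, numeric(1L), 1L), panel$species)
}

#' Read / write a reference panel as TSV
#'
#' The TSV has columns `species`, `peaks` (semicolon-separated degrees
#' Celsius) and `batch`.  Round trips are lossless at 0.01 degrees Celsius.
#'
#' @param path File path.
#' @param panel_id,primer_set Metadata attached on read (default: file name,
#'   unknown).
#' @return [read_panel()] returns a `ReferencePanel`; [write_panel()] returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, panel_id = sub("\\.tsv$", "", basename(path)),
                       primer_set = "unknown") {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("species", "peaks", "batch")
  if (!all(need %in% names(df))) {
    stop("panel TSV must have columns species, peaks, batch", call. = FALSE)
  }
  peaks <- lapply(strsplit(df$peaks, ";", fixed = TRUE),
                  function(p) as.numeric(trimws(p)))
  reference_panel(panel_id, primer_set, df$species, peaks, df$batch)
}

#' @rdname read_panel
#' @param panel A [reference_panel()].
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(
    species = panel$species,
    peaks = vapply(panel$peaks,
                   function(p) paste(sprintf("%.2f", p), collapse = ";"),
                   character(1L)),
    batch = panel$batch,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_panel
#' @export
write_panel_json <- function(panel, path) {
  obj <- list(
    panel_id = panel$panel_id,
    primer_set = panel$primer_set,
    entries = lapply(seq_along(panel$species), function(i) {
      list(species = panel$species[i], peaks = panel$peaks[[i]],
           batch = panel$batch[i])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_panel
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  reference_panel(
    obj$panel_id, obj$primer_set,
    species = vapply(obj$entries, `[[`, character(1L), "species"),
    peaks = lapply(obj$entries, function(e) unlist(e$peaks)),
    batch = vapply(obj$entries, `[[`, character(1L), "batch")
  )
}

#' Bundled reference panels
#'
#' Loads one of the reference Tm panels shipped with the package: the
#' ten-species COXII panel (`"cox2"`), its five-species Sarcophagidae
#' re-extraction replicate (`"cox2_repeat"`), the co-amplified larval-run
#' panel (`"cox2_larva"`), and the six-species COXI panel (`"c1"`) in which
#' one species shows a three-peak melt signature.
#'
#' @param name Panel name.
#' @return A [reference_panel()].
#' @examples
#' hrm_panel("cox2")
#' @export
hrm_panel <- function(name = c("cox2", "c1", "cox2_repeat", "cox2_larva")) {
  name <- match.arg(name)
  meta <- switch(name,
    cox2        = list(file = "cox2_tm_panel.tsv",    primers = "COX2-519/COX2-615"),
    c1          = list(file = "c1_tm_panel.tsv",      primers = "C1-J-2495/C1-N-2800"),
    cox2_repeat = list(file = "cox2_repeat_panel.tsv", primers = "COX2-519/COX2-615"),
    cox2_larva  = list(file = "cox2_larva_panel.tsv", primers = "COX2-519/COX2-615")
  )
  path <- system.file("extdata", meta$file, package = "hrmid", mustWork = TRUE)
  read_panel(path, panel_id = name, primer_set = meta$primers)
}
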