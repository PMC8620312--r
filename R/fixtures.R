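# md5 checksums of the packaged catalog files; load_table_fixture()
# refuses to return silently corrupted tables.
.fixture_md5 <- c(
  lacticaseibacillus_genus_barcode_sizes.tsv =
    "f63b5ab90387a2a6f4c634428013cca4",
  paracasei_species_strain_barcode_sizes.tsv =
    "5362a50b099e894559d53bf268054d01")

#' Bundled catalog of published Lacticaseibacillus marker-set sizes
#'
#' Loads the packaged transcription of the published barcode-size
#' catalog for the genus \emph{Lacticaseibacillus}: 75 genomes with
#' their genus-specific marker 18-mer counts, and 47 \emph{L.
#' paracasei} genomes with phylogroup labels (I-IV, or "-" for
#' singleton lineages), species-specific and strain-specific marker
#' counts, and a \code{retained} flag marking the 31 genomes whose
#' strain-specific sets were large enough to keep for metagenome
#' profiling (the 16 smallest sets, including two empty ones, were
#' dropped). File integrity is verified by checksum.
#'
#' @return A list of two data frames: \code{genus} (75 rows: idx,
#'   strain, species, phylogroup, genus_specific_kmers) and
#'   \code{species} (47 rows: idx, strain, phylogroup,
#'   species_specific_kmers, strain_specific_kmers, retained).
#' @examples
#' fx <- load_table_fixture()
#' sum(fx$species$retained)  # 31
#' @export
load_table_fixture <- function() {
  dir <- system.file("extdata", package = "kbarcode")
  out <- list()
  for (nm in names(.fixture_md5)) {
    path <- file.path(dir, nm)
    if (!file.exists(path))
      stop("packaged fixture missing: ", nm, call. = FALSE)
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.fixture_md5[nm])))
      stop(sprintf("fixture integrity error: %s has md5 %s, expected %s",
                   nm, got, .fixture_md5[nm]), call. = FALSE)
    out[[nm]] <- utils::read.delim(path, stringsAsFactors = FALSE,
                                   check.names = TRUE)
  }
  list(genus = out[[1]], species = out[[2]])
}

#' Summary statistics of a barcode-size column
#'
#' Minimum, maximum and mean of one size column over a subset of
#' catalog rows; the mean is additionally reported rounded half-up to
#' an integer, the convention used when quoting average marker-set
#' sizes.
#'
#' @param rows Data frame of catalog rows (already subset as desired).
#' @param column Name of the numeric size column.
#' @return A list: \code{min}, \code{max}, \code{mean},
#'   \code{mean_rounded}, \code{n}.
#' @examples
#' fx <- load_table_fixture()
#' summarize_barcode_sizes(fx$species[fx$species$retained, ],
#'                         "strain_specific_kmers")
#' @export
summarize_barcode_sizes <- function(rows, column) {
  stopifnot(is.data.frame(rows))
  if (!column %in% names(rows))
    stop("no column '", column, "' in the supplied rows", call. = FALSE)
  v <- rows[[column]]
  if (length(v) == 0L) stop("empty subset", call. = FALSE)
  m <- mean(v)
  list(min = min(v), max = max(v), mean = m,
       mean_rounded = floor(m + 0.5), n = length(v))
}
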