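#' Read genome FASTA files via a taxonomy manifest
#'
#' The manifest is a TSV with columns \code{genome_id}, \code{genus},
#' \code{species}, \code{strain}, \code{role} (one of
#' \code{chromosome}, \code{plasmid}, \code{host}), \code{path} (FASTA,
#' plain or gzip, relative paths resolved against the manifest
#' location) and optional \code{record_ids} (comma-separated subset of
#' record names within the FASTA). Several rows may share one
#' \code{genome_id} (e.g. a chromosome row plus a plasmid row); all
#' records of a multi-record FASTA are treated as contigs of that
#' genome.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param params A [kmer_params] for the resulting collection.
#' @return A [reference_collection].
#' @export
read_collection <- function(manifest_path, params = kmer_params()) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  required <- c("genome_id", "genus", "species", "strain", "role", "path")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(man$role), c("chromosome", "plasmid", "host"))
  if (length(bad))
    stop("unknown role(s) in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  genomes <- lapply(split(man, man$genome_id)[unique(man$genome_id)],
                    function(rows) {
    seqs <- character(0); plasmid <- logical(0)
    for (r in seq_len(nrow(rows))) {
      p <- rows$path[r]
      if (!file.exists(p)) p <- file.path(base, rows$path[r])
      recs <- read_fasta(p)
      if (!is.null(rows$record_ids) && !is.na(rows$record_ids[r]) &&
          nzchar(rows$record_ids[r])) {
        want <- trimws(strsplit(rows$record_ids[r], ",")[[1]])
        recs <- recs[want]
      }
      seqs <- c(seqs, unname(recs))
      plasmid <- c(plasmid, rep(rows$role[r] == "plasmid", length(recs)))
    }
    genome_record(rows$genome_id[1], seqs,
                  genus = rows$genus[1], species = rows$species[1],
                  strain = rows$strain[1], is_plasmid = plasmid,
                  is_host = rows$role[1] == "host")
  })
  reference_collection(unname(genomes), params)
}

#' Read / write FASTA as a named character vector
#'
#' Thin wrappers over \pkg{Biostrings}; gzip input is handled
#' transparently.
#'
#' @param path FASTA file.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ reads
#'
#' \code{read_fastq} returns the reads of a FASTQ file (plain or gzip)
#' as a named character vector; qualities are retained as an attribute
#' \code{"quality"} so a read/write cycle is lossless.
#'
#' @param path FASTQ file (may be \code{.gz}).
#' @return Named character vector of read sequences with attribute
#'   \code{"quality"}.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- stats::setNames(as.character(x), names(x))
  attr(out, "quality") <- as.character(Biostrings::quality(x))
  out
}

#' @rdname read_fastq
#' @param reads Named character vector of read sequences; per-read
#'   quality strings may be supplied via \code{attr(reads, "quality")}
#'   (defaults to constant "I").
#' @export
write_fastq <- function(reads, path) {
  qual <- attr(reads, "quality")
  if (is.null(qual))
    qual <- vapply(nchar(reads), function(n)
      paste(rep("I", n), collapse = ""), character(1))
  # Biostrings warns about dropping its own internal metadata columns
  withCallingHandlers({
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(unname(reads)),
      Biostrings::PhredQuality(unname(qual)))
    names(x) <- names(reads)
    Biostrings::writeQualityScaledXStringSet(x, filepath = path,
                                             compress = grepl("\\.gz$", path))
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  invisible(path)
}

#' Read / write plain TSV tables
#'
#' Standard tab-separated IO used for abundance tables, design tables
#' and phylogroup maps; no quoting, no row names.
#'
#' @param path File path.
#' @return \code{read_tsv}: a \code{data.frame}.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x A data frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
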