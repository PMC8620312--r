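#' A genome with taxonomy labels
#'
#' Container for one genome of a reference collection: its contig
#' sequences, taxonomy labels at the three ranks used for barcoding, and
#' flags marking plasmid sequences and host (e.g. human) entries.
#' Plasmid and host sequences never contribute marker k-mers; they only
#' enlarge the exclusion set.
#'
#' @param genome_id Stable identifier, unique within a collection.
#' @param sequences Character vector of contig/chromosome sequences.
#' @param genus,species,strain Taxonomy labels (strain defaults to
#'   \code{genome_id}).
#' @param is_plasmid Logical vector, one flag per sequence (recycled).
#' @param is_host Logical; \code{TRUE} marks a host-genome entry whose
#'   k-mers must be excluded from every barcode.
#' @return An object of class \code{genome_record}.
#' @export
genome_record <- function(genome_id, sequences, genus = NA_character_,
                          species = NA_character_, strain = genome_id,
                          is_plasmid = FALSE, is_host = FALSE) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("'genome_id' must be a non-empty string", call. = FALSE)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L)
    stop("'sequences' must contain at least one sequence", call. = FALSE)
  is_plasmid <- rep_len(as.logical(is_plasmid), length(sequences))
  structure(list(genome_id = genome_id, sequences = sequences,
                 genus = genus, species = species, strain = strain,
                 is_plasmid = is_plasmid, is_host = isTRUE(is_host)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d sequence(s), %s bp%s%s\n", x$genome_id,
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","),
              if (any(x$is_plasmid)) sprintf(" (%d plasmid)",
                                             sum(x$is_plasmid)) else "",
              if (x$is_host) " [host]" else ""))
  invisible(x)
}

#' A reference collection of genomes
#'
#' The set of genomes a barcode is built against, together with the
#' k-mer parameters shared by every operation on the collection.
#'
#' @param genomes List of [genome_record] objects.
#' @param params A [kmer_params] object.
#' @return An object of class \code{reference_collection}.
#' @export
reference_collection <- function(genomes, params = kmer_params()) {
  stopifnot(inherits(params, "kmer_params"))
  if (length(genomes) == 0L)
    stop("collection needs at least one genome", call. = FALSE)
  if (!all(vapply(genomes, inherits, logical(1), "genome_record")))
    stop("'genomes' must be a list of genome_record objects", call. = FALSE)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids))
    stop("duplicate genome_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(genomes) <- ids
  structure(list(genomes = genomes, params = params),
            class = "reference_collection")
}

#' @export
print.reference_collection <- function(x, ...) {
  cat(sprintf("<reference_collection> %d genome(s), k = %d (%s)\n",
              length(x$genomes), x$params$k,
              if (x$params$canonical) "canonical" else "literal"))
  invisible(x)
}

#' Fingerprint of a collection + parameters
#'
#' Order-independent digest over genome ids, sequences, flags and k-mer
#' parameters; stored inside every barcode so that barcodes built
#' against different collections are never silently mixed.
#'
#' @param collection A [reference_collection].
#' @return A hex digest string.
#' @export
collection_digest <- function(collection) {
  stopifnot(inherits(collection, "reference_collection"))
  per_genome <- vapply(collection$genomes, function(g)
    digest::digest(list(g$genome_id, g$sequences, g$genus, g$species,
                        g$strain, g$is_plasmid, g$is_host)), character(1))
  digest::digest(list(sort(unname(per_genome)),
                      collection$params$k, collection$params$canonical))
}

specificity_levels <- c("genus", "species", "strain")

# Chromosomal (non-plasmid) sequences of a genome record.
chromosome_sequences <- function(g) g$sequences[!g$is_plasmid]

taxon_label <- function(g, level) {
  switch(level, genus = g$genus, species = g$species, strain = g$strain)
}

#' Build a specificity-filtered k-mer barcode
#'
#' Computes the marker k-mer set of one target genome: all k-mers of its
#' chromosomal sequences that are absent from every sequence of the
#' exclusion set. The exclusion set always contains all plasmid
#' sequences and all host-genome sequences in the collection; on top of
#' that it contains the chromosomes of every genome whose taxonomy
#' label at the requested rank differs from the target's. At
#' \code{"strain"} level the exclusion set is every genome in the
#' collection except the target itself, so a marker occurs in exactly
#' one genome. Exclusion sets are therefore nested genus < species <
#' strain, and barcodes shrink as specificity grows.
#'
#' Exclusion genomes are processed one at a time (incremental
#' subtraction), so the peak working set is one genome's k-mers, and the
#' result is independent of processing order. An empty result is legal
#' (two identical genomes leave each other no strain-specific markers)
#' and is reported with a warning, not an error.
#'
#' @param target A [genome_record]; matched against the collection by
#'   \code{genome_id} if present there, otherwise used as supplied.
#' @param collection A [reference_collection].
#' @param level One of \code{"genus"}, \code{"species"}, \code{"strain"}.
#' @return An object of class \code{barcode}: \code{genome_id},
#'   \code{level}, \code{kmers} (a \code{kmer_set}), \code{size},
#'   \code{collection_digest}.
#' @examples
#' p <- kmer_params(k = 3, canonical = FALSE)
#' tg <- genome_record("t", "ACGTAACC", genus = "G", species = "s")
#' ex <- genome_record("e", "TTACGTT", genus = "H", species = "h")
#' col <- reference_collection(list(tg, ex), p)
#' build_barcode(tg, col, "genus")$size  # 4
#' @export
build_barcode <- function(target, collection,
                          level = c("genus", "species", "strain")) {
  level <- match.arg(level)
  stopifnot(inherits(target, "genome_record"),
            inherits(collection, "reference_collection"))
  if (level != "strain" && is.na(taxon_label(target, level)))
    stop(sprintf("target '%s' has no %s label; cannot build a %s-level barcode",
                 target$genome_id, level, level), call. = FALSE)
  params <- collection$params
  words <- kmers_of_sequences(chromosome_sequences(target), params)$words
  for (g in collection$genomes) {
    if (length(words) == 0L) break
    excl <- exclusion_sequences(g, target, level)
    for (s in excl) {
      if (length(words) == 0L) break
      words <- words[!(words %in% extract_kmers(s, params)$words)]
    }
  }
  if (length(words) == 0L)
    warning(sprintf("empty %s-level barcode for genome '%s'",
                    level, target$genome_id), call. = FALSE)
  new_barcode(target$genome_id, level, kmer_set(words, params),
              collection_digest(collection))
}

# Sequences of collection genome `g` that belong to the exclusion set of
# `target` at `level`. Plasmids and host sequences are always excluded.
exclusion_sequences <- function(g, target, level) {
  seqs <- g$sequences[g$is_plasmid]
  if (g$is_host) {
    seqs <- g$sequences
  } else if (g$genome_id != target$genome_id) {
    differs <- if (level == "strain") TRUE else
      !identical(taxon_label(g, level), taxon_label(target, level))
    if (isTRUE(differs)) seqs <- c(seqs, chromosome_sequences(g))
  }
  seqs
}

new_barcode <- function(genome_id, level, kmers, collection_digest) {
  structure(list(genome_id = genome_id, level = level, kmers = kmers,
                 size = length(kmers$words),
                 collection_digest = collection_digest),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode> %s [%s-specific]: %s marker %d-mers\n",
              x$genome_id, x$level, format(x$size, big.mark = ","),
              x$kmers$params$k))
  invisible(x)
}

#' Build barcodes for every genome of a collection
#'
#' Convenience wrapper calling [build_barcode()] for each non-host
#' genome at one specificity level.
#'
#' @inheritParams build_barcode
#' @return Named list of [barcode] objects (empty barcodes included).
#' @export
build_barcodes <- function(collection,
                           level = c("genus", "species", "strain")) {
  level <- match.arg(level)
  targets <- Filter(function(g) !g$is_host, collection$genomes)
  lapply(targets, build_barcode, collection = collection, level = level)
}

#' Remove cross-linking k-mers from a set of barcodes
#'
#' Deletes every k-mer that occurs in two or more of the input barcodes
#' from all of them, so the surviving marker sets are pairwise disjoint
#' and a read hit identifies a single target unambiguously. Idempotent;
#' output order matches input order.
#'
#' @param barcodes List of [barcode] objects sharing one [kmer_params].
#' @return List of [barcode] objects with cross-links removed.
#' @export
clear_cross_links <- function(barcodes) {
  if (length(barcodes) == 0L) return(barcodes)
  stopifnot(all(vapply(barcodes, inherits, logical(1), "barcode")))
  params <- barcodes[[1]]$kmers$params
  for (b in barcodes)
    if (!same_params(b$kmers$params, params))
      stop("all barcodes must share the same k-mer parameters", call. = FALSE)
  counts <- table(unlist(lapply(barcodes, function(b) b$kmers$words),
                         use.names = FALSE))
  shared <- names(counts)[counts >= 2L]
  lapply(barcodes, function(b) {
    kept <- b$kmers$words[!(b$kmers$words %in% shared)]
    new_barcode(b$genome_id, b$level, kmer_set(kept, params),
                b$collection_digest)
  })
}

#' Write a barcode to disk
#'
#' Persists one barcode as a sorted plain-text k-mer list (one word per
#' line) plus a JSON sidecar holding the metadata needed for a bit-exact
#' round trip (genome id, level, k, canonical flag, size, collection
#' digest).
#'
#' @param barcode A [barcode].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the k-mer list file.
#' @seealso [read_barcode()]
#' @export
write_barcode <- function(barcode, dir) {
  stopifnot(inherits(barcode, "barcode"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, sprintf("%s.%s", barcode$genome_id, barcode$level))
  kfile <- paste0(stem, ".kmers")
  writeLines(barcode$kmers$words, kfile)
  meta <- list(genome_id = barcode$genome_id, level = barcode$level,
               k = barcode$kmers$params$k,
               canonical = barcode$kmers$params$canonical,
               size = barcode$size,
               collection_digest = barcode$collection_digest)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(kfile)
}

#' Read a barcode written by [write_barcode()]
#'
#' @param kmers_file Path to the \code{.kmers} list; the \code{.json}
#'   sidecar is expected next to it.
#' @return A [barcode].
#' @export
read_barcode <- function(kmers_file) {
  sidecar <- sub("\\.kmers$", ".json", kmers_file)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  words <- readLines(kmers_file)
  if (length(words) == 1L && !nzchar(words)) words <- character(0)
  if (length(words) != meta$size)
    stop(sprintf("barcode '%s': %d k-mers on disk but sidecar says %d",
                 meta$genome_id, length(words), meta$size), call. = FALSE)
  new_barcode(meta$genome_id, meta$level,
              kmer_set(words, kmer_params(meta$k, meta$canonical)),
              meta$collection_digest)
}

#' Read every barcode in a directory
#'
#' @param dir Directory containing \code{.kmers}/\code{.json} pairs.
#' @return Named list of [barcode] objects.
#' @export
read_barcodes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.kmers$", full.names = TRUE))
  if (length(files) == 0L) stop("no .kmers files in ", dir, call. = FALSE)
  bcs <- lapply(files, read_barcode)
  names(bcs) <- vapply(bcs, `[[`, character(1), "genome_id")
  bcs
}
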