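#' Scan metagenome reads for marker k-mers
#'
#' Counts, for every barcode, the number of reads that carry at least
#' one of its marker k-mers. Counting is per read, not per k-mer
#' occurrence: a read with several markers of one genome contributes 1
#' to that genome, while a read matching markers of several genomes
#' contributes 1 to each of them. Reads shorter than \code{min_len} are
#' dropped before counting and do not enter \code{reads_total}. Read
#' k-mers are extracted under the same canonical/degenerate-window
#' rules as genome k-mers, so in canonical mode scanning is
#' strand-agnostic.
#'
#' @param reads Either a path to a FASTQ file (plain or gzip) or a
#'   character vector of read sequences.
#' @param barcodes List of [barcode] objects sharing one [kmer_params].
#' @param min_len Minimum read length retained (default 20; must be >=
#'   k).
#' @param sample_id Sample label carried into the result.
#' @return An object of class \code{read_scan_result}: \code{sample_id},
#'   \code{reads_total} (reads passing the length filter),
#'   \code{reads_hit} (named integer vector, one entry per barcode),
#'   \code{params}, \code{n_short} (reads dropped by the length
#'   filter).
#' @examples
#' p <- kmer_params(3, canonical = TRUE)
#' col <- reference_collection(list(genome_record("g", "ACGAA")), p)
#' bc <- build_barcode(col$genomes$g, col, "strain")
#' scan_reads(c("ACGT", "TTTT", "CGTA"), list(bc), min_len = 3)
#' @export
scan_reads <- function(reads, barcodes, min_len = 20L,
                       sample_id = "sample") {
  stopifnot(is.list(barcodes), length(barcodes) > 0L,
            all(vapply(barcodes, inherits, logical(1), "barcode")))
  params <- barcodes[[1]]$kmers$params
  for (b in barcodes)
    if (!same_params(b$kmers$params, params))
      stop("all barcodes must share the same k-mer parameters", call. = FALSE)
  min_len <- as.integer(min_len)
  if (min_len < params$k)
    stop(sprintf("min_len (%d) must be >= k (%d)", min_len, params$k),
         call. = FALSE)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  reads <- toupper(as.character(reads))
  keep <- nchar(reads) >= min_len
  n_short <- sum(!keep)
  reads <- reads[keep]
  ids <- vapply(barcodes, `[[`, character(1), "genome_id")
  hits <- stats::setNames(integer(length(barcodes)), ids)
  if (length(reads) > 0L) {
    win <- read_windows(reads, params)
    for (b in seq_along(barcodes)) {
      if (barcodes[[b]]$size == 0L) next
      hits[b] <- length(unique(
        win$read[win$kmer %in% barcodes[[b]]$kmers$words]))
    }
  }
  structure(list(sample_id = sample_id, reads_total = length(reads),
                 reads_hit = hits, params = params, n_short = n_short),
            class = "read_scan_result")
}

# All (read index, k-mer) windows over a read set, vectorized; windows
# containing non-ACGT symbols are dropped, canonicalization applied.
read_windows <- function(reads, params) {
  k <- params$k
  w <- nchar(reads)
  nwin <- pmax(w - k + 1L, 0L)
  starts <- sequence(nwin)
  seq_rep <- rep.int(reads, nwin)
  read_idx <- rep.int(seq_along(reads), nwin)
  kmers <- substring(seq_rep, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[ok]; read_idx <- read_idx[ok]
  if (params$canonical && length(kmers)) kmers <- canonicalize(kmers)
  list(read = read_idx, kmer = kmers)
}

#' @export
print.read_scan_result <- function(x, ...) {
  cat(sprintf("<read_scan_result> sample %s: %d reads scanned (%d short), %d barcode(s)\n",
              x$sample_id, x$reads_total, x$n_short, length(x$reads_hit)))
  invisible(x)
}

#' Combine scan results of split read sets
#'
#' Adds \code{reads_total} and \code{reads_hit} component-wise, so
#' scanning a concatenated FASTQ equals combining the scans of its
#' parts.
#'
#' @param ... \code{read_scan_result} objects over identical barcode
#'   sets.
#' @return A \code{read_scan_result}.
#' @export
combine_scans <- function(...) {
  scans <- list(...)
  stopifnot(length(scans) >= 1L,
            all(vapply(scans, inherits, logical(1), "read_scan_result")))
  ref <- scans[[1]]
  for (s in scans[-1]) {
    if (!identical(names(s$reads_hit), names(ref$reads_hit)))
      stop("scan results cover different barcode sets", call. = FALSE)
  }
  structure(list(
    sample_id = ref$sample_id,
    reads_total = sum(vapply(scans, `[[`, integer(1), "reads_total")),
    reads_hit = Reduce(`+`, lapply(scans, `[[`, "reads_hit")),
    params = ref$params,
    n_short = sum(vapply(scans, `[[`, integer(1), "n_short"))),
    class = "read_scan_result")
}

#' Barcode sizes of a barcode list
#'
#' @param barcodes List of [barcode] objects.
#' @return Named integer vector genome_id -> number of marker k-mers.
#' @export
barcode_sizes <- function(barcodes) {
  stats::setNames(vapply(barcodes, `[[`, integer(1), "size"),
                  vapply(barcodes, `[[`, character(1), "genome_id"))
}

#' Default normalization constants
#'
#' Species-level abundances are normalized per one million marker
#' k-mers; strain-level abundances per 37,000 (the rounded average size
#' of the retained strain-specific marker sets in the bundled
#' Lacticaseibacillus catalog).
#'
#' @param level \code{"species"} or \code{"strain"}.
#' @return The normalization constant.
#' @export
default_norm_const <- function(level = c("species", "strain")) {
  switch(match.arg(level), species = 1e6, strain = 3.7e4)
}

#' Normalize read-hit counts into comparable abundances
#'
#' Converts per-genome read hits into the percentage of scanned reads
#' that carry a marker, then rescales by \code{C / markers_n} so that
#' genomes with barcodes of different sizes become comparable:
#' \deqn{normalized = 100 \cdot reads\_hit / reads\_total \cdot C / markers_n.}
#' Genomes whose barcode is empty cannot be normalized and are skipped
#' with a warning.
#'
#' @param scan A [scan_reads()] result.
#' @param barcode_sizes Named numeric vector genome_id -> barcode size
#'   (use [barcode_sizes()] on the scanned barcode list).
#' @param C Normalization constant (see [default_norm_const()]).
#' @param level Specificity level recorded in the output.
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{genome_id}, \code{level}, \code{reads_total},
#'   \code{reads_hit}, \code{percent_reads}, \code{markers_n},
#'   \code{norm_const}, \code{normalized}.
#' @export
normalize_abundance <- function(scan, barcode_sizes,
                                C = default_norm_const(level),
                                level = c("species", "strain", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(scan, "read_scan_result"))
  if (scan$reads_total <= 0L)
    stop("no reads passed the length filter; cannot normalize", call. = FALSE)
  ids <- names(scan$reads_hit)
  sizes <- barcode_sizes[ids]
  empty <- is.na(sizes) | sizes == 0
  if (any(empty)) {
    warning("skipping genome(s) with empty barcode: ",
            paste(ids[empty], collapse = ", "), call. = FALSE)
    ids <- ids[!empty]; sizes <- sizes[!empty]
  }
  hits <- scan$reads_hit[ids]
  percent <- 100 * hits / scan$reads_total
  data.frame(sample_id = rep(scan$sample_id, length(ids)),
             genome_id = ids, level = rep(level, length(ids)),
             reads_total = scan$reads_total, reads_hit = unname(hits),
             percent_reads = unname(percent), markers_n = unname(sizes),
             norm_const = C,
             normalized = unname(percent * C / sizes),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate abundances by phylogroup
#'
#' Summarizes the per-genome normalized abundances of one sample over
#' phylogroups (intraspecies clades). Genomes mapped to the label
#' \code{"singleton"} (or \code{"-"}) do not form a joint group: each is
#' reported individually under its own genome id.
#'
#' @param records Abundance data frame from [normalize_abundance()]
#'   (one sample, one level).
#' @param phylogroups Named character vector genome_id -> phylogroup
#'   label; every profiled genome must be mapped.
#' @return A \code{data.frame} with columns \code{phylogroup},
#'   \code{n_genomes}, \code{mean}, \code{median}, \code{q1}, \code{q3}.
#' @export
aggregate_by_phylogroup <- function(records, phylogroups) {
  stopifnot(is.data.frame(records), "normalized" %in% names(records))
  unmapped <- setdiff(records$genome_id, names(phylogroups))
  if (length(unmapped))
    stop("genome(s) missing from the phylogroup map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  grp <- unname(phylogroups[records$genome_id])
  single <- grp %in% c("singleton", "-")
  grp[single] <- records$genome_id[single]
  agg <- lapply(split(records$normalized, grp), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n_genomes = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3])
  })
  out <- do.call(rbind, agg)
  out <- data.frame(phylogroup = names(agg), out,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$phylogroup), , drop = FALSE]
}

#' Classify paired abundance trajectories
#'
#' Orders each genome's abundance within each subject along the time
#' points given in the design table (e.g. baseline, post-antibiotic,
#' post-recovery) and classifies the trajectory: the response to the
#' perturbation at the second time point (\code{decrease},
#' \code{no-change}, \code{increase} relative to baseline, using a
#' relative-change threshold), and the outcome at the final time point
#' relative to baseline (\code{recovery} within the threshold band,
#' \code{overshoot} above it, \code{further-decline} below it). A zero
#' baseline makes any nonzero later value an increase/overshoot.
#' Subjects missing a time point for a genome are flagged incomplete
#' and carry \code{NA} classifications.
#'
#' @param records Abundance data frame covering several samples
#'   (columns \code{sample_id}, \code{genome_id}, \code{normalized}).
#' @param design Data frame with columns \code{sample_id},
#'   \code{subject}, \code{time_point} (orderable), optional
#'   \code{arm}.
#' @param threshold Relative change below which a difference counts as
#'   no change (default 0.2, i.e. 20%).
#' @return A \code{data.frame}, one row per genome x subject:
#'   \code{genome_id}, \code{subject}, \code{arm}, \code{values}
#'   (comma-separated ordered abundances), \code{complete},
#'   \code{response}, \code{outcome}.
#' @export
paired_trajectory <- function(records, design, threshold = 0.2) {
  stopifnot(is.data.frame(records), is.data.frame(design),
            all(c("sample_id", "subject", "time_point") %in% names(design)))
  tps <- sort(unique(design$time_point))
  if (length(tps) < 2L)
    stop("design must contain at least two time points", call. = FALSE)
  m <- merge(records, design, by = "sample_id")
  out <- list()
  for (g in unique(m$genome_id)) {
    mg <- m[m$genome_id == g, , drop = FALSE]
    for (s in unique(design$subject)) {
      ms <- mg[mg$subject == s, , drop = FALSE]
      v <- ms$normalized[match(tps, ms$time_point)]
      arm <- if ("arm" %in% names(design))
        design$arm[design$subject == s][1] else NA_character_
      complete <- !anyNA(v)
      cls <- if (complete)
        classify_trajectory(v, threshold) else
        list(response = NA_character_, outcome = NA_character_)
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g, subject = s, arm = arm,
        values = paste(signif(v, 8), collapse = ","),
        complete = complete, response = cls$response,
        outcome = cls$outcome, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

classify_trajectory <- function(v, threshold) {
  base <- v[1]; mid <- v[2]; fin <- v[length(v)]
  band <- function(x) {
    if (base == 0) {
      if (x > 0) "above" else "within"
    } else if (x > base * (1 + threshold)) "above"
    else if (x < base * (1 - threshold)) "below"
    else "within"
  }
  response <- switch(band(mid), above = "increase", below = "decrease",
                     within = "no-change")
  outcome <- switch(band(fin), above = "overshoot",
                    below = "further-decline", within = "recovery")
  list(response = response, outcome = outcome)
}

#' Count trajectory scenarios
#'
#' Tabulates the (response, outcome) combinations over the complete
#' trajectories returned by [paired_trajectory()]; incomplete
#' trajectories are excluded from the counts and reported separately.
#'
#' @param trajectories Output of [paired_trajectory()].
#' @return A list with \code{counts} (data frame: response, outcome, n)
#'   and \code{n_incomplete}.
#' @export
trajectory_scenarios <- function(trajectories) {
  cc <- trajectories[trajectories$complete, , drop = FALSE]
  if (nrow(cc) == 0L) {
    tab <- data.frame(response = character(0), outcome = character(0),
                      n = integer(0))
  } else {
    tab <- as.data.frame(table(response = cc$response, outcome = cc$outcome),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    tab <- tab[tab$n > 0, , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(counts = tab, n_incomplete = sum(!trajectories$complete))
}
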