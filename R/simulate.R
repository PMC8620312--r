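# Run code under a temporary RNG state so simulations are reproducible
# from their seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a pangenome with known strain structure
#'
#' Generates \code{n_strains} genomes sharing a common core sequence,
#' phylogroup-structured accessory blocks (each phylogroup shares one
#' accessory segment) and one strain-private segment of length
#' \code{unique_len}, all drawn i.i.d. uniform over A/C/G/T from the
#' seed. The private segment is the ground-truth source of
#' strain-specific markers: in the absence of chance k-mer collisions a
#' strain's non-canonical strain-level barcode has exactly
#' \code{unique_len - k + 1} words. The uniform model carries no GC
#' bias or repeat structure; it is a correctness harness, not a
#' biological sequence model.
#'
#' @param n_strains Number of strains.
#' @param core_len Length of the shared core (>= k).
#' @param n_groups Number of phylogroups the strains are assigned to
#'   (round-robin).
#' @param accessory_len Length of each phylogroup-shared accessory
#'   block (0 to disable).
#' @param unique_len Length of each strain-private segment; must be
#'   >= k unless 0 with \code{allow_zero_unique = TRUE} (which makes
#'   every strain-specific barcode empty by construction).
#' @param k Word length the lengths are validated against (default 18).
#' @param seed Integer seed; fully determines the output.
#' @param allow_zero_unique Permit \code{unique_len = 0}.
#' @return A list with \code{genomes} (list of [genome_record], genus
#'   "SimGenus", species "sim_species", strains "strain01", ...),
#'   \code{truth} (composition per strain: phylogroup, segment lengths,
#'   private segment), \code{phylogroups} (named map), \code{seed}.
#' @export
simulate_pangenome <- function(n_strains, core_len = 20000L, n_groups = 4L,
                               accessory_len = 5000L, unique_len = 3000L,
                               k = 18L, seed = 1L,
                               allow_zero_unique = FALSE) {
  n_strains <- as.integer(n_strains)
  stopifnot(n_strains >= 1L, core_len >= k, accessory_len >= 0L)
  if (unique_len == 0L) {
    if (!allow_zero_unique)
      stop("unique_len = 0 requires allow_zero_unique = TRUE", call. = FALSE)
  } else if (unique_len < k) {
    stop(sprintf("unique_len (%d) must be >= k (%d)", unique_len, k),
         call. = FALSE)
  }
  with_seed(seed, {
    core <- random_sequence(core_len)
    groups <- rep_len(seq_len(n_groups), n_strains)
    accessory <- vapply(seq_len(n_groups), function(i)
      random_sequence(accessory_len), character(1))
    ids <- sprintf("strain%02d", seq_len(n_strains))
    private <- vapply(ids, function(i) random_sequence(unique_len),
                      character(1))
    # segments are separate contigs: no junction k-mers, so the
    # strain-specific markers are exactly the private-segment windows
    genomes <- lapply(seq_len(n_strains), function(i) {
      segs <- c(core,
                if (accessory_len > 0L) accessory[groups[i]],
                if (unique_len > 0L) private[[i]])
      genome_record(ids[i], segs, genus = "SimGenus",
                    species = "sim_species", strain = ids[i])
    })
    truth <- data.frame(genome_id = ids,
                        phylogroup = as.character(as.roman(groups)),
                        core_len = core_len, accessory_len = accessory_len,
                        unique_len = unique_len,
                        private_segment = unname(private),
                        stringsAsFactors = FALSE)
    list(genomes = genomes, truth = truth,
         phylogroups = stats::setNames(truth$phylogroup, ids), seed = seed)
  })
}

#' Simulate a shotgun metagenome with known strain proportions
#'
#' Draws reads from the supplied genomes: for each read a strain is
#' chosen according to \code{proportions}, a start position uniformly
#' over all windows that fit inside a single contig (no chimeric
#' junction reads), and a strand uniformly at random (the read is the
#' reverse complement of the sampled window half the time). Substitution errors are applied per base at
#' \code{error_rate}; there are no indels, matching the exact-match
#' contract of the profiler. Qualities are a constant placeholder
#' ("I"). Output is byte-reproducible from the seed.
#'
#' @param genomes List of [genome_record] objects.
#' @param proportions Numeric vector summing to 1, one entry per
#'   genome.
#' @param n_reads Number of reads (> 0).
#' @param read_len Read length (>= k of the downstream analysis).
#' @param error_rate Per-base substitution probability in [0, 1).
#' @param seed Integer seed.
#' @return A list with \code{reads} (named character vector, names
#'   "read0000001", ...; attribute "quality" set), \code{truth} (data
#'   frame: read id, source genome, position, strand), \code{seed}.
#' @export
simulate_metagenome <- function(genomes, proportions, n_reads,
                                read_len = 100L, error_rate = 0,
                                seed = 1L) {
  stopifnot(is.list(genomes), length(genomes) >= 1L,
            all(vapply(genomes, inherits, logical(1), "genome_record")))
  if (length(proportions) != length(genomes))
    stop("one proportion per genome required", call. = FALSE)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  n_reads <- as.integer(n_reads)
  if (n_reads <= 0L) stop("n_reads must be positive", call. = FALSE)
  # admissible windows per genome: starts that keep a read inside one
  # contig; stored as (contig string, cumulative window counts)
  windows <- lapply(genomes, function(g) {
    lens <- nchar(g$sequences)
    nwin <- pmax(lens - read_len + 1L, 0L)
    if (sum(nwin) == 0L)
      stop(sprintf("genome '%s' has no contig of length >= read_len",
                   g$genome_id), call. = FALSE)
    list(contigs = g$sequences, nwin = nwin, total = sum(nwin))
  })
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  with_seed(seed, {
    src <- sample.int(length(genomes), n_reads, replace = TRUE,
                      prob = proportions)
    # global window index within the genome, mapped to (contig, offset)
    widx <- vapply(src, function(i)
      1L + floor(stats::runif(1) * windows[[i]]$total), numeric(1))
    reads <- character(n_reads)
    pos <- integer(n_reads)
    contig <- integer(n_reads)
    for (r in seq_len(n_reads)) {
      w <- windows[[src[r]]]
      ci <- findInterval(widx[r] - 1L, cumsum(w$nwin)) + 1L
      off <- widx[r] - c(0L, cumsum(w$nwin))[ci]
      reads[r] <- substr(w$contigs[ci], off, off + read_len - 1L)
      pos[r] <- off; contig[r] <- ci
    }
    fwd <- stats::runif(n_reads) < 0.5
    reads[!fwd] <- revcomp(reads[!fwd])
    if (error_rate > 0) reads <- apply_substitutions(reads, error_rate)
    names(reads) <- sprintf("read%07d", seq_len(n_reads))
    attr(reads, "quality") <- rep(paste(rep("I", read_len), collapse = ""),
                                  n_reads)
    truth <- data.frame(read_id = names(reads), genome_id = ids[src],
                        contig = contig, position = pos,
                        strand = ifelse(fwd, "+", "-"),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, seed = seed)
  })
}

# Uniform substitution errors: each base independently replaced by one
# of the three other bases with probability `rate`.
apply_substitutions <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
  hit <- matrix(stats::runif(length(mat)) < rate, nrow = nrow(mat))
  if (any(hit)) {
    old <- mat[hit]
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    mat[hit] <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
  }
  apply(mat, 1L, paste, collapse = "")
}
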