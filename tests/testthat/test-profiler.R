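pc <- kmer_params(3, canonical = TRUE)

mk_bc <- function(id, words, params = pc) {
  structure(list(genome_id = id, level = "strain",
                 kmers = structure(list(words = sort(words), params = params),
                                   class = "kmer_set"),
                 size = length(words), collection_digest = "x"),
            class = "barcode")
}

mk_scan <- function(reads_hit, reads_total, sample_id = "s1",
                    params = pc) {
  structure(list(sample_id = sample_id, reads_total = reads_total,
                 reads_hit = reads_hit, params = params, n_short = 0L),
            class = "read_scan_result")
}

test_that("read scanning counts per read with canonical matching", {
  bc <- mk_bc("g", "ACG")
  scan <- scan_reads(c("ACGT", "TTTT", "CGTA"), list(bc), min_len = 3)
  expect_equal(scan$reads_total, 3L)
  expect_equal(scan$reads_hit, c(g = 2L))  # CGTA hits via canonical CGT->ACG
  # literal mode misses the reverse-strand read
  bl <- mk_bc("g", "ACG", kmer_params(3, FALSE))
  lit <- scan_reads(c("ACGT", "TTTT", "CGTA"), list(bl), min_len = 3)
  expect_equal(lit$reads_hit, c(g = 1L))
})

test_that("a read with several markers of one genome counts once", {
  bc <- mk_bc("g", c("AAC", "ACA"), kmer_params(3, FALSE))
  scan <- scan_reads("AACACA", list(bc), min_len = 3)
  expect_equal(scan$reads_hit, c(g = 1L))
  # but one read may hit several genomes
  b2 <- mk_bc("h", "CAC", kmer_params(3, FALSE))
  scan2 <- scan_reads("AACACA", list(bc, b2), min_len = 3)
  expect_equal(scan2$reads_hit, c(g = 1L, h = 1L))
})

test_that("short reads are dropped before counting", {
  bc <- mk_bc("g", "ACG")
  scan <- scan_reads(c("ACGTACG", "ACG", "AC"), list(bc), min_len = 5)
  expect_equal(scan$reads_total, 1L)
  expect_equal(scan$n_short, 2L)
  expect_error(scan_reads("ACGT", list(bc), min_len = 2), "min_len")
})

test_that("empty barcodes never hit and scanning is order-invariant", {
  bc <- mk_bc("g", character(0))
  reads <- c("ACGT", "CGTA", "GTAC")
  expect_equal(scan_reads(reads, list(bc), min_len = 3)$reads_hit, c(g = 0L))
  full <- mk_bc("h", c("ACG", "AGT"))
  a <- scan_reads(reads, list(full), min_len = 3)
  b <- scan_reads(rev(reads), list(full), min_len = 3)
  expect_equal(a$reads_hit, b$reads_hit)
})

test_that("canonical scanning is invariant under read-wise reverse complement", {
  set.seed(31)
  reads <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  words <- unique(vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = ""),
    character(1)))
  bc <- mk_bc("g", unique(pmin(words, revcomp(words))))
  a <- scan_reads(reads, list(bc), min_len = 3)
  b <- scan_reads(revcomp(reads), list(bc), min_len = 3)
  expect_equal(a$reads_hit, b$reads_hit)
  expect_equal(a$reads_total, b$reads_total)
})

test_that("scan of concatenated read sets equals component-wise sums", {
  set.seed(32)
  reads <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE), collapse = ""),
    character(1))
  bc <- mk_bc("g", c("AAA", "ACA", "AGA"))
  whole <- scan_reads(reads, list(bc), min_len = 3)
  parts <- combine_scans(scan_reads(reads[1:25], list(bc), min_len = 3),
                         scan_reads(reads[26:60], list(bc), min_len = 3))
  expect_equal(whole$reads_total, parts$reads_total)
  expect_equal(whole$reads_hit, parts$reads_hit)
})

test_that("FASTQ input path gives the same scan as in-memory reads", {
  set.seed(33)
  reads <- stats::setNames(
    vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
            collapse = ""), character(1)),
    sprintf("r%02d", 1:20))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  bc <- mk_bc("g", c("AAA", "ACG"))
  expect_equal(scan_reads(path, list(bc), min_len = 3)$reads_hit,
               scan_reads(unname(reads), list(bc), min_len = 3)$reads_hit)
})

test_that("normalization follows percent * C / markers", {
  scan <- mk_scan(c(g = 50L), 100000L)
  out <- normalize_abundance(scan, c(g = 500000), C = 1e6,
                             level = "species")
  expect_equal(out$percent_reads, 0.05)
  expect_equal(out$normalized, 0.1)
  # zero hits give zero abundance
  z <- normalize_abundance(mk_scan(c(g = 0L), 1000L), c(g = 100), C = 1e6)
  expect_equal(z$normalized, 0)
  # defaults per level
  expect_equal(default_norm_const("species"), 1e6)
  expect_equal(default_norm_const("strain"), 3.7e4)
})

test_that("empty-barcode genomes are skipped with a warning", {
  scan <- mk_scan(c(g = 5L, e = 0L), 1000L)
  expect_warning(out <- normalize_abundance(scan, c(g = 100, e = 0), C = 1e6),
                 "e")
  expect_equal(out$genome_id, "g")
})

test_that("abundance records are recomputable from stored fields", {
  scan <- mk_scan(c(a = 7L, b = 2L), 500L)
  out <- normalize_abundance(scan, c(a = 120, b = 80), C = 3.7e4,
                             level = "strain")
  expect_equal(out$normalized,
               100 * out$reads_hit / out$reads_total * out$norm_const /
                 out$markers_n)
})

test_that("phylogroup aggregation averages groups and isolates singletons", {
  rec <- data.frame(sample_id = "s1",
                    genome_id = c("a", "b", "c", "d", "e"),
                    normalized = c(0.1, 0.3, 0.02, 0.04, 0.5))
  map <- c(a = "I", b = "I", c = "II", d = "II", e = "singleton")
  out <- aggregate_by_phylogroup(rec, map)
  expect_equal(out$mean[out$phylogroup == "I"], 0.2)
  expect_equal(out$median[out$phylogroup == "I"], 0.2)
  expect_equal(out$mean[out$phylogroup == "II"], 0.03)
  expect_equal(out$phylogroup, sort(c("I", "II", "e")))
  expect_equal(out$n_genomes[out$phylogroup == "e"], 1L)
  expect_equal(out$mean[out$phylogroup == "e"], 0.5)
  # four-value arithmetic
  rec4 <- data.frame(sample_id = "s1", genome_id = letters[1:4],
                     normalized = c(0.02, 0.04, 0.06, 0.08))
  out4 <- aggregate_by_phylogroup(rec4, c(a = "I", b = "I", c = "I", d = "I"))
  expect_equal(out4$mean, 0.05)
  expect_error(aggregate_by_phylogroup(rec, map[-1]), "a")
})

trajectory_records <- function(vals) {
  data.frame(sample_id = c("t1", "t2", "t3"), genome_id = "g",
             normalized = vals)
}

traj_design <- data.frame(sample_id = c("t1", "t2", "t3"), subject = "p1",
                          time_point = 1:3, arm = "probiotic")

test_that("trajectories classify decrease, recovery, overshoot and no-change", {
  out <- paired_trajectory(trajectory_records(c(0.05, 0.025, 0.05)),
                           traj_design)
  expect_equal(out$response, "decrease")
  expect_equal(out$outcome, "recovery")
  out2 <- paired_trajectory(trajectory_records(c(0.0027, 0, 0.0051)),
                            traj_design)
  expect_equal(out2$response, "decrease")
  expect_equal(out2$outcome, "overshoot")
  out3 <- paired_trajectory(trajectory_records(c(0.05, 0.05, 0.05)),
                            traj_design)
  expect_equal(out3$response, "no-change")
  expect_equal(out3$outcome, "recovery")
  out4 <- paired_trajectory(trajectory_records(c(0.05, 0.08, 0.01)),
                            traj_design)
  expect_equal(out4$response, "increase")
  expect_equal(out4$outcome, "further-decline")
})

test_that("incomplete trajectories are flagged and excluded from counts", {
  rec <- trajectory_records(c(0.05, 0.025, 0.05))[-2, ]
  out <- paired_trajectory(rec, traj_design)
  expect_false(out$complete)
  expect_true(is.na(out$response))
  sc <- trajectory_scenarios(out)
  expect_equal(sum(sc$counts$n), 0L)
  expect_equal(sc$n_incomplete, 1L)
})
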