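p3 <- kmer_params(3, canonical = FALSE)

two_genome_collection <- function() {
  tg <- genome_record("t", "ACGTAACC", genus = "G", species = "Gs")
  ex <- genome_record("e", "TTACGTT", genus = "H", species = "Hs")
  reference_collection(list(tg, ex), p3)
}

test_that("subtraction against an exclusion genome matches hand enumeration", {
  col <- two_genome_collection()
  b <- build_barcode(col$genomes$t, col, "genus")
  expect_setequal(b$kmers$words, c("GTA", "TAA", "AAC", "ACC"))
  expect_equal(b$size, 4L)
})

test_that("a duplicated genome leaves an empty strain barcode", {
  a <- genome_record("a", "ACGTACGTAA", genus = "G", species = "Gs")
  b <- genome_record("b", "ACGTACGTAA", genus = "G", species = "Gs")
  col <- reference_collection(list(a, b), p3)
  expect_warning(bc <- build_barcode(a, col, "strain"), "empty")
  expect_equal(bc$size, 0L)
  # same genomes still share everything at species level, so species
  # barcodes are whole k-mer sets
  sp <- build_barcode(a, col, "species")
  expect_equal(sp$kmers$words, extract_kmers("ACGTACGTAA", p3)$words)
})

test_that("a singleton collection yields all distinct k-mers at strain level", {
  a <- genome_record("a", "ACGTAACC", genus = "G", species = "Gs")
  col <- reference_collection(list(a), p3)
  b <- build_barcode(a, col, "strain")
  expect_equal(b$kmers$words, extract_kmers("ACGTAACC", p3)$words)
})

test_that("missing taxonomy label at the requested level is an error", {
  a <- genome_record("a", "ACGTAACC")
  col <- reference_collection(list(a), p3)
  expect_error(build_barcode(a, col, "genus"), "label")
  expect_silent(build_barcode(a, col, "strain"))
})

test_that("barcodes agree with the brute-force oracle at all three levels", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    canon <- i %% 2 == 0
    col <- random_collection(sample(2:6, 1), sample(200:800, 1), k, canon,
                             with_plasmid = TRUE, with_host = TRUE)
    targets <- Filter(function(g) !g$is_host, col$genomes)
    tg <- targets[[sample(length(targets), 1)]]
    for (level in c("genus", "species", "strain")) {
      got <- suppressWarnings(build_barcode(tg, col, level))
      expect_equal(got$kmers$words,
                   oracle_barcode(tg, col$genomes, level, k, canon),
                   info = sprintf("iter=%d level=%s", i, level))
    }
  }
})

test_that("barcode nesting strain within species within genus", {
  set.seed(12)
  for (i in 1:15) {
    col <- random_collection(sample(3:6, 1), 600, 4, TRUE)
    tg <- col$genomes[[1]]
    g <- suppressWarnings(build_barcode(tg, col, "genus"))
    s <- suppressWarnings(build_barcode(tg, col, "species"))
    st <- suppressWarnings(build_barcode(tg, col, "strain"))
    expect_true(all(st$kmers$words %in% s$kmers$words))
    expect_true(all(s$kmers$words %in% g$kmers$words))
    expect_true(st$size <= s$size && s$size <= g$size)
  }
})

test_that("barcode is invariant under exclusion-genome order", {
  set.seed(13)
  col <- random_collection(5, 700, 4, TRUE)
  tg <- col$genomes[[2]]
  ref <- suppressWarnings(build_barcode(tg, col, "strain"))
  for (i in 1:5) {
    perm <- reference_collection(sample(col$genomes), col$params)
    got <- suppressWarnings(build_barcode(tg, perm, "strain"))
    expect_identical(got$kmers$words, ref$kmers$words)
  }
})

test_that("canonical barcodes survive reverse-complementing all inputs", {
  set.seed(14)
  col <- random_collection(4, 500, 4, TRUE)
  rc_genomes <- lapply(col$genomes, function(g) {
    g$sequences <- revcomp(g$sequences)
    g
  })
  rc_col <- reference_collection(rc_genomes, col$params)
  for (i in seq_along(col$genomes)) {
    a <- suppressWarnings(build_barcode(col$genomes[[i]], col, "strain"))
    b <- suppressWarnings(build_barcode(rc_genomes[[i]], rc_col, "strain"))
    expect_identical(a$kmers$words, b$kmers$words)
  }
})

test_that("cross-link removal deletes shared words and is idempotent", {
  mk <- function(id, words) {
    structure(list(genome_id = id, level = "strain",
                   kmers = structure(list(words = sort(words), params = p3),
                                     class = "kmer_set"),
                   size = length(words), collection_digest = "x"),
              class = "barcode")
  }
  b1 <- mk("b1", c("AAA", "CCC"))
  b2 <- mk("b2", c("CCC", "GGG"))
  out <- clear_cross_links(list(b1, b2))
  expect_equal(out[[1]]$kmers$words, "AAA")
  expect_equal(out[[2]]$kmers$words, "GGG")
  # disjoint inputs unchanged
  out2 <- clear_cross_links(list(mk("a", "AAA"), mk("b", "TTT")))
  expect_equal(vapply(out2, `[[`, integer(1), "size"), c(1L, 1L))
  # identical inputs both emptied
  out3 <- clear_cross_links(list(mk("a", c("AAA", "TTT")),
                                 mk("b", c("AAA", "TTT"))))
  expect_equal(vapply(out3, `[[`, integer(1), "size"), c(0L, 0L))
  # idempotent and pairwise disjoint on random inputs
  set.seed(15)
  bcs <- lapply(1:4, function(i)
    mk(paste0("g", i), sample(apply(expand.grid(c("A", "C"), c("A", "C"),
                                                c("A", "C")), 1, paste,
                                    collapse = ""), 5)))
  once <- clear_cross_links(bcs)
  twice <- clear_cross_links(once)
  expect_identical(lapply(once, `[[`, "kmers"),
                   lapply(twice, `[[`, "kmers"))
  words <- lapply(once, function(b) b$kmers$words)
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(words[[i]], words[[j]]), 0)
})

test_that("mixed k across barcodes is rejected", {
  mk <- function(id, words, params) {
    structure(list(genome_id = id, level = "strain",
                   kmers = structure(list(words = words, params = params),
                                     class = "kmer_set"),
                   size = length(words), collection_digest = "x"),
              class = "barcode")
  }
  expect_error(clear_cross_links(list(mk("a", "AAA", p3),
                                      mk("b", "AAAA", kmer_params(4, FALSE)))),
               "parameters")
})

test_that("barcode persistence round-trips bit-exactly", {
  col <- two_genome_collection()
  b <- build_barcode(col$genomes$t, col, "genus")
  dir <- withr::local_tempdir()
  write_barcode(b, dir)
  back <- read_barcode(file.path(dir, "t.genus.kmers"))
  expect_identical(back$kmers$words, b$kmers$words)
  expect_identical(back$collection_digest, b$collection_digest)
  expect_identical(back$kmers$params, b$kmers$params)
  expect_identical(back$level, b$level)
  # empty barcode round-trips too
  a <- genome_record("a", "ACGTACGTAA", genus = "G", species = "Gs")
  dup <- genome_record("b", "ACGTACGTAA", genus = "G", species = "Gs")
  col2 <- reference_collection(list(a, dup), p3)
  e <- suppressWarnings(build_barcode(a, col2, "strain"))
  write_barcode(e, dir)
  eback <- read_barcode(file.path(dir, "a.strain.kmers"))
  expect_equal(eback$size, 0L)
})

test_that("collection digest tracks content, not genome order", {
  col <- two_genome_collection()
  perm <- reference_collection(rev(col$genomes), col$params)
  expect_identical(collection_digest(col), collection_digest(perm))
  other <- reference_collection(list(col$genomes$t), col$params)
  expect_false(identical(collection_digest(col), collection_digest(other)))
})
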