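# Independent brute-force oracles. Deliberately naive (per-character
# loops, direct enumeration); they share no code with the package.

oracle_revcomp1 <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- rev(strsplit(s, "")[[1]])
  paste(map[chars], collapse = "")
}

oracle_kmers <- function(s, k, canonical) {
  s <- toupper(s)
  out <- character(0)
  if (nchar(s) >= k) {
    for (i in 1:(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) {
        if (canonical) {
          rc <- oracle_revcomp1(w)
          if (rc < w) w <- rc
        }
        out <- c(out, w)
      }
    }
  }
  sort(unique(out))
}

# Brute-force barcode: enumerate every window of every sequence in the
# collection and subtract in one pass.
oracle_barcode <- function(target, genomes, level, k, canonical) {
  mine <- character(0)
  for (s in target$sequences[!target$is_plasmid])
    mine <- union(mine, oracle_kmers(s, k, canonical))
  excl <- character(0)
  lab <- function(g) switch(level, genus = g$genus, species = g$species,
                            strain = g$genome_id)
  for (g in genomes) {
    for (i in seq_along(g$sequences)) {
      s <- g$sequences[i]
      exclude <- g$is_plasmid[i] || g$is_host ||
        (g$genome_id != target$genome_id &&
           !identical(lab(g), lab(target)))
      if (exclude) excl <- union(excl, oracle_kmers(s, k, canonical))
    }
  }
  sort(setdiff(mine, excl))
}

# Random small collection for oracle-equivalence properties.
random_collection <- function(n_genomes, total_len, k, canonical,
                              with_plasmid = FALSE, with_host = FALSE) {
  lens <- as.integer(stats::rmultinom(1, total_len, rep(1, n_genomes)))
  lens <- pmax(lens, k + 1L)
  genera <- sample(c("Ga", "Gb"), n_genomes, replace = TRUE)
  species <- paste0(genera, sample(c("s1", "s2"), n_genomes, replace = TRUE))
  genomes <- lapply(seq_len(n_genomes), function(i) {
    seqs <- paste(sample(c("A", "C", "G", "T", "N"), lens[i],
                         replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                  collapse = "")
    plasmid <- FALSE
    if (with_plasmid && stats::runif(1) < 0.3) {
      seqs <- c(seqs, paste(sample(c("A", "C", "G", "T"), 30,
                                   replace = TRUE), collapse = ""))
      plasmid <- c(FALSE, TRUE)
    }
    genome_record(sprintf("g%02d", i), seqs, genus = genera[i],
                  species = species[i], is_plasmid = plasmid)
  })
  if (with_host && stats::runif(1) < 0.5) {
    genomes <- c(genomes, list(genome_record(
      "host", paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = ""), is_host = TRUE)))
  }
  reference_collection(genomes, kmer_params(k, canonical))
}

# Mann-Whitney permutation oracle on raw values: U from direct pairwise
# comparison, p from enumerating every group assignment.
oracle_mwu <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b)
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  u_all <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Random additive distance matrix from a random tree with known topology.
random_additive <- function(n) {
  tree <- ape::rtree(n, rooted = FALSE, br = function(nb)
    stats::runif(nb, 0.1, 2))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
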