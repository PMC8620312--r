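#' Sorensen (Dice) distance between two barcodes
#'
#' \deqn{D = 1 - 2|A \cap B| / (|A| + |B|)}
#' on the two marker k-mer sets: 0 for identical sets, 1 for disjoint
#' ones. Reported as a fraction; multiply by 100 to display as a
#' percentage.
#'
#' @param a,b [barcode] objects built with the same [kmer_params].
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' p <- kmer_params(3, canonical = FALSE)
#' col <- reference_collection(list(
#'   genome_record("x", "ACGTAACC"), genome_record("y", "ACGTTTTT")), p)
#' bx <- build_barcode(col$genomes$x, col, "strain")
#' by <- build_barcode(col$genomes$y, col, "strain")
#' sorensen_distance(bx, by)
#' @export
sorensen_distance <- function(a, b) {
  stopifnot(inherits(a, "barcode"), inherits(b, "barcode"))
  if (!same_params(a$kmers$params, b$kmers$params))
    stop("barcodes were built with different k-mer parameters", call. = FALSE)
  na <- a$size; nb <- b$size
  if (na + nb == 0L)
    stop("Sorensen distance undefined: both barcodes are empty", call. = FALSE)
  shared <- sum(a$kmers$words %in% b$kmers$words)
  1 - 2 * shared / (na + nb)
}

#' Pairwise Sorensen distance matrix over barcodes
#'
#' @param barcodes List of at least three non-empty [barcode] objects
#'   sharing one [kmer_params]; label order of the matrix is input
#'   order.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set
#'   to the genome ids.
#' @export
pairwise_distance_matrix <- function(barcodes) {
  stopifnot(is.list(barcodes),
            all(vapply(barcodes, inherits, logical(1), "barcode")))
  if (length(barcodes) < 3L)
    stop("need at least 3 barcodes for a distance matrix", call. = FALSE)
  empty <- vapply(barcodes, function(b) b$size == 0L, logical(1))
  if (any(empty))
    stop("empty barcode(s) present: ",
         paste(vapply(barcodes[empty], `[[`, character(1), "genome_id"),
               collapse = ", "), call. = FALSE)
  ids <- vapply(barcodes, `[[`, character(1), "genome_id")
  n <- length(barcodes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- sorensen_distance(barcodes[[i]], barcodes[[j]])
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix has a non-zero diagonal", call. = FALSE)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at every step the pair
#' minimizing \eqn{Q(i,j) = (r-2) d(i,j) - R_i - R_j} (with \eqn{R_i}
#' the row sum over the \eqn{r} active nodes) is joined, branch lengths
#' follow the standard formulas, and distances to the new node are
#' \eqn{(d(i,k) + d(j,k) - d(i,j))/2}. Exact on additive matrices: the
#' generating topology is recovered and path lengths reproduce the
#' input.
#'
#' Two determinism rules make the output reproducible where the
#' algorithm itself is unspecified: ties in \eqn{Q} are broken by the
#' lexicographically smallest pair of node labels, and negative branch
#' lengths (possible on non-additive input) are clamped to zero with a
#' message reporting the clamped total.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   names (at least 3 taxa).
#' @return An unrooted \code{phylo} tree (package \pkg{ape}) whose tip
#'   labels are the matrix labels.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(neighbor_joining(d))
#' @export
neighbor_joining <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  # node "payloads" are partial Newick strings; joining wraps them
  nodes <- labels
  clamped <- 0
  fmt <- function(len) {
    if (len < 0) { clamped <<- clamped + abs(len); len <- 0 }
    sprintf("%.17g", len)
  }
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest (label_i, label_j) pair
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rownames(d)[ij[1]], rownames(d)[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    dij <- d[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dk <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    lab <- c(rownames(d)[keep], min(rownames(d)[c(i, j)]))
    dimnames(d2) <- list(lab, lab)
    d <- d2
    nodes <- c(nodes[keep], merged)
  }
  # final three nodes join at one central (possibly degree-3) vertex
  dij <- d[1, 2]; dik <- d[1, 3]; djk <- d[2, 3]
  l1 <- (dij + dik - djk) / 2
  l2 <- (dij + djk - dik) / 2
  l3 <- (dik + djk - dij) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(l1),
                    nodes[2], fmt(l2), nodes[3], fmt(l3))
  if (clamped > 0)
    message(sprintf(
      "neighbor_joining: clamped negative branch lengths (total %.3g)",
      clamped))
  ape::read.tree(text = newick)
}

#' Write / read a square-PHYLIP distance matrix
#'
#' Plain square PHYLIP: first line the number of taxa, then one row per
#' taxon (label, then all distances). Distances are written with full
#' double precision so the matrix round-trips exactly.
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output (input) file path.
#' @return \code{write_phylip} returns \code{path} invisibly;
#'   \code{read_phylip} returns the matrix.
#' @export
write_phylip <- function(d, path) {
  d <- validate_distance_matrix(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i],
                       sprintf("%.17g", d[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(lines[1 + seq_len(n)], "\t", fixed = TRUE)
  labels <- vapply(parts, `[[`, character(1), 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  validate_distance_matrix(d)
}

#' Write a distance matrix as TSV
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  d <- validate_distance_matrix(d)
  df <- data.frame(genome_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
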