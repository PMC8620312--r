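#' Mann-Whitney U test
#'
#' Rank-sum comparison of two unpaired groups. The U statistic uses the
#' midrank convention, so tied observations contribute 1/2 per pair and
#' the conservation identity \eqn{U_x + U_y = n_x n_y} always holds.
#' When both groups have at most \code{exact_max} observations the
#' p-value is computed by full enumeration of all
#' \eqn{\binom{n_x+n_y}{n_x}} group assignments of the pooled values
#' (valid under ties); larger groups use the normal approximation with
#' tie correction and continuity correction. The two-sided p-value is
#' \eqn{\min(1, 2\min(P(U \le u), P(U \ge u)))}.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (alternatives on the location of \code{x}
#'   relative to \code{y}).
#' @param exact_max Largest group size for which exact enumeration is
#'   used (default 10).
#' @return A list with \code{U} (the U statistic of \code{x}),
#'   \code{p_value}, \code{method} (\code{"exact"} or
#'   \code{"normal"}).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact_max = 10L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values in input", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    p <- mwu_exact_p(r, nx, u_obs, alternative)
    method <- "exact"
  } else {
    p <- mwu_normal_p(r, nx, ny, u_obs, alternative)
    method <- "normal"
  }
  list(U = u_obs, p_value = p, method = method)
}

# Exact permutation null: U for every choice of nx pooled ranks.
mwu_exact_p <- function(r, nx, u_obs, alternative) {
  offset <- nx * (nx + 1) / 2
  u_all <- utils::combn(r, nx, FUN = sum) - offset
  tol <- 1e-9
  p_le <- mean(u_all <= u_obs + tol)
  p_ge <- mean(u_all >= u_obs - tol)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

# Normal approximation with tie correction and continuity correction.
mwu_normal_p <- function(r, nx, ny, u_obs, alternative) {
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  z_le <- (u_obs - mu + 0.5) / sigma
  z_ge <- (u_obs - mu - 0.5) / sigma
  p_le <- stats::pnorm(z_le)
  p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

#' Log2 fold change with pseudocount
#'
#' \deqn{\log_2((after + \epsilon) / (before + \epsilon))}, with a
#' pseudocount keeping the ratio finite when an abundance drops to
#' zero. Vectorized over \code{before}/\code{after}.
#'
#' @param before,after Non-negative abundances.
#' @param eps Positive pseudocount; the conventional default is half
#'   the smallest nonzero abundance in the dataset (see
#'   [default_pseudocount()]).
#' @return Numeric vector of log2 fold changes.
#' @examples
#' fold_change(0.05, 0.025, eps = 1e-12)  # ~ -1
#' @export
fold_change <- function(before, after, eps) {
  if (missing(eps) || !is.numeric(eps) || eps <= 0)
    stop("'eps' must be a positive pseudocount", call. = FALSE)
  if (any(before < 0) || any(after < 0))
    stop("abundances must be non-negative", call. = FALSE)
  log2((after + eps) / (before + eps))
}

#' Conventional pseudocount for a dataset
#'
#' Half the smallest nonzero value among the supplied abundances.
#'
#' @param values Numeric vector of abundances.
#' @return A positive number.
#' @export
default_pseudocount <- function(values) {
  nz <- values[values > 0 & is.finite(values)]
  if (length(nz) == 0L)
    stop("no nonzero abundances; supply 'eps' explicitly", call. = FALSE)
  min(nz) / 2
}

#' Compare two sample groups per genome
#'
#' Unpaired Mann-Whitney comparison of normalized abundances between
#' two groups of samples, one test per genome (or per phylogroup if the
#' records are pre-aggregated).
#'
#' @param records Abundance data frame (columns \code{sample_id},
#'   \code{genome_id}, \code{normalized}).
#' @param design Data frame mapping \code{sample_id} to \code{group}.
#' @param group_a,group_b The two group labels to compare.
#' @param alternative Passed to [mann_whitney_u()].
#' @return A \code{data.frame}: \code{genome_id}, \code{n_a},
#'   \code{n_b}, \code{median_a}, \code{median_b}, \code{U},
#'   \code{p_value}.
#' @export
compare_groups <- function(records, design, group_a, group_b,
                           alternative = "two.sided") {
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  m <- merge(records, design[, c("sample_id", "group")], by = "sample_id")
  out <- lapply(split(m, m$genome_id), function(mg) {
    a <- mg$normalized[mg$group == group_a]
    b <- mg$normalized[mg$group == group_b]
    if (length(a) == 0L || length(b) == 0L)
      stop("genome ", mg$genome_id[1], " missing from one group",
           call. = FALSE)
    w <- mann_whitney_u(a, b, alternative)
    data.frame(genome_id = mg$genome_id[1], n_a = length(a),
               n_b = length(b), median_a = stats::median(a),
               median_b = stats::median(b), U = w$U,
               p_value = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-genome fold-change / significance (volcano) table
#'
#' For each genome, pairs the abundances of every subject at two time
#' points, averages the per-subject log2 fold changes, and attaches a
#' two-sided Mann-Whitney p-value comparing the before and after
#' abundance vectors across subjects. Raw p-values are the default (a
#' Benjamini-Hochberg option is provided); significance is called at
#' \code{alpha}. Genomes with pairs for at most half the subjects are
#' excluded with a message.
#'
#' @param records Abundance data frame (columns \code{sample_id},
#'   \code{genome_id}, \code{normalized}).
#' @param design Data frame with columns \code{sample_id},
#'   \code{subject}, \code{time_point}.
#' @param before,after The two time-point labels to contrast.
#' @param alpha Significance level (default 0.05).
#' @param eps Pseudocount; defaults to half the smallest nonzero
#'   abundance among the records.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @param phylogroups Optional named vector genome_id -> phylogroup,
#'   copied into the output.
#' @return A \code{data.frame}: \code{genome_id}, \code{phylogroup},
#'   \code{n_pairs}, \code{mean_log2fc}, \code{p_value},
#'   \code{significant}.
#' @export
volcano_table <- function(records, design, before, after, alpha = 0.05,
                          eps = NULL, adjust = c("none", "BH"),
                          phylogroups = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("sample_id", "subject", "time_point") %in% names(design)))
  m <- merge(records, design, by = "sample_id")
  m <- m[m$time_point %in% c(before, after), , drop = FALSE]
  n_subjects <- length(unique(design$subject[design$time_point %in%
                                               c(before, after)]))
  if (n_subjects < 3L)
    stop("need at least 3 paired subjects", call. = FALSE)
  if (is.null(eps)) eps <- default_pseudocount(m$normalized)
  rows <- list(); dropped <- character(0)
  for (g in unique(m$genome_id)) {
    mg <- m[m$genome_id == g, , drop = FALSE]
    bv <- av <- numeric(0)
    for (s in unique(mg$subject)) {
      b <- mg$normalized[mg$subject == s & mg$time_point == before]
      a <- mg$normalized[mg$subject == s & mg$time_point == after]
      if (length(b) == 1L && length(a) == 1L) {
        bv <- c(bv, b); av <- c(av, a)
      }
    }
    if (length(bv) <= n_subjects / 2) { dropped <- c(dropped, g); next }
    w <- mann_whitney_u(bv, av, "two.sided")
    rows[[g]] <- data.frame(
      genome_id = g,
      phylogroup = if (is.null(phylogroups)) NA_character_ else
        unname(phylogroups[g]),
      n_pairs = length(bv),
      mean_log2fc = mean(fold_change(bv, av, eps)),
      p_value = w$p_value, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    message("volcano_table: excluded genome(s) paired in <= half the subjects: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out
}

#' Wilcoxon signed-rank alternative for paired designs
#'
#' Non-default paired alternative to the unpaired Mann-Whitney
#' contrast: applies \code{stats::wilcox.test(..., paired = TRUE)} to
#' the per-subject before/after abundances of one genome.
#'
#' @param before,after Paired numeric vectors (same subjects, same
#'   order).
#' @return A list with \code{V} and \code{p_value}.
#' @export
paired_signed_rank <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 1L)
  w <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
  list(V = unname(w$statistic), p_value = w$p.value)
}
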