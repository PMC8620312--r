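#' Resolve a run configuration
#'
#' Accepts a named list or a path to a JSON/YAML file and fills in
#' defaults for every tunable of the pipeline. The resolved
#' configuration is written next to the outputs of [run_pipeline()] so
#' any run can be reproduced from its artifact directory alone.
#'
#' @param config Named list, or path to a \code{.json}/\code{.yaml}
#'   file.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package",
             call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(mode = "phylogeny", manifest = NULL, fastq = NULL,
                   sample_id = "sample", level = "strain", k = 18L,
                   canonical = TRUE, min_len = 20L, norm_const = NULL,
                   clear = FALSE, alpha = 0.05, eps = NULL, seed = 1L,
                   out_dir = "kbarcode_out")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("phylogeny", "profile"))
    stop("mode must be 'phylogeny' or 'profile'", call. = FALSE)
  if (is.null(cfg$norm_const) && cfg$level %in% c("species", "strain"))
    cfg$norm_const <- default_norm_const(cfg$level)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the barcode pipeline end to end
#'
#' Chains the package stages as configured and writes every artifact
#' into one directory. \code{mode = "phylogeny"} runs barcode building
#' for every genome of the manifest, the pairwise Sorensen distance
#' matrix and the neighbor-joining tree (\code{barcodes/},
#' \code{dist.phylip}, \code{dist.tsv}, \code{tree.nwk}). \code{mode =
#' "profile"} runs barcode building, optional cross-link removal, read
#' scanning of the configured FASTQ file(s) and abundance
#' normalization (\code{barcodes/}, \code{abundance.tsv}). Each run
#' also writes \code{config.json} (the resolved configuration) and
#' \code{inputs.json} (md5 digests of every input file). A failing
#' stage aborts with the stage named.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$manifest))
    stop("config must name a genome 'manifest'", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  inputs <- c(cfg$manifest, cfg$fastq)
  params <- kmer_params(cfg$k, cfg$canonical)
  collection <- stage("read_collection", read_collection(cfg$manifest, params))
  barcodes <- stage("barcode",
                    build_barcodes(collection, level = cfg$level))
  if (isTRUE(cfg$clear))
    barcodes <- stage("clear_cross_links", clear_cross_links(barcodes))
  bdir <- file.path(cfg$out_dir, "barcodes")
  for (b in barcodes) write_barcode(b, bdir)
  if (cfg$mode == "phylogeny") {
    nonempty <- Filter(function(b) b$size > 0L, barcodes)
    if (length(nonempty) < length(barcodes))
      message("run_pipeline: dropped ", length(barcodes) - length(nonempty),
              " empty barcode(s) before distance computation")
    d <- stage("distmat", pairwise_distance_matrix(nonempty))
    write_phylip(d, file.path(cfg$out_dir, "dist.phylip"))
    write_distance_tsv(d, file.path(cfg$out_dir, "dist.tsv"))
    tree <- stage("tree", neighbor_joining(d))
    ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
  } else {
    if (is.null(cfg$fastq))
      stop("profile mode needs 'fastq' in the config", call. = FALSE)
    scans <- lapply(cfg$fastq, function(f)
      stage("scan_reads",
            scan_reads(f, barcodes, min_len = cfg$min_len,
                       sample_id = cfg$sample_id)))
    scan <- do.call(combine_scans, scans)
    abund <- stage("normalize",
                   normalize_abundance(scan, barcode_sizes(barcodes),
                                       C = cfg$norm_const,
                                       level = cfg$level))
    write_tsv(abund, file.path(cfg$out_dir, "abundance.tsv"))
  }
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  digests <- lapply(inputs, function(f) unname(tools::md5sum(f)))
  names(digests) <- inputs
  jsonlite::write_json(digests, file.path(cfg$out_dir, "inputs.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$out_dir)
}
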