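#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `proteins.faa`, `genes.fna` (FASTA, wrapped at 60 columns),
#' `counts.tsv` (genes x samples), `metabolites.tsv`, `phenotypes.tsv`,
#' `samples.tsv`, `truth.tsv` and `config.json`.  The bundle round-trips
#' losslessly through [read_study_bundle()].
#'
#' @param study a `synthetic_study`.
#' @param directory target directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_bundle <- function(study, directory) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create ", directory, call. = FALSE)
  writeXStringSet(AAStringSet(study$proteins),
                  file.path(directory, "proteins.faa"), width = 60)
  writeXStringSet(DNAStringSet(study$genes),
                  file.path(directory, "genes.fna"), width = 60)
  .write_matrix(study$counts, file.path(directory, "counts.tsv"), "gene_id")
  .write_tsv(study$metabolites, file.path(directory, "metabolites.tsv"))
  .write_tsv(study$phenotypes, file.path(directory, "phenotypes.tsv"))
  .write_tsv(study$samples, file.path(directory, "samples.tsv"))
  .write_tsv(study$truth, file.path(directory, "truth.tsv"))
  .write_tsv(study$gene_info, file.path(directory, "gene_info.tsv"))
  .write_matrix(1L * study$presence, file.path(directory, "presence.tsv"),
                "species")
  cfg <- unclass(study$config)
  cfg$overdispersion <- if (is.null(cfg$overdispersion)) NA else cfg$overdispersion
  jsonlite::write_json(cfg, file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a study bundle written by [write_study_bundle()]
#'
#' @param directory bundle directory.
#' @return A `synthetic_study` equivalent to the one written.
#' @export
read_study_bundle <- function(directory) {
  proteins <- readAAStringSet(file.path(directory, "proteins.faa"))
  genes <- readDNAStringSet(file.path(directory, "genes.fna"))
  counts_df <- read.delim(file.path(directory, "counts.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  storage.mode(counts) <- "integer"
  cfg <- jsonlite::read_json(file.path(directory, "config.json"),
                             simplifyVector = TRUE)
  if (length(cfg$overdispersion) == 0 || is.na(cfg$overdispersion)) {
    cfg$overdispersion <- NULL
  }
  cfg$covariate_effects <- unlist(cfg$covariate_effects)
  config <- do.call(simulation_config, cfg)
  pres_df <- read.delim(file.path(directory, "presence.tsv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  presence <- as.matrix(pres_df[, -1, drop = FALSE]) > 0
  rownames(presence) <- pres_df[[1]]
  structure(list(
    config = config,
    presence = presence,
    proteins = setNames(as.character(proteins), names(proteins)),
    genes = setNames(as.character(genes), names(genes)),
    gene_info = read.delim(file.path(directory, "gene_info.tsv"),
                           stringsAsFactors = FALSE),
    truth = read.delim(file.path(directory, "truth.tsv"),
                       stringsAsFactors = FALSE),
    counts = counts,
    metabolites = read.delim(file.path(directory, "metabolites.tsv"),
                             stringsAsFactors = FALSE),
    samples = read.delim(file.path(directory, "samples.tsv"),
                         stringsAsFactors = FALSE),
    phenotypes = read.delim(file.path(directory, "phenotypes.tsv"),
                            stringsAsFactors = FALSE),
    seed_used = config$seed), class = "synthetic_study")
}
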