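## Shared TSV readers/writers.  All pipeline outputs are tab-separated
## text with a header; numeric values are written with full precision so
## write -> read round-trips reproduce matrices exactly.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits the on-disk formats every downstream reader consumes: per-type
#' subdirectories with gene/miRNA count TSVs, a sample sheet
#' (\code{sample_id}, \code{group}, \code{tumour_type}), CNA level and
#' methylation beta matrices, a probe map, and a clinical table; at the
#' top level, feature length TSVs, the target catalogue, the pathway GMT,
#' and the known gene/miRNA/pair lists.  When a cohort carries no
#' methylation probes the MET files are omitted and the manifest notes the
#' absence.
#'
#' @param cohort the \code{cohort} element of \code{\link{generate_cohort}}.
#' @param directory output directory (created if needed).
#' @return data.frame manifest (\code{file}, \code{kind},
#'   \code{tumour_type}), invisibly reusable by \code{\link{read_cohort}}.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  manifest <- list()
  note <- function(file, kind, tt = NA_character_)
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = file, kind = kind, tumour_type = tt, stringsAsFactors = FALSE)

  for (tt in names(cohort$types)) {
    ty <- cohort$types[[tt]]
    d <- file.path(directory, tt)
    dir.create(d, showWarnings = FALSE)
    write_matrix_tsv(ty$genes$counts, file.path(d, "gene_counts.tsv"))
    note(file.path(tt, "gene_counts.tsv"), "gene_counts", tt)
    write_matrix_tsv(ty$mirnas$counts, file.path(d, "mirna_counts.tsv"))
    note(file.path(tt, "mirna_counts.tsv"), "mirna_counts", tt)
    sheet <- data.frame(sample_id = colnames(ty$genes$counts),
                        group = as.character(ty$genes$groups),
                        tumour_type = tt, stringsAsFactors = FALSE)
    write_tsv(sheet, file.path(d, "samples.tsv"))
    note(file.path(tt, "samples.tsv"), "samples", tt)
    write_matrix_tsv(ty$cna, file.path(d, "cna.tsv"))
    note(file.path(tt, "cna.tsv"), "cna", tt)
    if (nrow(ty$met_beta) > 0) {
      write_matrix_tsv(ty$met_beta, file.path(d, "met_beta.tsv"),
                       id_col = "probe")
      note(file.path(tt, "met_beta.tsv"), "met_beta", tt)
      write_tsv(ty$probe_map, file.path(d, "probe_map.tsv"))
      note(file.path(tt, "probe_map.tsv"), "probe_map", tt)
    } else {
      note(NA_character_, "met_absent", tt)
    }
    write_tsv(ty$clinical, file.path(d, "clinical.tsv"))
    note(file.path(tt, "clinical.tsv"), "clinical", tt)
  }

  write_tsv(data.frame(gene = names(cohort$gene_lengths),
                       length_bp = unname(cohort$gene_lengths)),
            file.path(directory, "gene_lengths.tsv"))
  note("gene_lengths.tsv", "gene_lengths")
  write_tsv(data.frame(mirna = names(cohort$mirna_lengths),
                       length_bp = unname(cohort$mirna_lengths)),
            file.path(directory, "mirna_lengths.tsv"))
  note("mirna_lengths.tsv", "mirna_lengths")
  write_tsv(cohort$targets, file.path(directory, "targets.tsv"))
  note("targets.tsv", "targets")
  write_gmt(cohort$pathways, file.path(directory, "pathways.gmt"))
  note("pathways.gmt", "pathways")
  writeLines(cohort$known_genes, file.path(directory, "known_genes.txt"))
  note("known_genes.txt", "known_genes")
  writeLines(cohort$known_mirnas, file.path(directory, "known_mirnas.txt"))
  note("known_mirnas.txt", "known_mirnas")
  write_tsv(cohort$known_pairs, file.path(directory, "known_pairs.tsv"))
  note("known_pairs.tsv", "known_pairs")
  writeLines(cohort$prad_like, file.path(directory, "prad_like.txt"))
  note("prad_like.txt", "prad_like")

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(directory, "manifest.tsv"))
  invisible(manifest)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param directory cohort directory.
#' @return a cohort list with the same structure as the \code{cohort}
#'   element of \code{\link{generate_cohort}}.
#' @export
read_cohort <- function(directory) {
  manifest <- read_tsv(file.path(directory, "manifest.tsv"))
  type_names <- unique(manifest$tumour_type[!is.na(manifest$tumour_type)])
  gl <- read_tsv(file.path(directory, "gene_lengths.tsv"))
  gene_lengths <- setNames(gl$length_bp, gl$gene)
  ml <- read_tsv(file.path(directory, "mirna_lengths.tsv"))
  mirna_lengths <- setNames(ml$length_bp, ml$mirna)

  types <- lapply(type_names, function(tt) {
    d <- file.path(directory, tt)
    sheet <- read_tsv(file.path(d, "samples.tsv"))
    genes <- count_matrix(read_matrix_tsv(file.path(d, "gene_counts.tsv")),
                          sheet$group, tt)
    mirnas <- count_matrix(read_matrix_tsv(file.path(d, "mirna_counts.tsv")),
                           sheet$group, tt)
    met_path <- file.path(d, "met_beta.tsv")
    if (file.exists(met_path)) {
      met_beta <- read_matrix_tsv(met_path)
      probe_map <- read_tsv(file.path(d, "probe_map.tsv"))
    } else {
      met_beta <- matrix(numeric(0), 0, 0)
      probe_map <- data.frame(probe = character(0), gene = character(0),
                              stringsAsFactors = FALSE)
    }
    list(genes = genes, mirnas = mirnas,
         cna = read_matrix_tsv(file.path(d, "cna.tsv")),
         met_beta = met_beta, probe_map = probe_map,
         clinical = read_tsv(file.path(d, "clinical.tsv"),
                             colClasses = c(stage_or_gleason = "character")))
  })
  names(types) <- type_names

  list(types = types, gene_lengths = gene_lengths,
       mirna_lengths = mirna_lengths,
       targets = read_tsv(file.path(directory, "targets.tsv")),
       pathways = read_gmt(file.path(directory, "pathways.gmt")),
       known_pairs = read_tsv(file.path(directory, "known_pairs.tsv")),
       known_genes = readLines(file.path(directory, "known_genes.txt")),
       known_mirnas = readLines(file.path(directory, "known_mirnas.txt")),
       prad_like = readLines(file.path(directory, "prad_like.txt"))[1],
       config = NULL)
}
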