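# Reading and writing the on-disk formats shared by the generator and the
# analysis modules: GFF3 gene annotation, operon table, peak lists,
# growth-curve CSV and residue-profile TSV. GFF3 is 1-based inclusive on
# disk (handled by rtracklayer); the in-memory annotation keeps the same
# 1-based convention in `start`/`end`.

#' Write a gene annotation to GFF3 (plus an operon table)
#'
#' @param annotation a `gene_annotation` data frame (see [sim_annotation()]).
#' @param gff_path output GFF3 path.
#' @param operon_path optional output TSV path for the operon table
#'   (`gene_id`, `operon_id`, `position_in_operon`).
#' @export
write_annotation <- function(annotation, gff_path, operon_path = NULL) {
  rl <- attr(annotation, "replicon_lengths")
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$locus_tag <- annotation$gene_id
  GenomeInfoDb::seqlengths(gr) <- rl[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(operon_path)) {
    write.table(data.frame(gene_id = annotation$gene_id,
                           operon_id = annotation$operon_id,
                           position_in_operon = annotation$operon_rank),
                operon_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(gff_path)
}

#' Read a gene annotation from GFF3 and an operon table
#'
#' Gene features (`type == "gene"`) are read from the GFF3; the start codon
#' is taken as the strand-appropriate end of the gene body. Operon
#' membership and order come from the operon table; genes absent from it are
#' treated as monocistronic.
#'
#' @param gff_path GFF3 file.
#' @param operon_path optional operon TSV (`gene_id`, `operon_id`,
#'   `position_in_operon`).
#' @return a `gene_annotation` data frame as produced by [sim_annotation()].
#' @export
read_annotation <- function(gff_path, operon_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$locus_tag
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("every gene needs a '+' or '-' strand", call. = FALSE)
  }
  ann <- data.frame(
    gene_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  ann$start_codon <- ifelse(ann$strand == "+", ann$start, ann$end)
  if (!is.null(operon_path)) {
    op <- read.delim(operon_path, stringsAsFactors = FALSE)
    i <- match(ann$gene_id, op$gene_id)
    ann$operon_id <- op$operon_id[i]
    ann$operon_rank <- op$position_in_operon[i]
  } else {
    ann$operon_id <- NA_character_
    ann$operon_rank <- NA_integer_
  }
  solo <- is.na(ann$operon_id)
  ann$operon_id[solo] <- paste0("mono_", ann$gene_id[solo])
  ann$operon_rank[solo] <- 1L
  rl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(rl))) {
    rl <- tapply(ann$end, ann$replicon, max) + 500
  }
  attr(ann, "replicon_lengths") <- rl
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read / write a binding-site (peak) table
#'
#' Columns: `tf`, `replicon`, `position`, `intensity`, `pvalue`.
#' @param path TSV path.
#' @export
read_peaks <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "replicon", "position", "pvalue")
  if (!all(need %in% names(x))) {
    stop("peak table must have columns tf, replicon, position, pvalue",
         call. = FALSE)
  }
  if (any(x$pvalue <= 0 | x$pvalue > 1)) {
    stop("peak p-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(x$position < 1)) stop("positions must be >= 1", call. = FALSE)
  x
}

#' @rdname read_peaks
#' @param sites peak data frame.
#' @export
write_peaks <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write residue-profile tables
#'
#' TSV with columns `tf`, `residues` (length-9 amino-acid strings).
#' @param path TSV path.
#' @return named character vector of profiles.
#' @export
read_residue_profiles <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "residues") %in% names(x)))
  setNames(x$residues, x$tf)
}

#' @rdname read_residue_profiles
#' @param profiles named character vector.
#' @export
write_residue_profiles <- function(profiles, path) {
  write.table(data.frame(tf = names(profiles), residues = unname(profiles)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a target map (tf, gene_id, provenance) to TSV
#'
#' @param target_map output of [assign_targets()].
#' @param path TSV path.
#' @export
write_target_map <- function(target_map, path) {
  write.table(as.data.frame(target_map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_map
#' @export
read_target_map <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("target_map", "data.frame")
  x
}
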