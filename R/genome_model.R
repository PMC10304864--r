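#' @importFrom methods as
#' @importFrom stats qt sd rbinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

# -- small sequence helpers (Biostrings-backed) -------------------------------

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

complement_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa))) stop("cannot translate codon(s): ",
                           paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

genome_subseq <- function(genome, from, to) substr(genome$sequence, from, to)

#' Load a single-record reference genome from FASTA
#'
#' @param path Path to a FASTA file holding exactly one nucleotide record over
#'   the alphabet A, C, G, T.
#' @return An object of class `genome_sequence`: a list with `id`, `sequence`
#'   (upper-case character string) and `length_bp`.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected a single-record FASTA, found %d records", length(set)))
  }
  seq <- toupper(as.character(set[[1]]))
  if (nchar(seq) == 0L) stop("FASTA record is empty")
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(seq, bad, bad), as.integer(bad)))
  }
  structure(list(id = sub("\\s.*$", "", names(set)[1]),
                 sequence = seq,
                 length_bp = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp\n", x$id, x$length_bp))
  invisible(x)
}

validate_gene_table <- function(genes, length_bp = NULL) {
  needed <- c("gene_no", "start", "end", "strand", "product")
  missing <- setdiff(needed, names(genes))
  if (length(missing)) stop("annotation lacks column(s): ",
                            paste(missing, collapse = ", "))
  genes$gene_no <- as.character(genes$gene_no)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_no)) stop("gene_no values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$end < genes$start)) stop("gene end before start")
  if (any(genes$end - genes$start + 1L < 3L)) stop("gene shorter than one codon")
  if (!is.null(length_bp) && any(genes$start < 1L | genes$end > length_bp)) {
    stop("gene span outside genome bounds")
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) > 1L && any(genes$start[-1] <= genes$end[-nrow(genes)])) {
    warning("overlapping gene spans; positions in overlaps are assigned to the first gene")
  }
  genes
}

#' Build a genome annotation from a gene table
#'
#' The native annotation format is a TSV with columns
#' `gene_no  start  end  strand  product` (1-based inclusive coordinates,
#' strand `+`/`-`). A data frame with those columns is accepted directly.
#'
#' @param x Path to a TSV file, or a data frame.
#' @param genome Optional `genome_sequence` used to bounds-check spans.
#' @return An object of class `genome_annotation`.
#' @export
read_gene_annotation <- function(x, genome = NULL) {
  genes <- if (is.character(x)) {
    read.delim(x, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character")
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  genes <- validate_gene_table(genes, if (!is.null(genome)) genome$length_bp)
  structure(list(genome_id = if (!is.null(genome)) genome$id else NA_character_,
                 genes = genes),
            class = "genome_annotation")
}

#' Read gene models from a GFF3 file
#'
#' Maps GFF3 `gene`/`CDS` features onto the same annotation type as
#' [read_gene_annotation()]. Requires the rtracklayer package.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type(s) to keep (default `c("gene", "CDS")`;
#'   the first type present is used).
#' @inheritParams read_gene_annotation
#' @export
read_gene_annotation_gff3 <- function(path, genome = NULL,
                                      feature_type = c("gene", "CDS")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  keep <- feature_type[feature_type %in% as.character(gr$type)][1]
  if (is.na(keep)) stop("no features of type ", paste(feature_type, collapse = "/"))
  gr <- gr[as.character(gr$type) == keep]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  prod <- if (!is.null(gr$product)) as.character(gr$product) else rep("", length(gr))
  genes <- data.frame(gene_no = ids,
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      strand = as.character(BiocGenerics::strand(gr)),
                      product = prod,
                      stringsAsFactors = FALSE)
  read_gene_annotation(genes, genome)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d gene model(s)\n", nrow(x$genes)))
  invisible(x)
}

gene_by_no <- function(annotation, gene_no) {
  i <- match(as.character(gene_no), annotation$genes$gene_no)
  if (is.na(i)) stop("no gene numbered ", gene_no, " in annotation")
  annotation$genes[i, , drop = FALSE]
}

#' Coding-strand nucleotide index of a genomic position within a gene
#'
#' For forward-strand genes the index counts from the gene start; for
#' reverse-strand genes it counts from the gene end, so that index 1 is
#' always the first base of the coding sequence.
#'
#' @param gene One row of an annotation's gene table (or a list with
#'   `start`, `end`, `strand`).
#' @param position 1-based genome coordinate inside the gene span.
#' @return 1-based coding-strand nucleotide index.
#' @export
nt_index_in_gene <- function(gene, position) {
  position <- as.integer(position)
  if (position < gene$start || position > gene$end) {
    stop(sprintf("position %d outside gene span %d..%d",
                 position, gene$start, gene$end))
  }
  if (gene$strand == "+") position - gene$start + 1L else gene$end - position + 1L
}

# reference codon on the coding strand for a 1-based codon number
gene_ref_codon <- function(genome, gene, codon_number) {
  if (gene$strand == "+") {
    p1 <- gene$start + 3L * (codon_number - 1L)
    genome_subseq(genome, p1, p1 + 2L)
  } else {
    hi <- gene$end - 3L * (codon_number - 1L)
    revcomp(genome_subseq(genome, hi - 2L, hi))
  }
}

#' Locate a genomic position relative to the gene models
#'
#' Maps a 1-based genome coordinate to its containing gene, codon number,
#' within-codon offset and reference codon (read on the coding strand,
#' i.e. reverse-complemented for reverse-strand genes), or to the flanking
#' gene pair for intergenic positions.
#'
#' @param annotation A `genome_annotation`.
#' @param genome A `genome_sequence`.
#' @param position 1-based genome coordinate.
#' @return A list of class `locus_context`. Genic loci carry `gene_no`,
#'   `strand`, `codon_number`, `within_codon_offset` and `ref_codon`;
#'   intergenic loci carry `upstream_no` and `downstream_no` (NA at the
#'   genome ends).
#' @export
locate_position <- function(annotation, genome, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > genome$length_bp) {
    stop(sprintf("position %s outside genome bounds 1..%d",
                 position, genome$length_bp))
  }
  genes <- annotation$genes
  hit <- which(genes$start <= position & genes$end >= position)
  if (length(hit) == 0L) {
    up <- genes$gene_no[genes$end < position]
    down <- genes$gene_no[genes$start > position]
    return(structure(list(kind = "intergenic",
                          position = position,
                          upstream_no = if (length(up)) up[length(up)] else NA_character_,
                          downstream_no = if (length(down)) down[1] else NA_character_),
                     class = "locus_context"))
  }
  if (length(hit) > 1L) {
    warning(sprintf("position %d falls in %d overlapping genes; using gene %s",
                    position, length(hit), genes$gene_no[hit[1]]))
    hit <- hit[1]
  }
  gene <- genes[hit, , drop = FALSE]
  nt_idx <- nt_index_in_gene(gene, position)
  codon_number <- (nt_idx - 1L) %/% 3L + 1L
  offset <- (nt_idx - 1L) %% 3L + 1L
  gene_len <- gene$end - gene$start + 1L
  n_codons <- gene_len %/% 3L
  ref_codon <- NA_character_
  if (codon_number > n_codons) {
    warning(sprintf(
      "position %d lies in the trailing partial codon of gene %s (length %d not a multiple of 3)",
      position, gene$gene_no, gene_len))
  } else {
    ref_codon <- gene_ref_codon(genome, gene, codon_number)
  }
  structure(list(kind = "genic",
                 position = position,
                 gene_no = gene$gene_no,
                 strand = gene$strand,
                 codon_number = codon_number,
                 within_codon_offset = offset,
                 ref_codon = ref_codon),
            class = "locus_context")
}

#' @export
print.locus_context <- function(x, ...) {
  if (x$kind == "genic") {
    cat(sprintf("<locus> pos %d: gene %s (%s) codon %d offset %d ref %s\n",
                x$position, x$gene_no, x$strand, x$codon_number,
                x$within_codon_offset, x$ref_codon))
  } else {
    cat(sprintf("<locus> pos %d: intergenic between genes %s and %s\n",
                x$position, x$upstream_no, x$downstream_no))
  }
  invisible(x)
}
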