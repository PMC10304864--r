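# Shared fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    fixture_cache$fx <- build_fixture_genome(seed = 101)
  }
  fixture_cache$fx
}

get_isolate_annotations <- function() {
  if (is.null(fixture_cache$iso_ann)) {
    fx <- get_fixture()
    fixture_cache$iso_ann <- annotate_mutations(fixture_isolate_mutations(),
                                                fx$genome, fx$annotation)
  }
  fixture_cache$iso_ann
}

get_population_annotations <- function() {
  if (is.null(fixture_cache$pop_ann)) {
    fx <- get_fixture()
    fixture_cache$pop_ann <- annotate_mutations(fixture_population_mutations(),
                                                fx$genome, fx$annotation)
  }
  fixture_cache$pop_ann
}

# positions whose published impact label the default property scheme
# reproduces (the remainder disagree with any single charge/polarity/volume
# table and are excluded from label assertions, never from codon/effect ones)
label_reproducible_positions <- c(11048, 19245, 19261, 19272, 28296, 28321,
                                  28383, 28411, 28446, 28463, 28469, 31700,
                                  31718, 35091, 38211, 38215, 39132, 48412)

# random genome + annotation for property-style tests
random_genome <- function(length_bp, seed) {
  set.seed(seed)
  structure(list(id = "rand",
                 sequence = paste(sample(c("A", "C", "G", "T"), length_bp,
                                         replace = TRUE), collapse = ""),
                 length_bp = length_bp),
            class = "genome_sequence")
}

# reverse-complement a genome and flip its annotation so that position p
# maps to length - p + 1
flip_genome <- function(genome) {
  structure(list(id = genome$id,
                 sequence = as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(genome$sequence))),
                 length_bp = genome$length_bp),
            class = "genome_sequence")
}

flip_annotation <- function(annotation, length_bp) {
  g <- annotation$genes
  flipped <- data.frame(gene_no = g$gene_no,
                        start = length_bp - g$end + 1L,
                        end = length_bp - g$start + 1L,
                        strand = ifelse(g$strand == "+", "-", "+"),
                        product = g$product,
                        stringsAsFactors = FALSE)
  read_gene_annotation(flipped)
}

# binary disk mask for particle-analysis unit tests
disk_mask <- function(nr, nc, ci, cj, r_px) {
  row_i <- matrix(seq_len(nr), nr, nc)
  col_j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (row_i - ci)^2 + (col_j - cj)^2 <= r_px^2
}

# nearest-detection matching of rendered truth to measured plaques
match_detections <- function(truth, detections) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((detections$centroid_x_mm - truth$x_mm[i])^2 +
              (detections$centroid_y_mm - truth$y_mm[i])^2)
    which.min(d)
  }, integer(1))
}
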