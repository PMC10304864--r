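# Synthetic-data generators: a fixture phage genome whose gene models and
# reference codons are consistent with the packaged mutation tables, plus
# generators for null mutation sets, adsorption assay counts, rendered plate
# images and population-dynamics series. Every generator is deterministic
# under a fixed seed.

#' Gene models of the fixture phage genome
#'
#' Spans for the two tail fiber genes (52, 57) are fixed by the packaged
#' mutation tables (gene 52 forward 24741..28516, 3,776 bp; gene 57 reverse
#' 31608..33980, 2,373 nt). The remaining genes have assumed minimal spans
#' (flagged `derived = TRUE`) chosen to be consistent with every genic and
#' intergenic call in the packaged tables.
#'
#' @return Data frame with columns `gene_no`, `start`, `end`, `strand`,
#'   `product`, `derived`.
#' @export
fixture_gene_table <- function() {
  data.frame(
    gene_no = c("33", "46", "47", "52", "57", "58", "59", "61", "62", "63", "85"),
    start = c(10701L, 18399L, 19253L, 24741L, 31608L, 34200L, 35200L,
              36500L, 38300L, 38559L, 48276L),
    end = c(11600L, 19244L, 19852L, 28516L, 33980L, 35000L, 35901L,
            37699L, 38500L, 39500L, 48455L),
    strand = c("+", "+", "+", "+", "-", "+", "+", "+", "+", "+", "-"),
    product = c("Portal protein", "Tail tape measure protein",
                "Tail tape measure protein", "Tail fiber protein",
                "Tail fiber protein", "DNA primase",
                "Transcriptional regulator", "Endonuclease",
                "Hypothetical protein", "Methylase", "Hypothetical protein"),
    derived = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Expected annotations of the packaged mutation catalog
#'
#' One row per distinct mutation across the packaged isolate and population
#' tables, with the codon pair, substitution label and effect class each
#' mutation must produce when annotated against the fixture genome, plus the
#' published impact label. Used by the fixture builder's internal
#' consistency oracle and by the round-trip tests.
#'
#' @return Data frame.
#' @export
fixture_expected_annotations <- function() {
  tab <- rbind(
    c("11048", "T->G", "33", "CGT", "CGG", "R116R", "synonymous", "Synonymous"),
    c("19245", "T->G", NA, NA, NA, NA, "intergenic", "Not applicable"),
    c("19261", "A->T", "47", "GTA", "GTT", "V3V", "synonymous", "Synonymous"),
    c("19272", "C->G", "47", "GCT", "GGT", "A7G", "nonsynonymous", "Nonpolar to polar"),
    c("28296", "C->A", "52", "CAT", "AAT", "H1186N", "nonsynonymous", "Positive to neutral, large to small"),
    c("28321", "C->A", "52", "ACG", "AAG", "T1194K", "nonsynonymous", "Neutral to positive, small to large"),
    c("28380", "C->A", "52", "CAA", "AAA", "Q1214K", "nonsynonymous", "Neutral to positive, small to large"),
    c("28381", "A->G", "52", "CAA", "CGA", "Q1214R", "nonsynonymous", "Neutral to positive, small to large"),
    c("28383", "G->A", "52", "GCT", "ACT", "A1215T", "nonsynonymous", "Nonpolar to polar"),
    c("28411", "G->T", "52", "GGA", "GTA", "G1224V", "nonsynonymous", "Polar to nonpolar"),
    c("28446", "C->A", "52", "CTT", "ATT", "L1236I", "nonsynonymous", "Nonsynonymous conserved"),
    c("28463", "C->G", "52", "AAC", "AAG", "N1241K", "nonsynonymous", "Neutral to positive, small to large"),
    c("28469", "C->A", "52", "AAC", "AAA", "N1243K", "nonsynonymous", "Neutral to positive, small to large"),
    c("31700", "+82 bp", "57", NA, NA, NA, "frameshift", "Frame-shifting insertion"),
    c("31718", "+86 bp", "57", NA, NA, NA, "frameshift", "Frame-shifting insertion"),
    c("31917", "C->A", "57", "AAG", "AAT", "K688N", "nonsynonymous", "Positive to neutral, small to large"),
    c("35091", "(A)8->7", NA, NA, NA, NA, "intergenic", "Not applicable"),
    c("38211", "del 1 bp", NA, NA, NA, NA, "intergenic", "Not applicable"),
    c("38215", "(T)5->4", NA, NA, NA, NA, "intergenic", "Not applicable"),
    c("39132", "T->G", "63", "TTT", "GTT", "F192V", "nonsynonymous", "Large to small"),
    c("39139", "C->A", "63", "TCT", "TAT", "S194Y", "nonsynonymous", "Polar to nonpolar, small to large"),
    c("48412", "G->T", "85", "TCA", "TAA", "S15*", "nonsense", "Early stop codon"),
    c("48438", "G->T", "85", "TTC", "TTA", "F6L", "nonsynonymous", "Large to small"),
    c("48444", "T->A", "85", "TTA", "TTT", "L4F", "nonsynonymous", "Small to large"),
    c("48446", "A->C", "85", "TTA", "GTA", "L4V", "nonsynonymous", "Nonsynonymous conserved"))
  out <- data.frame(position = as.integer(tab[, 1]), bp_change = tab[, 2],
                    gene_no = tab[, 3], ref_codon = tab[, 4],
                    alt_codon = tab[, 5], aa_label = tab[, 6],
                    effect = tab[, 7], published_impact = tab[, 8],
                    stringsAsFactors = FALSE)
  out
}

# codon embeddings implied by the expected annotations, plus intergenic
# reference bases and homopolymer runs
fixture_embeddings <- function() {
  exp <- fixture_expected_annotations()
  genic <- exp[!is.na(exp$ref_codon), ]
  codon_no <- as.integer(sub("^[A-Z*]([0-9]+)[A-Z*]$", "\\1", genic$aa_label))
  list(codons = data.frame(gene_no = genic$gene_no, codon_number = codon_no,
                           ref_codon = genic$ref_codon,
                           stringsAsFactors = FALSE),
       bases = data.frame(position = 19245L, base = "T",
                          stringsAsFactors = FALSE),
       homopolymers = data.frame(base = c("A", "T"),
                                 start = c(35091L, 38211L),
                                 length = c(8L, 5L),
                                 stringsAsFactors = FALSE))
}

#' Build the fixture phage genome and annotation
#'
#' Generates a random 49,223 bp background sequence (deterministic under
#' `seed`), embeds the reference codons, intergenic bases and homopolymer
#' runs required by the packaged mutation tables, and verifies the result
#' with an internal consistency oracle that re-annotates every catalogued
#' mutation and aborts on any mismatch.
#'
#' @param seed Integer seed for the background sequence.
#' @param dir Optional output directory; writes `genome.fa`, `genes.tsv` and
#'   a `genome_truth.json` sidecar of generator parameters.
#' @param genome_length Genome length in bp (default 49223).
#' @return List with `genome` (a `genome_sequence`), `annotation`
#'   (a `genome_annotation`), `gene_table` and, when `dir` is given, `paths`.
#' @export
build_fixture_genome <- function(seed = 1, dir = NULL, genome_length = 49223L) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  emb <- fixture_embeddings()
  genes <- fixture_gene_table()
  for (i in seq_len(nrow(emb$codons))) {
    g <- genes[genes$gene_no == emb$codons$gene_no[i], ]
    codon <- emb$codons$ref_codon[i]
    k <- emb$codons$codon_number[i]
    if (g$strand == "+") {
      p1 <- g$start + 3L * (k - 1L)
      bases[p1:(p1 + 2L)] <- strsplit(codon, "")[[1]]
    } else {
      hi <- g$end - 3L * (k - 1L)
      bases[(hi - 2L):hi] <- strsplit(revcomp(codon), "")[[1]]
    }
  }
  for (i in seq_len(nrow(emb$bases))) {
    bases[emb$bases$position[i]] <- emb$bases$base[i]
  }
  for (i in seq_len(nrow(emb$homopolymers))) {
    h <- emb$homopolymers[i, ]
    run <- h$start:(h$start + h$length - 1L)
    bases[run] <- h$base
    # terminate the run so its printed length is exact
    for (p in c(h$start - 1L, h$start + h$length)) {
      if (p >= 1L && p <= genome_length && bases[p] == h$base) bases[p] <- "C"
    }
  }
  genome <- structure(list(id = "fixture_phage",
                           sequence = paste(bases, collapse = ""),
                           length_bp = genome_length),
                      class = "genome_sequence")
  annotation <- read_gene_annotation(genes[, c("gene_no", "start", "end",
                                               "strand", "product")], genome)
  verify_fixture_consistency(genome, annotation)
  out <- list(genome = genome, annotation = annotation, gene_table = genes)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    dss <- Biostrings::DNAStringSet(genome$sequence)
    names(dss) <- genome$id
    Biostrings::writeXStringSet(dss, fa)
    gt <- file.path(dir, "genes.tsv")
    write.table(genes, gt, sep = "\t", quote = FALSE, row.names = FALSE)
    js <- file.path(dir, "genome_truth.json")
    jsonlite::write_json(list(seed = seed, genome_length = genome_length,
                              n_genes = nrow(genes)),
                         js, auto_unbox = TRUE)
    out$paths <- c(genome = fa, genes = gt, truth = js)
  }
  out
}

# re-annotate every catalogued mutation and abort on the first mismatch
verify_fixture_consistency <- function(genome, annotation) {
  exp <- fixture_expected_annotations()
  rec <- parse_mutation_table(data.frame(position = exp$position,
                                         bp_change = exp$bp_change,
                                         source_id = "oracle",
                                         stringsAsFactors = FALSE))
  ann <- annotate_mutations(rec, genome, annotation)
  for (i in seq_len(nrow(exp))) {
    ok <- ann$effect[i] == exp$effect[i] &&
      identical(ann$gene_no[i], exp$gene_no[i]) &&
      (is.na(exp$ref_codon[i]) ||
         (identical(ann$ref_codon[i], exp$ref_codon[i]) &&
          identical(ann$alt_codon[i], exp$alt_codon[i]) &&
          identical(ann$aa_label[i], exp$aa_label[i])))
    if (!ok) {
      stop(sprintf(
        "fixture consistency oracle failed at position %d (%s): got gene %s %s/%s %s [%s], expected gene %s %s/%s %s [%s]",
        exp$position[i], exp$bp_change[i],
        ann$gene_no[i], ann$ref_codon[i], ann$alt_codon[i], ann$aa_label[i], ann$effect[i],
        exp$gene_no[i], exp$ref_codon[i], exp$alt_codon[i], exp$aa_label[i], exp$effect[i]))
    }
  }
  invisible(TRUE)
}

fixture_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phagevo")
  if (path == "") stop("packaged fixture not found: ", file)
  path
}

#' Packaged isolate mutation records
#'
#' Long-format transcription of the published isolate mutation grid: one row
#' per (mutation, isolate) occurrence, with the source population.
#' @return Parsed mutation records (see [parse_mutation_table()]).
#' @export
fixture_isolate_mutations <- function() {
  parse_mutation_table(fixture_extdata("isolate_mutations.tsv"))
}

#' Packaged population mutation records
#'
#' Long-format transcription of the published whole-population sequencing
#' table, with read-support frequencies.
#' @return Parsed mutation records with `frequency`.
#' @export
fixture_population_mutations <- function() {
  parse_mutation_table(fixture_extdata("population_mutations.tsv"))
}

#' Packaged ancestral-stock polymorphisms
#'
#' @return Data frame with `position`, `bp_change`, `frequency`.
#' @export
fixture_stock_polymorphisms <- function() {
  read.delim(fixture_extdata("stock_polymorphisms.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Generate mutation sets under the uniform-placement null
#'
#' Each population receives `m_per_population` mutations at independent
#' uniform positions; SNV alleles are drawn uniformly (reference base
#' uniform over A/C/G/T, alternate uniform over the remaining three).
#' Positions are not tied to any genome sequence: records are intended for
#' placement statistics, not codon annotation.
#'
#' @param n_populations,m_per_population Experiment shape (m >= 0).
#' @param genome_length Genome length in bp.
#' @param seed Integer seed.
#' @return Data frame: `position`, `bp_change`, `source_id`, `population`.
#' @export
generate_null_mutations <- function(n_populations, m_per_population,
                                    genome_length, seed = 1) {
  set.seed(seed)
  n <- n_populations * m_per_population
  if (n == 0) {
    return(data.frame(position = integer(0), bp_change = character(0),
                      source_id = character(0), population = character(0)))
  }
  pop <- rep(sprintf("pop%02d", seq_len(n_populations)),
             each = m_per_population)
  pos <- sample.int(genome_length, n, replace = TRUE)
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  data.frame(position = pos, bp_change = paste0(ref, "->", alt),
             source_id = pop, population = pop, stringsAsFactors = FALSE)
}

#' Generate adsorption assay plate counts with known true rate
#'
#' Free phage decay exponentially: `E[T1] = T0 * exp(-rate * density * time)`.
#' Plate counts at the given dilutions are Poisson-sampled.
#'
#' @param true_rate True adsorption rate (mL cell^-1 h^-1).
#' @param time_h Incubation time (default 0.5 h).
#' @param cell_density Host density (default 2e9 cells/mL).
#' @param t0_titer Starting titer (default 1e6 PFU/mL).
#' @param n_replicates Replicates (default 9).
#' @param plated_volume_mL Plated volume (default 0.1 mL).
#' @param dilution_t0,dilution_t1 Plating dilution factors (default 1e3).
#' @param seed Integer seed.
#' @return Assay data frame for [adsorption_rates_from_counts()], with the
#'   generator parameters attached as attribute `"truth"`.
#' @export
generate_adsorption_counts <- function(true_rate, time_h = 0.5,
                                       cell_density = 2e9, t0_titer = 1e6,
                                       n_replicates = 9,
                                       plated_volume_mL = 0.1,
                                       dilution_t0 = 1e3, dilution_t1 = 1e3,
                                       seed = 1) {
  if (t0_titer <= 0 || time_h <= 0 || cell_density <= 0) {
    stop("t0_titer, time_h and cell_density must be > 0")
  }
  set.seed(seed)
  t1_titer <- t0_titer * exp(-true_rate * cell_density * time_h)
  lam0 <- t0_titer * plated_volume_mL / dilution_t0
  lam1 <- t1_titer * plated_volume_mL / dilution_t1
  if (lam0 < 1 || lam1 < 1) {
    warning(sprintf("expected plate count < 1 (T0 %.3g, T1 %.3g); assay uninformative",
                    lam0, lam1))
  }
  out <- data.frame(replicate_id = seq_len(n_replicates),
                    t0_count = rpois(n_replicates, lam0),
                    t1_count = rpois(n_replicates, lam1),
                    dilution_t0 = dilution_t0, dilution_t1 = dilution_t1,
                    volume_mL = plated_volume_mL, time_h = time_h,
                    cell_density = cell_density)
  attr(out, "truth") <- list(true_rate = true_rate, t0_titer = t0_titer,
                             t1_titer = t1_titer, seed = seed)
  out
}

#' Render a synthetic plate image with known plaque diameters
#'
#' Anti-aliased bright disks (plaques) on a darker lawn with an optional
#' linear illumination gradient and Gaussian pixel noise. Plaque centres are
#' rejection-sampled to be non-overlapping and fully inside the elliptical
#' region of interest.
#'
#' @param plaque_diameters_mm Vector of true plaque diameters (mm).
#' @param mm_per_px Render scale (default 0.15 mm/px).
#' @param lawn_intensity,plaque_intensity 8-bit intensities (defaults 60, 210).
#' @param illumination_gradient Peak-to-peak linear gradient across the
#'   plate, in intensity units (default 20; 0 disables).
#' @param noise_sd Gaussian pixel noise SD (default 5; 0 disables).
#' @param seed Integer seed.
#' @param plate_diameter_mm Plate diameter (default 86).
#' @param roi_width_mm,roi_height_mm ROI ellipse (default 72.24 x 72.24).
#' @param min_gap_mm Minimum gap between plaque rims (default 1).
#' @param max_tries Placement attempts per plaque before giving up.
#' @param dir Optional output directory (PNG + truth CSV + params JSON;
#'   PNG written only if the png package is available).
#' @return List: `image` (a `plate_image`), `truth` (centres and diameters),
#'   `params`.
#' @export
generate_plate_image <- function(plaque_diameters_mm, mm_per_px = 0.15,
                                 lawn_intensity = 60, plaque_intensity = 210,
                                 illumination_gradient = 20, noise_sd = 5,
                                 seed = 1, plate_diameter_mm = 86,
                                 roi_width_mm = 72.24, roi_height_mm = 72.24,
                                 min_gap_mm = 1, max_tries = 20000,
                                 dir = NULL) {
  set.seed(seed)
  npx <- round(plate_diameter_mm / mm_per_px)
  cx <- (npx + 1) / 2 * mm_per_px   # centre in mm
  a <- roi_width_mm / 2; b <- roi_height_mm / 2
  r_mm <- plaque_diameters_mm / 2
  ord <- order(r_mm, decreasing = TRUE)   # place big plaques first
  xs <- ys <- numeric(length(r_mm))
  placed <- logical(length(r_mm))
  for (i in ord) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, cx - a, cx + a); y <- runif(1, cx - b, cx + b)
      margin <- r_mm[i] + min_gap_mm
      if (((x - cx) / (a - margin))^2 + ((y - cx) / (b - margin))^2 > 1) next
      if (any(placed & sqrt((xs - x)^2 + (ys - y)^2) <
                (r_mm + r_mm[i] + min_gap_mm))) next
      xs[i] <- x; ys[i] <- y; placed[i] <- TRUE; ok <- TRUE
      break
    }
    if (!ok) stop("could not place all plaques without overlap; ",
                  "reduce their number or size")
  }
  col_x <- (seq_len(npx) - 0.5) * mm_per_px
  grad_row <- if (illumination_gradient > 0) {
    illumination_gradient * (col_x / plate_diameter_mm - 0.5)
  } else rep(0, npx)
  img <- matrix(lawn_intensity, npx, npx) +
    matrix(grad_row, npx, npx, byrow = TRUE)
  for (i in seq_along(r_mm)) {
    r_px <- r_mm[i] / mm_per_px
    ci <- ys[i] / mm_per_px + 0.5; cj <- xs[i] / mm_per_px + 0.5
    ri <- max(1, floor(ci - r_px - 2)):min(npx, ceiling(ci + r_px + 2))
    rj <- max(1, floor(cj - r_px - 2)):min(npx, ceiling(cj + r_px + 2))
    d <- sqrt(outer((ri - ci)^2, (rj - cj)^2, "+"))
    alpha <- pmin(1, pmax(0, r_px + 0.5 - d))
    target <- plaque_intensity +
      matrix(grad_row[rj], length(ri), length(rj), byrow = TRUE)
    img[ri, rj] <- img[ri, rj] * (1 - alpha) + alpha * target
  }
  # dark rim outside the physical plate
  row_i <- matrix(seq_len(npx), npx, npx)
  col_j <- t(row_i)
  cpx <- (npx + 1) / 2
  outside <- (row_i - cpx)^2 + (col_j - cpx)^2 > (plate_diameter_mm / 2 / mm_per_px)^2
  img[outside] <- 15
  if (noise_sd > 0) img <- img + rnorm(npx * npx, sd = noise_sd)
  img <- pmin(pmax(img, 0), 255)
  image <- plate_image(img, mm_per_px, plate_diameter_mm,
                       roi_width_mm, roi_height_mm)
  truth <- data.frame(x_mm = xs, y_mm = ys, diameter_mm = plaque_diameters_mm)
  params <- list(mm_per_px = mm_per_px, lawn_intensity = lawn_intensity,
                 plaque_intensity = plaque_intensity,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(truth, file.path(dir, "plate_truth.csv"), row.names = FALSE)
    jsonlite::write_json(params, file.path(dir, "plate_params.json"),
                         auto_unbox = TRUE)
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(img / 255, file.path(dir, "plate.png"))
    }
  }
  list(image = image, truth = truth, params = params)
}

#' Generate titer and resistance series with known fates
#'
#' Emulates serial-passage dynamics: all populations rise by day 1;
#' extinction-bound populations then decline below the titer detection limit
#' around day 5 and never recover, survival-bound populations persist well
#' above it. Cross-streak resistance counts are drawn binomially with
#' resistance rising over the experiment.
#'
#' @param n_populations Number of replicate populations (default 10).
#' @param extinction_fraction Fraction of populations bound for extinction
#'   (default 0.5).
#' @param n_days Experiment length in days (default 10).
#' @param detection_limit Titer detection limit (default 100 PFU/mL).
#' @param seed Integer seed.
#' @return List: `titers` (population, day, titer with NA = below
#'   detection), `resistance` (population, day, n_tested, n_sensitive),
#'   `truth` (population, fate, extinction_day).
#' @export
generate_dynamics <- function(n_populations = 10, extinction_fraction = 0.5,
                              n_days = 10, detection_limit = 100, seed = 1) {
  if (extinction_fraction < 0 || extinction_fraction > 1) {
    stop("extinction_fraction must lie in [0,1]")
  }
  set.seed(seed)
  n_ext <- round(extinction_fraction * n_populations)
  fate <- sample(rep(c("extinction_bound", "survival_bound"),
                     c(n_ext, n_populations - n_ext)))
  pops <- sprintf("pop%02d", seq_len(n_populations))
  titer_rows <- list(); truth_rows <- list()
  for (i in seq_len(n_populations)) {
    days <- 0:n_days
    log10_titer <- numeric(length(days))
    log10_titer[1] <- 4                          # inoculum
    log10_titer[2] <- rnorm(1, 8, 0.2)           # growth on sensitive hosts
    if (fate[i] == "extinction_bound") {
      e_day <- sample(4:6, 1)
      for (d in 3:length(days)) {
        day <- days[d]
        log10_titer[d] <- if (day >= e_day) NA else
          max(log10(detection_limit) + 1,
              log10_titer[2] - (log10_titer[2] - 2.5) * (day - 1) / (e_day - 1) +
                rnorm(1, 0, 0.2))
      }
      ext_day <- e_day
    } else {
      for (d in 3:length(days)) {
        log10_titer[d] <- max(4, rnorm(1, 6, 0.8))
      }
      ext_day <- NA_real_
    }
    titer_rows[[i]] <- data.frame(population = pops[i], day = days,
                                  titer = 10^log10_titer,
                                  stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(population = pops[i], fate = fate[i],
                                  extinction_day = ext_day,
                                  stringsAsFactors = FALSE)
  }
  res_days <- c(1, 5, 10); res_n <- c(20, 40, 20); res_p <- c(0.6, 0.9, 0.99)
  res_rows <- lapply(seq_len(n_populations), function(i) {
    data.frame(population = pops[i], day = res_days, n_tested = res_n,
               n_sensitive = rbinom(length(res_days), res_n, 1 - res_p),
               stringsAsFactors = FALSE)
  })
  list(titers = do.call(rbind, titer_rows),
       resistance = do.call(rbind, res_rows),
       truth = do.call(rbind, truth_rows))
}
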