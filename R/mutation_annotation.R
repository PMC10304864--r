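# Parsing of mutation tables, codon-level annotation, amino-acid property
# classification and isolate/population summaries.

normalize_bp_change <- function(s) {
  s <- gsub("→", "->", s)          # arrow
  s <- gsub("Δ", "del", s)         # capital delta
  s <- gsub("_", "", s)
  s <- gsub("\\s+", " ", trimws(s))
  s
}

#' Parse one BP-change descriptor
#'
#' Accepts the dialect of published mutation tables: `"C->A"` (SNV),
#' `"(A)8->7"` (homopolymer run change, normalised to an indel of the net
#' length), `"+82 bp"` (insertion), `"del 1 bp"` / `"Δ1 bp"` (deletion).
#'
#' @param s A single descriptor string.
#' @return A list with `change_kind` and kind-specific fields.
#' @export
parse_bp_change <- function(s) {
  raw <- s
  s <- normalize_bp_change(s)
  m <- regmatches(s, regexec("^([ACGT]) ?-> ?([ACGT])$", s))[[1]]
  if (length(m)) {
    if (m[2] == m[3]) stop("SNV with identical alleles: ", raw)
    return(list(change_kind = "snv", ref_base = m[2], alt_base = m[3]))
  }
  m <- regmatches(s, regexec("^\\(([ACGT])\\)([0-9]+) ?-> ?([0-9]+)$", s))[[1]]
  if (length(m)) {
    from <- as.integer(m[3]); to <- as.integer(m[4])
    if (from == to) stop("homopolymer change with equal run lengths: ", raw)
    return(list(change_kind = if (to < from) "homopolymer_contraction"
                              else "homopolymer_expansion",
                hp_base = m[2], hp_from = from, hp_to = to,
                indel_length = abs(from - to)))
  }
  m <- regmatches(s, regexec("^\\+ ?([0-9]+) ?bp$", s))[[1]]
  if (length(m)) {
    return(list(change_kind = "insertion", indel_length = as.integer(m[2])))
  }
  m <- regmatches(s, regexec("^del ?([0-9]+) ?bp$", s))[[1]]
  if (length(m)) {
    return(list(change_kind = "deletion", indel_length = as.integer(m[2])))
  }
  stop("unparseable BP-change string: ", raw)
}

parse_frequency <- function(x) {
  if (is.na(x) || x == "") return(NA_real_)
  x <- trimws(as.character(x))
  if (grepl("%$", x)) {
    v <- as.numeric(sub("%$", "", x))
    if (is.na(v) || v < 0 || v > 100) stop("frequency outside [0,100]%: ", x)
    return(v / 100)
  }
  v <- as.numeric(x)
  if (is.na(v) || v < 0 || v > 1) stop("frequency outside [0,1]: ", x)
  v
}

# canonical (position, change) key used for uniqueness and matching
change_key <- function(position, parsed) {
  desc <- switch(parsed$change_kind,
    snv = paste0(parsed$ref_base, ">", parsed$alt_base),
    insertion = paste0("ins", parsed$indel_length),
    deletion = paste0("del", parsed$indel_length),
    homopolymer_contraction = paste0("del", parsed$indel_length),
    homopolymer_expansion = paste0("ins", parsed$indel_length))
  paste0(position, ":", desc)
}

#' Parse a mutation table
#'
#' Reads a TSV with columns `position`, `bp_change`, `source_id` and
#' optionally `frequency` (read-support fraction, `"77.2%"` or `0.772`) and
#' `population`. Thousands separators in positions are tolerated.
#'
#' @param x Path to a TSV file (`#` comments allowed) or a data frame.
#' @return A data frame of mutation records, one row per (mutation, source),
#'   with parsed change fields and a canonical `change_key`.
#' @export
parse_mutation_table <- function(x) {
  tab <- if (is.character(x)) {
    read.delim(x, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character")
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (!all(c("position", "bp_change") %in% names(tab))) {
    stop("mutation table needs columns 'position' and 'bp_change'")
  }
  if (is.null(tab$source_id)) tab$source_id <- NA_character_
  n <- nrow(tab)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- as.integer(gsub("[, ]", "", tab$position[i]))
    if (is.na(pos) || pos < 1L) stop("bad position in row ", i, ": ", tab$position[i])
    parsed <- tryCatch(parse_bp_change(tab$bp_change[i]),
                       error = function(e) stop("row ", i, ": ", conditionMessage(e)))
    freq <- if (!is.null(tab$frequency)) {
      tryCatch(parse_frequency(tab$frequency[i]),
               error = function(e) stop("row ", i, ": ", conditionMessage(e)))
    } else NA_real_
    out[[i]] <- data.frame(
      position = pos,
      change_kind = parsed$change_kind,
      ref_base = parsed$ref_base %||% NA_character_,
      alt_base = parsed$alt_base %||% NA_character_,
      indel_length = parsed$indel_length %||% NA_integer_,
      hp_base = parsed$hp_base %||% NA_character_,
      hp_from = parsed$hp_from %||% NA_integer_,
      hp_to = parsed$hp_to %||% NA_integer_,
      source_id = as.character(tab$source_id[i]),
      population = if (!is.null(tab$population)) as.character(tab$population[i]) else NA_character_,
      frequency = freq,
      change_key = change_key(pos, parsed),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- amino-acid property classification ---------------------------------------

#' Default amino-acid property table
#'
#' Classifies the 20 standard residues by charge (positive/negative/neutral),
#' polarity (polar/nonpolar) and side-chain volume (small/large). The scheme:
#' charge positive K, R, H; negative D, E; polar C, D, E, G, H, K, N, Q, R, S,
#' T, W, Y; small A, C, D, G, N, P, S, T, V. Users may supply their own table
#' of the same shape to [classify_property_change()].
#'
#' @return Data frame with columns `aa`, `charge`, `polarity`, `volume`.
#' @export
aa_property_table <- function() {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  charge <- ifelse(aa %in% c("K", "R", "H"), "positive",
                   ifelse(aa %in% c("D", "E"), "negative", "neutral"))
  polar <- c("C","D","E","G","H","K","N","Q","R","S","T","W","Y")
  small <- c("A","C","D","G","N","P","S","T","V")
  data.frame(aa = aa,
             charge = charge,
             polarity = ifelse(aa %in% polar, "polar", "nonpolar"),
             volume = ifelse(aa %in% small, "small", "large"),
             stringsAsFactors = FALSE)
}

cap1 <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

#' Classify the property change of an amino-acid substitution
#'
#' @param aa_from,aa_to Single-letter residue codes (stop `*` is not
#'   classified; such changes are nonsense and handled upstream).
#' @param table Property table as from [aa_property_table()].
#' @return A list with per-class `(from, to)` pairs (`NULL` when unchanged),
#'   `conserved` (TRUE when charge, polarity and volume are all unchanged)
#'   and a human-readable `label`.
#' @export
classify_property_change <- function(aa_from, aa_to, table = aa_property_table()) {
  i <- match(aa_from, table$aa); j <- match(aa_to, table$aa)
  if (is.na(i)) stop("unknown residue: ", aa_from)
  if (is.na(j)) stop("unknown residue: ", aa_to)
  res <- list(charge = NULL, polarity = NULL, volume = NULL)
  for (cl in c("charge", "polarity", "volume")) {
    if (table[[cl]][i] != table[[cl]][j]) {
      res[[cl]] <- c(from = table[[cl]][i], to = table[[cl]][j])
    }
  }
  res$conserved <- is.null(res$charge) && is.null(res$polarity) && is.null(res$volume)
  pieces <- character(0)
  for (cl in c("charge", "polarity", "volume")) {
    if (!is.null(res[[cl]])) {
      pieces <- c(pieces, paste(res[[cl]][["from"]], "to", res[[cl]][["to"]]))
    }
  }
  res$label <- if (length(pieces) == 0) {
    "Nonsynonymous conserved"
  } else {
    pieces[1] <- cap1(pieces[1])
    paste(pieces, collapse = ", ")
  }
  res
}

# -- codon-level annotation ----------------------------------------------------

annotate_one <- function(rec, genome, annotation, property_table) {
  locus <- locate_position(annotation, genome, rec$position)
  ann <- list(gene_no = NA_character_, strand = NA_character_,
              codon_number = NA_integer_, within_codon_offset = NA_integer_,
              ref_codon = NA_character_, alt_codon = NA_character_,
              aa_from = NA_character_, aa_to = NA_character_,
              aa_label = NA_character_, effect = NA_character_,
              property_label = NA_character_, conserved = NA,
              upstream_no = NA_character_, downstream_no = NA_character_)
  if (rec$change_kind == "snv") {
    here <- genome_subseq(genome, rec$position, rec$position)
    if (here != rec$ref_base) {
      stop(sprintf("reference mismatch at %d: record says %s, genome has %s",
                   rec$position, rec$ref_base, here))
    }
  }
  if (locus$kind == "intergenic") {
    ann$effect <- "intergenic"
    ann$upstream_no <- locus$upstream_no
    ann$downstream_no <- locus$downstream_no
    ann$property_label <- "Not applicable"
    return(ann)
  }
  ann$gene_no <- locus$gene_no
  ann$strand <- locus$strand
  if (rec$change_kind == "snv") {
    ann$codon_number <- locus$codon_number
    ann$within_codon_offset <- locus$within_codon_offset
    ann$ref_codon <- locus$ref_codon
    if (is.na(locus$ref_codon)) return(ann)  # trailing partial codon
    alt_coding <- if (locus$strand == "-") complement_base(rec$alt_base) else rec$alt_base
    alt_codon <- locus$ref_codon
    substr(alt_codon, locus$within_codon_offset, locus$within_codon_offset) <- alt_coding
    ann$alt_codon <- alt_codon
    ann$aa_from <- translate_codon(locus$ref_codon)
    ann$aa_to <- translate_codon(alt_codon)
    ann$aa_label <- paste0(ann$aa_from, locus$codon_number, ann$aa_to)
    if (ann$aa_from == ann$aa_to) {
      ann$effect <- "synonymous"
      ann$conserved <- TRUE
      ann$property_label <- "Synonymous"
    } else if (ann$aa_to == "*") {
      ann$effect <- "nonsense"
      ann$property_label <- "Early stop codon"
    } else {
      ann$effect <- "nonsynonymous"
      pc <- classify_property_change(ann$aa_from, ann$aa_to, property_table)
      ann$conserved <- pc$conserved
      ann$property_label <- pc$label
    }
  } else {
    net <- rec$indel_length
    ann$effect <- if (net %% 3L != 0L) "frameshift" else "in_frame_indel"
    word <- if (rec$change_kind %in% c("insertion", "homopolymer_expansion"))
      "insertion" else "deletion"
    ann$property_label <- if (ann$effect == "frameshift")
      paste("Frame-shifting", word) else paste("In-frame", word)
  }
  ann
}

#' Annotate mutation records against an annotated genome
#'
#' Derives, for each record, the containing gene (or flanking gene pair),
#' codon number and within-codon offset, reference and alternate codons on
#' the coding strand (substituted alleles are complemented for reverse-strand
#' genes), amino-acid change, effect class (synonymous, nonsynonymous,
#' nonsense, frameshift, in_frame_indel, intergenic) and the amino-acid
#' property change. SNV records state alleles on the forward genome strand
#' and are checked against the reference sequence.
#'
#' @param records Data frame from [parse_mutation_table()].
#' @param genome A `genome_sequence`.
#' @param annotation A `genome_annotation`.
#' @param property_table Property table for [classify_property_change()].
#' @return The records data frame with annotation columns appended.
#' @export
annotate_mutations <- function(records, genome, annotation,
                               property_table = aa_property_table()) {
  ann <- lapply(seq_len(nrow(records)), function(i) {
    a <- annotate_one(records[i, ], genome, annotation, property_table)
    as.data.frame(a, stringsAsFactors = FALSE)
  })
  cbind(records, do.call(rbind, ann))
}

# -- summaries -----------------------------------------------------------------

#' Summarize annotated mutations across isolates
#'
#' Mutation uniqueness is keyed on (position, change); amino-acid-change
#' uniqueness on the substitution label (e.g. `"H1186N"`); the mean counts
#' every occurrence, so a substitution shared by two isolates counts once
#' among unique mutations but twice in the mean.
#'
#' @param annotations Data frame from [annotate_mutations()] with one row per
#'   (mutation, isolate) occurrence.
#' @return List with `n_unique_mutations`, `n_unique_aa_changes`,
#'   `n_isolates`, `mean_mutations_per_isolate` and `gene_summary` (per gene:
#'   number and fraction of isolates carrying at least one nonsynonymous
#'   change, nonsense included).
#' @export
summarize_isolates <- function(annotations) {
  isolates <- unique(annotations$source_id)
  n_iso <- length(isolates)
  aa_labels <- annotations$aa_label[!is.na(annotations$aa_label) &
                                    annotations$effect != "synonymous"]
  genes <- sort(unique(annotations$gene_no[!is.na(annotations$gene_no)]))
  gene_summary <- do.call(rbind, lapply(genes, function(g) {
    sel <- annotations$gene_no %in% g &
      annotations$effect %in% c("nonsynonymous", "nonsense")
    hit_iso <- unique(annotations$source_id[sel])
    data.frame(gene_no = g,
               n_isolates_nonsyn = length(hit_iso),
               fraction_isolates = length(hit_iso) / n_iso,
               stringsAsFactors = FALSE)
  }))
  list(n_unique_mutations = length(unique(annotations$change_key)),
       n_unique_aa_changes = length(unique(aa_labels)),
       n_isolates = n_iso,
       mean_mutations_per_isolate = nrow(annotations) / n_iso,
       gene_summary = gene_summary)
}

#' Compare isolate genotypes to population-level sequencing
#'
#' Finds mutations fixed in a population's read pool (frequency at or above
#' `fixed_threshold`) that are absent from the isolate sampled from the same
#' population. Matching is keyed on (position, change).
#'
#' @param isolate_annotations Annotated isolate records carrying a
#'   `population` column.
#' @param population_annotations Annotated population records with
#'   `frequency` (error if absent).
#' @param fixed_threshold Frequency at or above which a population allele is
#'   considered fixed (default 1.0).
#' @return List with `mismatches` (data frame: population, position,
#'   change_key, aa_label) and `n_mismatches`.
#' @export
compare_isolate_to_population <- function(isolate_annotations,
                                          population_annotations,
                                          fixed_threshold = 1.0) {
  if (all(is.na(population_annotations$frequency))) {
    stop("population records carry no read frequencies")
  }
  pops <- unique(population_annotations$population)
  pops <- pops[!is.na(pops)]
  if (length(pops) == 0L) {
    pops <- unique(population_annotations$source_id)
    population_annotations$population <- population_annotations$source_id
  }
  rows <- list()
  for (p in pops) {
    pop <- population_annotations[population_annotations$population %in% p &
                                  !is.na(population_annotations$frequency) &
                                  population_annotations$frequency >= fixed_threshold, ]
    iso_keys <- isolate_annotations$change_key[isolate_annotations$population %in% p]
    miss <- pop[!(pop$change_key %in% iso_keys), , drop = FALSE]
    if (nrow(miss)) {
      rows[[p]] <- data.frame(population = p,
                              position = miss$position,
                              change_key = miss$change_key,
                              aa_label = miss$aa_label,
                              stringsAsFactors = FALSE)
    }
  }
  mismatches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(0), position = integer(0),
               change_key = character(0), aa_label = character(0))
  rownames(mismatches) <- NULL
  list(mismatches = mismatches, n_mismatches = nrow(mismatches))
}

#' Partition mutations into evolved and pre-existing
#'
#' Any mutation matching a stock polymorphism (same position and change) is
#' classed pre-existing regardless of its stock frequency, and is thereby
#' excluded from parallelism claims.
#'
#' @param annotations Annotated mutation records.
#' @param stock Data frame (or TSV path) with columns `position`,
#'   `bp_change`, `frequency` describing polymorphisms in the ancestral stock.
#' @return List with `evolved`, `preexisting` (disjoint, exhaustive) and
#'   `unused_stock` (stock keys matching no record).
#' @export
filter_preexisting <- function(annotations, stock) {
  if (is.null(stock) || (is.data.frame(stock) && nrow(stock) == 0L)) {
    return(list(evolved = annotations,
                preexisting = annotations[0, , drop = FALSE],
                unused_stock = character(0)))
  }
  stock_rec <- parse_mutation_table(stock)
  if (any(!is.na(stock_rec$frequency) &
          (stock_rec$frequency < 0 | stock_rec$frequency > 1))) {
    stop("stock frequencies must lie in [0,1]")
  }
  keys <- unique(stock_rec$change_key)
  pre <- annotations$change_key %in% keys
  list(evolved = annotations[!pre, , drop = FALSE],
       preexisting = annotations[pre, , drop = FALSE],
       unused_stock = setdiff(keys, annotations$change_key))
}
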