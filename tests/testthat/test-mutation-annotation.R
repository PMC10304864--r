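test_that("BP-change descriptors parse in the published dialect", {
  snv <- parse_bp_change("C→A")
  expect_equal(snv$change_kind, "snv")
  expect_equal(snv$ref_base, "C"); expect_equal(snv$alt_base, "A")
  expect_equal(parse_bp_change("C->A")$alt_base, "A")

  hp <- parse_bp_change("(A)_8→7_")
  expect_equal(hp$change_kind, "homopolymer_contraction")
  expect_equal(hp$indel_length, 1L)
  expect_equal(parse_bp_change("(A)8->7")$indel_length, 1L)

  expect_equal(parse_bp_change("+82 bp")$change_kind, "insertion")
  expect_equal(parse_bp_change("+82 bp")$indel_length, 82L)
  expect_equal(parse_bp_change("Δ1 bp")$change_kind, "deletion")
  expect_equal(parse_bp_change("del 1 bp")$indel_length, 1L)

  expect_error(parse_bp_change("C=>A"), "unparseable")
  expect_error(parse_bp_change("A->A"), "identical alleles")
})

test_that("mutation tables parse positions, sources and frequencies", {
  tab <- data.frame(position = c("28,296", "31700"),
                    bp_change = c("C->A", "+82 bp"),
                    source_id = c("iso1", "popA"),
                    frequency = c("", "77.2%"))
  rec <- parse_mutation_table(tab)
  expect_equal(rec$position, c(28296L, 31700L))
  expect_equal(rec$frequency, c(NA, 0.772))
  expect_equal(parse_mutation_table(data.frame(position = 1, bp_change = "C->A",
                                               frequency = "100%"))$frequency, 1.0)
  expect_error(parse_mutation_table(data.frame(position = 1, bp_change = "C->A",
                                               frequency = "120%")),
               "outside \\[0,100\\]")
})

test_that("SNV annotation derives printed codon changes on both strands", {
  fx <- get_fixture()
  rec <- parse_mutation_table(data.frame(
    position = c(28380, 31917, 11048, 48412, 31700),
    bp_change = c("C->A", "C->A", "T->G", "G->T", "+82 bp"),
    source_id = "t"))
  ann <- annotate_mutations(rec, fx$genome, fx$annotation)
  expect_equal(ann$ref_codon[1:4], c("CAA", "AAG", "CGT", "TCA"))
  expect_equal(ann$alt_codon[1:4], c("AAA", "AAT", "CGG", "TAA"))
  expect_equal(ann$aa_label[1:4], c("Q1214K", "K688N", "R116R", "S15*"))
  expect_equal(ann$effect,
               c("nonsynonymous", "nonsynonymous", "synonymous", "nonsense",
                 "frameshift"))
})

test_that("annotation rejects records whose reference base mismatches", {
  fx <- get_fixture()
  rec <- parse_mutation_table(data.frame(position = 28296, bp_change = "G->A",
                                         source_id = "t"))
  expect_error(annotate_mutations(rec, fx$genome, fx$annotation),
               "reference mismatch")
})

test_that("every catalogued mutation round-trips from the fixture genome", {
  fx <- get_fixture()
  exp <- fixture_expected_annotations()
  rec <- parse_mutation_table(data.frame(position = exp$position,
                                         bp_change = exp$bp_change,
                                         source_id = "cat"))
  ann <- annotate_mutations(rec, fx$genome, fx$annotation)
  expect_equal(ann$effect, exp$effect)
  genic <- !is.na(exp$ref_codon)
  expect_equal(ann$ref_codon[genic], exp$ref_codon[genic])
  expect_equal(ann$alt_codon[genic], exp$alt_codon[genic])
  expect_equal(ann$aa_label[genic], exp$aa_label[genic])
  # impact labels, on the subset the default property scheme reproduces
  sel <- exp$position %in% label_reproducible_positions
  expect_equal(ann$property_label[sel], exp$published_impact[sel])
})

test_that("amino-acid property transitions follow charge/polarity/volume", {
  hn <- classify_property_change("H", "N")
  expect_equal(unname(hn$charge), c("positive", "neutral"))
  expect_equal(unname(hn$volume), c("large", "small"))
  expect_null(hn$polarity)
  expect_equal(hn$label, "Positive to neutral, large to small")

  tk <- classify_property_change("T", "K")
  expect_equal(tk$label, "Neutral to positive, small to large")

  expect_true(classify_property_change("L", "I")$conserved)
  expect_true(classify_property_change("A", "A")$conserved)
  expect_error(classify_property_change("A", "B"), "unknown residue")
})

test_that("synonymous changes are always property-conserved", {
  fx <- get_fixture()
  ann <- get_population_annotations()
  syn <- ann[ann$effect %in% "synonymous", ]
  expect_true(nrow(syn) > 0)
  expect_true(all(syn$aa_from == syn$aa_to))
  expect_true(all(syn$conserved))
})

test_that("frameshift calls depend only on indel length mod 3", {
  fx <- get_fixture()
  gene52 <- fx$annotation$genes[fx$annotation$genes$gene_no == "52", ]
  pos <- gene52$start + 30L
  rec <- parse_mutation_table(data.frame(
    position = pos,
    bp_change = c("+82 bp", "+86 bp", "del 1 bp", "+3 bp", "del 6 bp"),
    source_id = "t"))
  ann <- annotate_mutations(rec, fx$genome, fx$annotation)
  expect_equal(ann$effect, c("frameshift", "frameshift", "frameshift",
                             "in_frame_indel", "in_frame_indel"))
})

test_that("isolate summaries reproduce the headline mutation statistics", {
  s <- summarize_isolates(get_isolate_annotations())
  expect_equal(s$n_unique_mutations, 11L)
  expect_equal(s$n_unique_aa_changes, 9L)
  expect_equal(s$n_isolates, 5L)
  expect_equal(s$mean_mutations_per_isolate, 3.4)
  gs <- s$gene_summary
  expect_equal(gs$n_isolates_nonsyn[gs$gene_no == "52"], 5L)
  expect_equal(gs$fraction_isolates[gs$gene_no == "52"], 1.0)
  expect_equal(gs$n_isolates_nonsyn[gs$gene_no == "57"], 3L)
  expect_equal(gs$fraction_isolates[gs$gene_no == "57"], 0.6)

  one <- summarize_isolates(get_isolate_annotations()[6, ])
  expect_equal(one$n_unique_mutations, 1L)
  expect_equal(one$mean_mutations_per_isolate, 1.0)
})

test_that("isolate-vs-population concordance finds the fixed-but-absent loci", {
  cmp <- compare_isolate_to_population(get_isolate_annotations(),
                                       get_population_annotations())
  expect_equal(cmp$n_mismatches, 3L)
  m <- cmp$mismatches
  expect_setequal(m$position[m$population == "Pop+6"], c(28380, 28446))
  expect_setequal(m$aa_label[m$population == "Pop+6"], c("Q1214K", "L1236I"))
  expect_equal(m$position[m$population == "Pop+4"], 38211)
  expect_false("Pop+2" %in% m$population)
  expect_false("Pop+8" %in% m$population)

  # identical sets -> empty
  iso <- get_isolate_annotations()
  self <- iso; self$frequency <- 1
  cmp0 <- compare_isolate_to_population(iso, self)
  expect_equal(cmp0$n_mismatches, 0L)

  no_freq <- get_population_annotations(); no_freq$frequency <- NA_real_
  expect_error(compare_isolate_to_population(iso, no_freq), "no read frequencies")
})

test_that("stock polymorphisms are partitioned out as pre-existing", {
  iso <- get_isolate_annotations()
  part <- filter_preexisting(iso, fixture_stock_polymorphisms())
  expect_equal(nrow(part$preexisting), 3L)   # one shared SNV in three isolates
  expect_setequal(part$preexisting$population, c("Pop+4", "Pop+8", "Pop+9"))
  expect_equal(unique(part$preexisting$aa_label), "Q1214K")
  expect_equal(nrow(part$evolved) + nrow(part$preexisting), nrow(iso))
  expect_equal(length(intersect(part$evolved$change_key,
                                part$preexisting$change_key)), 0L)
  # the stock duplication matches nothing and is reported unused
  expect_equal(part$unused_stock, "31648:ins86")

  all_evolved <- filter_preexisting(iso, NULL)
  expect_equal(nrow(all_evolved$evolved), nrow(iso))
})
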