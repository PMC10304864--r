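test_that("conservative probability reproduces the printed tail fiber values", {
  p52 <- conservative_parallel_probability(3776, 49223, 5)
  expect_equal(p52$probability, (3776 / 49223)^4)
  expect_equal(p52$display, "0.00003")
  p57 <- conservative_parallel_probability(2372, 49223, 3)
  expect_equal(p57$probability, (2372 / 49223)^2)
  expect_equal(p57$display, "0.002")
  expect_equal(conservative_parallel_probability(1000, 49223, 1)$probability, 1.0)
  expect_error(conservative_parallel_probability(1000, 49223, 0), "k_hit")
  expect_error(conservative_parallel_probability(0, 49223, 2), "L_gene")
})

test_that("conservative probability is monotone in gene length and hit count", {
  L <- seq(500, 40000, length.out = 20)
  p <- vapply(L, function(l)
    conservative_parallel_probability(l, 49223, 4)$probability, numeric(1))
  expect_true(all(diff(p) > 0))
  k <- 1:8
  pk <- vapply(k, function(kk)
    conservative_parallel_probability(3776, 49223, kk)$probability, numeric(1))
  expect_true(all(diff(pk) < 0))
})

test_that("hit matrices honour effect filters and stock exclusion", {
  iso <- get_isolate_annotations()
  hm <- build_hit_matrix(iso, filter = "nonsynonymous_only",
                         stock = fixture_stock_polymorphisms())
  expect_equal(sum(hm$hit[, "52"]), 5L)
  expect_equal(sum(hm$hit[, "57"]), 3L)
  expect_setequal(rownames(hm$hit)[hm$hit[, "57"]],
                  c("Pop+6", "Pop+8", "Pop+9"))

  # intergenic changes never count as gene hits
  hm_any <- build_hit_matrix(iso, filter = "any")
  expect_false(any(is.na(colnames(hm_any$hit))))
  expect_setequal(colnames(hm_any$hit), c("52", "57"))

  empty <- build_hit_matrix(iso[0, ])
  expect_equal(dim(empty$hit), c(0L, 0L))

  single <- build_hit_matrix(iso[1, ])
  expect_true(single$hit["Pop+4", "52"])
})

test_that("exact null matches closed-form expectations at the boundaries", {
  expect_equal(null_parallel_probability_exact(3776, 49223, 1, 1), 3776 / 49223)
  expect_equal(null_parallel_probability_exact(49223, 49223, 4, 7), 1.0)
  expect_error(null_parallel_probability_exact(3776, 49223, 0, 1), "k >= 1")
})

test_that("Monte-Carlo null agrees with the closed form and is seed-stable", {
  exact <- null_parallel_probability_exact(3776, 49223, 5, 3)
  mc <- null_parallel_probability_mc(3776, 49223, 5, 3, n_sims = 2e5, seed = 7)
  expect_lt(abs(mc$estimate - exact), 3 * mc$se)
  mc2 <- null_parallel_probability_mc(3776, 49223, 5, 3, n_sims = 2e5, seed = 7)
  expect_identical(mc$estimate, mc2$estimate)
})

test_that("MC estimator is unbiased over repeated seeds", {
  exact <- null_parallel_probability_exact(5000, 49223, 3, 2)
  runs <- lapply(1:20, function(s)
    null_parallel_probability_mc(5000, 49223, 3, 2, n_sims = 2e4, seed = s))
  est <- vapply(runs, `[[`, numeric(1), "estimate")
  pooled_se <- sqrt(exact * (1 - exact) / (20 * 2e4))
  expect_lt(abs(mean(est) - exact), 3 * pooled_se)
})

test_that("conditioning on the first hit recovers the conservative formula", {
  mc <- null_parallel_probability_mc(10000, 49223, 3, 1, n_sims = 2e5,
                                     seed = 3, condition_on_first = TRUE)
  expect_lt(abs(mc$estimate - (10000 / 49223)^2), 3 * mc$se)
  expect_gt(mc$n_conditioning, 0)
})

test_that("per-population hit probability makes the conditional null exceed the conservative one", {
  for (L in c(1000, 3776, 10000)) {
    for (k in 2:5) {
      for (m in 1:4) {
        conditional_exact <- null_parallel_probability_exact(L, 49223, k - 1, m)
        conservative <- conservative_parallel_probability(L, 49223, k)$probability
        expect_gte(conditional_exact, conservative * (1 - 1e-12))
      }
    }
  }
})

test_that("display rounding keeps one significant figure in fixed notation", {
  expect_equal(format_probability(3.46e-5), "0.00003")
  expect_equal(format_probability(2.32e-3), "0.002")
  expect_equal(format_probability(0.049), "0.05")
})

test_that("shared sub-fixation alleles are detected across populations", {
  pop <- fixture_population_mutations()
  sh <- shared_polymorphisms(pop)
  expect_true("48438:G>T" %in% sh$change_key)   # F6L at ~9% in three populations
  expect_equal(sh$n_populations[sh$change_key == "48438:G>T"], 3L)
  # fixed alleles (100%) never qualify
  expect_false("28380:C>A" %in% sh$change_key)
  # gene-85 alleles each occur in at most 3 populations
  sh4 <- shared_polymorphisms(pop, min_populations = 4)
  expect_false(any(sh4$position >= 48276 & sh4$position <= 48455))
  empty <- shared_polymorphisms(pop[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("null mutation generator matches the all-hit closed form", {
  L <- 3776; G <- 49223; k <- 5; m <- 3
  n_rep <- 400
  hits <- vapply(seq_len(n_rep), function(s) {
    mut <- generate_null_mutations(k, m, G, seed = 1000 + s)
    in_gene <- mut$position <= L
    all(vapply(split(in_gene, mut$population), any, logical(1)))
  }, logical(1))
  exact <- null_parallel_probability_exact(L, G, k, m)
  se <- sqrt(exact * (1 - exact) / n_rep)
  expect_lt(abs(mean(hits) - exact), 3 * se + 1e-12)
  expect_equal(nrow(generate_null_mutations(3, 0, G)), 0L)
  expect_identical(generate_null_mutations(2, 5, G, seed = 4),
                   generate_null_mutations(2, 5, G, seed = 4))
})
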