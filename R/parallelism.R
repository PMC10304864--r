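# Parallel-evolution statistics: per-gene hit matrices across replicate
# populations, the conservative same-gene probability, and exact /
# Monte-Carlo null models of uniform mutation placement.

#' Build a per-gene hit matrix across populations
#'
#' @param annotations Annotated mutation records with a `population` column
#'   (falls back to `source_id` when absent/NA).
#' @param filter `"any"` counts any genic mutation as a hit;
#'   `"nonsynonymous_only"` restricts to nonsynonymous and nonsense changes.
#'   Intergenic changes never count.
#' @param stock Optional stock polymorphism table; matching mutations are
#'   removed (see [filter_preexisting()]) before counting.
#' @return List of class `gene_hit_matrix`: logical `hit` matrix
#'   (populations x genes) and integer `mutation_count` per population
#'   (qualifying mutations after filtering, genic or not).
#' @export
build_hit_matrix <- function(annotations,
                             filter = c("any", "nonsynonymous_only"),
                             stock = NULL) {
  filter <- match.arg(filter)
  if (!is.null(stock)) {
    annotations <- filter_preexisting(annotations, stock)$evolved
  }
  pop <- annotations$population
  if (is.null(pop)) pop <- annotations$source_id
  pop[is.na(pop)] <- annotations$source_id[is.na(pop)]
  populations <- sort(unique(pop))
  mutation_count <- vapply(populations, function(p) sum(pop == p), integer(1))
  qual <- if (filter == "nonsynonymous_only") {
    annotations$effect %in% c("nonsynonymous", "nonsense")
  } else {
    !is.na(annotations$gene_no)
  }
  genes <- sort(unique(annotations$gene_no[qual & !is.na(annotations$gene_no)]))
  hit <- matrix(FALSE, length(populations), length(genes),
                dimnames = list(populations, genes))
  for (i in which(qual & !is.na(annotations$gene_no))) {
    hit[pop[i], annotations$gene_no[i]] <- TRUE
  }
  structure(list(populations = populations, genes = genes,
                 hit = hit, mutation_count = mutation_count),
            class = "gene_hit_matrix")
}

#' @export
print.gene_hit_matrix <- function(x, ...) {
  cat(sprintf("<gene_hit_matrix> %d population(s) x %d gene(s)\n",
              length(x$populations), length(x$genes)))
  print(x$hit)
  invisible(x)
}

#' Display a probability at one significant figure
#'
#' Fixed-notation display rounding used for reporting parallelism
#' probabilities, e.g. 3.46e-5 -> "0.00003", 2.32e-3 -> "0.002".
#'
#' @param p Probability.
#' @return Character string.
#' @export
format_probability <- function(p) {
  format(signif(p, 1), scientific = FALSE, trim = TRUE)
}

#' Conservative probability of same-gene parallelism
#'
#' Probability that, given one population already carries a mutation in a
#' gene, the remaining `k_hit - 1` replicate populations each also acquire a
#' mutation in that gene by chance: `(L_gene / L_genome)^(k_hit - 1)`.
#' Conditioning on the first hit makes the estimate conservative (it charges
#' nothing for the first population).
#'
#' @param L_gene,L_genome Gene and genome lengths in bp.
#' @param k_hit Number of populations with a mutation in the gene (>= 1).
#' @return List with exact `probability`, `display` (one significant figure,
#'   fixed notation) and the inputs.
#' @export
conservative_parallel_probability <- function(L_gene, L_genome, k_hit) {
  if (L_gene <= 0 || L_gene > L_genome) stop("need 0 < L_gene <= L_genome")
  if (k_hit < 1) stop("k_hit must be >= 1 (probability undefined for 0 hits)")
  p <- (L_gene / L_genome)^(k_hit - 1)
  list(probability = p,
       display = format_probability(p),
       L_gene = L_gene, L_genome = L_genome, k_hit = k_hit)
}

#' Exact null probability that all populations hit a gene
#'
#' Closed form for the null model in which each of `k` populations places
#' `m` mutations uniformly and independently over the genome: the chance
#' that every population hits the gene at least once is
#' `(1 - (1 - L_gene/L_genome)^m)^k`.
#'
#' @inheritParams conservative_parallel_probability
#' @param k Number of populations (>= 1).
#' @param m Mutations per population (>= 1).
#' @export
null_parallel_probability_exact <- function(L_gene, L_genome, k, m) {
  if (m < 1 || k < 1) stop("need m >= 1 and k >= 1")
  if (L_gene <= 0 || L_gene > L_genome) stop("need 0 < L_gene <= L_genome")
  (1 - (1 - L_gene / L_genome)^m)^k
}

#' Monte-Carlo null probability of all-population gene hits
#'
#' Simulates `m` uniform mutation placements in each of `k` populations and
#' estimates the probability that every population hits a gene of length
#' `L_gene`. With `condition_on_first = TRUE` the estimate is restricted to
#' simulations in which population 1 hits the gene, estimating the
#' conditional probability that the remaining `k - 1` populations also hit
#' (with `m = 1` this converges to the conservative formula
#' `(L_gene/L_genome)^(k-1)`).
#'
#' @inheritParams null_parallel_probability_exact
#' @param n_sims Number of simulated experiments (>= 1000).
#' @param seed Integer seed; fixed seed gives identical estimates.
#' @param condition_on_first Condition on population 1 hitting the gene.
#' @return List with `estimate`, `se` (binomial standard error), `n_sims`
#'   and, when conditioning, `n_conditioning`.
#' @export
null_parallel_probability_mc <- function(L_gene, L_genome, k, m,
                                         n_sims = 1e5, seed = 1,
                                         condition_on_first = FALSE) {
  if (n_sims < 1000) stop("n_sims must be >= 1000")
  if (m < 1 || k < 1) stop("need m >= 1 and k >= 1")
  set.seed(seed)
  chunk <- 200000L
  succ <- 0; denom <- 0
  remaining <- as.integer(n_sims)
  while (remaining > 0L) {
    nb <- min(chunk, remaining)
    pos <- sample.int(L_genome, nb * k * m, replace = TRUE)
    hit_each <- pos <= L_gene             # gene occupies [1, L_gene] wlog
    dim(hit_each) <- c(m, k, nb)
    pop_hit <- apply(hit_each, c(2, 3), any)   # k x nb
    if (condition_on_first) {
      cond <- pop_hit[1, ]
      if (k == 1L) {
        succ <- succ + sum(cond); denom <- denom + sum(cond)
      } else {
        rest <- colSums(pop_hit[-1, , drop = FALSE]) == (k - 1L)
        succ <- succ + sum(cond & rest)
        denom <- denom + sum(cond)
      }
    } else {
      succ <- succ + sum(colSums(pop_hit) == k)
      denom <- denom + nb
    }
    remaining <- remaining - nb
  }
  if (condition_on_first && denom == 0) {
    stop("no simulations had population 1 hitting the gene; increase n_sims")
  }
  est <- succ / denom
  out <- list(estimate = est,
              se = sqrt(est * (1 - est) / denom),
              n_sims = as.integer(n_sims))
  if (condition_on_first) out$n_conditioning <- denom
  out
}

#' Alleles below fixation shared across populations
#'
#' Returns (position, change) keys observed at sub-fixation frequency in at
#' least `min_populations` populations; recurrence of the same minor allele
#' across replicates flags it as potentially adaptive.
#'
#' @param population_records Parsed population mutation records with
#'   `frequency` and `population` columns.
#' @param min_freq Minimum frequency (inclusive, default 0.05).
#' @param min_populations Minimum number of populations (default 2).
#' @return Data frame: change_key, position, n_populations, frequencies
#'   (comma-joined, in population order).
#' @export
shared_polymorphisms <- function(population_records, min_freq = 0.05,
                                 min_populations = 2) {
  rec <- population_records
  if (nrow(rec) == 0L) {
    return(data.frame(change_key = character(0), position = integer(0),
                      n_populations = integer(0), frequencies = character(0)))
  }
  pop <- rec$population
  if (all(is.na(pop))) pop <- rec$source_id
  keep <- !is.na(rec$frequency) & rec$frequency >= min_freq & rec$frequency < 1
  rec <- rec[keep, , drop = FALSE]; pop <- pop[keep]
  keys <- unique(rec$change_key)
  rows <- lapply(keys, function(kk) {
    sel <- rec$change_key == kk
    npop <- length(unique(pop[sel]))
    if (npop < min_populations) return(NULL)
    data.frame(change_key = kk,
               position = rec$position[sel][1],
               n_populations = npop,
               frequencies = paste(rec$frequency[sel], collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(change_key = character(0), position = integer(0),
                      n_populations = integer(0), frequencies = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
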