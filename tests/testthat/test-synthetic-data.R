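test_that("degenerate regimes produce the promised alphabets", {
  spec <- genome_spec("cg", 2000L, composition_regime("fixed", gc = 1),
                      seed = 1L)
  g <- generate_genome(spec)
  expect_identical(nchar(g$residues), 2000L)
  expect_false(grepl("[AT]", g$residues))

  spec0 <- genome_spec("at", 2000L, composition_regime("fixed", gc = 0),
                       seed = 1L)
  expect_false(grepl("[CG]", generate_genome(spec0)$residues))
})

test_that("identical specs give byte-identical sequences; seeds are mandatory", {
  spec <- genome_spec("d", 5000L, composition_regime("beta"), seed = 33L)
  expect_identical(generate_genome(spec)$residues,
                   generate_genome(spec)$residues)
  expect_error(genome_spec("d", 5000L, composition_regime("beta")),
               "seed")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(555)
  a <- runif(1)
  set.seed(555)
  invisible(generate_genome(genome_spec("g", 1000L,
                                        composition_regime("fixed"),
                                        seed = 9L)))
  expect_identical(runif(1), a)
})

test_that("cohort members can be regenerated in isolation via derived seeds", {
  groups <- list(
    list(name = "ga", regime = composition_regime("fixed", gc = 0.4),
         n = 2L, length = 20000L),
    list(name = "gb", regime = composition_regime("beta"),
         n = 2L, length = 20000L))
  cohort <- generate_cohort(groups, seed = 77L)
  expect_length(cohort$genomes, 4L)
  labels <- vapply(cohort$genomes, `[[`, "", "label")
  expect_false(anyDuplicated(labels) > 0)
  expect_identical(cohort$group, c("ga", "ga", "gb", "gb"))

  lone <- generate_genome(genome_spec("ga_01", 20000L,
                                      composition_regime("fixed", gc = 0.4),
                                      seed = derive_seed(77L, 1L, 1L)))
  expect_identical(lone$residues, cohort$genomes[[1]]$residues)
  expect_identical(cohort$manifest$seed[1], derive_seed(77L, 1L, 1L))
})

test_that("empirical GC tracks the regime mean within binomial error", {
  len <- 200000L
  for (gc in c(0.3, 0.5, 0.7)) {
    g <- generate_genome(genome_spec("g", len,
                                     composition_regime("fixed", gc = gc),
                                     seed = 17L))
    emp <- sum(strsplit(g$residues, "")[[1]] %in% c("C", "G")) / len
    expect_lt(abs(emp - gc), 3 * sqrt(gc * (1 - gc) / len))
  }
})

test_that("skews shift the within-pair base balance as specified", {
  g <- generate_genome(genome_spec("sk", 100000L,
                                   composition_regime("fixed", gc = 0.5,
                                                      at_skew = 0.5,
                                                      cg_skew = -0.5),
                                   seed = 21L))
  cnt <- block_counts(g$residues)
  # expected p(A)=0.375, p(T)=0.125, p(C)=0.125, p(G)=0.375
  expect_gt(cnt[["A"]], 2.5 * cnt[["T"]])
  expect_gt(cnt[["G"]], 2.5 * cnt[["C"]])
  expect_error(composition_regime("fixed", at_skew = 1.5), "skews")
})

test_that("entropy histogram shape follows the composition regime", {
  sch <- make_binning()
  occupied_runs <- function(d) {
    r <- rle(d$counts > 0)
    sum(r$values)
  }
  uni <- generate_genome(genome_spec("uni", 300000L,
                                     composition_regime("fixed", gc = 0.5),
                                     seed = 5L))
  d_uni <- histogram_entropies(entropy_profile(uni, 100), sch)
  expect_identical(occupied_runs(d_uni), 1L)

  bi <- generate_genome(genome_spec("bi", 300000L,
                                    composition_regime("two_point",
                                                       gc1 = 0.1, gc2 = 0.5),
                                    seed = 5L))
  d_bi <- histogram_entropies(entropy_profile(bi, 100), sch)
  expect_gte(occupied_runs(d_bi), 2L)
})

test_that("wider GC spread yields larger superinformation", {
  sch <- make_binning()
  hs_of <- function(regime) {
    g <- generate_genome(genome_spec("g", 300000L, regime, seed = 13L))
    superinformation(histogram_entropies(entropy_profile(g, 100), sch))
  }
  expect_gt(hs_of(composition_regime("beta", alpha = 2, beta = 2)),
            hs_of(composition_regime("fixed", gc = 0.5)))
})

test_that("mean block entropy at balanced composition matches the plug-in bias", {
  g <- generate_genome(genome_spec("bias", 1000000L,
                                   composition_regime("fixed", gc = 0.5),
                                   seed = 3L))
  p <- entropy_profile(g, 100)
  expected <- 2 - 3 / (2 * 100 * log(2))
  se <- stats::sd(p$entropies) / sqrt(p$n_blocks)
  expect_lt(abs(mean(p$entropies) - expected), 3 * se)
})
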