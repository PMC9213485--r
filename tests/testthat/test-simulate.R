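small_cfg <- function(...) sim_config(n_chromosomes = 1,
  markers_per_chromosome = 12, pairs_per_generation = 500,
  offspring_per_pair = 4, ...)

test_that("F2 genotype frequencies are Mendelian 1:2:1 and F1-derived gametes segregate", {
  sim <- simulate_ail(small_cfg(final_generation = 2, seed = 301))
  n <- nrow(sim$geno$calls)
  expect_equal(n, 2000L)
  for (j in c(1L, 6L, 12L)) {
    cnt <- table(factor(sim$geno$calls[, j], levels = 0:2))
    chi <- chisq.test(cnt, p = c(0.25, 0.5, 0.25))
    expect_gt(chi$p.value, 0.01)
  }
  # every F2 gamete comes from a heterozygous F1, so both alleles appear
  expect_true(all(colMeans(sim$haplotypes$pat) > 0.3 &
                  colMeans(sim$haplotypes$pat) < 0.7))
})

test_that("map expansion: more recombinant two-locus haplotypes in generation 10 than in F2", {
  # markers 10 cM apart: with cM_per_Mb = 0.5 and 12 markers over 80 cM,
  # adjacent markers sit ~6.6 cM apart, so use markers 1 and 3 (~13 cM).
  pick <- function(sim, d_cM = 10) {
    cm <- sim$map$cM
    j <- which.min(abs((cm - cm[1]) - d_cM))
    c(1L, j)
  }
  recomb_fraction <- function(sim) {
    jj <- pick(sim)
    # oracle: direct count of parental vs recombinant gamete haplotypes
    h <- rbind(sim$haplotypes$pat[, jj], sim$haplotypes$mat[, jj])
    mean(h[, 1] != h[, 2])
  }
  f2 <- simulate_ail(small_cfg(final_generation = 2, seed = 311))
  g10 <- simulate_ail(small_cfg(final_generation = 10, seed = 311))
  r2 <- recomb_fraction(f2)
  r10 <- recomb_fraction(g10)
  n2 <- 2 * nrow(f2$haplotypes$pat)
  n10 <- 2 * nrow(g10$haplotypes$pat)
  tst <- prop.test(c(r10 * n10, r2 * n2), c(n10, n2), alternative = "greater")
  expect_lt(tst$p.value, 0.01)
  expect_gt(r10, r2)
})

test_that("same seed gives identical output and marker density does not touch the pedigree", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 15,
                    pairs_per_generation = 10, offspring_per_pair = 4,
                    final_generation = 5, seed = 321, missing_rate = 0.05)
  s1 <- simulate_ail(cfg)
  s2 <- simulate_ail(cfg)
  expect_identical(s1$geno$calls, s2$geno$calls)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(simulate_phenotypes(s1), simulate_phenotypes(s2))
  cfg_dense <- cfg; cfg_dense$markers_per_chromosome <- 45L
  s3 <- simulate_ail(cfg_dense)
  expect_identical(s1$pedigree, s3$pedigree)
})

test_that("pedigree is generation-consistent and allele frequencies stay near 0.5", {
  sim <- simulate_ail(sim_config(n_chromosomes = 2, markers_per_chromosome = 20,
                                 pairs_per_generation = 125,
                                 offspring_per_pair = 4,
                                 final_generation = 10, seed = 331))
  ped <- sim$pedigree
  gen <- setNames(ped$generation, ped$id)
  kids <- ped[!is.na(ped$sire), ]
  expect_true(all(gen[kids$sire] == kids$generation - 1L))
  expect_true(all(gen[kids$dam] == kids$generation - 1L))
  expect_true(all(kids$sire != kids$dam))
  # no full-sib matings from F2 onward
  late <- kids[kids$generation >= 3L, ]
  sp <- ped[match(late$sire, ped$id), c("sire", "dam")]
  dp <- ped[match(late$dam, ped$id), c("sire", "dam")]
  expect_false(any(sp$sire == dp$sire & sp$dam == dp$dam))
  # drift check at n = 500 per generation: mean allele frequency over markers
  freq <- colMeans(sim$geno$calls, na.rm = TRUE) / 2
  expect_lt(abs(mean(freq) - 0.5), 0.02)
  # an impossible pairing request errors with advice
  expect_error(simulate_ail(sim_config(pairs_per_generation = 3,
                                       offspring_per_pair = 2,
                                       final_generation = 4, seed = 1)),
               "pairs")
})

test_that("phenotype generation follows the additive-dominance covariate model", {
  base <- sim_config(n_chromosomes = 1, markers_per_chromosome = 10,
                     pairs_per_generation = 125, offspring_per_pair = 8,
                     final_generation = 4, seed = 341)
  sim <- simulate_ail(base)
  # all effects zero: trait is standard normal noise
  ph0 <- simulate_phenotypes(sim)
  expect_lt(abs(mean(ph0$trait1)), 3 / sqrt(nrow(ph0)))
  expect_lt(abs(sd(ph0$trait1) - 1), 0.1)
  # complete dominance toward line 1 (d = a): HET and HOM1 indistinguishable,
  # both above HOM2
  cfg_dom <- base; cfg_dom$qtl_specs <- list(list(chr = 1, pos_cM = 40,
                                                  a = 1, d = 1, trait = "y"))
  ph1 <- simulate_phenotypes(sim, cfg_dom)
  truth <- attr(ph1, "qtl_truth")
  g <- sim$geno$calls[, truth$marker[1]]
  y <- ph1$y
  expect_gt(t.test(y[g == 1], y[g == 0])$statistic, 3)
  expect_gt(t.test(y[g == 2], y[g == 0])$statistic, 3)
  expect_gt(t.test(y[g == 2], y[g == 1])$p.value, 0.01)
  # overdominance (a = 0, d > 0): heterozygote exceeds both homozygotes,
  # class means recovered by direct group averaging
  cfg_od <- base; cfg_od$qtl_specs <- list(list(chr = 1, pos_cM = 40,
                                                a = 0, d = 0.8, trait = "y"))
  ph2 <- simulate_phenotypes(sim, cfg_od)
  g2 <- sim$geno$calls[, attr(ph2, "qtl_truth")$marker[1]]
  cl <- tapply(ph2$y, g2, mean)
  expect_gt(cl["1"], cl["0"])
  expect_gt(cl["1"], cl["2"])
  expect_lt(abs(cl["1"] - cl["0"] - 0.8), 3 / sqrt(min(table(g2))))
  # sex / subfamily / litter effects show up in the screen
  cfg_cov <- base
  cfg_cov$sex_effect <- 1.5; cfg_cov$subfamily_sd <- 1; cfg_cov$litter_slope <- 0.4
  ph3 <- simulate_phenotypes(sim, cfg_cov)
  sel <- screen_covariates(ph3)
  expect_true(all(sel$selected))
})

test_that("annotation simulation edge cases", {
  empty <- simulate_annotations(c("a", "b"),
                                annotation_frequencies(stop_gain = 0,
    stop_loss = 0, missense_deleterious_domain = 0, missense_deleterious = 0,
    missense_tolerated_domain = 0, missense_tolerated = 0, promoter = 0,
    splice_site = 0, utr = 0, enhancer = 0, ctcf = 0), seed = 351)
  expect_equal(nrow(empty$annotations), 0L)
  expect_equal(empty$truth$truth_score, c(0, 0))
  # forced categories reproduce the deleterious-domain worked score of 12
  forced <- simulate_annotations("Astn1",
                                 annotation_frequencies(stop_gain = 0,
    stop_loss = 0, missense_deleterious_domain = 1, missense_deleterious = 0,
    missense_tolerated_domain = 0, missense_tolerated = 0, promoter = 1,
    splice_site = 0, utr = 1, enhancer = 1, ctcf = 1), seed = 351)
  expect_equal(forced$truth$truth_score, 12)
  expect_error(simulate_annotations("a", c(annotation_frequencies()[-1],
                                           stop_gain = 1.2)),
               "unknown category|\\[0, 1\\]")
})
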