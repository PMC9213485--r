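test_that("lambda estimation and correction follow the genomic-control rule", {
  set.seed(11)
  # uniform p-values: lambda near 1 (mean over replicate draws of n = 10,000)
  lambdas <- replicate(5, lambda_correct(runif(10000))$lambda)
  expect_lt(abs(mean(lambdas) - 1), 0.03)
  # constructed list whose 1-df quantiles have median 0.9098728: lambda = 2,
  # and the median corrected p is 0.5
  q <- c(0.2, 0.9098728, 2.5)
  p <- pchisq(q, 1, lower.tail = FALSE)
  lc2 <- lambda_correct(p)
  expect_equal(lc2$lambda, 2, tolerance = 1e-6)
  expect_true(lc2$lambda_applied)
  expect_equal(median(lc2$p_corrected), 0.5, tolerance = 1e-6)
  # below the trigger nothing is corrected but lambda is still reported
  q3 <- c(0.2, 0.4549364 * 1.04, 2.5)
  lc3 <- lambda_correct(pchisq(q3, 1, lower.tail = FALSE),
                        lambda_trigger = 1.05)
  expect_equal(lc3$lambda, 1.04, tolerance = 1e-6)
  expect_false(lc3$lambda_applied)
  expect_identical(lc3$p_corrected, pchisq(q3, 1, lower.tail = FALSE))
  expect_error(lambda_correct(numeric(0)), "no p-values")
  expect_error(lambda_correct(c(0.5, 0)), "must lie in")
})

test_that("simpleM reproduces hand-computed eigen cases", {
  # two duplicated markers: eigenvalues {2, 0} -> Meff 1
  x <- sample(0:2, 40, replace = TRUE)
  calls <- cbind(m1 = x, m2 = x)
  rownames(calls) <- sprintf("i%02d", 1:40)
  gm <- genotype_matrix(calls, marker_map(c("m1", "m2"), c("1", "1"),
                                          c(100, 200)))
  expect_equal(simpleM_effective_tests(gm), 1L)

  # B perfect-LD blocks of size s built from orthogonal base columns -> B
  H <- hadamard(5)                       # 32 x 32, columns orthogonal
  base <- (H[, 2:5] + 1)                 # four orthogonal 0/2 columns
  calls <- base[, rep(1:4, each = 3)]    # 4 blocks of 3 duplicates
  dimnames(calls) <- list(sprintf("i%02d", 1:32), sprintf("m%02d", 1:12))
  gm <- genotype_matrix(calls, marker_map(colnames(calls), rep("1", 12),
                                          (1:12) * 100))
  expect_equal(simpleM_effective_tests(gm), 4L)

  # M exactly orthogonal markers -> ceiling(0.995 M)
  H <- hadamard(8)                       # 256 x 256
  calls <- H[, -1] + 1                   # 255 orthogonal 0/2 markers
  dimnames(calls) <- list(sprintf("i%03d", 1:256), sprintf("m%03d", 1:255))
  gm <- genotype_matrix(calls, marker_map(colnames(calls), rep("1", 255),
                                          (1:255) * 100))
  expect_equal(simpleM_effective_tests(gm), ceiling(0.995 * 255))
  # Meff never exceeds the marker count; equals it at fraction 1 (full rank)
  expect_equal(simpleM_effective_tests(gm, variance_fraction = 1), 255L)
})

test_that("Bonferroni LOD thresholds display the conventional values", {
  th <- lod_thresholds(1365)
  expect_equal(th$lod_sig_display, 4.4)
  expect_equal(th$lod_highsig_display, 5.1)
  expect_equal(th$lod_sig, -log10(0.05 / 1365))
  expect_equal(lod_thresholds(1)$lod_sig_display, 1.3)
})

test_that("scan F-tests match a first-principles sum-of-squares oracle", {
  set.seed(21)
  gm <- random_geno(30, 10, p_missing = 0.05)
  gm <- apply_marker_qc(gm, group_min = 3)$geno
  y <- rnorm(30) + 0.8 * (gm$calls[, 1] %in% 2L)
  ph <- make_pheno(data.frame(y = y), ids = rownames(gm$calls))
  sc <- qtl_scan(ph, gm, "y", config = run_config(lambda_trigger = Inf))
  for (j in seq_len(ncol(gm$calls))) {
    g <- gm$calls[, j]
    ok <- !is.na(g) & !is.na(y)
    gg <- g[ok]; yy <- y[ok]
    # one-way ANOVA from group-mean arithmetic
    grp_means <- tapply(yy, gg, mean)
    grand <- mean(yy)
    ssb <- sum(tapply(yy, gg, length) * (grp_means - grand)^2)
    ssw <- sum((yy - grp_means[as.character(gg)])^2)
    k <- length(grp_means)
    f <- (ssb / (k - 1)) / (ssw / (length(yy) - k))
    p_oracle <- pf(f, k - 1, length(yy) - k, lower.tail = FALSE)
    expect_equal(sc$table$p_raw[sc$table$marker == colnames(gm$calls)[j]],
                 p_oracle, tolerance = 1e-10)
    # partial R2 with no covariates is SSB/SST * 100
    expect_equal(sc$table$partial_r2[sc$table$marker == colnames(gm$calls)[j]],
                 ssb / (ssb + ssw) * 100, tolerance = 1e-8)
  }
})

test_that("a trait equal to a covariate leaves no genotype signal", {
  set.seed(31)
  gm <- random_geno(80, 15, p_missing = 0)
  litter <- sample(3:9, 80, replace = TRUE)
  ph <- make_pheno(data.frame(y = 2 + 0.5 * litter), litter_size = litter,
                   ids = rownames(gm$calls))
  sc <- qtl_scan(ph, gm, "y", covariates = "litter_size")
  expect_true(all(sc$table$lod_raw < 1e-8))
})

test_that("scan handles markers with < 2 observed classes as NA records", {
  calls <- cbind(m1 = rep(c(0L, 1L, 2L), each = 10),
                 m2 = rep(1L, 30),
                 m3 = rep(NA_integer_, 30))
  rownames(calls) <- sprintf("i%02d", 1:30)
  gm <- genotype_matrix(calls, marker_map(colnames(calls), rep("1", 3),
                                          c(1, 2, 3) * 100))
  set.seed(5)
  ph <- make_pheno(data.frame(y = rnorm(30)), ids = rownames(calls))
  sc <- qtl_scan(ph, gm, "y")
  expect_false(is.na(sc$table$p_raw[1]))
  expect_true(is.na(sc$table$p_raw[2]))   # monomorphic
  expect_true(is.na(sc$table$p_raw[3]))   # all missing
  expect_true(all(is.na(sc$table[3, c("mean_HOM1", "mean_HET", "mean_HOM2")])))
})

test_that("corrected LOD never exceeds raw LOD when inflation is corrected", {
  set.seed(41)
  sim <- simulate_ail(sim_config(n_chromosomes = 3, markers_per_chromosome = 30,
                                 pairs_per_generation = 30, offspring_per_pair = 5,
                                 final_generation = 6, seed = 41,
                                 qtl_specs = list(list(chr = 1, pos_cM = 30,
                                                       a = 1, d = 0,
                                                       trait = "y")),
                                 subfamily_sd = 1))
  ph <- simulate_phenotypes(sim)
  sc <- qtl_scan(ph, apply_marker_qc(sim$geno)$geno, "y")
  if (sc$lambda_applied && sc$lambda > 1) {
    ok <- !is.na(sc$table$lod_raw)
    expect_true(all(sc$table$lod_corrected[ok] <= sc$table$lod_raw[ok] + 1e-12))
  }
  expect_true(all(sc$table$partial_r2 >= 0 & sc$table$partial_r2 <= 100,
                  na.rm = TRUE))
})

test_that("LOD-drop regions follow the first-marker-past-the-drop rule", {
  mk_scan <- function(lods, bps = seq_along(lods) * 10) {
    tab <- data.frame(marker = sprintf("m%d", seq_along(lods)), chr = "1",
                      bp = bps, n_HOM1 = 10L, n_HET = 10L, n_HOM2 = 10L,
                      p_raw = 10^-lods, lod_raw = lods,
                      p_corrected = 10^-lods, lod_corrected = lods,
                      partial_r2 = 5, mean_HOM1 = 1, mean_HET = 0,
                      mean_HOM2 = -1, stringsAsFactors = FALSE)
    structure(list(trait = "y", table = tab, lambda = 1,
                   lambda_applied = FALSE, meff = length(lods),
                   thresholds = lod_thresholds(length(lods)),
                   covariates = character(), cofactor = NULL),
              class = "scan_result")
  }
  r <- lod_drop_region(mk_scan(c(1.0, 2.0, 5.0, 3.6, 3.4, 2.0)), "1")
  expect_equal(c(r$start_bp, r$top_bp, r$stop_bp), c(20, 30, 50))
  # top at the chromosome's first marker
  r2 <- lod_drop_region(mk_scan(c(5.0, 4.5, 3.0)), "1")
  expect_equal(c(r2$start_bp, r2$top_bp, r2$stop_bp), c(10, 10, 30))
  # adjacent tie at the maximum: earlier bp wins
  r3 <- lod_drop_region(mk_scan(c(1.0, 5.0, 5.0, 1.0)), "1")
  expect_equal(r3$top_bp, 20)
  # below threshold: no region, not an error
  expect_null(lod_drop_region(mk_scan(c(1, 2, 1)), "1", threshold = 4))
  # widening the drop never shrinks the region, and the top is always inside
  set.seed(51)
  for (i in 1:25) {
    lods <- round(runif(12, 0, 6), 2)
    s <- mk_scan(lods)
    r_a <- lod_drop_region(s, "1", lod_drop = 1.0)
    r_b <- lod_drop_region(s, "1", lod_drop = 2.5)
    expect_lte(r_b$start_bp, r_a$start_bp)
    expect_gte(r_b$stop_bp, r_a$stop_bp)
    expect_true(r_a$start_bp <= r_a$top_bp && r_a$top_bp <= r_a$stop_bp)
  }
})

test_that("MQM treats the cofactor and its LD proxies as NA and matches the single scan when the cofactor is null", {
  set.seed(61)
  sim <- simulate_ail(sim_config(n_chromosomes = 2, markers_per_chromosome = 25,
                                 pairs_per_generation = 60,
                                 offspring_per_pair = 8,
                                 final_generation = 5, seed = 61))
  ph <- simulate_phenotypes(sim)  # pure-noise trait
  gm <- apply_marker_qc(sim$geno)$geno
  cof <- colnames(gm$calls)[1]
  # duplicate the cofactor under a new name to create a perfect-LD marker
  calls2 <- cbind(gm$calls, dupmk = gm$calls[, cof])
  map2 <- rbind(gm$map, data.frame(marker_id = "dupmk", chr = gm$map$chr[1],
                                   bp = max(gm$map$bp) + 10L,
                                   cM = max(gm$map$cM) + 1))
  gm2 <- genotype_matrix(calls2, marker_map(map2$marker_id, map2$chr,
                                            map2$bp, map2$cM))
  single <- qtl_scan(ph, gm2, "trait1", config = run_config(lambda_trigger = Inf))
  mqm <- mqm_scan(ph, gm2, "trait1", cofactor_marker = cof,
                  config = run_config(lambda_trigger = Inf))
  expect_true(is.na(mqm$table$p_raw[mqm$table$marker == cof]))
  expect_true(is.na(mqm$table$p_raw[mqm$table$marker == "dupmk"]))
  # a cofactor with no effect barely changes the genome-wide LODs
  other <- mqm$table$chr != mqm$table$chr[mqm$table$marker == cof]
  ok <- other & !is.na(mqm$table$lod_raw) & !is.na(single$table$lod_raw)
  expect_lt(mean(abs(mqm$table$lod_raw[ok] - single$table$lod_raw[ok])), 0.1)
})
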