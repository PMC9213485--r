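#' Simulation configuration for an advanced intercross line
#'
#' Defines the generative model used throughout the test-bed: an AIL bred
#' from two fully inbred founder lines (line 1 homozygous for one allele at
#' every marker, line 2 for the other), random monogamous non-sib mating
#' from F2 onward, Haldane (no-interference) meiosis with a linear
#' bp-to-cM map, trait values built from sex/subfamily/litter-size covariate
#' effects plus additive-dominance QTL effects and Gaussian noise.
#'
#' Litter sizes vary: each generation's total offspring count
#' (`pairs_per_generation * offspring_per_pair`) is allocated to pairs
#' multinomially, so the litter-size covariate has realistic spread while
#' the expected population size per generation stays fixed.
#'
#' @param n_chromosomes Number of simulated chromosomes (autosome-like).
#' @param markers_per_chromosome Evenly spaced markers per chromosome.
#' @param chromosome_length_cM Genetic length of each chromosome (default 80).
#' @param cM_per_Mb Linear map rate (default 0.5, the mouse genome-wide
#'   average scale).
#' @param pairs_per_generation Breeding pairs per generation.
#' @param offspring_per_pair Mean offspring per pair.
#' @param final_generation Last intercross generation (default 10).
#' @param qtl_specs List of QTL specifications, each a list with elements
#'   `chr`, `pos_cM`, `a` (additive effect), `d` (dominance effect),
#'   `trait`.  The genotype value at the nearest marker enters the trait as
#'   +a / d / -a for HOM1 / HET / HOM2.
#' @param sex_effect Additive shift for males.
#' @param subfamily_sd SD of per-dam random family effects.
#' @param litter_slope Linear litter-size effect per pup.
#' @param residual_sd Residual (environmental) SD, default 1.
#' @param trait_intercept Baseline trait value.
#' @param missing_rate Uniform genotype missingness rate injected after
#'   simulation (default 0).
#' @param seed Integer master seed; all stages derive their streams from it.
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_ail()], [simulate_phenotypes()]
#' @export
sim_config <- function(n_chromosomes = 5L, markers_per_chromosome = 100L,
                       chromosome_length_cM = 80, cM_per_Mb = 0.5,
                       pairs_per_generation = 25L, offspring_per_pair = 5L,
                       final_generation = 10L,
                       qtl_specs = list(),
                       sex_effect = 0, subfamily_sd = 0, litter_slope = 0,
                       residual_sd = 1, trait_intercept = 0,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 19,
            markers_per_chromosome >= 2,
            chromosome_length_cM > 0, cM_per_Mb > 0,
            pairs_per_generation >= 1, offspring_per_pair >= 1,
            final_generation >= 2,
            residual_sd >= 0, missing_rate >= 0, missing_rate < 1)
  for (q in qtl_specs) {
    stopifnot(all(c("chr", "pos_cM", "a", "d", "trait") %in% names(q)))
    if (!as.character(q$chr) %in% as.character(seq_len(n_chromosomes)))
      stop("QTL chromosome ", q$chr, " not in the simulated map")
    stopifnot(is.finite(q$a), is.finite(q$d))
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 chromosome_length_cM = chromosome_length_cM,
                 cM_per_Mb = cM_per_Mb,
                 pairs_per_generation = as.integer(pairs_per_generation),
                 offspring_per_pair = as.integer(offspring_per_pair),
                 final_generation = as.integer(final_generation),
                 qtl_specs = qtl_specs,
                 sex_effect = sex_effect, subfamily_sd = subfamily_sd,
                 litter_slope = litter_slope, residual_sd = residual_sd,
                 trait_intercept = trait_intercept,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evenly spaced marker map over the configured chromosomes.
sim_marker_map <- function(config) {
  chr_len_bp <- config$chromosome_length_cM / config$cM_per_Mb * 1e6
  m <- config$markers_per_chromosome
  per_chr <- lapply(seq_len(config$n_chromosomes), function(cc) {
    bp <- round(seq(1e6, chr_len_bp, length.out = m))
    data.frame(marker_id = sprintf("c%dm%03d", cc, seq_len(m)),
               chr = as.character(cc), bp = as.integer(bp),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, per_chr)
  map$cM <- map$bp * config$cM_per_Mb / 1e6
  marker_map(map$marker_id, map$chr, map$bp, map$cM)
}

# Random monogamous pairing avoiding full-sib pairs (same sire and dam).
# All F1 animals are full sibs by construction, so callers skip the sib rule
# when pairing F1.
.form_pairs <- function(members, n_pairs, avoid_sibs = TRUE, max_try = 100L) {
  males <- members[members$sex == "M", , drop = FALSE]
  females <- members[members$sex == "F", , drop = FALSE]
  if (nrow(males) < n_pairs || nrow(females) < n_pairs)
    stop("not enough animals of each sex to form ", n_pairs,
         " pairs; increase pairs_per_generation or offspring_per_pair")
  for (try in seq_len(max_try)) {
    m_pool <- males[sample.int(nrow(males)), , drop = FALSE]
    f_pool <- females[sample.int(nrow(females)), , drop = FALSE]
    sire_ids <- character(n_pairs); dam_ids <- character(n_pairs)
    used <- rep(FALSE, nrow(m_pool))
    ok <- TRUE
    for (i in seq_len(n_pairs)) {
      f <- f_pool[i, ]
      cand <- which(!used & (!avoid_sibs |
                             !(m_pool$sire == f$sire & m_pool$dam == f$dam)))
      if (!length(cand)) { ok <- FALSE; break }
      j <- cand[1L]
      used[j] <- TRUE
      sire_ids[i] <- m_pool$id[j]
      dam_ids[i] <- f_pool$id[i]
    }
    if (ok) return(data.frame(sire = sire_ids, dam = dam_ids,
                              stringsAsFactors = FALSE))
  }
  stop("could not form ", n_pairs, " non-sib pairs after ", max_try,
       " attempts; increase pairs_per_generation")
}

#' Simulate an advanced intercross line
#'
#' Forward-simulates an AIL from two fully inbred founders: F1 from the
#' single founder pair, then random monogamous mating within each
#' generation (full-sib pairs excluded from F2 onward) up to
#' `final_generation`.  Meiosis follows Haldane's no-interference model:
#' the crossover count per chromosome is Poisson with mean
#' `chromosome_length_cM / 100` and crossover positions are uniform.
#' Marker genetic positions come from the linear `cM_per_Mb` map.
#'
#' The random streams are ordered so that the pedigree (sexes, litter
#' allocation, pairings) is drawn before any meiosis, and genotype emission
#' from crossover breakpoints is deterministic; changing the marker density
#' therefore does not perturb the pedigree.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{geno}{[genotype_matrix()] of the final generation;}
#'     \item{pedigree}{data.frame (id, generation, sire, dam, sex) for all
#'       generations;}
#'     \item{haplotypes}{list of two individuals x markers 0/1 allele
#'       matrices (`pat`, `mat`), the phased gametes of the final
#'       generation;}
#'     \item{map}{the marker map;}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_ail(sim_config(n_chromosomes = 2,
#'   markers_per_chromosome = 10, pairs_per_generation = 5,
#'   offspring_per_pair = 4, final_generation = 3, seed = 42))
#' dim(sim$geno)
#' @export
simulate_ail <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- sim_marker_map(config)
  chrs <- unique(map$chr)
  pos_by_chr <- split(map$cM, factor(map$chr, levels = chrs))
  n_mark <- nrow(map)

  ## ---- phase A: pedigree ----
  n_per_gen <- config$pairs_per_generation * config$offspring_per_pair
  n_f1 <- max(2L * config$pairs_per_generation, n_per_gen)
  ped <- data.frame(id = c("F0_1", "F0_2"), generation = 0L,
                    sire = NA_character_, dam = NA_character_,
                    sex = c("M", "F"), stringsAsFactors = FALSE)
  gen_members <- list()
  # F1: single founder pair
  f1_sex <- ifelse(runif(n_f1) < 0.5, "M", "F")
  f1 <- data.frame(id = sprintf("G1_%03d", seq_len(n_f1)), generation = 1L,
                   sire = "F0_1", dam = "F0_2", sex = f1_sex,
                   stringsAsFactors = FALSE)
  ped <- rbind(ped, f1)
  gen_members[[1L]] <- f1
  for (g in 2:config$final_generation) {
    parents <- gen_members[[g - 1L]]
    pairs <- .form_pairs(parents, config$pairs_per_generation,
                         avoid_sibs = (g > 2L))
    litter <- as.integer(rmultinom(1L, n_per_gen,
                                   rep(1, config$pairs_per_generation)))
    kids <- data.frame(id = sprintf("G%d_%03d", g, seq_len(n_per_gen)),
                       generation = g,
                       sire = rep(pairs$sire, litter),
                       dam = rep(pairs$dam, litter),
                       sex = ifelse(runif(n_per_gen) < 0.5, "M", "F"),
                       stringsAsFactors = FALSE)
    ped <- rbind(ped, kids)
    gen_members[[g]] <- kids
  }

  ## ---- phase B: meioses (crossover counts, phases, positions) ----
  # two gametes (pat, mat) per (offspring, chromosome), in pedigree order;
  # drawn in bulk so the stream depends only on pedigree size and
  # chromosome count, never on marker density
  nonfounders <- ped[ped$generation > 0L, , drop = FALSE]
  nf <- nrow(nonfounders)
  nchr <- length(chrs)
  len <- config$chromosome_length_cM
  nmei <- nf * nchr * 2L
  xo_n <- rpois(nmei, len / 100)
  xo_start <- sample(c(1L, 2L), nmei, replace = TRUE)
  xo_pos <- runif(sum(xo_n), 0, len)
  grp <- rep.int(seq_len(nmei), xo_n)
  xo_pos <- xo_pos[order(grp, xo_pos)]  # sorted within each meiosis
  xo_off <- c(0L, cumsum(xo_n))

  ## ---- phase C: deterministic haplotype propagation ----
  # gamete from parent haplotype pair (h1, h2) under meiosis `mk` for the
  # markers at genetic positions `pos`
  emit <- function(h1, h2, mk, pos) {
    n <- xo_n[mk]; s <- xo_start[mk]
    if (n == 0L) return(if (s == 1L) h1 else h2)
    xo <- xo_pos[(xo_off[mk] + 1L):(xo_off[mk] + n)]
    use2 <- ((s - 1L + findInterval(pos, xo)) %% 2L) == 1L
    out <- h1
    out[use2] <- h2[use2]
    out
  }
  haps <- list(
    F0_1 = list(pat = rep(1L, n_mark), mat = rep(1L, n_mark)),
    F0_2 = list(pat = rep(0L, n_mark), mat = rep(0L, n_mark)))
  mk_chr_idx <- split(seq_len(n_mark), factor(map$chr, levels = chrs))
  sires <- nonfounders$sire; dams <- nonfounders$dam
  for (i in seq_len(nf)) {
    sire_h <- haps[[sires[i]]]; dam_h <- haps[[dams[i]]]
    pat <- integer(n_mark); mat <- integer(n_mark)
    base <- (i - 1L) * nchr * 2L
    for (k in seq_len(nchr)) {
      idx <- mk_chr_idx[[k]]
      pos <- pos_by_chr[[k]]
      pat[idx] <- emit(sire_h$pat[idx], sire_h$mat[idx], base + 2L * k - 1L, pos)
      mat[idx] <- emit(dam_h$pat[idx], dam_h$mat[idx], base + 2L * k, pos)
    }
    haps[[nonfounders$id[i]]] <- list(pat = pat, mat = mat)
  }
  final <- gen_members[[config$final_generation]]
  pat_m <- t(vapply(final$id, function(id) haps[[id]]$pat, integer(n_mark)))
  mat_m <- t(vapply(final$id, function(id) haps[[id]]$mat, integer(n_mark)))
  calls <- pat_m + mat_m
  dimnames(calls) <- list(final$id, map$marker_id)
  dimnames(pat_m) <- dimnames(mat_m) <- dimnames(calls)

  ## ---- phase D: missingness ----
  if (config$missing_rate > 0) {
    drop <- runif(length(calls)) < config$missing_rate
    calls[drop] <- NA_integer_
  }

  list(geno = genotype_matrix(calls, map), pedigree = ped,
       haplotypes = list(pat = pat_m, mat = mat_m),
       map = map, config = config)
}

#' Simulate phenotypes on an AIL population
#'
#' Trait values follow a linear model:
#' `intercept + sex_effect * 1[male] + subfamily effect + litter_slope *
#' litter_size + sum over QTLs of g(genotype; a, d) + Normal(0, residual_sd^2)`
#' where the genotype value g is +a for HOM1, d for HET and -a for HOM2 at
#' the marker nearest each QTL's genetic position.  Subfamily effects are
#' drawn per dam from `Normal(0, subfamily_sd^2)`, independently per trait.
#' Litter size is the realized offspring count of the individual's dam.
#'
#' Individuals with a missing genotype at a QTL marker get a missing trait
#' value (flagged NA, never silently zero).
#'
#' @param sim Result of [simulate_ail()].
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @param seed Seed for the phenotype stream; defaults to a fixed offset of
#'   the master seed so genotype and phenotype draws stay decoupled.
#' @return A [phenotype_table()] for the final generation, with attribute
#'   `"qtl_truth"`: a data.frame mapping each QTL to the marker that carries
#'   its effect.
#' @export
simulate_phenotypes <- function(sim, config = sim$config,
                                seed = config$seed + 500009L) {
  set.seed(seed)
  ped <- sim$pedigree
  final <- ped[ped$generation == max(ped$generation), , drop = FALSE]
  final <- final[match(rownames(sim$geno$calls), final$id), , drop = FALSE]
  n <- nrow(final)
  litter <- table(ped$dam[ped$generation == max(ped$generation)])
  litter_size <- as.integer(litter[final$dam])

  traits <- unique(vapply(config$qtl_specs, `[[`, "", "trait"))
  if (!length(traits)) traits <- "trait1"
  map <- sim$geno$map

  truth <- data.frame(trait = character(), chr = character(),
                      marker = character(), a = numeric(), d = numeric(),
                      stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, n, length(traits),
                 dimnames = list(final$id, traits))
  dams <- unique(final$dam)
  for (tr in traits) {
    subfam_eff <- setNames(rnorm(length(dams), 0, config$subfamily_sd), dams)
    y <- config$trait_intercept +
      config$sex_effect * (final$sex == "M") +
      subfam_eff[final$dam] +
      config$litter_slope * litter_size
    for (q in config$qtl_specs) {
      if (q$trait != tr) next
      on_chr <- map[map$chr == as.character(q$chr), , drop = FALSE]
      mk <- on_chr$marker_id[which.min(abs(on_chr$cM - q$pos_cM))]
      g <- sim$geno$calls[, mk]
      y <- y + ifelse(is.na(g), NA_real_,
                      ifelse(g == 2L, q$a, ifelse(g == 1L, q$d, -q$a)))
      truth <- rbind(truth, data.frame(trait = tr, chr = as.character(q$chr),
                                       marker = mk, a = q$a, d = q$d,
                                       stringsAsFactors = FALSE))
    }
    vals[, tr] <- y + rnorm(n, 0, config$residual_sd)
  }
  ph <- phenotype_table(final$id, final$sex, final$dam, litter_size,
                        as.data.frame(vals))
  attr(ph, "qtl_truth") <- truth
  ph
}

#' Simulate two-group expression intensities
#'
#' Per-gene baseline log2 intensities are Normal(`baseline_mean`,
#' `baseline_sd`^2); genes listed in `de_specs` are shifted by their
#' `log2_effect` in group 1 (the line of interest); i.i.d. Normal noise with
#' SD `noise_sd` is added per sample; intensities are exported on the raw
#' `2^x` scale so the normalization stage exercises its log2 step.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Integer vector of length 2: samples in groups 1 and 2
#'   (default `c(6, 5)`, matching a typical small array comparison).
#' @param de_specs List of `list(gene = <index or name>, log2_effect = <x>)`.
#' @param baseline_mean,baseline_sd Baseline log2 intensity distribution.
#' @param noise_sd Per-sample log2 noise SD (default 0.25).
#' @param seed Integer seed.
#' @return List with `expr` (an [expression_matrix()], raw scale, groups
#'   `LINE1`/`LINE2`) and `truth` (data.frame gene, log2_effect, is_de).
#' @export
simulate_expression <- function(n_genes = 500L, n_per_group = c(6L, 5L),
                                de_specs = list(), baseline_mean = 8,
                                baseline_sd = 2, noise_sd = 0.25, seed = 1L) {
  if (any(n_per_group < 2L)) stop("need at least 2 samples per group")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  groups <- factor(rep(c("LINE1", "LINE2"), n_per_group),
                   levels = c("LINE1", "LINE2"))
  base <- rnorm(n_genes, baseline_mean, baseline_sd)
  shift <- setNames(numeric(n_genes), genes)
  for (sp in de_specs) {
    g <- if (is.numeric(sp$gene)) genes[sp$gene] else sp$gene
    shift[g] <- sp$log2_effect
  }
  logx <- matrix(base, n_genes, sum(n_per_group)) +
    outer(shift, as.numeric(groups == "LINE1")) +
    matrix(rnorm(n_genes * sum(n_per_group), 0, noise_sd), n_genes)
  dimnames(logx) <- list(genes, sprintf("%s_s%d", as.character(groups),
                                        unlist(lapply(n_per_group, seq_len))))
  list(expr = expression_matrix(2^logx, groups, log2_transformed = FALSE),
       truth = data.frame(gene = genes, log2_effect = unname(shift),
                          is_de = shift != 0, stringsAsFactors = FALSE))
}

#' Default annotation category frequencies
#'
#' Per-gene Bernoulli probabilities for each variant-annotation category
#' drawn by [simulate_annotations()].
#'
#' @param ... Named overrides of individual frequencies.
#' @return Named numeric vector over the categories
#'   stop_gain, stop_loss, missense_deleterious_domain,
#'   missense_deleterious, missense_tolerated_domain, missense_tolerated,
#'   promoter, splice_site, utr, enhancer, ctcf.
#' @export
annotation_frequencies <- function(...) {
  f <- c(stop_gain = 0.02, stop_loss = 0.01,
         missense_deleterious_domain = 0.05, missense_deleterious = 0.05,
         missense_tolerated_domain = 0.05, missense_tolerated = 0.10,
         promoter = 0.15, splice_site = 0.05, utr = 0.20,
         enhancer = 0.20, ctcf = 0.15)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(f))
    if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
    f[names(over)] <- over
  }
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  f
}

#' Simulate a variant-annotation table with known truth scores
#'
#' For each gene, each annotation category is drawn independently with its
#' configured frequency and emitted as one table row.  Alongside the table,
#' the generator reports the prioritization score each gene must receive
#' under the decision tree given its drawn categories and the supplied
#' DE/KEGG status; the truth arithmetic here is written independently of
#' the scoring module so the two can be checked against each other.
#'
#' @param genes Character vector of gene symbols.
#' @param frequencies Named vector from [annotation_frequencies()].
#' @param de_genes Genes counted as differentially expressed (score 2).
#' @param kegg_genes Genes counted as pathway members (score 1).
#' @param seed Integer seed.
#' @return List with `annotations` (a [variant_annotation_table()]) and
#'   `truth` (data.frame gene, truth_score).
#' @export
simulate_annotations <- function(genes, frequencies = annotation_frequencies(),
                                 de_genes = character(),
                                 kegg_genes = character(), seed = 1L) {
  if (any(frequencies < 0 | frequencies > 1))
    stop("frequencies must lie in [0, 1]")
  set.seed(seed)
  rows <- list()
  truth <- numeric(length(genes))
  mk_row <- function(gene, cons, sift, dom, reg) {
    data.frame(gene_id = gene, gene_symbol = gene, chr = "1",
               bp = length(rows) + 1L, consequence = cons, sift = sift,
               in_domain = dom, regulatory = reg, stringsAsFactors = FALSE)
  }
  for (i in seq_along(genes)) {
    g <- genes[i]
    has <- runif(length(frequencies)) < frequencies
    names(has) <- names(frequencies)
    if (has["stop_gain"]) rows[[length(rows) + 1L]] <- mk_row(g, "stop_gain", "n/a", FALSE, "none")
    if (has["stop_loss"]) rows[[length(rows) + 1L]] <- mk_row(g, "stop_loss", "n/a", FALSE, "none")
    if (has["missense_deleterious_domain"]) rows[[length(rows) + 1L]] <- mk_row(g, "missense", "deleterious", TRUE, "none")
    if (has["missense_deleterious"]) rows[[length(rows) + 1L]] <- mk_row(g, "missense", "deleterious", FALSE, "none")
    if (has["missense_tolerated_domain"]) rows[[length(rows) + 1L]] <- mk_row(g, "missense", "tolerated", TRUE, "none")
    if (has["missense_tolerated"]) rows[[length(rows) + 1L]] <- mk_row(g, "missense", "tolerated", FALSE, "none")
    for (reg in c("promoter", "splice_site", "utr", "enhancer", "ctcf")) {
      if (has[reg]) {
        reg_lab <- if (reg == "ctcf") "ctcf_binding_site" else reg
        rows[[length(rows) + 1L]] <- mk_row(g, "none", "n/a", FALSE, reg_lab)
      }
    }
    # independent truth arithmetic for the decision tree
    s <- 0
    if (has["stop_gain"] || has["stop_loss"]) s <- s + 3
    if (has["missense_deleterious_domain"] || has["missense_tolerated_domain"]) s <- s + 3
    if (has["missense_deleterious_domain"] || has["missense_deleterious"]) {
      s <- s + 3
    } else if (has["missense_tolerated_domain"] || has["missense_tolerated"]) {
      s <- s + 1
    }
    if (has["promoter"]) s <- s + 3
    if (has["splice_site"]) s <- s + 3
    if (has["utr"]) s <- s + 1
    if (has["enhancer"]) s <- s + 1
    if (has["ctcf"]) s <- s + 1
    if (g %in% de_genes) s <- s + 2
    if (g %in% kegg_genes) s <- s + 1
    truth[i] <- s
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), gene_symbol = character(),
               chr = character(), bp = integer(), consequence = character(),
               sift = character(), in_domain = logical(),
               regulatory = character(), stringsAsFactors = FALSE)
  ann$bp <- seq_len(nrow(ann)) + 0L
  list(annotations = variant_annotation_table(ann),
       truth = data.frame(gene = genes, truth_score = truth,
                          stringsAsFactors = FALSE))
}
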