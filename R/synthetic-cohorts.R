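# Synthetic two-cohort generator with planted ground truth. Every source of
# randomness flows from the single config seed through a documented
# seed-splitting scheme (.derive_seed): no global random state leaks in or
# out, and the same config always produces byte-identical bundles.

.derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Specification of one synthetic analyte
#'
#' The analyte's latent trait is
#' `L = sum(gamma_j * z(cov_j)) + sum(slope_k * dosage_k) + loading * batch
#'  + N(0, noise_sd)` on the transformed (association) scale; the raw assay
#' value is `exp(L)` and the LLOQ is placed at the `censor_q` quantile of
#' the raw distribution so the below-LLOQ fraction is controlled exactly.
#'
#' @param analyte_id identifier.
#' @param causal_variants character vector of variant ids with planted
#'   effects (may be empty).
#' @param slopes numeric, transformed-scale effect per alt-allele copy, one
#'   per causal variant.
#' @param covariate_effects named numeric over standardized covariates
#'   (`age`, `bmi`, `pack_years`, `sex`, `current_smoker`).
#' @param censor_q quantile of the raw distribution at which the LLOQ sits,
#'   in [0, 1); 0 means effectively uncensored.
#' @param batch_loading loading on the cohort's latent batch factor.
#' @param noise_sd residual SD of the latent trait; `NULL` budgets the
#'   noise so the latent variance is approximately 1 (never below SD 0.2).
#' @param cellcount_effects optional named numeric over the seven cell-count
#'   covariates (standardized), for the CBC sensitivity analysis.
#' @param gene_chromosome,gene_start,gene_end encoding-gene locus; defaults
#'   (`NA`) place the gene at the first causal variant (making it local) or,
#'   with no causal variant, on chromosome "1" at 1-10001 bp.
#' @return list of class `analyte_spec`.
#' @export
analyte_spec <- function(analyte_id, causal_variants = character(),
                         slopes = numeric(), covariate_effects = c(age = 0.2),
                         censor_q = 0, batch_loading = 0, noise_sd = NULL,
                         cellcount_effects = NULL,
                         gene_chromosome = NA, gene_start = NA, gene_end = NA) {
  if (length(causal_variants) != length(slopes))
    stop("causal_variants and slopes must have equal length")
  if (censor_q < 0 || censor_q >= 1)
    stop("censor_q must be in [0, 1)")
  structure(list(analyte_id = analyte_id, causal_variants = causal_variants,
                 slopes = slopes, covariate_effects = covariate_effects,
                 censor_q = censor_q, batch_loading = batch_loading,
                 noise_sd = noise_sd, cellcount_effects = cellcount_effects,
                 gene_chromosome = gene_chromosome, gene_start = gene_start,
                 gene_end = gene_end),
            class = "analyte_spec")
}

#' Specification of one synthetic trio
#'
#' @param variant_id,analyte_id,phenotype the trio members; `phenotype`
#'   names a phenotype-table column.
#' @param graph generating causal graph: `"causal"` (g -> B -> D),
#'   `"reactive"` (g -> D -> B), `"independent"` (B <- g -> D), `"collide"`
#'   (g -> B <- D), `"complete"` (all edges), or `"null"` (no edges into D).
#' @param binary generate the phenotype through a logistic link?
#' @param strengths named list of edge coefficients: `snp_disease`,
#'   `biomarker_disease`, `disease_biomarker`, `noise_sd`; defaults give
#'   strong, comfortably detectable edges at cohorts of several hundred.
#' @return list of class `trio_spec`.
#' @export
trio_spec <- function(variant_id, analyte_id, phenotype,
                      graph = c("causal", "reactive", "independent",
                                "collide", "complete", "null"),
                      binary = FALSE, strengths = list()) {
  graph <- match.arg(graph)
  def <- list(snp_disease = 0.45, biomarker_disease = 0.6,
              disease_biomarker = 0.6, noise_sd = 1)
  def[names(strengths)] <- strengths
  structure(list(variant_id = variant_id, analyte_id = analyte_id,
                 phenotype = phenotype, graph = graph, binary = binary,
                 strengths = def),
            class = "trio_spec")
}

#' Configuration of a synthetic two-cohort study
#'
#' Defaults emulate the structure of a two-site COPD biomarker-GWAS study:
#' cohorts of 750 and 590 subjects, genotypes in Hardy-Weinberg proportions
#' over a MAF spectrum shared between cohorts, optional LD proxy blocks,
#' covariate-correlated log-normal biomarkers with planted local/distant
#' pQTL effects and LLOQ left-censoring, and phenotypes generated under
#' specified trio causal graphs.
#'
#' @param seed mandatory integer master seed.
#' @param n1,n2 cohort sizes (defaults 750 and 590).
#' @param n_variants number of variants in the shared panel.
#' @param maf_range range the per-variant MAF is drawn uniformly from.
#' @param n_sites number of clinical sites per cohort.
#' @param ld_blocks list of lists `list(seed_variant =, proxies =,
#'   copy_prob =)`: each proxy allele copies the block seed variant's allele
#'   with probability `copy_prob` (else a fresh Bernoulli(MAF) draw), giving
#'   allele-level correlation ~ `copy_prob`, i.e. dosage r^2 ~ copy_prob^2.
#' @param analytes list of [analyte_spec()]s.
#' @param trios list of [trio_spec()]s (at most one per analyte).
#' @param missing_rate genotype missingness rate, default 0.
#' @param cell_counts simulate the seven CBC covariates?
#' @param effect_multiplier length-2 multiplier on planted pQTL slopes per
#'   cohort (heterogeneity knob), default `c(1, 1)`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n1 = 750, n2 = 590, n_variants = 50,
                       maf_range = c(0.01, 0.5), n_sites = 3,
                       ld_blocks = list(), analytes = list(), trios = list(),
                       missing_rate = 0, cell_counts = FALSE,
                       effect_multiplier = c(1, 1)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            length(effect_multiplier) == 2)
  an_ids <- vapply(analytes, function(a) a$analyte_id, character(1))
  if (anyDuplicated(an_ids)) stop("duplicate analyte ids in config")
  tr_an <- vapply(trios, function(t) t$analyte_id, character(1))
  if (anyDuplicated(tr_an))
    stop("conflicting trio specs: an analyte may appear in only one graph")
  structure(list(seed = as.integer(seed), n1 = n1, n2 = n2,
                 n_variants = n_variants, maf_range = maf_range,
                 n_sites = n_sites, ld_blocks = ld_blocks,
                 analytes = analytes, trios = trios,
                 missing_rate = missing_rate, cell_counts = cell_counts,
                 effect_multiplier = effect_multiplier),
            class = "sim_config")
}

# shared variant panel: ids, positions round-robin over chromosomes, MAFs
.sim_panel <- function(config) {
  nv <- config$n_variants
  ids <- sprintf("v%04d", seq_len(nv))
  chr <- as.character(rep_len(1:22, nv))
  pos <- 100000L + 100000L * (seq_len(nv) - 1L) %/% 22L
  set.seed(.derive_seed(config$seed, "maf"))
  maf <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  list(variants = variant_info(ids, chr, pos, rep("A", nv), rep("G", nv)),
       maf = stats::setNames(maf, ids))
}

#' Simulate a cohort's genotype matrix
#'
#' Genotypes are drawn in Hardy-Weinberg proportions (two independent
#' Bernoulli(MAF) allele copies) from a MAF spectrum shared across cohorts;
#' within an LD block, each proxy allele copies the block seed variant's
#' allele with the stated probability. Optional uniform missingness.
#'
#' @param config a `sim_config`.
#' @param cohort 1 or 2.
#' @return a `genotype_matrix`.
#' @export
simulate_genotypes <- function(config, cohort) {
  panel <- .sim_panel(config)
  n <- if (cohort == 1) config$n1 else config$n2
  nv <- config$n_variants
  ids <- panel$variants$variant_id
  set.seed(.derive_seed(config$seed, paste0("geno", cohort)))
  # allele-level simulation so LD proxies can copy allele copies
  a1 <- matrix(stats::rbinom(n * nv, 1, rep(panel$maf, each = n)), n, nv)
  a2 <- matrix(stats::rbinom(n * nv, 1, rep(panel$maf, each = n)), n, nv)
  colnames(a1) <- colnames(a2) <- ids
  for (blk in config$ld_blocks) {
    sv <- blk$seed_variant
    for (pv in blk$proxies) {
      keep1 <- stats::rbinom(n, 1, blk$copy_prob) == 1
      keep2 <- stats::rbinom(n, 1, blk$copy_prob) == 1
      a1[keep1, pv] <- a1[keep1, sv]
      a2[keep2, pv] <- a2[keep2, sv]
    }
  }
  dos <- a1 + a2
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * nv) < config$missing_rate, n, nv)
    dos[miss] <- NA_real_
  }
  subjects <- sprintf("C%d_%04d", cohort, seq_len(n))
  genotype_matrix(dos, panel$variants, subjects)
}

#' Simulate a cohort's covariate table
#'
#' Site uniform over `n_sites`; sex Bernoulli(0.5); age N(66, 8); BMI
#' N(28, 5); pack-years N(50, 25) truncated at 10; current smoker
#' Bernoulli(0.3); optionally seven log-normal-scale cell counts.
#'
#' @param config a `sim_config`.
#' @param cohort 1 or 2.
#' @return covariate data frame with `subject_id` first.
#' @export
simulate_covariates <- function(config, cohort) {
  n <- if (cohort == 1) config$n1 else config$n2
  set.seed(.derive_seed(config$seed, paste0("cov", cohort)))
  out <- data.frame(
    subject_id = sprintf("C%d_%04d", cohort, seq_len(n)),
    site = paste0("site", sample.int(config$n_sites, n, replace = TRUE)),
    sex = stats::rbinom(n, 1, 0.5),
    age = stats::rnorm(n, 66, 8),
    bmi = stats::rnorm(n, 28, 5),
    pack_years = pmax(10, stats::rnorm(n, 50, 25)),
    current_smoker = stats::rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE
  )
  if (config$cell_counts) {
    means <- c(neutrophil = 4.4, lymphocyte = 2.0, monocyte = 0.55,
               eosinophil = 0.2, basophil = 0.05, red_blood_cells = 4.7,
               platelet = 250)
    for (nm in names(means))
      out[[nm]] <- means[[nm]] * exp(stats::rnorm(n, 0, 0.25))
  }
  out
}

# standardized covariate/cell-count columns used as latent-trait inputs
.std_cols <- function(covariates, nms) {
  sapply(nms, function(nm) {
    x <- covariates[[nm]]
    if (is.null(x)) stop("covariate ", nm, " referenced by spec but absent")
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
}

# latent trait for one analyte (before noise); returns list(mean, planned_var)
.analyte_latent_mean <- function(spec, genotypes, covariates, batch, maf,
                                 eff_mult) {
  n <- nrow(genotypes$dosage)
  mu <- rep(0, n)
  planned <- 0
  if (length(spec$causal_variants) > 0) {
    for (k in seq_along(spec$causal_variants)) {
      v <- spec$causal_variants[k]
      if (!v %in% colnames(genotypes$dosage))
        stop("causal variant ", v, " not in the genotype panel")
      sl <- spec$slopes[k] * eff_mult
      d <- genotypes$dosage[, v]
      d[is.na(d)] <- 2 * maf[v]
      mu <- mu + sl * d
      planned <- planned + sl^2 * 2 * maf[v] * (1 - maf[v])
    }
  }
  if (length(spec$covariate_effects) > 0) {
    Zc <- .std_cols(covariates, names(spec$covariate_effects))
    mu <- mu + as.vector(Zc %*% spec$covariate_effects)
    planned <- planned + sum(spec$covariate_effects^2)
  }
  if (!is.null(spec$cellcount_effects) && length(spec$cellcount_effects) > 0) {
    Zb <- .std_cols(covariates, names(spec$cellcount_effects))
    mu <- mu + as.vector(Zb %*% spec$cellcount_effects)
    planned <- planned + sum(spec$cellcount_effects^2)
  }
  if (spec$batch_loading != 0) {
    mu <- mu + spec$batch_loading * batch
    planned <- planned + spec$batch_loading^2
  }
  list(mean = mu, planned_var = planned)
}

.analyte_noise_sd <- function(spec, planned_var) {
  if (!is.null(spec$noise_sd)) return(spec$noise_sd)
  sqrt(max(0.04, 1 - planned_var))
}

# exponentiate a latent trait and censor at the censor_q quantile
.latent_to_raw <- function(latent, censor_q) {
  raw <- exp(latent)
  lloq <- if (censor_q > 0) unname(stats::quantile(raw, censor_q)) else min(raw) / 2
  list(raw = raw, lloq = lloq)
}

#' Simulate a cohort's biomarker panel with planted pQTL effects
#'
#' Each analyte's latent trait combines standardized-covariate effects,
#' planted per-allele slopes (scaled by the cohort's effect multiplier), a
#' latent batch factor, and gaussian noise budgeted so the latent variance
#' is near 1 unless `noise_sd` is given; raw values are `exp(latent)` with
#' the LLOQ at the configured raw-scale quantile.
#'
#' @param config a `sim_config`.
#' @param genotypes the cohort's `genotype_matrix`.
#' @param covariates the cohort's covariate table.
#' @param cohort 1 or 2.
#' @return list: `panel` (a `biomarker_panel`), `latent` (matrix of latent
#'   traits), `batch` (latent batch factor), `truth` (per-analyte list of
#'   causal variants, slopes, noise SD, LLOQ).
#' @export
simulate_biomarkers <- function(config, genotypes, covariates, cohort) {
  if (length(config$analytes) == 0) stop("config has no analyte specs")
  n <- nrow(genotypes$dosage)
  panel <- .sim_panel(config)
  eff_mult <- config$effect_multiplier[cohort]
  set.seed(.derive_seed(config$seed, paste0("biom", cohort)))
  batch <- stats::rnorm(n)
  ids <- vapply(config$analytes, function(a) a$analyte_id, character(1))
  raw <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  latent <- raw
  lloq <- stats::setNames(numeric(length(ids)), ids)
  truth <- list()
  for (j in seq_along(config$analytes)) {
    spec <- config$analytes[[j]]
    lm_ <- .analyte_latent_mean(spec, genotypes, covariates, batch,
                                panel$maf, eff_mult)
    nsd <- .analyte_noise_sd(spec, lm_$planned_var)
    L <- lm_$mean + stats::rnorm(n, 0, nsd)
    lr <- .latent_to_raw(L, spec$censor_q)
    latent[, j] <- L
    raw[, j] <- lr$raw
    lloq[j] <- lr$lloq
    truth[[spec$analyte_id]] <- list(causal_variants = spec$causal_variants,
                                     slopes = spec$slopes * eff_mult,
                                     noise_sd = nsd, lloq = lr$lloq,
                                     censor_q = spec$censor_q)
  }
  gene <- lapply(config$analytes, function(spec) {
    if (!is.na(spec$gene_chromosome))
      return(spec[c("gene_chromosome", "gene_start", "gene_end")])
    if (length(spec$causal_variants) > 0) {
      vi <- panel$variants[match(spec$causal_variants[1],
                                 panel$variants$variant_id), ]
      list(gene_chromosome = vi$chromosome, gene_start = vi$position,
           gene_end = vi$position + 10000L)
    } else list(gene_chromosome = "1", gene_start = 1L, gene_end = 10001L)
  })
  am <- analyte_meta(ids, toupper(ids),
                     vapply(gene, function(g) as.character(g$gene_chromosome), character(1)),
                     vapply(gene, function(g) as.integer(g$gene_start), integer(1)),
                     vapply(gene, function(g) as.integer(g$gene_end), integer(1)),
                     lloq)
  bp <- biomarker_panel(raw, am, subjects = genotypes$subjects)
  list(panel = bp, latent = latent, batch = batch, truth = truth)
}

#' Simulate a cohort's phenotypes under the configured trio graphs
#'
#' For each trio spec the phenotype is generated under its causal graph
#' (see [trio_spec()]); graphs with an edge into the biomarker
#' (`reactive`, `collide`) regenerate that analyte's latent trait and its
#' censored raw panel column. Phenotype columns not referenced by any trio
#' get covariate-driven noise: `emphysema_pct` and `fev1pp` continuous,
#' `chronic_bronchitis` and `exacerbation_any` binary.
#'
#' @param config a `sim_config`.
#' @param genotypes,biomarkers,covariates cohort components (`biomarkers`
#'   is the list returned by [simulate_biomarkers()]).
#' @param cohort 1 or 2.
#' @return list: `phenotypes` (data frame), `biomarkers` (possibly updated),
#'   `truth` (per-trio generating graph and coefficients).
#' @export
simulate_phenotypes <- function(config, genotypes, biomarkers, covariates,
                                cohort) {
  n <- nrow(genotypes$dosage)
  set.seed(.derive_seed(config$seed, paste0("pheno", cohort)))
  Zc <- .std_cols(covariates, c("age", "bmi", "pack_years"))
  base_eta <- function() as.vector(Zc %*% c(0.15, 0.1, 0.15)) + stats::rnorm(n)
  phen <- data.frame(subject_id = genotypes$subjects,
                     emphysema_pct = pmax(0, 10 + 8 * base_eta()),
                     fev1pp = 60 + 15 * base_eta(),
                     chronic_bronchitis = stats::rbinom(n, 1, 0.25),
                     exacerbation_any = stats::rbinom(n, 1, 0.35),
                     stringsAsFactors = FALSE)
  truth <- list()
  panel <- .sim_panel(config)
  eff_mult <- config$effect_multiplier[cohort]
  for (tr in config$trios) {
    st <- tr$strengths
    g <- genotypes$dosage[, tr$variant_id]
    g[is.na(g)] <- 2 * panel$maf[tr$variant_id]
    Bl <- biomarkers$latent[, tr$analyte_id]
    spec <- config$analytes[[match(tr$analyte_id,
                                   vapply(config$analytes,
                                          function(a) a$analyte_id,
                                          character(1)))]]
    covD <- as.vector(Zc %*% c(0.15, 0.1, 0.15))
    epsD <- stats::rnorm(n, 0, st$noise_sd)
    eta <- switch(tr$graph,
      causal = st$biomarker_disease * Bl + covD + epsD,
      reactive = st$snp_disease * g + covD + epsD,
      independent = st$snp_disease * g + covD + epsD,
      collide = covD + epsD,
      complete = st$snp_disease * g + st$biomarker_disease * Bl + covD + epsD,
      null = covD + epsD)
    if (tr$graph %in% c("reactive", "collide")) {
      # edge into the biomarker: regenerate the analyte's latent trait
      Dsrc <- eta
      keep_g <- if (tr$graph == "collide") {
        sl <- if (length(spec$slopes) > 0) spec$slopes[1] * eff_mult else 0.5
        sl * g
      } else 0
      nsd <- biomarkers$truth[[tr$analyte_id]]$noise_sd
      Bl2 <- keep_g + st$disease_biomarker * scale(Dsrc)[, 1] +
        spec$batch_loading * biomarkers$batch + stats::rnorm(n, 0, nsd)
      lr <- .latent_to_raw(Bl2, spec$censor_q)
      biomarkers$latent[, tr$analyte_id] <- Bl2
      biomarkers$panel$raw[, tr$analyte_id] <- lr$raw
      biomarkers$panel$below_lloq[, tr$analyte_id] <- lr$raw < lr$lloq
      am <- biomarkers$panel$analytes
      am$lloq[am$analyte_id == tr$analyte_id] <- lr$lloq
      biomarkers$panel <- biomarker_panel(biomarkers$panel$raw, am,
                                          subjects = biomarkers$panel$subjects)
      biomarkers$truth[[tr$analyte_id]]$lloq <- lr$lloq
    }
    if (tr$binary) {
      pr <- stats::plogis(scale(eta)[, 1] + stats::qlogis(0.35))
      D <- stats::rbinom(n, 1, pr)
    } else {
      D <- eta
    }
    if (!tr$phenotype %in% names(phen))
      stop("trio phenotype ", tr$phenotype, " is not a phenotype column")
    phen[[tr$phenotype]] <- D
    truth[[paste(tr$variant_id, tr$analyte_id, tr$phenotype, sep = "|")]] <-
      list(graph = tr$graph, strengths = st, binary = tr$binary)
  }
  list(phenotypes = phen, biomarkers = biomarkers, truth = truth)
}

#' Simulate a full two-cohort study with ground truth
#'
#' Runs the generator for both cohorts over a shared variant panel and
#' shared planted effects (cohort-specific covariate draws and optional
#' effect multipliers), assembles `cohort_bundle`s, and returns the truth
#' table for validation.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_study`: `cohort1`, `cohort2` (bundles),
#'   `truth` (per-analyte effects, per-trio graphs, per-cohort batch
#'   factors, shared MAFs).
#' @export
simulate_study <- function(config) {
  panel <- .sim_panel(config)
  build <- function(cohort) {
    g <- simulate_genotypes(config, cohort)
    cov <- simulate_covariates(config, cohort)
    bm <- simulate_biomarkers(config, g, cov, cohort)
    ph <- simulate_phenotypes(config, g, bm, cov, cohort)
    bundle <- cohort_bundle(paste0("cohort", cohort), g, ph$biomarkers$panel,
                            cov, ph$phenotypes)
    list(bundle = bundle, analyte_truth = ph$biomarkers$truth,
         trio_truth = ph$truth, batch = ph$biomarkers$batch)
  }
  c1 <- build(1)
  c2 <- build(2)
  structure(list(
    cohort1 = c1$bundle, cohort2 = c2$bundle,
    truth = list(maf = panel$maf,
                 analytes = list(cohort1 = c1$analyte_truth,
                                 cohort2 = c2$analyte_truth),
                 trios = c1$trio_truth,
                 batch = list(cohort1 = c1$batch, cohort2 = c2$batch))),
    class = "sim_study")
}

#' Planted slope needed for a target variance fraction
#'
#' For a variant with minor allele frequency `maf`, the per-allele slope
#' whose dosage term contributes `frac` of a latent trait with total
#' variance `total_var`: `sqrt(frac * total_var / (2 maf (1 - maf)))`.
#'
#' @param frac target variance fraction in (0, 1).
#' @param maf minor allele frequency.
#' @param total_var total latent variance (default 1).
#' @return slope per alt-allele copy.
#' @export
slope_for_variance <- function(frac, maf, total_var = 1) {
  stopifnot(frac > 0, frac < 1, maf > 0, maf < 1)
  sqrt(frac * total_var / (2 * maf * (1 - maf)))
}

#' Write a simulated study to native-format TSV files
#'
#' Emits, per cohort, the genotype dosage table, biomarker panel, LLOQ
#' sidecar, covariate and phenotype tables, plus a truth summary - the file
#' set [read_cohort()] consumes.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (cn in c("cohort1", "cohort2")) {
    b <- study[[cn]]
    p <- function(x) file.path(dir, paste0(cn, "_", x, ".tsv"))
    write_genotype_table(b$genotypes, p("genotypes"))
    bm <- data.frame(subject_id = b$biomarkers$subjects,
                     b$biomarkers$raw, check.names = FALSE)
    utils::write.table(bm, p("biomarkers"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    am <- b$biomarkers$analytes
    lq <- data.frame(analyte_id = am$analyte_id, gene_symbol = am$gene_symbol,
                     gene_chr = am$gene_chromosome, gene_start = am$gene_start,
                     gene_end = am$gene_end, lloq = am$lloq)
    utils::write.table(lq, p("lloq"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(b$covariates, p("covariates"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(b$phenotypes, p("phenotypes"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, genotypes = p("genotypes"), biomarkers = p("biomarkers"),
               lloq = p("lloq"), covariates = p("covariates"),
               phenotypes = p("phenotypes"))
  }
  tr <- data.frame(
    analyte_id = names(study$truth$analytes$cohort1),
    causal_variants = vapply(study$truth$analytes$cohort1, function(a)
      paste(a$causal_variants, collapse = ","), character(1)),
    slopes = vapply(study$truth$analytes$cohort1, function(a)
      paste(signif(a$slopes, 10), collapse = ","), character(1)))
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
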