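#' pqtlmeta: censoring-aware pQTL mapping with two-cohort meta-analysis
#'
#' Protein quantitative trait locus (pQTL) mapping for blood biomarker panels
#' measured in two genotyped cohorts, with left-censored (tobit) regression
#' for analytes partially below the assay lower limit of quantification,
#' sample-size-weighted signed-Z meta-analysis, recursive conditioning for
#' independent signals, and conditional-independence classification of
#' SNP-biomarker-phenotype trios.
#'
#' @section Typical workflow:
#' \enumerate{
#'   \item Read or simulate per-cohort data: [read_cohort()], [simulate_study()].
#'   \item Variant QC and genotype PCs: [filter_variants()], [genotype_pcs()].
#'   \item Biomarker preparation: [prepare_analyte()], [biomarker_pc1()].
#'   \item Per-cohort scans and meta-analysis: [scan_analyte()], [meta_scan()].
#'   \item Independent signals and replication: [recursive_conditioning()],
#'     [replication_check()].
#'   \item Trio causal classification: [classify_trios()].
#' }
#'
#' @importFrom stats dnorm pnorm qnorm lm.fit glm.fit binomial coef optim
#'   optimHess rbinom rnorm runif sd var cor quantile complete.cases
#'   ks.test model.matrix setNames
#' @importFrom utils read.delim write.table
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain constructors
# ---------------------------------------------------------------------------

#' Variant metadata table
#'
#' @param variant_id character vector, unique within a cohort.
#' @param chromosome character vector.
#' @param position integer vector, 1-based basepairs.
#' @param allele_ref,allele_alt non-empty allele strings; `allele_alt` is the
#'   counted (dosage) allele.
#' @return A `data.frame` of class `variant_info`.
#' @export
variant_info <- function(variant_id, chromosome, position, allele_ref, allele_alt) {
  variant_id <- as.character(variant_id)
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  if (anyDuplicated(variant_id))
    stop("variant_id must be unique within a cohort")
  if (any(position < 1L))
    stop("position must be >= 1 (1-based coordinates)")
  if (any(!nzchar(allele_ref)) || any(!nzchar(allele_alt)))
    stop("allele strings must be non-empty")
  out <- data.frame(
    variant_id = variant_id, chromosome = chromosome, position = position,
    allele_ref = as.character(allele_ref), allele_alt = as.character(allele_alt),
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_info", "data.frame")
  out
}

#' Genotype matrix with variant metadata
#'
#' Additive alt-allele dosages in \{0, 1, 2, NA\}, subjects in rows.
#'
#' @param dosage numeric matrix, subjects x variants; values 0/1/2 or `NA`.
#' @param variants a [variant_info()] table, one row per dosage column.
#' @param subjects character vector of subject identifiers (rows of `dosage`).
#' @return A list of class `genotype_matrix` with elements `subjects`,
#'   `variants`, `dosage`.
#' @export
genotype_matrix <- function(dosage, variants, subjects = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(subjects)) stop("subject identifiers are required")
  subjects <- as.character(subjects)
  if (nrow(dosage) != length(subjects))
    stop("dosage rows must match subjects")
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns must match variants")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or missing; found ",
         paste(unique(dosage[bad]), collapse = ", "))
  rownames(dosage) <- subjects
  colnames(dosage) <- variants$variant_id
  structure(list(subjects = subjects, variants = variants, dosage = dosage),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$subjects), " subjects x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Analyte metadata with LLOQ and encoding-gene locus
#'
#' @param analyte_id,gene_symbol character.
#' @param gene_chromosome character; `gene_start`, `gene_end` integer bp
#'   (1-based inclusive).
#' @param lloq positive lower limit of quantification, assay units.
#' @param analysis_mode one of `"unset"`, `"drop"`, `"linear"`, `"tobit"`;
#'   set by [triage_analyte()], `"unset"` before triage.
#' @return A `data.frame` of class `analyte_meta`.
#' @export
analyte_meta <- function(analyte_id, gene_symbol, gene_chromosome,
                         gene_start, gene_end, lloq,
                         analysis_mode = "unset") {
  if (any(lloq <= 0)) stop("lloq must be > 0")
  gene_start <- as.integer(gene_start); gene_end <- as.integer(gene_end)
  if (any(gene_start > gene_end)) stop("gene_start must be <= gene_end")
  analysis_mode <- rep_len(as.character(analysis_mode), length(analyte_id))
  if (!all(analysis_mode %in% c("unset", "drop", "linear", "tobit")))
    stop("invalid analysis_mode")
  out <- data.frame(
    analyte_id = as.character(analyte_id), gene_symbol = as.character(gene_symbol),
    gene_chromosome = as.character(gene_chromosome),
    gene_start = gene_start, gene_end = gene_end,
    lloq = as.numeric(lloq), analysis_mode = analysis_mode,
    stringsAsFactors = FALSE
  )
  class(out) <- c("analyte_meta", "data.frame")
  out
}

#' Biomarker panel: raw measurements plus below-LLOQ mask
#'
#' @param raw numeric matrix, subjects x analytes, nonnegative assay units,
#'   `NA` allowed (missing, as distinct from censored).
#' @param analytes an [analyte_meta()] table.
#' @param subjects subject identifiers.
#' @param below_lloq logical mask, same shape as `raw`; defaults to
#'   `raw < lloq` per analyte.
#' @return A list of class `biomarker_panel`.
#' @export
biomarker_panel <- function(raw, analytes, subjects = rownames(raw),
                            below_lloq = NULL) {
  raw <- as.matrix(raw)
  subjects <- as.character(subjects)
  if (nrow(raw) != length(subjects)) stop("raw rows must match subjects")
  if (ncol(raw) != nrow(analytes)) stop("raw columns must match analytes")
  if (is.null(below_lloq))
    below_lloq <- sweep(raw, 2, analytes$lloq, `<`)
  below_lloq <- as.matrix(below_lloq)
  below_lloq[is.na(raw)] <- NA
  if (!identical(dim(below_lloq), dim(raw)))
    stop("below_lloq mask must match raw shape")
  chk <- sweep(raw, 2, analytes$lloq, `<`)
  ok <- is.na(raw) | (below_lloq == chk)
  if (!all(ok, na.rm = TRUE))
    stop("below_lloq mask inconsistent with raw values and LLOQ")
  rownames(raw) <- rownames(below_lloq) <- subjects
  colnames(raw) <- colnames(below_lloq) <- analytes$analyte_id
  structure(list(subjects = subjects, analytes = analytes,
                 raw = raw, below_lloq = below_lloq),
            class = "biomarker_panel")
}

#' Per-cohort bundle of aligned data tables
#'
#' All components share the same subjects in the same order.
#'
#' @param name cohort label.
#' @param genotypes a `genotype_matrix`.
#' @param biomarkers a `biomarker_panel`.
#' @param covariates,phenotypes data frames with a `subject_id` column.
#' @return A list of class `cohort_bundle` with `name`, `n`, `genotypes`,
#'   `biomarkers`, `covariates`, `phenotypes`.
#' @export
cohort_bundle <- function(name, genotypes, biomarkers, covariates, phenotypes) {
  s <- genotypes$subjects
  if (!identical(s, biomarkers$subjects) ||
      !identical(s, as.character(covariates$subject_id)) ||
      !identical(s, as.character(phenotypes$subject_id)))
    stop("cohort components must share identical, identically ordered subjects")
  structure(list(name = name, n = length(s), genotypes = genotypes,
                 biomarkers = biomarkers, covariates = covariates,
                 phenotypes = phenotypes),
            class = "cohort_bundle")
}

#' @exportS3Method base::print
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> '", x$name, "': n = ", x$n, ", ",
      nrow(x$genotypes$variants), " variants, ",
      nrow(x$biomarkers$analytes), " analytes\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers / writers (native TSV formats)
# ---------------------------------------------------------------------------

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a native genotype dosage table
#'
#' Tab-separated, one row per variant with columns `variant_id`, `chromosome`,
#' `position`, `allele_ref`, `allele_alt`, followed by one column per subject
#' holding dosages 0/1/2 or `NA`.
#'
#' @param path path to the TSV file.
#' @return A `genotype_matrix`.
#' @export
read_genotype_table <- function(path) {
  tab <- .read_tsv(path)
  meta_cols <- c("variant_id", "chromosome", "position", "allele_ref", "allele_alt")
  if (!all(meta_cols %in% names(tab)))
    stop("genotype table ", path, " lacks required columns: ",
         paste(setdiff(meta_cols, names(tab)), collapse = ", "))
  subj <- setdiff(names(tab), meta_cols)
  if (length(subj) == 0) stop("genotype table ", path, " has no subject columns")
  dos <- t(as.matrix(tab[, subj, drop = FALSE]))
  mode(dos) <- "numeric"
  bad <- which(!(dos %in% c(0, 1, 2) | is.na(dos)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid dosage in ", path, " at variant line ", bad[1, 2] + 1L,
         " (value ", dos[bad[1, 1], bad[1, 2]], "); dosages must be 0/1/2/NA")
  vi <- variant_info(tab$variant_id, tab$chromosome, tab$position,
                     tab$allele_ref, tab$allele_alt)
  genotype_matrix(dos, vi, subjects = subj)
}

#' Write a genotype matrix in the native dosage-table format
#'
#' @param g a `genotype_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  tab <- cbind(g$variants, as.data.frame(t(g$dosage), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a biomarker panel plus its LLOQ sidecar
#'
#' The panel TSV has a `subject_id` column and one numeric column per analyte
#' (raw assay units). The sidecar TSV has columns `analyte_id`, `gene_symbol`,
#' `gene_chr`, `gene_start`, `gene_end`, `lloq`.
#'
#' @param panel_path,lloq_path TSV paths.
#' @return A `biomarker_panel`; `below_lloq` computed as `raw < lloq`.
#' @export
read_biomarker_panel <- function(panel_path, lloq_path) {
  tab <- .read_tsv(panel_path)
  if (!"subject_id" %in% names(tab))
    stop("biomarker table ", panel_path, " lacks subject_id column")
  lq <- .read_tsv(lloq_path)
  need <- c("analyte_id", "gene_symbol", "gene_chr", "gene_start", "gene_end", "lloq")
  if (!all(need %in% names(lq)))
    stop("LLOQ sidecar ", lloq_path, " lacks columns: ",
         paste(setdiff(need, names(lq)), collapse = ", "))
  analyte_cols <- setdiff(names(tab), "subject_id")
  if (!setequal(analyte_cols, lq$analyte_id))
    stop("analytes in ", panel_path, " do not match LLOQ sidecar")
  lq <- lq[match(analyte_cols, lq$analyte_id), ]
  am <- analyte_meta(lq$analyte_id, lq$gene_symbol, lq$gene_chr,
                     lq$gene_start, lq$gene_end, lq$lloq)
  raw <- as.matrix(tab[, analyte_cols, drop = FALSE])
  mode(raw) <- "numeric"
  biomarker_panel(raw, am, subjects = tab$subject_id)
}

#' Read a full cohort and align subjects across all tables
#'
#' Restricts to the intersection of subjects present in every table, orders
#' subjects lexicographically, and drops subjects with any missing covariate
#' (complete-case), logging the dropped count to stderr.
#'
#' @param genotype_path native dosage table (see [read_genotype_table()]).
#' @param biomarker_path,lloq_path biomarker panel and LLOQ sidecar.
#' @param covariate_path TSV with `subject_id`, `site`, `sex`, `age`, `bmi`,
#'   `pack_years`, `current_smoker` and optional cell-count columns.
#' @param phenotype_path TSV with `subject_id` and phenotype columns.
#' @param name cohort label.
#' @return A `cohort_bundle`.
#' @export
read_cohort <- function(genotype_path, biomarker_path, lloq_path,
                        covariate_path, phenotype_path, name = "cohort") {
  g <- read_genotype_table(genotype_path)
  b <- read_biomarker_panel(biomarker_path, lloq_path)
  cov <- .read_tsv(covariate_path)
  phe <- .read_tsv(phenotype_path)
  for (nm in c("subject_id", "site", "sex", "age", "bmi", "pack_years",
               "current_smoker"))
    if (!nm %in% names(cov))
      stop("covariate table ", covariate_path, " lacks column ", nm)
  if (!"subject_id" %in% names(phe))
    stop("phenotype table ", phenotype_path, " lacks subject_id column")

  common <- Reduce(intersect, list(g$subjects, b$subjects,
                                   as.character(cov$subject_id),
                                   as.character(phe$subject_id)))
  if (length(common) == 0) stop("empty subject intersection across input tables")
  common <- sort(common)

  cov <- cov[match(common, cov$subject_id), , drop = FALSE]
  cc <- stats::complete.cases(cov)
  n_drop <- sum(!cc)
  if (n_drop > 0) {
    message(n_drop, " subject(s) dropped due to missing covariate values")
    common <- common[cc]
    cov <- cov[cc, , drop = FALSE]
  }
  if (length(common) == 0) stop("no subjects remain after complete-case filter")

  gi <- match(common, g$subjects)
  bi <- match(common, b$subjects)
  g2 <- genotype_matrix(g$dosage[gi, , drop = FALSE], g$variants, common)
  b2 <- biomarker_panel(b$raw[bi, , drop = FALSE], b$analytes, common,
                        below_lloq = b$below_lloq[bi, , drop = FALSE])
  phe <- phe[match(common, phe$subject_id), , drop = FALSE]
  cov$subject_id <- common
  phe$subject_id <- common
  rownames(cov) <- rownames(phe) <- NULL
  cohort_bundle(name, g2, b2, cov, phe)
}

#' Import genotypes from a VCF (GT fields only)
#'
#' Diploid GT fields are converted to alt-allele dosages; multi-allelic
#' records are skipped with a warning; missing genotypes (`./.`) become `NA`.
#'
#' @param path VCF 4.x path (plain text or bgzip).
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alt alleles in GT strings like 0/1, 1|1, ./.
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dos <- t(apply(gt, c(1, 2), count_alt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  vi <- variant_info(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                     fix[, "REF"], fix[, "ALT"])
  genotype_matrix(dos, vi, subjects = colnames(gt))
}

#' Import genotypes from PLINK text .ped/.map files
#'
#' The counted (dosage) allele per variant is the minor allele observed in
#' the file; `0` codes a missing allele.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return A `genotype_matrix`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed .map file: ", map_path)
  names(map)[1:4] <- c("chr", "id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  n_var <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_var)
    stop("malformed .ped file: expected ", 6 + 2 * n_var, " columns, got ", ncol(ped))
  subjects <- as.character(ped[[2]])
  dos <- matrix(NA_real_, nrow(ped), n_var)
  ref <- alt <- character(n_var)
  for (j in seq_len(n_var)) {
    a1 <- as.character(ped[[6 + 2 * j - 1]])
    a2 <- as.character(ped[[6 + 2 * j]])
    alleles <- c(a1, a2)
    obs <- alleles[alleles != "0"]
    lev <- sort(unique(obs))
    if (length(lev) == 0) { ref[j] <- alt[j] <- "N"; next }
    cnt <- table(factor(obs, levels = lev))
    minor <- names(cnt)[which.min(cnt)]
    major <- if (length(lev) == 1) lev else names(cnt)[which.max(cnt)]
    if (minor == major && length(lev) > 1) minor <- setdiff(lev, major)[1]
    ref[j] <- major; alt[j] <- if (length(lev) == 1) lev else minor
    miss <- a1 == "0" | a2 == "0"
    dj <- (a1 == minor) + (a2 == minor)
    dj[miss] <- NA_real_
    if (length(lev) == 1) dj[!miss] <- 0  # monomorphic: no counted-allele copies
    dos[, j] <- dj
  }
  vi <- variant_info(map$id, map$chr, map$pos, ref, alt)
  genotype_matrix(dos, vi, subjects = subjects)
}

# ---------------------------------------------------------------------------
# Association-table serialization (S3/S4-table-like layout)
# ---------------------------------------------------------------------------

.assoc_cols <- c("variant_id", "chr", "pos", "analyte", "cohort", "model",
                 "n", "beta", "se", "z", "p")

#' Write / read per-cohort association results
#'
#' Tab-separated with header `variant_id, chr, pos, analyte, cohort, model,
#' n, beta, se, z, p`; numeric columns serialized at 17 significant digits so
#' the round trip is lossless.
#'
#' @param results data frame with the columns above.
#' @param path output TSV path.
#' @return `path` invisibly (write); the results data frame (read).
#' @export
write_association_table <- function(results, path) {
  miss <- setdiff(.assoc_cols, names(results))
  if (length(miss) > 0)
    stop("association results lack columns: ", paste(miss, collapse = ", "))
  out <- results[, .assoc_cols, drop = FALSE]
  for (nm in c("beta", "se", "z", "p"))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write association table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  tab <- .read_tsv(path)
  miss <- setdiff(.assoc_cols, names(tab))
  if (length(miss) > 0)
    stop("association table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  for (nm in c("pos", "n")) tab[[nm]] <- as.integer(tab[[nm]])
  for (nm in c("beta", "se", "z", "p")) tab[[nm]] <- as.numeric(tab[[nm]])
  for (nm in c("variant_id", "chr", "analyte", "cohort", "model"))
    tab[[nm]] <- as.character(tab[[nm]])
  tab
}
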