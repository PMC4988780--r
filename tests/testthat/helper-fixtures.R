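# Builders for tiny in-code fixtures shared across test files.

# write the five native-format files for a small hand-built cohort; returns
# the paths plus the objects used to build them
write_tiny_cohort <- function(dir, drop_bmi_for = NULL) {
  subj <- sprintf("s%02d", 1:5)
  vi <- variant_info(c("rs1", "rs2", "rs3"), c("1", "1", "2"),
                     c(1000L, 2000L, 500L), c("A", "C", "G"), c("G", "T", "A"))
  dos <- matrix(c(0, 1, 2, 1, 0,
                  2, 2, 1, 0, 1,
                  0, 0, 0, 1, 2), nrow = 5, ncol = 3)
  g <- genotype_matrix(dos, vi, subj)
  write_genotype_table(g, file.path(dir, "geno.tsv"))

  raw <- matrix(c(12, 3, 15, 20, 8,
                  100, 150, 40, 60, 300), nrow = 5, ncol = 2)
  bm <- data.frame(subject_id = subj, il6 = raw[, 1], crp = raw[, 2])
  write.table(bm, file.path(dir, "biom.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lq <- data.frame(analyte_id = c("il6", "crp"), gene_symbol = c("IL6", "CRP"),
                   gene_chr = c("7", "1"), gene_start = c(100L, 1500L),
                   gene_end = c(5000L, 2500L), lloq = c(10, 50))
  write.table(lq, file.path(dir, "lloq.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  cov <- data.frame(subject_id = subj, site = c("a", "a", "b", "b", "a"),
                    sex = c(0, 1, 0, 1, 0), age = c(60, 65, 70, 55, 62),
                    bmi = c(25, 30, 28, 22, 27), pack_years = c(20, 40, 10, 50, 30),
                    current_smoker = c(0, 1, 1, 0, 0))
  if (!is.null(drop_bmi_for)) cov$bmi[cov$subject_id == drop_bmi_for] <- NA
  write.table(cov, file.path(dir, "cov.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  phe <- data.frame(subject_id = subj, emphysema_pct = c(5, 12, 3, 8, 20),
                    fev1pp = c(80, 65, 90, 72, 50),
                    chronic_bronchitis = c(0, 1, 0, 0, 1),
                    exacerbation_any = c(1, 0, 0, 1, 1))
  write.table(phe, file.path(dir, "phe.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(paths = list(genotypes = file.path(dir, "geno.tsv"),
                    biomarkers = file.path(dir, "biom.tsv"),
                    lloq = file.path(dir, "lloq.tsv"),
                    covariates = file.path(dir, "cov.tsv"),
                    phenotypes = file.path(dir, "phe.tsv")),
       genotypes = g, raw = raw, covariates = cov, phenotypes = phe)
}

# 3-sample, 2-site VCF; dosages hand-read in the tests
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "2\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0|0\t./.\t0/1"
  ), path)
  path
}

# independent brute-force HWE oracle: direct factorial products, no logs
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1.0)
  prob_of <- function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, prob_of, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# default per-cohort covariate designs for a simulated study
study_designs <- function(st, cell_counts = FALSE) {
  list(X1 = covariate_design(st$cohort1$covariates, cell_counts = cell_counts),
       X2 = covariate_design(st$cohort2$covariates, cell_counts = cell_counts))
}

# prepare one analyte from a bundle
prep_analyte <- function(bundle, analyte_id) {
  am <- bundle$biomarkers$analytes
  prepare_analyte(bundle$biomarkers$raw[, analyte_id],
                  bundle$biomarkers$below_lloq[, analyte_id],
                  am$lloq[am$analyte_id == analyte_id], analyte_id)
}
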