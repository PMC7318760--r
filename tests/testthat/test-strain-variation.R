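test_that("haploid consensus calls follow depth and majority rules", {
  p <- data.frame(A = c(10L, 1L, 6L, 5L),
                  C = c(0L, 0L, 0L, 0L),
                  G = c(0L, 0L, 4L, 5L),
                  T = c(0L, 0L, 0L, 0L))
  calls <- call_haploid_genotypes(p, min_depth = 3, majority_fraction = 0.6)
  expect_equal(calls, c("A", NA, "A", NA))
  expect_error(call_haploid_genotypes(p, majority_fraction = 0.5), "majority")
  expect_error(call_haploid_genotypes(p, min_depth = 0), "min_depth")
})

test_that("genotyping a simulated pileup recovers the true sequence at depth", {
  truth <- generate_genome(2000, 0.5, seed = 110)$sequence
  pile <- simulate_pileup(truth, mean_depth = 20, error_rate = 0.005, seed = 111)
  calls <- call_haploid_genotypes(pile, min_depth = 5, majority_fraction = 0.8)
  called <- !is.na(calls)
  expect_gt(mean(called), 0.95)
  expect_true(all(calls[called] == strsplit(truth, "")[[1L]][called]))
})

test_that("SNP ascertainment keeps segregating biallelic sites with missing-to-ref", {
  ref <- c("A", "C", "G", "T", "A")
  calls <- rbind(
    s1 = c("A", "C", "G", "T", "C"),
    s2 = c("A", NA,  "G", "A", "G"),
    s3 = c("A", "C", NA,  "T", "T"))
  gm <- ascertain_snps(calls, ref)
  # site 1: monomorphic; site 2: missing->ref, monomorphic; site 3 same;
  # site 4: ref T + alt A, biallelic; site 5: three observed alleles, excluded
  expect_equal(gm$sites$position, 4L)
  expect_equal(gm$sites$ref, "T")
  expect_equal(gm$sites$alt, "A")
  expect_equal(unname(gm$calls[, 1]), c("T", "A", "T"))

  all_ref <- ascertain_snps(rbind(a = ref, b = ref), ref)
  expect_equal(nrow(all_ref$sites), 0L)
  expect_error(ascertain_snps(rbind(a = ref), ref), "2 modern samples")
})

test_that("full-information filtering drops sites missing in any historical sample", {
  gm <- ascertain_snps(rbind(s1 = c("A", "G", "T"), s2 = c("C", "A", "A")),
                       ref = c("A", "A", "T"))
  expect_equal(nrow(gm$sites), 3L)
  hist_calls <- rbind(h1 = c("A", NA, "T"), h2 = c("C", "A", "T"))
  filt <- full_information_filter(gm, hist_calls)
  expect_equal(nrow(filt$sites), 2L)
  expect_equal(nrow(filt$calls), 4L)

  same <- full_information_filter(gm, rbind(h1 = c("A", "A", "T")))
  expect_equal(nrow(same$sites), 3L)

  expect_warning(full_information_filter(gm, rbind(h1 = c(NA, NA, NA))),
                 "no site")
})

test_that("snp identity is exact Hamming agreement, symmetric, unit diagonal", {
  expect_equal(snp_identity(c("A", "C", "G"), c("A", "C", "G")), 1)
  expect_equal(snp_identity(c("A", "C", "G"), c("A", "C", "T")), 2 / 3)
  expect_error(snp_identity(c("A"), c("A", "C")), "length")

  panel <- simulate_strain_panel(genome_length = 5000, seed = 120)
  geno <- genotypes_from_sequences(c(panel$modern, panel$historical),
                                   panel$reference)
  gm <- ascertain_snps(geno$calls[names(panel$modern), , drop = FALSE],
                       geno$ref, geno$positions)
  hist_calls <- geno$calls[names(panel$historical),
                           match(gm$sites$position, geno$positions),
                           drop = FALSE]
  full <- full_information_filter(gm, hist_calls)
  im <- snp_identity_matrix(full)
  expect_equal(im, t(im))
  expect_true(all(diag(im) == 1))
  # brute-force per-pair Hamming agreement
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(im[i, j], mean(full$calls[i, ] == full$calls[j, ]))
  }
})

test_that("PCA matches an independent eigendecomposition and handles rank-1 cases", {
  two <- structure(list(
    sites = data.frame(position = 1:3, ref = rep("A", 3), alt = rep("C", 3)),
    calls = rbind(x = c("A", "C", "C"), y = c("C", "A", "A"))),
    class = "genotype_matrix")
  p2 <- snp_pca(two, n_components = 1)
  expect_equal(p2$var_explained[1], 100)

  dup <- structure(list(
    sites = two$sites,
    calls = rbind(x = c("A", "C", "C"), x2 = c("A", "C", "C"),
                  y = c("C", "A", "A"))), class = "genotype_matrix")
  pd <- snp_pca(dup)
  expect_equal(pd$scores["x", ], pd$scores["x2", ], ignore_attr = TRUE)

  # 4 x 6 hand matrix vs eigen() of the covariance matrix
  enc <- matrix(c(0, 1, 0, 1, 1, 0,
                  1, 1, 0, 0, 1, 0,
                  0, 0, 1, 1, 0, 1,
                  1, 0, 1, 0, 0, 1), 4, 6, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), NULL))
  gm <- structure(list(
    sites = data.frame(position = 1:6, ref = rep("A", 6), alt = rep("C", 6)),
    calls = matrix(c("A", "C")[enc + 1], 4, 6,
                   dimnames = dimnames(enc))), class = "genotype_matrix")
  p <- snp_pca(gm, n_components = 3)
  centered <- scale(enc, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(centered), symmetric = TRUE)
  expect_equal(sort(p$sdev^2, decreasing = TRUE)[1:3],
               ev$values[1:3], tolerance = 1e-10)
  for (k in 1:2) {
    proj <- centered %*% ev$vectors[, k]
    # eigenvectors are sign-ambiguous
    expect_true(isTRUE(all.equal(unname(p$scores[, k]), as.numeric(proj),
                                 tolerance = 1e-8)) ||
                isTRUE(all.equal(unname(p$scores[, k]), -as.numeric(proj),
                                 tolerance = 1e-8)))
  }
  expect_equal(p$var_explained,
               ev$values[1:3] / sum(ev$values) * 100, tolerance = 1e-10)

  const <- structure(list(
    sites = data.frame(position = 1:2, ref = rep("A", 2), alt = rep("C", 2)),
    calls = rbind(a = c("A", "A"), b = c("A", "A"))), class = "genotype_matrix")
  expect_error(snp_pca(const), "no variance")
})

test_that("site order permutation changes no identity value and no eigenvalue", {
  panel <- simulate_strain_panel(genome_length = 4000, seed = 130)
  geno <- genotypes_from_sequences(panel$modern, panel$reference)
  gm <- ascertain_snps(geno$calls, geno$ref, geno$positions)
  set.seed(131)
  perm <- sample(nrow(gm$sites))
  gm_p <- structure(list(sites = gm$sites[perm, ],
                         calls = gm$calls[, perm, drop = FALSE]),
                    class = "genotype_matrix")
  expect_equal(snp_identity_matrix(gm), snp_identity_matrix(gm_p))
  expect_equal(snp_pca(gm)$sdev, snp_pca(gm_p)$sdev, tolerance = 1e-10)
})

test_that("historical samples cluster with their source clade", {
  panel <- simulate_strain_panel(genome_length = 20000, seed = 140)
  geno <- genotypes_from_sequences(c(panel$modern, panel$historical),
                                   panel$reference)
  gm <- ascertain_snps(geno$calls[names(panel$modern), , drop = FALSE],
                       geno$ref, geno$positions)
  # historical genotypes via simulated pileups at the ascertained sites
  hist_calls <- do.call(rbind, lapply(names(panel$historical), function(h) {
    site_seq <- paste(strsplit(panel$historical[[h]], "")[[1L]][gm$sites$position],
                      collapse = "")
    pile <- simulate_pileup(site_seq, mean_depth = 15, seed = 141)
    call_haploid_genotypes(pile, min_depth = 3, majority_fraction = 0.7)
  }))
  rownames(hist_calls) <- names(panel$historical)
  full <- full_information_filter(gm, hist_calls)
  im <- snp_identity_matrix(full)
  c1 <- names(panel$cluster)[panel$cluster == "cluster1"]
  c2 <- names(panel$cluster)[panel$cluster == "cluster2"]
  for (h in names(panel$historical)) {
    expect_gt(mean(im[h, c1]), mean(im[h, c2]))
  }
  pca <- snp_pca(full)
  for (h in names(panel$historical)) {
    d <- sqrt(rowSums((pca$scores[c(c1, c2), , drop = FALSE] -
                         matrix(pca$scores[h, ], length(c(c1, c2)), 2,
                                byrow = TRUE))^2))
    expect_true(names(which.min(d)) %in% c1)
  }
})

test_that("the genotype TSV parser is strict and round-trips alleles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CHROM\tPOS\tREF\tALT\ts1\ts2",
               "chr\t10\tA\tG\t0\t1",
               "chr\t20\tC\tT\t.\t0"), path)
  g <- read_genotype_tsv(path)
  expect_equal(g$calls["s1", ], c("A", NA))
  expect_equal(g$calls["s2", ], c("G", "C"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CHROM\tPOS\tREF\tALT\ts1", "chr\t10\tA\tG\t2"), bad)
  expect_error(read_genotype_tsv(bad), "0/1")
})
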