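test_that("the family template yields the expected labeled pair counts", {
  ped <- family_template()
  expect_equal(nrow(ped), 15)
  pp <- pedigree_pairs(ped)
  counts <- table(pp$relationship)
  expect_equal(unname(counts[c("parent_child", "full_sibs",
                               "second_degree", "unrelated")]),
               c(22L, 20L, 40L, 22L), ignore_attr = TRUE)
  expect_equal(nrow(pp), 104)
  # labels come from structure only; no genotypes involved
  expect_true(all(pp$id_a %in% ped$id) && all(pp$id_b %in% ped$id))
})

test_that("exhaustive transmission enumeration recovers the IBD coefficient table", {
  for (nm in c("parent_child", "full_sibs", "half_sibs", "grandparent",
               "avuncular", "first_cousins", "unrelated")) {
    rp <- relationship_pedigree(nm)
    phi <- enumerate_ibd(rp$ped, rp$pair[1], rp$pair[2])
    want <- switch(nm,
      parent_child = c(0, 1, 0),
      full_sibs = c(0.25, 0.5, 0.25),
      half_sibs = , grandparent = , avuncular = c(0, 0.5, 0.5),
      first_cousins = c(0, 0.25, 0.75),
      unrelated = c(0, 0, 1))
    expect_equal(unname(phi), want, label = nm)
  }
})

test_that("founder simulation is HWE at panel frequencies and seed-deterministic", {
  panel <- synthetic_panel(1, c(0.4, 0.4), populations = "SIM", seed = 3)
  p <- panel$SIM[1]
  n <- 5e4
  f <- simulate_founders(panel, "SIM", n = n, ids = paste0("i", 1:n), seed = 101)
  het <- mean(f$A1[1, ] != f$A2[1, ])
  expect_lt(abs(het - 2 * p * (1 - p)), 3 * sqrt(2 * p * (1 - p) *
                                                 (1 - 2 * p * (1 - p)) / n))
  alt_frac <- mean(c(f$A1[1, ], f$A2[1, ]) == panel$alt[1])
  expect_lt(abs(alt_frac - p), 3 * sqrt(p * (1 - p) / (2 * n)))
  f2 <- simulate_founders(panel, "SIM", n = n, ids = paste0("i", 1:n), seed = 101)
  expect_identical(f$A1, f2$A1)
  expect_error(simulate_founders(panel, "NOPE", 1), "population")
})

test_that("gene-dropped pairs show the expected IBD sharing", {
  # parent-child shares >= 1 allele IBD at every locus; empirical phi bands
  phi_pc <- empirical_phi("parent_child", n = 5000, seed = 21)
  expect_equal(unname(phi_pc), c(0, 1, 0))
  n <- 2e4
  se <- function(p) sqrt(p * (1 - p) / n)
  phi_fs <- empirical_phi("full_sibs", n = n, seed = 22)
  expect_lt(abs(phi_fs["phi2"] - 0.25), 3 * se(0.25))
  expect_lt(abs(phi_fs["phi1"] - 0.5), 3 * se(0.5))
  expect_lt(abs(phi_fs["phi0"] - 0.25), 3 * se(0.25))
  phi_gp <- empirical_phi("grandparent", n = n, seed = 23)
  expect_equal(unname(phi_gp["phi2"]), 0)
  expect_lt(abs(phi_gp["phi1"] - 0.5), 3 * se(0.5))
})

test_that("error-free parent-child pairs share an allele at every locus in both modes", {
  panel <- synthetic_panel(400, c(0.4, 0.5), populations = "SIM",
                           spacing_cm = 5, seed = 31)
  rp <- relationship_pedigree("parent_child")
  for (mode in c("independent", "haldane")) {
    fdr <- simulate_founders(panel, "SIM", n = 2, ids = c("f1", "f2"), seed = 32)
    gs <- gene_drop(rp$ped, fdr, mode = mode, seed = 33)
    jf <- match("f1", gs$samples); jc <- match("c", gs$samples)
    share <- mapply(function(p1, p2, c1, c2) any(c(c1, c2) %in% c(p1, p2)),
                    gs$A1[, jf], gs$A2[, jf], gs$A1[, jc], gs$A2[, jc])
    expect_true(all(share))
  }
})

test_that("haldane transmission keeps tightly linked loci on one parental haplotype", {
  # all loci at the same genetic position: a transmitted haplotype must be
  # one of the parent's two haplotypes end to end
  d <- data.frame(snp_id = paste0("s", 1:50), chrom = "1",
                  pos = seq(1e6, 2e6, length.out = 50), ref = "A", alt = "G",
                  SIM = 0.5)
  f <- write_panel_file(d)
  gm <- read_genetic_map(write_map_file(c("1\t1\t0.0", "1\t200000000\t0.0001")))
  panel <- read_panel(f, gm)
  lf <- labeled_founders(panel, c("f1", "f2"))
  rp <- relationship_pedigree("parent_child")
  gs <- gene_drop(rp$ped, lf, mode = "haldane", seed = 55)
  jc <- match("c", gs$samples)
  expect_equal(length(unique(gs$A1[, jc])), 1)  # whole paternal haplotype
  expect_equal(length(unique(gs$A2[, jc])), 1)
})

test_that("error injection is a per-allele uniform substitution with exact determinism", {
  panel <- synthetic_panel(100, c(0.4, 0.5), populations = "SIM", seed = 41)
  f <- simulate_founders(panel, "SIM", n = 500, ids = paste0("i", 1:500),
                         seed = 42)
  expect_identical(inject_error(f, 0), f)
  e1 <- inject_error(f, 0.05, seed = 43)
  e2 <- inject_error(f, 0.05, seed = 43)
  expect_identical(e1$A1, e2$A1)
  nall <- length(f$A1) + length(f$A2)
  flipped <- sum(e1$A1 != f$A1) + sum(e1$A2 != f$A2)
  expect_lt(abs(flipped / nall - 0.05), 3 * sqrt(0.05 * 0.95 / nall))
  # substitutions never reproduce the original allele
  expect_true(all(e1$A1[e1$A1 != f$A1] != f$A1[e1$A1 != f$A1]))
  expect_error(inject_error(f, 1.2), "rate")
})

test_that("simulate_study assembles families with the paper-scale manifest", {
  panel <- synthetic_panel(20, c(0.4, 0.5), populations = "SIM", seed = 51)
  st <- simulate_study(3, panel, "SIM", error_rate = 0.01, seed = 52)
  expect_s3_class(st, "kin_study")
  expect_equal(nrow(st$pairs), 3 * 104)
  expect_equal(length(st$genotypes$samples), 3 * 15)
  expect_equal(unname(table(st$pairs$relationship)[c("parent_child",
      "full_sibs", "second_degree", "unrelated")]),
      c(66L, 60L, 120L, 66L), ignore_attr = TRUE)
  # same seed reproduces; different seed changes genotypes, not labels
  st2 <- simulate_study(3, panel, "SIM", error_rate = 0.01, seed = 52)
  expect_identical(st$genotypes$A1, st2$genotypes$A1)
  st3 <- simulate_study(3, panel, "SIM", error_rate = 0.01, seed = 53)
  expect_false(identical(st$genotypes$A1, st3$genotypes$A1))
  expect_identical(st$pairs, st3$pairs)
  prof <- study_profile(st, "fam1_g1")
  expect_s3_class(prof, "genotype_profile")
  expect_equal(nrow(prof), 20)
  expect_true(all(prof$a1 <= prof$a2))
})
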