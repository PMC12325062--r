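test_that("joint genotype probabilities given IBD match the classical table entries", {
  expect_equal(joint_prob_ibd("AA", "AA", 2, c(A = 0.5, G = 0.5)), 0.25)
  expect_equal(joint_prob_ibd("AG", "AG", 2, c(A = 0.3, G = 0.7)), 0.42)
  expect_equal(joint_prob_ibd("AA", "GG", 1, c(A = 0.3, G = 0.7)), 0)
  expect_equal(joint_prob_ibd("AG", "AC", 1, c(A = 0.5, G = 0.3, C = 0.2)), 0.03)
  expect_equal(joint_prob_ibd("AA", "AG", 1, c(A = 0.6, G = 0.4)), 0.6^2 * 0.4)
  expect_equal(joint_prob_ibd("AA", "AG", 0, c(A = 0.6, G = 0.4)), 2 * 0.6^3 * 0.4)
  expect_equal(joint_prob_ibd("AG", "CT", 0,
                              c(A = 0.1, G = 0.2, C = 0.3, T = 0.4)),
               4 * 0.1 * 0.2 * 0.3 * 0.4)
  # symmetry in (x, y)
  f <- c(A = 0.5, G = 0.3, C = 0.2)
  for (k in 0:2) {
    expect_equal(joint_prob_ibd("AG", "AC", k, f), joint_prob_ibd("AC", "AG", k, f))
    expect_equal(joint_prob_ibd("AA", "AG", k, f), joint_prob_ibd("AG", "AA", k, f))
  }
  expect_error(joint_prob_ibd(NA, "AA", 0, f), "missing")
  expect_error(joint_prob_ibd("AT", "AA", 0, f), "frequency")
})

test_that("IBD-conditional probabilities normalise and marginalise to HWE", {
  set.seed(5)
  hwe <- function(g, f) {
    a <- strsplit(g, "")[[1]]
    if (a[1] == a[2]) f[[a[1]]]^2 else 2 * f[[a[1]]] * f[[a[2]]]
  }
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    f <- random_freqs(k)
    gts <- all_genotypes(names(f))
    for (ibd in 0:2) {
      tot <- 0
      for (x in gts) {
        marg <- 0
        for (y in gts) {
          pr <- joint_prob_ibd(x, y, ibd, f)
          tot <- tot + pr
          marg <- marg + pr
        }
        expect_equal(marg, hwe(x, f), tolerance = 1e-12)
      }
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("parent-child likelihood matches exhaustive transmission enumeration", {
  set.seed(8)
  f2 <- c(A = 0.5, G = 0.5)
  v <- parent_child_likelihood("AA", "GG", f2, mu = 1e-3)
  expect_gt(v, 0)
  expect_lt(v, 1e-3)
  expect_equal(v, oracle_parent_child("AA", "GG", f2, 1e-3), tolerance = 1e-12)
  expect_equal(parent_child_likelihood("AA", "GG", f2, 0), 0)
  expect_equal(parent_child_likelihood("AA", "AG", c(A = 0.6, G = 0.4), 0), 0.144)
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    f <- random_freqs(k)
    gts <- all_genotypes(names(f))
    mu <- sample(c(0, 1e-3, 0.02), 1)
    for (x in gts) for (y in gts) {
      expect_equal(parent_child_likelihood(x, y, f, mu),
                   oracle_parent_child(x, y, f, mu), tolerance = 1e-12)
      # symmetrised by construction
      expect_equal(parent_child_likelihood(x, y, f, mu),
                   parent_child_likelihood(y, x, f, mu), tolerance = 1e-15)
    }
  }
})

test_that("zero-mutation parent-child equals the IBD=1 column on all 9 configurations", {
  f <- c(A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  configs <- list(c("AA", "AA"), c("AA", "CC"), c("AA", "AC"), c("AC", "AA"),
                  c("AA", "CG"), c("CG", "AA"), c("AC", "AC"), c("AC", "AG"),
                  c("AC", "GT"))
  for (cf in configs) {
    expect_equal(parent_child_likelihood(cf[1], cf[2], f, mu = 0),
                 joint_prob_ibd(cf[1], cf[2], 1, f), tolerance = 1e-14,
                 label = paste(cf, collapse = ","))
  }
})

test_that("locus likelihood mixes IBD states with the hypothesis coefficients", {
  f <- c(A = 0.5, G = 0.5)
  expect_equal(locus_likelihood("AA", "AA", "unrelated", f), 0.0625)
  expect_equal(locus_likelihood("AA", "AA", "full_sibs", f), 0.140625)
  expect_equal(locus_likelihood("AA", "AA", "identical_twins", f), 0.25)
  expect_equal(locus_likelihood("AA", "GG", "parent_child", f, mu = 0), 0)
  v <- locus_likelihood("AA", "GG", "parent_child", f, mu = 1e-3)
  expect_gt(v, 0); expect_lt(v, 1e-3)
  # all hypotheses are symmetric in the pair
  for (h in c(kinship_hypotheses(), "first_cousins")) {
    expect_equal(locus_likelihood("AG", "AA", h, f),
                 locus_likelihood("AA", "AG", h, f), tolerance = 1e-15)
  }
})

test_that("the vectorised engine agrees with the scalar likelihood, with and without the error channel", {
  set.seed(31)
  n <- 300
  ref <- sample(NTS, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(NTS, r), 1), character(1))
  p_alt <- runif(n, 0.05, 0.95)
  draw <- function() {
    a1 <- ifelse(runif(n) < 0.5, ref, alt)
    a2 <- ifelse(runif(n) < 0.5, ref, alt)
    # sprinkle in some off-panel alleles for the error-channel case
    swap <- runif(n) < 0.05
    a1[swap] <- sample(NTS, sum(swap), replace = TRUE)
    list(a1 = pmin(a1, a2), a2 = pmax(a1, a2))
  }
  ga <- draw(); gb <- draw()
  for (h in c(kinship_hypotheses(), "first_cousins", "identical_twins")) {
    for (err in c(0, 0.01)) {
      eng <- snpkin:::locus_lik_engine(ga$a1, ga$a2, gb$a1, gb$a2,
                                       ref, alt, p_alt, h, mu = 1e-3, err = err)
      idx <- sample(n, 40)
      for (i in idx) {
        f <- setNames(c(1 - p_alt[i], p_alt[i]), c(ref[i], alt[i]))
        onpanel <- all(c(ga$a1[i], ga$a2[i], gb$a1[i], gb$a2[i]) %in% names(f))
        if (err == 0 && !onpanel) next
        sc <- locus_likelihood(genotype(ga$a1[i], ga$a2[i]),
                               genotype(gb$a1[i], gb$a2[i]),
                               h, f, mu = 1e-3, genotyping_error = err)
        expect_equal(eng[i], sc, tolerance = 1e-12)
      }
    }
  }
})

test_that("cumulative log-likelihood sums per-locus logs and skips unusable loci", {
  gm <- toy_map()
  d <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
                  pos = c(1e6, 40e6, 80e6), ref = "A", alt = "G", P1 = 0.5)
  panel <- read_panel(write_panel_file(d), gm)
  prof <- function(a1, a2) data.frame(snp_id = c("s1", "s2", "s3"),
                                      chrom = "1", pos = c(1e6, 40e6, 80e6),
                                      a1 = a1, a2 = a2,
                                      stringsAsFactors = FALSE)
  a <- prof(c("A", "A", NA), c("A", "G", NA))
  r <- cumulative_loglik(a, a, panel, "unrelated", "P1")
  expect_equal(r$n_loci, 2)
  expect_equal(r$loglik, log(0.0625) + log(0.25))
  # additivity: adding locus 3 adds exactly its log term
  b <- prof(c("A", "A", "G"), c("A", "G", "G"))
  r3 <- cumulative_loglik(b, b, panel, "unrelated", "P1")
  expect_equal(r3$loglik, r$loglik + log(0.0625))
  expect_equal(r3$n_loci, 3)
  # off-panel allele (no frequency) is skipped like missing
  cc <- prof(c("A", "C", NA), c("A", "C", NA))
  rc <- cumulative_loglik(cc, a, panel, "unrelated", "P1")
  expect_equal(rc$n_loci, 1)
  none <- prof(c(NA, NA, NA), c(NA, NA, NA))
  expect_error(cumulative_loglik(none, a, panel, "unrelated", "P1"),
               "no overlapping markers")
})

test_that("likelihood ratios and classification behave as defined", {
  gm <- toy_map()
  n <- 40
  d <- data.frame(snp_id = sprintf("s%02d", 1:n), chrom = "1",
                  pos = seq(1e6, by = 40e6 / n * 40, length.out = n),
                  ref = "A", alt = "G", P1 = runif(n, 0.42, 0.58))
  panel <- read_panel(write_panel_file(d), gm)
  set.seed(3)
  fdr <- simulate_founders(panel, "P1", n = 1, ids = "x")
  a <- study_profile(fdr, "x")
  # same hypothesis on both sides: LR exactly 0
  expect_equal(pair_lr(a, a, panel, "full_sibs", "full_sibs", "P1")$log10_lr, 0)
  # identical profiles: LR(twins vs unrelated) = 1 / prod(HWE probs)
  lr <- pair_lr(a, a, panel, "identical_twins", "unrelated", "P1")
  hwe <- cumulative_loglik(a, a, panel, "identical_twins", "P1")$loglik
  expect_equal(lr$log10_lr, -hwe / log(10), tolerance = 1e-9)
  cls <- classify_pair(a, a, panel, "P1",
                       hypotheses = c("unrelated", "parent_child",
                                      "full_sibs", "second_degree",
                                      "identical_twins"))
  expect_identical(cls$call, "identical_twins")
  # two-hypothesis margin is exactly the pair LR of best vs other
  two <- classify_pair(a, a, panel, "P1",
                       hypotheses = c("unrelated", "identical_twins"))
  lr2 <- pair_lr(a, a, panel, "identical_twins", "unrelated", "P1")
  expect_equal(two$margin_log10, lr2$log10_lr, tolerance = 1e-9)
})

test_that("kinship_test fits, reports calls and exposes methods", {
  panel <- synthetic_panel(80, c(0.4, 0.5), populations = c("P1", "P2"),
                           seed = 12)
  rp <- relationship_pedigree("parent_child")
  fdr <- simulate_founders(panel, "P1", n = 2, ids = c("f1", "f2"), seed = 13)
  gs <- gene_drop(rp$ped, fdr, seed = 14)
  fit <- kinship_test(study_profile(gs, "f1"), study_profile(gs, "c"), panel)
  expect_s3_class(fit, "kinship_test")
  expect_identical(fit$calls$call, c("parent_child", "parent_child"))
  expect_equal(dim(coef(fit)), c(2, 4))
  expect_equal(unname(coef(fit)["P1", ]),
               unname(fit$loglik["P1", ] / log(10)))
  expect_output(print(fit), "parent_child")
  expect_output(print(summary(fit)), "Calls")
  expect_equal(nrow(fit$per_marker), 2 * fit$n_loci)
})
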