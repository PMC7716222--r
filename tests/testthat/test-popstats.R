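test_that("haplotype keys apply the range, ignore-list and PHP rules", {
  opts_diff <- comparison_options(php_mode = "differences")
  opts_ign <- comparison_options(php_mode = "ignored")
  base <- transition_token(263)

  # insertions at the ten common length-heteroplasmy positions are ignored
  a <- profile_from_strings("A", c(base, "315.1C"), test_ref)
  b <- profile_from_strings("B", base, test_ref)
  expect_identical(haplotype_key(a, opts_diff), haplotype_key(b, opts_diff))

  # PHPs distinguish keys only when counted as differences
  c_ <- profile_from_strings("C", c(base, "C16093Y"))
  expect_false(haplotype_key(c_, opts_diff) == haplotype_key(b, opts_diff))
  expect_identical(haplotype_key(c_, opts_ign), haplotype_key(b, opts_ign))

  # a non-ignored insertion position separates keys
  d <- profile_from_strings("D", c(base, "291.1A"), test_ref)
  expect_false(haplotype_key(d, opts_diff) == haplotype_key(b, opts_diff))

  # control-region keys drop coding-region variants
  opts_cr <- comparison_options(range = "control_region")
  e <- profile_from_strings("E", c(base, transition_token(8000)), test_ref)
  expect_identical(haplotype_key(e, opts_cr), haplotype_key(b, opts_cr))
})

test_that("haplotype tabulation and the match statistics agree with hand
           calculations", {
  # 112 all-distinct profiles
  all_unique <- haplotype_counts(rep(1L, 112))
  expect_equal(all_unique$distinct, 112L)
  expect_equal(all_unique$unique, 112L)
  expect_equal(observed_rmp(all_unique), 1 / 112)
  expect_equal(empirical_rmp(all_unique), 0)
  expect_equal(haplotype_diversity(all_unique), 1)

  # two doubletons plus 108 singletons: 116/12544 and 4/12432
  coaf_ex <- haplotype_counts(c(2L, 2L, rep(1L, 108)))
  expect_equal(observed_rmp(coaf_ex), 116 / 12544)
  expect_equal(empirical_rmp(coaf_ex), 4 / (112 * 111))

  # four doubletons among 171: 8/(171*170)
  dsna <- haplotype_counts(c(rep(2L, 4), rep(1L, 163)))
  expect_equal(empirical_rmp(dsna), 8 / (171 * 170))
  expect_equal(mitohap:::round_half_up(haplotype_diversity(dsna), 4), 0.9997)

  # degenerate compositions
  expect_equal(observed_rmp(haplotype_counts(5L)), 1)
  expect_equal(empirical_rmp(haplotype_counts(5L)), 1)
  expect_equal(haplotype_diversity(haplotype_counts(c(3L))), 0)
  expect_error(empirical_rmp(haplotype_counts(1L)), "n >= 2")

  # tabulation by key over profiles: {2,2} and {3}
  p <- function(id, toks) profile_from_strings(id, toks, test_ref)
  t1 <- transition_token(750); t2 <- transition_token(4769)
  four <- list(p("a", t1), p("b", t1), p("c", t2), p("d", t2))
  hc <- haplotype_counts(four)
  expect_equal(hc$sizes, c(2L, 2L))
  three <- list(p("a", t1), p("b", t1), p("c", t1))
  expect_equal(haplotype_counts(three)$sizes, 3L)
})

test_that("the three statistics satisfy their exact identities", {
  set.seed(23)
  for (i in 1:200) {
    n_classes <- sample(2:40, 1)
    sizes <- sample(1:6, n_classes, replace = TRUE)
    h <- haplotype_counts(sizes)
    n <- h$n
    obs <- observed_rmp(h)
    expect_equal(empirical_rmp(h), (n * obs - 1) / (n - 1), tolerance = 1e-12)
    expect_equal(haplotype_diversity(h), n / (n - 1) * (1 - obs),
                 tolerance = 1e-12)
    expect_lte(empirical_rmp(h), obs)
    expect_gte(obs, 1 / n)
    if (all(sizes == 1L)) expect_equal(obs, 1 / n)
  }
})

test_that("partition recovery from printed statistics is exact and unique
           where forced", {
  # composition with n=109, 102 classes, 97 singletons matching 1.09/0.17/
  # 0.9983 is uniquely {4,2,2,2,2} + 97 singletons
  found <- resolve_partition(109, 102, 97, 1.09, 0.17, 0.9983)
  expect_length(found, 1L)
  expect_equal(sort(found[[1]][found[[1]] > 1]), c(2L, 2L, 2L, 2L, 4L))

  # the competing {3,3,2,2,2} partition is excluded by the observed RMP
  alt <- haplotype_counts(c(3L, 3L, 2L, 2L, 2L, rep(1L, 97)))
  expect_false(mitohap:::round_half_up(100 * observed_rmp(alt), 2) == 1.09)

  # n=256 with 251 classes and 247 singletons admits only {3,2,2,2}
  found2 <- resolve_partition(256, 251, 247, 0.41, 0.02, 0.9998)
  expect_length(found2, 1L)
  expect_equal(sort(found2[[1]][found2[[1]] > 1]), c(2L, 2L, 2L, 3L))
})

test_that("K2P distances match the closed form and an independent
           implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)

  # P = 0.01, Q = 0 over 100 sites
  a <- strrep("A", 100)
  b <- paste0("G", strrep("A", 99))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.98), tolerance = 1e-12)

  # P = 0.1, Q = 0.05: 10 transitions and 5 transversions over 100 sites
  b2 <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(k2p_distance(a, b2), -0.5 * log(0.75 * sqrt(0.9)),
               tolerance = 1e-12)

  # N and ambiguity sites are excluded from the comparison
  expect_equal(k2p_distance("NACGT", "TACGT"), 0)
  expect_equal(k2p_distance("YACGT", "CACGT"), 0)

  # saturation is an error, not a number
  expect_error(k2p_distance(strrep("A", 10), strrep("G", 10)), "saturated")

  # first-order agreement with the p-distance at small divergence
  a3 <- strrep("A", 10000)
  b3 <- paste0(strrep("G", 5), strrep("C", 3), strrep("A", 9992))
  expect_lt(abs(k2p_distance(a3, b3) - 8e-4), 1e-4)

  skip_if_not_installed("ape")
  set.seed(29)
  for (i in 1:10) {
    n <- 500
    sa <- sample(c("a", "c", "g", "t"), n, TRUE)
    sb <- sa
    idx <- sample(n, 25)
    sb[idx] <- sample(c("a", "c", "g", "t"), 25, TRUE)
    m <- rbind(sa, sb)
    d_ape <- ape::dist.dna(ape::as.DNAbin(m), model = "K80")
    d_our <- k2p_distance(paste(sa, collapse = ""), paste(sb, collapse = ""))
    expect_equal(d_our, as.numeric(d_ape), tolerance = 1e-10)
  }
})

test_that("profile-level K2P agrees with the sequence-level route", {
  set.seed(37)
  for (i in 1:10) {
    mk <- function(id) {
      pos <- sample(setdiff(2000:9000, 3107), sample(5:25, 1))
      toks <- vapply(pos, transition_token, "")
      profile_from_strings(id, toks, test_ref)
    }
    a <- mk("a"); b <- mk("b")
    d_sparse <- k2p_profile_distance(a, b, test_ref)
    sa <- profile_to_sequence(a, test_ref)
    sb <- profile_to_sequence(b, test_ref)
    expect_equal(d_sparse, k2p_distance(sa, sb), tolerance = 1e-12)
  }
})

test_that("Phi-st behaves at its analytic anchor points", {
  mk <- function(id, toks, popn) {
    profile_from_strings(id, toks, test_ref, population = popn)
  }
  t1 <- transition_token(750); t2 <- transition_token(4769)
  t3 <- transition_token(12000)

  # identical populations: no among-group variance (the finite-sample
  # estimator is biased slightly negative in this case), insignificant p
  popA <- list(mk("a1", t1, "A"), mk("a2", t2, "A"), mk("a3", t3, "A"),
               mk("a4", character(0), "A"))
  popA2 <- lapply(popA, function(p) { p$sample_id <- paste0(p$sample_id, "x"); p })
  r0 <- pairwise_phist(popA, popA2, test_ref, n_permutations = 200, seed = 1)
  expect_lt(r0$phi_st, 0.05)
  expect_gt(r0$p_value, 0.05)

  # two populations each fixed for a different haplotype: Phi-st = 1
  popB <- lapply(1:5, function(i) mk(paste0("b", i), t1, "B"))
  popC <- lapply(1:5, function(i) mk(paste0("c", i), t2, "C"))
  r1 <- pairwise_phist(popB, popC, test_ref, n_permutations = 200, seed = 1)
  expect_equal(r1$phi_st, 1)
  expect_lte(r1$p_value, 0.05)

  # symmetry and seed reproducibility
  r2 <- pairwise_phist(popC, popB, test_ref, n_permutations = 200, seed = 1)
  expect_equal(r2$phi_st, r1$phi_st)
  r3 <- pairwise_phist(popB, popC, test_ref, n_permutations = 200, seed = 1)
  expect_identical(r3$p_value, r1$p_value)

  # p-value bounds from the +1 smoothing
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r0$p_value, 1)
})

test_that("PCoA reproduces embeddings and orders its axes", {
  # three collinear points: one positive axis explains everything
  D <- as.matrix(dist(c(0, 1, 3)))
  p <- pcoa_embed(D)
  expect_equal(p$explained[1], 1)
  expect_equal(as.numeric(dist(p$coordinates[, 1])), as.numeric(dist(c(0, 1, 3))),
               tolerance = 1e-9)

  # a Euclidean distance matrix of random 2-D points is reconstructed
  set.seed(41)
  xy <- matrix(rnorm(16), ncol = 2)
  D2 <- as.matrix(dist(xy))
  p2 <- pcoa_embed(D2)
  expect_lt(max(abs(as.matrix(dist(p2$coordinates)) - D2)), 1e-9)
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_lte(sum(p2$explained), 1 + 1e-12)

  # identical points: no positive eigenvalues
  p3 <- pcoa_embed(matrix(0, 4, 4))
  expect_equal(ncol(p3$coordinates), 0L)
  expect_lt(max(abs(p3$eigenvalues)), 1e-12)

  expect_error(pcoa_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(pcoa_embed(matrix(c(1, 0, 0, 1), 2, 2)), "diagonal")

  skip_if_not_installed("ape")
  pa <- ape::pcoa(as.dist(D2))
  expect_equal(abs(p2$coordinates[, 1]), abs(pa$vectors[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PHP characterization classifies pairs, regions and folded
           frequencies", {
  v1 <- new_variant(16192, "substitution", ref = "C", call = "Y",
                    major_freq = 0.92, major_base = "C")
  v2 <- new_variant(16265, "substitution", ref = "A", call = "M",
                    major_freq = 0.9, major_base = "A")
  v3 <- new_variant(709, "substitution", ref = "A", call = "R",
                    major_freq = 0.93, major_base = "G")  # variant is major
  p1 <- mito_profile("S1", rbind(v1, v2))
  p2 <- mito_profile("S2", v3)
  p3 <- mito_profile("S3")
  s <- php_characterize(list(p1, p2, p3))
  expect_equal(unname(s$per_individual), c(1L, 1L, 1L, 0L))
  expect_equal(s$n_individuals_with_php, 2L)
  vv <- s$variants
  expect_equal(vv$class[vv$position == 16192], "transition_Y")
  expect_equal(vv$region[vv$position == 16192], "CR")
  expect_equal(vv$class[vv$position == 16265], "transversion")
  expect_equal(vv$class[vv$position == 709], "transition_R")
  expect_equal(vv$region[vv$position == 709], "CDS")
  # variant VF 0.93 folds to 0.07
  expect_equal(vv$folded_vf[vv$position == 709], 0.07)
  expect_equal(s$fraction_transitions, 2 / 3)
})

test_that("ancestry assignment uses longest-prefix haplogroup matching", {
  mk <- function(id, hg) profile_from_strings(id, character(0),
                                              haplogroup = hg)
  profs <- list(mk("1", "L2a1"), mk("2", "B2"), mk("3", "B4"),
                mk("4", "H1"), mk("5", "X2a1"), mk("6", "QQ9"))
  a <- ancestry_proportions(profs)
  asg <- a$assignments
  expect_equal(asg$continent[asg$haplogroup == "L2a1"], "African")
  expect_equal(asg$continent[asg$haplogroup == "B2"], "Native American")
  expect_equal(asg$continent[asg$haplogroup == "B4"], "Asian")
  expect_equal(asg$continent[asg$haplogroup == "H1"], "European")
  expect_equal(asg$continent[asg$haplogroup == "X2a1"], "Native American")
  expect_equal(asg$continent[asg$haplogroup == "QQ9"], "unassigned")
  expect_equal(sum(a$continent), 1)
  expect_error(ancestry_proportions(list(mk("1", NA))), "haplogroup label")
})
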