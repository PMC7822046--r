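test_that("EM without double heterozygotes equals direct counting", {
  ga <- c(0, 0, 1, 2, 2, 1, 0, 2)
  gb <- c(0, 0, 0, 2, 2, 2, 0, 2)  # no (1,1) pair
  f <- two_locus_em(ga, gb)
  # haplotypes countable directly: each individual contributes known pairs
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # three (2,2) pairs give six AB haplotypes; the (1,2) accession one more
  expect_equal(unname(f["AB"]), 7 / 16)
  expect_equal(unname(f["ab"]), 7 / 16)
  stats <- ld_statistics(f)
  expect_gt(stats$r2, 0.5)
})

test_that("perfectly correlated markers reach complete disequilibrium", {
  g <- c(0, 0, 1, 1, 2, 2, 0, 2, 1, 2)
  f <- two_locus_em(g, g)
  expect_equal(unname(f["AB"] + f["ab"]), 1, tolerance = 1e-8)
  stats <- ld_statistics(f)
  expect_equal(stats$d_prime, 1, tolerance = 1e-8)
  expect_equal(stats$r2, 1, tolerance = 1e-8)
})

test_that("EM matches the grid-search likelihood oracle on unphased data", {
  cases <- list(
    list(n = 50, pA = 0.5, pB = 0.5, d = 0.15),
    list(n = 50, pA = 0.3, pB = 0.4, d = 0.10),
    list(n = 50, pA = 0.2, pB = 0.3, d = -0.04)
  )
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    dat <- sim_unphased_pair(cs$n, cs$pA, cs$pB, cs$d, seed = 100 + k)
    f <- two_locus_em(dat$ga, dat$gb)
    fAB_oracle <- em_grid_oracle(dat$ga, dat$gb)
    expect_equal(unname(f["AB"]), fAB_oracle, tolerance = 1e-4)
  }
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  set.seed(12)
  for (k in 1:10) {
    dat <- sim_unphased_pair(40, runif(1, 0.2, 0.5), runif(1, 0.2, 0.5), 0.05,
                             seed = k)
    tr <- attr(two_locus_em(dat$ga, dat$gb), "loglik_trace")
    expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("disequilibrium statistics follow their definitions", {
  s <- ld_statistics(c(0.5, 0, 0, 0.5))
  expect_equal(s$D, 0.25)
  expect_equal(s$d_prime, 1)
  expect_equal(s$r2, 1)

  s0 <- ld_statistics(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(s0$D, 0)
  expect_equal(s0$d_prime, 0)
  expect_equal(s0$r2, 0)

  s1 <- ld_statistics(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(s1$D, 0.15)
  expect_equal(s1$d_prime, 0.6)
  expect_equal(s1$r2, 0.36)

  mono <- ld_statistics(c(0.7, 0.3, 0, 0))
  expect_true(is.na(mono$d_prime) && is.na(mono$r2))
  expect_error(ld_statistics(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("D changes sign but D' and r2 are invariant under allele relabeling", {
  dat <- sim_unphased_pair(60, 0.4, 0.35, 0.08, seed = 7)
  s <- ld_statistics(two_locus_em(dat$ga, dat$gb))
  s_swap_locus <- ld_statistics(two_locus_em(dat$gb, dat$ga))
  expect_equal(s$D, s_swap_locus$D, tolerance = 1e-8)
  s_flip <- ld_statistics(two_locus_em(2 - dat$ga, dat$gb))
  expect_equal(s_flip$D, -s$D, tolerance = 1e-8)
  expect_equal(s_flip$d_prime, s$d_prime, tolerance = 1e-8)
  expect_equal(s_flip$r2, s$r2, tolerance = 1e-8)
})

test_that("pairwise scope enumerates the expected pairs", {
  set.seed(5)
  codes <- matrix(rbinom(40 * 5, 1, 0.4) * 2, 40, 5)
  g <- toy_genotypes(codes, pos = c(1e5, 2e5, 3e5, 5e5, 8e5))
  pairs <- pairwise_ld(g)
  expect_equal(nrow(pairs), choose(5, 2))
  expect_true(all(c("D", "d_prime", "r2") %in% names(pairs)))

  # a rare SNP is excluded from every pair
  codes2 <- cbind(codes, rare = c(1, rep(0, 39)))  # maf 1/80 > 0.01? = 0.0125
  codes3 <- cbind(codes, rare = rep(0, 40))
  codes3[1, 6] <- 1  # maf 1/80
  g3 <- toy_genotypes(codes3, pos = c(1e5, 2e5, 3e5, 5e5, 8e5, 9e5))
  pairs3 <- pairwise_ld(g3, maf_min = 0.02)
  expect_false(any(pairs3$snp_a == "rare" | pairs3$snp_b == "rare"))

  # window scope: only pairs with the index within the window
  win <- pairwise_ld(g, scope = "window", index_snp = g$map$snp_id[2],
                     window_bp = 150000)
  expect_true(all(win$snp_a == g$map$snp_id[2]))
  expect_true(all(win$distance <= 150000))
  expect_equal(nrow(win), 2)  # positions 1e5 and 3e5
})

test_that("decay parameters are recovered exactly on noiseless curves", {
  a <- 0.6; b <- 120000; cc <- 0.05
  d <- seq(1000, 1e6, length.out = 300)
  pairs <- tibble::tibble(distance = d, d_prime = a * exp(-d / b) + cc,
                          r2 = NA_real_)
  fit <- decay_fit(pairs, statistic = "d_prime", cutoff = 0.1)
  expect_equal(unname(fit$params["a"]), a, tolerance = 0.01)
  expect_equal(unname(fit$params["b"]), b, tolerance = 0.01)
  expect_equal(unname(fit$params["c"]), cc, tolerance = 0.01)
  analytic <- -b * log((0.1 - cc) / a)
  expect_equal(fit$decay_distance_bp, analytic, tolerance = 0.01)
})

test_that("a flat statistic never crosses the cutoff", {
  pairs <- tibble::tibble(distance = seq(1e3, 1e6, length.out = 100),
                          d_prime = 0.5, r2 = 0.5)
  fit <- suppressWarnings(decay_fit(pairs, statistic = "d_prime", cutoff = 0.1))
  expect_true(is.infinite(fit$decay_distance_bp))
})

test_that("hill-weir fit recovers the decay scale from its own curve", {
  rho <- 2e-5; n <- 768
  d <- exp(seq(log(100), log(2e6), length.out = 400))
  pairs <- tibble::tibble(distance = d,
                          r2 = gwaspect:::hill_weir_r2(d, rho, n),
                          d_prime = NA_real_)
  fit <- decay_fit(pairs, statistic = "r2", cutoff = 0.1, n = n)
  expect_equal(unname(fit$params["rho"]), rho, tolerance = 0.01)
})

test_that("strong-LD windows extend until the first weak neighbour", {
  # 9 SNPs: index in the centre, 3 perfect proxies each side, then noise
  set.seed(42)
  base <- rbinom(60, 1, 0.5) * 2
  noise <- function() rbinom(60, 1, 0.5) * 2
  codes <- cbind(noise(), base, base, base, base, base, base, base, noise())
  pos <- seq(1e5, 9e5, by = 1e5)
  g <- toy_genotypes(codes, pos = pos)
  idx <- g$map$snp_id[5]
  win <- strong_ld_window(g, idx, d_prime_min = 0.80)
  expect_equal(win$start, 2e5)
  expect_equal(win$end, 8e5)
  expect_equal(win$n_snps, 7)

  # immediate neighbours below threshold -> degenerate window
  codes2 <- cbind(noise(), base, noise())
  g2 <- toy_genotypes(codes2, pos = c(1e5, 2e5, 3e5))
  win2 <- strong_ld_window(g2, g2$map$snp_id[2])
  expect_equal(win2$start, win2$end)
  expect_equal(win2$n_snps, 1)

  expect_error(strong_ld_window(toy_genotypes(cbind(rep(0, 10), base[1:10]),
                                              pos = c(100, 200)),
                                "snp01"),
               "monomorphic")
})

test_that("candidate windows use inclusive overlap and the 150 kb flank", {
  genes <- tibble::tibble(
    gene_id = c("left_touch", "inside", "right_touch", "outside"),
    chrom = "Araip.B08",
    start = c(12579161, 12800000, 12979161, 13100000),
    end = c(12679161, 12810000, 13050000, 13200000),
    strand = "+"
  )
  hits <- candidate_genes(genes, chrom = "Araip.B08", center = 12829161,
                          flank_bp = 150000)
  # interval is [12679161, 12979161]; touching genes are included
  expect_equal(hits$gene_id, c("left_touch", "inside", "right_touch"))
  none <- candidate_genes(genes[0, ], chrom = "Araip.B08",
                          center = 12829161)
  expect_equal(nrow(none), 0)
  other <- candidate_genes(genes, chrom = "Aradu.A09", center = 12829161)
  expect_equal(nrow(other), 0)
})
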