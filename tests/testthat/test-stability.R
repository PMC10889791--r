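test_that("delta-Ct stability matches hand-enumerated pairwise SDs", {
  # constant offset between two genes -> zero instability
  m <- matrix(c(20, 23, 21, 24, 22.5, 25.5), 2, 3,
              dimnames = list(c("A", "B"), NULL))
  st <- delta_ct_stability(make_ct(m))
  expect_equal(st$value, c(0, 0))

  m3 <- matrix(c(20, 21, 25, 20, 22, 25, 20, 23, 26), 3, 3,
               dimnames = list(c("g1", "g2", "g3"), NULL))
  st3 <- delta_ct_stability(make_ct(m3))
  # gene 1: mean(SD(-1,-2,-3), SD(-5,-5,-6)) = (1 + 0.57735)/2
  expect_equal(st3$value[1], (1 + sd(c(-5, -5, -6))) / 2, tolerance = 1e-12)
  expect_equal(st3$value[2], (sd(c(1, 2, 3)) + sd(c(-4, -3, -3))) / 2,
               tolerance = 1e-12)
  expect_equal(st3$value[3], (sd(c(5, 5, 6)) + sd(c(4, 3, 3))) / 2,
               tolerance = 1e-12)
  # genes 1 and 2 tie on 0.7887; gene 3 is most stable
  expect_equal(st3$rank, c(2.5, 2.5, 1))

  expect_error(delta_ct_stability(make_ct(m3[1, , drop = FALSE])),
               "2 genes")
  expect_error(delta_ct_stability(make_ct(m3[, 1:2])), "3 samples")
})

test_that("geNorm M equals the brute-force oracle on seeded instances", {
  for (seed in 1:5) {
    tab <- random_ct(4, 6, seed = seed)
    expect_equal(genorm_m(tab), oracle_genorm_m(tab), tolerance = 1e-12)
  }
  # with non-default amplification factors
  set.seed(99)
  tab <- make_ct(matrix(rnorm(5 * 8, 22, 1), 5, 8),
                 amp_factor = setNames(seq(1.8, 2.2, length.out = 5),
                                       paste0("G", 1:5)))
  expect_equal(genorm_m(tab), oracle_genorm_m(tab), tolerance = 1e-12)
  # and on subsets
  expect_equal(genorm_m(tab, c("G1", "G3", "G4")),
               oracle_genorm_m(tab, c("G1", "G3", "G4")), tolerance = 1e-12)
})

test_that("geNorm M is zero for scalar-multiple expression profiles", {
  base <- c(20, 21.5, 19, 23, 22)
  m <- rbind(A = base, B = base + 2, C = base - 1.3)
  expect_equal(unname(genorm_m(make_ct(m))), c(0, 0, 0), tolerance = 1e-12)
})

test_that("geNorm stepwise ranking removes the noisy gene first", {
  set.seed(4)
  base <- rnorm(10, 22, 1)
  m <- rbind(A = base + 0.1 * rnorm(10), B = base + 0.1 * rnorm(10),
             C = base + 0.1 * rnorm(10), D = base + 0.1 * rnorm(10),
             noisy = base + 3 * rnorm(10))
  gr <- genorm_rank(make_ct(m))
  expect_equal(gr$trace$gene[1], "noisy")
  expect_equal(sort(c(gr$trace$gene, gr$final_pair)), sort(rownames(m)))
  expect_equal(gr$stability$value[gr$stability$gene == "noisy"],
               gr$trace$m[1])
  # values at removal are the M of that step's subset
  step2 <- genorm_m(make_ct(m), setdiff(rownames(m), "noisy"))
  expect_equal(gr$trace$m[2], unname(step2[gr$trace$gene[2]]),
               tolerance = 1e-12)
})

test_that("duplicated expression profiles survive to the geNorm final pair", {
  set.seed(12)
  base <- rnorm(8, 22, 1)
  m <- rbind(copy1 = base, copy2 = base,
             n1 = base + rnorm(8, 0, 1), n2 = base + rnorm(8, 0, 1),
             n3 = base + rnorm(8, 0, 1))
  gr <- genorm_rank(make_ct(m))
  expect_setequal(gr$final_pair, c("copy1", "copy2"))
  expect_equal(sort(gr$stability$rank[gr$stability$gene %in%
                                        c("copy1", "copy2")]), c(1, 2))
})

test_that("two-gene geNorm input warns and returns the trivial pair", {
  tab <- random_ct(2, 5, seed = 2)
  expect_warning(gr <- genorm_rank(tab), "2 genes")
  expect_setequal(gr$final_pair, tab$genes)
})

test_that("pairwise variation matches the brute-force oracle and is local", {
  for (seed in 1:3) {
    tab <- random_ct(6, 8, seed = seed)
    rk <- paste0("G", 1:6)
    v <- pairwise_variation(tab, rk)
    expect_equal(v$n, 2:5)
    expect_equal(v$v, oracle_pairwise_v(tab, rk), tolerance = 1e-12)
  }
  # identical profiles -> all V zero
  base <- c(20, 21, 19.5, 22, 20.7)
  m <- rbind(A = base, B = base + 1, C = base - 2, D = base + 0.5)
  v0 <- pairwise_variation(make_ct(m), c("A", "B", "C", "D"))
  expect_equal(v0$v, rep(0, 2), tolerance = 1e-12)

  # V_2 depends only on the top three ranked genes
  tab <- random_ct(6, 8, seed = 31)
  v1 <- pairwise_variation(tab, paste0("G", 1:6))
  v2 <- pairwise_variation(tab, c(paste0("G", 1:3), "G5", "G4", "G6"))
  expect_equal(v1$v[1], v2$v[1], tolerance = 1e-12)
})

test_that("NormFinder detects pure sample effects as perfectly stable", {
  base <- c(20, 24, 28)
  loading <- c(0, 1.2, -0.8, 0.5, 2)
  m <- outer(base, loading, "+")
  rownames(m) <- c("A", "B", "C")
  st <- normfinder_stability(make_ct(m))
  expect_equal(st$value, c(0, 0, 0), tolerance = 1e-9)
})

test_that("NormFinder variance reconstruction satisfies the closed-form total", {
  for (seed in 1:5) {
    tab <- random_ct(6, 10, seed = seed, sd = 0.7)
    st <- normfinder_stability(tab)
    dec <- attr(st, "decomposition")
    k <- 6
    # without clamping, the bias-corrected variances re-sum to the total
    reconstructed <- (dec$raw_var - dec$total / k^2) / (1 - 2 / k)
    if (all(reconstructed >= 0))
      expect_equal(sum(reconstructed), dec$total, tolerance = 1e-9)
    expect_equal(dec$sigma2, pmax(reconstructed, 0), tolerance = 1e-12)
  }
})

test_that("NormFinder flags a gene with an injected group effect", {
  set.seed(21)
  groups <- rep(c("a", "b", "c"), each = 6)
  base <- seq(19, 25, length.out = 5)
  m <- matrix(rep(base, 18), 5, 18) + rnorm(5 * 18, 0, 0.3)
  # gene 3: +2 cycles in group b only
  m[3, groups == "b"] <- m[3, groups == "b"] + 2
  rownames(m) <- paste0("G", 1:5)
  st <- normfinder_stability(make_ct(m, group = groups), groups = TRUE)
  expect_equal(st$gene[which.max(st$value)], "G3")
  expect_equal(st$rank[st$gene == "G3"], 5)

  expect_error(normfinder_stability(make_ct(m[1:2, ])), "3 genes")
  expect_error(
    normfinder_stability(make_ct(m, group = c("solo", groups[-1])),
                         groups = TRUE),
    ">= 2 samples")
})

test_that("BestKeeper descriptives match hand calculations", {
  m <- rbind(flat = c(21, 21, 21), rising = c(20, 21, 22))
  st <- bestkeeper_stats(make_ct(m))
  expect_equal(st$value[st$gene == "flat"], 0)
  expect_equal(st$cv[st$gene == "flat"], 0)
  expect_equal(st$rank[st$gene == "flat"], 1)
  expect_equal(st$value[st$gene == "rising"], 1)
  expect_equal(st$cv[st$gene == "rising"], 100 / 21, tolerance = 1e-12)
  expect_equal(st$ar_mean[st$gene == "rising"], 21)
  expect_equal(st$geo_mean[st$gene == "rising"],
               prod(c(20, 21, 22))^(1 / 3), tolerance = 1e-12)

  # mad mode: mean absolute deviation from the arithmetic mean
  st2 <- bestkeeper_stats(make_ct(m), deviation = "mad")
  expect_equal(st2$value[st2$gene == "rising"], mean(abs(c(-1, 0, 1))))

  # a gene tracking the index correlates perfectly
  base <- c(20, 22, 21, 23)
  m2 <- rbind(A = base, B = base, C = base)
  st3 <- bestkeeper_stats(make_ct(m2))
  expect_equal(st3$r_index, rep(1, 3), tolerance = 1e-12)
})

test_that("sample-shift invariance holds for delta-Ct, geNorm, NormFinder", {
  tab <- random_ct(5, 8, seed = 17)
  shifted <- tab
  shifted$ct[, 3] <- shifted$ct[, 3] + 5
  shifted <- make_ct(shifted$ct)

  expect_equal(delta_ct_stability(tab)$value,
               delta_ct_stability(shifted)$value, tolerance = 1e-9)
  expect_equal(genorm_m(tab), genorm_m(shifted), tolerance = 1e-9)
  expect_equal(normfinder_stability(tab)$value,
               normfinder_stability(shifted)$value, tolerance = 1e-9)
  # BestKeeper operates on raw Ct and is expected to change
  expect_false(isTRUE(all.equal(bestkeeper_stats(tab)$value,
                                bestkeeper_stats(shifted)$value)))
})

test_that("all four methods are equivariant under gene permutation", {
  tab <- random_ct(6, 9, seed = 23)
  perm <- c(4, 1, 6, 2, 5, 3)
  ptab <- subset_ct(tab, genes = perm)
  reorder <- function(st) st[match(tab$genes[perm], st$gene), ]
  for (fn in list(delta_ct_stability,
                  function(x) genorm_rank(x)$stability,
                  normfinder_stability,
                  bestkeeper_stats)) {
    a <- fn(tab); b <- fn(ptab)
    expect_equal(reorder(a)$value, b$value, tolerance = 1e-9)
    expect_equal(reorder(a)$rank, b$rank)
  }
})

test_that("inflating one gene's noise never lowers its stability value", {
  methods <- list(
    delta_ct = function(x) delta_ct_stability(x)$value,
    genorm = function(x) genorm_m(x),
    normfinder = function(x) normfinder_stability(x)$value,
    bestkeeper = function(x) bestkeeper_stats(x)$value)
  worse <- sapply(1:20, function(seed) {
    set.seed(seed)
    base <- matrix(rep(seq(19, 24, length.out = 5), 10), 5, 10) +
      rnorm(50, 0, 0.3)
    extra <- rnorm(10, 0, 0.8)
    m1 <- base; m2 <- base
    m2[2, ] <- m2[2, ] + extra            # same draw, scaled below
    m3 <- base; m3[2, ] <- m3[2, ] + 2 * extra
    rownames(m1) <- rownames(m2) <- rownames(m3) <- paste0("G", 1:5)
    sapply(names(methods), function(mn) {
      v2 <- methods[[mn]](make_ct(m2))[2]
      v3 <- methods[[mn]](make_ct(m3))[2]
      v3 >= v2 - 1e-12
    })
  })
  # monotone in expectation: holds in (nearly) all seeded replicates
  expect_gte(mean(worse), 0.95)
})

test_that("stability_all returns consistent tables for all four methods", {
  sim <- simulate_ct(study_like_spec(seed = 5))
  agg <- aggregate_technical_replicates(sim$ct)
  st <- stability_all(agg)
  expect_named(st, c("delta_ct", "genorm", "normfinder", "bestkeeper"))
  for (m in names(st)) {
    expect_equal(sort(st[[m]]$gene), sort(agg$genes))
    expect_equal(sort(st[[m]]$rank), as.numeric(1:15))
    expect_true(all(st[[m]]$value >= 0))
  }
  expect_length(attr(st$genorm, "final_pair"), 2L)
})
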