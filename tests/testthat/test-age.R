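test_that("delta is the excess association and flags non-estimable cases", {
  d <- ld_delta(4 / 18, 0.01042)
  expect_equal(as.numeric(d), (4 / 18 - 0.01042) / (1 - 0.01042))
  expect_true(attr(d, "estimable"))
  expect_equal(as.numeric(ld_delta(1, 0.3)), 1)
  d0 <- ld_delta(0.2, 0.2)
  expect_equal(as.numeric(d0), 0)
  expect_false(attr(d0, "estimable"))
  expect_false(attr(ld_delta(0.1, 0.3), "estimable"))
  expect_error(ld_delta(0.5, 1), "p_n")
})

test_that("decay ages equal direct arithmetic on published block inputs", {
  # g = ln(delta)/ln(1-theta), rounded half-up
  cases <- list(
    list(p_d = 4 / 18, p_n = 0.01042, theta = 0.01242, g = 123),
    list(p_d = 6 / 18, p_n = 0.01042, theta = 0.01068, g = 104),
    list(p_d = 8 / 18, p_n = 0.06510, theta = 0.01009, g = 89),
    list(p_d = 16 / 18, p_n = 0.57753, theta = 0.00192, g = 159),
    list(p_d = 14 / 18, p_n = 0.01042, theta = 0.00130, g = 196))
  for (cs in cases) {
    est <- risch_age(cs$p_d, cs$p_n, cs$theta)
    direct <- log((cs$p_d - cs$p_n) / (1 - cs$p_n)) / log(1 - cs$theta)
    expect_equal(est$generations, direct)
    expect_equal(est$rounded, cs$g)
  }
  expect_equal(risch_age(1, 0.5, 0.01)$generations, 0)  # delta = 1
  expect_error(risch_age(0.1, 0.3, 0.01), "not estimable")
  expect_error(risch_age(0.5, 0.1, 0), "theta")
})

test_that("decay age is monotone decreasing in P_D and in theta", {
  g_pd <- vapply(seq(0.3, 0.9, by = 0.1),
                 function(p) risch_age(p, 0.05, 0.01)$generations, numeric(1))
  expect_true(all(diff(g_pd) < 0))
  # holding delta fixed, larger theta means fewer generations
  g_th <- vapply(c(0.001, 0.005, 0.01, 0.02),
                 function(th) risch_age(0.5, 0.05, th)$generations, numeric(1))
  expect_true(all(diff(g_th) < 0))
})

test_that("transition matrix is column-stochastic and preserves the simplex", {
  m <- goldstein_model(a = 0.0745, c = 0.01, mu = 1e-8)
  expect_equal(colSums(m$K), c(1, 1), tolerance = 1e-12)
  v <- c(1, 0)
  for (i in 1:50) {
    v <- as.vector(m$K %*% v)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
  # ancestral frequency decreases toward the control frequency
  expect_lt(v[1], 1)
  expect_gt(v[1], m$a)
})

test_that("iterated decay matches the closed form analytically at mu = 0", {
  expect_equal(goldstein_age(0.75, p_n = 0.5, theta = 0.01, mu = 0)$generations,
               log(0.5) / log(0.99), tolerance = 1e-9)
  for (a in c(0.01, 0.1, 0.3)) for (cc in c(0.002, 0.01, 0.02)) {
    for (pd in c(0.95, 0.6, 0.25)) {
      if (pd <= a) next
      expect_equal(goldstein_age(pd, p_n = a, theta = cc, mu = 0)$generations,
                   risch_age(pd, a, cc)$generations, tolerance = 1e-6)
    }
  }
  expect_equal(goldstein_age(1, p_n = 0.1, theta = 0.01)$generations, 0)
  expect_error(goldstein_age(0.05, p_n = 0.1, theta = 0.01), "not estimable")
})

test_that("published-scale inputs give matching iterative and decay ages", {
  r <- risch_age(4 / 18, 0.01042, 0.01242)
  g <- goldstein_age(4 / 18, p_n = 0.01042, theta = 0.01242, mu = 1e-8)
  expect_equal(g$rounded, 123)
  expect_lt(abs(g$generations - r$generations), 1)
})

test_that("Gamma estimator: formula, CI and censoring conventions", {
  # one chromosome: two one-sided segments summing to S = 0.02 Morgans
  est <- gamma_age(c(0.005, 0.015), censored = c(FALSE, FALSE))
  expect_equal(est$generations, (2 * 1 - 1) / 0.02)  # (2n - 1)/S -> 50
  expect_equal(est$ci_low, qgamma(0.025, 2) / 0.02)
  expect_equal(est$ci_high, qgamma(0.975, 2) / 0.02)

  # censored segments add to S but not the shape
  est2 <- gamma_age(c(0.01, 0.03), censored = c(FALSE, TRUE))
  expect_equal(est2$generations, max(1 - 1, 1) / 0.04)
  est3 <- gamma_age(c(0.01, 0.03), censored = c(FALSE, TRUE),
                    correction = "mle")
  expect_equal(est3$generations, 1 / 0.04)
  expect_error(gamma_age(c(0, 0), censored = c(FALSE, FALSE)), "zero")
})

test_that("Gamma bias correction: (2n-1)/S nearly unbiased, 2n/S biased up", {
  set.seed(2024)
  g_true <- 100; n <- 5; reps <- 10000
  S <- matrix(rexp(2 * n * reps, rate = g_true), nrow = reps)
  S <- rowSums(S)
  corrected <- (2 * n - 1) / S
  naive <- (2 * n) / S
  expect_lt(abs(mean(corrected) - g_true) / g_true, 0.02)
  expect_gt(mean(naive), g_true * 1.05)
})

test_that("Gamma CI covers the truth at near-nominal rate", {
  set.seed(7)
  g_true <- 100; n <- 18; reps <- 400
  hit <- 0
  for (r in seq_len(reps)) {
    lens <- rexp(2 * n, rate = g_true)
    est <- gamma_age(lens, censored = rep(FALSE, 2 * n))
    hit <- hit + (est$ci_low <= g_true && g_true <= est$ci_high)
  }
  expect_gte(hit / reps, 0.90)
})

test_that("correlated genealogy collapses shared lineages and lowers the shape", {
  panel <- clcc1_panel()
  founder <- infer_founder(panel$carriers, panel$map)
  seg <- segment_lengths(panel$carriers, panel$map, founder)
  ev <- derive_family_events(panel$carriers, panel$map, founder)
  ind <- gamma_age(seg, genealogy = "independent")
  cor <- gamma_age(seg, genealogy = "correlated", events = ev)
  expect_lt(cor$n_uncensored, ind$n_uncensored)
  expect_lt(cor$S, ind$S)
  # both are founder-age estimates of the order of 1e2 generations
  expect_gt(cor$generations, 10); expect_lt(cor$generations, 1000)
})

test_that("bootstrap CI is deterministic, degenerate at P_D = 1, and covers", {
  est <- function(p) risch_age(p, 0.05, 0.01)
  ci1 <- bootstrap_ci(est, 14 / 18, 18, B = 500, seed = 42)
  ci2 <- bootstrap_ci(est, 14 / 18, 18, B = 500, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] < ci1[2])

  ci_deg <- bootstrap_ci(function(p) risch_age(p, 0, 0.01), 1, 18,
                         B = 200, seed = 1)
  expect_equal(as.numeric(ci_deg), c(0, 0))

  expect_error(
    bootstrap_ci(function(p) risch_age(p, 0.9, 0.01), 2 / 18, 18,
                 B = 100, seed = 1),
    "more than half")
})

test_that("age table reproduces the published grid and range summary", {
  inputs <- clcc1_block_inputs()
  inputs$theta_pub <- inputs$theta
  panel <- clcc1_panel()
  founder <- infer_founder(panel$carriers, panel$map)
  partition <- partition_blocks(panel$carriers, panel$map, founder)
  inputs$theta <- unname(block_theta(partition, panel$map)[inputs$label])
  tab <- age_table(inputs, n_chrom = 18, mu = 1e-8)
  pick <- function(lab, meth, src) {
    tab$rounded[tab$label == lab & tab$method == meth & tab$source == src]
  }
  expect_equal(pick("rs12403629", "risch", "EM"), 123)
  expect_equal(pick("rs345292", "risch", "EM"), 104)
  expect_equal(pick("rs17020437", "risch", "CHM"), 89)
  expect_equal(pick("rs587727", "risch", "EM"), 159)
  expect_equal(pick("rs17014495", "risch", "EM"), 185)
  expect_equal(pick("rs12239350", "risch", "CHM"), 134)
  # iterative estimator within one generation of the closed form everywhere
  wide <- merge(tab[tab$method == "risch", c("label", "source", "generations")],
                tab[tab$method == "goldstein", c("label", "source", "generations")],
                by = c("label", "source"))
  expect_true(all(abs(wide$generations.x - wide$generations.y) < 1,
                  na.rm = TRUE))
  # the distal two-marker block is not estimable by decay (delta <= 0)
  expect_true(all(!tab$estimable[tab$label == "rs11102121"]))
  rng <- age_range(tab)
  expect_equal(rng$min_generations, 79)
  expect_equal(rng$max_generations, 196)
  expect_equal(rng$min_years, 1975)
  expect_equal(rng$max_years, 4900)
})

test_that("empty estimable set yields an NA summary", {
  inputs <- data.frame(label = "b1", n_shared = 2, fn_em = 0.5, fn_chm = 0.5,
                       theta = 0.01)
  tab <- age_table(inputs, n_chrom = 18)
  expect_true(all(!tab$estimable))
  expect_true(is.na(age_range(tab)$min_generations))
})
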