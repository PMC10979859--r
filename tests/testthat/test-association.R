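test_that("the binomial GLM coefficient equals the 2x2 log odds ratio", {
  # non-carrier 20 dead / 10 alive, carrier 10 dead / 30 alive
  carrier <- rep(c(0, 1), c(30, 40))
  alive <- c(rep(c(0, 1), c(20, 10)), rep(c(0, 1), c(10, 30)))
  fit <- glm_binomial(alive, data.frame(carrier = carrier))
  expect_equal(fit$table$estimate[fit$table$term == "carrier"],
               log(6), tolerance = 1e-6)
  expect_false(fit$separation)

  # exact identity on random all-positive 2x2 tables
  set.seed(24)
  for (rep in 1:20) {
    tab <- matrix(sample(3:40, 4, replace = TRUE), 2)
    x <- rep(c(0, 0, 1, 1), tab)
    y <- rep(c(0, 1, 0, 1), tab)
    fit2 <- glm_binomial(y, data.frame(x = x))
    or <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
    expect_equal(fit2$table$estimate, log(or), tolerance = 1e-6)
  }
})

test_that("separation is flagged and the LRT p-value is the fallback", {
  x <- rep(c(0, 1), each = 20)
  y <- x  # perfect separation
  fit <- suppressWarnings(glm_binomial(y, data.frame(x = x)))
  expect_true(fit$separation)
  expect_false(is.na(fit$table$p_lrt))
  expect_lt(fit$table$p, 1e-8)
  expect_identical(fit$table$p, fit$table$p_lrt)

  expect_warning(glm_binomial(rep(c(0, 1), 10),
                              data.frame(a = rep(1, 20),
                                         b = rep(c(0, 1), 10))),
                 "constant predictor")
  expect_error(glm_binomial(rep(1, 10), data.frame(x = rnorm(10))),
               "single value")
})

test_that("null GLM p-values are approximately uniform", {
  set.seed(25)
  p <- replicate(200, {
    x <- rbinom(120, 2, 0.3)
    y <- rbinom(120, 1, 0.5)
    fit <- suppressWarnings(glm_binomial(y, data.frame(x = x)))
    fit$table$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("marker tests use the stated codings and drop constants", {
  set.seed(26)
  st <- fix_sample_table(40)
  markers <- data.frame(snp = rbinom(40, 2, 0.4),
                        flat = rep(1, 40),
                        cnv = rbinom(40, 1, 0.5))
  expect_warning(res <- marker_tests(st, markers), "constant")
  expect_setequal(res$marker, c("snp", "cnv"))
  # dose enters untransformed: same estimate as a direct fit
  direct <- glm_binomial(as.integer(st$phenotype == "resistant"),
                         data.frame(marker = markers$snp))
  expect_equal(res$estimate[res$marker == "snp"],
               direct$table$estimate, tolerance = 1e-12)
})

test_that("stepwise selection is LRT-driven with deterministic ties", {
  set.seed(27)
  st <- fix_sample_table(200, phenotype = c(rep("resistant", 100),
                                            rep("susceptible", 100)))
  y <- as.integer(st$phenotype == "resistant")

  # pure noise: the null model survives
  null_markers <- data.frame(a = rnorm(200), b = rnorm(200))
  sw0 <- stepwise_build(st, null_markers, alpha = 0.001)
  expect_identical(sw0$selected, character())

  # two perfectly collinear copy-number markers: exactly one enters
  cn <- rbinom(200, 1, 0.5) * sample(1:6, 200, replace = TRUE)
  y2 <- rbinom(200, 1, stats::plogis(-0.5 + 0.8 * (cn > 0)))
  st2 <- st; st2$phenotype <- ifelse(y2 == 1, "resistant", "susceptible")
  sw2 <- stepwise_build(st2, data.frame(gene1 = cn, gene2 = cn))
  expect_identical(length(sw2$selected), 1L)
  expect_identical(sw2$selected, "gene1")  # tie broken by marker order

  # causal marker is preferred over null markers
  carrier <- rbinom(200, 1, 0.5)
  y3 <- rbinom(200, 1, stats::plogis(-1 + 1.6 * carrier))
  st3 <- st; st3$phenotype <- ifelse(y3 == 1, "resistant", "susceptible")
  mk <- data.frame(causal = carrier, n1 = rnorm(200), n2 = rnorm(200),
                   n3 = rbinom(200, 2, 0.3))
  sw3 <- stepwise_build(st3, mk)
  expect_identical(sw3$selected[1], "causal")
  # log-likelihood is non-decreasing along the path and all entry p < alpha
  expect_true(all(diff(sw3$loglik_path) > -1e-10))
  expect_true(all(sw3$p_path < 0.05))
})

test_that("the contamination filter excludes tracking sites only", {
  set.seed(28)
  n <- 80
  st <- fix_sample_table(n, contamination = runif(n, 0, 0.05))
  g <- random_genoset(40, n)
  # make site 7 track contamination strongly
  ranked <- rank(st$contamination)
  g$calls[7, ] <- as.integer(cut(ranked, 3)) - 1L
  kept <- contamination_filter(g, st, alpha = 0.05)
  expect_false(7L %in% kept)

  # zero-variance contamination: nothing excluded
  st0 <- fix_sample_table(n, contamination = 0)
  expect_identical(contamination_filter(g, st0), seq_len(40L))
})

test_that("snp_gwas applies its filters before testing", {
  set.seed(29)
  g <- random_genoset(60, 50)
  g$calls[3, 5] <- NA_integer_  # one missing call: site excluded
  st <- fix_sample_table(50)
  res <- snp_gwas(g, st, min_mac = 5L)
  expect_false(3L %in% res$site)
  expect_true(all(res$mac >= 5L))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # site indices refer to the input genotype set
  expect_true(all(res$pos == g$sites$pos[res$site]))
})

test_that("BH selection reproduces the step-up rule", {
  expect_identical(nrow(fdr_select(data.frame(p = rep(1, 20)), q = 0.01)), 0L)

  # step-up by hand: p_(10) = 1e-5 <= 0.01 * 10/1000, so all ten enter;
  # at p = 0.001 the same ten would fail (0.001 > 1e-4) and none enters
  p <- c(rep(1e-5, 10), rep(0.9, 990))
  tab <- data.frame(site = seq_along(p), p = p)
  sel <- fdr_select(tab, q = 0.01)
  expect_identical(sel$site, 1:10)
  tab2 <- data.frame(site = 1:1000, p = c(rep(0.001, 10), rep(0.9, 990)))
  expect_identical(nrow(fdr_select(tab2, q = 0.01)), 0L)

  set.seed(30)
  for (rep in 1:100) {
    p2 <- runif(sample(5:60, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- fdr_select(data.frame(site = seq_along(p2), p = p2), q)$site
    expect_identical(got, oracle_bh_select(p2, q))
  }
})

test_that("windowed GWAS counting matches brute force", {
  # 12 top SNPs in one tile: flagged; 9 in another: not
  p_tab <- data.frame(contig = "2L",
                      pos = c(seq(1000, by = 50, length.out = 12),
                              seq(200001, by = 50, length.out = 9)),
                      p = rep(1e-6, 21))
  extra <- data.frame(contig = "2L",
                      pos = seq(500001, by = 13, length.out = 400),
                      p = runif(400, 0.5, 1))
  res <- windowed_gwas(rbind(p_tab, extra), top_n = 21L,
                       window_bp = 100000L, min_hits = 10L)
  expect_true(res$flagged[res$start == 0])
  expect_false(res$flagged[res$start == 200000])

  set.seed(31)
  for (rep in 1:100) {
    n <- sample(50:300, 1)
    tab <- data.frame(contig = "2L", pos = sort(sample.int(5e5, n)),
                      p = runif(n))
    top_n <- sample(c(20L, 50L), 1)
    min_hits <- sample(2:6, 1)
    res2 <- windowed_gwas(tab, top_n, 100000L, min_hits)
    want <- oracle_windowed_gwas(tab$pos, tab$p, top_n, 100000L, min_hits)
    got <- sort(res2$start[res2$flagged] / 100000L)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("power simulation is calibrated at its edge cases", {
  # no effect: rejection rate near alpha
  pr0 <- cnv_power_simulation(120, 0.5, 0.3, 0.3, n_sims = 400L, seed = 5L)
  expect_gt(pr0$power, 0.01)
  expect_lt(pr0$power, 0.10)

  # deterministic outcome split: near-certain detection via the LRT fallback
  pr1 <- cnv_power_simulation(60, 0.5, 1, 0, n_sims = 100L, seed = 6L)
  expect_gt(pr1$power, 0.99)

  # the Monte-Carlo SE follows the binomial formula and seeds reproduce
  pr2 <- cnv_power_simulation(80, 0.4, 0.5, 0.2, n_sims = 150L, seed = 7L)
  expect_equal(pr2$se, sqrt(pr2$power * (1 - pr2$power) / 150))
  pr3 <- cnv_power_simulation(80, 0.4, 0.5, 0.2, n_sims = 150L, seed = 7L)
  expect_identical(pr2$power, pr3$power)
})
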