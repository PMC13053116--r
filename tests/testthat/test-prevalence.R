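test_that("aggregate allele frequency sums per-group AFs linearly", {
  expect_equal(aggregate_allele_frequency(make_variants(integer(), integer(),
                                                        character()), "nfe"), 0)
  v <- make_variants(ac = c(10L, 20L), an = c(10000L, 10000L), group = "nfe")
  expect_equal(aggregate_allele_frequency(v, "nfe"), 0.003)
  expect_equal(aggregate_allele_frequency(v, "afr"), 0)

  # random 50-variant, 9-group table vs brute-force double loop
  set.seed(3)
  groups <- ancestry_groups()
  tab <- make_variants(1L, 10000L, "nfe")[0, ]
  for (i in 1:50) {
    row <- make_variants(0L, 10000L, "nfe")[1, ]
    row$pos <- i
    for (g in groups) {
      row[[paste0("AC_", g)]] <- sample(0:50, 1)
      row[[paste0("AN_", g)]] <- sample(c(8000L, 10000L, 12000L), 1)
    }
    tab <- rbind(tab, row)
  }
  for (g in groups) {
    brute <- 0
    for (i in 1:50) brute <- brute + tab[[paste0("AC_", g)]][i] /
        tab[[paste0("AN_", g)]][i]
    expect_equal(aggregate_allele_frequency(tab, g), brute)
  }
  # pooled "all" frequency uses summed AC over summed AN per variant
  brute_all <- sum(sapply(1:50, function(i) {
    sum(sapply(groups, function(g) tab[[paste0("AC_", g)]][i])) /
      sum(sapply(groups, function(g) tab[[paste0("AN_", g)]][i]))
  }))
  expect_equal(aggregate_allele_frequency(tab, "all"), brute_all)

  bad <- make_variants(9000L, 10000L, "nfe")[rep(1, 2), ]
  expect_error(aggregate_allele_frequency(bad, "nfe"), "exceeds 1")
  expect_error(aggregate_allele_frequency(tab, "martian"), "unknown ancestry")
})

test_that("variants with no allele number contribute zero with a warning", {
  v <- make_variants(ac = c(5L, 0L), an = c(10000L, 0L), group = "mid")
  expect_warning(af <- group_allele_frequency(v, "mid"), "AF = 0")
  expect_equal(af, c(5 / 10000, 0))
})

test_that("carrier frequency is the stated 2*sum_q approximation", {
  expect_equal(carrier_frequency(0), 0)
  set.seed(4)
  q <- runif(20, 0, 0.4)
  expect_equal(carrier_frequency(q), 2 * q)
  expect_error(carrier_frequency(0.51), "exceed 1")
  # back-derived from the printed Ashkenazi prevalence denominator
  expect_equal(format_one_in(carrier_frequency(1 / sqrt(16258))), "1 in 64")
})

test_that("(sum q)^2 equals the brute-force genotype double sum", {
  expect_equal(genetic_prevalence(0.5), 0.25)
  expect_equal(genetic_prevalence(0.001), 1e-6)
  set.seed(5)
  for (rep in 1:10) {
    q <- runif(sample(2:30, 1), 0, 0.01)
    double_sum <- 0
    for (i in seq_along(q)) {
      for (j in seq_along(q)) double_sum <- double_sum + q[i] * q[j]
    }
    expect_equal(genetic_prevalence(sum(q)), double_sum)
  }
})

test_that("single-variant homozygote frequency squares the group AF", {
  v <- make_variants(0L, 0L, "nfe")[1, ]
  v$AC_asj <- 192L; v$AN_asj <- 27200L
  expect_equal(one_in_denominator(homozygote_frequency(v, "asj")), 20069)
  expect_error(homozygote_frequency(v, "mid"), "no frequency data")
  set.seed(6)
  for (q in runif(10, 0, 0.01)) {
    an <- 20000L
    v$AC_eas <- as.integer(round(q * an)); v$AN_eas <- an
    expect_equal(homozygote_frequency(v, "eas"), (v$AC_eas / an)^2)
  }
})

test_that("1-in-N formatting rounds halves away from zero", {
  expect_equal(format_one_in(0.015625), "1 in 64")
  expect_equal(format_one_in(2 / sqrt(235776)), "1 in 243")
  expect_equal(format_one_in(2 / sqrt(1127547)), "1 in 531")
  expect_equal(format_one_in(1 / 2.5), "1 in 3")   # 2.5 rounds up, not to even
  expect_error(format_one_in(0), "positive")
  expect_equal(format_percent(0.0041234), "0.41%")
  expect_equal(format_percent(0.015685), "1.57%")
})

test_that("every printed carrier denominator is recoverable from its prevalence", {
  t1 <- gbe1_table1()
  for (i in seq_len(nrow(t1))) {
    sum_q <- sqrt(1 / t1$prevalence_denom[i])
    expect_equal(format_one_in(carrier_frequency(sum_q)),
                 paste("1 in", t1$carrier_denom[i]), info = t1$group[i])
  }
})

test_that("estimate_all_groups reports every group with exact identities", {
  v <- make_variants(ac = 30L, an = 30000L, group = "fin")
  est <- estimate_all_groups(v)
  expect_equal(est$group, ancestry_groups(display = TRUE))
  fin <- est[est$group == "fin", ]
  expect_equal(fin$carrier_freq, 2 * 0.001)
  expect_equal(fin$prevalence, 1e-6)
  expect_equal(fin$n_variants, 1L)
  # identity holds on every row before formatting
  expect_equal(est$prevalence, (est$carrier_freq / 2)^2)

  # monotonicity: adding a variant with positive AF never lowers estimates
  v2 <- rbind(v, make_variants(1L, 30000L, "fin"))
  est2 <- estimate_all_groups(v2)
  expect_true(all(est2$sum_q >= est$sum_q))
  expect_true(all(est2$prevalence >= est$prevalence))
})

test_that("relaxed estimates dominate conservative estimates per group", {
  res <- fixture_pipeline()
  cons <- res$estimates$conservative
  rel <- res$estimates$relaxed
  expect_equal(cons$group, rel$group)
  expect_true(all(rel$sum_q >= cons$sum_q))
  expect_true(all(rel$carrier_freq >= cons$carrier_freq))
  expect_true(all(rel$prevalence >= cons$prevalence))
})
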