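# Gonad zone assignment, the N/5 subdivision and the category statistics.

test_that("the N/5 meiotic subdivision follows the printed formula", {
  expect_identical(split_meiotic_zones(25), c(5L, 5L, 5L, 5L, 5L))
  expect_identical(split_meiotic_zones(27), c(5L, 5L, 5L, 5L, 7L))
  expect_identical(split_meiotic_zones(22), c(4L, 4L, 4L, 4L, 6L))
  for (N in 5:200) {
    w <- split_meiotic_zones(N)
    expect_identical(sum(w), as.integer(N))
    expect_true(all(w[1:4] == w[1]))
    expect_identical(w[1], as.integer(floor(N / 5 + 0.5)))
  }
  expect_error(split_meiotic_zones(4))
})

make_gonad_table <- function(pm = 10, tz = 11, pa = 15, per_row = 4,
                             tail_rows = 6) {
  rows <- pm + tz + pa + tail_rows
  df <- expand.grid(j = seq_len(per_row), row = seq_len(rows))
  df$nucleus_id <- sprintf("n%03d", seq_len(nrow(df)))
  df$clustered <- df$row > pm & df$row <= pm + tz
  df$chrI_state <- ifelse(df$row <= pm, "unaligned",
                   ifelse(df$row <= pm + tz,
                          sample(alignment_levels(), nrow(df), TRUE,
                                 prob = c(0.4, 0.3, 0.3)),
                          "full"))
  df
}

test_that("zone assignment recovers a planted transition zone", {
  set.seed(1)
  df <- make_gonad_table(pm = 10, tz = 11, pa = 15)
  z <- assign_zones(df, zone_scheme(premeiotic_rows = 10))
  tz <- attr(z, "tz_span")
  expect_false(is.null(tz))
  expect_lte(abs(tz[1] - 11), 1)
  expect_lte(abs(tz[2] - 21), 1)
  expect_true(all(z$zone[z$row <= 10] == "premeiotic"))
  # pachytene window starts 5 rows after the TZ end
  expect_true(all(z$zone[z$row == tz[2] + 5] == "pachytene"))
  expect_true(all(z$zone[z$row == tz[2] + 1] == "unzoned"))
  # every nucleus carries exactly one label
  expect_false(any(is.na(z$zone)))
})

test_that("a gonad with no clustered rows has an empty transition zone", {
  df <- make_gonad_table(pm = 10, tz = 0, pa = 0, tail_rows = 10)
  df$clustered <- FALSE
  df$chrI_state <- "full"
  z <- assign_zones(df, zone_scheme())
  expect_null(attr(z, "tz_span"))
  expect_true(all(z$zone[z$row > 10] == "unzoned"))
})

test_that("the six-zone scheme partitions the meiotic region", {
  set.seed(2)
  df <- make_gonad_table(pm = 8, tz = 27, pa = 0, tail_rows = 0)
  z <- assign_zones(df, zone_scheme("syp1_six_zone", premeiotic_rows = 8))
  expect_equal(attr(z, "meiotic_start"), 9)
  widths <- as.integer(table(factor(z$zone[!duplicated(z$row)],
                                    levels = paste0("zone", 2:6))))
  expect_identical(widths, c(5L, 5L, 5L, 5L, 7L))
})

test_that("the joint alignment matrix tallies nine categories", {
  a <- c("full", "full", "full")
  b <- c("full", "full", "full")
  m <- joint_alignment_matrix(a, b)
  expect_identical(sum(m), 3L)
  expect_identical(m["full", "full"], 3L)
  set.seed(3)
  a2 <- sample(alignment_levels(), 60, TRUE)
  b2 <- sample(alignment_levels(), 60, TRUE)
  m2 <- joint_alignment_matrix(a2, b2)
  expect_identical(sum(m2), 60L)
  # brute-force tally of one cell
  expect_identical(m2["partial", "unaligned"],
                   sum(a2 == "partial" & b2 == "unaligned"))
})

test_that("Fisher exact equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_two_tailed(matrix(c(3, 0, 0, 3), 2)), 0.1)
  # exhaustive check over all 2x2 tables with total at most 14
  for (n in 1:14) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[parts$a + parts$b + parts$c <= n, ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(c(parts$a[i], parts$b[i], parts$c[i],
                      n - parts$a[i] - parts$b[i] - parts$c[i]), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_two_tailed(tab), oracle_fisher(tab),
                   tolerance = 1e-7)
    }
  }
})

test_that("Mann-Whitney matches brute-force rank enumeration for small n", {
  expect_equal(mann_whitney_two_tailed(c(1, 2, 3), c(1, 2, 3)), 1)
  cases <- list(list(x = c(1.2, 3.4, 5.1), y = c(2.2, 6.3, 7.7, 9.1)),
                list(x = c(10, 12), y = c(1, 2, 3, 4)),
                list(x = c(1, 5, 9, 13), y = c(2, 6, 10, 14)),
                list(x = c(0.3, 0.9, 2.5, 4.1, 6.6), y = c(1.5, 3.2, 5.9)))
  for (cs in cases) {
    expect_equal(mann_whitney_two_tailed(cs$x, cs$y),
                 oracle_mann_whitney(cs$x, cs$y), tolerance = 1e-9)
  }
})

test_that("chi-square behaves on proportional and degenerate tables", {
  tab <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(chi_square_two_tailed(tab), 1)
  expect_error(chi_square_two_tailed(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("zone summaries reproduce hand-computed statistics", {
  rec <- data.frame(
    zone = c("transition", "transition", "transition", "transition"),
    genotype = "wildtype", chromosome_id = "chrI",
    segment_count_k = c(1, 1, 2, 2),
    highly_extended = c(TRUE, TRUE, FALSE, TRUE),
    alignment_state = c("full", "partial", "unaligned", "full"))
  out <- summarize_zone_metrics(rec)
  full_stratum <- out$segments[out$segments$stratum == "TZ Full", ]
  nf_stratum <- out$segments[out$segments$stratum == "TZ NF", ]
  expect_identical(full_stratum$n, 2L)
  expect_identical(nf_stratum$n, 2L)
  all_mean <- mean(c(1, 1, 2, 2)); all_sd <- sd(c(1, 1, 2, 2))
  pooled <- data.frame(zone = "pachytene", genotype = "wt",
                       chromosome_id = "chrI",
                       segment_count_k = c(1, 1, 2, 2),
                       highly_extended = TRUE, alignment_state = "full")
  out2 <- summarize_zone_metrics(pooled)
  expect_equal(out2$segments$mean_k, 1.5)
  expect_equal(out2$segments$sd_k, all_sd)
  expect_equal(out2$extension$pct_highly_extended, 100)
})
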