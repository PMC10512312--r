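test_that("metabolite split is inclusive at the threshold and conserves hits", {
  h <- hit_table(rep("sp1", 4), c("m1", "m2", "m3", "m4"),
                 c(75.0, 74.9, 100, 0))
  out <- split_by_threshold(h)
  expect_setequal(out$high$category, c("m1", "m3"))
  expect_setequal(out$low$category, c("m2", "m4"))
  expect_equal(sum(out$high$count) + sum(out$low$count), nrow(h))

  set.seed(42)
  h2 <- hit_table(sample(sprintf("sp%d", 1:3), 200, TRUE),
                  sample(sprintf("m%d", 1:5), 200, TRUE),
                  round(runif(200, 0, 100), 1))
  out2 <- split_by_threshold(h2)
  expect_equal(sum(out2$high$count) + sum(out2$low$count), 200L)
  expect_equal(sum(out2$high$count), sum(h2$match_percent >= 75))
})

test_that("peptide bins partition the retained range with the printed labels", {
  scheme <- amp_bin_scheme()
  dash <- "\u2013"
  cases <- data.frame(
    value = c(100, 99.9, 95.0, 94.9, 90.0, 89.95, 89.9, 80.0, 79.9, 70,
              69.9, 51.0),
    label = c("100", paste0("99.9", dash, "95.0"),
              paste0("99.9", dash, "95.0"), paste0("94.9", dash, "90.0"),
              paste0("94.9", dash, "90.0"), paste0("89.9", dash, "80.0"),
              paste0("89.9", dash, "80.0"), paste0("89.9", dash, "80.0"),
              paste0("79.9", dash, "70"), paste0("79.9", dash, "70"),
              paste0("69.9", dash, "51.0"), paste0("69.9", dash, "51.0")),
    stringsAsFactors = FALSE)
  got <- bgcrank:::assign_bins(cases$value, scheme)
  expect_equal(got, cases$label)
  # the exclusion rule: 50.9 and below are dropped, 51.0 retained
  expect_true(all(is.na(bgcrank:::assign_bins(c(50.9, 50.0, 0), scheme))))
  expect_false(is.na(bgcrank:::assign_bins(51.0, scheme)))
})

test_that("every value on a 0.1 grid is excluded or lands in exactly one bin", {
  scheme <- amp_bin_scheme()
  grid <- round(seq(0, 1000) / 10, 1)
  lab <- bgcrank:::assign_bins(grid, scheme)
  excluded <- is.na(lab)
  expect_true(all(grid[excluded] < 51.0))
  expect_true(all(grid[!excluded] >= 51.0))
  m <- bgcrank:::bin_membership_matrix(grid[!excluded], scheme)
  expect_true(all(rowSums(m) == 1L))
})

test_that("binning hits reports dropped records and conserves the rest", {
  set.seed(7)
  h <- hit_table(sample(sprintf("sp%d", 1:4), 500, TRUE),
                 sprintf("pep%03d", 1:500),
                 round(runif(500, 0, 100), 1))
  out <- bin_amp_matches(h)
  expect_equal(sum(out$counts$count) + out$dropped, 500L)
  expect_equal(out$dropped, sum(h$match_percent < 51.0))
  expect_equal(sum(vapply(out$per_bin, function(x) sum(x$count), numeric(1))),
               500 - out$dropped)

  overlapping <- data.frame(label = c("a", "b"), lower = c(50, 40),
                            upper = c(100, 60), lower_inclusive = TRUE,
                            upper_inclusive = TRUE)
  expect_error(bin_scheme(overlapping, 40), class = "bgcrank_config_error")
})

test_that("keyword categorization is first-match, case-insensitive, conserving", {
  h <- hit_table(
    rep("sp1", 5), sprintf("p%d", 1:5), rep(99, 5),
    c("Hypothetical Protein, partial",
      "glycoside hydrolase family 18 protein",
      "NRPS-like protein with peptidase domain",  # matches two categories
      "",
      "completely novel description"))
  out <- bin_keywords(h)
  expect_equal(sum(out$count), 5L)
  cnt <- setNames(out$count, out$category)
  expect_equal(unname(cnt[["hypothetical protein"]]), 1L)
  expect_equal(unname(cnt[["glycoside hydrolase family"]]), 1L)
  # first category in scheme order wins the two-way match
  expect_equal(unname(cnt[["non-ribosomal peptide synthetase"]]), 1L)
  expect_false("peptidase" %in% names(cnt))
  expect_equal(unname(cnt[["other"]]), 2L)
})

test_that("hypothetical fraction skips species with no hits", {
  kc <- count_table(c("sp1", "sp1", "sp2"),
                    c("hypothetical protein", "peptidase",
                      "hypothetical protein"),
                    c(7L, 3L, 4L))
  f <- hypothetical_fraction(kc)
  expect_equal(unname(f[["sp1"]]), 0.7)
  expect_equal(unname(f[["sp2"]]), 1.0)
  expect_false("sp3" %in% names(f))
  kc0 <- count_table("sp3", "peptidase", 0L)
  expect_length(hypothetical_fraction(kc0), 0L)
})

test_that("top-k annotations break ties lexicographically and drop the fallback", {
  kc <- count_table(rep("sp1", 4), c("B", "A", "C", "other"),
                    c(3L, 3L, 1L, 99L))
  top <- top_k_annotations(kc, k = 2)
  expect_equal(top[["sp1"]], c("A", "B"))
  top3 <- top_k_annotations(kc, k = 10)
  expect_equal(top3[["sp1"]], c("A", "B", "C"))
  with_other <- top_k_annotations(kc, k = 1, exclude_fallback = FALSE)
  expect_equal(with_other[["sp1"]], "other")
  expect_error(top_k_annotations(kc, k = 0), class = "bgcrank_config_error")
})

test_that("genome totals include zero-count species from the taxonomy", {
  sp <- species_table(c("sp1", "sp2"), c("s1", "s1"))
  ct <- count_table(c("sp1", "sp1"), c("c1", "c2"), c(2L, 3L))
  tot <- genome_totals(ct, sp)
  expect_equal(unname(tot[["sp1"]]), 5)
  expect_equal(unname(tot[["sp2"]]), 0)
  expect_equal(sum(tot), sum(ct$count))
})

test_that("section averages divide by all species in the section", {
  sp <- species_table(c("sp1", "sp2", "sp3"), c("s1", "s1", "s2"))
  ct <- count_table(c("sp1", "sp3"), c("c1", "c1"), c(4L, 6L))
  m <- section_average(ct, sp)
  expect_equal(m["s1", "c1"], 2.0)  # (4 + implicit 0) / 2
  expect_equal(m["s2", "c1"], 6.0)  # single-species section
  expect_equal(attr(m, "species_counts"), c(s1 = 2L, s2 = 1L))
  expect_error(section_average(ct, species_table(character(0), character(0))),
               class = "bgcrank_config_error")
  expect_error(
    section_average(count_table("ghost", "c1", 1L), sp),
    class = "bgcrank_validation_error")
})

test_that("section averages match a direct recomputation on random tables", {
  for (seed in 1:25) {
    fx <- random_count_fixture(seed)
    m <- section_average(fx$counts, fx$species)
    n_per <- attr(m, "species_counts")
    for (s in rownames(m)) {
      in_sec <- fx$species$species_id[fx$species$section == s]
      for (cc in colnames(m)) {
        direct <- sum(fx$counts$count[fx$counts$species_id %in% in_sec &
                                        fx$counts$category == cc])
        expect_lt(abs(m[s, cc] * n_per[[s]] - direct), 1e-9)
      }
    }
  }
})

test_that("section averaging is linear in the counts", {
  fx <- random_count_fixture(99)
  m1 <- section_average(fx$counts, fx$species)
  doubled <- fx$counts
  doubled$count <- doubled$count * 2L
  m2 <- section_average(doubled, fx$species)
  expect_equal(unclass(m2), unclass(m1) * 2)
})
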