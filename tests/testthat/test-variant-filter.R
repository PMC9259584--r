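test_that("PON membership requires distinct supporting subjects", {
  normals <- tibble::tibble(
    subject_id = c("A", "B", "A", "A", "C"),
    chrom = "1",
    pos = c(100L, 100L, 200L, 200L, 300L),
    ref = "A", alt = "G"
  )
  pon <- build_pon(normals, min_support = 2)
  keys <- normalize_variant_key("1", c(100, 200, 300), "A", "G")
  # brute-force oracle: per key, the set of distinct subjects
  support <- vapply(keys, function(k) {
    kk <- normalize_variant_key(normals$chrom, normals$pos, normals$ref,
                                normals$alt)
    length(unique(normals$subject_id[kk == k]))
  }, numeric(1))
  expect_equal(unname(pon_member(pon, keys)), unname(support >= 2))
  expect_true(pon_member(pon, keys[1]))    # subjects A and B
  expect_false(pon_member(pon, keys[2]))   # A only, duplicate records
  expect_equal(pon$n_subjects[pon$key == keys[2]], 1L)
  expect_false(pon_member(pon, keys[3]))   # single subject
})

test_that("an empty normal set yields an empty panel, not an error", {
  pon <- build_pon(tibble::tibble())
  expect_equal(nrow(pon), 0)
  expect_false(pon_member(pon, "1:1:A>T"))
})

test_that("strongest consequence picks severity then smallest transcript", {
  expect_equal(
    strongest_consequence(tibble::tibble(
      transcript_id = c("T1", "T2"),
      consequence = c("intronic", "missense")))$transcript_id, "T2")
  one <- strongest_consequence(tibble::tibble(
    transcript_id = "T1", consequence = "missense"))
  expect_equal(one$consequence, "missense")
  tie <- strongest_consequence(tibble::tibble(
    transcript_id = c("T2", "T1"), consequence = c("missense", "missense")))
  expect_equal(tie$transcript_id, "T1")
  expect_error(strongest_consequence(tibble::tibble(
    transcript_id = "T1", consequence = "bogus")), "bogus")
})

test_that("cosmic rescue semantics match truth-table enumeration", {
  cfg_on <- filter_config(steps = c("population_af", "dbsnp_common"),
                          cosmic_rescue = TRUE)
  cfg_off <- filter_config(steps = c("population_af", "dbsnp_common"),
                           cosmic_rescue = FALSE)
  grid <- expand.grid(pop_af = c(0.0001, 0.01, NA), dbsnp = c(TRUE, FALSE),
                      cosmic = c(TRUE, FALSE))
  v <- tibble::tibble(
    chrom = "1", pos = seq_len(nrow(grid)) + 10L, ref = "A", alt = "T",
    pop_af = grid$pop_af, dbsnp_common = grid$dbsnp, in_cosmic = grid$cosmic
  )
  res_on <- apply_filter_hierarchy(v, cfg_on)
  res_off <- apply_filter_hierarchy(v, cfg_off)
  # independent truth table for the two-step chain
  keep_off <- (is.na(grid$pop_af) | grid$pop_af <= 0.001) & !grid$dbsnp
  keep_on <- keep_off | grid$cosmic
  expect_equal(v$pos %in% res_on$called$pos, keep_on)
  expect_equal(v$pos %in% res_off$called$pos, keep_off)
  # toggling the rescue only ever adds back COSMIC variants
  added <- setdiff(res_on$called$pos, res_off$called$pos)
  expect_true(all(v$in_cosmic[v$pos %in% added]))
})

test_that("a first-step rejection leaves a trail of length one", {
  v <- tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "T",
                      caller_pass = FALSE)
  res <- apply_filter_hierarchy(v, filter_config())
  expect_equal(unname(res$trail[1, "caller_pass"]), FALSE)
  expect_true(all(is.na(res$trail[1, -1])))
  expect_equal(nrow(res$called), 0)
})

test_that("retention is monotone, order-invariant, and the trail replays", {
  co <- quiet(simulate_cohort(small_config(seed = 4)))
  pon <- build_pon(co$normals)
  res <- apply_filter_hierarchy(co$variants, filter_config(), pon)
  expect_true(all(res$retention$n_out <= res$retention$n_in))
  expect_true(all(diff(res$retention$pct_remaining) <= 1e-12))
  # input order must not matter
  shuffled <- co$variants[sample.int(nrow(co$variants)), ]
  res2 <- apply_filter_hierarchy(shuffled, filter_config(), pon)
  expect_setequal(res$called$key, res2$called$key)
  # replaying recorded verdicts reproduces the called set exactly
  replayed <- replay_filter_trail(res)
  expect_equal(replayed$key, res$called$key)
})

test_that("artifacts supported by two or more normals are always removed", {
  co <- quiet(simulate_cohort(small_config(seed = 5)))
  pon <- build_pon(co$normals)
  res <- apply_filter_hierarchy(co$variants, filter_config(), pon)
  art_keys <- unique(add_variant_key(
    co$variants[co$variants$truth == "artifact", ])$key)
  supported <- art_keys[pon_member(pon, art_keys)]
  expect_gt(length(supported), 0)
  expect_false(any(supported %in% res$called$key))
})

test_that("empty input returns empty outputs with a zero-row retention table", {
  res <- apply_filter_hierarchy(tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character()), filter_config())
  expect_equal(nrow(res$called), 0)
  expect_equal(nrow(res$retention), 0)
})

test_that("unpaired samples can face a stricter VAF floor", {
  v <- tibble::tibble(chrom = "1", pos = c(1L, 2L), ref = "A", alt = "T",
                      vaf = 0.07, paired_normal = c(TRUE, FALSE))
  cfg <- filter_config(steps = "min_vaf", unpaired_strict = TRUE)
  res <- apply_filter_hierarchy(v, cfg)
  expect_equal(res$called$pos, 1L)
})
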