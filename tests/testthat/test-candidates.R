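pat <- function(target, upper, lower, a1, b2, c3) {
  data.table::data.table(target_sab = target, upper_sab = upper,
                         lower_sab = lower, a1 = a1, b2 = b2, c3 = c3)
}

test_that("Data Set 1 merges source permutations sharing the concept triple", {
  # the published merge case: same target and concept triple reached via
  # two different (upper, lower) permutations counts once
  p <- rbind(
    pat("SNOMEDCT_US", "NCI", "MEDCIN", "C0035412", "C0206631", "C0909793"),
    pat("SNOMEDCT_US", "HPO", "MEDCIN", "C0035412", "C0206631", "C0909793"),
    pat("HPO", "NCI", "SNOMEDCT_US", "C0000010", "C0000020", "C0000030"))
  ds1 <- build_dataset1(p)
  expect_equal(nrow(ds1), 2L)
  merged <- ds1[ds1$a1 == "C0035412", ]
  expect_equal(merged$n_sources, 2L)
  expect_equal(merged$sources, "HPO/MEDCIN;NCI/MEDCIN")
})

test_that("Data Set 1 count: duplicate groups shrink patterns to candidates", {
  # five patterns containing exactly two duplicated groups -> three candidates
  p <- rbind(
    pat("A", "B", "C", "C0000001", "C0000002", "C0000003"),
    pat("A", "C", "B", "C0000001", "C0000002", "C0000003"),
    pat("A", "B", "C", "C0000004", "C0000005", "C0000006"),
    pat("A", "C", "B", "C0000004", "C0000005", "C0000006"),
    pat("B", "A", "C", "C0000007", "C0000008", "C0000009"))
  ds1 <- build_dataset1(p)
  expect_equal(nrow(ds1), 3L)
  expect_true(nrow(ds1) <= nrow(p))
  expect_equal(nrow(build_dataset1(p[0L])), 0L)
})

test_that("Data Set 1 deduplication is idempotent and bounded", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 20,
                                      n_planted_ladders = 2, seed = 5))
  loaded <- load_fixture(fx)
  p <- detect_fire_ladders(loaded$dags)
  ds1 <- build_dataset1(p)
  expect_true(nrow(ds1) <= nrow(p))
  expect_identical(as.data.frame(build_dataset1(rbind(p, p))),
                   as.data.frame(ds1))
})

test_that("anchored Data Set 2 admits sibling C3s under a pattern stem", {
  # one b2 with two qualifying children in the lower source, only one of
  # which closes a full ladder (the published reticulospinal-tract case
  # shape: one stem, several C3 positions)
  a1 <- "C0000001"; b2 <- "C0000002"; c3a <- "C0000003"; c3b <- "C0000004"
  atoms <- rbind(
    mk_atoms(c(a1, c3a), "TGT"), mk_atoms(c(a1, b2), "UPR"),
    mk_atoms(c(b2, c3a, c3b), "LWR"))
  rels <- rbind(
    mk_rels(b2, a1, "UPR"),
    mk_rels(c(c3a, c3b), b2, "LWR"),
    mk_rels(c3a, a1, "TGT"))
  dags <- mk_dags(atoms, rels, c("TGT", "UPR", "LWR"))
  p <- detect_fire_ladders(dags)
  expect_equal(nrow(p), 1L)

  strict <- build_dataset2(dags, p, mode = "strict")
  anchored <- build_dataset2(dags, p, mode = "anchored")
  expect_equal(nrow(strict), 1L)
  expect_equal(nrow(anchored), 2L)
  expect_equal(sort(anchored$c3), c(c3a, c3b))
  expect_equal(anchored$anchor_a1, rep(a1, 2L))

  expect_equal(nrow(build_dataset2(dags, p[0L])), 0L)
  expect_error(build_dataset2(dags, p, mode = "loose"))
})

test_that("strict Data Set 2 equals the pattern projection and is a subset of anchored", {
  for (seed in c(2, 9, 17)) {
    fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 20,
                                        n_planted_ladders = 2,
                                        n_decoys = seed %% 3, seed = seed))
    loaded <- load_fixture(fx)
    p <- detect_fire_ladders(loaded$dags)
    strict <- build_dataset2(loaded$dags, p, mode = "strict")
    proj <- unique(p[, c("upper_sab", "lower_sab", "b2", "c3")])
    data.table::setorder(proj, upper_sab, lower_sab, b2, c3)
    expect_identical(as.data.frame(strict[, 1:4]), as.data.frame(proj))

    anchored <- build_dataset2(loaded$dags, p, mode = "anchored")
    key <- function(x) do.call(paste, x[, 1:4])
    expect_true(all(key(strict) %in% key(anchored)))
  }
})

test_that("triple summaries pool permutations and conserve the total", {
  p <- rbind(
    pat("A", "B", "C", "C0000001", "C0000002", "C0000003"),
    pat("A", "C", "B", "C0000004", "C0000005", "C0000006"))
  s <- summarize_by_triple(p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$sab_set, "A,B,C")
  expect_equal(s$pattern_count, 2L)
  expect_equal(nrow(summarize_by_triple(p[0L])), 0L)

  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 20,
                                      n_planted_ladders = 2, seed = 13))
  loaded <- load_fixture(fx)
  det <- detect_fire_ladders(loaded$dags)
  expect_equal(sum(summarize_by_triple(det)$pattern_count), nrow(det))
})
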