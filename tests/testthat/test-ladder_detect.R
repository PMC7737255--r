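test_that("enumerate_triples lists ordered 3-permutations in input order", {
  t3 <- enumerate_triples(c("A", "B", "C"))
  expect_equal(nrow(t3), 6L)
  expect_equal(t3$target, c("A", "A", "B", "B", "C", "C"))
  expect_equal(t3$upper, c("B", "C", "A", "C", "A", "B"))
  expect_equal(t3$lower, c("C", "B", "C", "A", "B", "A"))

  expect_equal(nrow(enumerate_triples(paste0("S", 1:4))), 24L)
  expect_error(enumerate_triples(c("A", "B")), "at least 3")
  expect_error(enumerate_triples(c("A", "B", "B")), "duplicates")
})

test_that("the worked-example fixture yields exactly its one pattern", {
  fx <- fig3_fixture()
  loaded <- load_fixture(fx)
  p <- detect_fire_ladders(loaded$dags)
  expect_equal(nrow(p), 1L)
  expect_equal(p$target_sab, "HPO")
  expect_equal(p$upper_sab, "NCI")
  expect_equal(p$lower_sab, "SNOMEDCT_US")
  expect_equal(p$b2, "C0345203")

  ann <- annotate_patterns(p, loaded$atoms)
  expect_equal(ann$a1_name, "Intestinal atresia")
  expect_equal(ann$b2_name, "Large Intestine Atresia")
  expect_equal(ann$c3_name, "Congenital atresia of rectum")

  expect_identical(as.data.frame(brute_force_ladders(loaded$dags)),
                   as.data.frame(p))
})

test_that("giving b2 an atom in the target kills the pattern, never adds one", {
  fx <- fig3_fixture()
  loaded <- load_fixture(fx)
  base <- detect_fire_ladders(loaded$dags)
  expect_equal(nrow(base), 1L)

  atoms2 <- rbind(loaded$atoms,
                  mk_atoms(base$b2, base$target_sab))
  dags2 <- build_ontdag(atoms2, loaded$rels, fx$config)
  after <- detect_fire_ladders(dags2)
  expect_equal(nrow(after), 0L)  # constraint 5 violated
  # monotone containment: adding presence can only remove patterns
  expect_true(all(
    do.call(paste, after) %in% do.call(paste, base)))
})

test_that("every detected pattern passes an independent constraint re-check", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 25,
                                      n_planted_ladders = 3, n_decoys = 4,
                                      n_cycles = 1, seed = 11))
  loaded <- load_fixture(fx)
  p <- detect_fire_ladders(loaded$dags)
  expect_true(nrow(p) >= 3L)
  for (i in seq_len(nrow(p))) {
    cc <- check_ladder_constraints(loaded$dags, p$target_sab[i], p$upper_sab[i],
                                   p$lower_sab[i], p$a1[i], p$b2[i], p$c3[i])
    expect_true(all(cc))
  }
})

test_that("consistent SAB relabeling relabels the output", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 20,
                                      n_planted_ladders = 2, seed = 3))
  loaded <- load_fixture(fx)
  p <- detect_fire_ladders(loaded$dags)

  map <- c(AAA = "ZZZ", BBB = "YYY", CCC = "XXX")
  atoms2 <- data.table::copy(loaded$atoms)[, sab := map[sab]]
  rels2 <- data.table::copy(loaded$rels)[, sab := map[sab]]
  dags2 <- suppressWarnings(mk_dags(atoms2, rels2, unname(map)))
  p2 <- detect_fire_ladders(dags2)

  relabeled <- data.table::copy(p)[, `:=`(
    target_sab = unname(map[target_sab]),
    upper_sab = unname(map[upper_sab]),
    lower_sab = unname(map[lower_sab]))]
  data.table::setorder(relabeled, target_sab, upper_sab, lower_sab, a1, b2, c3)
  expect_identical(as.data.frame(p2), as.data.frame(relabeled))
})

test_that("triples naming an unknown SAB are rejected", {
  fx <- fig3_fixture()
  dags <- load_fixture(fx)$dags
  bad <- data.table::data.table(target = "HPO", upper = "NCI", lower = "LNC")
  expect_error(detect_fire_ladders(dags, bad), "LNC")
  expect_error(brute_force_ladders(dags, bad), "LNC")
})

test_that("detector and brute-force oracle agree on random fixtures", {
  for (seed in 1:10) {
    fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 20,
                                        n_planted_ladders = seed %% 3,
                                        n_decoys = seed %% 4,
                                        n_cycles = seed %% 2, seed = seed))
    loaded <- load_fixture(fx)
    p <- detect_fire_ladders(loaded$dags)
    b <- brute_force_ladders(loaded$dags)
    expect_identical(as.data.frame(p), as.data.frame(b))
  }
})
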