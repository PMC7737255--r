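test_that("identical specs produce byte-identical fixtures", {
  spec <- fixture_spec(c("AAA", "BBB", "CCC"), 25, n_planted_ladders = 2,
                       n_decoys = 3, n_cycles = 1, seed = 7)
  f1 <- generate_fixture(spec)
  f2 <- generate_fixture(spec)
  expect_identical(readLines(f1$mrconso), readLines(f2$mrconso))
  expect_identical(readLines(f1$mrrel), readLines(f2$mrrel))

  f3 <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 25, 2, 3, 1,
                                      seed = 8))
  expect_false(identical(readLines(f1$mrrel), readLines(f3$mrrel)))
})

test_that("planted ladders are recovered exactly", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 30,
                                      n_planted_ladders = 2, seed = 7))
  loaded <- load_fixture(fx)
  p <- detect_fire_ladders(loaded$dags)
  expect_equal(nrow(p), 2L)
  expect_identical(as.data.frame(p), as.data.frame(fx$truth$planted_patterns))
  expect_identical(as.data.frame(brute_force_ladders(loaded$dags)),
                   as.data.frame(p))
})

test_that("each decoy violates exactly its named constraint and none detect", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 30,
                                      n_decoys = 9, seed = 7))
  loaded <- load_fixture(fx)
  expect_equal(nrow(detect_fire_ladders(loaded$dags)), 0L)
  expect_equal(nrow(brute_force_ladders(loaded$dags)), 0L)

  d <- fx$truth$decoys
  expect_equal(d$constraint, 1:9)
  for (i in seq_len(nrow(d))) {
    cc <- check_ladder_constraints(loaded$dags, d$target_sab[i],
                                   d$upper_sab[i], d$lower_sab[i],
                                   d$a1[i], d$b2[i], d$c3[i])
    expect_equal(which(!cc), d$constraint[i], ignore_attr = TRUE)
  }
})

test_that("chaff rows exist in the files and are filtered on read", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 10, seed = 3))
  raw_conso <- readLines(fx$mrconso)
  raw_rel <- readLines(fx$mrrel)
  expect_true(any(grepl("|FRE|", raw_conso, fixed = TRUE)))
  expect_true(any(grepl("|O|", raw_conso, fixed = TRUE)))
  expect_true(any(grepl("|O|", raw_rel, fixed = TRUE)))

  loaded <- load_fixture(fx)
  expect_false(any(loaded$atoms$lat != "ENG"))
  expect_false(any(loaded$atoms$suppress != "N"))
  # a background CUI is shared into a second SAB (atom without edges)
  shared <- loaded$atoms[, .(n_sabs = length(unique(sab))), by = cui]
  expect_true(any(shared$n_sabs >= 2L))
})

test_that("fixtures round-trip through the readers exactly", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 20,
                                      n_planted_ladders = 1, n_decoys = 2,
                                      n_cycles = 1, seed = 21))
  loaded <- load_fixture(fx)
  expect_identical(as.data.frame(loaded$atoms), as.data.frame(fx$truth$atoms))
  expect_identical(as.data.frame(loaded$rels), as.data.frame(fx$truth$rels))
})

test_that("every planted cycle is broken and the audit trail names it", {
  fx <- generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 15,
                                      n_cycles = 3, seed = 2))
  loaded <- load_fixture(fx)
  removed <- loaded$dags$removed
  cyc <- fx$truth$cycle_edges
  cyc_key <- paste(cyc$sab, cyc$child, cyc$parent)
  rem_key <- paste(removed$sab, removed$child, removed$parent)
  expect_true(all(rem_key %in% cyc_key))  # only planted edges get removed
  # at least one edge removed from each planted cycle's SAB component
  for (s in unique(cyc$sab)) {
    expect_true(any(removed$sab == s))
    expect_true(is_acyclic_oracle(loaded$dags$graphs[[s]]))
  }
})

test_that("infeasible concept budgets are rejected", {
  expect_error(generate_fixture(fixture_spec(c("AAA", "BBB", "CCC"), 4,
                                             n_planted_ladders = 2,
                                             n_decoys = 5, seed = 1)),
               "infeasible")
})

test_that("the worked-example fixture encodes the printed concepts", {
  fx <- fig3_fixture()
  loaded <- load_fixture(fx)
  atoms <- loaded$atoms
  expect_true("C0266190" %in% atoms$cui)  # Colonic atresia
  expect_true("C0345203" %in% atoms$cui)  # Large intestinal atresia
  # the two are distinct concepts even though one is a synonym string of
  # the other in the source vocabulary
  expect_false(any(atoms$cui[atoms$str_name == "Colonic atresia"] == "C0345203"))
  expect_setequal(
    atoms$code[atoms$sab == "HPO"], c("HP:0011100", "HP:0025023", "HP:0010448"))
  expect_setequal(
    atoms$code[atoms$sab == "SNOMEDCT_US"], c("204711007", "91375006"))
  expect_setequal(atoms$code[atoms$sab == "NCI"], c("C84790", "C98827"))

  p <- detect_fire_ladders(loaded$dags)
  expect_identical(as.data.frame(p), as.data.frame(fx$truth$planted_patterns))
})
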