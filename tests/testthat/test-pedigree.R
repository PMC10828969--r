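test_that("family clusters are connected components of parent sharing", {
  rec <- make_records(c("A", "B"), c("M1", "M1"), c("F1", "F1"))
  cl <- sibling_clusters(rec)
  expect_equal(nrow(cl), 2)
  expect_equal(unique(cl$kind), "full_only")

  # transitive closure through the shared mother
  rec <- make_records(c("A", "B", "C"), c("M1", "M1", "M1"),
                      c("F1", "F1", "F2"))
  cl <- sibling_clusters(rec)
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(unique(cl$kind), "mixed")
  expect_setequal(cl$person_id, c("A", "B", "C"))

  # unrelated children form no clusters
  rec <- make_records(paste0("U", 1:4), paste0("M", 1:4), paste0("F", 1:4))
  expect_equal(nrow(sibling_clusters(rec)), 0)

  bad <- make_records("A", "A", "F1")
  expect_error(sibling_clusters(bad), "own parent")
})

test_that("pair relationships classify by shared parents", {
  a <- list(mother_id = "M1", father_id = "F1")
  expect_equal(classify_pair(a, list(mother_id = "M1", father_id = "F1")),
               "full")
  expect_equal(classify_pair(a, list(mother_id = "M2", father_id = "F1")),
               "paternal_half")
  expect_equal(classify_pair(a, list(mother_id = "M1", father_id = "F2")),
               "maternal_half")
  expect_error(classify_pair(a, list(mother_id = "M9", father_id = "F9")),
               "not siblings")
})

test_that("a two-member full cluster always yields that pair", {
  rec <- make_records(c("A", "B"), c("M1", "M1"), c("F1", "F1"))
  cl <- sibling_clusters(rec)
  for (s in c(1, 2, 77)) {
    pr <- select_study_pairs(cl, rec, seed = s)
    expect_equal(nrow(pr), 1)
    expect_setequal(c(pr$index_id, pr$sibling_id), c("A", "B"))
    expect_equal(pr$relationship, "full")
    expect_equal(pr$k_additive, 0.5)
    expect_equal(pr$k_shared_env, 1)
  }
})

test_that("paternal priority holds on every RNG branch of a mixed trio", {
  # A, B full siblings; C a paternal half-sibling of both: whichever index
  # is drawn, a paternal half-sib partner exists, so no full or maternal
  # pair can ever be returned
  rec <- make_records(c("A", "B", "C"), c("M1", "M1", "M2"),
                      c("F1", "F1", "F1"))
  cl <- sibling_clusters(rec)
  idx_seen <- character()
  for (s in 1:120) {
    pr <- select_study_pairs(cl, rec, seed = s)
    expect_equal(nrow(pr), 1)
    expect_equal(pr$relationship, "paternal_half")
    idx_seen <- union(idx_seen, pr$index_id)
  }
  expect_setequal(idx_seen, c("A", "B", "C"))
})

test_that("selection returns one vertex-disjoint pair per cluster", {
  reg <- simulate_registry(simulation_params(n_clusters = 3000,
                                             baseline_prevalence = 0.05,
                                             seed = 12))
  cl <- sibling_clusters(reg)
  pr <- select_study_pairs(cl, reg, seed = 13)
  expect_equal(nrow(pr), length(unique(cl$cluster_id)))
  members <- c(pr$index_id, pr$sibling_id)
  expect_equal(anyDuplicated(members), 0)
  # mixed clusters never produce full pairs; full-only never half pairs
  kind <- cl$kind[match(pr$index_id, cl$person_id)]
  expect_true(all(pr$relationship[kind == "full_only"] == "full"))
  expect_true(all(pr$relationship[kind == "mixed"] != "full"))
})

test_that("a thousand full trios give a thousand disjoint full pairs", {
  n <- 1000
  rec <- make_records(paste0("P", 1:(3 * n)),
                      rep(paste0("M", 1:n), each = 3),
                      rep(paste0("F", 1:n), each = 3))
  cl <- sibling_clusters(rec)
  pr <- select_study_pairs(cl, rec, seed = 4)
  expect_equal(nrow(pr), n)
  expect_true(all(pr$relationship == "full"))
  expect_equal(length(unique(c(pr$index_id, pr$sibling_id))), 2 * n)
})

test_that("twin partners are excluded from selection", {
  rec <- make_records(c("A", "B"), c("M1", "M1"), c("F1", "F1"),
                      birth_year = c(1980, 1980), is_twin = c(FALSE, TRUE))
  cl <- sibling_clusters(rec)
  expect_equal(nrow(select_study_pairs(cl, rec, seed = 1)), 0)
  # a twin-flagged sibling born in a different year is an ordinary sibling
  rec$birth_year <- c(1980, 1983)
  expect_equal(nrow(select_study_pairs(cl, rec, seed = 1)), 1)
})

test_that("selection is deterministic given seed and input order", {
  reg <- simulate_registry(simulation_params(n_clusters = 400,
                                             baseline_prevalence = 0.05,
                                             seed = 20))
  cl <- sibling_clusters(reg)
  expect_identical(select_study_pairs(cl, reg, seed = 5),
                   select_study_pairs(cl, reg, seed = 5))
})
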