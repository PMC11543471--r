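toy_family <- function(values, ids = sprintf("c%d", seq_along(values))) {
  candidate_family(
    "toy", tibble::tibble(candidate_id = ids, smiles = NA_character_),
    descriptors = tibble::tibble(id = ids, d1 = values))
}

test_that("clustering selector picks the centroid-nearest candidate", {
  # 1-D brute force: values {0, 1, 10}, centroid 11/3, nearest is 1
  fam <- toy_family(c(0, 1, 10))
  sel <- select_by_clustering(fam)
  expect_equal(sel$chosen_id, "c2")
  sc <- sel$scores[[1]]
  expect_equal(unname(sc), abs(c(0, 1, 10) - 11 / 3), tolerance = 1e-12)
  expect_false(sel$tie)

  # singleton family
  single <- candidate_family("s", tibble::tibble(candidate_id = "only",
                                                 smiles = NA_character_))
  expect_equal(select_by_clustering(single)$chosen_id, "only")

  # identical candidates tie and resolve by order
  same <- toy_family(c(2, 2, 2))
  sel3 <- select_by_clustering(same)
  expect_equal(sel3$chosen_id, "c1")
  expect_true(sel3$tie)

  expect_error(select_by_clustering(fam, k = 5), class = "sfelip_error_bad_k")
})

test_that("k > 1 clustering targets the largest cluster", {
  # two tight clusters, sizes 3 vs 2: representative comes from the triple
  fam <- toy_family(c(0, 0.1, -0.1, 10, 10.1))
  sel <- select_by_clustering(fam, k = 2)
  expect_true(sel$chosen_id %in% c("c1", "c2", "c3"))
  expect_equal(sel$chosen_id, "c1")  # centroid 0, nearest is the exact 0
})

test_that("Tanimoto scores follow the set definition and its properties", {
  # bit-set definition: A={1,2,3}, B={2,3,4} -> 2/4
  bits <- rbind(A = c(1, 1, 1, 0), B = c(0, 1, 1, 1))
  tm <- tanimoto_matrix(bits)
  expect_equal(tm["A", "B"], 0.5)
  expect_equal(diag(tm), c(A = 1, B = 1))

  # identical structures
  fam <- candidate_family("x", tibble::tibble(
    candidate_id = c("a", "b"),
    smiles = rep("CCCCCCCC(=O)OCC(O)CO", 2)))
  res <- rank_by_tanimoto(fam)
  expect_equal(min(attr(res, "tanimoto")), 1)
  expect_true(res$tie)

  # property: symmetric, unit diagonal, [0, 1] on generated families
  for (s in 1:5) {
    f <- positional_isomer_family("glycerophospholipids", 32 + 2 * s,
                                  1 + s %% 3, 4, seed = s)
    r <- rank_by_tanimoto(candidate_family(f$shorthand[1], f))
    tm <- attr(r, "tanimoto")
    expect_equal(tm, t(tm))
    expect_equal(unname(diag(tm)), rep(1, nrow(tm)))
    expect_true(all(tm >= 0 & tm <= 1))
  }
})

test_that("IDAC concordance ranking minimises squared error to the mean curve", {
  ids <- c("a", "b", "c")
  fam <- candidate_family("f", tibble::tibble(candidate_id = ids,
                                              smiles = NA_character_))
  base <- seq(0, 1, length.out = 11)
  delta <- 0.3
  curves <- rbind(base, base, base + delta)
  sel <- rank_by_idac(fam, curves)
  expect_equal(sel$chosen_id, "a")
  expect_true(sel$tie)   # two identical curves share the minimum
  sc <- sel$scores[[1]]
  m <- length(base)
  expect_equal(unname(sc), c((delta / 3)^2 * m, (delta / 3)^2 * m,
                             (2 * delta / 3)^2 * m), tolerance = 1e-12)

  same <- rank_by_idac(fam, rbind(base, base, base))
  expect_equal(same$chosen_id, "a")
  single <- candidate_family("s", tibble::tibble(candidate_id = "z",
                                                 smiles = NA_character_))
  expect_equal(rank_by_idac(single)$chosen_id, "z")
  expect_error(rank_by_idac(fam, curves[1:2, ]),
               class = "sfelip_error_misaligned")
})

test_that("selectors are permutation-equivariant up to the order tie-break", {
  vals <- c(0.4, -1.2, 3.1, 0.9)
  fam <- toy_family(vals)
  ref <- select_by_clustering(fam)$chosen_id
  perm <- c(3, 1, 4, 2)
  fam_p <- toy_family(vals[perm], ids = sprintf("c%d", seq_along(vals))[perm])
  expect_equal(select_by_clustering(fam_p)$chosen_id, ref)

  f <- positional_isomer_family("glycerolipids", 36, 2, 4, seed = 11)
  ref_t <- rank_by_tanimoto(candidate_family("g", f))
  if (!ref_t$tie) {
    fp <- f[rev(seq_len(nrow(f))), ]
    perm_t <- rank_by_tanimoto(candidate_family("g", fp))
    expect_equal(perm_t$chosen_id, ref_t$chosen_id)
  }
})

test_that("planted representatives are recovered from descriptor space", {
  hits <- vapply(1:50, function(s) {
    pf <- make_planted_family(n_candidates = 5, n_descriptors = 8, seed = s)
    select_by_clustering(pf$family)$chosen_id == pf$planted
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("selection comparison reports concordance", {
  mk <- function(method, chosen) {
    tibble::tibble(shorthand = sprintf("f%d", seq_along(chosen)),
                   method = method, chosen_id = chosen,
                   chosen_smiles = NA_character_, tie = FALSE,
                   scores = list(NULL))
  }
  full <- dplyr::bind_rows(mk("kmedoids", c("a", "b", "c")),
                           mk("tanimoto", c("a", "b", "c")))
  cmp <- compare_selections(full)
  expect_equal(attr(cmp, "concordance"), 1)
  one_off <- dplyr::bind_rows(
    mk("kmedoids", sprintf("x%d", 1:10)),
    mk("tanimoto", c(sprintf("x%d", 1:9), "zzz")))
  cmp2 <- compare_selections(one_off)
  expect_equal(attr(cmp2, "concordance"), 0.9)
  expect_equal(glance(cmp2)$concordance, 0.9)
  bad <- dplyr::bind_rows(mk("kmedoids", c("a", "b")),
                          mk("tanimoto", "a")[1, ])
  expect_error(compare_selections(bad),
               class = "sfelip_error_mismatched_families")
})
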