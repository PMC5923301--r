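test_that("compute_tpm matches the closed form and sums to 1e6", {
  expect_equal(compute_tpm(c(10, 10), c(100, 100)), c(500000, 500000))
  expect_equal(compute_tpm(c(10, 10), c(100, 200)),
               1e6 * c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(compute_tpm(c(0, 5), c(100, 100)), c(0, 1e6))
  expect_error(compute_tpm(c(0, 0), c(100, 100)), "zero")
  expect_error(compute_tpm(c(1, 1), c(100, 0)), "positive")
  expect_error(compute_tpm(c(-1, 1), c(1, 1)), "nonnegative")
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    counts <- rpois(n, 20)
    counts[1] <- counts[1] + 1   # guarantee a positive count
    tpm <- compute_tpm(counts, runif(n, 100, 3000))
    expect_equal(sum(tpm), 1e6, tolerance = 1e-6)
  }
})

test_that("presence calling applies the 5x-over-90% rule with its boundary", {
  expect_true(call_presence(rep(5L, 100)))
  # exactly 10% below threshold is not "more than 10%": still present
  expect_true(call_presence(c(rep(5L, 90), rep(4L, 10))))
  expect_false(call_presence(c(rep(5L, 89), rep(4L, 11))))
  expect_error(call_presence(integer()), "empty")
  expect_error(call_presence(c(1L, -1L)), "nonnegative")
})

test_that("presence calling is monotone in depth", {
  set.seed(7)
  for (i in 1:40) {
    d <- rpois(50, 5)
    before <- call_presence(d)
    d2 <- d
    j <- sample(50, 5)
    d2[j] <- d2[j] + sample(1:3, 5, replace = TRUE)
    after <- call_presence(d2)
    expect_true(!before || after)
  }
})

test_that("toxin counts per individual equal presence column sums", {
  pres <- scutulatus_presence()
  counts <- count_toxins_present(pres)
  expect_equal(unname(counts["CLP1930"]), 42)
  expect_equal(unname(counts["CLP2142"]), 69)
  all_true <- matrix(TRUE, 75, 4,
                     dimnames = list(paste0("t", 1:75), paste0("s", 1:4)))
  expect_true(all(count_toxins_present(all_true) == 75))
  set.seed(3)
  rnd <- matrix(runif(40) > 0.5, 10, 4,
                dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
  brute <- vapply(1:4, function(j) sum(rnd[, j]), numeric(1))
  expect_equal(unname(count_toxins_present(rnd)), brute)
})

test_that("presence patterns partition the toxins found somewhere", {
  pres <- scutulatus_presence()
  types <- scutulatus_types()
  cls <- classify_presence_patterns(pres, types)
  expect_length(cls$exclusive_A, 3)
  expect_length(cls$exclusive_B, 17)
  expect_length(cls$in_all, 33)
  expect_length(cls$shared_not_all, 22)
  expect_setequal(cls$exclusive_A, c("Pla2gA2-MTXA", "Pla2gB2-MTXB", "MYO-8"))
  expect_true(all(c("SVMPII-1", "CTL-3", "MYO-6") %in% cls$exclusive_B))

  all_true <- matrix(TRUE, 3, 4, dimnames = list(letters[1:3],
                                                 names(types)[1:4]))
  c2 <- classify_presence_patterns(all_true, types)
  expect_setequal(c2$in_all, letters[1:3])
  expect_length(c2$exclusive_A, 0)

  one <- matrix(c(TRUE, FALSE), 1, 2,
                dimnames = list("tox", c("a1", "b1")))
  c3 <- classify_presence_patterns(one, c(a1 = "A", b1 = "B"))
  expect_identical(c3$exclusive_A, "tox")
  expect_error(classify_presence_patterns(one, c(a1 = "A")), "unlabeled")

  set.seed(9)
  for (i in 1:20) {
    m <- matrix(runif(9 * 8) > 0.5, 8, 9,
                dimnames = list(paste0("t", 1:8), names(types)))
    cl <- classify_presence_patterns(m, types)
    ids <- unlist(cl)
    expect_false(any(duplicated(ids)))
    expect_setequal(ids, rownames(m)[rowSums(m) > 0])
  }
})

test_that("family composition reproduces the printed percentages", {
  tox <- scutulatus_toxins()
  fc <- family_composition(tox$expression, tox$catalog)
  pick <- function(fam, s) fc$percent_total[fc$family == fam & fc$sample_id == s]
  expect_equal(round(pick("MYO", "CLP1936"), 1), 60.4)
  expect_equal(round(pick("MYO", "CLP1835"), 1), 10.1)
  expect_equal(round(pick("CTL", "CLP1959"), 1), 10.2)
  expect_equal(round(pick("CTL", "CLP1961"), 1), 12.4)
  myo <- fc$percent_total[fc$family == "MYO"]
  expect_equal(round(range(myo), 1), c(1.0, 60.4))
  # per sample, family sums recover the toxin total and stay within 100%
  for (s in unique(fc$sample_id)) {
    sub <- fc[fc$sample_id == s, ]
    expect_equal(sum(sub$tpm_sum),
                 sum(unclass(tox$expression)[s, ]), tolerance = 1e-9)
    expect_lte(sum(sub$percent_total), 100 + 1e-9)
    expect_equal(sum(sub$percent_toxin), 100, tolerance = 1e-9)
  }
})

test_that("a one-family dataset is 100% of the toxin transcriptome", {
  expr <- random_tpm(2, 3, seed = 5)
  colnames(expr) <- paste0("MYO-", 1:3)
  cat1 <- transcript_catalog(colnames(expr))
  fc <- family_composition(expr, cat1)
  expect_true(all(fc$percent_toxin == 100))
  bad <- expression_matrix(unclass(expr), "tpm")
  colnames(bad)[1] <- "UNKNOWN-1"
  cat_missing <- transcript_catalog(colnames(expr)[-1])
  expect_error(family_composition(bad, cat_missing), "catalog")
})

test_that("family diversity counts the packaged catalog's 17 families", {
  div <- family_diversity(scutulatus_toxins()$catalog)
  expect_equal(attr(div, "n_families"), 17)
  get <- function(f) div$n_transcripts[div$family == f]
  expect_equal(get("CTL"), 23)
  expect_equal(get("SVSP"), 14)
  expect_equal(get("SVMPIII"), 10)
  expect_equal(get("MYO"), 8)
  expect_equal(get("PLA2"), 6)
  empty <- family_diversity(transcript_catalog(character()))
  expect_equal(nrow(empty), 0)
  two <- family_diversity(transcript_catalog(c("A-1", "B-1")))
  expect_equal(two$n_transcripts, c(1L, 1L))
})

test_that("reference-set profiling matches call_presence element-wise", {
  set.seed(13)
  ids <- paste0("PLA2-", 1:4)
  coverage <- lapply(1:3, function(s) {
    stats::setNames(lapply(ids, function(i) rpois(80, sample(3:8, 1))), ids)
  })
  names(coverage) <- paste0("S", 1:3)
  prof <- profile_reference_set(coverage, ids)
  for (s in names(coverage)) {
    for (i in ids) {
      expect_identical(prof[i, s], call_presence(coverage[[s]][[i]]))
    }
  }
  expect_error(profile_reference_set(coverage, c(ids, "missing")), "coverage")
})

test_that("depth tables parse to per-transcript vectors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx1\t1\t5", "tx1\t2\t6", "tx2\t1\t0"), path)
  cov <- read_depth_table(path)
  expect_equal(cov$tx1, c(5L, 6L))
  expect_equal(cov$tx2, 0L)
  writeLines(c("tx1\t1\t5", "tx1\t3\t6"), path)
  expect_error(read_depth_table(path), "position")
})
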