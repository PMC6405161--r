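test_that("reading a delimited matrix yields a validated connectome with default labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.5,0.2", "0.5,0,0", "0.2,0,0"), f)
  cn <- read_connectome(f)
  expect_s3_class(cn, "connectome")
  expect_equal(n_regions(cn), 3)
  expect_equal(cn$labels, c("R001", "R002", "R003"))
  expect_equal(cn$weights[1, 2], 0.5)

  # whitespace dialect and label sidecar
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 0"), f2)
  lf <- withr::local_tempfile()
  writeLines(c("lh-LOC", "lh-FuG"), lf)
  cn2 <- read_connectome(f2, lf)
  expect_equal(cn2$labels, c("lh-LOC", "lh-FuG"))
})

test_that("validation rejects malformed matrices with specific messages", {
  f <- withr::local_tempfile()
  writeLines(c("0,1,2,3", "1,0,2,3", "2,2,0,3"), f)  # 3x4
  expect_error(read_connectome(f), "non-square")

  w <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  expect_error(connectome(w), "negative entry -0.5 at \\[2, 1\\]")

  w <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(connectome(w, labels = c("a", "b", "c")), "label count")
  expect_error(connectome(matrix(c(0, Inf, Inf, 0), 2, 2)), "non-finite")
  expect_error(connectome(matrix(c(1, 0, 0, 0), 2, 2)), "diagonal")
})

test_that("asymmetric matrices beyond tolerance are symmetrized with a warning", {
  w <- matrix(c(0, 0.5, 0.6, 0), 2, 2)
  expect_warning(cn <- connectome(w), "symmetrizing")
  expect_equal(cn$weights[1, 2], 0.55)
  expect_equal(cn$weights, t(cn$weights))
})

test_that("normalization divides by the maximum, is idempotent, and rejects zero matrices", {
  w <- matrix(c(0, 5, 2, 5, 0, 0, 2, 0, 0), 3, 3)
  cn <- normalize_connectome(connectome(w))
  expect_equal(max(cn$weights), 1)
  expect_equal(cn$weights[1, 3], 0.4)
  expect_true(cn$normalized)
  # bit-for-bit idempotence
  expect_identical(normalize_connectome(cn)$weights, cn$weights)
  expect_error(normalize_connectome(connectome(matrix(0, 2, 2))), "all-zero")
})

test_that("edge removal zeroes exactly the symmetric pair and rejects bad indices", {
  w <- matrix(0, 6, 6)
  w[3, 6] <- w[6, 3] <- 0.7
  w[1, 2] <- w[2, 1] <- 0.7
  cn <- connectome(w)
  cn2 <- remove_edge(cn, 3, 6)
  expect_equal(cn2$weights[3, 6], 0)
  expect_equal(cn2$weights[6, 3], 0)
  expect_equal(cn2$weights[1, 2], 0.7)  # other 0.7 entry untouched
  # idempotent
  expect_identical(remove_edge(cn2, 3, 6)$weights, cn2$weights)
  expect_error(remove_edge(cn, 4, 4), "self-edge")
  expect_error(remove_edge(cn, 0, 2), "out of range")
  expect_error(remove_edge(cn, 1, 7), "out of range")
})

test_that("edge removal preserves symmetry and zero diagonal on random connectomes", {
  for (s in 1:5) {
    cn <- generate_modular(synth_params(n_nodes = 12, seed = s))
    e <- incident_edges(cn, seq_len(12))
    pick <- e[sample.int(nrow(e), 1), ]
    cn2 <- remove_edge(cn, pick$i, pick$j)
    expect_identical(cn2$weights, t(cn2$weights))
    expect_true(all(diag(cn2$weights) == 0))
  }
})

test_that("averaging takes the element-wise mean and renormalizes", {
  w1 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  w2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  avg <- average_connectomes(list(connectome(w1), connectome(w2)))
  # mean is 0.4, renormalized to max 1
  expect_equal(avg$weights[1, 2], 1)
  # mean before renormalization recoverable: 0.4 = (0.2 + 0.6)/2
  expect_equal((w1[1, 2] + w2[1, 2]) / 2, 0.4)

  cn <- generate_modular(synth_params(n_nodes = 8, seed = 2))
  same <- average_connectomes(list(cn, cn, cn))
  expect_equal(same$weights, normalize_connectome(cn)$weights, tolerance = 1e-15)

  big <- generate_modular(synth_params(n_nodes = 10, seed = 1))
  expect_error(average_connectomes(list(cn, big)), "size mismatch")
  expect_error(average_connectomes(list()), "non-empty")
})

test_that("writer/reader round-trip is exact at full precision", {
  cn <- generate_modular(synth_params(n_nodes = 9, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  lf <- withr::local_tempfile()
  write_connectome(cn, f, lf)
  back <- read_connectome(f, lf)
  expect_identical(back$weights, cn$weights)
  expect_identical(back$labels, cn$labels)
})

test_that("incident_edges sorts by descending weight with index tie-breaks", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.5
  w[1, 4] <- w[4, 1] <- 0.9
  w[3, 4] <- w[4, 3] <- 0.1
  cn <- connectome(w)
  e <- incident_edges(cn, 1)
  expect_equal(e$j, c(4, 2, 3))     # 0.9 first, then ties 2 before 3
  e2 <- incident_edges(cn, c(1, 4), exclusive = TRUE)
  # (1,4) has both endpoints inside and is excluded; (1,2),(1,3),(3,4) leave the set
  expect_equal(nrow(e2), 3)
  expect_equal(e2$weight, c(0.5, 0.5, 0.1))
})
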