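test_that("time-series reader handles delimiters, headers and shape", {
  d <- withr::local_tempdir()
  m <- matrix(round(rnorm(200 * 39), 4), 200, 39)

  f_csv <- file.path(d, "a.csv")
  utils::write.table(m, f_csv, sep = ",", row.names = FALSE, col.names = FALSE)
  ts <- read_time_series(f_csv, "a", tr = 2.0)
  expect_equal(dim(ts$values), c(200L, 39L))
  expect_equal(ts$values, m, ignore_attr = TRUE)

  # header row is auto-detected and stripped
  f_hdr <- file.path(d, "b.csv")
  utils::write.table(m, f_hdr, sep = ",", row.names = FALSE,
                     col.names = paste0("roi_", 1:39))
  ts2 <- read_time_series(f_hdr, "b", tr = 2.0)
  expect_equal(ts2$values, ts$values)

  # tab and whitespace delimiters are sniffed
  f_tsv <- file.path(d, "c.tsv")
  utils::write.table(m[1:10, 1:5], f_tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  expect_equal(dim(read_time_series(f_tsv, "c", 2)$values), c(10L, 5L))
  f_ws <- file.path(d, "d.txt")
  utils::write.table(m[1:10, 1:5], f_ws, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  expect_equal(read_time_series(f_ws, "d", 2)$values,
               read_time_series(f_tsv, "c", 2)$values)
})

test_that("time-series reader rejects bad input naming the location", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.csv")
  m <- matrix(1.5, 5, 4)
  m2 <- m; m2[3, 2] <- NaN
  utils::write.table(m2, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_time_series(f, "x", 2), "row 3, column 2")

  writeLines(c("1,2,3", "4,5", "6,7,8"), f)   # ragged
  expect_error(read_time_series(f, "x", 2))

  utils::write.table(m[1:2, ], f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_time_series(f, "x", 2), "timepoints")
  utils::write.table(m[, 1:2], f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_time_series(f, "x", 2), "ROIs")
  expect_error(subject_ts(matrix(1, 5, 5), "x", tr = 0), "tr")
})

test_that("vectorize uses the strict upper triangle, row-major", {
  w <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  v <- vectorize_matrix(conn_matrix(w, "s"))
  expect_equal(v$features, c(.1, .2, .3))
  expect_length(vectorize_matrix(complete_matrix(4))$features, 6L)
})

test_that("devectorize inverts vectorize bitwise", {
  v <- structure(list(subject_id = "s", features = c(.1, .2, .3), n_rois = 3L,
                      kind = "phase_interaction"), class = "edge_vector")
  m <- devectorize(v)
  expect_identical(m$weights,
                   matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3))
  expect_error(devectorize(rnorm(5), n_rois = 4), "N\\(N-1\\)/2")
  z <- devectorize(numeric(3), n_rois = 3)
  expect_identical(z$weights, diag(3))

  set.seed(42)
  for (n in c(3, 5, 9)) {
    m <- random_symmetric_matrix(n)
    expect_identical(devectorize(vectorize_matrix(m))$weights, m$weights)
  }
})

test_that("assemble_cohort joins by subject id, not position", {
  set.seed(1)
  vs <- lapply(c("s1", "s2", "s3"), function(id)
    vectorize_matrix(random_symmetric_matrix(3, id)))
  phen <- mini_phen(c("s1", "s2", "s3"), c("A", "A", "B"))
  co <- assemble_cohort(vs, phen)
  expect_s3_class(co, "conn_cohort")
  expect_equal(dim(co$features), c(3L, 3L))

  co_shuffled <- assemble_cohort(vs[c(3, 1, 2)], phen)
  expect_identical(co$features, co_shuffled$features)
  expect_identical(co$phenotypes, co_shuffled$phenotypes)

  expect_error(assemble_cohort(vs, mini_phen(c("s1", "s2", "zz"), c("A", "A", "B"))),
               "s3")
  vs4 <- c(vs[1:2], list(vectorize_matrix(random_symmetric_matrix(4, "s3"))))
  expect_error(assemble_cohort(vs4, phen), "Mixed ROI")
})

test_that("phenotype validation enforces mandatory columns and completeness", {
  expect_error(read_phenotypes(tempfile()), "not found")
  p <- mini_phen(c("a", "a"), c("A", "B"))
  expect_error(connharmony:::validate_phenotypes(p), "Duplicated")
  p2 <- mini_phen(c("a", "b"), c("A", "B"))
  p2$age[1] <- NA
  expect_error(connharmony:::validate_phenotypes(p2), "age")
  expect_warning(connharmony:::validate_phenotypes(
    tibble::tibble(subject_id = c("a", "b"), site = c("A", "B"))), "absent")
})

test_that("connectivity matrices persist as CSV with a JSON sidecar", {
  d <- withr::local_tempdir()
  set.seed(7)
  m <- random_symmetric_matrix(5, "subj-5")
  p <- file.path(d, "subj-5_conn.csv")
  write_conn_matrix(m, p)
  expect_true(file.exists(paste0(p, ".json")))
  m2 <- read_conn_matrix(p)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_identical(m2$subject_id, "subj-5")
  expect_identical(m2$kind, m$kind)
})

test_that("conn_matrix validates symmetry, diagonal and range", {
  w <- matrix(0.2, 4, 4); diag(w) <- 1
  w2 <- w; w2[1, 2] <- 0.9
  expect_error(conn_matrix(w2, "x"), "asymmetric")
  w3 <- w; diag(w3) <- 0.5
  expect_error(conn_matrix(w3, "x"), "diagonal")
  w4 <- w; w4[1, 2] <- w4[2, 1] <- 1.5
  expect_error(conn_matrix(w4, "x"), "-1, 1")
  expect_silent(conn_matrix(w4, "x", kind = "pearson", tol = 1e-10))
})
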