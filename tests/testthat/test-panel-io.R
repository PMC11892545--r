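test_that("the CSV round trip is lossless", {
  p <- small_panel()
  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  q <- read_panel(f)
  expect_equal(as.data.frame(p), as.data.frame(q))
  expect_s3_class(q, "perio_panel")
})

test_that("schema violations raise errors naming the columns", {
  p <- small_panel()
  f <- tempfile(fileext = ".csv")

  broken <- p; broken$X_2012 <- NULL
  write.csv(as.data.frame(broken), f, row.names = FALSE)
  expect_error(read_panel(f), "X_2012")

  broken <- p; broken$hist_extractions <- NULL
  write.csv(as.data.frame(broken), f, row.names = FALSE)
  expect_error(read_panel(f), "hist_extractions")

  # flip one event flag to break monotonicity
  broken <- as.data.frame(p)
  i <- which(broken$Y_2013 == 1 & broken$O_2014 == 1)[1]
  expect_false(is.na(i))
  broken$Y_2014[i] <- 0
  write.csv(broken, f, row.names = FALSE)
  expect_error(read_panel(f), "monotone")

  broken <- as.data.frame(p)
  broken$X_2011[2] <- "WEEKLY"
  write.csv(broken, f, row.names = FALSE)
  expect_error(read_panel(f), "X_2011")
})

test_that("panels convert to the estimator layout", {
  d <- as_lmtp_data(small_panel())
  expect_equal(d$tau, 3)
  expect_equal(nrow(d$X), 400)
  expect_equal(ncol(d$O), 4)
  expect_equal(d$Y[, 1], rep(0L, 400))
  expect_true(all(d$L[[1]]$income >= 0 & d$L[[1]]$income <= 1))
  # one-of-K education coding drops the reference level
  expect_true("educ_primary" %in% names(d$C))
  expect_false("educ_vocational" %in% names(d$C))
})
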