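test_that("read_fasta parses entries, normalizes case, rejects bad residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKV", ">p2", "mavl", "gw"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$sequence, "MKV")
  expect_equal(recs[[2]]$sequence, "MAVLGW")  # upper-cased, lines joined
  expect_null(recs[[1]]$labels)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_length(read_fasta(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">weird", "MK1V"), bad)
  expect_error(read_fasta(bad), "weird")
})

test_that("annotation records derive protein-level truth flags", {
  f <- withr::local_tempfile(fileext = ".ann")
  writeLines(c(">p1", "MKV", "SSN",
               ">p2", "MAV", "NTN",
               ">p3", "MAV", "NNN"), f)
  recs <- read_annotations(f)
  truth <- lapply(recs, sigunet:::record_truth)
  expect_true(truth[[1]]$is_sp)
  expect_false(truth[[1]]$is_tm)
  expect_false(truth[[2]]$is_sp)
  expect_true(truth[[2]]$is_tm)   # T within first 70, no S
  expect_false(truth[[3]]$is_sp)
  expect_false(truth[[3]]$is_tm)
})

test_that("a T beyond position 70 does not make a transmembrane negative", {
  rec <- protein_record("late", random_sequence(90),
                        labels = paste0(strrep("N", 75), strrep("T", 10),
                                        strrep("N", 5)))
  expect_false(sigunet:::record_truth(rec)$is_tm)
})

test_that("annotation parsing enforces the label contract", {
  f <- withr::local_tempfile(fileext = ".ann")
  writeLines(c(">p1", "MKV", "SS"), f)
  expect_error(read_annotations(f), "p1")

  f2 <- withr::local_tempfile(fileext = ".ann")
  writeLines(c(">p1", "MKV", "SSX"), f2)
  expect_error(read_annotations(f2), "label")
})

test_that("annotations round-trip byte-identically", {
  set.seed(31)
  recs <- generate_dataset(synthetic_spec(5, 4, 3, seed = 31))
  f <- withr::local_tempfile(fileext = ".ann")
  write_annotations(recs, f)
  back <- read_annotations(f)
  f2 <- withr::local_tempfile(fileext = ".ann")
  write_annotations(back, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_identical(vapply(back, `[[`, character(1), "sequence"),
                   vapply(recs, `[[`, character(1), "sequence"))
  expect_identical(vapply(back, `[[`, character(1), "labels"),
                   vapply(recs, `[[`, character(1), "labels"))
})

test_that("encode_sequence places one-hot rows in alphabetical columns", {
  x <- encode_sequence("M")
  expect_equal(dim(x), c(96L, 20L))
  expect_equal(which(x[1, ] == 1), c(M = 11L))  # 'M' in ACDEFGHIKLMNPQRSTVWY
  expect_equal(sum(x), 1)

  # ambiguity letter -> all-zero row
  x2 <- encode_sequence("MKVLAXW")
  expect_equal(sum(x2[6, ]), 0)
  expect_equal(rowSums(x2)[1:7], c(1, 1, 1, 1, 1, 0, 1),
               ignore_attr = TRUE)

  # residues beyond 96 are discarded
  long <- random_sequence(120)
  x3 <- encode_sequence(long)
  expect_equal(x3, encode_sequence(substr(long, 1, 96)))
})

test_that("encode_sequence row sums count exactly the standard residues", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:130, 1)
    chars <- sample(c(aa20, "X", "B", "Z", "U", "O"), n, TRUE,
                    prob = c(rep(1, 20), rep(0.3, 5)))
    seq <- paste(chars, collapse = "")
    x <- encode_sequence(seq)
    expect_true(all(rowSums(x) %in% c(0, 1)))
    n_std <- sum(chars[seq_len(min(n, 96))] %in% aa20)
    expect_equal(sum(x), n_std)
  }
})

test_that("encode_labels one-hot encodes with N padding", {
  rec <- protein_record("p", "MKV", labels = "STN")
  y <- encode_labels(rec)
  expect_equal(y[1, ], c(S = 1, T = 0, N = 0))
  expect_equal(y[2, ], c(S = 0, T = 1, N = 0))
  expect_equal(y[3, ], c(S = 0, T = 0, N = 1))
  expect_true(all(y[4:96, 3] == 1))      # padding is class N
  expect_true(all(rowSums(y) == 1))

  rec96 <- protein_record("q", random_sequence(96), labels = strrep("N", 96))
  expect_true(all(encode_labels(rec96)[, 3] == 1))
})

test_that("encode_labels rows sum to 1 for arbitrary valid input", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:130, 1)
    rec <- protein_record("r", random_sequence(n),
                          labels = paste(sample(c("S", "T", "N"), n, TRUE),
                                         collapse = ""))
    expect_true(all(rowSums(encode_labels(rec)) == 1))
  }
})

test_that("encoding errors are informative", {
  expect_error(encode_labels(protein_record("p", "MKV")), "labels")
  expect_error(protein_record("p", ""), "length")
})

test_that("encode_records carries ids, n_valid and truth flags", {
  recs <- list(protein_record("a", random_sequence(120),
                              labels = paste0("SSSS",
                                              strrep("N", 116))),
               protein_record("b", "MAV", labels = "NTN"))
  ss <- encode_records(recs)
  expect_equal(ss[[1]]$source_id, "a")
  expect_equal(ss[[1]]$n_valid, 96L)
  expect_equal(ss[[2]]$n_valid, 3L)
  expect_true(ss[[1]]$true_is_sp)
  expect_true(ss[[2]]$true_is_tm)
})
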