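test_that("cognate_matrix enforces its invariants", {
  st <- rbind(A = c(1L, 0L), B = c(0L, 1L))
  m <- cognate_matrix(st)
  expect_s3_class(m, "cognate_matrix")
  expect_equal(dim(m), c(2L, 2L))
  # all-zero column is unobservable
  expect_error(cognate_matrix(rbind(A = c(1L, 0L), B = c(1L, 0L))),
               "unobservable")
  expect_error(cognate_matrix(rbind(A = c(1L, 2L), B = c(1L, 0L))),
               "0, 1 or NA")
  st2 <- st; rownames(st2) <- c("A", "A")
  expect_error(cognate_matrix(st2), "unique")
})

test_that("NEXUS reader transcribes a small binary matrix directly", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=3 NCHAR=3;",
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX",
               "    tA 101", "    tB 011", "    tC 110",
               "  ;", "END;"), f)
  m <- read_nexus_binary(f)
  expect_equal(m$taxa, c("tA", "tB", "tC"))
  expect_equal(unname(rowSums(m$states)), c(2, 2, 2))
  expect_equal(unname(m$states["tA", ]), c(1L, 0L, 1L))
})

test_that("NEXUS write/read round-trip is lossless including missing marks", {
  fx <- make_fixture("tiny4")
  m <- fx$matrix
  m$states[2, 3] <- NA  # inject a missing entry
  m <- cognate_matrix(m$states, m$meaning_class)
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_binary(m, f)
  m2 <- read_nexus_binary(f)
  expect_equal(m2$taxa, m$taxa)
  expect_equal(unname(m2$states), unname(m$states))
  expect_equal(m2$meaning_class, m$meaning_class)
})

test_that("malformed NEXUS input fails with located errors", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "  MATRIX",
               "    tA 10A1", "  ;", "END;"), f)
  expect_error(read_nexus_binary(f), "line 4")
  writeLines(c("BEGIN DATA;", "MATRIX", "tA 101", ";", "END;"), f)
  expect_error(read_nexus_binary(f), "NEXUS header")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=2 NCHAR=5;", "  MATRIX",
               "    tA 101", "    tB 011", "  ;", "END;"), f)
  expect_error(read_nexus_binary(f), "NCHAR")
})

test_that("encode_cognate_sets builds one observable column per class", {
  enc <- encode_cognate_sets(list(
    dog = c(A = "I", B = "I", C = "II"),
    eye = c(A = "I", B = "II", C = NA)))
  expect_equal(ncol(enc$states), 4L)
  expect_equal(unname(enc$states[, 1]), c(1L, 1L, 0L))
  expect_equal(unname(enc$states[, 2]), c(0L, 0L, 1L))
  # C unscored for "eye": missing in both eye columns
  expect_true(all(is.na(enc$states["C", enc$meaning_class == "eye"])))
  expect_false(any(colSums(enc$states == 1L, na.rm = TRUE) == 0))

  # class counts (2,1,3) over 5 taxa -> 6 columns
  taxa <- LETTERS[1:5]
  asg <- list(
    m1 = setNames(c("a", "a", "a", "b", "b"), taxa),
    m2 = setNames(rep("u", 5), taxa),
    m3 = setNames(c("x", "x", "y", "y", "z"), taxa))
  expect_equal(ncol(encode_cognate_sets(asg)$states), 6L)

  # 200 universal meanings over 19 taxa -> 200 all-ones columns
  taxa19 <- sprintf("t%02d", 1:19)
  asg200 <- setNames(lapply(1:200, function(i) setNames(rep("u", 19), taxa19)),
                     sprintf("m%03d", 1:200))
  enc200 <- encode_cognate_sets(asg200)
  expect_equal(dim(enc200$states), c(19L, 200L))
  expect_true(all(enc200$states == 1L))
})

test_that("pairwise similarity counts shared cognates per meaning", {
  # 2 taxa, 4 meanings, sharing in 3 -> s = 0.75
  enc <- encode_cognate_sets(list(
    m1 = c(A = "x", B = "x"), m2 = c(A = "x", B = "x"),
    m3 = c(A = "x", B = "x"), m4 = c(A = "x", B = "y")))
  s <- cognate_similarity(enc)
  expect_equal(s$similarity["A", "B"], 0.75)
  expect_equal(s$distance["A", "B"], 0.25)

  # identical rows -> s = 1, d = 0
  m <- cognate_matrix(rbind(A = c(1L, 0L, 1L), B = c(1L, 0L, 1L),
                            C = c(0L, 1L, 1L)),
                      meaning_class = c("m1", "m1", "m2"))
  s2 <- cognate_similarity(m)
  expect_equal(s2$similarity["A", "B"], 1.0)
  expect_equal(s2$distance["A", "B"], 0.0)
})

test_that("4-taxon similarity equals the exhaustive per-meaning tally", {
  asg <- list(
    m1 = c(A = "x", B = "x", C = "y", D = "y"),
    m2 = c(A = "x", B = "y", C = "y", D = "x"),
    m3 = c(A = "x", B = "x", C = "x", D = "z"),
    m4 = c(A = "x", B = "y", C = "z", D = "w"),
    m5 = c(A = "x", B = "x", C = NA, D = "x"))
  enc <- encode_cognate_sets(asg)
  s <- cognate_similarity(enc)$similarity
  # oracle: direct per-pair tally over the assignment lists
  taxa <- LETTERS[1:4]
  for (i in 1:3) for (j in (i + 1):4) {
    shared <- 0; scored <- 0
    for (mn in asg) {
      if (is.na(mn[taxa[i]]) || is.na(mn[taxa[j]])) next
      scored <- scored + 1
      if (mn[taxa[i]] == mn[taxa[j]]) shared <- shared + 1
    }
    expect_equal(s[taxa[i], taxa[j]], shared / scored)
  }
})

test_that("similarity flags pairs with no jointly scored meaning", {
  st <- rbind(A = c(1L, NA), B = c(NA, 1L), C = c(1L, 1L))
  m <- cognate_matrix(st, meaning_class = c("m1", "m2"))
  s <- cognate_similarity(m)
  expect_false(s$defined["A", "B"])
  expect_true(is.na(s$similarity["A", "B"]))
  expect_true(s$defined["A", "C"])
})

test_that("similarity is invariant to column order and taxa relabeling", {
  fx <- make_fixture("tiny4")
  m <- fx$matrix
  s1 <- cognate_similarity(m)$similarity
  perm <- c(3, 1, 4, 2)
  m2 <- cognate_matrix(m$states[perm, rev(seq_len(ncol(m$states)))],
                       rev(m$meaning_class))
  s2 <- cognate_similarity(m2)$similarity
  expect_equal(s2[m$taxa, m$taxa], s1)
})

test_that("taxon coordinates round-trip and validate", {
  geo <- tibble::tibble(taxon = c("A", "B"), lat = c(43.1, 45.2),
                        lon = c(141.3, 142.0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxon_geo(geo, f)
  g2 <- read_taxon_geo(f)
  expect_equal(as.data.frame(g2), as.data.frame(geo))
  expect_error(write_taxon_geo(tibble::tibble(taxon = "A", lat = 91, lon = 0)),
               "latitude")
})
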