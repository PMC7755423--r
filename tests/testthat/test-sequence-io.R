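test_that("residue codes honour the published anchors and are bijective", {
  ab <- residueAlphabet()
  expect_identical(unname(ab[c("L", "H", "R")]), c(3L, 16L, 17L))
  expect_identical(unname(ab["X"]), 21L)
  expect_identical(encodeResidue(c("L", "H", "R", "X")),
                   c(3L, 16L, 17L, 21L))
  # bijective on the 20 standard residues
  std <- setdiff(names(ab), "X")
  expect_identical(decodeResidue(encodeResidue(std)), std)
  expect_identical(anyDuplicated(encodeResidue(std)), 0L)
  # non-standard letters collapse to 21; non-letters error
  expect_identical(encodeResidue("B"), 21L)
  expect_error(encodeResidue("1"), "non-alphabet")
})

test_that("center alignment pads floor-left, remainder right", {
  expect_identical(centerAlignSegment("CAR", 5),
                   c(0L, encodeResidue(c("C", "A", "R")), 0L))
  expect_identical(centerAlignSegment("CARD", 5),
                   c(encodeResidue(c("C", "A", "R", "D")), 0L))
  expect_identical(centerAlignSegment("", 3), c(0L, 0L, 0L))
  expect_error(centerAlignSegment("CARDS", 4, id = "ab1"), "ab1")
})

test_that("CSV reading normalises case and maps unknown letters to X", {
  rec <- makeRecords(3)
  rec$cdr3h <- c("cars", "CARB", "ARDY")
  path <- writeTempCsv(rec[, c("id", LOOPS, "reactivity_count", "source")])
  expect_warning(got <- readRepertoire(path), "mapped to X")
  expect_identical(got$cdr3h, c("CARS", "CARX", "ARDY"))
  expect_identical(nrow(got), 3L)
  expect_true(all(got$label == "unknown"))
  # schema remap
  rec2 <- makeRecords(2)
  names(rec2)[names(rec2) == "cdr3h"] <- "CDRH3_AA"
  p2 <- writeTempCsv(rec2[, c("id", setdiff(LOOPS, "cdr3h"), "CDRH3_AA")])
  got2 <- readRepertoire(p2, schema = c(cdr3h = "CDRH3_AA"))
  expect_identical(got2$cdr3h, rec2$CDRH3_AA)
  # missing column and empty file
  p3 <- writeTempCsv(rec[, c("id", setdiff(LOOPS, "cdr3h"))])
  expect_error(readRepertoire(p3), "cdr3h")
  p4 <- tempfile(fileext = ".csv")
  writeLines(paste(c("id", LOOPS), collapse = ","), p4)
  expect_error(readRepertoire(p4), "empty")
})

test_that("labeling schemes follow the two-or-more and 4-7/0 rules", {
  rec <- makeRecords(8, reactivity = 0:7)
  full <- assignPolyreactivityLabels(rec, "full")
  expect_identical(as.character(full$label),
                   c(rep("non_polyreactive", 2), rep("polyreactive", 6)))
  parsed <- assignPolyreactivityLabels(rec, "parsed")
  expect_identical(as.character(parsed$label),
                   c("non_polyreactive", rep("excluded", 3),
                     rep("polyreactive", 4)))
  # label partition: counts sum to N
  expect_identical(sum(table(parsed$label)), 8L)
  bad <- makeRecords(1, reactivity = 9L)
  expect_error(assignPolyreactivityLabels(bad, "full"), "0-7")
  na <- makeRecords(1); na$reactivity_count <- NA_integer_
  expect_error(assignPolyreactivityLabels(na, "full"), "set on every")
})

test_that("encoding layout arithmetic, auto widths and block order hold", {
  rec <- makeRecords(2, cdr1l = "AST", cdr2l = "GGS", cdr3l = "QQY",
                     cdr1h = "GFT", cdr2h = "ISS", cdr3h = "ARD")
  em <- encodeRepertoire(rec, bufferWidth = 1L)
  expect_identical(ncol(encodedValues(em)), 6L * 3L + 5L * 1L)
  # auto width = max observed per slot over all records
  rec2 <- makeRecords(2, cdr3h = c("ARDYGSSGYD", "ARDYGSSGYDAMDY"))
  em2 <- encodeRepertoire(rec2)
  expect_identical(
    unname(segmentSpans(matrixLayout(em2))["cdr3h", "end"] -
           segmentSpans(matrixLayout(em2))["cdr3h", "start"]), 14L)
  # class blocks: polyreactive rows first
  rec3 <- makeRecords(4, reactivity = c(0L, 5L, 0L, 6L))
  rec3 <- assignPolyreactivityLabels(rec3, "parsed")
  em3 <- encodeRepertoire(rec3)
  expect_identical(as.character(rowLabels(em3)),
                   c("polyreactive", "polyreactive",
                     "non_polyreactive", "non_polyreactive"))
})

test_that("encode/decode round-trips random repertoires exactly", {
  set.seed(42)
  for (rep in 1:5) {
    gen <- generateRepertoire(fixtureSpec(nPoly = 15, nNon = 15),
                              seed = rep)
    em <- encodeRepertoire(gen$records)
    dec <- decodeRepertoire(em)
    src <- gen$records[match(dec$id, gen$records$id), ]
    for (lp in LOOPS) expect_identical(dec[[lp]], src[[lp]])
    # buffer conservation: zeros per row = L - residue count
    v <- encodedValues(em)
    resid <- rowSums(vapply(LOOPS, function(lp) nchar(src[[lp]]),
                            numeric(nrow(src))))
    expect_identical(rowSums(v == 0), ncol(v) - resid)
  }
})

test_that("gene usage tabulates counts, differences and threshold flags", {
  rec <- makeRecords(8, reactivity = c(rep(5L, 4), rep(0L, 4)),
                     v_gene_h = c("VH1-69", "VH1-69", "VH3-23", "VH4-59",
                                  "VH3-23", "VH3-23", "VH3-7", "VH3-7"))
  rec <- assignPolyreactivityLabels(rec, "parsed")
  tab <- geneUsageTable(rec)
  expect_equal(tab$freq_polyreactive[tab$gene == "VH1-69"], 0.5)
  # per-class frequencies sum to 1
  expect_equal(sum(tab$freq_polyreactive), 1)
  expect_equal(sum(tab$freq_non_polyreactive), 1)
  expect_identical(sum(tab$count_polyreactive), 4L)
  # VH1-69 present only in polyreactive at 0.5 -> flagged in the other
  expect_identical(tab$below_threshold_in[tab$gene == "VH1-69"],
                   "non_polyreactive")
  # identical call lists -> all differences zero
  rec2 <- makeRecords(6, reactivity = c(5L, 5L, 5L, 0L, 0L, 0L),
                      v_gene_h = rep(c("VH1-2", "VH3-23", "VH4-34"), 2))
  rec2 <- assignPolyreactivityLabels(rec2, "parsed")
  expect_true(all(geneUsageTable(rec2)$freq_diff == 0))
  expect_error(geneUsageTable(makeRecords(3)), "AIRR")
})

test_that("AIRR gene calls merge by sequence id", {
  rec <- makeRecords(3)
  airr <- data.frame(sequence_id = c("r002", "r001", "r003"),
                     v_call = c("IGHV1-69*01", "IGHV3-23*01", "IGHV4-59*01"),
                     j_call = c("IGHJ4*02", "IGHJ6*02", "IGHJ4*02"))
  p <- tempfile(fileext = ".tsv")
  utils::write.table(airr, p, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- readAirrGeneCalls(rec, p, chain = "heavy")
  expect_identical(got$v_gene_h,
                   c("IGHV3-23*01", "IGHV1-69*01", "IGHV4-59*01"))
})

test_that("encoded matrices export to CSV with a JSON layout sidecar", {
  gen <- generateRepertoire(fixtureSpec(nPoly = 5, nNon = 5), seed = 3)
  em <- encodeRepertoire(gen$records)
  csv <- tempfile(fileext = ".csv")
  paths <- writeEncodedMatrix(em, csv)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(nrow(back), nrow(encodedValues(em)))
  side <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_identical(side$segment_names, LOOPS)
  expect_identical(as.integer(side$buffer_width), 3L)
})

test_that("FASTA single-loop lists load into the repertoire schema", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">a1", "ARDYW", ">a2", "CARDGY"), p)
  rec <- readLoopFasta(p, loop = "cdr3h")
  expect_identical(rec$cdr3h, c("ARDYW", "CARDGY"))
  expect_true(all(rec$cdr1l == ""))
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readLoopFasta(empty, "cdr3h"), "empty")
})
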