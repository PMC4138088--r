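test_that("parse_prosite_pattern reads the grammar", {
  p <- parse_prosite_pattern("C-x(2)-C.", "PS00190")
  expect_length(p$elements, 3L)
  expect_equal(vapply(p$elements, `[[`, "", "kind"),
               c("exact", "any", "exact"))
  expect_equal(p$elements[[2]]$min, 2L)
  expect_equal(p$elements[[2]]$max, 2L)
  expect_false(p$anchored_start)

  p2 <- parse_prosite_pattern("<A-[ST]>", "PS00001")
  expect_true(p2$anchored_start)
  expect_true(p2$anchored_end)
  expect_equal(p2$elements[[2]]$kind, "class")
  expect_equal(p2$elements[[2]]$residues, c("S", "T"))

  p3 <- parse_prosite_pattern("A-x(2,3)-{P}", "PS00002")
  expect_equal(p3$elements[[2]]$min, 2L)
  expect_equal(p3$elements[[2]]$max, 3L)
  expect_equal(p3$elements[[3]]$kind, "negated_class")
})

test_that("parse errors are located and non-pattern accessions rejected", {
  expect_error(parse_prosite_pattern("A-[ST", "PS00001"),
               "element 2.*unbalanced")
  expect_error(parse_prosite_pattern("A-x(3,2)", "PS00001"),
               "element 2.*max < min")
  expect_error(parse_prosite_pattern("A-J", "PS00001"),
               "element 2.*unknown residue")
  expect_error(parse_prosite_pattern("A-B", "PS51072"), "not a PROSITE pattern")
  expect_error(parse_prosite_pattern("A-B", "PF01602"), "not a PROSITE pattern")
})

test_that("render/parse round trip is grammar-equivalent", {
  for (text in c("C-x(2)-C.", "<A-[ST]>.", "A-x(2,3)-{P}.",
                 "[DE](2)-x-G-{PQ}(0,3)-A.")) {
    p1 <- parse_prosite_pattern(text, "PS00003")
    p2 <- parse_prosite_pattern(render_prosite_pattern(p1), "PS00003")
    expect_equal(p1, p2, info = text)
  }
})

test_that("A-x(2,3)-{P} accepts exactly its brute-force expansion", {
  # enumerate all strings of length <= 5 over {A,C,D,P} and compare
  p <- parse_prosite_pattern("<A-x(2,3)-{P}>", "PS00004")
  alphabet <- c("A", "C", "D", "P")
  for (len in 1:5) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    strings <- apply(grid, 1L, paste, collapse = "")
    accepted <- vapply(strings, function(s)
      nrow(scan_sequence(p, s)) > 0L, logical(1))
    # reference: length 4 or 5, starts with A, ends with non-P
    expected <- nchar(strings) %in% 4:5 &
      startsWith(strings, "A") & !endsWith(strings, "P")
    expect_equal(unname(accepted), unname(expected), info = paste("len", len))
  }
})

test_that("scan_sequence reports overlapping matches, one span per start", {
  p <- parse_prosite_pattern("A-x-A", "PS00005")
  hits <- scan_sequence(p, "ABACA", "s1")
  expect_equal(hits$start, c(1L, 3L))
  expect_equal(hits$end, c(3L, 5L))
  expect_equal(hits$sequence_id, c("s1", "s1"))

  anchored <- parse_prosite_pattern("<M>", "PS00006")
  expect_equal(scan_sequence(anchored, "M")$start, 1L)
  expect_equal(nrow(scan_sequence(anchored, "AM")), 0L)

  expect_equal(nrow(scan_sequence(p, "")), 0L)
  expect_error(scan_sequence(p, "AB1"), "invalid letter")
})

test_that("per start the span is leftmost-longest (greedy repeats)", {
  p <- parse_prosite_pattern("A(1,3)", "PS00007")
  hits <- scan_sequence(p, "AAA")
  expect_equal(hits$start, 1:3)
  expect_equal(hits$end, c(3L, 3L, 3L))           # greedy from each start
  # backtracking: greedy first element must yield to let the tail match
  p2 <- parse_prosite_pattern("A(1,2)-A-C", "PS00008")
  hits2 <- scan_sequence(p2, "AAC")
  expect_equal(hits2$start, 1L)
  expect_equal(hits2$end, 3L)
})

test_that("sequence X matches only the wildcard", {
  expect_equal(nrow(scan_sequence(parse_prosite_pattern("A", "PS00009"), "X")), 0L)
  expect_equal(nrow(scan_sequence(parse_prosite_pattern("[AC]", "PS00010"), "X")), 0L)
  expect_equal(nrow(scan_sequence(parse_prosite_pattern("{P}", "PS00011"), "X")), 0L)
  expect_equal(scan_sequence(parse_prosite_pattern("x", "PS00012"), "X")$start, 1L)
  # and scanning is case-insensitive
  expect_equal(scan_sequence(parse_prosite_pattern("A-C", "PS00013"), "ac")$start, 1L)
})

test_that("scanner agrees with the regex-translation oracle", {
  instances <- generate_pattern_instances(40, seed = 421)
  for (inst in instances) {
    p <- parse_prosite_pattern(inst$pattern_text, inst$accession)
    for (id in names(inst$sequences)) {
      got <- scan_sequence(p, inst$sequences[[id]], id)$start
      expect_equal(got, oracle_match_starts(p, inst$sequences[[id]]),
                   info = paste(inst$pattern_text, id))
    }
  }
})

test_that("unanchored match starts are monotone under sequence extension", {
  instances <- generate_pattern_instances(20, seed = 99)
  for (inst in instances) {
    p <- parse_prosite_pattern(inst$pattern_text, inst$accession)
    if (p$anchored_end) next
    s <- inst$sequences[[1]]
    before <- scan_sequence(p, s)$start
    after <- scan_sequence(p, paste0(s, "ACDE"))$start
    expect_true(all(before %in% after), info = inst$pattern_text)
  }
})

test_that("annotate_proteome builds a sparse accession map", {
  pats <- list(parse_prosite_pattern("C-x(2)-C", "PS00190"),
               parse_prosite_pattern("<M-A", "PS00020"))
  seqs <- c(p1 = "ACHHCA", p2 = "MADDD", p3 = "KKKK")
  annot <- annotate_proteome(pats, seqs)
  expect_equal(annot, list(p1 = "PS00190", p2 = "PS00020"))
  expect_false("p3" %in% names(annot))              # sparse, no empty sets
  expect_equal(annotate_proteome(pats, setNames(character(0), character(0))),
               list())
  expect_error(annotate_proteome(pats, c(a = "MA", a = "MA")),
               "duplicate FASTA id")
})

test_that("annotate_proteome reads FASTA files", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">p1 description", "ACHH", "CA", ">p2", "MADDD"), path)
  annot <- annotate_proteome(list(parse_prosite_pattern("C-x(2)-C", "PS00190")),
                             path)
  expect_equal(annot, list(p1 = "PS00190"))
})
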