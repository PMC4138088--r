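ab_evidence <- function() fixture_ab()$evidence

test_that("consensus support uses the inclusive >=10 rule", {
  ev <- ab_evidence()
  at1g77490 <- ev[ev$locus == "At1g77490", ]            # score 22.8
  expect_true(consensus_supported(at1g77490))
  at4g34450 <- ev[ev$locus == "At4g34450", ]            # score 0.4
  expect_false(consensus_supported(at4g34450))
  boundary <- list(locus = "x", dialect = "consensus", cp_score = 10.0)
  expect_true(consensus_supported(boundary))
  expect_false(consensus_supported(list(locus = "x", dialect = "consensus",
                                        cp_score = 9.999)))
  wrong <- list(locus = "x", dialect = "single_predictor", cp_score = 50)
  expect_error(consensus_supported(wrong), "consensus dialect only")
})

test_that("integrate_evidence maps records onto the 4-level lattice", {
  ev <- ab_evidence()
  # experimental support without a consensus score
  chc2 <- integrate_evidence(ev[ev$locus == "At3g08530", ])
  expect_equal(chc2$level, "experimental_only")
  expect_true(any(grepl("experimental", chc2$reasons)))
  # no support from any source
  gamma <- integrate_evidence(ev[ev$locus == "At4g34450", ])
  expect_equal(gamma$level, "unsupported")
  expect_length(gamma$reasons, 0L)
  # both prediction and experiment
  sapx <- integrate_evidence(ev[ev$locus == "At4g08390", ])
  expect_equal(sapx$level, "strong")
  # prediction only (high score, no experimental flag from either source)
  acc2 <- integrate_evidence(ev[ev$locus == "At1g36180", ])
  expect_equal(acc2$level, "consensus_only")
  # rice dialect: the single predictor call plays the prediction role
  rice <- integrate_evidence(list(locus = "L", dialect = "single_predictor",
                                  suba = "none", c2010 = "no",
                                  targetp_cp = TRUE))
  expect_equal(rice$level, "consensus_only")
  # all-zero synthetic record
  zero <- integrate_evidence(list(locus = "z", dialect = "consensus",
                                  cp_score = 0, suba = "none", c2010 = "no"))
  expect_equal(zero$level, "unsupported")
  expect_length(zero$reasons, 0L)
  expect_error(integrate_evidence(list(locus = "", dialect = "consensus",
                                       cp_score = 0)), "locus")
})

test_that("every record maps to exactly one level (exhaustive grid)", {
  grid <- expand.grid(cp = c(0, 5, 9.99, 10, 25),
                      suba = c("none", "yes"),
                      c2010 = c("no", "yes"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    v <- integrate_evidence(list(locus = "g", dialect = "consensus",
                                 cp_score = grid$cp[i], suba = grid$suba[i],
                                 c2010 = grid$c2010[i]))
    expect_true(v$level %in% c("unsupported", "consensus_only",
                               "experimental_only", "strong"))
    predicted <- grid$cp[i] >= 10
    experimental <- grid$suba[i] == "yes" || grid$c2010[i] == "yes"
    expected <- if (predicted && experimental) "strong"
                else if (experimental) "experimental_only"
                else if (predicted) "consensus_only"
                else "unsupported"
    expect_equal(v$level, expected)
  }
})

test_that("verdict level is monotone under single-field upgrades", {
  rank <- c(unsupported = 0, consensus_only = 1, experimental_only = 2,
            strong = 3)
  level_of <- function(cp, suba, c2010) {
    integrate_evidence(list(locus = "m", dialect = "consensus", cp_score = cp,
                            suba = suba, c2010 = c2010))$level
  }
  cps <- c(0, 9, 10, 20)
  subas <- c("none", "yes")
  cs <- c("no", "yes")
  for (cp in cps) for (s in subas) for (c2 in cs) {
    base <- rank[level_of(cp, s, c2)]
    for (cp2 in cps[cps > cp]) {
      expect_gte(rank[level_of(cp2, s, c2)], base)
    }
    if (s == "none") expect_gte(rank[level_of(cp, "yes", c2)], base)
    if (c2 == "no") expect_gte(rank[level_of(cp, s, "yes")], base)
  }
})

test_that("join_evidence covers every hit locus and flags leftovers", {
  fx <- fixture_ab()
  res <- suppressWarnings(screen_proteome(fx$proteome, build_catalog(fx$queries)))
  verdicts <- join_evidence(res, fx$evidence)
  expect_length(verdicts, 29L)
  expect_setequal(names(verdicts),
                  c(res$single_subunit_loci, res$multi_subunit_loci))

  # no evidence at all -> everything unsupported with reason "no record"
  none <- join_evidence(res, fx$evidence[0, ])
  expect_true(all(vapply(none, `[[`, "", "level") == "unsupported"))
  expect_equal(none[["At3g08530"]]$reasons, "no record")

  # evidence for non-hit loci is ignored and reported
  extra <- fx$evidence
  extra <- rbind(extra, transform(extra[1, ], locus = "At9g99990"))
  expect_message(v2 <- join_evidence(res, extra), "ignored")
  expect_equal(attr(v2, "ignored"), "At9g99990")

  dup <- rbind(fx$evidence, fx$evidence[1, ])
  expect_error(join_evidence(res, dup), "duplicate evidence")
})

test_that("evidence tables are validated at the file boundary", {
  expect_error(load_evidence_table(write_evidence_tsv(c(
    evidence_row("L1"), evidence_row("L1")))), "duplicate")
  expect_error(load_evidence_table(write_evidence_tsv(
    "L1\tbayes\t1\t0\t0\tnone\t\tno\tfalse")), "dialect")
  expect_error(load_evidence_table(write_evidence_tsv(
    "L1\tconsensus\t\t0\t0\tnone\t\tno\tfalse")), "require numeric")
  ok <- load_evidence_table(write_evidence_tsv(
    evidence_row("L1", cp = 12.5, suba = "yes", c2010 = "yes")))
  expect_equal(ok$cp_score, 12.5)
})
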