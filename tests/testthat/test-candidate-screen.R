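test_that("screening matches by superset containment", {
  fx <- fixture_ab()
  catalog <- build_catalog(fx$queries)
  res <- suppressWarnings(screen_proteome(fx$proteome, catalog))

  # a single-domain candidate hits the light chain only
  light <- res$hits[res$hits$locus == "At2g40060", ]
  expect_equal(light$identity, "CCV/triskelion/light chain")

  # the two-domain coatomer-gamma-like locus hits six identities
  multi <- res$hits[res$hits$locus == "At4g34450", ]
  expect_setequal(multi$identity,
                  c("CCV/AP1/β1", "CCV/AP2/β2", "CCV/AP3/δ",
                    "CCV/AP3/β3", "CCV/AP4/ε", "COPI/F-COPI/γ"))
  expect_true(all(multi$multi))

  # extra domains do not block a hit (candidate is a superset)
  chld <- res$hits[res$hits$locus == "At1g08520", ]
  expect_equal(chld$identity, "COPI/F-COPI/ζ")
})

test_that("empty domain sets and empty proteomes yield no hits", {
  catalog <- tiny_catalog()
  prot <- load_proteome_table(write_proteome_tsv(c(
    "L1\tempty\t\trole",
    "L2\tlight\tPF01086\trole"
  )))
  res <- screen_proteome(prot, catalog)
  expect_false("L1" %in% res$hits$locus)
  expect_equal(res$hits$locus, "L2")

  empty <- load_proteome_table(write_proteome_tsv(character(0)))
  res0 <- screen_proteome(empty, catalog)
  expect_equal(nrow(res0$hits), 0L)
  expect_equal(count_candidates(res0, c("CCV", "triskelion", "light chain")), 0L)

  expect_error(screen_proteome(prot, build_catalog(
    load_query_table(write_queries_tsv(character(0))))), "empty")
})

test_that("unknown proteome accessions are ignored with one warning", {
  catalog <- tiny_catalog()
  prot <- load_proteome_table(write_proteome_tsv(
    "L1\tx\tPF01086;PF99999\trole"))
  expect_warning(res <- screen_proteome(prot, catalog), "not in any signature")
  expect_equal(res$unknown_accessions, "PF99999")
  expect_equal(res$hits$locus, "L1")   # the known domain still matches
  expect_silent(screen_proteome(prot, catalog, warn_unknown = FALSE))
})

test_that("witness is the smallest matching signature, ties by source", {
  q <- load_query_table(write_queries_tsv(c(
    "BIG\tyeast\tCCV\tAP1\tgamma\tPF01602;PF08752",
    "SMALL\tyeast\tCCV\tAP1\tgamma\tPF01602"
  )))
  res <- screen_proteome(
    load_proteome_table(write_proteome_tsv("L1\tx\tPF01602;PF08752\tr")),
    build_catalog(q))
  expect_equal(nrow(res$hits), 1L)           # one row per (locus, identity)
  expect_equal(res$hits$witness_source, "SMALL")
})

test_that("count_candidates respects the multi-subunit exclusion", {
  res <- run_fixture_screen()$result
  expect_equal(count_candidates(res, c("COPI", "B-COPI", "beta-prime"),
                                exclude_multi = TRUE), 8L)
  expect_equal(count_candidates(res, c("COPI", "F-COPI", "gamma"),
                                exclude_multi = TRUE), 0L)
  expect_equal(count_candidates(res, c("COPI", "F-COPI", "gamma"),
                                exclude_multi = FALSE), 1L)
  expect_warning(n <- count_candidates(res, "CCV/AP9/nope"), "not in catalog")
  expect_equal(n, 0L)
})

test_that("compare_signatures partitions reference and candidate domains", {
  cmp <- compare_signatures(c("PS50234", "PF13519", "PF01078"), "PF01217")
  expect_equal(cmp$missing, "PF01217")
  expect_equal(cmp$extra, c("PF01078", "PF13519", "PS50234"))
  expect_equal(compare_signatures("PF01217", "PF01217"),
               list(missing = character(0), extra = character(0)))
  expect_equal(compare_signatures(character(0), c("PF01217", "PF01602")),
               list(missing = c("PF01217", "PF01602"), extra = character(0)))
})

test_that("screen equals the brute-force subset oracle on random cases", {
  set.seed(7001)
  for (rep in 1:20) {
    case <- random_screen_case(n_loci = sample(5:50, 1))
    res <- suppressWarnings(screen_proteome(case$proteome, case$catalog))
    brute <- oracle_screen(case$proteome, case$catalog)
    got <- split(res$hits$identity, res$hits$locus)
    expect_equal(sort_named(got), sort_named(brute))
  }
})

test_that("hits are monotone in domains and signatures", {
  set.seed(7002)
  case <- random_screen_case()
  res1 <- suppressWarnings(screen_proteome(case$proteome, case$catalog))
  # adding a domain to every locus never removes hits
  prot2 <- case$proteome
  extra <- case$catalog$signatures$required[[1]][1]
  prot2$domains <- lapply(prot2$domains, function(d) sort(union(d, extra)))
  res2 <- suppressWarnings(screen_proteome(prot2, case$catalog))
  before <- paste(res1$hits$locus, res1$hits$identity)
  after <- paste(res2$hits$locus, res2$hits$identity)
  expect_true(all(before %in% after))
})

test_that("single/multi partition invariant holds on random inputs", {
  set.seed(7003)
  for (rep in 1:10) {
    case <- random_screen_case(n_loci = sample(5:40, 1))
    res <- suppressWarnings(screen_proteome(case$proteome, case$catalog))
    all_loci <- unique(res$hits$locus)
    expect_setequal(c(res$multi_subunit_loci, res$single_subunit_loci),
                    all_loci)
    expect_length(intersect(res$multi_subunit_loci,
                            res$single_subunit_loci), 0L)
    for (locus in all_loci) {
      k <- length(unique(res$hits$identity[res$hits$locus == locus]))
      expect_equal(locus %in% res$multi_subunit_loci, k >= 2L, info = locus)
    }
  }
})
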