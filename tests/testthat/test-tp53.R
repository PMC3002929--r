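test_that("the mutation grammar parses the clinical dialect", {
  cases <- list(
    list("R213X", "nonsense", 213L),
    list("239 insT", "frameshift_ins", 239L),
    list("IVS5-2 A > C (splice)", "splice", NA_integer_),
    list("224 splice G > A", "splice", 224L),
    list("218delGTG", "inframe_del", 218L),
    list("G266E", "missense", 266L),
    list("wild type", "wild_type", NA_integer_),
    list("NA", "not_sequenced", NA_integer_),
    list("del 255", "inframe_del", 255L),
    list("del 155-156", "inframe_del", 155L),
    list("155_156del", "inframe_del", 155L),
    list("239_240delCA", "frameshift_del", 239L),
    list("255_256delTCA", "inframe_del", 255L),
    list("283insGC", "frameshift_ins", 283L),
    list("110 delC", "frameshift_del", 110L),
    list("V216 M", "missense", 216L)
  )
  for (cs in cases) {
    rec <- parse_mutation(cs[[1]])
    expect_equal(rec$kind, cs[[2]], info = cs[[1]])
    expect_equal(rec$codon, cs[[3]], info = cs[[1]])
  }
  # comma-separated lists yield one record per mutation
  multi <- parse_mutation("110 delC, Q100X")
  expect_equal(multi$kind, c("frameshift_del", "nonsense"))
  # unparseable tokens are errors carrying the token
  expect_error(parse_mutation("gibberish!!"), "gibberish")
  expect_error(parse_mutation("   "), "empty")
})

test_that("parse -> format -> parse is stable", {
  raws <- c("R213X", "G266E", "wild type", "NA", "239 insT", "del 155-156",
            "IVS5-2 A > C (splice)", "218delGTG")
  for (raw in raws) {
    r1 <- parse_mutation(raw)
    r2 <- parse_mutation(format_mutation(r1))
    expect_equal(r1$kind, r2$kind, info = raw)
    expect_equal(r1$codon, r2$codon, info = raw)
  }
})

test_that("classification separates complex, hotspot and plain missense", {
  rec <- classify_mutations(parse_mutation("R248W"))
  expect_false(rec$is_complex)
  expect_true(rec$is_hotspot)
  rec2 <- classify_mutations(parse_mutation("K305X"))
  expect_true(rec2$is_complex)
  expect_false(rec2$is_hotspot)
  rec3 <- classify_mutations(parse_mutation("T55I"))
  expect_false(rec3$is_complex)
  expect_false(rec3$is_hotspot)
  # hotspot needs the matching reference residue, not just the codon
  rec4 <- classify_mutations(parse_mutation("A248W"))
  expect_false(rec4$is_hotspot)
  wt <- classify_mutations(parse_mutation("wild type"))
  expect_false(any(wt$is_complex, wt$is_missense, wt$is_hotspot))
  expect_equal(nrow(tp53_hotspots()), 29)
})

test_that("every fixture row parses and reproduces its printed complex flag", {
  rec <- read_mutation_table(tp53_fixture_path())
  expect_equal(length(unique(rec$sample_id[rec$group == "BRCA1"])), 27)
  expect_equal(length(unique(rec$sample_id)), 27 + 17 + 21 + 31)
  flagged <- rec[!is.na(rec$complex_printed) & rec$complex_printed != "NA", ]
  tumor_complex <- tapply(flagged$is_complex, flagged$sample_id, any)
  tumor_printed <- tapply(as.integer(flagged$complex_printed) == 1L,
                          flagged$sample_id, any)
  expect_equal(tumor_complex, tumor_printed)
})

test_that("tumor-level summaries count tumors, not mutations", {
  tab <- data.frame(
    sample_id = c("t1", "t1", "t1", "t2", "t3"),
    group = "G",
    mutation = c("R213X", "110 delC", "K305X", "wild type", "NA"),
    predicted_deleterious = c(TRUE, TRUE, TRUE, NA, NA),
    abundance = NA_real_, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- group_summary(read_mutation_table(path), "G")
  expect_equal(s$n_sequenced, 2) # t3 unsequenced
  expect_equal(s$n_mutated, 1)
  expect_equal(s$n_complex, 1)  # three complex mutations, one tumor
  expect_error(group_summary(read_mutation_table(path), "nope"),
               "unknown group")
})

test_that("the abundance filter removes low-abundance mutations", {
  tab <- data.frame(
    sample_id = c("t1", "t2"), group = "G",
    mutation = c("R175H", "R175H"),
    predicted_deleterious = TRUE,
    abundance = c(0.1, 0.6), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- group_summary(read_mutation_table(path), "G")
  expect_equal(s$n_mutated, 1)
  expect_equal(s$n_hotspot, 1)
})

test_that("the exact test matches full enumeration and fisher.test", {
  # independent oracle: enumerate all tables with the observed margins
  enum_p <- function(m) {
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    if (min(r1, r2, c1, sum(m[, 2])) == 0) return(1)
    ks <- max(0, c1 - r2):min(r1, c1)
    pr <- vapply(ks, function(k)
      choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1), numeric(1))
    obs <- pr[ks == m[1, 1]]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  set.seed(71)
  for (i in 1:60) {
    repeat {
      m <- matrix(rpois(4, 3), 2)
      if (sum(m) >= 1 && sum(m) <= 30) break
    }
    p <- fisher_exact_two_tailed(m)
    expect_lt(abs(p - enum_p(m)), 1e-12)
    if (min(rowSums(m), colSums(m)) > 0)
      expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-7)
    # invariances: transpose, and swapping both rows and columns
    expect_equal(p, fisher_exact_two_tailed(t(m)), tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_tailed(m[2:1, 2:1]), tolerance = 1e-12)
  }
  expect_equal(fisher_exact_two_tailed(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_two_tailed(matrix(c(0, 0, 3, 4), 2)), 1)
})

test_that("group comparisons build the published contingency tables", {
  rec <- read_mutation_table(tp53_fixture_path())
  blbc <- group_summary(rec, "BLBC")
  lumh <- group_summary(rec, "luminal-H")
  cmp <- compare_groups(blbc, lumh, "complex")
  expect_equal(unname(cmp$table), matrix(c(12, 9, 2, 29), 2, byrow = TRUE))
  expect_equal(signif(cmp$p, 1), 8e-5)
  self <- compare_groups(blbc, blbc, "mutated")
  expect_equal(self$p, 1)
  brca <- group_summary(rec, "BRCA1")
  lumj <- group_summary(rec, "luminal-J")
  hs <- compare_groups(brca, lumj, "hotspot")
  expect_gt(hs$p, 0.01) # hotspot enrichment is not significant
})
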