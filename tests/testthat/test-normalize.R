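test_that("stem_and_clean lowercases, drops stopwords, singularizes, stems", {
  expect_identical(stem_and_clean("left extremities"),
                   c("left", porter_stem("extremity")))
  expect_identical(stem_and_clean("the heart"), "heart")
  expect_identical(stem_and_clean(""), character(0))
  expect_identical(stem_and_clean("feet"), "foot")
  expect_identical(stem_and_clean("the pancreases"),
                   stem_and_clean("pancreas"))
})

test_that("strip_positional splits modifiers and keeps protected names", {
  sp <- strip_positional(stem_and_clean("legs bilaterally"),
                         res$positional, ont)
  expect_identical(sp$positionals, "bilateral")
  expect_identical(sp$core, "leg")

  sp2 <- strip_positional(stem_and_clean("left extremities"),
                          res$positional, ont)
  expect_identical(sp2$positionals, "left")
  expect_identical(sp2$core, porter_stem("extremity"))

  sp3 <- strip_positional(stem_and_clean("heart"), res$positional, ont)
  expect_identical(sp3$positionals, character(0))
  expect_identical(sp3$core, "heart")

  # positional words inside a protected alias span survive
  sp4 <- strip_positional(stem_and_clean("right lower extremity"),
                          res$positional, ont)
  expect_identical(sp4$positionals, "right")
  expect_identical(sp4$core, stem_and_clean("lower extremity"))
})

test_that("stripping never alters a sequence that equals an ontology alias", {
  for (node in ont$nodes) {
    for (term in c(node$formal_name, node$aliases)) {
      toks <- stem_and_clean(term)
      sp <- strip_positional(toks, res$positional, ont)
      expect_identical(sp$core, toks)
      expect_length(sp$positionals, 0)
    }
  }
})

test_that("expand_abbreviation consults the dictionary", {
  ex <- expand_abbreviation(stem_and_clean("heent"), res$abbrev)
  expect_length(ex, 5)
  expect_identical(vapply(ex, paste, character(1), collapse = " "),
                   vapply(c("head", "eye", "ear", "nose", "throat"),
                          function(x) paste(stem_and_clean(x),
                                            collapse = " "),
                          character(1), USE.NAMES = FALSE))
  expect_identical(attr(ex, "source"), "dictionary")

  ex2 <- expand_abbreviation(stem_and_clean("ext"), res$abbrev)
  expect_length(ex2, 1)
  expect_identical(ex2[[1]], stem_and_clean("extremity"))

  expect_length(expand_abbreviation(stem_and_clean("qzx"), res$abbrev), 0)
})

test_that("coreference chains beat the dictionary and match by initials", {
  chains <- data.frame(
    chain_id = c("c9", "c9", "c9"),
    doc_id = c("d1", "d1", "d1"),
    member_text = c("LE", "left elbow", "LE"),
    stringsAsFactors = FALSE)
  # in this document LE corefers with "left elbow", overriding the global
  # dictionary entry (lower extremity)
  ex <- expand_abbreviation(stem_and_clean("le"), res$abbrev, chains,
                            doc_id = "d1", chain_id = "c9")
  expect_identical(attr(ex, "source"), "coreference")
  expect_identical(ex[[1]], stem_and_clean("left elbow"))
  # without the chain, the dictionary answers
  ex2 <- expand_abbreviation(stem_and_clean("le"), res$abbrev, chains,
                             doc_id = "d1", chain_id = "")
  expect_identical(attr(ex2, "source"), "dictionary")
  # prefix-style local abbreviation
  chains2 <- data.frame(chain_id = "c1", doc_id = "d2",
                        member_text = "extremity",
                        stringsAsFactors = FALSE)
  ex3 <- expand_abbreviation(stem_and_clean("ext"), list(), chains2,
                             doc_id = "d2", chain_id = "c1")
  expect_identical(ex3[[1]], stem_and_clean("extremity"))
})

test_that("normalize_mention composes the stages and flags provenance", {
  nm <- normalize_mention(list(surface = "legs bilaterally"), res, ont)
  expect_identical(nm$positionals, "bilateral")
  expect_identical(nm$core_tokens, "leg")
  expect_identical(nm$provenance, "plain")
  expect_length(nm$expansions, 0)

  nm2 <- normalize_mention(list(surface = "EXT"), res, ont)
  expect_identical(nm2$provenance, "dictionary")
  expect_identical(nm2$expansions[[1]], stem_and_clean("extremity"))

  nm3 <- normalize_mention(list(surface = "heart"), res, ont)
  expect_identical(nm3$core_tokens, "heart")
  expect_length(nm3$positionals, 0)
  expect_length(nm3$expansions, 0)

  expect_error(normalize_mention(list(surface = ""), res, ont),
               "invalid mention")
})

test_that("normalization is idempotent on its rendered output", {
  surfaces <- c("legs bilaterally", "left extremities", "the heart",
                vapply(ont$nodes, `[[`, "", "formal_name"))
  for (s in surfaces) {
    first <- normalize_mention(list(surface = s), res, ont)
    rendered <- paste(c(first$positionals, first$core_tokens),
                      collapse = " ")
    second <- normalize_mention(list(surface = rendered), res, ont)
    expect_identical(second$core_tokens, first$core_tokens, info = s)
    expect_identical(second$positionals, first$positionals, info = s)
  }
})

test_that("naive plurals of every formal name resolve to the same node", {
  for (node in ont$nodes) {
    words <- strsplit(node$formal_name, " ", fixed = TRUE)[[1]]
    words[length(words)] <- naive_plural(words[length(words)])
    plural <- paste(words, collapse = " ")
    got <- resolve_term(ont, stem_and_clean(plural))
    expect_identical(got$id, node$id, info = plural)
  }
})

test_that("reattach_positional prefixes canonical modifiers in order", {
  expect_identical(reattach_positional("bilateral", "lower extremity"),
                   "bilateral lower extremity")
  expect_identical(reattach_positional("left", "extremity"),
                   "left extremity")
  expect_identical(reattach_positional(character(0), "heart"), "heart")
  expect_identical(reattach_positional(c("left", "upper"), "extremity"),
                   "left upper extremity")
})

test_that("strip then reattach reproduces the positional-prefixed name", {
  for (s in c("left kidney", "bilateral lung", "right colon")) {
    toks <- stem_and_clean(s)
    sp <- strip_positional(toks, res$positional, ont)
    node <- resolve_term(ont, sp$core)
    expect_false(is.null(node))
    label <- reattach_positional(sp$positionals, node$formal_name)
    modifier <- strsplit(s, " ", fixed = TRUE)[[1]][1]
    expect_identical(label, paste(modifier, node$formal_name))
  }
})
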