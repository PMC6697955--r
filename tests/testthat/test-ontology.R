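test_that("packaged ontology has the nine top-level regions and validates", {
  expect_s3_class(ont, "thbp_ontology")
  roots <- sort(vapply(ont$roots, function(id) ont$nodes[[id]]$formal_name,
                       character(1), USE.NAMES = FALSE))
  expect_identical(roots, sort(c("head", "neck", "chest", "abdomen",
                                 "pelvis", "back", "hip", "extremity",
                                 "trunk")))
  report <- validate_ontology(ont)
  expect_length(report$problems, 0)
  expect_identical(report$root_count, 9L)
})

test_that("a one-node file loads as a single root at depth 0", {
  path <- write_ontology_json(list(
    list(id = "heart", formal_name = "heart", aliases = list(),
         parent = NULL)))
  o <- load_ontology(path)
  expect_length(o$roots, 1)
  expect_identical(o$nodes[["heart"]]$depth, 0L)
})

test_that("self-parenting and malformed records are rejected", {
  self <- write_ontology_json(list(
    list(id = "x", formal_name = "x part", aliases = list(), parent = "x")))
  expect_error(load_ontology(self), "validation")
  bad <- write_ontology_json(list(list(id = "y", aliases = list())))
  expect_error(load_ontology(bad), "format error")
  empty_alias <- write_ontology_json(list(
    list(id = "z", formal_name = "z part", aliases = list(""),
         parent = NULL)))
  expect_error(load_ontology(empty_alias), "empty string")
})

test_that("validate_ontology reports collisions and orphans", {
  collide <- write_ontology_json(list(
    list(id = "a", formal_name = "alpha part", aliases = list("le"),
         parent = NULL),
    list(id = "b", formal_name = "beta part", aliases = list("le"),
         parent = NULL)))
  o <- load_ontology(collide, validate = FALSE)
  rep <- validate_ontology(o)
  expect_true(any(grepl("alias collision", rep$problems) &
                  grepl("a, b", rep$problems)))

  orphan <- write_ontology_json(list(
    list(id = "a", formal_name = "alpha part", aliases = list(),
         parent = NULL),
    list(id = "b", formal_name = "beta part", aliases = list(),
         parent = "ghost")))
  o2 <- load_ontology(orphan, validate = FALSE)
  rep2 <- validate_ontology(o2)
  expect_true(any(grepl("unreachable", rep2$problems)))
})

test_that("load -> write -> load round trips field-by-field", {
  path <- tempfile(fileext = ".json")
  write_ontology(ont, path)
  again <- load_ontology(path)
  expect_identical(again$nodes, ont$nodes)
  expect_identical(again$alias_index, ont$alias_index)
  expect_identical(again$roots, ont$roots)
})

test_that("resolve_term honours aliases, abbreviations, and misses", {
  expect_identical(resolve_term(ont, stem_and_clean("abd"))$id, "abdomen")
  expect_identical(resolve_term(ont, stem_and_clean("eye"))$id, "eye")
  expect_identical(resolve_term(ont, stem_and_clean("peritoneal cavity"))$id,
                   "abdomen")
  expect_null(resolve_term(ont, stem_and_clean("myocarditis")))
  expect_null(resolve_term(ont, character(0)))
  # every alias of every node resolves back to that node
  for (node in ont$nodes) {
    for (term in c(node$formal_name, node$aliases)) {
      expect_identical(resolve_term(ont, stem_and_clean(term))$id, node$id)
    }
  }
})

test_that("find_matches_in_text accumulates offsets per part", {
  tokens <- build_stream(list(heart = c(3L, 10L)))
  occs <- find_matches_in_text(ont, tokens)
  expect_length(occs, 1)
  expect_identical(occs[[1]]$part_id, "heart")
  expect_identical(occs[[1]]$offsets, c(3L, 10L))
  expect_identical(occs[[1]]$count, 2L)
  # aliases of the same part pool into one occurrence list
  toks2 <- c("cardiac", "quartz", "heart")
  occs2 <- find_matches_in_text(ont, toks2)
  expect_length(occs2, 1)
  expect_identical(occs2[[1]]$count, 2L)
  expect_length(find_matches_in_text(ont, test_fillers), 0)
})

test_that("repeated aliases are counted exactly k times", {
  for (k in 1:10) {
    tokens <- rep("quartz", 3 * k + 2)
    tokens[seq_len(k) * 3] <- "colon"
    occs <- find_matches_in_text(ont, tokens)
    expect_length(occs, 1)
    expect_identical(occs[[1]]$count, k)
  }
})

test_that("longest match wins for every nested alias pair", {
  keys <- names(ont$alias_index)
  split_keys <- strsplit(keys, " ", fixed = TRUE)
  checked <- 0L
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      a <- split_keys[[i]]; b <- split_keys[[j]]
      if (length(b) > length(a) &&
          identical(a, b[seq_along(a)])) {
        # a is a proper token-prefix of b: text holding only b must yield
        # only b's part
        occs <- find_matches_in_text(ont, c("quartz", b, "quartz"))
        expect_identical(vapply(occs, `[[`, "", "part_id"),
                         unname(ont$alias_index[keys[j]]))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0)  # e.g. "thyroid" under "thyroid gland"
  # nesting at a non-initial token: "lower extremity" must not also
  # register the "extremity" inside it
  occs <- find_matches_in_text(ont, stem_and_clean("lower extremity"))
  expect_identical(vapply(occs, `[[`, "", "part_id"), "lower_extremity")
})
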